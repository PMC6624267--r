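# Helical lattice construction and fitting. Filaments are built about the +z
# axis with subunit 0 at the -z end; growth (the "b"-face end) is toward +z.
# Subunit j carries the screw applied j times: rotation j*twist about z and
# translation j*rise along z. A negative twist is a left-handed helix.

.chain_pool <- c(LETTERS, letters, as.character(0:9))

#' Helical lattice parameters
#' @param rise axial translation per subunit, Angstrom (0 < rise < 100).
#' @param twist rotation per subunit, degrees, signed (negative =
#'   left-handed about the growth axis); |twist| <= 180.
#' @return object of class `helical_parameters`.
#' @export
helical_parameters <- function(rise, twist) {
  stopifnot(is.finite(rise), is.finite(twist))
  if (rise <= 0 || rise >= 100) stop("rise must be in (0, 100) Angstrom")
  if (abs(twist) > 180) stop("twist must be in [-180, 180] degrees")
  structure(list(rise = rise, twist = twist), class = "helical_parameters")
}

#' @export
print.helical_parameters <- function(x, ...) {
  hand <- if (x$twist < 0) "left-handed" else "right-handed"
  cat(sprintf("<helical parameters> rise %.3f A, twist %.2f deg (%s)\n",
              x$rise, abs(x$twist), hand))
  invisible(x)
}

#' Build a filament from a protomer and helical parameters
#'
#' Generates `n_subunits` symmetry copies of a protomer about the +z axis:
#' subunit j (j = 0..n-1) is the protomer rotated by `j * twist` and
#' translated by `j * rise` along z. The caller pre-aligns the protomer to
#' the lattice frame (axis +z through the origin). Subunit 0 sits at the -z
#' ("a"-face exposed) end; the +z end is the growing "b"-face end.
#'
#' @param protomer a model data.frame (see [new_model()]).
#' @param params a [helical_parameters()] object (or list with rise/twist).
#' @param n_subunits integer >= 1.
#' @return object of class `filament`: list with `protomer`, `params`,
#'   `n_subunits`, and `xyz` (list of per-subunit coordinate matrices,
#'   index j stored at position j+1).
#' @export
build_filament <- function(protomer, params, n_subunits) {
  protomer <- new_model(protomer)
  if (!inherits(params, "helical_parameters"))
    params <- helical_parameters(params$rise, params$twist)
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 1L) stop("n_subunits must be >= 1")
  x0 <- coords(protomer)
  xyz <- vector("list", n_subunits)
  for (j in seq_len(n_subunits) - 1L) {
    tf <- screw_transform(j * params$twist, j * params$rise)
    xyz[[j + 1L]] <- apply_transform(x0, tf)
  }
  structure(list(protomer = protomer, params = params,
                 n_subunits = n_subunits, xyz = xyz),
            class = "filament")
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf("<filament> %d subunits x %d atoms; rise %.3f A, twist %.2f deg\n",
              x$n_subunits, nrow(x$protomer), x$params$rise, x$params$twist))
  invisible(x)
}

#' Flatten a filament to a single multi-chain model
#'
#' Each subunit becomes one chain (A, B, C, ... from a 62-character pool) and
#' carries a `subunit` column with its 0-based index.
#'
#' @param filament a [build_filament()] object.
#' @return a model data.frame with an extra `subunit` column.
#' @export
filament_model <- function(filament) {
  stopifnot(inherits(filament, "filament"))
  if (filament$n_subunits > length(.chain_pool))
    stop("more subunits than available chain identifiers")
  parts <- lapply(seq_len(filament$n_subunits), function(i) {
    m <- filament$protomer
    coords(m) <- filament$xyz[[i]]
    m$chain <- .chain_pool[i]
    m$subunit <- i - 1L
    m
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Fit helical parameters from a filament
#'
#' Superposes each consecutive subunit pair (j onto j+1), screw-decomposes
#' each transform, and returns the mean rise and mean signed twist with the
#' per-pair spread as a regularity diagnostic.
#'
#' @param x a [build_filament()] object, or a model data.frame carrying a
#'   `subunit` column, or a multi-chain model whose chains are taken as
#'   subunits in chain order.
#' @return object of class `helical_fit`: list with `rise`, `twist`
#'   (means), `rise_sd`, `twist_sd`, `per_pair` data.frame, `n_subunits`.
#' @export
fit_helical_params <- function(x) {
  if (inherits(x, "filament")) {
    mats <- x$xyz
  } else if (is.data.frame(x)) {
    key <- if (!is.null(x$subunit)) x$subunit else x$chain
    ids <- unique(key)
    mats <- lapply(ids, function(k) coords(x[key == k, , drop = FALSE]))
    sizes <- vapply(mats, nrow, integer(1L))
    if (length(unique(sizes)) != 1L)
      stop("subunits have inconsistent atom counts; cannot fit helical parameters")
  } else stop("x must be a filament or a subunit-labelled model")
  ns <- length(mats)
  if (ns < 2L) stop("need at least 2 subunits to fit helical parameters")
  pairs <- lapply(seq_len(ns - 1L), function(j) {
    fit <- kabsch_superpose(mats[[j]], mats[[j + 1L]])
    sp <- screw_transform_params(fit$transform)
    c(rise = sp$rise, twist = sp$twist, rmsd = fit$rmsd)
  })
  pp <- as.data.frame(do.call(rbind, pairs))
  pp$pair <- paste(seq_len(ns - 1L) - 1L, seq_len(ns - 1L), sep = "-")
  structure(list(rise = mean(pp$rise), twist = mean(pp$twist),
                 rise_sd = stats::sd(pp$rise), twist_sd = stats::sd(pp$twist),
                 per_pair = pp[, c("pair", "rise", "twist", "rmsd")],
                 n_subunits = ns),
            class = "helical_fit")
}

#' @export
print.helical_fit <- function(x, ...) {
  hand <- if (x$twist < 0) "left-handed" else "right-handed"
  cat(sprintf("<helical fit> %d subunits\n  rise  %.4f A (sd %.2g)\n  twist %.4f deg (%s; sd %.2g)\n",
              x$n_subunits, x$rise, x$rise_sd, abs(x$twist), hand, x$twist_sd))
  invisible(x)
}

#' Interface type of a subunit pair by start number
#'
#' Death-domain filament interfaces are typed by the start number of the
#' helical symmetry that relates the two subunits: |i - j| = 3 is Type I
#' (3-start), 4 is Type II (4-start), 1 is Type III (1-start). Other index
#' separations are not canonical interfaces and return `NA`.
#'
#' @param i,j subunit indices (i != j).
#' @return `"I"`, `"II"`, `"III"`, or `NA_character_`.
#' @export
classify_start <- function(i, j) {
  if (any(i == j)) stop("subunit indices must differ")
  d <- abs(i - j)
  out <- rep(NA_character_, length(d))
  out[d == 3] <- "I"
  out[d == 4] <- "II"
  out[d == 1] <- "III"
  out
}

#' Start number of an interface type
#' @param type `"I"`, `"II"` or `"III"`.
#' @return 3, 4 or 1.
#' @export
interface_start <- function(type) {
  unname(c(I = 3L, II = 4L, III = 1L)[match.arg(type, c("I", "II", "III"))])
}

#' Enumerate contacting neighbors of every subunit
#'
#' Computes, for each subunit of a filament, the set of other subunits with
#' any heavy-atom pair within `cutoff`, annotated with the interface type of
#' the index separation and the minimum distance. An interior subunit of a
#' lattice realizing all three canonical interfaces contacts exactly the six
#' neighbors at index offsets -4, -3, -1, +1, +3, +4.
#'
#' @param filament a [build_filament()] object.
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.5, a
#'   typical van der Waals contact distance; reported in output).
#' @param max_offset largest |i - j| examined (default 8; contacts beyond
#'   this are geometrically impossible for realistic rises).
#' @param method `"grid"` or `"brute"` minimum-distance engine.
#' @return data.frame with `subunit`, `neighbor`, `offset`, `interface_type`,
#'   `min_distance`, plus attribute `cutoff`.
#' @export
enumerate_contacting_neighbors <- function(filament, cutoff = 4.5,
                                           max_offset = 8L,
                                           method = c("grid", "brute")) {
  stopifnot(inherits(filament, "filament"))
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  heavy <- !filament$protomer$hydrogen
  n <- filament$n_subunits
  rows <- list()
  for (i in seq_len(n) - 1L) {
    for (j in seq_len(n) - 1L) {
      if (j <= i || j - i > max_offset) next
      d <- .min_pair_distance(filament$xyz[[i + 1L]][heavy, , drop = FALSE],
                              filament$xyz[[j + 1L]][heavy, , drop = FALSE],
                              cutoff, method)
      if (is.finite(d) && d <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          subunit = c(i, j), neighbor = c(j, i), offset = c(j - i, i - j),
          interface_type = classify_start(i, j), min_distance = d)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subunit = integer(), neighbor = integer(), offset = integer(),
               interface_type = character(), min_distance = numeric())
  out <- out[order(out$subunit, out$neighbor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Neighbor offsets of an interior subunit
#'
#' Convenience accessor: the sorted index offsets contacted by a given
#' subunit in a neighbor table from [enumerate_contacting_neighbors()].
#'
#' @param neighbors the neighbor table.
#' @param subunit 0-based subunit index.
#' @return sorted integer offsets (e.g. `c(-4, -3, -1, 1, 3, 4)`).
#' @export
neighbor_offsets <- function(neighbors, subunit) {
  sort(neighbors$offset[neighbors$subunit == subunit])
}
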