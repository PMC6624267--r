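# Residue contacts, Shrake-Rupley SASA, and buried-area accounting.

# --- spatial grid -----------------------------------------------------------

# cell-list neighbor search: returns data.frame(i, j, d) of inter-set atom
# pairs with d <= cutoff. Grid cells of edge `cutoff`; each atom of A is
# compared against B atoms in its 27 surrounding cells.
.grid_pairs <- function(A, B, cutoff) {
  stopifnot(cutoff > 0)
  keyf <- function(M) {
    g <- floor(M / cutoff)
    paste(g[, 1L], g[, 2L], g[, 3L])
  }
  gB <- floor(B / cutoff)
  mapB <- split(seq_len(nrow(B)), paste(gB[, 1L], gB[, 2L], gB[, 3L]))
  gA <- floor(A / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (i in seq_len(nrow(A))) {
    cand <- integer(0)
    for (k in seq_len(27L)) {
      key <- paste(gA[i, 1L] + offs[k, 1L], gA[i, 2L] + offs[k, 2L],
                   gA[i, 3L] + offs[k, 3L])
      hit <- mapB[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    d2 <- (B[cand, 1L] - A[i, 1L])^2 + (B[cand, 2L] - A[i, 2L])^2 +
          (B[cand, 3L] - A[i, 3L])^2
    keep <- d2 <= cutoff^2
    if (any(keep)) {
      out_i <- c(out_i, rep.int(i, sum(keep)))
      out_j <- c(out_j, cand[keep])
      out_d <- c(out_d, sqrt(d2[keep]))
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

# brute-force counterpart; candidate screen by expanded form, final distance
# recomputed from coordinate differences so both methods agree bitwise
.brute_pairs <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  idx <- which(d2 <= cutoff^2 * (1 + 1e-9) + 1e-9, arr.ind = TRUE)
  dd2 <- (B[idx[, 2L], 1L] - A[idx[, 1L], 1L])^2 +
         (B[idx[, 2L], 2L] - A[idx[, 1L], 2L])^2 +
         (B[idx[, 2L], 3L] - A[idx[, 1L], 3L])^2
  keep <- dd2 <= cutoff^2
  data.frame(i = idx[keep, 1L], j = idx[keep, 2L], d = sqrt(dd2[keep]))
}

# minimum inter-set distance (Inf if no pair within cutoff, grid method)
.min_pair_distance <- function(A, B, cutoff, method = "grid") {
  if (method == "brute") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    return(sqrt(max(0, min(d2))))
  }
  p <- .grid_pairs(A, B, cutoff)
  if (nrow(p)) min(p$d) else Inf
}

# --- contacts ---------------------------------------------------------------

#' Residue-level contacts between two atom groups
#'
#' Reports every residue pair (one residue from each group) whose minimum
#' inter-atomic distance is at or below `cutoff`. With `heavy_only` (the
#' default) hydrogens are excluded, matching the convention of defining
#' sub-domain contacts on heavy atoms. For an ensemble, pass a list of
#' model pairs via [contact_residues_ensemble()].
#'
#' @param group_a,group_b model data.frames (disjoint atom sets).
#' @param cutoff distance cutoff in Angstrom (default 2.5, the intra-dimer
#'   sub-domain contact criterion).
#' @param heavy_only exclude hydrogens (default TRUE).
#' @param method `"grid"` (cell lists) or `"brute"` (all pairs); both give
#'   identical results, `"brute"` is the validation path.
#' @return data.frame of class `contact_table`: `chain_a`, `res_a`,
#'   `res_name_a`, `chain_b`, `res_b`, `res_name_b`, `min_distance`.
#' @export
contact_residues <- function(group_a, group_b, cutoff = 2.5,
                             heavy_only = TRUE,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (heavy_only) {
    group_a <- group_a[!group_a$hydrogen, , drop = FALSE]
    group_b <- group_b[!group_b$hydrogen, , drop = FALSE]
  }
  if (!nrow(group_a) || !nrow(group_b))
    stop("empty atom group after filtering")
  ka <- paste(group_a$chain, group_a$res_seq, group_a$ins, group_a$atom)
  kb <- paste(group_b$chain, group_b$res_seq, group_b$ins, group_b$atom)
  if (length(intersect(ka, kb)))
    stop("atom groups overlap; contacts require disjoint groups")
  A <- coords(group_a); B <- coords(group_b)
  p <- if (method == "grid") .grid_pairs(A, B, cutoff) else .brute_pairs(A, B, cutoff)
  if (!nrow(p)) {
    out <- data.frame(chain_a = character(), res_a = integer(),
                      res_name_a = character(), chain_b = character(),
                      res_b = integer(), res_name_b = character(),
                      min_distance = numeric())
  } else {
    ra <- paste(group_a$chain[p$i], group_a$res_seq[p$i], group_a$ins[p$i])
    rb <- paste(group_b$chain[p$j], group_b$res_seq[p$j], group_b$ins[p$j])
    key <- paste(ra, rb, sep = "|")
    agg <- tapply(p$d, key, min)
    first <- !duplicated(key)
    ii <- p$i[first]; jj <- p$j[first]
    out <- data.frame(
      chain_a = group_a$chain[ii], res_a = group_a$res_seq[ii],
      res_name_a = group_a$res_name[ii],
      chain_b = group_b$chain[jj], res_b = group_b$res_seq[jj],
      res_name_b = group_b$res_name[jj],
      min_distance = as.numeric(agg[key[first]]))
    out <- out[order(out$chain_a, out$res_a, out$chain_b, out$res_b), ]
    rownames(out) <- NULL
  }
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Ensemble contacts under the "any model" rule
#'
#' Runs [contact_residues()] in every model of an ensemble and keeps a
#' residue pair if it is in contact in at least one model (`any_model =
#' TRUE`, the convention for NMR-ensemble sub-domain contacts), reporting
#' the per-pair minimum distance over models. With `any_model = FALSE` a
#' list of per-model tables is returned instead.
#'
#' @param ensemble an `hc_ensemble`.
#' @param select_a,select_b functions mapping a model to the two atom
#'   groups (e.g. `function(m) select_atoms(m, res_range = c(2, 97))`).
#' @param cutoff,heavy_only,method passed to [contact_residues()].
#' @param any_model combine across models (default TRUE).
#' @return a `contact_table` (or list of them when `any_model = FALSE`).
#' @export
contact_residues_ensemble <- function(ensemble, select_a, select_b,
                                      cutoff = 2.5, heavy_only = TRUE,
                                      any_model = TRUE,
                                      method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(ensemble, "hc_ensemble"))
  tabs <- lapply(seq_len(n_models(ensemble)), function(i) {
    m <- get_model(ensemble, i)
    contact_residues(select_a(m), select_b(m), cutoff = cutoff,
                     heavy_only = heavy_only, method = method)
  })
  if (!any_model) return(tabs)
  all <- do.call(rbind, tabs)
  if (!nrow(all)) {
    attr(all, "cutoff") <- cutoff
    return(all)
  }
  key <- paste(all$chain_a, all$res_a, all$chain_b, all$res_b)
  mins <- tapply(all$min_distance, key, min)
  out <- all[!duplicated(key), , drop = FALSE]
  out$min_distance <- as.numeric(mins[paste(out$chain_a, out$res_a,
                                            out$chain_b, out$res_b)])
  out <- out[order(out$chain_a, out$res_a, out$chain_b, out$res_b), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("contact_table", "data.frame")
  out
}

# --- SASA -------------------------------------------------------------------

#' Default van der Waals radii (Angstrom)
#'
#' Fixed published element radii used for SASA: C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20, P 1.80; unlisted elements require an override.
#' @return named numeric vector.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, D = 1.20, P = 1.80)
}

# deterministic golden-spiral unit-sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe of radius `probe_radius` over the atom set: each atom's
#' solvent sphere (vdW + probe) is sampled with a deterministic golden-spiral
#' point set and the exposed fraction gives its area. Hydrogens are excluded
#' by default (heavy-atom united convention).
#'
#' @param model a model data.frame.
#' @param probe_radius Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (>= 92; default 960).
#' @param radii named vdW radius table; see [vdw_radii()]. Unknown elements
#'   raise an error unless present here.
#' @param heavy_only exclude hydrogens (default TRUE).
#' @return object of class `sasa_result`: list with `atom_area` (per kept
#'   atom), `residue` (per-residue data.frame: chain, res_seq, res_name,
#'   area), `total`, `probe_radius`, `n_points`.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960L,
                 radii = vdw_radii(), heavy_only = TRUE) {
  if (n_points < 92L) stop("n_points must be >= 92")
  m <- if (heavy_only) model[!model$hydrogen, , drop = FALSE] else model
  if (!nrow(m)) stop("no atoms for SASA")
  el <- toupper(m$element)
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown))
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "),
         " (supply via `radii`)")
  R <- unname(radii[el]) + probe_radius
  X <- coords(m)
  n <- nrow(X)
  pts <- .sphere_points(n_points)
  # neighbor lists via grid at the largest possible interaction distance
  maxR <- max(R)
  nb <- .grid_pairs(X, X, 2 * maxR)
  nb <- nb[nb$i != nb$j & nb$d < R[nb$i] + R[nb$j], , drop = FALSE]
  nb_by_i <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  area <- numeric(n)
  for (i in seq_len(n)) {
    P <- pts * R[i]
    P <- sweep(P, 2L, X[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb_by_i[[i]]) {
      if (!any(exposed)) break
      dx <- P[exposed, 1L] - X[j, 1L]
      dy <- P[exposed, 2L] - X[j, 2L]
      dz <- P[exposed, 3L] - X[j, 3L]
      d2 <- dx * dx + dy * dy + dz * dz
      # asymmetric tie-break (with tolerance) so exactly coincident spheres
      # are counted once, not twice or zero times
      exposed[exposed] <- if (j < i) d2 > R[j]^2 * (1 + 1e-9)
                          else d2 >= R[j]^2 * (1 - 1e-9)
    }
    area[i] <- 4 * pi * R[i]^2 * sum(exposed) / n_points
  }
  rkey <- paste(m$chain, m$res_seq, m$ins)
  ragg <- tapply(area, rkey, sum)
  first <- !duplicated(rkey)
  res <- data.frame(chain = m$chain[first], res_seq = m$res_seq[first],
                    res_name = m$res_name[first],
                    area = as.numeric(ragg[rkey[first]]))
  structure(list(atom_area = area, residue = res, total = sum(area),
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<SASA> total %.1f A^2 over %d residues (probe %.2f A, %d points)\n",
              x$total, nrow(x$residue), x$probe_radius, x$n_points))
  invisible(x)
}

#' Buried surface area of named components in a complex
#'
#' For each component, buried area = SASA(component isolated) -
#' SASA(component within the full complex), and fraction buried =
#' buried / SASA(isolated). The components must partition the complex
#' disjointly (they need not cover it: atoms outside every component still
#' contribute to the complex context).
#'
#' @param complex a model data.frame.
#' @param partition named list; each element is a logical/integer row index
#'   into `complex` or a function taking the model and returning such an
#'   index.
#' @param ... passed to [sasa()].
#' @return data.frame of class `buried_area_table`: `component`,
#'   `sasa_isolated`, `sasa_in_complex`, `buried`, `fraction_buried`.
#' @export
buried_area <- function(complex, partition, ...) {
  stopifnot(is.list(partition), length(partition) >= 1L,
            !is.null(names(partition)))
  idxs <- lapply(partition, function(p) {
    if (is.function(p)) p <- p(complex)
    if (is.logical(p)) p <- which(p)
    p
  })
  for (nm in names(idxs)) if (!length(idxs[[nm]])) stop("empty component: ", nm)
  if (anyDuplicated(unlist(idxs))) stop("components overlap")
  dots <- list(...)
  # per-atom areas in full-complex context, computed once
  full <- do.call(sasa, c(list(model = complex), dots))
  kept <- which(if (isFALSE(dots$heavy_only)) rep(TRUE, nrow(complex))
                else !complex$hydrogen)
  pos <- match(seq_len(nrow(complex)), kept)     # complex row -> area index
  rows <- lapply(names(idxs), function(nm) {
    iso <- do.call(sasa, c(list(model = complex[idxs[[nm]], , drop = FALSE]), dots))
    in_ctx <- sum(full$atom_area[stats::na.omit(pos[idxs[[nm]]])])
    data.frame(component = nm, sasa_isolated = iso$total,
               sasa_in_complex = in_ctx,
               buried = iso$total - in_ctx,
               fraction_buried = (iso$total - in_ctx) / iso$total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("buried_area_table", "data.frame")
  out
}

#' Ensemble-averaged buried area
#'
#' Applies [buried_area()] to every model of an ensemble and averages the
#' per-component results.
#'
#' @param ensemble an `hc_ensemble`.
#' @param partition as in [buried_area()] (indices refer to topology rows).
#' @param ... passed to [sasa()].
#' @return `buried_area_table` of per-component means, with an extra
#'   `buried_sd` column across models.
#' @export
buried_area_ensemble <- function(ensemble, partition, ...) {
  stopifnot(inherits(ensemble, "hc_ensemble"))
  tabs <- lapply(seq_len(n_models(ensemble)), function(i)
    buried_area(get_model(ensemble, i), partition, ...))
  comp <- tabs[[1L]]$component
  num <- c("sasa_isolated", "sasa_in_complex", "buried", "fraction_buried")
  out <- tabs[[1L]]
  for (cn in num)
    out[[cn]] <- rowMeans(vapply(tabs, function(t) t[[cn]], numeric(length(comp))))
  out$buried_sd <- apply(vapply(tabs, function(t) t$buried,
                                numeric(length(comp))), 1L, stats::sd)
  class(out) <- c("buried_area_table", "data.frame")
  out
}

# --- typed interface reports ------------------------------------------------

#' Typed per-interface residue contact tables
#'
#' Two schemes:
#' * `filament_typed`: residue contacts between filament subunits, grouped
#'   by the interface type of the subunit index separation (Type I/II/III =
#'   3-/4-/1-start); non-canonical separations are dropped.
#' * `dimer_subdomain`: residue contacts between named sub-domain residue
#'   ranges within one model (e.g. CARD 2-97, linker 98-111, coiled-coil
#'   112+), labelled by the sub-domain pair; both inter- and intra-chain
#'   contacts across different sub-domains are reported.
#'
#' @param structure a `filament` (for `filament_typed`) or a model
#'   data.frame / `hc_ensemble` (for `dimer_subdomain`).
#' @param scheme `"filament_typed"` or `"dimer_subdomain"`.
#' @param subdomains named list of residue ranges `c(lo, hi)` for the dimer
#'   scheme.
#' @param cutoff Angstrom; defaults: 4.5 for filaments (van der Waals
#'   contact), 2.5 for the dimer sub-domain criterion.
#' @param any_model for ensembles: combine across models (default TRUE).
#' @return data.frame with an `interface` label column plus the contact
#'   columns of [contact_residues()] (for filaments: `subunit_a`,
#'   `subunit_b`, `offset` as well).
#' @export
interface_report <- function(structure,
                             scheme = c("filament_typed", "dimer_subdomain"),
                             subdomains = list(CARD = c(2, 97),
                                               linker = c(98, 111),
                                               coiled_coil = c(112, 9999)),
                             cutoff = NULL, any_model = TRUE) {
  scheme <- match.arg(scheme)
  if (scheme == "filament_typed") {
    stopifnot(inherits(structure, "filament"))
    if (is.null(cutoff)) cutoff <- 4.5
    nb <- enumerate_contacting_neighbors(structure, cutoff = cutoff)
    nb <- nb[!is.na(nb$interface_type) & nb$offset > 0, , drop = FALSE]
    fm <- filament_model(structure)
    rows <- lapply(seq_len(nrow(nb)), function(k) {
      a <- fm[fm$subunit == nb$subunit[k], , drop = FALSE]
      b <- fm[fm$subunit == nb$neighbor[k], , drop = FALSE]
      ct <- contact_residues(a, b, cutoff = cutoff)
      if (!nrow(ct)) return(NULL)
      cbind(data.frame(interface = paste0("Type", nb$interface_type[k]),
                       subunit_a = nb$subunit[k], subunit_b = nb$neighbor[k],
                       offset = nb$offset[k]), as.data.frame(ct))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(interface = character(), subunit_a = integer(),
                        subunit_b = integer(), offset = integer())
    rownames(out) <- NULL
    attr(out, "cutoff") <- cutoff
    return(out)
  }

  # dimer_subdomain
  if (is.null(cutoff)) cutoff <- 2.5
  stopifnot(length(subdomains) >= 2L, !is.null(names(subdomains)))
  pair_tab <- function(model) {
    nms <- names(subdomains)
    rows <- list()
    for (ai in seq_along(nms)) for (bi in seq_along(nms)) {
      if (bi <= ai) next
      ga <- select_atoms(model, res_range = subdomains[[ai]])
      gb <- select_atoms(model, res_range = subdomains[[bi]])
      if (!nrow(ga) || !nrow(gb)) next
      ct <- contact_residues(ga, gb, cutoff = cutoff)
      if (nrow(ct))
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(interface = paste(nms[ai], nms[bi], sep = "-")),
          as.data.frame(ct))
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(interface = character())
  }
  if (inherits(structure, "hc_ensemble")) {
    tabs <- lapply(seq_len(n_models(structure)),
                   function(i) pair_tab(get_model(structure, i)))
    all <- do.call(rbind, tabs)
    if (!any_model || !nrow(all)) { attr(all, "cutoff") <- cutoff; return(all) }
    key <- paste(all$interface, all$chain_a, all$res_a, all$chain_b, all$res_b)
    mins <- tapply(all$min_distance, key, min)
    out <- all[!duplicated(key), , drop = FALSE]
    out$min_distance <- as.numeric(mins[paste(out$interface, out$chain_a,
                                              out$res_a, out$chain_b, out$res_b)])
    rownames(out) <- NULL
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  out <- pair_tab(structure)
  attr(out, "cutoff") <- cutoff
  out
}

#' Write per-residue values into the B-factor column of a PDB
#'
#' Visualization helper: annotates a model with per-residue scalars (e.g.
#' SASA, contact flags, perturbation classes) in the B-factor column and
#' writes it out.
#'
#' @param model a model data.frame.
#' @param values named numeric vector keyed by residue number (applied to
#'   all chains), or a data.frame with `res_seq` and `value`.
#' @param path output PDB path.
#' @param default B-factor for unlisted residues (default 0).
#' @return `path`, invisibly.
#' @export
write_bfactor_annotation <- function(model, values, path, default = 0) {
  if (is.data.frame(values)) {
    v <- values$value
    names(v) <- values$res_seq
    values <- v
  }
  b <- unname(values[as.character(model$res_seq)])
  b[is.na(b)] <- default
  model$b <- b
  write_structure(model, path)
}
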