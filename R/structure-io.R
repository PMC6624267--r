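# Atom records are plain data.frames with one row per atom and columns
#   atom, element, res_name, res_seq, ins, chain, x, y, z, occ, b, hydrogen
# A "model" is such a data.frame; an "ensemble" holds one shared topology
# (the same data.frame without coordinates) plus one n_atoms x 3 coordinate
# matrix per model.

.model_cols <- c("atom", "element", "res_name", "res_seq", "ins", "chain",
                 "x", "y", "z", "occ", "b", "hydrogen")

#' Construct and validate an atomic model
#'
#' A model is a data.frame of atoms ordered by (chain, res_seq, atom order as
#' given), with Cartesian coordinates in Angstrom. Duplicate
#' (chain, res_seq, ins, atom) keys are rejected, elements must be non-empty
#' and coordinates finite. The `hydrogen` flag is derived from the element.
#'
#' @param atoms data.frame with at least columns `atom`, `element`,
#'   `res_name`, `res_seq`, `chain`, `x`, `y`, `z`. Optional: `ins`
#'   (insertion code, default `""`), `occ`, `b`.
#' @return A validated model data.frame (class `c("hc_model", "data.frame")`).
#' @export
new_model <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom", "element", "res_name", "res_seq", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("model is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("model has no atoms")
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in model")
  if (any(!nzchar(atoms$element))) stop("empty element symbols in model")
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$hydrogen <- toupper(atoms$element) %in% c("H", "D")
  key <- paste(atoms$chain, atoms$res_seq, atoms$ins, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, ins, atom) keys in model: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  atoms <- atoms[, .model_cols]
  rownames(atoms) <- NULL
  class(atoms) <- c("hc_model", "data.frame")
  atoms
}

#' Bundle models into a coordinate ensemble
#'
#' All models must share an identical topology key (chain, res_seq, ins,
#' res_name, atom, in order); only coordinates may differ between models.
#'
#' @param models list of models (see [new_model()]).
#' @return An object of class `hc_ensemble`: list with elements `atoms` (the
#'   shared topology, coordinates of model 1) and `xyz` (list of n_atoms x 3
#'   matrices, one per model).
#' @export
as_ensemble <- function(models) {
  if (!length(models)) stop("ensemble needs at least one model")
  models <- lapply(models, new_model)
  key <- function(m) paste(m$chain, m$res_seq, m$ins, m$res_name, m$atom)
  k1 <- key(models[[1L]])
  for (i in seq_along(models)) {
    if (!identical(key(models[[i]]), k1))
      stop("inconsistent topology between model 1 and model ", i)
  }
  structure(
    list(atoms = models[[1L]],
         xyz = lapply(models, function(m) unname(as.matrix(m[, c("x", "y", "z")])))),
    class = "hc_ensemble")
}

#' @export
print.hc_ensemble <- function(x, ...) {
  cat("<hc_ensemble> ", n_models(x), " model(s), ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  invisible(x)
}

#' Number of models in an ensemble
#' @param ensemble an `hc_ensemble`.
#' @return integer model count.
#' @export
n_models <- function(ensemble) length(ensemble$xyz)

#' Extract one model from an ensemble
#' @param ensemble an `hc_ensemble`.
#' @param i model index (1-based).
#' @return A model data.frame with that model's coordinates.
#' @export
get_model <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "hc_ensemble"), i >= 1L, i <= n_models(ensemble))
  m <- ensemble$atoms
  m[, c("x", "y", "z")] <- ensemble$xyz[[i]]
  m
}

# element guess from a PDB atom name when the element column is absent;
# names with a leading digit (e.g. "1HB2") are hydrogens by convention
.guess_element <- function(name) {
  nm <- trimws(name)
  el <- ifelse(grepl("^[0-9]", nm), "H", substr(gsub("[^A-Za-z].*$", "", nm), 1, 1))
  el[el == ""] <- "C"
  toupper(el)
}

#' Read a (multi-model) PDB structure into an ensemble
#'
#' Parses ATOM/HETATM/MODEL/ENDMDL/TER records (ANISOU/CONECT are ignored) via
#' the bio3d reader. One model is created per MODEL record; a file without
#' MODEL records yields a single-model ensemble. Chain identifiers and residue
#' numbering are preserved verbatim; no renumbering is performed. Alternate
#' locations are reduced to a single conformer by highest occupancy (ties:
#' first occurrence). Hydrogen flags are set from the element column (guessed
#' from the atom name where absent).
#'
#' @param path path to a PDB file.
#' @param format only `"pdb"` is supported.
#' @return An [as_ensemble()] object.
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  # quick well-formedness scan so malformed lines fail with a line number
  co <- substr(lines[is_atom], 31, 54)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(co, 1, 8)))) |
               is.na(suppressWarnings(as.numeric(substr(co, 9, 16)))) |
               is.na(suppressWarnings(as.numeric(substr(co, 17, 24)))))
  if (length(bad))
    stop("malformed ATOM record at line ", which(is_atom)[bad[1L]], " of ", path)

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$chain[is.na(at$chain)] <- " "
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el[is.na(el) | !nzchar(trimws(el))] <- NA_character_
  el <- ifelse(is.na(el), .guess_element(at$elety), toupper(trimws(el)))

  keep <- seq_len(nrow(at))
  if (any(nzchar(at$alt))) {
    grp <- paste(at$chain, at$resno, at$insert, at$elety)
    ord <- order(-at$o, seq_len(nrow(at)))   # highest occupancy, ties first seen
    keep <- sort(ord[!duplicated(grp[ord])])
  }

  base <- data.frame(
    atom = at$elety[keep], element = el[keep], res_name = at$resid[keep],
    res_seq = at$resno[keep], ins = at$insert[keep], chain = at$chain[keep],
    x = 0, y = 0, z = 0, occ = at$o[keep], b = at$b[keep],
    stringsAsFactors = FALSE)

  models <- vector("list", nmod)
  for (i in seq_len(nmod)) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    m <- base
    m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
    models[[i]] <- tryCatch(new_model(m),
      error = function(e) stop("while reading model ", i, " of ", path, ": ",
                               conditionMessage(e)))
  }
  as_ensemble(models)
}

.format_atom_name <- function(name, element) {
  # short names are element-justified in columns 14-16; 4-char names fill 13-16
  ifelse(nchar(name) >= 4, substr(sprintf("%-4s", name), 1, 4),
         sprintf(" %-3s", name))
}

#' Write an ensemble (or single model) as a PDB file
#'
#' Multi-model ensembles are framed with MODEL/ENDMDL records; coordinates are
#' written at 3 decimals. The output is re-readable by [read_structure()] and
#' by standard PDB readers.
#'
#' @param ensemble an `hc_ensemble` or a single model data.frame.
#' @param path output file path.
#' @param format only `"pdb"`.
#' @param model_records write MODEL/ENDMDL framing even for a single-model
#'   ensemble (default: only when more than one model).
#' @return `path`, invisibly.
#' @export
write_structure <- function(ensemble, path, format = "pdb",
                            model_records = NULL) {
  format <- match.arg(format, "pdb")
  if (is.data.frame(ensemble)) ensemble <- as_ensemble(list(ensemble))
  stopifnot(inherits(ensemble, "hc_ensemble"))
  a <- ensemble$atoms
  if (any(a$res_seq > 9999L))
    stop("residue numbers exceed 9999; renumber before writing PDB")
  nmod <- n_models(ensemble)
  if (is.null(model_records)) model_records <- nmod > 1L
  name_f <- .format_atom_name(a$atom, a$element)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nmod)) {
    if (model_records) writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- ensemble$xyz[[i]]
    lines <- sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     (seq_len(nrow(a)) - 1L) %% 99999L + 1L, name_f,
                     substr(a$res_name, 1, 3), substr(a$chain, 1, 1),
                     a$res_seq, substr(paste0(a$ins, " "), 1, 1),
                     xyz[, 1], xyz[, 2], xyz[, 3], a$occ, a$b,
                     toupper(substr(a$element, 1, 2)))
    writeLines(lines, con)
    if (model_records) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atoms from a model
#'
#' Subsets a model by chain, residue-number range (or explicit residue set),
#' atom names, and/or heavy atoms only. The subset preserves model order and
#' may be empty. Selecting a chain identifier absent from the model is an
#' error (a typo guard); an empty result from residue/atom filters is not.
#'
#' @param model a model data.frame.
#' @param chain character vector of chain ids, or NULL for all.
#' @param res_range length-2 numeric `c(lo, hi)` residue-number range
#'   (inclusive), or NULL.
#' @param res_seq explicit residue numbers, or NULL.
#' @param atoms atom-name vector (e.g. `c("N","CA","C","O")`), or NULL.
#' @param heavy_only drop hydrogens/deuteriums.
#' @return the selected rows of `model`.
#' @export
select_atoms <- function(model, chain = NULL, res_range = NULL, res_seq = NULL,
                         atoms = NULL, heavy_only = FALSE) {
  stopifnot(is.data.frame(model))
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chain)) {
    unknown <- setdiff(chain, unique(model$chain))
    if (length(unknown)) stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
    keep <- keep & model$chain %in% chain
  }
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L)
    keep <- keep & model$res_seq >= res_range[1L] & model$res_seq <= res_range[2L]
  }
  if (!is.null(res_seq)) keep <- keep & model$res_seq %in% res_seq
  if (!is.null(atoms)) keep <- keep & model$atom %in% atoms
  if (heavy_only) keep <- keep & !model$hydrogen
  model[keep, , drop = FALSE]
}

# coordinate matrix of a model (n x 3)
coords <- function(model) unname(as.matrix(model[, c("x", "y", "z")]))

# replace coordinates of a model
`coords<-` <- function(model, value) {
  model[, c("x", "y", "z")] <- value
  model
}
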