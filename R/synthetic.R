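# Synthetic fixtures: toy lattice protomers, noisy coordinate ensembles, and
# NMR/HDX perturbation datasets. All generators are deterministic for a
# fixed rng_seed and every fixture is validated against the checks of its
# consuming module before it is returned.

#' Generate a toy protomer realizing the three-interface helical lattice
#'
#' Builds a pseudo-atom protomer (carbon radii, synthetic residue labels)
#' placed on a ring of radius `ring_radius` about the +z axis, with paired
#' interface patch atoms positioned so that under the lattice
#' (`rise`, `twist`) the "b"-side patch of subunit j meets the "a"-side
#' patch of subunit j+k for each enabled start number k. With the canonical
#' starts {1, 3, 4} an interior subunit of the resulting filament contacts
#' exactly six neighbors (index offsets -4, -3, -1, +1, +3, +4) at the
#' default filament contact cutoff, which is verified before returning
#' (generation error otherwise).
#'
#' The patch pair for start k sits at fraction `patch_fraction` of the way
#' from the subunit center toward the centers of subunits j+k ("b" side,
#' residue name `PBk`) and j-k ("a" side, `PAk`), giving an inter-patch gap
#' of `(1 - 2 * patch_fraction) * |center(j+k) - center(j)|`.
#'
#' @param n_core core pseudo-atoms (default 20; must be >= 1).
#' @param core_radius core cluster radius, Angstrom (default 2.5).
#' @param ring_radius distance of the subunit center from the helix axis
#'   (default 15).
#' @param rise,twist lattice parameters the patches are tuned for
#'   (defaults 5.1 and -101.6).
#' @param starts enabled interface start numbers (default `c(1, 3, 4)`).
#' @param patch_fraction see above (default 0.42).
#' @param contact_cutoff cutoff used for the post-hoc validation (default
#'   4.5, the filament neighbor default).
#' @param n_validate subunits in the validation filament (default 10).
#' @param rng_seed seed for the core-atom jitter.
#' @return a model data.frame; core atoms have residue name `COR`, patch
#'   atoms `PA<k>`/`PB<k>`.
#' @export
make_toy_protomer <- function(n_core = 20L, core_radius = 2.5,
                              ring_radius = 15, rise = 5.1, twist = -101.6,
                              starts = c(1L, 3L, 4L), patch_fraction = 0.42,
                              contact_cutoff = 4.5, n_validate = 10L,
                              rng_seed = 1L) {
  if (n_core < 1L) stop("n_core must be >= 1")
  stopifnot(ring_radius > 0, patch_fraction > 0, patch_fraction < 0.5)
  starts <- sort(unique(as.integer(starts)))
  if (!length(starts) || any(starts < 1L))
    stop("starts must be positive integers")
  center <- function(j) {
    a <- j * twist * pi / 180
    c(ring_radius * cos(a), ring_radius * sin(a), j * rise)
  }
  c0 <- center(0)
  set.seed(as.integer(rng_seed))
  # deterministic jittered core: uniform directions, radii within core_radius
  u <- matrix(stats::rnorm(3L * n_core), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  rad <- core_radius * stats::runif(n_core)^(1 / 3)
  core <- sweep(u * rad, 2L, c0, `+`)
  rows <- data.frame(
    atom = "C", element = "C", res_name = "COR",
    res_seq = seq_len(n_core), ins = "", chain = "A",
    x = core[, 1L], y = core[, 2L], z = core[, 3L], occ = 1, b = 0)
  nres <- n_core
  for (k in starts) {
    pb <- c0 + patch_fraction * (center(k) - c0)
    pa <- c0 + patch_fraction * (center(-k) - c0)
    rows <- rbind(rows, data.frame(
      atom = "C", element = "C",
      res_name = c(sprintf("PB%d", k), sprintf("PA%d", k)),
      res_seq = nres + 1:2, ins = "", chain = "A",
      x = c(pb[1L], pa[1L]), y = c(pb[2L], pa[2L]), z = c(pb[3L], pa[3L]),
      occ = 1, b = 0))
    nres <- nres + 2L
  }
  protomer <- new_model(rows)

  # post-hoc validation: interior subunits must contact exactly the enabled
  # offsets (and, for the canonical starts, exactly six neighbors)
  fl <- build_filament(protomer, helical_parameters(rise, twist), n_validate)
  nb <- enumerate_contacting_neighbors(fl, cutoff = contact_cutoff)
  expected <- sort(c(starts, -starts))
  interior <- seq.int(max(starts), n_validate - 1L - max(starts))
  for (j in interior) {
    got <- neighbor_offsets(nb, j)
    if (!identical(as.integer(got), as.integer(expected)))
      stop("toy protomer failed lattice validation: interior subunit ", j,
           " contacts offsets {", paste(got, collapse = ", "),
           "} instead of {", paste(expected, collapse = ", "), "}")
  }
  protomer
}

#' Perturb a model into a noisy coordinate ensemble
#'
#' Model 1 is the input unchanged; models 2..n add isotropic Gaussian noise
#' of standard deviation `sigma` per coordinate to every atom,
#' independently per model. Deterministic for fixed `rng_seed`.
#'
#' @param model a model data.frame.
#' @param sigma per-coordinate noise sd, Angstrom (>= 0).
#' @param n_models total models (>= 2).
#' @param rng_seed integer seed.
#' @return an `hc_ensemble`.
#' @export
perturb_ensemble <- function(model, sigma, n_models, rng_seed = 1L) {
  stopifnot(sigma >= 0)
  if (n_models < 2L) stop("n_models must be >= 2")
  model <- new_model(model)
  set.seed(as.integer(rng_seed))
  x0 <- coords(model)
  models <- vector("list", n_models)
  models[[1L]] <- model
  for (i in 2:n_models) {
    m <- model
    coords(m) <- x0 + matrix(stats::rnorm(length(x0), sd = sigma),
                             nrow(x0), 3L)
    models[[i]] <- m
  }
  as_ensemble(models)
}

#' Generate a synthetic NMR/HDX perturbation dataset
#'
#' Emulates the data shapes of an intensity-perturbation experiment plus an
#' HDX uptake comparison:
#'
#' * a peak table over `residues` in which the designated `broadened` set
#'   has intensity ratio `broadened_ratio` (default 0.1) and all other
#'   residues `unaffected_ratio` (default 0.9), with multiplicative
#'   Gaussian noise `intensity_noise` (default 2%);
#' * an overlapping peptide tiling (lengths cycling through
#'   `peptide_lengths`, start offset `peptide_offset`) with reference
#'   uptake curves `1 - exp(-k t)` over log-spaced labeling times, and test
#'   curves time-dilated by `deprotect_pf` for peptides whose residue
#'   majority falls inside a designated `deprotected` segment (plus
#'   additive noise `uptake_noise`).
#'
#' @param residues residue range (default `2:142`).
#' @param broadened residues designated as selectively broadened (default:
#'   30 residues drawn deterministically from `residues`).
#' @param deprotected list of `c(start, end)` segments (default
#'   `list(c(24, 38))`).
#' @param broadened_ratio,unaffected_ratio target intensity ratios.
#' @param intensity_noise multiplicative sd on intensities (default 0.02).
#' @param deprotect_pf dilation factor applied over deprotected segments
#'   (default 0.3; < 1 = faster exchange).
#' @param uptake_noise additive sd on fractional uptake (default 0.02).
#' @param peptide_lengths,peptide_offset tiling controls (defaults 8..15
#'   cycling, offset 3).
#' @param times labeling times, seconds (default 8 log-spaced points,
#'   30 s to 1 day).
#' @param rng_seed integer seed.
#' @return list with `peaks` (peak table data.frame), `reference_curves`,
#'   `test_curves` (named lists of [uptake_curve()]), `broadened`,
#'   `deprotected`, `deprotect_pf`.
#' @export
make_perturbation_dataset <- function(residues = 2:142,
                                      broadened = NULL,
                                      deprotected = list(c(24L, 38L)),
                                      broadened_ratio = 0.1,
                                      unaffected_ratio = 0.9,
                                      intensity_noise = 0.02,
                                      deprotect_pf = 0.3,
                                      uptake_noise = 0.02,
                                      peptide_lengths = 8:15,
                                      peptide_offset = 3L,
                                      times = round(exp(seq(log(30), log(86400),
                                                            length.out = 8L))),
                                      rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  residues <- sort(unique(as.integer(residues)))
  if (is.null(broadened))
    broadened <- sort(sample(residues, min(30L, length(residues) %/% 4L)))
  if (!all(broadened %in% residues))
    stop("broadened set must lie within the residue range")
  for (seg in deprotected)
    if (seg[1L] < min(residues) || seg[2L] > max(residues))
      stop("deprotected segments must lie within the residue range")

  n <- length(residues)
  apo <- exp(stats::rnorm(n, mean = log(1e5), sd = 0.4))
  target <- ifelse(residues %in% broadened, broadened_ratio, unaffected_ratio)
  pert <- apo * target * (1 + stats::rnorm(n, sd = intensity_noise))
  pert[pert < 0] <- 0
  peaks <- data.frame(res_seq = residues, apo_intensity = apo,
                      perturbed_intensity = pert,
                      overlapped = FALSE, unassigned = FALSE)

  in_deprot <- function(r) any(vapply(deprotected, function(s)
    r >= s[1L] && r <= s[2L], logical(1L)))
  dep_mask <- vapply(residues, in_deprot, logical(1L))

  starts <- seq(min(residues), max(residues), by = peptide_offset)
  ref <- list(); tst <- list()
  li <- 0L
  for (s in starts) {
    li <- li + 1L
    len <- peptide_lengths[(li - 1L) %% length(peptide_lengths) + 1L]
    e <- min(s + len - 1L, max(residues))
    if (e - s + 1L < 3L) next
    key <- paste(s, e, sep = "-")
    if (!is.null(ref[[key]])) next
    k <- exp(stats::runif(1L, log(2e-5), log(2e-4)))   # intrinsic-ish rates
    span <- s:e
    frac_dep <- mean(dep_mask[match(span, residues)], na.rm = TRUE)
    pf <- if (!is.na(frac_dep) && frac_dep > 0.5) deprotect_pf else 1
    u_ref <- 1 - exp(-k * times)
    u_tst <- 1 - exp(-k * times / pf)
    u_ref <- pmin(1, pmax(0, u_ref + stats::rnorm(length(times), sd = uptake_noise)))
    u_tst <- pmin(1, pmax(0, u_tst + stats::rnorm(length(times), sd = uptake_noise)))
    ref[[key]] <- uptake_curve(s, e, times, u_ref)
    tst[[key]] <- uptake_curve(s, e, times, u_tst)
  }

  list(peaks = peaks, reference_curves = ref, test_curves = tst,
       broadened = broadened, deprotected = deprotected,
       deprotect_pf = deprotect_pf)
}

#' Write a peak table as TSV
#' @param peaks data.frame from [make_perturbation_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a set of uptake curves as TSV
#' @param curves named list of [uptake_curve()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(curves, path) {
  rows <- lapply(curves, function(cu)
    data.frame(peptide_start = cu$start_res, peptide_end = cu$end_res,
               time_s = cu$times, uptake = cu$uptake))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
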