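# NMR line-broadening / chemical-shift-perturbation classification and
# HDX protection-factor estimation with residue-level consensus.

#' Classify per-residue line broadening from peak-intensity ratios
#'
#' The intensity ratio perturbed/apo is computed per residue and classified
#' as `selective` (ratio < `low`, i.e. strong broadening), `minimal`
#' (ratio > `high`) or `intermediate`. Defaults (0.25, 0.50) express the
#' ">75% reduction" / "<50% reduction" convention for a ~35 kDa target; for
#' a small conjugate such as ubiquitin, (0.05, 0.10) is the matching choice.
#' Records flagged as overlapped/unassigned, or with apo intensity of zero,
#' are excluded from classification (class `NA`).
#'
#' @param records data.frame with columns `res_seq`, `apo_intensity`,
#'   `perturbed_intensity`, optional logical `overlapped` / `unassigned`.
#' @param low,high ratio thresholds, `0 < low < high < 1`.
#' @param reference_residues optional residue numbers used for a global
#'   normalization: all ratios are divided by the median ratio of these
#'   residues (off when NULL, the default; raw-ratio convention).
#' @return data.frame with `res_seq`, `ratio`, `class` (factor
#'   selective/intermediate/minimal, NA when excluded), `excluded` flag.
#' @export
intensity_ratio_classify <- function(records, low = 0.25, high = 0.50,
                                     reference_residues = NULL) {
  stopifnot(is.data.frame(records))
  if (!(low > 0 && low < high && high < 1))
    stop("thresholds must satisfy 0 < low < high < 1")
  need <- c("res_seq", "apo_intensity", "perturbed_intensity")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(records$apo_intensity)) ||
      any(!is.finite(records$perturbed_intensity)))
    stop("intensities must be finite")
  if (any(records$apo_intensity < 0) || any(records$perturbed_intensity < 0))
    stop("intensities must be non-negative")
  flagged <- rep(FALSE, nrow(records))
  for (fcol in c("overlapped", "unassigned"))
    if (!is.null(records[[fcol]])) flagged <- flagged | records[[fcol]]
  zero_apo <- records$apo_intensity == 0
  excluded <- flagged | zero_apo
  ratio <- ifelse(zero_apo, NA_real_,
                  records$perturbed_intensity / records$apo_intensity)
  if (!is.null(reference_residues)) {
    ref <- ratio[records$res_seq %in% reference_residues & !excluded]
    if (!length(ref)) stop("no usable reference residues for normalization")
    ratio <- ratio / stats::median(ref)
  }
  cls <- rep(NA_character_, nrow(records))
  ok <- !excluded
  cls[ok & ratio < low] <- "selective"
  cls[ok & ratio > high] <- "minimal"
  cls[ok & is.na(cls)] <- "intermediate"
  data.frame(res_seq = records$res_seq, ratio = ratio,
             class = factor(cls, levels = c("selective", "intermediate", "minimal")),
             excluded = excluded)
}

#' Combined amide chemical shift perturbation
#'
#' CSP per residue as the weighted Euclidean shift distance
#' `sqrt(dH^2 + (w * dN)^2)` with the conventional nitrogen scaling
#' `w = 0.14`. Residues missing a shift in either state are omitted.
#'
#' @param apo,perturbed data.frames with `res_seq`, `h_ppm`, `n_ppm`.
#' @param n_weight nitrogen weight (default 0.14).
#' @return data.frame with `res_seq`, `d_h`, `d_n`, `csp`; attribute
#'   `omitted` lists residues present in only one state.
#' @export
chemical_shift_perturbation <- function(apo, perturbed, n_weight = 0.14) {
  stopifnot(all(c("res_seq", "h_ppm", "n_ppm") %in% names(apo)),
            all(c("res_seq", "h_ppm", "n_ppm") %in% names(perturbed)))
  common <- intersect(apo$res_seq, perturbed$res_seq)
  omitted <- c(setdiff(apo$res_seq, common), setdiff(perturbed$res_seq, common))
  a <- apo[match(common, apo$res_seq), ]
  p <- perturbed[match(common, perturbed$res_seq), ]
  keep <- is.finite(a$h_ppm) & is.finite(a$n_ppm) &
          is.finite(p$h_ppm) & is.finite(p$n_ppm)
  omitted <- c(omitted, common[!keep])
  a <- a[keep, ]; p <- p[keep, ]
  dh <- p$h_ppm - a$h_ppm
  dn <- p$n_ppm - a$n_ppm
  out <- data.frame(res_seq = a$res_seq, d_h = dh, d_n = dn,
                    csp = sqrt(dh^2 + (n_weight * dn)^2))
  attr(out, "omitted") <- sort(unique(omitted))
  out
}

#' Build an uptake curve
#' @param start_res,end_res peptide bounds (inclusive residue numbers).
#' @param times labeling times in seconds, strictly increasing, >= 2 points.
#' @param uptake deuterium uptake per time (fractional or Da).
#' @param sd optional replicate standard deviations.
#' @return object of class `uptake_curve`.
#' @export
uptake_curve <- function(start_res, end_res, times, uptake, sd = NULL) {
  stopifnot(length(times) == length(uptake), length(times) >= 2L,
            start_res <= end_res)
  if (any(diff(times) <= 0)) stop("labeling times must be strictly increasing")
  structure(list(start_res = as.integer(start_res),
                 end_res = as.integer(end_res),
                 times = as.numeric(times), uptake = as.numeric(uptake),
                 sd = sd),
            class = "uptake_curve")
}

#' HDX protection factor by time dilation
#'
#' Estimates the multiplicative change in exchange rate between a reference
#' (e.g. unconjugated) and test (e.g. conjugated) uptake curve of the same
#' peptide. The protection factor PF is the time-dilation factor that best
#' overlays the test curve on the reference, `test(t) ~ reference(t / PF)`,
#' found by least squares over a log-spaced PF grid spanning `pf_range` with
#' monotone (log-time, clamped) interpolation of the reference. PF = 1 means
#' no change; PF < 1 means the test state exchanges faster (de-protection);
#' PF > 1 means protection. Curves with no resolvable exchange amplitude are
#' flagged undefined.
#'
#' @param reference,test [uptake_curve()] objects for the same peptide.
#' @param pf_range log-grid limits (default `c(1e-3, 1e3)`).
#' @param n_grid coarse log-grid size (default 241); the coarse optimum is
#'   refined by golden-section search between its grid neighbours, so the
#'   final resolution is much finer than the grid step.
#' @return object of class `protection_result`: list with `start_res`,
#'   `end_res`, `pf`, `residual` (RMS fit residual), `undefined` flag.
#' @export
protection_factor <- function(reference, test, pf_range = c(1e-3, 1e3),
                              n_grid = 241L) {
  stopifnot(inherits(reference, "uptake_curve"), inherits(test, "uptake_curve"))
  if (reference$start_res != test$start_res ||
      reference$end_res != test$end_res)
    stop("reference and test curves are for different peptides")
  if (length(test$times) < 3L)
    stop("need at least 3 time points to estimate a protection factor")
  amp <- max(reference$uptake) - min(reference$uptake)
  if (amp < 1e-6 || (max(test$uptake) - min(test$uptake)) < 1e-6) {
    return(structure(list(start_res = reference$start_res,
                          end_res = reference$end_res,
                          pf = NA_real_, residual = NA_real_,
                          undefined = TRUE),
                     class = "protection_result"))
  }
  ref_u <- cummax(reference$uptake)             # enforce monotone uptake
  ref_lt <- log(reference$times)
  lt <- log(test$times)
  obj <- function(la) {                         # la = log(alpha)
    pred <- stats::approx(ref_lt, ref_u, xout = lt - la, rule = 2)$y
    sum((test$uptake - pred)^2)
  }
  lg <- seq(log(pf_range[1L]), log(pf_range[2L]), length.out = n_grid)
  rss <- vapply(lg, obj, numeric(1L))
  b <- which.min(rss)
  lo <- lg[max(1L, b - 1L)]; hi <- lg[min(n_grid, b + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-6)
  structure(list(start_res = reference$start_res, end_res = reference$end_res,
                 pf = exp(opt$minimum),
                 residual = sqrt(opt$objective / length(test$times)),
                 undefined = FALSE),
            class = "protection_result")
}

#' @export
print.protection_result <- function(x, ...) {
  if (x$undefined)
    cat(sprintf("<PF> peptide %d-%d: undefined (flat curve)\n",
                x$start_res, x$end_res))
  else
    cat(sprintf("<PF> peptide %d-%d: PF = %.3g (rms residual %.3g)\n",
                x$start_res, x$end_res, x$pf, x$residual))
  invisible(x)
}

#' Residue-level consensus over overlapping peptide protection factors
#'
#' Each residue is voted on by every peptide covering it: a peptide votes
#' `deprotected` if its PF is below `deprotect_threshold`, `protected` if
#' its PF is above `1 / deprotect_threshold`, otherwise `unaffected`.
#' A residue takes the plurality label of its covering peptides (ties break
#' toward the perturbed call, deprotected over protected over unaffected,
#' so marginal boundary residues are not silently dropped); residues covered
#' by no peptide are labelled `no_coverage`. Contiguous equal-label runs are
#' merged into segments.
#'
#' @param results list of [protection_factor()] results (undefined ones are
#'   ignored).
#' @param deprotect_threshold PF below this is a de-protection vote
#'   (default 0.7).
#' @return list with `residue` (data.frame `res_seq`, `label`,
#'   `n_covering`) and `segments` (data.frame `start`, `end`, `label`),
#'   covering exactly the union of peptide spans.
#' @export
region_consensus <- function(results, deprotect_threshold = 0.7) {
  stopifnot(deprotect_threshold > 0, deprotect_threshold < 1)
  results <- Filter(function(r) !isTRUE(r$undefined), results)
  if (!length(results)) stop("no defined protection factors to combine")
  spans <- lapply(results, function(r) r$start_res:r$end_res)
  res_all <- sort(unique(unlist(spans)))
  lab <- character(length(res_all))
  ncov <- integer(length(res_all))
  pfs <- vapply(results, `[[`, numeric(1L), "pf")
  votes <- ifelse(pfs < deprotect_threshold, "deprotected",
                  ifelse(pfs > 1 / deprotect_threshold, "protected",
                         "unaffected"))
  for (k in seq_along(res_all)) {
    r <- res_all[k]
    cov <- vapply(results, function(x) r >= x$start_res && r <= x$end_res,
                  logical(1L))
    ncov[k] <- sum(cov)
    if (!ncov[k]) { lab[k] <- "no_coverage"; next }
    tab <- table(factor(votes[cov],
                        levels = c("deprotected", "protected", "unaffected")))
    lab[k] <- names(tab)[which.max(tab)]   # which.max: first max wins the tie
  }
  residue <- data.frame(res_seq = res_all, label = lab, n_covering = ncov)
  # contiguous runs (gaps in residue numbering always split segments)
  brk <- c(TRUE, diff(res_all) != 1L | lab[-1L] != lab[-length(lab)])
  grp <- cumsum(brk)
  segments <- do.call(rbind, lapply(split(seq_along(res_all), grp), function(ix)
    data.frame(start = res_all[ix[1L]], end = res_all[ix[length(ix)]],
               label = lab[ix[1L]])))
  rownames(segments) <- NULL
  list(residue = residue, segments = segments)
}

#' Read a peak-intensity table (TSV)
#'
#' Expected columns: `res_seq`, `apo_intensity`, `perturbed_intensity`,
#' optionally `h_ppm_apo`, `n_ppm_apo`, `h_ppm_perturbed`,
#' `n_ppm_perturbed`, `overlapped`, `unassigned`.
#' @param path TSV file with a header row.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read an uptake-curve table (TSV) into a list of curves
#'
#' Expected columns: `peptide_start`, `peptide_end`, `time_s`, `uptake`,
#' optional `sd`. Rows are grouped by peptide bounds.
#' @param path TSV file with a header row.
#' @return named list of [uptake_curve()] objects (`"start-end"` keys).
#' @export
read_uptake_table <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE)
  key <- paste(d$peptide_start, d$peptide_end, sep = "-")
  lapply(split(d, key), function(g) {
    g <- g[order(g$time_s), ]
    uptake_curve(g$peptide_start[1L], g$peptide_end[1L], g$time_s, g$uptake,
                 sd = if (!is.null(g$sd)) g$sd)
  })
}
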