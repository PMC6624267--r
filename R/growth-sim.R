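# Exact stochastic (Gillespie) nucleation-elongation-capping simulator.
#
# Model: monomer species carry two interface faces. A filament grows only at
# its "b"-face end (+z end of the lattice): an incoming monomer binds through
# its own "a" face (so it must be a-face functional) and then presents its
# "b" face for the next addition. A monomer whose b face is dead therefore
# permanently caps the filament. Primary nucleation consumes n* monomers,
# all of which must be fully functional on both faces. Optional
# depolymerization removes the terminal monomer of an uncapped filament.

#' Monomer species specification
#' @param name species label.
#' @param count initial free monomer count (particles, >= 0).
#' @param a_face_functional can bind to a growing end (default TRUE).
#' @param b_face_functional can accept the next monomer after incorporation
#'   (default TRUE); a FALSE value makes the species a capper.
#' @param labeled marks the species whose polymerized fraction is reported
#'   as the fluorescence-polarization proxy (default FALSE).
#' @return object of class `species_spec`.
#' @export
species_spec <- function(name, count, a_face_functional = TRUE,
                         b_face_functional = TRUE, labeled = FALSE) {
  stopifnot(count >= 0)
  structure(list(name = name, count = as.integer(count),
                 a_face_functional = isTRUE(a_face_functional),
                 b_face_functional = isTRUE(b_face_functional),
                 labeled = isTRUE(labeled)),
            class = "species_spec")
}

#' Kinetic parameters for the polymerization simulator
#' @param k_nuc primary nucleation rate constant, per distinct
#'   n*-combination of fully functional free monomers per unit time.
#' @param nucleus_size critical nucleus size n* (integer >= 2, default 4).
#' @param k_on elongation rate constant, per free bindable monomer per
#'   uncapped filament end per unit time.
#' @param k_off depolymerization rate per uncapped filament end per unit
#'   time (default 0).
#' @param t_end simulated time span.
#' @param n_samples number of evenly spaced sample points recorded
#'   (default 201).
#' @return object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_nuc = 2e-11, nucleus_size = 4L, k_on = 5e-4,
                           k_off = 0, t_end = 200, n_samples = 201L) {
  stopifnot(k_nuc >= 0, k_on >= 0, k_off >= 0, t_end > 0,
            nucleus_size >= 2L, n_samples >= 2L)
  structure(list(k_nuc = k_nuc, nucleus_size = as.integer(nucleus_size),
                 k_on = k_on, k_off = k_off, t_end = t_end,
                 n_samples = as.integer(n_samples)),
            class = "kinetic_params")
}

#' Simulate nucleation-elongation-capping polymerization
#'
#' Exact Gillespie simulation of the reaction set described above. All
#' randomness flows from `rng_seed`, so identical inputs give identical
#' event sequences. Total monomer count (free + polymerized) is conserved at
#' every event, and a capped filament never changes after capping.
#'
#' @param params a [kinetic_params()] object.
#' @param species list of [species_spec()] objects (>= 1), or a single spec.
#' @param seeds optional list of pre-formed filaments, each a list with
#'   `length` (subunits, counted against no species pool) or a vector
#'   `composition` of species names; seeds are uncapped unless
#'   `capped = TRUE`.
#' @param rng_seed integer seed (default 1).
#' @return object of class `polymer_trajectory`: list with `samples` (a
#'   data.frame: `time`, `free_<species>`, `poly_<species>`, `n_filaments`,
#'   `capped_fraction`, `polymer_mass`, `polymer_mass_fraction`,
#'   `fp_proxy`), `filaments` (final per-filament `length`, `capped`),
#'   `params`, `species_names`, `n_events`.
#' @export
simulate_polymerization <- function(params, species, seeds = list(),
                                    rng_seed = 1L) {
  stopifnot(inherits(params, "kinetic_params"))
  if (inherits(species, "species_spec")) species <- list(species)
  if (!length(species) && !length(seeds))
    stop("need at least one species or one seed")
  sp_names <- vapply(species, `[[`, character(1L), "name")
  if (anyDuplicated(sp_names)) stop("duplicate species names")
  ns <- length(species)
  free <- vapply(species, `[[`, integer(1L), "count")
  a_ok <- vapply(species, `[[`, logical(1L), "a_face_functional")
  b_ok <- vapply(species, `[[`, logical(1L), "b_face_functional")
  labeled <- vapply(species, `[[`, logical(1L), "labeled")
  full_ok <- a_ok & b_ok
  nstar <- params$nucleus_size

  # filament state: per-filament species sequence (0 = anonymous seed subunit)
  fil <- list(); capped <- logical(0)
  for (s in seeds) {
    if (!is.null(s$composition)) {
      comp <- match(s$composition, sp_names)
      if (anyNA(comp)) stop("seed composition names unknown species")
    } else {
      comp <- rep(0L, s$length)
    }
    fil[[length(fil) + 1L]] <- comp
    capped <- c(capped, isTRUE(s$capped))
  }

  poly <- integer(ns)                   # polymerized count per species
  for (f in fil) for (k in f) if (k > 0L) poly[k] <- poly[k] + 1L
  seed_mass0 <- sum(vapply(fil, length, integer(1L)))
  total_monomers <- sum(free) + sum(poly) +
    (seed_mass0 - sum(vapply(fil, function(f) sum(f > 0L), integer(1L))))

  set.seed(as.integer(rng_seed))
  t_now <- 0
  sample_times <- seq(0, params$t_end, length.out = params$n_samples)
  next_sample <- 1L
  n_events <- 0L
  rows <- vector("list", params$n_samples)

  snap <- function() {
    lens <- vapply(fil, length, integer(1L))
    mass <- sum(lens)
    lab_free <- sum(free[labeled]); lab_poly <- sum(poly[labeled])
    c(time = t_now,
      if (ns) stats::setNames(as.numeric(free), paste0("free_", sp_names)),
      if (ns) stats::setNames(as.numeric(poly), paste0("poly_", sp_names)),
      n_filaments = length(fil),
      capped_fraction = if (length(fil)) mean(capped) else 0,
      polymer_mass = mass,
      polymer_mass_fraction = if (total_monomers > 0) mass / total_monomers else 0,
      fp_proxy = if (lab_free + lab_poly > 0) lab_poly / (lab_free + lab_poly)
                 else NA_real_)
  }

  static_warned <- FALSE
  repeat {
    m_full <- sum(free[full_ok])
    a_nuc <- if (m_full >= nstar) params$k_nuc * choose(m_full, nstar) else 0
    A_bind <- sum(free[a_ok])
    open_f <- which(!capped)
    shrinkable <- open_f[vapply(fil[open_f], length, integer(1L)) > 0L]
    a_el <- params$k_on * A_bind * length(open_f)
    a_off <- params$k_off * length(shrinkable)
    a_tot <- a_nuc + a_el + a_off

    if (a_tot <= 0) {
      if (!length(fil) && !static_warned && sum(free) > 0) {
        warning("no reactions possible: trajectory is static")
        static_warned <- TRUE
      }
      t_next <- Inf
    } else {
      t_next <- t_now + stats::rexp(1L, a_tot)
    }

    while (next_sample <= params$n_samples &&
           sample_times[next_sample] <= min(t_next, params$t_end)) {
      t_save <- t_now; t_now <- sample_times[next_sample]
      rows[[next_sample]] <- snap()
      t_now <- t_save
      next_sample <- next_sample + 1L
    }
    if (next_sample > params$n_samples || t_next > params$t_end) break
    t_now <- t_next
    n_events <- n_events + 1L

    u <- stats::runif(1L) * a_tot
    if (u < a_nuc) {
      # draw n* fully functional monomers without replacement
      pool <- rep(seq_len(ns), free * full_ok)
      pick <- sample(pool, nstar)
      for (k in pick) { free[k] <- free[k] - 1L; poly[k] <- poly[k] + 1L }
      fil[[length(fil) + 1L]] <- pick
      capped <- c(capped, FALSE)
    } else if (u < a_nuc + a_el) {
      fi <- open_f[sample.int(length(open_f), 1L)]
      w <- free * a_ok
      k <- sample.int(ns, 1L, prob = w)
      free[k] <- free[k] - 1L; poly[k] <- poly[k] + 1L
      fil[[fi]] <- c(fil[[fi]], k)
      if (!b_ok[k]) capped[fi] <- TRUE
    } else {
      fi <- shrinkable[sample.int(length(shrinkable), 1L)]
      f <- fil[[fi]]
      k <- f[length(f)]
      fil[[fi]] <- f[-length(f)]
      if (k > 0L) { free[k] <- free[k] + 1L; poly[k] <- poly[k] - 1L }
      if (!length(fil[[fi]])) { fil[[fi]] <- NULL; capped <- capped[-fi] }
    }
  }

  lens <- vapply(fil, length, integer(1L))
  structure(list(
    samples = as.data.frame(do.call(rbind, rows)),
    filaments = data.frame(length = lens, capped = capped),
    params = params, species_names = sp_names, n_events = n_events,
    rng_seed = as.integer(rng_seed)),
    class = "polymer_trajectory")
}

#' @export
print.polymer_trajectory <- function(x, ...) {
  last <- x$samples[nrow(x$samples), ]
  cat(sprintf(paste0("<trajectory> %d events, %d filaments at t = %g\n",
                     "  polymer mass fraction %.3f, capped fraction %.3f\n"),
              x$n_events, last$n_filaments, last$time,
              last$polymer_mass_fraction, last$capped_fraction))
  invisible(x)
}

#' @export
plot.polymer_trajectory <- function(x, ...) {
  s <- x$samples
  plot(s$time, s$polymer_mass_fraction, type = "l", xlab = "time",
       ylab = "polymer mass fraction (turbidity proxy)", ylim = c(0, 1), ...)
  invisible(x)
}

#' Lag time of a trajectory
#'
#' First sampled time at which the polymer mass fraction reaches
#' `threshold` (default 10%). Returns `Inf` (censored) if never reached.
#' @param trajectory a `polymer_trajectory`.
#' @param threshold mass fraction (default 0.1).
#' @return time (possibly `Inf`).
#' @export
lag_time <- function(trajectory, threshold = 0.1) {
  s <- trajectory$samples
  hit <- which(s$polymer_mass_fraction >= threshold)
  if (length(hit)) s$time[hit[1L]] else Inf
}

#' Interface-mutant capping assay
#'
#' Compares wild-type polymerization against polymerization in the presence
#' of an interface-dead mutant at a given molar ratio, with matched random
#' seeds per replicate (paired design). `a_dead` mutants cannot bind a
#' growing end and are expected to leave growth unchanged; `b_dead` mutants
#' incorporate and permanently cap, suppressing wild-type polymer mass.
#'
#' @param params a [kinetic_params()] object.
#' @param wt_count wild-type monomer count.
#' @param mutant `"a_dead"` or `"b_dead"`.
#' @param ratio mutant:wild-type molar ratio (>= 0; default 1).
#' @param n_replicates paired replicates (default 100).
#' @param base_seed first replicate seed (replicate r uses `base_seed + r`).
#' @param alpha one-sided significance level for the paired Wilcoxon test of
#'   reduced wild-type polymer mass (default 0.01).
#' @return object of class `capping_assay`: list with `endpoint`
#'   (per-replicate data.frame), `effect` (means, difference, 95% CI),
#'   `p_value`, `significant`, `mutant`, `ratio`.
#' @export
capping_assay <- function(params, wt_count, mutant = c("b_dead", "a_dead"),
                          ratio = 1, n_replicates = 100L, base_seed = 1L,
                          alpha = 0.01) {
  mutant <- match.arg(mutant)
  stopifnot(ratio >= 0, n_replicates >= 2L)
  mut_spec <- if (mutant == "a_dead")
    species_spec("mutant", round(ratio * wt_count), a_face_functional = FALSE)
  else
    species_spec("mutant", round(ratio * wt_count), b_face_functional = FALSE)
  run <- function(with_mutant, seed) {
    sp <- list(species_spec("WT", wt_count))
    if (with_mutant && mut_spec$count > 0L) sp <- c(sp, list(mut_spec))
    tr <- simulate_polymerization(params, sp, rng_seed = seed)
    last <- tr$samples[nrow(tr$samples), ]
    c(wt_poly = last$poly_WT,
      mean_length = if (nrow(tr$filaments)) mean(tr$filaments$length) else 0,
      capped_fraction = last$capped_fraction)
  }
  reps <- lapply(seq_len(n_replicates), function(r) {
    seed <- base_seed + r
    ctrl <- run(FALSE, seed); trt <- run(TRUE, seed)
    data.frame(replicate = r,
               control_wt_poly = ctrl[["wt_poly"]],
               treated_wt_poly = trt[["wt_poly"]],
               control_mean_length = ctrl[["mean_length"]],
               treated_mean_length = trt[["mean_length"]],
               treated_capped_fraction = trt[["capped_fraction"]])
  })
  ep <- do.call(rbind, reps)
  diffs <- ep$control_wt_poly - ep$treated_wt_poly
  p <- if (all(diffs == 0)) 1 else
    stats::wilcox.test(ep$control_wt_poly, ep$treated_wt_poly,
                       paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  ci <- stats::t.test(diffs)$conf.int
  structure(list(
    endpoint = ep,
    effect = list(control_mean = mean(ep$control_wt_poly),
                  treated_mean = mean(ep$treated_wt_poly),
                  mean_difference = mean(diffs), ci95 = as.numeric(ci)),
    p_value = p, significant = p < alpha, alpha = alpha,
    mutant = mutant, ratio = ratio),
    class = "capping_assay")
}

#' @export
print.capping_assay <- function(x, ...) {
  cat(sprintf(paste0("<capping assay> %s mutant at %.2g:1\n",
                     "  WT polymer at endpoint: control %.1f, treated %.1f\n",
                     "  paired one-sided p = %.3g (%ssignificant at alpha = %g)\n"),
              x$mutant, x$ratio, x$effect$control_mean, x$effect$treated_mean,
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Seeded-nucleation assay
#'
#' Paired comparison of lag times (time to 10% polymer mass) with and
#' without pre-formed seed filaments, sharing the random seed per replicate.
#' Seeding bypasses the nucleation barrier, so the seeded median lag should
#' be shorter whenever nucleation is rate-limiting.
#'
#' @param params a [kinetic_params()] object.
#' @param seed_count number of pre-formed filaments (each of
#'   `seed_length` anonymous subunits).
#' @param monomer_count free monomer pool (> 0).
#' @param seed_length subunits per pre-formed filament (default
#'   `params$nucleus_size`).
#' @param n_replicates paired replicates (default 25).
#' @param base_seed first replicate seed.
#' @param threshold lag-time mass fraction (default 0.1).
#' @return object of class `seeding_assay`: list with `lags` (per-replicate
#'   seeded/unseeded, `Inf` = censored), `median_seeded`,
#'   `median_unseeded`, `n_censored`.
#' @export
seeded_nucleation_assay <- function(params, seed_count, monomer_count,
                                    seed_length = NULL, n_replicates = 25L,
                                    base_seed = 1L, threshold = 0.1) {
  stopifnot(monomer_count > 0, seed_count >= 0)
  if (is.null(seed_length)) seed_length <- params$nucleus_size
  seeds <- if (seed_count > 0)
    replicate(seed_count, list(length = seed_length), simplify = FALSE)
  else list()
  lag1 <- function(seeded, seed) {
    tr <- simulate_polymerization(
      params, list(species_spec("WT", monomer_count)),
      seeds = if (seeded) seeds else list(), rng_seed = seed)
    lag_time(tr, threshold)
  }
  lags <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    s <- base_seed + r
    data.frame(replicate = r, seeded = lag1(TRUE, s),
               unseeded = lag1(FALSE, s))
  }))
  structure(list(lags = lags,
                 median_seeded = stats::median(lags$seeded),
                 median_unseeded = stats::median(lags$unseeded),
                 n_censored = sum(!is.finite(c(lags$seeded, lags$unseeded))),
                 threshold = threshold),
            class = "seeding_assay")
}

#' @export
print.seeding_assay <- function(x, ...) {
  cat(sprintf(paste0("<seeding assay> median lag to %.0f%% polymer mass:\n",
                     "  seeded %g, unseeded %g (%d censored runs)\n"),
              100 * x$threshold, x$median_seeded, x$median_unseeded,
              x$n_censored))
  invisible(x)
}
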