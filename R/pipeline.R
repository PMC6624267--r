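# Reproducible run orchestration: each subcommand reads its inputs, applies
# parameter overrides, writes TSV/PDB/JSON outputs into an output directory,
# and records a run manifest (inputs, package version, seed, effective
# parameters) sufficient to reproduce the run.

.hc_log <- function(level, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " [", level, "] ",
                ...)
  message(msg)
}

.write_tsv <- function(d, path, header_params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_params))
    writeLines(paste0("# ", names(header_params), " = ",
                      vapply(header_params, function(x)
                        paste(format(x), collapse = ","), character(1L))), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.known_config_keys <- c(
  "protomer", "structure", "peaks", "uptake_reference", "uptake_test",
  "rise", "twist", "n_subunits", "cutoff", "low", "high",
  "deprotect_threshold", "probe_radius", "n_points",
  "k_nuc", "nucleus_size", "k_on", "k_off", "t_end", "n_samples",
  "monomer_count", "seed_count", "n_core", "res_range", "chain", "mode",
  "seed", "out_dir", "log_level")

#' Assemble and validate a pipeline configuration
#'
#' Plain key-value configuration (a YAML file and/or an override list;
#' overrides win). Unknown keys are rejected; the effective configuration
#' is echoed into every output header and the run manifest.
#'
#' @param config_file optional YAML file of key-value pairs.
#' @param overrides named list of overrides (e.g. from CLI flags).
#' @return named list of validated configuration values.
#' @export
pipeline_config <- function(config_file = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    cfg <- yaml::read_yaml(config_file)
    if (is.null(cfg)) cfg <- list()
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Run one pipeline stage
#'
#' Subcommands:
#' * `synth`: generate the toy protomer (and a perturbation dataset) into
#'   the output directory.
#' * `filament-build`: build a filament from a protomer PDB and
#'   rise/twist/n_subunits; writes a multi-chain PDB.
#' * `filament-fit`: fit helical parameters from a multi-chain filament
#'   PDB; writes a TSV of per-pair screws and a JSON summary.
#' * `interfaces`: neighbor enumeration + typed interface report for a
#'   built filament (protomer + parameters).
#' * `ensemble-stats`: ensemble RMSD (both modes) and per-residue
#'   dihedrals for a multi-model PDB.
#' * `nmr-map`: classify a peak table.
#' * `hdx-map`: protection factors + residue consensus from reference/test
#'   uptake TSVs.
#' * `simulate`: run the polymerization simulator; writes the trajectory
#'   TSV and an endpoint JSON.
#'
#' Every run writes `manifest.json` (inputs, package version, seed,
#' effective parameters, outputs). Any stage error is propagated with the
#' stage name; the CLI wrapper converts it into a non-zero exit.
#'
#' @param subcommand one of the stage names above.
#' @param config a [pipeline_config()] list (or named list).
#' @param out_dir output directory (created if needed; default
#'   `config$out_dir` or "helicard-out").
#' @return named list of output file paths (invisibly), plus the manifest
#'   path.
#' @export
run_pipeline <- function(subcommand = c("synth", "filament-build",
                                        "filament-fit", "interfaces",
                                        "ensemble-stats", "nmr-map",
                                        "hdx-map", "simulate"),
                         config = list(), out_dir = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- pipeline_config(overrides = config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir %||% "helicard-out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed %||% 1L)
  .hc_log("INFO", "stage ", subcommand, " (seed ", seed, ") -> ", out_dir)

  outputs <- tryCatch(
    switch(subcommand,
      "synth" = {
        prot <- make_toy_protomer(n_core = cfg$n_core %||% 20L,
                                  rng_seed = seed)
        p1 <- file.path(out_dir, "toy_protomer.pdb")
        write_structure(prot, p1)
        ds <- make_perturbation_dataset(rng_seed = seed)
        p2 <- file.path(out_dir, "peaks.tsv")
        write_peak_table(ds$peaks, p2)
        p3 <- file.path(out_dir, "uptake_reference.tsv")
        write_uptake_table(ds$reference_curves, p3)
        p4 <- file.path(out_dir, "uptake_test.tsv")
        write_uptake_table(ds$test_curves, p4)
        list(protomer = p1, peaks = p2, uptake_reference = p3,
             uptake_test = p4)
      },
      "filament-build" = {
        if (is.null(cfg$protomer)) stop("missing input: protomer")
        prot <- get_model(read_structure(cfg$protomer), 1L)
        params <- helical_parameters(cfg$rise %||% 5.1, cfg$twist %||% -101.6)
        fl <- build_filament(prot, params, cfg$n_subunits %||% 10L)
        p1 <- file.path(out_dir, "filament.pdb")
        fm <- filament_model(fl)
        write_structure(fm[, setdiff(names(fm), "subunit")], p1)
        list(filament = p1)
      },
      "filament-fit" = {
        if (is.null(cfg$structure)) stop("missing input: structure")
        m <- get_model(read_structure(cfg$structure), 1L)
        fit <- fit_helical_params(m)
        p1 <- file.path(out_dir, "helical_fit.tsv")
        .write_tsv(fit$per_pair, p1, cfg)
        p2 <- file.path(out_dir, "helical_fit.json")
        jsonlite::write_json(list(rise = fit$rise, twist = fit$twist,
                                  rise_sd = fit$rise_sd,
                                  twist_sd = fit$twist_sd,
                                  n_subunits = fit$n_subunits),
                             p2, auto_unbox = TRUE, digits = NA)
        list(fit_tsv = p1, fit_json = p2)
      },
      "interfaces" = {
        if (is.null(cfg$protomer)) stop("missing input: protomer")
        prot <- get_model(read_structure(cfg$protomer), 1L)
        params <- helical_parameters(cfg$rise %||% 5.1, cfg$twist %||% -101.6)
        fl <- build_filament(prot, params, cfg$n_subunits %||% 10L)
        cutoff <- cfg$cutoff %||% 4.5
        nb <- enumerate_contacting_neighbors(fl, cutoff = cutoff)
        p1 <- file.path(out_dir, "neighbors.tsv")
        .write_tsv(nb, p1, c(cfg, list(cutoff = cutoff)))
        rep <- interface_report(fl, "filament_typed", cutoff = cutoff)
        p2 <- file.path(out_dir, "interface_report.tsv")
        .write_tsv(rep, p2, c(cfg, list(cutoff = cutoff)))
        interior <- with(nb, subunit >= 4 & subunit <= fl$n_subunits - 5)
        counts <- table(nb$subunit[interior])
        p3 <- file.path(out_dir, "interfaces_summary.json")
        jsonlite::write_json(list(
          cutoff = cutoff,
          interior_neighbor_count = if (length(counts))
            as.numeric(counts[1L]) else 0), p3, auto_unbox = TRUE, digits = NA)
        list(neighbors = p1, report = p2, summary = p3)
      },
      "ensemble-stats" = {
        if (is.null(cfg$structure)) stop("missing input: structure")
        ens <- read_structure(cfg$structure)
        rr <- cfg$res_range
        stats_tm <- ensemble_rmsd(ens, res_range = rr,
                                  atoms = c("N", "CA", "C", "O"),
                                  mode = "to_mean")
        stats_mp <- ensemble_rmsd(ens, res_range = rr,
                                  atoms = c("N", "CA", "C", "O"),
                                  mode = "mean_pairwise")
        p1 <- file.path(out_dir, "ensemble_rmsd.tsv")
        .write_tsv(stats_tm$per_model, p1,
                   c(cfg, list(mode = "to_mean",
                               mean_rmsd = stats_tm$mean_rmsd)))
        dh <- backbone_dihedrals(get_model(ens, 1L), chain = cfg$chain)
        p2 <- file.path(out_dir, "dihedrals.tsv")
        .write_tsv(dh, p2, cfg)
        p3 <- file.path(out_dir, "ensemble_summary.json")
        jsonlite::write_json(list(n_models = n_models(ens),
                                  rmsd_to_mean = stats_tm$mean_rmsd,
                                  rmsd_mean_pairwise = stats_mp$mean_rmsd),
                             p3, auto_unbox = TRUE, digits = NA)
        list(rmsd = p1, dihedrals = p2, summary = p3)
      },
      "nmr-map" = {
        if (is.null(cfg$peaks)) stop("missing input: peaks")
        peaks <- read_peak_table(cfg$peaks)
        cls <- intensity_ratio_classify(peaks, low = cfg$low %||% 0.25,
                                        high = cfg$high %||% 0.50)
        p1 <- file.path(out_dir, "broadening_classes.tsv")
        .write_tsv(cls, p1, cfg)
        list(classes = p1)
      },
      "hdx-map" = {
        if (is.null(cfg$uptake_reference) || is.null(cfg$uptake_test))
          stop("missing input: uptake_reference/uptake_test")
        refs <- read_uptake_table(cfg$uptake_reference)
        tsts <- read_uptake_table(cfg$uptake_test)
        common <- intersect(names(refs), names(tsts))
        pfs <- lapply(common, function(k) protection_factor(refs[[k]], tsts[[k]]))
        pf_tab <- data.frame(
          peptide = common,
          start = vapply(pfs, `[[`, integer(1L), "start_res"),
          end = vapply(pfs, `[[`, integer(1L), "end_res"),
          pf = vapply(pfs, `[[`, numeric(1L), "pf"))
        p1 <- file.path(out_dir, "protection_factors.tsv")
        .write_tsv(pf_tab, p1, cfg)
        cons <- region_consensus(pfs,
          deprotect_threshold = cfg$deprotect_threshold %||% 0.7)
        p2 <- file.path(out_dir, "consensus_segments.tsv")
        .write_tsv(cons$segments, p2, cfg)
        list(protection_factors = p1, segments = p2)
      },
      "simulate" = {
        params <- kinetic_params(
          k_nuc = cfg$k_nuc %||% 2e-11,
          nucleus_size = cfg$nucleus_size %||% 4L,
          k_on = cfg$k_on %||% 5e-4, k_off = cfg$k_off %||% 0,
          t_end = cfg$t_end %||% 200,
          n_samples = cfg$n_samples %||% 201L)
        tr <- simulate_polymerization(
          params, list(species_spec("WT", cfg$monomer_count %||% 500L)),
          rng_seed = seed)
        p1 <- file.path(out_dir, "trajectory.tsv")
        .write_tsv(tr$samples, p1, cfg)
        last <- tr$samples[nrow(tr$samples), ]
        p2 <- file.path(out_dir, "simulation_summary.json")
        jsonlite::write_json(list(
          n_events = tr$n_events,
          polymer_mass_fraction = last$polymer_mass_fraction,
          n_filaments = last$n_filaments,
          lag_time = lag_time(tr)), p2, auto_unbox = TRUE, digits = NA)
        list(trajectory = p1, summary = p2)
      }),
    error = function(e) stop("stage '", subcommand, "' failed: ",
                             conditionMessage(e), call. = FALSE))

  manifest <- list(
    subcommand = subcommand,
    package_version = as.character(utils::packageVersion("helicard")),
    r_version = as.character(getRversion()),
    seed = seed,
    parameters = cfg,
    inputs = cfg[intersect(names(cfg),
                           c("protomer", "structure", "peaks",
                             "uptake_reference", "uptake_test"))],
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .hc_log("INFO", "stage ", subcommand, " complete; manifest at ", mp)
  invisible(c(outputs, list(manifest = mp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
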