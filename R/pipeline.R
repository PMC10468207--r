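#' Run configuration
#'
#' A single human-readable configuration drives a reproducible pipeline run:
#' one global seed governs all stochastic stages through derived sub-streams,
#' and every stage's tunable parameters live under its own section.  Unknown
#' keys are rejected, so typos fail loudly rather than silently falling back
#' to defaults.
#'
#' @param seed integer global seed.
#' @param outdir output directory for tables and the JSON report.
#' @param stages character vector of stages to run, in order, from
#'   `c("synth", "kinetics", "xlms", "masspt", "imaging")`.
#' @param kinetics,xlms,masspt,imaging named lists of stage parameters;
#'   omitted entries take the documented defaults (the resolved values are
#'   echoed in the run report).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = tempfile("holophos_run_"),
                       stages = c("synth", "kinetics", "xlms", "masspt", "imaging"),
                       kinetics = list(), xlms = list(), masspt = list(),
                       imaging = list()) {
  known_stages <- c("synth", "kinetics", "xlms", "masspt", "imaging")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) abort_validation(paste("unknown stage(s):", paste(bad, collapse = ", ")))

  defaults <- list(
    kinetics = list(saturating = 100, truth = list(A1 = 0.6, r1 = 0.3, k2 = 0.004,
                                                   noise_sd = 0.05)),
    xlms = list(scenario = "ihp", n_crosslinks = 200L, hetero_ratio = 0.25,
                denominator = "homotypic_sum", hetero_floor = 0),
    masspt = list(monomer_kda = 55, candidates = c(1L, 2L, 4L, 12L, 24L, 28L),
                  ligand_kda = 16.7, ligand_count = 1L,
                  components = list(mean = c(110, 592, 1320),
                                    sd = c(15, 30, 60),
                                    weight = c(0.05, 0.85, 0.10)),
                  n_events = 10000L),
    imaging = list(top_fraction = 0.01, alpha = 0.05, control = "basal",
                   coloc_fractions = c(basal = 0.05, activated = 0.6),
                   n_images = 3L)
  )
  merge_params <- function(user, def, stage) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) {
      abort_validation(sprintf("unknown %s parameter(s): %s", stage,
                               paste(bad, collapse = ", ")))
    }
    utils::modifyList(def, user)
  }
  structure(list(
    seed = as.integer(seed), outdir = outdir, stages = stages,
    kinetics = merge_params(kinetics, defaults$kinetics, "kinetics"),
    xlms = merge_params(xlms, defaults$xlms, "xlms"),
    masspt = merge_params(masspt, defaults$masspt, "masspt"),
    imaging = merge_params(imaging, defaults$imaging, "imaging"),
    version = as.character(utils::packageVersion("holophos"))
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return a [run_config()] (read) or the path invisibly (write).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- c("seed", "outdir", "stages", "kinetics", "xlms", "masspt", "imaging")
  bad <- setdiff(names(y), known)
  if (length(bad)) abort_validation(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config a [run_config()].
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[c("seed", "outdir", "stages", "kinetics",
                                     "xlms", "masspt", "imaging")], path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order (synthetic inputs first, then each
#' analysis), writes all tables under `config$outdir`, and returns (and
#' writes) a machine-readable JSON report recording the resolved parameters,
#' per-stage results, record-count bookkeeping (inputs = used + excluded,
#' with reasons), the package version and the seed.  Idempotent given an
#' identical configuration.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly; written to
#'   `file.path(config$outdir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, version = config$version,
                 stages = config$stages, parameters = unclass(config)[
                   c("kinetics", "xlms", "masspt", "imaging")])

  failed <- NULL
  for (stage in config$stages) {
    res <- tryCatch(
      switch(stage,
        synth = run_stage_synth(config),
        kinetics = run_stage_kinetics(config),
        xlms = run_stage_xlms(config),
        masspt = run_stage_masspt(config),
        imaging = run_stage_imaging(config)
      ),
      error = function(e) structure(list(error = conditionMessage(e)),
                                    class = "stage_failure")
    )
    report[[stage]] <- if (inherits(res, "stage_failure")) unclass(res) else res
    if (inherits(res, "stage_failure")) {
      failed <- stage
      break
    }
  }
  report$failed_stage <- failed
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(failed)) {
    stop(errorCondition(
      sprintf("stage '%s' failed: %s (partial report written)", failed,
              report[[failed]]$error),
      class = c("holophos_pipeline_error", "error")))
  }
  invisible(report)
}

run_stage_synth <- function(config) {
  kt <- do.call(kinetic_truth,
                c(config$kinetics$truth, list(seed = substream_seed(config$seed, 11L))))
  tc <- gen_timecourse(kt)
  write_timecourse_tsv(tc, file.path(config$outdir, "timecourse.tsv"))

  scn <- xl_scenario(config$xlms$scenario, n_crosslinks = config$xlms$n_crosslinks,
                     hetero_ratio = config$xlms$hetero_ratio,
                     seed = substream_seed(config$seed, 12L))
  xl <- gen_xl_table(scn)
  write_xl_tsv(xl, file.path(config$outdir, "crosslinks.tsv"))

  mm <- mass_mixture_truth(as.data.frame(config$masspt$components),
                           n_events = config$masspt$n_events,
                           seed = substream_seed(config$seed, 13L))
  ev <- gen_mass_events(mm)
  write_mass_csv(ev, file.path(config$outdir, "mass_events.csv"))

  list(n_timecourse_rows = nrow(tc), n_crosslink_rows = nrow(xl),
       n_mass_events = length(ev))
}

run_stage_kinetics <- function(config) {
  tc <- read_timecourse_tsv(file.path(config$outdir, "timecourse.tsv"))
  fit <- fit_global(tc, saturating = config$kinetics$saturating)
  list(A1 = fit$A1, r1 = fit$r1, k2 = fit$k2,
       weighted_rss = fit$weighted_rss,
       half_times = as.list(fit$half_times),
       n_obs_in = nrow(tc), n_obs_used = fit$n_obs,
       n_obs_excluded = nrow(tc) - fit$n_obs)
}

run_stage_xlms <- function(config) {
  xl <- read_xl_tsv(file.path(config$outdir, "crosslinks.tsv"))
  q <- compute_R(xl, denominator = config$xlms$denominator,
                 hetero_floor = config$xlms$hetero_floor)
  het <- build_heatmap(q, "heterotypic", require_both_replicates = TRUE,
                       hetero_floor = config$xlms$hetero_floor)
  hom <- build_heatmap(q, "homotypic", require_both_replicates = TRUE,
                       hetero_floor = config$xlms$hetero_floor)
  ratios <- summarize_ratios(q)
  utils::write.table(ratios, file.path(config$outdir, "ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_undef <- sum(!q$R_defined)
  list(n_records_in = nrow(xl), n_R_defined = sum(q$R_defined),
       n_R_undefined = n_undef,
       heterotypic_heatmap = unclass(het)[,], homotypic_heatmap = unclass(hom)[,],
       ratios = ratios)
}

run_stage_masspt <- function(config) {
  ev <- read_mass_csv(file.path(config$outdir, "mass_events.csv"))
  fit <- decompose_masses(ev, monomer_mass = config$masspt$monomer_kda,
                          candidates = config$masspt$candidates,
                          ligand_mass = config$masspt$ligand_kda,
                          ligand_count = config$masspt$ligand_count)
  utils::write.table(fit$peaks, file.path(config$outdir, "mass_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(n_events_in = length(ev), n_events_used = fit$n_events,
       n_events_excluded = length(ev) - fit$n_events, peaks = fit$peaks)
}

run_stage_imaging <- function(config) {
  fracs <- config$imaging$coloc_fractions
  scores <- list()
  for (cond in names(fracs)) {
    for (i in seq_len(config$imaging$n_images)) {
      tr <- spot_image_truth(coloc_fraction = fracs[[cond]],
                             seed = substream_seed(config$seed, 20L + 10L * i +
                                                     match(cond, names(fracs))))
      pair <- gen_spot_images(tr)
      cr <- pearson_coloc(pair$channel_1, pair$channel_2,
                          top_fraction = config$imaging$top_fraction,
                          condition = cond, replicate = i)
      scores[[length(scores) + 1L]] <-
        data.frame(condition = cond, replicate = i, pearson_r = cr$pearson_r,
                   n_pixels = cr$n_pixels_used)
    }
  }
  scores <- do.call(rbind, scores)
  utils::write.table(scores, file.path(config$outdir, "coloc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp <- compare_to_control(data.frame(condition = scores$condition,
                                       value = scores$pearson_r),
                            control = config$imaging$control,
                            alpha = config$imaging$alpha)
  list(n_image_pairs = nrow(scores), scores = scores, comparisons = cmp)
}
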