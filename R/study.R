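#' Run the full study pipeline
#'
#' End-to-end driver: synthesize the sample cohort, generate the virtual
#' population by Gibbs sampling, simulate both therapy arms for a subset of
#' the population, and compare them. All stage outputs are written to
#' `out_dir` (cohort and population CSVs, per-arm outcome CSVs, a
#' comparison report JSON and a manifest recording seeds, sizes and the
#' configuration hash), so a manifest plus the package version suffices to
#' reproduce every table. The run is deterministic given `seeds`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Model configuration from [twin_config()].
#' @param seeds Named list with integer `sample`, `population` and
#'   `variability` seeds.
#' @param n_burn,n_keep Gibbs sampler sizes (study values: 20000 / 3000).
#' @param n_simulate Number of population members simulated in each arm
#'   (the comparison scales linearly in this; 200 gives a faithful
#'   scaled-down comparison).
#' @param check_interval_h Twin-policy checkpoint interval (h).
#' @param horizon_h Therapy horizon (h).
#' @return The `ft_comparison` object, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_study <- function(out_dir, config = twin_config(),
                      seeds = list(sample = 1, population = 2, variability = 3),
                      n_burn = 20000, n_keep = 3000, n_simulate = 200,
                      check_interval_h = 8, horizon_h = 72) {
  require_config_sections(config)
  stopifnot(all(c("sample", "population", "variability") %in% names(seeds)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t_start <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(stage, ...)))
  }

  log_stage("sample: synthesizing 20-patient cohort (seed %d)", seeds$sample)
  cohort <- generate_sample_cohort(seed = seeds$sample)
  write_cohort(cohort, file.path(out_dir, "sample.csv"))

  log_stage("population: Gibbs sampler burn %d keep %d (seed %d)",
            n_burn, n_keep, seeds$population)
  pop <- gibbs_sample_population(
    cohort, gibbs_config(n_burn, n_keep, seed = seeds$population)
  )
  write_cohort(pop, file.path(out_dir, "population.csv"))

  n_simulate <- min(n_simulate, nrow(pop))
  sim_pop <- pop[seq_len(n_simulate), ]
  log_stage("simulate: %d patients, conventional arm", n_simulate)
  conv <- simulate_population(
    sim_pop, therapy_policy("conventional", horizon_h = horizon_h),
    config, seed = seeds$variability
  )
  readr::write_csv(conv, file.path(out_dir, "outcomes_conventional.csv"))

  log_stage("simulate: %d patients, twin-assisted arm", n_simulate)
  twin <- simulate_population(
    sim_pop,
    therapy_policy("twin_assisted", check_interval_h = check_interval_h,
                   vas_target = config$thresholds$vas_target,
                   horizon_h = horizon_h),
    config, seed = seeds$variability
  )
  readr::write_csv(twin, file.path(out_dir, "outcomes_twin.csv"))

  log_stage("compare: population outcome report")
  comparison <- population_compare(conv, twin, horizon_h = horizon_h)
  report <- list(
    arms = tidy(comparison),
    deltas = glance(comparison),
    correlations = comparison$correlations,
    subgroup = list(
      n_subgroup = comparison$subgroup$n_subgroup,
      tests = comparison$subgroup$tests,
      female_male_ratio = as.list(comparison$subgroup$female_male_ratio)
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)

  manifest <- list(
    package = "fentatwin",
    version = as.character(utils::packageVersion("fentatwin")),
    seeds = seeds,
    sizes = list(n_sample = nrow(cohort), n_burn = n_burn, n_keep = n_keep,
                 n_simulate = n_simulate),
    policy = list(check_interval_h = check_interval_h,
                  horizon_h = horizon_h,
                  vas_target = config$thresholds$vas_target),
    config_hash = config_hash(config),
    elapsed_s = round(as.numeric(Sys.time() - t_start, units = "secs"), 1)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(comparison)
}

# stable content hash of a configuration (djb2 over its YAML serialization)
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config), precision = 15)
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
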