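#' Per-patient therapy outcomes
#'
#' Summarizes one simulated therapy: plasma and effect extrema over the
#' hourly grid, total and longest-contiguous time without pain (VAS
#' strictly below 3, durations computed by linear interpolation between
#' hourly samples at the threshold crossings), patch count and the safety
#' flags (plasma above the toxicity threshold, ventilation below the
#' hypoventilation threshold).
#'
#' @param sim An `ft_simulation` from [run_simulation()].
#' @param thresholds Threshold list (`config$thresholds`).
#' @return One-row tibble with `max_c_p_ng_ml`, `min_vas`, `mean_vas`,
#'   `min_ventilation_L_min`, `mean_ventilation_L_min`,
#'   `time_without_pain_h`, `time_without_pain_longest_h`, `n_patches`,
#'   `toxicity_exceeded`, `hypoventilation`.
#' @export
patient_outcomes <- function(sim, thresholds = sim$twin$config$thresholds) {
  stopifnot(inherits(sim, "ft_simulation"))
  s <- sim$series
  pain_free <- time_below_threshold(s$time_h, s$vas, thresholds$vas_target)
  tibble::tibble(
    max_c_p_ng_ml = max(s$c_p_ng_ml),
    min_vas = min(s$vas),
    mean_vas = mean(s$vas),
    min_ventilation_L_min = min(s$ventilation_L_min),
    mean_ventilation_L_min = mean(s$ventilation_L_min),
    time_without_pain_h = pain_free$total,
    time_without_pain_longest_h = pain_free$longest,
    n_patches = length(sim$patch_events_h),
    toxicity_exceeded = max(s$c_p_ng_ml) > thresholds$toxicity_ng_ml,
    hypoventilation = min(s$ventilation_L_min) < thresholds$hypoventilation_L_min
  )
}

#' Duration below a threshold for a piecewise-linear signal
#'
#' Measures the total time, and the longest contiguous time, a sampled
#' signal spends *strictly* below `threshold`, treating the signal as
#' linear between samples and locating the crossings exactly. Samples equal
#' to the threshold do not count as below it.
#'
#' @param time Sample times (increasing).
#' @param value Sampled signal.
#' @param threshold Threshold value.
#' @return List with `total` and `longest` durations (same unit as `time`).
#' @export
time_below_threshold <- function(time, value, threshold) {
  stopifnot(length(time) == length(value), !is.unsorted(time))
  total <- 0
  longest <- 0
  run <- 0
  for (i in seq_len(length(time) - 1)) {
    dt <- time[i + 1] - time[i]
    v0 <- value[i] - threshold
    v1 <- value[i + 1] - threshold
    if (v0 < 0 && v1 < 0) {
      below <- dt
    } else if (v0 >= 0 && v1 >= 0) {
      below <- 0
    } else {
      frac <- v0 / (v0 - v1)  # crossing position within the segment
      below <- if (v0 < 0) dt * frac else dt * (1 - frac)
    }
    total <- total + below
    if (below == dt) {
      run <- run + dt
    } else {
      # partial segments close (and possibly start) a contiguous run
      run <- run + if (v0 < 0) below else 0
      longest <- max(longest, run)
      run <- if (v1 < 0) below else 0
      if (v0 >= 0 && v1 >= 0) run <- 0
    }
    longest <- max(longest, run)
  }
  list(total = total, longest = longest)
}

#' Compare conventional and twin-assisted therapy over a population
#'
#' Paired comparison of the two arms on the same patients: percent changes
#' of the population mean and SD of the per-patient average pain, median
#' and interquartile range of time without pain, the fraction of patients
#' whose pain stays below target for more than half the horizon, percent
#' changes of mean plasma concentration and mean ventilation, Pearson
#' correlations of outcomes with the covariates, and the heavy-user
#' subgroup analysis of the twin arm.
#'
#' @param conventional,twin_assisted Outcome tables from
#'   [simulate_population()] (same patients, same order not required).
#' @param horizon_h Therapy horizon used for the half-duration fraction.
#' @return A list of class `ft_comparison`: `arms` (per-arm summary
#'   tibble), `deltas` (named changes, conventional -> twin),
#'   `correlations` (outcome x covariate tibble per arm) and `subgroup`
#'   (see [subgroup_heavy_users()]).
#' @export
population_compare <- function(conventional, twin_assisted, horizon_h = 72) {
  if (!setequal(conventional$id, twin_assisted$id) ||
      nrow(conventional) != nrow(twin_assisted)) {
    stop("The two arms must contain the same patients.")
  }
  conventional <- dplyr::arrange(conventional, .data$id)
  twin_assisted <- dplyr::arrange(twin_assisted, .data$id)

  summarize_arm <- function(df, arm) {
    tibble::tibble(
      arm = arm,
      mean_pain = mean(df$mean_vas),
      sd_pain = stats::sd(df$mean_vas),
      median_time_without_pain_h = stats::median(df$time_without_pain_h),
      iqr_time_without_pain_h = stats::IQR(df$time_without_pain_h),
      fraction_pain_free_half = mean(df$time_without_pain_h > horizon_h / 2),
      mean_max_c_p_ng_ml = mean(df$max_c_p_ng_ml),
      mean_ventilation_L_min = mean(df$mean_ventilation_L_min),
      mean_n_patches = mean(df$n_patches)
    )
  }
  arms <- dplyr::bind_rows(summarize_arm(conventional, "conventional"),
                           summarize_arm(twin_assisted, "twin_assisted"))
  pct <- function(a, b) if (a == 0) NA_real_ else 100 * (b - a) / a
  deltas <- list(
    pain_pct = pct(arms$mean_pain[1], arms$mean_pain[2]),
    pain_sd_pct = pct(arms$sd_pain[1], arms$sd_pain[2]),
    median_time_without_pain_delta_h =
      arms$median_time_without_pain_h[2] - arms$median_time_without_pain_h[1],
    iqr_time_without_pain_pct =
      pct(arms$iqr_time_without_pain_h[1], arms$iqr_time_without_pain_h[2]),
    fraction_pain_free_half =
      c(conventional = arms$fraction_pain_free_half[1],
        twin_assisted = arms$fraction_pain_free_half[2]),
    plasma_pct = pct(arms$mean_max_c_p_ng_ml[1], arms$mean_max_c_p_ng_ml[2]),
    ventilation_pct =
      pct(arms$mean_ventilation_L_min[1], arms$mean_ventilation_L_min[2])
  )

  cor_arm <- function(df, arm) {
    covars <- tibble::tibble(
      age = df$age_years, weight = df$weight_kg, height = df$height_m,
      bmi = df$weight_kg / df$height_m^2
    )
    purrr::map_dfr(names(covars), function(cv) {
      # degenerate outcomes (e.g. a constant patch count) have no defined
      # correlation; report NA quietly
      tibble::tibble(
        arm = arm, covariate = cv,
        cor_time_without_pain = suppressWarnings(
          stats::cor(df$time_without_pain_h, covars[[cv]])
        ),
        cor_n_patches = suppressWarnings(stats::cor(df$n_patches, covars[[cv]]))
      )
    })
  }
  correlations <- dplyr::bind_rows(cor_arm(conventional, "conventional"),
                                   cor_arm(twin_assisted, "twin_assisted"))
  structure(
    list(arms = arms, deltas = deltas, correlations = correlations,
         subgroup = subgroup_heavy_users(twin_assisted,
                                         horizon_days = horizon_h / 24),
         tables = list(conventional = conventional,
                       twin_assisted = twin_assisted)),
    class = "ft_comparison"
  )
}

#' Heavy-user subgroup analysis
#'
#' Selects the patients who needed more than one patch per day under the
#' twin-assisted policy and compares their age, weight and height
#' distributions, and their gender composition, against the full
#' population. Because the underlying test is not uniquely determined,
#' both a Welch t-test and a two-sample Kolmogorov-Smirnov test are
#' reported for each covariate. An empty subgroup yields missing tests,
#' not an error.
#'
#' @param twin_assisted Outcome table of the twin arm (needs `n_patches`).
#' @param horizon_days Therapy duration in days; the subgroup criterion is
#'   `n_patches > horizon_days`.
#' @return A list: `n_subgroup`, `ids`, `tests` (tibble with mean shift,
#'   Welch and KS p-values per covariate), `female_male_ratio` (subgroup
#'   and population).
#' @export
subgroup_heavy_users <- function(twin_assisted, horizon_days = 3) {
  stopifnot("n_patches" %in% names(twin_assisted))
  heavy <- twin_assisted$n_patches > horizon_days
  ratio <- function(g) {
    if (sum(g == 1) == 0) NA_real_ else sum(g == 0) / sum(g == 1)
  }
  covars <- c(age = "age_years", weight = "weight_kg", height = "height_m")
  tests <- purrr::map_dfr(names(covars), function(nm) {
    col <- covars[[nm]]
    sub <- twin_assisted[[col]][heavy]
    all_v <- twin_assisted[[col]]
    if (sum(heavy) < 2 || sum(!heavy) < 2) {
      tibble::tibble(covariate = nm, mean_shift = NA_real_,
                     p_welch = NA_real_, p_ks = NA_real_)
    } else {
      tibble::tibble(
        covariate = nm,
        mean_shift = mean(sub) - mean(all_v),
        p_welch = stats::t.test(sub, all_v[!heavy])$p.value,
        p_ks = suppressWarnings(
          stats::ks.test(sub, all_v[!heavy])$p.value
        )
      )
    }
  })
  list(
    n_subgroup = sum(heavy),
    ids = twin_assisted$id[heavy],
    tests = tests,
    female_male_ratio = c(
      subgroup = if (sum(heavy) == 0) NA_real_
                 else ratio(twin_assisted$gender[heavy]),
      population = ratio(twin_assisted$gender)
    )
  )
}

#' @export
print.ft_comparison <- function(x, ...) {
  cat("Conventional vs digital-twin-assisted therapy\n")
  print(x$arms)
  d <- x$deltas
  cat(sprintf("mean pain: %+.1f%%, pain SD: %+.1f%%\n",
              d$pain_pct, d$pain_sd_pct))
  cat(sprintf("median time without pain: %+.1f h, IQR: %+.1f%%\n",
              d$median_time_without_pain_delta_h, d$iqr_time_without_pain_pct))
  cat(sprintf("pain-free > half horizon: %.1f%% -> %.1f%%\n",
              100 * d$fraction_pain_free_half[["conventional"]],
              100 * d$fraction_pain_free_half[["twin_assisted"]]))
  cat(sprintf("mean peak plasma: %+.1f%%, mean ventilation: %+.1f%%\n",
              d$plasma_pct, d$ventilation_pct))
  invisible(x)
}
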