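#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its hourly series
#'
#' @param x An `ft_simulation`.
#' @param ... Unused.
#' @return The hourly series tibble.
#' @method tidy ft_simulation
#' @export
tidy.ft_simulation <- function(x, ...) x$series

#' One-row outcome summary of a simulation
#'
#' @param x An `ft_simulation`.
#' @param ... Unused.
#' @return The [patient_outcomes()] row.
#' @method glance ft_simulation
#' @export
glance.ft_simulation <- function(x, ...) patient_outcomes(x)

#' Tidy a cohort summary
#'
#' @param x An `ft_cohort_summary`.
#' @param ... Unused.
#' @return The per-covariate moments tibble.
#' @method tidy ft_cohort_summary
#' @export
tidy.ft_cohort_summary <- function(x, ...) x$moments

#' @rdname tidy.ft_cohort_summary
#' @method glance ft_cohort_summary
#' @export
glance.ft_cohort_summary <- function(x, ...) {
  tibble::tibble(n = x$n, male_count = x$male_count,
                 female_count = x$female_count,
                 cor_gender_height = x$pearson["gender", "height_m"],
                 cor_gender_weight = x$pearson["gender", "weight_kg"],
                 cor_weight_height = x$pearson["weight_kg", "height_m"])
}

#' Tidy an arm comparison
#'
#' @param x An `ft_comparison`.
#' @param ... Unused.
#' @return `tidy()` returns the per-arm summary tibble; `glance()` one row
#'   with the headline changes from conventional to twin-assisted therapy.
#' @method tidy ft_comparison
#' @export
tidy.ft_comparison <- function(x, ...) x$arms

#' @rdname tidy.ft_comparison
#' @method glance ft_comparison
#' @export
glance.ft_comparison <- function(x, ...) {
  d <- x$deltas
  tibble::tibble(
    pain_pct = d$pain_pct,
    pain_sd_pct = d$pain_sd_pct,
    median_time_without_pain_delta_h = d$median_time_without_pain_delta_h,
    iqr_time_without_pain_pct = d$iqr_time_without_pain_pct,
    fraction_pain_free_half_conventional =
      d$fraction_pain_free_half[["conventional"]],
    fraction_pain_free_half_twin =
      d$fraction_pain_free_half[["twin_assisted"]],
    plasma_pct = d$plasma_pct,
    ventilation_pct = d$ventilation_pct
  )
}

#' Plot a simulated therapy
#'
#' Plasma concentration, VAS pain score and minute ventilation against
#' time, with the toxicity, pain-target and hypoventilation thresholds and
#' the patch application times.
#'
#' @param object An `ft_simulation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ft_simulation
#' @export
autoplot.ft_simulation <- function(object, ...) {
  th <- object$twin$config$thresholds
  long <- tidyr::pivot_longer(
    object$series[, c("time_h", "c_p_ng_ml", "vas", "ventilation_L_min")],
    -"time_h", names_to = "signal", values_to = "value"
  )
  refs <- tibble::tibble(
    signal = c("c_p_ng_ml", "vas", "ventilation_L_min"),
    value = c(th$toxicity_ng_ml, th$vas_target, th$hypoventilation_L_min)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$patch_events_h,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          c_p_ng_ml = "plasma fentanyl [ng/ml]",
                          vas = "VAS pain score",
                          ventilation_L_min = "minute ventilation [L/min]"
                        ))) +
    ggplot2::labs(x = "time [h]", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot population covariate distributions
#'
#' @param object An `ft_population` (or `ft_cohort`) tibble.
#' @param ... Unused.
#' @return A ggplot object with per-gender covariate densities.
#' @method autoplot ft_population
#' @export
autoplot.ft_population <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object),
                  gender = ifelse(.data$gender == 1, "male", "female")),
    c("age_years", "weight_kg", "height_m"),
    names_to = "covariate", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$gender)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~covariate, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}

#' @method autoplot ft_cohort
#' @export
autoplot.ft_cohort <- autoplot.ft_population

#' Plot the arm comparison
#'
#' Distribution of time without pain per therapy arm.
#'
#' @param object An `ft_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ft_comparison
#' @export
autoplot.ft_comparison <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$tables$conventional, arm = "conventional"),
    dplyr::mutate(object$tables$twin_assisted, arm = "twin-assisted")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm,
                                   y = .data$time_without_pain_h)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "time without pain [h]") +
    ggplot2::theme_minimal()
}
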