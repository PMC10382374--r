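#' Synthetic 20-patient sample cohort
#'
#' The individual-level records of the clinical cohort behind the study are
#' unpublished; only summary statistics are available: 10 women and 10 men,
#' ages 40-68, age 56.75 (SD 9.82) years, weight 72.8 (SD 14.8) kg, height
#' 1.70 (SD 0.12) m, and point-biserial/Pearson correlations
#' gender-height 0.87, gender-weight 0.43, weight-height 0.38 (gender coded
#' male = 1, female = 0). `generate_sample_cohort()` constructs a synthetic
#' stand-in whose *empirical* moments and correlations match those targets
#' exactly (up to numerical tolerance), so that it can serve as likelihood
#' data for virtual-population generation.
#'
#' Construction: gender is fixed at n/2 males and n/2 females; weight and
#' height are drawn from a Gaussian copula and then affinely re-standardized
#' against the standardized gender column so the target means, SDs and the
#' three target correlations hold exactly. Age is drawn from a beta shape on
#' the printed 40-68 range, re-standardized to the exact target mean/SD, and
#' redrawn until all values stay inside the range. Weight/height pairs are
#' redrawn until every BMI lies in 15-45 kg/m^2 (the validated range of the
#' dermis-thickness equation). The whole procedure is deterministic given
#' `seed`.
#'
#' @param seed Integer seed; the cohort is reproducible bit-for-bit.
#' @param n Cohort size, even (half male, half female). Default 20.
#' @param targets Named list of target summary values; see
#'   [cohort_targets()] for the defaults taken from the printed summaries.
#' @return A tibble of class `ft_cohort` with columns `id`, `age_years`,
#'   `gender` (1 = male, 0 = female), `weight_kg`, `height_m`.
#' @examples
#' cohort <- generate_sample_cohort(seed = 1)
#' summarize_cohort(cohort)
#' @export
generate_sample_cohort <- function(seed, n = 20, targets = cohort_targets()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n %% 2 != 0 || n < 6) {
    stop("`n` must be an even number >= 6 (half male, half female).")
  }
  tg <- targets
  # gender/weight/height target correlation matrix must be PSD before any
  # draws are attempted
  rho <- matrix(c(
    1, tg$cor_gender_weight, tg$cor_gender_height,
    tg$cor_gender_weight, 1, tg$cor_weight_height,
    tg$cor_gender_height, tg$cor_weight_height, 1
  ), 3, 3, dimnames = list(c("gender", "weight", "height"),
                           c("gender", "weight", "height")))
  r_g <- c(tg$cor_gender_weight, tg$cor_gender_height)
  resid_cov <- rho[2:3, 2:3] - tcrossprod(r_g)
  chol_resid <- tryCatch(chol(resid_cov), error = function(e) NULL)
  if (is.null(chol_resid) || any(eigen(rho, only.values = TRUE)$values < -1e-10)) {
    stop(
      "Target correlation matrix for (gender, weight, height) is not ",
      "positive semi-definite after gender dichotomization; cannot ",
      "construct a matching cohort."
    )
  }

  withr_seed(seed, {
    gender <- rep(c(1, 0), each = n / 2)
    g_std <- standardize(gender)

    for (try in seq_len(500L)) {
      # residual scores orthogonal to gender, whitened to unit sample cov
      z <- matrix(stats::rnorm(n * 2), n, 2)
      e <- whiten_residuals(z, cbind(1, gender))
      x_std <- outer(g_std, r_g) + e %*% chol_resid
      weight <- tg$weight_mean + tg$weight_sd * x_std[, 1]
      height <- tg$height_mean + tg$height_sd * x_std[, 2]
      bmi <- weight / height^2
      ok <- all(weight >= 30, weight <= 150, height >= 1.2, height <= 2.2,
                bmi >= 15, bmi <= 45)
      if (ok) break
      if (try == 500L) stop("Could not draw a cohort satisfying BMI bounds.")
    }

    for (try in seq_len(500L)) {
      # U-shaped beta on the printed range gives a sample whose exact
      # re-standardization can honour both the SD and the range bounds
      shape <- beta_shape_for(
        (tg$age_mean - tg$age_min) / (tg$age_max - tg$age_min),
        tg$age_sd / (tg$age_max - tg$age_min)
      )
      raw <- tg$age_min +
        (tg$age_max - tg$age_min) * stats::rbeta(n, shape[1], shape[2])
      age <- tg$age_mean + tg$age_sd * standardize(raw)
      if (all(age >= tg$age_min & age <= tg$age_max)) break
      if (try == 500L) stop("Could not draw ages inside the target range.")
    }

    new_cohort(tibble::tibble(
      id = seq_len(n),
      age_years = age,
      gender = gender,
      weight_kg = weight,
      height_m = height
    ))
  })
}

#' Printed summary targets for the sample cohort
#'
#' @return Named list of the marginal means/SDs, the age range and the three
#'   cross-correlations the synthetic cohort is matched to.
#' @export
cohort_targets <- function() {
  list(
    age_mean = 56.75, age_sd = 9.82, age_min = 40, age_max = 68,
    weight_mean = 72.8, weight_sd = 14.8,
    height_mean = 1.70, height_sd = 0.12,
    cor_gender_height = 0.87,
    cor_gender_weight = 0.43,
    cor_weight_height = 0.38
  )
}

#' Summarize a cohort or population
#'
#' Exact sample moments (SD with denominator n-1) and the 4x4 Pearson
#' correlation matrix over (gender, age, weight, height), gender treated as
#' 0/1 numeric. Correlations that are undefined (zero variance, e.g. a
#' single-gender cohort) are reported as `NA`, never as zero.
#'
#' @param cohort A tibble with columns `age_years`, `gender`, `weight_kg`,
#'   `height_m` (as produced by [generate_sample_cohort()] or
#'   [gibbs_sample_population()]).
#' @return A list of class `ft_cohort_summary`: `n`, `male_count`,
#'   `female_count`, a `moments` tibble (mean/sd per covariate) and
#'   `pearson`, the correlation matrix.
#' @export
summarize_cohort <- function(cohort) {
  validate_patients(cohort)
  x <- as.data.frame(cohort[, c("gender", "age_years", "weight_kg", "height_m")])
  n <- nrow(x)
  if (n < 1) stop("Cohort is empty.")
  moments <- tibble::tibble(
    variable = c("age_years", "weight_kg", "height_m"),
    mean = unname(vapply(x[, c("age_years", "weight_kg", "height_m")], mean, 0)),
    sd = unname(vapply(x[, c("age_years", "weight_kg", "height_m")], stats::sd, 0))
  )
  sds <- vapply(x, stats::sd, 0)
  pearson <- matrix(NA_real_, 4, 4, dimnames = list(names(x), names(x)))
  ok <- which(is.finite(sds) & sds > 0)
  if (length(ok) >= 2) {
    pearson[ok, ok] <- suppressWarnings(stats::cor(x[, ok, drop = FALSE]))
  }
  diag(pearson) <- 1
  structure(
    list(
      n = n,
      male_count = sum(x$gender == 1),
      female_count = sum(x$gender == 0),
      moments = moments,
      pearson = pearson
    ),
    class = "ft_cohort_summary"
  )
}

#' @export
print.ft_cohort_summary <- function(x, ...) {
  cat("Cohort summary: n =", x$n,
      sprintf("(%d male / %d female)\n", x$male_count, x$female_count))
  print(x$moments)
  cat("Pearson correlations:\n")
  print(round(x$pearson, 3))
  invisible(x)
}

#' Read and write cohort/population CSV files
#'
#' The on-disk dialect is a plain CSV with header
#' `id,age_years,gender,weight_kg,height_m` and gender coded 0/1.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns an `ft_cohort` tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_patients(cohort)
  readr::write_csv(
    cohort[, c("id", "age_years", "gender", "weight_kg", "height_m")], path
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  validate_patients(df)
  new_cohort(tibble::as_tibble(df))
}

# ---- internal helpers -------------------------------------------------------

new_cohort <- function(df) {
  class(df) <- unique(c("ft_cohort", class(df)))
  df
}

#' Validate patient-profile invariants
#'
#' Checks the covariate bounds every patient row must satisfy:
#' age in 18-100 years, weight in 30-150 kg, height in 1.2-2.2 m and gender
#' coded 0/1.
#'
#' @param df Data frame of patient rows.
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_patients <- function(df) {
  need <- c("age_years", "gender", "weight_kg", "height_m")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("Patient table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) return(invisible(df))
  with(df, {
    if (!all(gender %in% c(0, 1))) stop("gender must be coded 0/1")
    if (!all(age_years >= 18 & age_years <= 100)) stop("age outside [18, 100]")
    if (!all(weight_kg >= 30 & weight_kg <= 150)) stop("weight outside [30, 150]")
    if (!all(height_m >= 1.2 & height_m <= 2.2)) stop("height outside [1.2, 2.2]")
  })
  invisible(df)
}

# standardize to empirical mean 0, sd 1 (denominator n-1)
standardize <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("Cannot standardize a constant vector.")
  (v - mean(v)) / s
}

# residualize columns of z against the column space of m, then whiten so the
# sample covariance (denominator n-1) is exactly the identity
whiten_residuals <- function(z, m) {
  qr_m <- qr(m)
  resid <- z - m %*% qr.coef(qr_m, z)
  resid <- sweep(resid, 2, colMeans(resid))
  cv <- crossprod(resid) / (nrow(resid) - 1)
  resid %*% solve(chol(cv))
}

# beta shape parameters for a given mean/sd on the unit interval
beta_shape_for <- function(m, s) {
  v <- s^2
  if (v >= m * (1 - m)) stop("Infeasible beta moments.")
  tot <- m * (1 - m) / v - 1
  c(m * tot, (1 - m) * tot)
}

# evaluate code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}
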