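#' Gibbs-sampler configuration for virtual-population generation
#'
#' The virtual population is drawn from the posterior implied by the
#' 20-patient sample cohort: gender is Bernoulli(p) with a uniform
#' (Beta(1,1)) prior on p; conditional on gender, (age, weight, height) is
#' multivariate normal with a normal-inverse-Wishart prior centred on the
#' per-gender sample moments. The study runs `n_burn = 20000` burn-in
#' iterations and keeps `n_keep = 3000` iterations, each kept iteration
#' emitting one posterior-predictive patient, so the kept count *is* the
#' population size.
#'
#' @param n_burn Burn-in iterations (>= 0). Default 20000.
#' @param n_keep Kept iterations = population size (>= 1). Default 3000.
#' @param seed Integer seed for the chain.
#' @param prior_strength Pseudo-observation count of the
#'   normal-inverse-Wishart prior (weakly informative; default 1).
#' @param draw `"predictive"` (default) emits a posterior-predictive patient
#'   per kept iteration; `"parameter_mean"` emits the current per-gender
#'   posterior mean vector instead, which produces the much tighter
#'   population spread that pure parameter uncertainty would give.
#' @return A list of class `ft_gibbs_config`.
#' @export
gibbs_config <- function(n_burn = 20000, n_keep = 3000, seed = 1,
                         prior_strength = 1,
                         draw = c("predictive", "parameter_mean")) {
  stopifnot(n_burn >= 0, n_keep >= 1, prior_strength > 0)
  structure(
    list(n_burn = as.integer(n_burn), n_keep = as.integer(n_keep),
         seed = as.integer(seed), prior_strength = prior_strength,
         draw = match.arg(draw)),
    class = "ft_gibbs_config"
  )
}

#' Generate a virtual patient population by Gibbs sampling
#'
#' Runs a Gibbs sampler on the joint model of (gender, age, weight, height)
#' described in [gibbs_config()], using `sample` as the likelihood data.
#' Every kept iteration emits one patient; draws violating the patient
#' covariate bounds (see [validate_patients()]) are rejected and redrawn at
#' the current parameter state. The chain, and therefore the population, is
#' reproducible bit-for-bit for a fixed sample and configuration.
#'
#' @param sample Sample cohort tibble (needs >= 2 members of each gender).
#' @param config An [gibbs_config()] list.
#' @return A tibble of class `ft_population` with the cohort columns; the
#'   generating config and sample summary are attached as attributes
#'   `config` and `sample_summary`.
#' @examples
#' sample <- generate_sample_cohort(seed = 1)
#' pop <- gibbs_sample_population(sample, gibbs_config(500, 200, seed = 2))
#' population_diagnostics(pop)
#' @export
gibbs_sample_population <- function(sample, config = gibbs_config()) {
  validate_patients(sample)
  stopifnot(inherits(config, "ft_gibbs_config"))
  x_all <- as.matrix(sample[, c("age_years", "weight_kg", "height_m")])
  gender <- sample$gender
  n_m <- sum(gender == 1)
  n_f <- sum(gender == 0)
  if (n_m < 2 || n_f < 2) {
    stop("Need at least 2 sample members of each gender, got ",
         n_m, " male / ", n_f, " female.")
  }
  d <- 3
  groups <- lapply(c(male = 1, female = 0), function(g) {
    x <- x_all[gender == g, , drop = FALSE]
    s <- stats::cov(x)
    if (inherits(tryCatch(chol(s), error = identity), "error")) {
      warning("Per-gender sample covariance not positive definite; ",
              "regularizing the diagonal by 1e-8.")
      s <- s + diag(1e-8, d)
    }
    list(x = x, n = nrow(x), xbar = colMeans(x), s = s)
  })

  kappa0 <- config$prior_strength
  nu0 <- d + 2  # weakest integer dof with E[Sigma] defined (= prior scale)
  predictive <- config$draw == "predictive"

  withr_seed(config$seed, {
    # initialize at the sample moments
    state <- lapply(groups, function(gr) list(mu = gr$xbar, sigma = gr$s))
    out <- matrix(NA_real_, config$n_keep, d)
    out_gender <- integer(config$n_keep)
    total <- config$n_burn + config$n_keep
    for (it in seq_len(total)) {
      p_male <- stats::rbeta(1, 1 + n_m, 1 + n_f)
      for (g in c("male", "female")) {
        gr <- groups[[g]]
        st <- state[[g]]
        kappa_n <- kappa0 + gr$n
        mu_n <- (kappa0 * gr$xbar + gr$n * gr$xbar) / kappa_n  # prior centred on sample mean
        # mu | sigma, data
        st$mu <- drop(mu_n + t(chol(st$sigma / kappa_n)) %*% stats::rnorm(d))
        # sigma | mu, data (inverse-Wishart)
        dev <- sweep(gr$x, 2, st$mu)
        scale_n <- gr$s + crossprod(dev) +
          kappa0 * tcrossprod(st$mu - gr$xbar)
        st$sigma <- inv_wishart_draw(nu0 + gr$n + 1, scale_n)
        state[[g]] <- st
      }
      if (it > config$n_burn) {
        k <- it - config$n_burn
        g_draw <- stats::rbinom(1, 1, p_male)
        st <- if (g_draw == 1) state$male else state$female
        for (attempt in seq_len(1000L)) {
          xi <- if (predictive) {
            drop(st$mu + t(chol(st$sigma)) %*% stats::rnorm(d))
          } else {
            st$mu
          }
          if (profile_in_bounds(xi)) break
          if (!predictive) break
          if (attempt == 1000L) stop("Rejection sampling failed to find an ",
                                     "in-bounds patient draw.")
        }
        out[k, ] <- xi
        out_gender[k] <- g_draw
      }
    }
    pop <- tibble::tibble(
      id = seq_len(config$n_keep),
      age_years = out[, 1],
      gender = out_gender,
      weight_kg = out[, 2],
      height_m = out[, 3]
    )
    pop <- new_cohort(pop)
    class(pop) <- unique(c("ft_population", class(pop)))
    attr(pop, "config") <- config
    attr(pop, "sample_summary") <- summarize_cohort(sample)
    validate_patients(pop)
    pop
  })
}

#' Population diagnostics
#'
#' Same contract as [summarize_cohort()], applied to a generated virtual
#' population: exact moments and the Pearson correlation matrix over
#' (gender, age, weight, height).
#'
#' @param pop An `ft_population` tibble.
#' @return An `ft_cohort_summary` list.
#' @export
population_diagnostics <- function(pop) {
  summarize_cohort(pop)
}

# ---- internal ---------------------------------------------------------------

profile_in_bounds <- function(x) {
  bmi <- x[2] / x[3]^2
  x[1] >= 18 && x[1] <= 100 && x[2] >= 30 && x[2] <= 150 &&
    x[3] >= 1.2 && x[3] <= 2.2 && bmi >= 15 && bmi <= 45
}

# draw from an inverse-Wishart(nu, scale) via the Wishart of the inverse scale
inv_wishart_draw <- function(nu, scale) {
  w <- stats::rWishart(1, df = nu, Sigma = chol2inv(chol(scale)))[, , 1]
  chol2inv(chol(w))
}
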