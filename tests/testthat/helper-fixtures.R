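# shared fixtures: a reference patient, deterministic configs and a fast
# coarse-numerics config for controller-logic tests

ref_patient <- function() {
  tibble::tibble(id = 1, age_years = 58, gender = 1,
                 weight_kg = 74.2, height_m = 1.73)
}

det_config <- function(...) {
  twin_config(variability = list(sd_theta = 0), ...)
}

coarse_config <- function(...) {
  dots <- list(...)
  num <- list(cells_per_layer = 8, dt_s = 600)
  if (!is.null(dots$numerics)) num[names(dots$numerics)] <- dots$numerics
  dots$numerics <- num
  do.call(twin_config, c(list(variability = list(sd_theta = 0)), dots))
}

small_population <- function(n_keep = 300, seed = 2) {
  sample <- generate_sample_cohort(seed = 1)
  gibbs_sample_population(sample, gibbs_config(500, n_keep, seed = seed))
}

# analytic series solution for a single uniform slab (capacity 1, uniform
# initial concentration c0, no-flux top, zero concentration at the bottom):
# independent oracle for the finite-volume solver
slab_series <- function(x, t, L, d, c0, n_terms = 400) {
  k <- seq_len(n_terms)
  lam <- (2 * k - 1) * pi / (2 * L)
  a <- 2 * c0 * (-1)^(k + 1) / (lam * L)
  vapply(x, function(xi) {
    sum(a * cos(lam * xi) * exp(-d * lam^2 * t))
  }, 0)
}

slab_series_flux <- function(t, L, d, c0, n_terms = 400) {
  # -D dc/dx at x = L (positive out of the slab)
  k <- seq_len(n_terms)
  lam <- (2 * k - 1) * pi / (2 * L)
  a <- 2 * c0 * (-1)^(k + 1) / (lam * L)
  d * sum(a * lam * sin(lam * L) * exp(-d * lam^2 * t))
}

# uniform-transport variant of the default constants (turns the multilayer
# stack into one homogeneous slab)
uniform_transport <- function(d = 3.84e-12) {
  tr <- twin_config()$transport
  tr$d_patch_m2_s <- tr$d_epidermis_m2_s <- tr$d_dermis_m2_s <- d
  tr$k_patch <- tr$k_epidermis <- tr$k_dermis <- 1
  tr
}
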