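make_pk <- function(patient = ref_patient(), cfg = det_config(), ...) {
  pk <- derive_pk_parameters(patient, cfg)
  mods <- list(...)
  for (nm in names(mods)) pk[[nm]] <- mods[[nm]]
  pk
}

# pk parameters with every elimination pathway switched off
conservative_pk <- function(f_u = 1) {
  pk <- make_pk()
  pk$f_u <- f_u
  pk$k_re_per_s <- 0
  pk$cl_h_L_s <- 0
  pk$k_met_per_s <- 0
  pk
}

test_that("the all-zero state with no input is a fixed point", {
  pk <- make_pk()
  expect_equal(unname(pk_rhs(c(p = 0, r = 0, s = 0, g = 0, l = 0), pk)),
               rep(0, 5))
  expect_error(pk_rhs(c(p = -1, r = 0, s = 0, g = 0, l = 0), pk), "Negative")
})

test_that("two-compartment exchange conserves amount and matches the closed form", {
  pk <- conservative_pk(f_u = 1)
  pk$flows_L_s <- c(rapid = 2e-3, slow = 0, gut = 0, liver = 0, portal = 0)
  v_c <- pk$volumes_L[["central"]]
  v_r <- pk$volumes_L[["rapid"]]
  k1 <- 2e-3 / v_c
  k2 <- 2e-3 / v_r
  c0 <- 5
  # closed-form oracle via eigen decomposition of the reduced 2x2 system
  m <- rbind(c(-k1, 2e-3 / v_c),
             c(2e-3 / v_r, -k2))
  ts <- c(0, 600, 3600, 10 * 3600)
  ev <- eigen(m)
  x0 <- c(c0, 0)
  exact <- vapply(ts, function(t) {
    Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors, x0))[1]
  }, 0)

  # integrate the full 5-state rhs with a fine RK4 (independent path)
  state <- c(p = c0, r = 0, s = 0, g = 0, l = 0)
  dt <- 10
  t_now <- 0
  got <- c(state[["p"]])
  for (target in ts[-1]) {
    while (t_now < target - 1e-9) {
      k1v <- pk_rhs(state, pk)
      k2v <- pk_rhs(pmax(state + dt / 2 * k1v, 0), pk)
      k3v <- pk_rhs(pmax(state + dt / 2 * k2v, 0), pk)
      k4v <- pk_rhs(pmax(state + dt * k3v, 0), pk)
      state <- state + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      t_now <- t_now + dt
    }
    got <- c(got, state[["p"]])
    total <- v_c * state[["p"]] + v_r * state[["r"]]
    expect_equal(total, v_c * c0, tolerance = 1e-8)
  }
  expect_equal(got, exact, tolerance = 1e-6)
})

test_that("constant input with elimination off grows total amount linearly", {
  pk <- conservative_pk(f_u = 1)
  flux <- 5000  # ng m^-2 s^-1
  area <- 31.5e-4
  state <- c(p = 0, r = 0, s = 0, g = 0, l = 0)
  dt <- 20
  for (i in seq_len(1800)) {  # 10 h
    k1v <- pk_rhs(state, pk, flux, area)
    k2v <- pk_rhs(pmax(state + dt / 2 * k1v, 0), pk, flux, area)
    k3v <- pk_rhs(pmax(state + dt / 2 * k2v, 0), pk, flux, area)
    k4v <- pk_rhs(pmax(state + dt * k3v, 0), pk, flux, area)
    state <- state + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  total_ng <- sum(pk$volumes_L * state[c("p", "r", "s", "g", "l")]) * 1000
  expect_equal(total_ng, flux * area * 36000, tolerance = 1e-6)
})

test_that("with elimination on and input stopped, all compartments decay to zero", {
  pk <- make_pk()  # default male references: elimination on
  sys <- pk_system_matrix(pk)
  ev <- eigen(sys$m, only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))  # composed system is dynamically stable
  x <- c(p = 2, r = 1.5, s = 0.5, g = 1, l = 1)
  e_mt <- as.matrix(Matrix::expm(Matrix::Matrix(sys$m * 1000 * 3600)))
  expect_lt(max(abs(e_mt %*% x)), 1e-3)
})

test_that("the literal renal sign turns elimination into a source", {
  pk_el <- make_pk()
  pk_src <- make_pk(literal_renal_sign = TRUE)
  state <- c(p = 1, r = 0, s = 0, g = 0, l = 0)
  d_el <- pk_rhs(state, pk_el)[["p"]]
  d_src <- pk_rhs(state, pk_src)[["p"]]
  expect_equal(d_src - d_el, 2 * pk_el$k_re_per_s * pk_el$f_u * 1,
               tolerance = 1e-12)
})

test_that("effect compartments follow the first-order closed form", {
  pd <- twin_config()$pd
  expect_equal(unname(effect_rhs(c(vas = 2, rd = 2), 2, pd)), c(0, 0))
  # constant plasma: c_e(t) = c_p (1 - exp(-k_e t))
  c_p <- 1.8
  for (endpoint in c("vas", "rd")) {
    k_e <- pd[[endpoint]]$k_e_per_s
    c_e <- 0
    dt <- 1
    for (i in seq_len(round(1 / k_e))) {  # integrate to t = 1/k_e
      c_e <- c_e + dt * k_e * (c_p - c_e)  # forward Euler, dt << 1/k_e
    }
    expect_equal(c_e / c_p, 1 - exp(-1), tolerance = 2e-3)
  }
  # pain site equilibrates 2e-3/7e-4 times faster than the ventilation site
  r <- effect_rhs(c(vas = 0, rd = 0), 1, pd)
  expect_equal(r[["vas"]] / r[["rd"]], 2e-3 / 7e-4, tolerance = 1e-12)
})

test_that("clinical effects reproduce the printed baselines, midpoints and limits", {
  pd <- twin_config()$pd
  pd$vas$ec50_ng_ml <- 1.31
  z <- clinical_effects(0, 0, pd)
  expect_identical(z$vas, 8)
  expect_identical(z$ventilation_L_min, 20)
  mid <- clinical_effects(1.31, 1.14, pd)
  expect_equal(mid$vas, 8 - 8 / 2)
  expect_equal(mid$ventilation_L_min, 20 - 20 * 0.91 / 2)
  inf <- clinical_effects(1e9, 1e9, pd)
  expect_equal(inf$vas, 0, tolerance = 1e-6)
  expect_equal(inf$ventilation_L_min, 20 - 20 * 0.91, tolerance = 1e-5)
})

test_that("both responses are strictly decreasing and bounded", {
  pd <- twin_config()$pd
  pd$vas$ec50_ng_ml <- 1.31
  grid <- seq(0, 10, by = 0.05)
  eff <- clinical_effects(grid, grid, pd)
  expect_true(all(diff(eff$vas) < 0))
  expect_true(all(diff(eff$ventilation_L_min) < 0))
  expect_true(all(eff$vas >= 0 & eff$vas <= 8))
  expect_true(all(eff$ventilation_L_min >= 20 - 20 * 0.91 &
                    eff$ventilation_L_min <= 20))
  # Hill complementarity around EC50: H(a x) + H(a / x) = 1 for gamma-true
  # sigmoids; brute-force curve check
  x <- c(1.3, 2, 5)
  h1 <- hill(1.31 * x, 1.31, 2.71)
  h2 <- hill(1.31 / x, 1.31, 2.71)
  expect_equal(h1 + h2, rep(1, 3), tolerance = 1e-12)
})
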