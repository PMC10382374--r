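test_that("conventional policy uses exactly one patch in 72 h", {
  twin <- assemble_twin(ref_patient(), coarse_config(), seed = 1)
  sim <- run_simulation(twin, therapy_policy("conventional"))
  expect_equal(sim$patch_events_h, 0)
  expect_equal(nrow(sim$series), 73)
  expect_equal(sim$series$time_h, 0:72)
})

test_that("controller replaces on schedule under forced pain and never otherwise", {
  twin <- assemble_twin(ref_patient(), coarse_config(), seed = 1)
  always <- run_simulation(
    twin, therapy_policy("twin_assisted", check_interval_h = 8,
                         vas_stub = function(t) 10)
  )
  expect_equal(always$patch_events_h, seq(0, 64, by = 8))
  expect_equal(length(always$patch_events_h), 9)

  never <- run_simulation(
    twin, therapy_policy("twin_assisted", check_interval_h = 8,
                         vas_stub = function(t) 0)
  )
  expect_equal(never$patch_events_h, 0)

  # patch count bound for any interval
  for (iv in c(12, 24, 36)) {
    sim <- run_simulation(
      twin, therapy_policy("twin_assisted", check_interval_h = iv,
                           vas_stub = function(t) 10)
    )
    expect_lte(length(sim$patch_events_h), 1 + 72 / iv)
  }
  expect_error(therapy_policy("twin_assisted", check_interval_h = 5),
               "check_interval_h")
})

test_that("the 72-h checkpoint policy reduces exactly to conventional therapy", {
  twin <- assemble_twin(ref_patient(), coarse_config(), seed = 1)
  conv <- run_simulation(twin, therapy_policy("conventional"))
  twin72 <- run_simulation(twin,
                           therapy_policy("twin_assisted", check_interval_h = 72))
  expect_identical(conv$series$c_p_ng_ml, twin72$series$c_p_ng_ml)
  expect_identical(conv$patch_events_h, twin72$patch_events_h)
})

test_that("policies agree when pain never crosses the target", {
  # a twin whose pain is relieved almost immediately (very low EC50)
  cfg <- coarse_config()
  twin <- assemble_twin(ref_patient(), cfg, seed = 1)
  twin$pd$vas$ec50_ng_ml <- 0.01
  conv <- run_simulation(twin, therapy_policy("conventional"), cfg)
  tw <- run_simulation(twin, therapy_policy("twin_assisted"), cfg)
  expect_equal(tw$patch_events_h, 0)
  expect_equal(tw$series$c_p_ng_ml, conv$series$c_p_ng_ml)
})

test_that("simulated trajectories are physical", {
  cfg <- twin_config()  # variability on
  pop <- generate_sample_cohort(seed = 3)
  for (i in c(1, 11)) {  # one male, one female
    twin <- assemble_twin(pop[i, ], cfg, seed = 40 + i)
    sim <- run_simulation(twin, therapy_policy("twin_assisted"))
    s <- sim$series
    expect_true(all(s$c_p_ng_ml >= 0))
    expect_true(all(s$vas >= 0 & s$vas <= 8))
    expect_true(all(s$ventilation_L_min >= 1.8 & s$ventilation_L_min <= 20))
    expect_true(all(s$mass_patch_ng >= 0 & s$mass_skin_ng >= 0))
    expect_true(all(diff(s$n_active_sites) >= 0))
  }
})

test_that("halving the time step changes hourly plasma by far less than 0.1%", {
  twin120 <- assemble_twin(ref_patient(), det_config(), seed = 1)
  sim120 <- run_simulation(twin120, therapy_policy("conventional"))
  cfg60 <- det_config(numerics = list(dt_s = 60))
  sim60 <- run_simulation(assemble_twin(ref_patient(), cfg60, seed = 1),
                          therapy_policy("conventional"), cfg60)
  rel <- max(abs(sim120$series$c_p_ng_ml - sim60$series$c_p_ng_ml)) /
    max(sim60$series$c_p_ng_ml)
  expect_lt(rel, 1e-3)
})

test_that("engine agrees with an independent stiff ODE integration", {
  # cross-check the monolithic stepper against deSolve on the same
  # semi-discrete system (method of lines, lsoda)
  library(deSolve)
  cfg <- det_config(numerics = list(cells_per_layer = 10))
  twin <- assemble_twin(ref_patient(), cfg, seed = 1)
  sim <- run_simulation(twin, therapy_policy("conventional"), cfg)

  sys <- fentatwin:::assemble_system(
    list(fentatwin:::new_site(twin, cfg, TRUE)), twin
  )
  x0 <- fentatwin:::pack_state(
    list(fentatwin:::new_site(twin, cfg, TRUE)),
    list(pk = c(p = 0, r = 0, s = 0, g = 0, l = 0),
         effect = c(vas = 0, rd = 0)), sys
  )
  a <- as.matrix(sys$a)
  sol <- deSolve::lsoda(
    y = x0, times = seq(0, 72 * 3600, by = 3600),
    func = function(t, y, p) list(as.numeric(a %*% y)),
    rtol = 1e-9, atol = 1e-12, hmax = 6 * 3600
  )
  cp_ode <- sol[, 1 + sys$ip]
  rel <- max(abs(sim$series$c_p_ng_ml - cp_ode)) / max(cp_ode)
  expect_lt(rel, 2e-3)
})

test_that("residual depot flag controls release from replaced sites", {
  twin <- assemble_twin(ref_patient(), coarse_config(), seed = 1)
  stub <- function(t) 10
  cfg_on <- coarse_config()
  sim_on <- run_simulation(
    twin, therapy_policy("twin_assisted", check_interval_h = 24,
                         vas_stub = stub), cfg_on
  )
  cfg_off <- coarse_config(numerics = list(residual_depot = FALSE))
  twin_off <- assemble_twin(ref_patient(), cfg_off, seed = 1)
  sim_off <- run_simulation(
    twin_off, therapy_policy("twin_assisted", check_interval_h = 24,
                             vas_stub = stub), cfg_off
  )
  # discarding old depots removes their contribution: less drug in skin and
  # less input to the blood late in therapy
  expect_lt(max(sim_off$series$n_active_sites), max(sim_on$series$n_active_sites))
  late <- sim_on$series$time_h > 30
  expect_true(all(sim_on$series$mass_skin_ng[late] >
                    sim_off$series$mass_skin_ng[late]))
  expect_gt(sum(sim_on$series$flux_ng_s[late]),
            sum(sim_off$series$flux_ng_s[late]))
})

test_that("checkpoint-frequency study reproduces the per-interval pattern", {
  cfg <- det_config(numerics = list(cells_per_layer = 12, dt_s = 300))
  twin <- assemble_twin(ref_patient(), cfg, seed = 1)
  study <- checkpoint_frequency_study(twin, intervals_h = c(8, 24, 72),
                                      config = cfg)
  expect_equal(nrow(study), 3)
  # the 72-h entry is conventional therapy
  conv <- patient_outcomes(run_simulation(twin, therapy_policy("conventional"),
                                          cfg))
  expect_equal(study$time_without_pain_h[3], conv$time_without_pain_h)
  # more frequent checking never hurts pain control for this patient
  expect_gte(study$time_without_pain_h[1], study$time_without_pain_h[2])
  expect_true(all(study$min_vas >= 0 & study$max_c_p_ng_ml > 0))
})
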