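test_that("grid partitions the stack exactly with faces at the interfaces", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  total <- geo$d_patch + geo$d_sc + geo$d_vep + geo$d_edm

  # uniform widths per layer at refinement 1
  g1 <- build_grid(geo, n_cells = 25, interface_refinement = 1)
  expect_equal(sum(g1$width), total, tolerance = 1e-15)
  for (ly in unique(g1$layer)) {
    w <- g1$width[g1$layer == ly]
    expect_lt(diff(range(w)), 1e-20)
  }
  # every layer boundary coincides with a cell face
  bounds <- cumsum(c(geo$d_patch, geo$d_sc, geo$d_vep))
  expect_true(all(vapply(bounds, function(b) any(abs(g1$face - b) < 1e-15), TRUE)))

  # graded widths increase monotonically away from each interface
  g2 <- build_grid(geo, n_cells = 24, interface_refinement = 1.2)
  for (ly in unique(g2$layer)) {
    w <- g2$width[g2$layer == ly]
    half <- length(w) %/% 2
    expect_true(all(diff(w[1:half]) > 0))
    expect_true(all(diff(w[(half + 1):length(w)]) < 0))
    expect_equal(w[2] / w[1], 1.2, tolerance = 1e-12)
  }

  bad <- geo
  bad$d_sc <- 0
  expect_error(build_grid(bad), "Degenerate")
})

test_that("site initialization places the full load in the patch as potential", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  tr <- twin_config()$transport
  grid <- build_grid(geo)
  psi <- initialize_site(grid, tr, geo$patch_load_ng, geo$patch_area_m2)
  # printed arithmetic: 12.6 mg over 31.5 cm2 x 50.8 um
  conc_ng_ml <- 12.6e6 / (31.5e-4 * 50.8e-6 * 1e6)
  expect_equal(unique(psi[grid$layer == "patch"]), conc_ng_ml / tr$k_patch,
               tolerance = 1e-12)
  expect_true(all(psi[grid$layer != "patch"] == 0))
  # the integral of K * psi over the patch recovers the load exactly
  m <- site_mass(psi, grid, tr, geo$patch_area_m2)
  expect_equal(unname(m["patch"]), 12.6e6, tolerance = 1e-12)
  expect_equal(unname(m["skin"]), 0)
  # zero load gives an identically zero state and zero flux
  psi0 <- initialize_site(grid, tr, 0, geo$patch_area_m2)
  expect_true(all(psi0 == 0))
  expect_equal(flux_out(psi0, grid, tr, 0), 0)
})

test_that("uniform potential equal to the boundary is an equilibrium", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  tr <- twin_config()$transport
  grid <- build_grid(geo)
  rhs <- diffusion_rhs(rep(3.7, length(grid$width)), grid, tr, bottom_psi = 3.7)
  expect_lt(max(abs(rhs)), 1e-12)
})

test_that("multilayer solver matches the analytic slab series when layers are identical", {
  # identical D and K = 1 in all layers: the stack is one homogeneous slab
  geo <- derive_skin_geometry(ref_patient(), det_config())
  tr <- uniform_transport(d = 3.84e-12)
  grid <- build_grid(geo, n_cells = 40, interface_refinement = 1)
  L <- sum(grid$width)
  c0 <- 100
  psi <- rep(c0, length(grid$width))  # uniform initial loading everywhere
  for (t_s in c(500, 2000, 8000)) {
    sol <- solve_site(psi, grid, tr, bottom_psi = 0, times = t_s,
                      method = "expm")
    exact <- slab_series(grid$center, t_s, L, 3.84e-12, c0)
    scale <- max(abs(exact))
    expect_lt(max(abs(sol[1, ] - exact)) / scale, 0.005)
    # bottom flux against the series oracle (x1e6: psi is ng/ml over metres)
    f_num <- flux_out(sol[1, ], grid, tr, 0)
    f_exact <- slab_series_flux(t_s, L, 3.84e-12, c0) * 1e6
    expect_lt(abs(f_num - f_exact) / abs(f_exact), 0.005)
  }
})

test_that("steady state with a held plasma potential honours the partition jump", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  tr <- twin_config()$transport
  grid <- build_grid(geo, n_cells = 10)
  psi_b <- 5
  # long-time limit: potential uniform at the boundary value, so the
  # concentration ratio across the patch/epidermis interface is K_pt/K_ep
  sol <- solve_site(rep(0, length(grid$width)), grid, tr, bottom_psi = psi_b,
                    times = 5e7, method = "expm")
  expect_equal(max(abs(sol[1, ] - psi_b)), 0, tolerance = 1e-6)
  c_patch <- tr$k_patch * sol[1, max(which(grid$layer == "patch"))]
  c_sc <- tr$k_epidermis * sol[1, min(which(grid$layer == "sc"))]
  expect_equal(c_patch / c_sc, 1 / 3.4, tolerance = 1e-5)
})

test_that("mass plus cumulative outflux balances the 12.6 mg load over 72 h", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  tr <- twin_config()$transport
  grid <- build_grid(geo)
  psi0 <- initialize_site(grid, tr, geo$patch_load_ng, geo$patch_area_m2)
  times <- c(24, 48, 72) * 3600
  sol <- solve_site(psi0, grid, tr, bottom_psi = 0, times = times,
                    method = "be", dt_s = 300)
  cum <- attr(sol, "cumulative_outflux_ng_m2")
  for (i in seq_along(times)) {
    m <- site_mass(sol[i, ], grid, tr, geo$patch_area_m2)
    balance <- m[["total"]] + cum[i] * geo$patch_area_m2
    expect_lt(abs(balance / 12.6e6 - 1), 1e-3)
  }
  # a substantial fraction of the load must actually have moved
  expect_gt(cum[3] * geo$patch_area_m2 / 12.6e6, 0.1)
})

test_that("potential stays non-negative under implicit stepping", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  set.seed(31)
  for (rep in 1:5) {
    tr <- twin_config()$transport
    tr$d_patch_m2_s <- tr$d_patch_m2_s * stats::runif(1, 0.3, 3)
    tr$d_epidermis_m2_s <- tr$d_epidermis_m2_s * stats::runif(1, 0.3, 3)
    grid <- build_grid(geo, n_cells = sample(6:20, 1))
    psi0 <- initialize_site(grid, tr, geo$patch_load_ng, geo$patch_area_m2)
    sol <- solve_site(psi0, grid, tr, bottom_psi = stats::runif(1, 0, 2),
                      times = c(3600, 36 * 3600), method = "be", dt_s = 600)
    expect_true(all(sol >= 0))
  }
})

test_that("grid convergence is second order on a smooth problem", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  rc <- richardson_convergence(geo, uniform_transport(3.84e-12), levels = 4,
                               base_cells = 6, t_eval_h = 1,
                               interface_refinement = 1)
  expect_gt(rc$order, 1.7)
  expect_lt(rc$order, 2.3)
  expect_false(rc$table$exceeds_tol[4])
})

test_that("default-resolution flux is within 0.1% of the extrapolated value", {
  geo <- derive_skin_geometry(ref_patient(), det_config())
  rc <- richardson_convergence(geo, twin_config()$transport, levels = 4,
                               base_cells = 6, t_eval_h = 24)
  # level 3 (24 cells/layer ~ default 25) already meets the 0.1% target
  expect_lt(rc$table$rel_error[3], 1e-3)
  expect_lt(rc$table$rel_error[4], 1e-3)
  # identical grids cannot be extrapolated
  expect_error(richardson_convergence(geo, twin_config()$transport,
                                      levels = 3, base_cells = 0),
               "distinct|>= 4")
})
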