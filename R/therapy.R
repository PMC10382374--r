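#' Patch-replacement policy
#'
#' Two policies are supported. `conventional` follows the product label:
#' one patch applied at t = 0 and replaced every `replacement_interval_h`
#' (72 h, i.e. never within the default horizon). `twin_assisted` lets the
#' digital twin check the simulated pain intensity every
#' `check_interval_h`; whenever the VAS score is strictly above
#' `vas_target` at a checkpoint, the current patch is removed and a fresh
#' patch of the same size is applied at a new site. The first check happens
#' one full interval after application, which implements the 8-h lockout
#' against over-frequent replacement.
#'
#' @param kind `"conventional"` or `"twin_assisted"`.
#' @param check_interval_h Checkpoint spacing in hours (one of 2, 4, 6, 8,
#'   12, 24, 36, 72).
#' @param vas_target Pain target; replacement triggers on `vas > target`.
#' @param replacement_interval_h Fixed replacement period of the
#'   conventional policy (h).
#' @param horizon_h Simulated therapy duration (h).
#' @param vas_stub Optional function `f(time_h)` returning a VAS value,
#'   used in place of the simulated pain at checkpoints (testing hook for
#'   controller logic).
#' @return List of class `ft_policy`.
#' @export
therapy_policy <- function(kind = c("conventional", "twin_assisted"),
                           check_interval_h = 8, vas_target = 3,
                           replacement_interval_h = 72, horizon_h = 72,
                           vas_stub = NULL) {
  kind <- match.arg(kind)
  if (!check_interval_h %in% c(2, 4, 6, 8, 12, 24, 36, 72)) {
    stop("check_interval_h must be one of 2, 4, 6, 8, 12, 24, 36, 72")
  }
  stopifnot(vas_target > 0, vas_target < 10, horizon_h > 0)
  structure(
    list(kind = kind, check_interval_h = check_interval_h,
         vas_target = vas_target,
         replacement_interval_h = replacement_interval_h,
         horizon_h = horizon_h, vas_stub = vas_stub),
    class = "ft_policy"
  )
}

#' Simulate one patient's therapy
#'
#' Integrates the coupled system — every active application site's
#' potential field, the five PBPK compartments and the two effect
#' compartments — over the policy horizon. Between patch events the system
#' is linear and autonomous, and is advanced by a Crank-Nicolson scheme
#' with a pre-factorized sparse operator, started with backward-Euler
#' half-steps after each event (Rannacher smoothing, which damps the
#' non-smooth modes a fresh patch introduces and keeps the potential field
#' non-negative); patch events are exact integration breakpoints. Output
#' is sampled on an hourly grid.
#'
#' On replacement the current patch is removed; if
#' `config$numerics$residual_depot` is `TRUE` (default) the drug already
#' stored in that site's skin keeps releasing into the blood, otherwise the
#' old site is discarded. The new patch always starts on fresh skin at a
#' new location with the full load.
#'
#' @param twin An `ft_twin` from [assemble_twin()].
#' @param policy An [therapy_policy()].
#' @param config Model configuration; defaults to the twin's own.
#' @return List of class `ft_simulation`: `series` (hourly tibble with
#'   plasma/compartment concentrations, effect-site concentrations, VAS,
#'   ventilation, total dermal input flux, active-site count and site mass
#'   audit), `patch_events` (application times, h; the first is always 0),
#'   `policy`, `twin`.
#' @examples
#' \donttest{
#' pt <- tibble::tibble(age_years = 58, gender = 1,
#'                      weight_kg = 74.2, height_m = 1.73)
#' twin <- assemble_twin(pt, twin_config(variability = list(sd_theta = 0)))
#' sim <- run_simulation(twin, therapy_policy("conventional"))
#' sim$series[c(1, 25, 73), c("time_h", "c_p_ng_ml", "vas")]
#' }
#' @export
run_simulation <- function(twin, policy = therapy_policy(), config = twin$config) {
  stopifnot(inherits(twin, "ft_twin"), inherits(policy, "ft_policy"))
  num <- config$numerics
  if ((3600 * num$output_step_h) %% num$dt_s != 0) {
    stop("dt_s must divide the output step")
  }
  horizon_s <- policy$horizon_h * 3600

  # event schedule: conventional replaces on the clock; twin checks the pain
  check_s <- if (policy$kind == "twin_assisted") {
    s <- seq(policy$check_interval_h * 3600, horizon_s,
             by = policy$check_interval_h * 3600)
    s[s < horizon_s]
  } else {
    s <- seq(policy$replacement_interval_h * 3600, horizon_s,
             by = policy$replacement_interval_h * 3600)
    s[s < horizon_s]
  }

  sites <- list(new_site(twin, config, with_patch = TRUE))
  patch_events_h <- 0
  out_times <- seq(0, horizon_s, by = num$output_step_h * 3600)
  rows <- vector("list", length(out_times))

  state <- list(pk = c(p = 0, r = 0, s = 0, g = 0, l = 0),
                effect = c(vas = 0, rd = 0))
  rows[[1]] <- record_row(0, sites, state, twin)

  seg_bounds <- sort(unique(c(0, check_s, horizon_s)))
  out_i <- 2
  needs_startup <- TRUE  # Rannacher smoothing after t = 0 and every event
  for (k in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[k]
    t1 <- seg_bounds[k + 1]
    seg_out <- out_times[out_times > t0 + 1e-9 & out_times <= t1 + 1e-9]
    stepped <- step_segment(sites, state, twin, config, t0, t1, seg_out,
                            smooth_start = needs_startup)
    needs_startup <- FALSE
    sites <- stepped$sites
    state <- stepped$state
    for (r in stepped$rows) {
      rows[[out_i]] <- r
      out_i <- out_i + 1
    }
    if (t1 < horizon_s) {
      replace <- if (policy$kind == "twin_assisted") {
        vas_now <- if (is.null(policy$vas_stub)) {
          clinical_effects(state$effect[["vas"]], state$effect[["rd"]],
                           twin$pd)$vas
        } else {
          policy$vas_stub(t1 / 3600)
        }
        vas_now > policy$vas_target
      } else {
        TRUE  # conventional: scheduled replacement
      }
      if (replace) {
        sites <- replace_patch(sites, twin, config)
        patch_events_h <- c(patch_events_h, t1 / 3600)
        needs_startup <- TRUE
      }
    }
  }

  series <- dplyr::bind_rows(rows)
  eff <- clinical_effects(series$c_e_vas, series$c_e_rd, twin$pd)
  series$vas <- eff$vas
  series$ventilation_L_min <- eff$ventilation_L_min
  structure(
    list(series = series, patch_events_h = patch_events_h,
         policy = policy, twin = twin),
    class = "ft_simulation"
  )
}

# ---- engine internals -------------------------------------------------------

new_site <- function(twin, config, with_patch = TRUE) {
  num <- config$numerics
  grid <- build_grid(twin$skin, n_cells = num$cells_per_layer,
                     interface_refinement = num$interface_refinement,
                     include_patch = with_patch)
  psi <- initialize_site(grid, twin$transport,
                         if (with_patch) twin$skin$patch_load_ng else 0,
                         twin$skin$patch_area_m2)
  list(grid = grid, psi = psi, has_patch = with_patch,
       area = twin$skin$patch_area_m2)
}

replace_patch <- function(sites, twin, config) {
  patched <- which(vapply(sites, function(s) s$has_patch, TRUE))
  keep_depot <- isTRUE(config$numerics$residual_depot)
  out <- list()
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    if (i %in% patched) {
      if (!keep_depot) next
      # strip the patch cells; the skin sub-grid is unchanged
      depot_grid <- build_grid(twin$skin,
                               n_cells = config$numerics$cells_per_layer,
                               interface_refinement =
                                 config$numerics$interface_refinement,
                               include_patch = FALSE)
      s <- list(grid = depot_grid, psi = s$psi[s$grid$layer != "patch"],
                has_patch = FALSE, area = s$area)
    }
    out[[length(out) + 1]] <- s
  }
  out[[length(out) + 1]] <- new_site(twin, config, with_patch = TRUE)
  out
}

# global sparse operator over all sites + 5 PK + 2 effect states
assemble_system <- function(sites, twin) {
  k_dm <- twin$transport$k_dermis
  v_c <- twin$pk$volumes_L[["central"]]
  n_cells <- vapply(sites, function(s) length(s$psi), 0L)
  offsets <- cumsum(c(0, n_cells))
  n_skin <- sum(n_cells)
  ip <- n_skin + 1L  # then r, s, g, l, vas, rd
  n_tot <- n_skin + 7L

  ii <- jj <- xx <- list()
  add <- function(i, j, x) {
    m <- length(ii) + 1
    ii[[m]] <<- i; jj[[m]] <<- j; xx[[m]] <<- x
  }
  flux_vec <- vector("list", length(sites))
  for (s in seq_along(sites)) {
    op <- site_operator(sites[[s]]$grid, twin$transport)
    n <- n_cells[s]
    idx <- offsets[s] + seq_len(n)
    tri <- Matrix::mat2triplet(op$m)
    add(idx[tri$i], idx[tri$j], tri$x)
    bot <- idx[n]
    # bottom Dirichlet potential = c_p / K_dermis
    add(bot, ip, op$b[n] / k_dm)
    # central compartment gains Flux_d * A / V_c (ng/ml/s)
    gain <- sites[[s]]$area * 1e-3 / v_c
    add(ip, bot, op$fq[n] * gain)
    add(ip, ip, -op$f0 / k_dm * gain)
    fv <- numeric(n_tot)
    fv[bot] <- op$fq[n]
    fv[ip] <- -op$f0 / k_dm
    flux_vec[[s]] <- fv  # flux density ng m^-2 s^-1
  }
  pk_sys <- pk_system_matrix(twin$pk)
  pk_idx <- ip + 0:4
  tri <- which(pk_sys$m != 0, arr.ind = TRUE)
  add(pk_idx[tri[, 1]], pk_idx[tri[, 2]], pk_sys$m[tri])
  ke_vas <- twin$pd$vas$k_e_per_s
  ke_rd <- twin$pd$rd$k_e_per_s
  add(c(ip + 5L, ip + 5L), c(ip, ip + 5L), c(ke_vas, -ke_vas))
  add(c(ip + 6L, ip + 6L), c(ip, ip + 6L), c(ke_rd, -ke_rd))

  a <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_tot, n_tot))
  list(a = a, offsets = offsets, n_cells = n_cells, ip = ip,
       n_tot = n_tot, flux_vec = flux_vec)
}

pack_state <- function(sites, state, sys) {
  x <- numeric(sys$n_tot)
  for (s in seq_along(sites)) {
    x[sys$offsets[s] + seq_len(sys$n_cells[s])] <- sites[[s]]$psi
  }
  x[sys$ip + 0:4] <- state$pk
  x[sys$ip + 5:6] <- state$effect
  x
}

unpack_state <- function(x, sites, sys) {
  for (s in seq_along(sites)) {
    sites[[s]]$psi <- x[sys$offsets[s] + seq_len(sys$n_cells[s])]
  }
  state <- list(pk = stats::setNames(x[sys$ip + 0:4], c("p", "r", "s", "g", "l")),
                effect = stats::setNames(x[sys$ip + 5:6], c("vas", "rd")))
  list(sites = sites, state = state)
}

# advance one inter-event segment with Crank-Nicolson time stepping; the
# first 2*dt after each event are taken as four backward-Euler half-steps
# (Rannacher smoothing), which damps the non-smooth modes a fresh patch
# introduces and keeps the potential field non-negative
step_segment <- function(sites, state, twin, config, t0, t1, out_times_s,
                         smooth_start = TRUE) {
  sys <- assemble_system(sites, twin)
  dt <- config$numerics$dt_s
  lu <- Matrix::lu(Matrix::Diagonal(sys$n_tot) - (dt / 2) * sys$a)
  x <- pack_state(sites, state, sys)
  rows <- vector("list", length(out_times_s))
  t_now <- t0
  oi <- 1
  emit <- function(t_now, x) {
    while (oi <= length(out_times_s) && t_now > out_times_s[oi] - dt / 2) {
      up <- unpack_state(x, sites, sys)
      rows[[oi]] <<- record_row(t_now, up$sites, up$state, twin, sys, x)
      oi <<- oi + 1
    }
  }
  startup <- if (smooth_start) 0L else 4L
  while (startup < 4L && t_now < t1 - 1e-9) {
    x <- as.numeric(Matrix::solve(lu, x))  # backward-Euler half-step
    t_now <- t_now + dt / 2
    startup <- startup + 1L
    if (startup %% 2L == 0L) emit(t_now, x)
  }
  while (t_now < t1 - 1e-9) {
    x <- as.numeric(Matrix::solve(lu, x + (dt / 2) * as.numeric(sys$a %*% x)))
    t_now <- t_now + dt
    emit(t_now, x)
  }
  up <- unpack_state(x, sites, sys)
  list(sites = up$sites, state = up$state, rows = rows[!vapply(rows, is.null, TRUE)])
}

record_row <- function(t_s, sites, state, twin, sys = NULL, x = NULL) {
  if (is.null(sys)) {
    sys <- assemble_system(sites, twin)
    x <- pack_state(sites, state, sys)
  }
  flux_ng_s <- sum(vapply(seq_along(sites), function(s) {
    drop(sys$flux_vec[[s]] %*% x) * sites[[s]]$area
  }, 0))
  masses <- vapply(sites, function(s) {
    site_mass(s$psi, s$grid, twin$transport, s$area)[c("patch", "skin")]
  }, c(patch = 0, skin = 0))
  tibble::tibble(
    time_h = t_s / 3600,
    c_p_ng_ml = state$pk[["p"]], c_r_ng_ml = state$pk[["r"]],
    c_s_ng_ml = state$pk[["s"]], c_g_ng_ml = state$pk[["g"]],
    c_l_ng_ml = state$pk[["l"]],
    c_e_vas = state$effect[["vas"]], c_e_rd = state$effect[["rd"]],
    flux_ng_s = flux_ng_s,
    n_active_sites = length(sites),
    mass_patch_ng = sum(masses["patch", ]),
    mass_skin_ng = sum(masses["skin", ])
  )
}

#' Checkpoint-frequency study for one patient
#'
#' Runs the twin-assisted policy for a set of checkpoint intervals (plus
#' the 72-h case, which coincides with conventional therapy) and summarizes
#' each run: mean/minimum pain, time without pain, maximum plasma
#' concentration, minimum/mean ventilation and the number of patches used.
#'
#' @param twin An `ft_twin`.
#' @param intervals_h Checkpoint intervals in hours.
#' @param config Model configuration.
#' @param vas_target Pain target for replacement.
#' @return A tibble with one row per interval (the [patient_outcomes()]
#'   fields plus `check_interval_h`).
#' @export
checkpoint_frequency_study <- function(twin,
                                       intervals_h = c(2, 4, 6, 8, 12, 24, 36, 72),
                                       config = twin$config, vas_target = 3) {
  purrr::map_dfr(intervals_h, function(iv) {
    sim <- run_simulation(
      twin,
      therapy_policy("twin_assisted", check_interval_h = iv,
                     vas_target = vas_target),
      config
    )
    dplyr::bind_cols(tibble::tibble(check_interval_h = iv),
                     patient_outcomes(sim))
  })
}

#' Simulate a whole population under one policy
#'
#' Convenience wrapper: assembles a twin per patient (seeded as
#' `seed + id`) and returns one outcome row per patient together with the
#' covariates.
#'
#' @param population Population tibble.
#' @param policy An [therapy_policy()].
#' @param config Model configuration.
#' @param seed Base seed for the per-patient variability draws.
#' @return Tibble: covariates + [patient_outcomes()] columns per patient.
#' @export
simulate_population <- function(population, policy, config = twin_config(),
                                seed = 1) {
  validate_patients(population)
  purrr::map_dfr(seq_len(nrow(population)), function(i) {
    twin <- assemble_twin(population[i, ], config, seed = seed + population$id[i])
    sim <- run_simulation(twin, policy, config)
    dplyr::bind_cols(
      tibble::as_tibble(population[i, c("id", "age_years", "gender",
                                        "weight_kg", "height_m")]),
      patient_outcomes(sim)
    )
  })
}
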