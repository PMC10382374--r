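#' Inter-individual variability draws
#'
#' Each physiology-derived parameter is multiplied by `exp(theta)` with an
#' independent `theta ~ Normal(0, sd_theta)` per parameter (default SD 0.1,
#' which puts 95% of each parameter within about +/-20% of its central
#' value). `draw_thetas()` draws the full named set for one patient;
#' `theta_names()` lists the parameters that receive a draw.
#'
#' @param sd_theta Standard deviation of theta (0 disables variability).
#' @return Named numeric vector of theta values.
#' @export
draw_thetas <- function(sd_theta = 0.1) {
  stats::setNames(stats::rnorm(length(theta_names()), 0, sd_theta),
                  theta_names())
}

#' @rdname draw_thetas
#' @export
theta_names <- function() {
  c("d_sc", "d_vep", "d_edm",
    "V_central", "V_rapid", "V_slow", "V_gut", "V_liver",
    "Q_rapid", "Q_slow", "Q_gut", "Q_liver", "Q_portal",
    "cl_h", "k_re", "ec50_vas")
}

zero_thetas <- function() {
  stats::setNames(rep(0, length(theta_names())), theta_names())
}

#' Patient-specific skin geometry
#'
#' Maps covariates to the layer thicknesses of the drug-uptake model:
#' stratum corneum (linear in age, with a 1.40 factor for women), viable
#' epidermis (gender factor around a calibrated base value) and equivalent
#' dermis (linear in BMI per gender, scaled by the calibrated age-scaling
#' ratio). Each thickness carries its own lognormal variability multiplier.
#' All outputs are in metres.
#'
#' The stratum-corneum expression is evaluated literally as printed,
#' `(0.125*Age + 11.80*(Gender + (1-Gender)*1.40)) * exp(theta)`; its
#' population mean (~21 um) exceeds the printed 18.0 um population mean, a
#' discrepancy the optional `skin$sc_calibration_factor` can absorb
#' (default off; see the methods vignette).
#'
#' @param patient One-row patient data (age_years, gender, weight_kg,
#'   height_m).
#' @param config An [twin_config()] list.
#' @param thetas Named theta vector (see [draw_thetas()]); default all zero.
#' @return List of class `ft_skin_geometry`: `d_sc`, `d_vep`, `d_edm`,
#'   `d_patch` (m), `patch_area_m2`, `patch_load_ng`.
#' @export
derive_skin_geometry <- function(patient, config = twin_config(),
                                 thetas = zero_thetas()) {
  sk <- config$skin
  age <- patient$age_years
  g <- patient$gender
  bmi <- patient$weight_kg / patient$height_m^2
  if (bmi < sk$bmi_range[1] || bmi > sk$bmi_range[2]) {
    stop(sprintf(
      "BMI %.1f outside the validated range [%g, %g] of the dermis equation",
      bmi, sk$bmi_range[1], sk$bmi_range[2]
    ))
  }
  d_sc_um <- (sk$sc_age_slope_um * age +
                sk$sc_base_um * (g + (1 - g) * sk$sc_female_factor)) *
    sk$sc_calibration_factor * exp(thetas[["d_sc"]])
  d_vep_um <- sk$vep_base_um * (g + (1 - g) / sk$vep_female_divisor) *
    exp(thetas[["d_vep"]])
  base_mm <- g * (sk$edm_male_bmi_slope * bmi + sk$edm_male_intercept) +
    (1 - g) * (sk$edm_female_bmi_slope * bmi + sk$edm_female_intercept)
  d_edm_um <- base_mm * 1000 * sk$edm_age_scaling_ratio * exp(thetas[["d_edm"]])
  structure(
    list(
      d_sc = d_sc_um * 1e-6,
      d_vep = d_vep_um * 1e-6,
      d_edm = d_edm_um * 1e-6,
      d_patch = config$patch$thickness_m,
      patch_area_m2 = config$patch$area_cm2 * 1e-4,
      patch_load_ng = config$patch$load_mg * 1e6
    ),
    class = "ft_skin_geometry"
  )
}

#' Patient-specific pharmacokinetic parameters
#'
#' Per-gender reference compartment volumes and inter-compartment flows are
#' scaled linearly by weight/70 and perturbed by independent lognormal
#' multipliers; hepatic clearance is scaled likewise. Rate constants for the
#' compartment balance equations are derived downstream from the stored
#' flows and volumes (each equation divides the shared flow by its own
#' compartment volume), never shared across equations.
#'
#' @inheritParams derive_skin_geometry
#' @return List of class `ft_pk_parameters`: `volumes_L` (central, rapid,
#'   slow, gut, liver), `flows_L_s` (rapid, slow, gut, liver, portal),
#'   `cl_h_L_s`, `k_re_per_s`, `k_met_per_s`, `f_u`, `literal_renal_sign`.
#' @export
derive_pk_parameters <- function(patient, config = twin_config(),
                                 thetas = zero_thetas()) {
  ref <- if (patient$gender == 1) config$pk_reference$male else config$pk_reference$female
  for (nm in c("volumes_L", "flows_L_min", "cl_h_L_min", "k_re_per_s")) {
    if (is.null(ref[[nm]])) stop("pk_reference is missing entry `", nm, "`")
  }
  w_scale <- patient$weight_kg / 70
  vol_theta <- exp(thetas[c("V_central", "V_rapid", "V_slow", "V_gut", "V_liver")])
  flow_theta <- exp(thetas[c("Q_rapid", "Q_slow", "Q_gut", "Q_liver", "Q_portal")])
  volumes <- ref$volumes_L * w_scale * as.numeric(vol_theta)
  flows <- ref$flows_L_min / 60 * w_scale * as.numeric(flow_theta)
  cl_h <- ref$cl_h_L_min / 60 * w_scale * exp(thetas[["cl_h"]])
  structure(
    list(
      volumes_L = stats::setNames(volumes, names(ref$volumes_L)),
      flows_L_s = stats::setNames(flows, names(ref$flows_L_min)),
      cl_h_L_s = cl_h,
      k_re_per_s = ref$k_re_per_s * exp(thetas[["k_re"]]),
      k_met_per_s = cl_h / volumes[["liver"]],
      f_u = config$pk_reference$f_u,
      literal_renal_sign = isTRUE(config$pk_reference$literal_renal_sign)
    ),
    class = "ft_pk_parameters"
  )
}

#' Patient-specific half-maximum-effect concentration for pain
#'
#' Evaluates the printed age-linear expression
#' `(-1.148e-2 * Age + 1.96) * exp(theta)` (ng/ml).
#'
#' @param age Age in years.
#' @param config An [twin_config()] list.
#' @param theta Lognormal variability draw (scalar, default 0).
#' @return EC50 for the VAS endpoint in ng/ml.
#' @export
derive_ec50_vas <- function(age, config = twin_config(), theta = 0) {
  v <- config$pd$vas
  ec50 <- (v$ec50_age_slope * age + v$ec50_intercept) * exp(theta)
  if (any(ec50 <= 0)) {
    stop("Non-positive EC50: age outside the supported range of the formula")
  }
  ec50
}

#' Assemble the full digital twin for one patient
#'
#' Bundles skin geometry, transport constants, PK parameters and the
#' patient-specific pharmacodynamics into one parameter set, drawing one
#' independent variability multiplier per parameter. All draws are recorded
#' in `$thetas` for reproducibility; the same patient and seed always yield
#' an identical twin.
#'
#' @param patient One-row patient tibble.
#' @param config An [twin_config()] list.
#' @param seed Integer seed for the variability draws.
#' @return A list of class `ft_twin` with elements `patient`, `skin`,
#'   `transport`, `pk`, `pd`, `thetas`.
#' @examples
#' pop <- generate_sample_cohort(seed = 1)
#' twin <- assemble_twin(pop[1, ], twin_config(), seed = 7)
#' twin$pd$vas$ec50_ng_ml
#' @export
assemble_twin <- function(patient, config = twin_config(), seed = 1) {
  require_config_sections(config)
  validate_patients(patient)
  stopifnot(nrow(patient) == 1)
  thetas <- withr_seed(seed, {
    if (config$variability$sd_theta == 0) zero_thetas()
    else draw_thetas(config$variability$sd_theta)
  })
  pd <- config$pd
  pd$vas$ec50_ng_ml <- derive_ec50_vas(patient$age_years, config,
                                       thetas[["ec50_vas"]])
  structure(
    list(
      patient = tibble::as_tibble(patient),
      skin = derive_skin_geometry(patient, config, thetas),
      transport = config$transport,
      pk = derive_pk_parameters(patient, config, thetas),
      pd = pd,
      thetas = thetas,
      config = config,
      seed = as.integer(seed)
    ),
    class = "ft_twin"
  )
}

#' Parameter audit table for a population
#'
#' Assembles a twin per patient and returns one row per patient with the
#' derived skin thicknesses (micrometres), PK volumes/clearance and the
#' pain EC50 — the per-patient parameter table used for audits.
#'
#' @param population Population tibble.
#' @param config An [twin_config()] list.
#' @param seed Base seed; patient `i` uses `seed + i`.
#' @return A tibble with one row per patient.
#' @export
parameter_table <- function(population, config = twin_config(), seed = 1) {
  validate_patients(population)
  purrr::map_dfr(seq_len(nrow(population)), function(i) {
    tw <- assemble_twin(population[i, ], config, seed = seed + i)
    tibble::tibble(
      id = population$id[i],
      age_years = tw$patient$age_years,
      gender = tw$patient$gender,
      weight_kg = tw$patient$weight_kg,
      height_m = tw$patient$height_m,
      d_sc_um = tw$skin$d_sc * 1e6,
      d_vep_um = tw$skin$d_vep * 1e6,
      d_edm_um = tw$skin$d_edm * 1e6,
      v_central_L = tw$pk$volumes_L[["central"]],
      cl_h_L_min = tw$pk$cl_h_L_s * 60,
      ec50_vas_ng_ml = tw$pd$vas$ec50_ng_ml
    )
  })
}
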