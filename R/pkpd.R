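#' Five-compartment PBPK system matrix
#'
#' Builds the linear system `dc/dt = M c + u * (Flux_d * A / V_c)` for the
#' concentrations (ng/ml) in the central, rapid-equilibrating,
#' slow-equilibrating, gastrointestinal and hepatic compartments. Each rate
#' constant divides the shared inter-compartment flow by the volume of the
#' compartment whose balance equation it appears in; the unbound fraction
#' `f_u` multiplies only the central-compartment outflow and elimination
#' terms, exactly as the model prints them (the resulting mild mass
#' asymmetry is the model's own; conservation tests set `f_u = 1`). Renal
#' clearance is implemented as an elimination term by default;
#' `literal_renal_sign = TRUE` reproduces the printed sign, which makes it a
#' source.
#'
#' @param pk An `ft_pk_parameters` list (see [derive_pk_parameters()]).
#' @return List with `m` (5x5 matrix, states `c("p","r","s","g","l")`) and
#'   `input` (unit input vector into the central compartment).
#' @export
pk_system_matrix <- function(pk) {
  v <- pk$volumes_L
  q <- pk$flows_L_s
  f_u <- pk$f_u
  renal_sign <- if (pk$literal_renal_sign) 1 else -1
  m <- matrix(0, 5, 5, dimnames = list(c("p", "r", "s", "g", "l"),
                                       c("p", "r", "s", "g", "l")))
  # central balance: losses at f_u, returns at the compartment concentrations
  m["p", "p"] <- -(q[["rapid"]] + q[["slow"]] + q[["liver"]] + q[["gut"]]) /
    v[["central"]] * f_u + renal_sign * pk$k_re_per_s * f_u
  m["p", "r"] <- q[["rapid"]] / v[["central"]]
  m["p", "s"] <- q[["slow"]] / v[["central"]]
  m["p", "l"] <- q[["liver"]] / v[["central"]]
  # rapid / slow equilibrating compartments
  m["r", "p"] <- q[["rapid"]] / v[["rapid"]]
  m["r", "r"] <- -q[["rapid"]] / v[["rapid"]]
  m["s", "p"] <- q[["slow"]] / v[["slow"]]
  m["s", "s"] <- -q[["slow"]] / v[["slow"]]
  # gastrointestinal: uptake from central, portal transfer to the liver
  m["g", "p"] <- q[["gut"]] / v[["gut"]]
  m["g", "g"] <- -q[["portal"]] / v[["gut"]]
  # hepatic: arterial + portal inflow, return to central, metabolization
  m["l", "p"] <- q[["liver"]] / v[["liver"]]
  m["l", "g"] <- q[["portal"]] / v[["liver"]]
  m["l", "l"] <- -q[["liver"]] / v[["liver"]] - pk$k_met_per_s
  list(m = m, input = c(p = 1, r = 0, s = 0, g = 0, l = 0))
}

#' PBPK right-hand side
#'
#' Time derivatives of the five compartment concentrations for a given
#' dermal flux. The transdermal input enters the central compartment as
#' `Flux_d x A / V_c`.
#'
#' @param state Named numeric vector `c(p, r, s, g, l)` in ng/ml (>= 0).
#' @param pk An `ft_pk_parameters` list.
#' @param flux_ng_m2_s Bottom-boundary flux density (ng m^-2 s^-1).
#' @param patch_area_m2 Total absorbing area (m^2).
#' @return Named derivative vector (ng/ml/s).
#' @export
pk_rhs <- function(state, pk, flux_ng_m2_s = 0, patch_area_m2 = 0) {
  if (any(state < 0)) stop("Negative compartment concentration.")
  sys <- pk_system_matrix(pk)
  input <- flux_ng_m2_s * patch_area_m2 / pk$volumes_L[["central"]] * 1e-3
  drop(sys$m %*% state) + sys$input * input
}

#' Effect-compartment right-hand side
#'
#' First-order lag between plasma and each effect site:
#' `dc_e/dt = k_e (c_p - c_e)`, with the pain site equilibrating about
#' 2.9x faster than the ventilation site (k_e 2e-3 vs 7e-4 per second).
#'
#' @param effect Named vector `c(vas, rd)` of effect-site concentrations
#'   (ng/ml).
#' @param c_p Plasma concentration (ng/ml).
#' @param pd PD parameter list (`config$pd`).
#' @return Named derivative vector (ng/ml/s).
#' @export
effect_rhs <- function(effect, c_p, pd) {
  c(vas = pd$vas$k_e_per_s * (c_p - effect[["vas"]]),
    rd = pd$rd$k_e_per_s * (c_p - effect[["rd"]]))
}

#' Sigmoid concentration-response (Hill) function
#'
#' @param c_e Effect-site concentration (ng/ml).
#' @param ec50 Half-maximum-effect concentration (ng/ml, > 0).
#' @param gamma Hill coefficient.
#' @return Fractional effect in `[0, 1)`.
#' @export
hill <- function(c_e, ec50, gamma) {
  stopifnot(all(ec50 > 0))
  c_e^gamma / (ec50^gamma + c_e^gamma)
}

#' Clinical effects from effect-site concentrations
#'
#' Sigmoid Emax responses on the decreasing branch for both endpoints:
#' fentanyl lowers the VAS pain score from its baseline of 8 towards 0, and
#' depresses minute ventilation from 20 L/min towards
#' `20 - 20 x 0.91 = 1.8` L/min.
#'
#' @param c_e_vas,c_e_rd Effect-site concentrations (ng/ml); vectorized.
#' @param pd PD parameter list carrying the patient-specific
#'   `vas$ec50_ng_ml` (see [assemble_twin()]).
#' @return Tibble with columns `vas` and `ventilation_L_min`.
#' @export
clinical_effects <- function(c_e_vas, c_e_rd, pd) {
  if (is.null(pd$vas$ec50_ng_ml)) {
    stop("pd$vas$ec50_ng_ml is missing; use the pd of an assembled twin ",
         "or set it explicitly.")
  }
  tibble::tibble(
    vas = pd$vas$e0 - pd$vas$emax *
      hill(c_e_vas, pd$vas$ec50_ng_ml, pd$vas$gamma),
    ventilation_L_min = pd$rd$e0_L_min - pd$rd$emax_L_min *
      hill(c_e_rd, pd$rd$ec50_ng_ml, pd$rd$gamma)
  )
}
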