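# Parameter containers. User-facing angles are in degrees (as usually quoted
# for bundling thresholds and branching angles); they are converted to
# radians internally.

#' Dynamic-instability parameters
#'
#' Speeds are in micrometres per second, rates in per second. The defaults
#' are standard interphase cortical-array values; the catastrophe rate `r_c`
#' is the usual tuning knob and has no universal default, so it must be given.
#'
#' @param r_c catastrophe rate (1/s).
#' @param v_plus plus-end growth speed.
#' @param v_minus plus-end shrinkage speed.
#' @param v_tm minus-end treadmilling (retraction) speed.
#' @param r_r rescue rate (1/s).
#' @param theta_c maximum collision angle for zippering, degrees.
#' @param P_cat probability of induced catastrophe for steep collisions.
#' @param cap_rc_factor multiplicative factor on `r_c` on cylinder caps
#'   (global bias; 1 = no bias, 1.08 = 8 percent increase).
#' @param b_max maximal fractional increase of the rescue rate under the
#'   orientation-dependent local bias (0 = no bias).
#' @param theta_r orientation (degrees, from the long axis) at which the
#'   rescue-rate bias is maximal; 90 favours transverse growth.
#' @return object of class `cm_dynamic_params`.
#' @export
dynamic_params <- function(r_c,
                           v_plus = 0.05, v_minus = 0.08, v_tm = 0.01,
                           r_r = 0.001,
                           theta_c = 40, P_cat = 0.5,
                           cap_rc_factor = 1, b_max = 0, theta_r = 90) {
  stopifnot(v_plus > 0, v_minus > 0, v_tm >= 0, v_plus > v_tm,
            r_c >= 0, r_r >= 0,
            theta_c > 0, theta_c < 90,
            P_cat >= 0, P_cat <= 1,
            cap_rc_factor > 0, b_max >= 0)
  structure(list(v_plus = v_plus, v_minus = v_minus, v_tm = v_tm,
                 r_c = r_c, r_r = r_r,
                 theta_c = theta_c, P_cat = P_cat,
                 cap_rc_factor = cap_rc_factor,
                 b_max = b_max, theta_r = theta_r),
            class = "cm_dynamic_params")
}

#' Nucleation parameters
#'
#' Covers the three nucleation modes. `ISO` uses only `r_n`. `GDD` splits
#' `r_n` into microtubule-bound and unbound parts according to the global
#' density. `LDD` resolves each complex appearance locally through `N_meta`
#' meta-trajectories of maximal length `R_max`.
#'
#' Branch-angle parameters (`f_*`, `eccentricity`, `theta_b`) describe the
#' daughter orientation relative to the parent for both GDD and LDD.
#'
#' @param mode `"ISO"`, `"GDD"` or `"LDD"`.
#' @param r_n areal nucleation rate for ISO/GDD (per square micrometre per s).
#' @param rho_half GDD half-saturation density (1/micrometre).
#' @param f_forward,f_backward,f_left,f_right branch-component probabilities
#'   (must sum to 1).
#' @param eccentricity ellipse eccentricity of the sideways branch density.
#' @param theta_b mean branching angle, degrees.
#' @param r_ins complex appearance rate for LDD (per square micrometre per s).
#' @param r_u per-complex unbound nucleation rate (1/s).
#' @param D_nc complex diffusion coefficient (square micrometres per s).
#' @param N_meta number of meta-trajectories.
#' @param R_max meta-trajectory exploration radius, micrometres.
#' @param alpha_bound acceptance probability of a tentative bound nucleation.
#' @param alpha_unbound acceptance probability of a tentative unbound
#'   nucleation.
#' @param rescaled use the statistically equivalent rescaled parametrization:
#'   appearance rate `alpha_bound * r_ins`, bound acceptance 1, unbound
#'   acceptance `alpha_unbound / alpha_bound`.
#' @param unbound_factor multiplier on the unbound nucleation share for GDD
#'   variant experiments (1 = standard).
#' @return object of class `cm_nucleation_params`.
#' @export
nucleation_params <- function(mode = c("LDD", "GDD", "ISO"),
                              r_n = 0.001, rho_half = 0.1,
                              f_forward = 0.31, f_backward = 0.07,
                              f_left = 0.31, f_right = 0.31,
                              eccentricity = 0.89, theta_b = 35,
                              r_ins = 0.0045, r_u = 0.002, D_nc = 0.013,
                              N_meta = 6L, R_max = 1.5,
                              alpha_bound = 0.24, alpha_unbound = 0.02,
                              rescaled = TRUE,
                              unbound_factor = 1) {
  mode <- match.arg(mode)
  stopifnot(abs(f_forward + f_backward + f_left + f_right - 1) < 1e-9,
            eccentricity >= 0, eccentricity < 1,
            alpha_unbound > 0, alpha_unbound <= alpha_bound, alpha_bound <= 1,
            N_meta >= 1L, R_max > 0, r_n >= 0, r_ins >= 0, r_u >= 0, D_nc > 0,
            unbound_factor >= 0)
  structure(list(mode = mode, r_n = r_n, rho_half = rho_half,
                 f_forward = f_forward, f_backward = f_backward,
                 f_left = f_left, f_right = f_right,
                 eccentricity = eccentricity, theta_b = theta_b,
                 r_ins = r_ins, r_u = r_u, D_nc = D_nc,
                 N_meta = as.integer(N_meta), R_max = R_max,
                 alpha_bound = alpha_bound, alpha_unbound = alpha_unbound,
                 rescaled = rescaled, unbound_factor = unbound_factor),
            class = "cm_nucleation_params")
}

#' Assemble a run configuration
#'
#' A self-contained record of one simulation: domain, dynamic-instability and
#' nucleation parameters, horizon and seed. Echoed verbatim into result
#' bundles so a run can be reproduced bit-exactly.
#'
#' @param domain a `cm_domain`.
#' @param dynamics a `cm_dynamic_params`.
#' @param nucleation a `cm_nucleation_params`.
#' @param T_end simulation horizon, seconds.
#' @param obs_interval observable sampling interval, seconds.
#' @param seed integer RNG seed for this run.
#' @param density_cap density (1/micrometre) above which the run is aborted
#'   with status `"density_cap"`; guards unbounded-growth parameter sets.
#' @param record_local_density record, for each LDD nucleation event, the
#'   local density over the grid cells touched by its meta-trajectories
#'   (planar domains; adds cost).
#' @param local_cell grid cell side used for the local-density record,
#'   micrometres.
#' @param initial_mts optional data.frame (`face, x, y, theta`, optional
#'   `length`) of microtubules present at time 0 (toy runs and oracles);
#'   default empty array.
#' @param scan_horizon lookahead arclength for tip collision scans,
#'   micrometres; `NULL` picks a domain-sized default.
#' @return object of class `cm_config`.
#' @export
sim_config <- function(domain, dynamics, nucleation,
                       T_end, obs_interval = 100, seed = 1L,
                       density_cap = 200,
                       record_local_density = FALSE, local_cell = 1,
                       initial_mts = NULL,
                       scan_horizon = NULL) {
  stopifnot(inherits(domain, "cm_domain"),
            inherits(dynamics, "cm_dynamic_params"),
            inherits(nucleation, "cm_nucleation_params"),
            T_end >= 0, obs_interval > 0)
  if (is.null(scan_horizon)) {
    scan_horizon <- switch(domain$shape,
                           periodic_rectangle = 1.5 * max(domain$L, domain$H),
                           capped_cylinder = 1.5 * max(domain$L, domain$C),
                           box = 1.5 * max(domain$L, domain$H, domain$W2))
  }
  structure(list(domain = domain, dynamics = dynamics, nucleation = nucleation,
                 T_end = T_end, obs_interval = obs_interval,
                 seed = as.integer(seed), density_cap = density_cap,
                 record_local_density = record_local_density,
                 local_cell = local_cell,
                 initial_mts = initial_mts,
                 scan_horizon = scan_horizon),
            class = "cm_config")
}
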