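# Thermodynamic model: disorder-based destabilization and the cellular
# heat budget
#
# The chain of arithmetic: a per-domain destabilization coefficient
# c = R * (S_target / S_ref) * n / 1000 (kcal.mol^-1.K^-1) from the ratio of
# mean disorder scores, the temperature rise that offsets a binding free
# energy, |dG0| / c (K), its partition over rigid-body degrees of freedom,
# and the temperature spike a cell's heat output produces in its own water
# mass.

#' Per-domain destabilization coefficient
#'
#' `gas_constant * (score_target / score_ref) * n_residues / 1000`, in
#' kcal·mol⁻¹·K⁻¹. With the printed domain means (0.37 for Notch-1 ANK
#' against reference 0.21 or 0.22) and 230 residues this is ~0.8.
#'
#' @param score_target mean disorder score of the domain of interest.
#' @param score_ref mean reference disorder score (> 0).
#' @param n_residues residue count of the domain (>= 0).
#' @param gas_constant molar gas constant in cal·mol⁻¹·K⁻¹ (default 1.987,
#'   i.e. Avogadro's number times the Boltzmann constant).
#' @return coefficient in kcal·mol⁻¹·K⁻¹.
#' @export
destabilization_coefficient <- function(score_target, score_ref, n_residues,
                                        gas_constant = 1.987) {
  if (score_ref <= 0) {
    stop("score_ref must be positive: the coefficient scales with the ",
         "ratio score_target/score_ref")
  }
  if (n_residues < 0) stop("n_residues must be >= 0")
  gas_constant * (score_target / score_ref) * n_residues / 1000
}

#' Temperature rise that offsets a binding free energy
#'
#' @param deltaG0 binding free energy in kcal·mol⁻¹ (its magnitude is used).
#' @param coefficient destabilization coefficient in kcal·mol⁻¹·K⁻¹ (> 0).
#' @return temperature rise in K.
#' @export
dissociation_delta_t <- function(deltaG0, coefficient) {
  if (coefficient <= 0) stop("coefficient must be positive")
  abs(deltaG0) / coefficient
}

#' Partition a temperature threshold over degrees of freedom
#'
#' @param delta_t temperature rise in K.
#' @param ndof degrees of freedom (>= 1); default 3 for the flexible long
#'   axis of the repeat stack.
#' @return `delta_t / ndof` in K.
#' @export
dof_threshold <- function(delta_t, ndof = 3) {
  if (ndof < 1) stop("ndof must be >= 1")
  delta_t / ndof
}

#' Temperature spike from a cellular heat budget
#'
#' `power * duration / (specific_heat * mass)` with nW·s = nJ, so nW, ng and
#' J·g⁻¹·K⁻¹ (= nJ·ng⁻¹·K⁻¹) combine directly to K. The 20 nW / 1 ng /
#' 4.184 / 1 s default case gives ~4.8 K.
#'
#' @param power_nw heat output per cell, nW.
#' @param mass_ng cell mass, ng (> 0).
#' @param specific_heat J·g⁻¹·K⁻¹ (> 0); default water, 4.184.
#' @param duration_s heating time, s.
#' @return temperature spike in K.
#' @export
heat_spike <- function(power_nw, mass_ng = 1, specific_heat = 4.184,
                       duration_s = 1) {
  if (mass_ng <= 0) stop("mass_ng must be positive")
  if (specific_heat <= 0) stop("specific_heat must be positive")
  if (power_nw < 0 || duration_s < 0) stop("power and duration must be >= 0")
  power_nw * duration_s / (specific_heat * mass_ng)
}

#' Full thermodynamic report
#'
#' Chains the coefficient, dissociation threshold, per-degree-of-freedom
#' threshold and heat spike; values are carried at full precision with
#' presentation rounding (1 d.p. for the coefficient, integer K for the
#' partitioned threshold) reported alongside.
#'
#' @inheritParams destabilization_coefficient
#' @param deltaG0 binding free energy, kcal·mol⁻¹.
#' @param ndof degrees of freedom.
#' @param power_nw,mass_ng,specific_heat,duration_s heat-budget inputs, see
#'   [heat_spike()].
#' @return named list with all intermediates.
#' @export
thermo_report <- function(score_target = 0.37, score_ref = 0.21,
                          n_residues = 230, deltaG0 = -8, ndof = 3,
                          gas_constant = 1.987, power_nw = 20, mass_ng = 1,
                          specific_heat = 4.184, duration_s = 1) {
  coef <- destabilization_coefficient(score_target, score_ref, n_residues,
                                      gas_constant)
  coef_rounded <- round(coef, 1)
  dt <- dissociation_delta_t(deltaG0, coef_rounded)
  dt_dof <- dof_threshold(dt, ndof)
  list(
    per_residue_cal = gas_constant * score_target / score_ref,
    coefficient_kcal_per_K = coef,
    coefficient_rounded = coef_rounded,
    dissociation_delta_t_K = dt,
    dof_threshold_K = dt_dof,
    dof_threshold_rounded_K = round(dt_dof),
    heat_spike_K = heat_spike(power_nw, mass_ng, specific_heat, duration_s)
  )
}
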