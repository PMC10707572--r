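# Van 't Hoff analysis of temperature-dependent binding constants and
# sign-based classification of the dominant binding forces.

#' Van 't Hoff regression of binding constants
#'
#' Ordinary least-squares fit of `ln Kb` against `1/T`:
#' `ln Kb = -dH/(R T) + dS/R`, assuming the binding enthalpy is constant
#' over the fitted temperature range. `dH` (kcal/mol) comes from the slope,
#' `dS` (cal/mol/K) from the intercept, with
#' R = 1.987204e-3 kcal/mol/K. Per-temperature `T*dS` and
#' `dG = dH - T*dS` are tabulated for every input temperature.
#'
#' @param temperature_K temperatures in Kelvin (>= 2 distinct values), or a
#'   data frame with columns `temperature_K` and `Kb_M1`.
#' @param Kb_M1 binding constants (M^-1, > 0), one per temperature; omitted
#'   when a data frame is given.
#' @return an object of class `thermo_result` with fields `dH_kcal_mol`,
#'   `dS_cal_mol_K`, `per_temperature` (data frame of `temperature_K`,
#'   `TdS_kcal_mol`, `dG_kcal_mol`), `r_squared`, `n_points`.
#' @examples
#' vant_hoff_fit(c(298, 303, 310, 315), c(1.89e4, 1.46e4, 1.20e4, 0.99e4))
#' @export
vant_hoff_fit <- function(temperature_K, Kb_M1 = NULL) {
  if (is.data.frame(temperature_K)) {
    Kb_M1 <- temperature_K$Kb_M1
    temperature_K <- temperature_K$temperature_K
  }
  temperature_K <- as.numeric(temperature_K)
  Kb_M1 <- as.numeric(Kb_M1)
  if (length(temperature_K) != length(Kb_M1))
    stop("temperature_K and Kb_M1 must have equal length", call. = FALSE)
  if (length(temperature_K) < 2L)
    stop("Van 't Hoff fit needs at least 2 temperatures", call. = FALSE)
  if (anyDuplicated(temperature_K))
    stop("duplicate temperatures are not allowed", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  if (any(Kb_M1 <= 0)) stop("all Kb must be > 0", call. = FALSE)

  ord <- order(temperature_K)            # result invariant under input order
  temperature_K <- temperature_K[ord]
  Kb_M1 <- Kb_M1[ord]

  R <- GAS_CONSTANT_KCAL
  inv_t <- 1 / temperature_K
  ln_kb <- log(Kb_M1)
  fit <- stats::lm(ln_kb ~ inv_t)
  dH <- -unname(stats::coef(fit)[2]) * R              # kcal/mol
  dS_kcal <- unname(stats::coef(fit)[1]) * R          # kcal/mol/K
  per <- data.frame(
    temperature_K = temperature_K,
    TdS_kcal_mol = temperature_K * dS_kcal,
    dG_kcal_mol = dH - temperature_K * dS_kcal)
  structure(
    list(dH_kcal_mol = dH,
         dS_cal_mol_K = dS_kcal * 1000,
         per_temperature = per,
         r_squared = fit_r_squared(fit, ln_kb),
         n_points = length(temperature_K),
         Kb_input = data.frame(temperature_K = temperature_K, Kb_M1 = Kb_M1)),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.4g kcal/mol, dS = %.4g cal/mol/K (r2 = %.6g, n = %d)\n",
              x$dH_kcal_mol, x$dS_cal_mol_K, x$r_squared, x$n_points))
  print(x$per_temperature, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.thermo_result <- function(x, ...) {
  rbind(
    data.frame(parameter = "dH_kcal_mol", temperature_K = NA_real_,
               value = x$dH_kcal_mol),
    data.frame(parameter = "dS_cal_mol_K", temperature_K = NA_real_,
               value = x$dS_cal_mol_K),
    data.frame(parameter = "TdS_kcal_mol",
               temperature_K = x$per_temperature$temperature_K,
               value = x$per_temperature$TdS_kcal_mol),
    data.frame(parameter = "dG_kcal_mol",
               temperature_K = x$per_temperature$temperature_K,
               value = x$per_temperature$dG_kcal_mol),
    data.frame(parameter = "r_squared", temperature_K = NA_real_,
               value = x$r_squared))
}

#' Gibbs free energy from enthalpy and entropy terms
#'
#' `dG = dH - T*dS`, with both arguments already in kcal/mol (the entropy
#' term is supplied pre-multiplied by temperature).
#'
#' @param dH_kcal_mol binding enthalpy (kcal/mol).
#' @param TdS_kcal_mol temperature times binding entropy (kcal/mol).
#' @return Gibbs free energy change in kcal/mol.
#' @examples
#' gibbs(-6.80, -0.98)  # -5.82 kcal/mol
#' @export
gibbs <- function(dH_kcal_mol, TdS_kcal_mol) {
  dH_kcal_mol - TdS_kcal_mol
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Sign-based rules relating the fitted enthalpy and entropy changes to the
#' dominant non-covalent interaction: both negative indicates van der Waals
#' contacts and hydrogen bonding; both positive indicates hydrophobic
#' association; near-zero or negative enthalpy with positive entropy
#' indicates electrostatic interactions. "Near zero" is an explicit
#' configurable band on |dH|.
#'
#' @param dH_kcal_mol binding enthalpy (kcal/mol).
#' @param dS_cal_mol_K binding entropy (cal/mol/K).
#' @param near_zero_band_kcal half-width of the |dH| band treated as
#'   "approximately zero" (kcal/mol).
#' @return an object of class `force_classification`: list with `force`
#'   (one of `"vdw_hbond"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"indeterminate"`), the inputs, and the band used.
#' @examples
#' binding_force_classification(-6.80, -3.3)   # vdw_hbond
#' @export
binding_force_classification <- function(dH_kcal_mol, dS_cal_mol_K,
                                         near_zero_band_kcal = 0.5) {
  force <- if (dS_cal_mol_K > 0 &&
               (dH_kcal_mol < 0 || abs(dH_kcal_mol) < near_zero_band_kcal)) {
    "electrostatic"
  } else if (dH_kcal_mol > 0 && dS_cal_mol_K > 0) {
    "hydrophobic"
  } else if (dH_kcal_mol < 0 && dS_cal_mol_K < 0) {
    "vdw_hbond"
  } else {
    "indeterminate"                              # dH > 0 with dS <= 0 etc.
  }
  structure(list(force = force, dH_kcal_mol = dH_kcal_mol,
                 dS_cal_mol_K = dS_cal_mol_K,
                 near_zero_band_kcal = near_zero_band_kcal),
            class = "force_classification")
}

#' @export
print.force_classification <- function(x, ...) {
  cat(sprintf("<force_classification> %s (dH = %.3g kcal/mol, dS = %.3g cal/mol/K, near-zero band %.2g)\n",
              x$force, x$dH_kcal_mol, x$dS_cal_mol_K, x$near_zero_band_kcal))
  invisible(x)
}
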