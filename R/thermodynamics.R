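# Gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

#' Standard Gibbs free energy of binding from Kd
#'
#' dG = R T ln(Kd) with Kd in mol/L against the 1 M standard state
#' (equivalently dG = -R T ln(Ka)). Returned in kJ/mol; negative for
#' sub-molar Kd, more negative for stronger binding.
#'
#' @param Kd Dissociation constant (M), > 0.
#' @param temperature_K Temperature (K).
#' @return dG in kJ/mol.
#' @export
gibbs_from_kd <- function(Kd, temperature_K = 298.15) {
  if (any(Kd <= 0)) stop("Kd must be positive", call. = FALSE)
  GAS_CONSTANT * temperature_K * log(Kd) / 1000
}

#' -T dS term in kJ/mol
#'
#' @param dS Entropy change (J mol^-1 K^-1).
#' @param temperature_K Temperature (K).
#' @return -T*dS in kJ/mol.
#' @export
minus_T_dS <- function(dS, temperature_K = 298.15) {
  -temperature_K * dS / 1000
}

#' Van't Hoff regression of ln(Kd) on 1/T
#'
#' With dG = R T ln(Kd) and dG = dH - T dS, ln(Kd) is linear in 1/T:
#' ln(Kd) = (dH/R) (1/T) - dS/R. A least-squares line through the measured
#' (T, Kd) points therefore yields dH = R * slope and dS = -R * intercept
#' (assuming dH, dS constant over the temperature span, i.e. negligible
#' heat-capacity change). dG and -T dS are then evaluated at `T_ref`.
#'
#' Weighting: `"none"` (default) is ordinary least squares;
#' `"sd"` weights each point by 1/var(ln Kd) with var(ln Kd) ~ (Kd_sd/Kd)^2
#' by error propagation, emphasising the most precisely measured Kd values.
#'
#' @param temperature_K Temperatures (K); >= 2 distinct values.
#' @param Kd Dissociation constants (M).
#' @param Kd_sd Optional Kd standard errors (M), used when
#'   `weighting = "sd"`.
#' @param T_ref Reference temperature for dG and -T dS (K).
#' @param weighting `"none"` or `"sd"`.
#' @return Object of class `vant_hoff_fit`: list with `dH` (kJ/mol), `dS`
#'   (J/mol/K), `dG_at_Tref`, `minus_TdS_at_Tref` (kJ/mol), `T_ref`,
#'   `dH_sd`, `dS_sd`, `r_squared`.
#' @export
vant_hoff_fit <- function(temperature_K, Kd, Kd_sd = NULL, T_ref = 298.15,
                          weighting = c("none", "sd")) {
  weighting <- match.arg(weighting)
  if (any(temperature_K <= 0) || any(Kd <= 0)) {
    stop("temperatures and Kd must be positive", call. = FALSE)
  }
  if (length(unique(temperature_K)) < 2L) {
    stop("rank deficient: need >= 2 distinct temperatures", call. = FALSE)
  }
  if (length(unique(temperature_K)) == 2L) {
    warning("only 2 distinct temperatures: zero residual degrees of freedom",
            call. = FALSE)
  }
  y <- log(Kd)
  invT <- 1 / temperature_K
  w <- rep(1, length(y))
  if (weighting == "sd") {
    if (is.null(Kd_sd) || any(Kd_sd <= 0)) {
      stop("weighting = 'sd' requires positive Kd_sd values", call. = FALSE)
    }
    w <- 1 / (Kd_sd / Kd)^2
  }
  fit <- stats::lm(y ~ invT, weights = w)
  co <- stats::coef(fit)
  # suppressWarnings: noise-free inputs trigger lm's perfect-fit warning
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) c(NA_real_, NA_real_))
  slope <- unname(co[2]); intercept <- unname(co[1])
  dH <- GAS_CONSTANT * slope / 1000        # kJ/mol
  dS <- -GAS_CONSTANT * intercept          # J/mol/K
  structure(list(
    dH = dH, dS = dS,
    dG_at_Tref = dH - T_ref * dS / 1000,
    minus_TdS_at_Tref = minus_T_dS(dS, T_ref),
    T_ref = T_ref,
    dH_sd = GAS_CONSTANT * unname(se[2]) / 1000,
    dS_sd = GAS_CONSTANT * unname(se[1]),
    r_squared = if (length(y) > 2) {
      suppressWarnings(summary(fit)$r.squared)
    } else NA_real_,
    slope = slope, intercept = intercept
  ), class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "<vant_hoff_fit> dH = %.1f kJ/mol, dS = %.0f J/mol/K, dG(%.2f K) = %.1f kJ/mol, -TdS = %.1f kJ/mol\n",
    x$dH, x$dS, x$T_ref, x$dG_at_Tref, x$minus_TdS_at_Tref))
  invisible(x)
}

#' Ratio of multivalent to monovalent thermodynamic magnitudes
#'
#' |multivalent| / |monovalent|; used to express, e.g., how many-fold the
#' multivalent binding entropy penalty exceeds the single-domain value
#' measured by isothermal titration calorimetry.
#'
#' @param multivalent_value,monovalent_value Same-unit quantities;
#'   `monovalent_value` nonzero.
#' @return Dimensionless ratio of magnitudes.
#' @export
monovalent_ratio <- function(multivalent_value, monovalent_value) {
  if (monovalent_value == 0) stop("monovalent value must be nonzero",
                                  call. = FALSE)
  abs(multivalent_value) / abs(monovalent_value)
}

#' Classify the thermodynamic driving force of binding
#'
#' For favorable binding (dG < 0), labels the interaction
#' `enthalpy_driven` when dH < 0 and the enthalpic term supplies more than
#' `dominance` of |dG|; `entropy_driven` when dH >= 0 so the favorable
#' -T dS term must supply all of dG (and more, offsetting any unfavorable
#' dH); `mixed` when both terms are favorable but neither dominates.
#'
#' @param fit A [vant_hoff_fit()] result (or any list with `dH`, `dS`,
#'   `T_ref`).
#' @param dominance Fraction of |dG| a favorable dH must exceed to count as
#'   enthalpy-driven.
#' @return One of `"enthalpy_driven"`, `"entropy_driven"`, `"mixed"`.
#' @export
classify_driving_force <- function(fit, dominance = 0.5) {
  dH <- fit$dH
  mTdS <- minus_T_dS(fit$dS, fit$T_ref)
  dG <- dH + mTdS
  if (dH < 0 && abs(dH) > dominance * abs(dG)) return("enthalpy_driven")
  if (dH >= 0 && mTdS < 0) return("entropy_driven")
  "mixed"
}
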