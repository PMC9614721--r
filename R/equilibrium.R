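#' Hill binding isotherm for the apparent FRET ratio
#'
#' F(x) = F0 + (Fmax - F0) * x^n / (Kd^n + x^n). At n = 1 this is the
#' standard Langmuir 1:1 isotherm; F0 is the baseline ratio at zero protein
#' (0 after acceptor direct-excitation correction).
#'
#' @param x Total protein concentration (M), >= 0.
#' @param Kd Apparent dissociation constant (M), > 0.
#' @param Fmax Maximal FRET ratio at saturation.
#' @param F0 Baseline FRET ratio.
#' @param n Hill coefficient, > 0.
#' @return Apparent FRET ratio.
#' @export
hill_model <- function(x, Kd, Fmax, F0 = 0, n = 1) {
  if (Kd <= 0 || n <= 0) stop("Kd and n must be positive", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  F0 + (Fmax - F0) * x^n / (Kd^n + x^n)
}

#' Construct a titration series
#'
#' One series = apparent FRET ratio vs total protein concentration measured
#' at a single temperature under a fixed protein:QD molar ratio (PQR).
#'
#' @param conc_M Strictly increasing total protein concentrations (M).
#' @param fret_ratio Apparent FRET ratios (replicate means).
#' @param fret_ratio_sd Per-point replicate SDs (0 if unknown).
#' @param temperature_K Temperature (K).
#' @param pqr Protein:QD molar ratio.
#' @param lectin Series label.
#' @return Object of class `titration_series`: a data frame of points with
#'   attributes `temperature_K`, `pqr`, `lectin`.
#' @export
titration_series <- function(conc_M, fret_ratio, fret_ratio_sd = 0,
                             temperature_K = 298.15, pqr = 1, lectin = "") {
  if (any(diff(conc_M) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (any(conc_M < 0) || any(!is.finite(fret_ratio))) {
    stop("invalid titration points", call. = FALSE)
  }
  fret_ratio_sd <- rep_len(fret_ratio_sd, length(conc_M))
  if (any(fret_ratio_sd < 0)) stop("SDs must be >= 0", call. = FALSE)
  structure(
    data.frame(conc_M = conc_M, fret_ratio = fret_ratio,
               fret_ratio_sd = fret_ratio_sd),
    temperature_K = temperature_K, pqr = pqr, lectin = lectin,
    class = c("titration_series", "data.frame")
  )
}

#' Fit the Hill isotherm to a titration series
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt). The Hill
#' coefficient is fixed at `fix_n` (default 1, the 1:1 assumption used when
#' each QD carries at most one lectin); pass `fix_n = NULL` to fit it. The
#' baseline F0 is fixed at 0 by default (spectra are acceptor
#' direct-excitation corrected); `fit_F0 = TRUE` frees it. When per-point
#' replicate SDs are available and `weights = "sd"`, points are weighted by
#' 1/SD^2.
#'
#' @param series A [titration_series()].
#' @param fix_n Fixed Hill coefficient, or `NULL` to estimate it.
#' @param fit_F0 Estimate the baseline instead of fixing it at 0?
#' @param weights `"sd"` (1/SD^2 when SDs are present and positive) or
#'   `"none"`.
#' @return Object of class `hill_fit`: list with `Kd`, `Fmax`, `F0`, `n`,
#'   `Kd_sd`, `Fmax_sd`, `r_squared`, `residuals`, `fitted`, `fixed`
#'   (logical flags), plus the input series.
#' @export
fit_hill <- function(series, fix_n = 1, fit_F0 = FALSE,
                     weights = c("sd", "none")) {
  weights <- match.arg(weights)
  stopifnot(inherits(series, "titration_series"))
  x <- series$conc_M
  Fobs <- series$fret_ratio
  if (length(x) < 4L) {
    warning("fewer than 4 titration points; Kd poorly constrained",
            call. = FALSE)
  }
  if (diff(range(Fobs)) < .Machine$double.eps^0.5 * max(1, abs(Fobs[1]))) {
    stop("degenerate data: FRET ratio constant across the titration",
         call. = FALSE)
  }
  w <- rep(1, length(x))
  if (weights == "sd" && all(series$fret_ratio_sd > 0)) {
    w <- 1 / series$fret_ratio_sd^2
  }

  # deterministic starting values: Fmax from the top of the curve, Kd from
  # the concentration nearest half-maximal signal
  Fmax0 <- max(Fobs)
  F00 <- if (fit_F0) min(Fobs) else 0
  Kd0 <- x[which.min(abs(Fobs - (F00 + (Fmax0 - F00) / 2)))]
  Kd0 <- max(Kd0, min(x[x > 0]), na.rm = TRUE)

  free_n <- is.null(fix_n)
  n_fix <- if (free_n) NA_real_ else fix_n

  form <- if (free_n && fit_F0) {
    fret_ratio ~ F0 + (Fmax - F0) * conc_M^n / (Kd^n + conc_M^n)
  } else if (free_n) {
    fret_ratio ~ Fmax * conc_M^n / (Kd^n + conc_M^n)
  } else if (fit_F0) {
    fret_ratio ~ F0 + (Fmax - F0) * conc_M / (Kd + conc_M)
  } else {
    fret_ratio ~ Fmax * conc_M / (Kd + conc_M)
  }
  start <- c(list(Kd = Kd0, Fmax = Fmax0),
             if (fit_F0) list(F0 = F00),
             if (free_n) list(n = 1))
  if (!free_n && n_fix != 1) {
    form <- if (fit_F0) {
      stats::as.formula(sprintf(
        "fret_ratio ~ F0 + (Fmax - F0) * conc_M^%.17g / (Kd^%.17g + conc_M^%.17g)",
        n_fix, n_fix, n_fix))
    } else {
      stats::as.formula(sprintf(
        "fret_ratio ~ Fmax * conc_M^%.17g / (Kd^%.17g + conc_M^%.17g)",
        n_fix, n_fix, n_fix))
    }
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = as.data.frame(series), start = start,
                      weights = w,
                      lower = c(Kd = 0, Fmax = -Inf,
                                if (fit_F0) c(F0 = -Inf),
                                if (free_n) c(n = 1e-6)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      stop(sprintf("Hill fit failed to converge: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(co)),
                                                     names(co)))
  fitted_vals <- stats::fitted(fit)
  res <- Fobs - fitted_vals
  ss_res <- sum(w * res^2)
  ss_tot <- sum(w * (Fobs - stats::weighted.mean(Fobs, w))^2)
  structure(list(
    Kd = unname(co["Kd"]),
    Fmax = unname(co["Fmax"]),
    F0 = if (fit_F0) unname(co["F0"]) else 0,
    n = if (free_n) unname(co["n"]) else n_fix,
    Kd_sd = unname(se["Kd"]),
    Fmax_sd = unname(se["Fmax"]),
    r_squared = 1 - ss_res / ss_tot,
    residuals = res,
    fitted = fitted_vals,
    fixed = c(n = !free_n, F0 = !fit_F0),
    series = series
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> Kd = %.3g M (+/- %.2g), Fmax = %.3g (+/- %.2g), n = %.3g%s, R2 = %.4f\n",
    x$Kd, x$Kd_sd, x$Fmax, x$Fmax_sd, x$n,
    if (x$fixed["n"]) " (fixed)" else "", x$r_squared))
  invisible(x)
}

#' Simulate a fixed-PQR titration
#'
#' Under a fixed protein:QD molar ratio the FRET ratio is proportional to
#' the *fraction* of lectin bound, so the titration traces out the binding
#' isotherm directly. `depletion = "ideal"` evaluates the hyperbola
#' F = Fmax x/(Kd + x) (free ~ total). `depletion = "mass_balance"` solves
#' the exact 1:1 quadratic at every point with protein total P0 = x and QD
#' total S0 = x/pqr (the QD treated as a single binding entity):
#' bound = ((P0 + S0 + Kd) - sqrt((P0 + S0 + Kd)^2 - 4 P0 S0)) / 2,
#' then F = Fmax * bound / P0.
#'
#' @param Kd Dissociation constant (M).
#' @param Fmax Saturating FRET ratio.
#' @param pqr Protein:QD molar ratio (> 0).
#' @param concentrations Protein concentrations (M), strictly increasing.
#' @param depletion `"ideal"` or `"mass_balance"`.
#' @param temperature_K,lectin Metadata carried on the output series.
#' @return A noise-free [titration_series()].
#' @export
simulate_fixed_pqr_titration <- function(Kd, Fmax, pqr, concentrations,
                                         depletion = c("ideal", "mass_balance"),
                                         temperature_K = 298.15, lectin = "") {
  depletion <- match.arg(depletion)
  if (pqr <= 0) stop("pqr must be positive", call. = FALSE)
  if (Kd <= 0) stop("Kd must be positive", call. = FALSE)
  x <- as.numeric(concentrations)
  F <- if (depletion == "ideal") {
    hill_model(x, Kd, Fmax)
  } else {
    P0 <- x
    S0 <- x / pqr
    bound <- ((P0 + S0 + Kd) - sqrt((P0 + S0 + Kd)^2 - 4 * P0 * S0)) / 2
    ifelse(P0 > 0, Fmax * bound / P0, 0)
  }
  titration_series(x, F, 0, temperature_K = temperature_K, pqr = pqr,
                   lectin = lectin)
}

#' Apparent Kd of a conventional fixed-QD titration
#'
#' Conventional QD-FRET assays titrate protein against a fixed QD
#' concentration and read Kd off the half-maximal signal. For strong binders
#' this is limited by ligand depletion: with total binding sites N * C_QD,
#' the half-saturation point cannot fall below C_QD * N * 50%, whatever the
#' true site constant. This function simulates that design with an
#' independent-site mass balance (site total S_tot = N * C_QD, site constant
#' `Kd_true`) and returns the protein concentration at half-maximal bound
#' signal, located by monotone interpolation on log-concentration.
#'
#' @param Kd_true True per-site dissociation constant (M).
#' @param C_QD QD concentration (M).
#' @param N Maximum proteins bound per QD (positive integer).
#' @param titration_grid Protein concentrations (M) spanning saturation.
#' @return Apparent Kd (M).
#' @export
apparent_kd_fixed_qd <- function(Kd_true, C_QD, N, titration_grid) {
  if (Kd_true <= 0 || C_QD <= 0) stop("Kd_true and C_QD must be positive",
                                      call. = FALSE)
  if (N < 1) stop("degenerate system: N must be >= 1", call. = FALSE)
  x <- sort(as.numeric(titration_grid))
  S0 <- N * C_QD
  bound <- ((x + S0 + Kd_true) - sqrt((x + S0 + Kd_true)^2 - 4 * x * S0)) / 2
  b_sat <- S0  # saturating bound signal
  if (max(bound) < 0.95 * b_sat) {
    stop("insufficient range: titration grid does not reach 95% saturation",
         call. = FALSE)
  }
  half <- b_sat / 2
  i <- which(bound >= half)[1]
  if (i == 1L) return(x[1])
  # monotone interpolation in log-concentration
  lx <- log(x)
  exp(lx[i - 1] + (half - bound[i - 1]) / (bound[i] - bound[i - 1]) *
        (lx[i] - lx[i - 1]))
}
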