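#' Construct a raw stopped-flow channel
#'
#' One channel = fluorescence intensity vs time at a single emission
#' wavelength (550 nm donor or 628 nm acceptor) for one replicate injection.
#'
#' @param time_s Uniformly sampled times (s), starting >= 0.
#' @param intensity Fluorescence intensities.
#' @param emission_nm 550 or 628.
#' @param replicate_id Replicate identifier.
#' @param role `"sample"` or `"background"`.
#' @return A data frame of class `kinetic_channel` with attributes
#'   `emission_nm`, `replicate_id`, `role`.
#' @export
kinetic_channel <- function(time_s, intensity, emission_nm,
                            replicate_id = 1L, role = "sample") {
  if (length(time_s) != length(intensity)) {
    stop("time and intensity must have equal length", call. = FALSE)
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9 * mean(dt)) {
    stop("time grid must be uniform and increasing", call. = FALSE)
  }
  if (!all(is.finite(intensity))) stop("intensities must be finite",
                                       call. = FALSE)
  structure(data.frame(time_s = time_s, intensity = intensity),
            emission_nm = emission_nm, replicate_id = replicate_id,
            role = role, class = c("kinetic_channel", "data.frame"))
}

same_grid <- function(a, b) {
  length(a$time_s) == length(b$time_s) &&
    all(abs(a$time_s - b$time_s) <= 1e-9)
}

#' Preprocess stopped-flow channels into a FRET-ratio trace
#'
#' Per emission wavelength: subtract the matching background channel from
#' each sample replicate, average replicates pointwise, then form the FRET
#' ratio as corrected 628 nm / corrected 550 nm. Optional block smoothing
#' replaces every `smoothing_block` consecutive ratio points by their mean
#' (non-overlapping blocks, block-center timestamps), e.g. block 5 on a
#' 0.0125 s grid gives 0.0625 s resolution — used when the raw ratio is too
#' noisy to fit.
#'
#' @param sample_channels List of `kinetic_channel` objects (both
#'   wavelengths, >= 1 replicate each).
#' @param background_channels List of background `kinetic_channel` objects
#'   on the same grids (one or more per wavelength; averaged if several).
#' @param smoothing_block Integer >= 1; non-overlapping block size.
#' @param x0 Initial protein concentration (M), carried as metadata.
#' @param direction `"association"` or `"dissociation"`.
#' @return A data frame of class `kinetic_trace` with columns `time_s`,
#'   `fret_ratio` and attributes `x0`, `direction`, `smoothing_block`.
#' @export
preprocess_trace <- function(sample_channels, background_channels,
                             smoothing_block = 1L, x0 = NA_real_,
                             direction = c("association", "dissociation")) {
  direction <- match.arg(direction)
  smoothing_block <- as.integer(smoothing_block)
  if (smoothing_block < 1L) stop("smoothing_block must be >= 1",
                                 call. = FALSE)
  corrected <- function(nm) {
    s <- Filter(function(ch) attr(ch, "emission_nm") == nm, sample_channels)
    b <- Filter(function(ch) attr(ch, "emission_nm") == nm,
                background_channels)
    if (length(s) == 0L || length(b) == 0L) {
      stop(sprintf("missing %d nm sample or background channel", nm),
           call. = FALSE)
    }
    for (ch in c(s, b)) if (!same_grid(ch, s[[1]])) stop_grid_mismatch()
    bg <- rowMeans(sapply(b, `[[`, "intensity"))
    rowMeans(sapply(s, function(ch) ch$intensity - bg))
  }
  donor <- corrected(550)
  acceptor <- corrected(628)
  if (any(donor <= 0)) {
    bad <- which(donor <= 0)
    stop(sprintf(
      "degenerate signal: corrected donor <= 0 at %d point(s) (first indices: %s)",
      length(bad), paste(utils::head(bad, 5), collapse = ", ")),
      call. = FALSE)
  }
  tgrid <- sample_channels[[1]]$time_s
  ratio <- acceptor / donor
  if (smoothing_block > 1L) {
    n <- (length(ratio) %/% smoothing_block) * smoothing_block
    grp <- rep(seq_len(n %/% smoothing_block), each = smoothing_block)
    ratio <- as.numeric(tapply(ratio[seq_len(n)], grp, mean))
    tgrid <- as.numeric(tapply(tgrid[seq_len(n)], grp, mean))
  }
  structure(data.frame(time_s = tgrid, fret_ratio = ratio),
            x0 = x0, direction = direction,
            smoothing_block = smoothing_block,
            class = c("kinetic_trace", "data.frame"))
}

#' Association kinetic model with linear drift
#'
#' Default (`form = "exponential"`) pseudo-first-order rise at equal donor
#' and protein concentrations x0:
#' y(t) = y_max (1 - exp(-k_on x0 t)) - a t.
#' The alternative `"hyperbolic"` form is the integrated equal-concentration
#' second-order progress curve y_max (k_on x0 t)/(1 + k_on x0 t) - a t.
#' The drift constant `a` absorbs slow linear signal change: positive a =
#' QD dimming in binding buffer; a negative fitted a indicates a slow
#' secondary association process superimposed on the main rise.
#'
#' @param t Time (s), >= 0.
#' @param y_max Saturating FRET ratio amplitude.
#' @param k_on Association rate constant (M^-1 s^-1).
#' @param x0 Initial protein concentration (M).
#' @param a Drift constant (s^-1); sign free.
#' @param form `"exponential"` or `"hyperbolic"`.
#' @return Modelled FRET ratio.
#' @export
association_model <- function(t, y_max, k_on, x0, a = 0,
                              form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  kx <- k_on * x0
  if (form == "exponential") {
    y_max * (1 - exp(-kx * t)) - a * t
  } else {
    y_max * (kx * t) / (1 + kx * t) - a * t
  }
}

#' Dissociation kinetic model with linear drift
#'
#' Pseudo-first-order decay under excess competitor:
#' y(t) = y_eq + (y_0 - y_eq) exp(-k_off' t) - a t, where k_off' is the
#' apparent (competition) dissociation rate constant.
#'
#' @param t Time (s), >= 0.
#' @param y_0 Initial FRET ratio.
#' @param y_eq Equilibrium (fully competed) FRET ratio.
#' @param k_off_prime Apparent dissociation rate constant (s^-1).
#' @param a Drift constant (s^-1).
#' @return Modelled FRET ratio.
#' @export
dissociation_model <- function(t, y_0, y_eq, k_off_prime, a = 0) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  y_eq + (y_0 - y_eq) * exp(-k_off_prime * t) - a * t
}

#' Association half-life
#'
#' t_1/2 = ln(2) / (x0 * k_on): the time for the bound signal to reach half
#' its plateau under the pseudo-first-order rise at protein concentration
#' x0.
#'
#' @param x0 Initial protein concentration (M), > 0.
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @return Half-life (s).
#' @export
half_life_association <- function(x0, k_on) {
  if (any(x0 <= 0) || any(k_on <= 0)) stop("x0 and k_on must be positive",
                                           call. = FALSE)
  log(2) / (x0 * k_on)
}

#' Dissociation half-life
#'
#' t_1/2 = ln(2) / k_off'.
#'
#' @param k_off_prime Apparent dissociation rate constant (s^-1), > 0.
#' @return Half-life (s).
#' @export
half_life_dissociation <- function(k_off_prime) {
  if (any(k_off_prime <= 0)) stop("k_off_prime must be positive",
                                  call. = FALSE)
  log(2) / k_off_prime
}

#' Fit the association model to a FRET-ratio trace
#'
#' Levenberg-Marquardt least squares over (y_max, k_on, a). Starting values
#' are deterministic: y_max from the trace maximum, rate from the time to
#' half-maximum, a = 0. The half-life is computed from the fitted k_on
#' (never fitted itself). A negative fitted `a` is flagged as secondary
#' association via the `drift_class` field.
#'
#' @param trace A [preprocess_trace()] output with
#'   `direction = "association"` and known `x0`.
#' @param form Model form passed to [association_model()].
#' @return Object of class `association_fit`: `y_max`, `k_on`, `a`,
#'   `t_half`, per-parameter `_sd` errors, `r_squared`, `drift_class`
#'   (`"qd_dimming"` for a >= 0, `"secondary_association"` for a < 0),
#'   `form`, `x0`.
#' @export
fit_association <- function(trace, form = c("exponential", "hyperbolic")) {
  form <- match.arg(form)
  stopifnot(inherits(trace, "kinetic_trace"))
  if (attr(trace, "direction") != "association") {
    stop("trace direction is not 'association'", call. = FALSE)
  }
  x0 <- attr(trace, "x0")
  if (!is.finite(x0) || x0 <= 0) stop("trace x0 must be positive",
                                      call. = FALSE)
  if (nrow(trace) < 5L) stop("insufficient data: need >= 5 points",
                             call. = FALSE)
  y <- trace$fret_ratio
  t <- trace$time_s
  ymax0 <- max(y)
  t_half0 <- t[which(y >= ymax0 / 2)[1]]
  if (!is.finite(t_half0) || t_half0 <= 0) t_half0 <- stats::median(t)
  start <- list(y_max = ymax0, k_on = log(2) / (t_half0 * x0), a = 0)
  df <- data.frame(t = t, y = y)
  formula <- if (form == "exponential") {
    y ~ y_max * (1 - exp(-k_on * x0 * t)) - a * t
  } else {
    y ~ y_max * (k_on * x0 * t) / (1 + k_on * x0 * t) - a * t
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = df, start = start,
                      lower = c(y_max = 0, k_on = 0,
                                a = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(sprintf("association fit failed: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     names(co)))
  res <- y - stats::fitted(fit)
  structure(list(
    y_max = unname(co["y_max"]), k_on = unname(co["k_on"]),
    a = unname(co["a"]),
    t_half = half_life_association(x0, unname(co["k_on"])),
    y_max_sd = unname(se["y_max"]), k_on_sd = unname(se["k_on"]),
    a_sd = unname(se["a"]),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
    drift_class = if (unname(co["a"]) < 0) "secondary_association"
                  else "qd_dimming",
    form = form, x0 = x0
  ), class = "association_fit")
}

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf(
    "<association_fit> y_max = %.3g, k_on = %.3g /M/s, a = %.3g /s (%s), t1/2 = %.3g s, R2 = %.4f\n",
    x$y_max, x$k_on, x$a, x$drift_class, x$t_half, x$r_squared))
  invisible(x)
}

#' Fit the dissociation model to a FRET-ratio trace
#'
#' Levenberg-Marquardt least squares over (y_0, y_eq, k_off_prime, a) with
#' deterministic starts (trace extrema, rate from time to half-decay,
#' a = 0). If the trace trends upward a direction-mismatch warning is
#' raised but the fit is still attempted.
#'
#' @param trace A [preprocess_trace()] output with
#'   `direction = "dissociation"`.
#' @return Object of class `dissociation_fit`: `y_0`, `y_eq`,
#'   `k_off_prime`, `a`, `t_half`, `_sd` errors, `r_squared`.
#' @export
fit_dissociation <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (attr(trace, "direction") != "dissociation") {
    stop("trace direction is not 'dissociation'", call. = FALSE)
  }
  if (nrow(trace) < 5L) stop("insufficient data: need >= 5 points",
                             call. = FALSE)
  y <- trace$fret_ratio
  t <- trace$time_s
  if (y[length(y)] > y[1]) {
    warning("direction mismatch: trace trends upward; fitting anyway",
            call. = FALSE)
  }
  m <- max(1L, length(y) %/% 20)
  y00 <- mean(y[seq_len(m)])
  yeq0 <- mean(y[seq.int(length(y) - m + 1L, length(y))])
  if (abs(y00 - yeq0) < 1e-12) y00 <- y00 + max(1e-6, abs(y00) * 1e-3)
  mid <- yeq0 + (y00 - yeq0) / 2
  crossed <- if (y00 > yeq0) y <= mid else y >= mid
  t_half0 <- t[which(crossed)[1]]
  if (!is.finite(t_half0) || t_half0 <= 0) t_half0 <- stats::median(t)
  start <- list(y_0 = y00, y_eq = yeq0, k_off_prime = log(2) / t_half0, a = 0)
  df <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y_eq + (y_0 - y_eq) * exp(-k_off_prime * t) - a * t,
      data = df, start = start,
      lower = c(y_0 = -Inf, y_eq = -Inf, k_off_prime = 0,
                a = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop(sprintf("dissociation fit failed: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4),
                                                     names(co)))
  res <- y - stats::fitted(fit)
  structure(list(
    y_0 = unname(co["y_0"]), y_eq = unname(co["y_eq"]),
    k_off_prime = unname(co["k_off_prime"]), a = unname(co["a"]),
    t_half = half_life_dissociation(unname(co["k_off_prime"])),
    y_0_sd = unname(se["y_0"]), y_eq_sd = unname(se["y_eq"]),
    k_off_prime_sd = unname(se["k_off_prime"]), a_sd = unname(se["a"]),
    r_squared = 1 - sum(res^2) / sum((y - mean(y))^2)
  ), class = "dissociation_fit")
}

#' @export
print.dissociation_fit <- function(x, ...) {
  cat(sprintf(
    "<dissociation_fit> y_0 = %.3g, y_eq = %.3g, k_off' = %.3g /s, a = %.3g /s, t1/2 = %.3g s, R2 = %.4f\n",
    x$y_0, x$y_eq, x$k_off_prime, x$a, x$t_half, x$r_squared))
  invisible(x)
}

#' Derived rate constants
#'
#' Two reconciliations of kinetics with equilibrium:
#' * `Kd_prime = k_off_prime / k_on` — the apparent Kd implied by the
#'   competition-measured dissociation rate. Because the competitor blocks
#'   rebinding, k_off' overestimates the natural off-rate and Kd_prime sits
#'   well above the equilibrium Kd for multivalent binders.
#' * `k_off_natural = k_on * Kd_equilibrium` — the dissociation rate
#'   consistent with the equilibrium Kd, a better estimate of the natural
#'   off-rate where rebinding is allowed.
#'
#' @param k_on Association rate constant (M^-1 s^-1), > 0.
#' @param k_off_prime Apparent dissociation rate (s^-1), > 0.
#' @param Kd_equilibrium Equilibrium dissociation constant (M), > 0.
#' @return List of class `derived_rates`: `Kd_prime` (M), `k_off_natural`
#'   (s^-1).
#' @export
derive_rates <- function(k_on, k_off_prime, Kd_equilibrium) {
  if (any(c(k_on, k_off_prime, Kd_equilibrium) <= 0)) {
    stop("all rate inputs must be positive", call. = FALSE)
  }
  structure(list(Kd_prime = k_off_prime / k_on,
                 k_off_natural = k_on * Kd_equilibrium),
            class = "derived_rates")
}
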