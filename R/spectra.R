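#' Construct an emission spectrum
#'
#' An emission spectrum pairs a strictly increasing wavelength grid (nm) with
#' fluorescence intensities (arbitrary units) collected at a fixed excitation
#' wavelength. Spectra intended for pointwise arithmetic (e.g. background
#' subtraction) must share an identical grid; use [resample_spectrum()] to put
#' a spectrum onto a new grid explicitly.
#'
#' @param wavelength_nm Numeric vector, strictly increasing, in nm.
#' @param intensity Numeric vector of the same length; finite values.
#' @param excitation_nm Scalar excitation wavelength in nm.
#' @param label Free-text sample identity.
#' @return An object of class `emission_spectrum`: a list with fields
#'   `wavelength_nm`, `intensity`, `excitation_nm`, `label`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm = 450,
                              label = "") {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity)) {
    stop("wavelength and intensity must have equal length", call. = FALSE)
  }
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  if (!all(is.finite(intensity))) {
    stop("intensities must be finite", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, intensity = intensity,
         excitation_nm = excitation_nm, label = label),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> '%s': %d points, %.0f-%.0f nm, ex %.0f nm\n",
              x$label, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), x$excitation_nm))
  invisible(x)
}

stop_grid_mismatch <- function() {
  stop(structure(
    class = c("qdfret_grid_mismatch", "error", "condition"),
    list(message = "wavelength/time grids do not match", call = NULL)
  ))
}

#' Background-correct a mixture spectrum
#'
#' Subtracts a protein-only (or buffer) background spectrum, recorded at the
#' same excitation wavelength and on the same wavelength grid, from a
#' mixture spectrum. This removes the acceptor direct-excitation contribution
#' so that residual acceptor emission reflects energy transfer only.
#' Negative corrected intensities (noise around zero) are kept, not clipped,
#' so that downstream averaging stays unbiased; their count is recorded in
#' the `n_negative` field and reported via a warning when nonzero.
#'
#' @param mixture,background `emission_spectrum` objects on identical grids
#'   with equal excitation wavelengths.
#' @return A `corrected_spectrum` (inherits `emission_spectrum`) with
#'   `provenance` (mixture/background labels) and `n_negative`.
#' @export
correct_spectrum <- function(mixture, background) {
  stopifnot(inherits(mixture, "emission_spectrum"),
            inherits(background, "emission_spectrum"))
  if (length(mixture$wavelength_nm) != length(background$wavelength_nm) ||
      any(mixture$wavelength_nm != background$wavelength_nm)) {
    stop_grid_mismatch()
  }
  if (mixture$excitation_nm != background$excitation_nm) {
    stop("excitation wavelengths differ between mixture and background",
         call. = FALSE)
  }
  corrected <- mixture$intensity - background$intensity
  n_neg <- sum(corrected < 0)
  if (n_neg > 0) {
    warning(sprintf("%d corrected intensities are negative (kept, not clipped)",
                    n_neg), call. = FALSE)
  }
  out <- emission_spectrum(mixture$wavelength_nm, corrected,
                           excitation_nm = mixture$excitation_nm,
                           label = mixture$label)
  out$provenance <- list(mixture = mixture$label, background = background$label)
  out$n_negative <- n_neg
  class(out) <- c("corrected_spectrum", class(out))
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; requested wavelengths must lie inside the original
#' range (no extrapolation). Resampling is never done implicitly by other
#' functions — grid mismatches are errors — so unit mistakes surface early.
#'
#' @param spectrum An `emission_spectrum`.
#' @param new_grid Strictly increasing wavelengths within the original range.
#' @return An `emission_spectrum` on `new_grid`.
#' @export
resample_spectrum <- function(spectrum, new_grid) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (min(new_grid) < min(spectrum$wavelength_nm) ||
      max(new_grid) > max(spectrum$wavelength_nm)) {
    stop("new grid extends outside the measured wavelength range",
         call. = FALSE)
  }
  yi <- stats::approx(spectrum$wavelength_nm, spectrum$intensity,
                      xout = new_grid)$y
  emission_spectrum(new_grid, yi, excitation_nm = spectrum$excitation_nm,
                    label = spectrum$label)
}

#' Extract donor and acceptor intensities from a corrected spectrum
#'
#' Reads the intensity at the grid point nearest each nominal emission
#' wavelength (QD donor ~550 nm, dye acceptor ~628 nm). With
#' `window_nm > 0` the mean over grid points within +/- `window_nm` is used
#' instead, which is slightly more robust to single-point noise on dense
#' grids.
#'
#' @param spectrum An `emission_spectrum` (typically a `corrected_spectrum`).
#' @param donor_nm,acceptor_nm Nominal peak wavelengths (nm).
#' @param window_nm Half-width of an optional averaging window (nm); 0 means
#'   nearest single grid point.
#' @return Named numeric vector `c(I_D = ..., I_A = ...)`.
#' @export
extract_intensities <- function(spectrum, donor_nm = 550, acceptor_nm = 628,
                                window_nm = 0) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength_nm
  pick <- function(nm) {
    if (nm < min(wl) || nm > max(wl)) {
      stop(sprintf("wavelength %g nm outside grid range [%g, %g]",
                   nm, min(wl), max(wl)), call. = FALSE)
    }
    if (window_nm > 0) {
      sel <- abs(wl - nm) <= window_nm
      mean(spectrum$intensity[sel])
    } else {
      spectrum$intensity[which.min(abs(wl - nm))]
    }
  }
  c(I_D = pick(donor_nm), I_A = pick(acceptor_nm))
}

#' Apparent FRET ratio
#'
#' The acceptor-to-donor intensity ratio I_A/I_D. Because it is a ratio of
#' two signals from the same sample it is independent of absolute intensity
#' scale (slit width, detector gain, concentration under fixed protein:QD
#' ratio), which is what makes it a robust binding readout.
#'
#' @param I_D Donor intensity (> 0).
#' @param I_A Acceptor intensity.
#' @return I_A / I_D.
#' @export
fret_ratio <- function(I_D, I_A) {
  if (any(I_D <= 0)) {
    stop("degenerate signal: donor intensity must be positive", call. = FALSE)
  }
  I_A / I_D
}

#' Check intensity-concentration linearity (inner-filter control)
#'
#' Fits intensity on concentration by ordinary least squares (with
#' intercept) and reports slope, intercept and R^2. If any absorbance at the
#' excitation wavelength (450 nm) is >= 0.01 the report flags inner-filter
#' risk: above that absorbance the excitation beam is attenuated enough for
#' the signal-concentration relationship to curve.
#'
#' @param concentrations Molar concentrations (>= 3 points).
#' @param intensities Matching fluorescence intensities.
#' @param absorbance_450 Optional absorbance values at 450 nm.
#' @return A list of class `linearity_report`: `slope`, `intercept`,
#'   `r_squared`, `max_absorbance_at_450`, `inner_filter_flag`.
#' @export
check_linearity <- function(concentrations, intensities,
                            absorbance_450 = NULL) {
  if (length(concentrations) < 3L) {
    stop("insufficient data: need >= 3 points for a linearity check",
         call. = FALSE)
  }
  fit <- stats::lm(intensities ~ concentrations)
  maxA <- if (is.null(absorbance_450)) NA_real_ else max(absorbance_450)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    # suppressWarnings: exactly linear input triggers the perfect-fit note
    r_squared = suppressWarnings(summary(fit)$r.squared),
    max_absorbance_at_450 = maxA,
    inner_filter_flag = isTRUE(maxA >= 0.01)
  ), class = "linearity_report")
}

#' Spectral overlap integral J
#'
#' Computes J = integral of f_D(lambda) eps_A(lambda) lambda^4 dlambda with
#' the donor emission f_D area-normalized, by trapezoidal quadrature on the
#' common wavelength grid. Units: M^-1 cm^-1 nm^4 when the acceptor
#' extinction is in M^-1 cm^-1 and wavelengths in nm.
#'
#' @param donor_emission `emission_spectrum` of the donor.
#' @param acceptor_extinction Data frame with columns `wavelength_nm` and
#'   `epsilon` (M^-1 cm^-1), on the same grid over the overlap region (use
#'   [resample_spectrum()] to align first if needed).
#' @return Overlap integral J (M^-1 cm^-1 nm^4).
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "emission_spectrum"))
  wlD <- donor_emission$wavelength_nm
  wlA <- acceptor_extinction$wavelength_nm
  lo <- max(min(wlD), min(wlA))
  hi <- min(max(wlD), max(wlA))
  if (lo >= hi) {
    stop("no spectral overlap between donor emission and acceptor extinction",
         call. = FALSE)
  }
  selD <- wlD >= lo & wlD <= hi
  grid <- wlD[selD]
  fD <- donor_emission$intensity[selD]
  area <- pracma::trapz(wlD, donor_emission$intensity)
  if (area <= 0) {
    stop("donor emission has non-positive total area; cannot normalize",
         call. = FALSE)
  }
  epsA <- stats::approx(wlA, acceptor_extinction$epsilon, xout = grid)$y
  pracma::trapz(grid, (fD / area) * epsA * grid^4)
}

#' Forster radius from photophysical parameters
#'
#' R0 = 0.02108 * (kappa^2 * n^-4 * Phi_D * J)^(1/6) nm, with J in
#' M^-1 cm^-1 nm^4. Defaults assume isotropic dynamic orientational
#' averaging (kappa^2 = 2/3) in aqueous buffer (n = 1.33).
#'
#' @param J Overlap integral (M^-1 cm^-1 nm^4).
#' @param donor_qy Donor fluorescence quantum yield, in (0, 1].
#' @param kappa2 Orientation factor.
#' @param refractive_index Medium refractive index.
#' @return Forster radius in nm.
#' @export
forster_radius <- function(J, donor_qy, kappa2 = 2 / 3,
                           refractive_index = 1.33) {
  if (any(c(J, donor_qy, kappa2, refractive_index) <= 0)) {
    stop("all Forster-radius inputs must be positive", call. = FALSE)
  }
  0.02108 * (kappa2 * refractive_index^-4 * donor_qy * J)^(1 / 6)
}

#' FRET-pair specification
#'
#' Bundles the photophysical parameters of a donor-acceptor pair and checks
#' that the stated Forster radius is consistent with them.
#'
#' @param donor_qy Donor quantum yield.
#' @param kappa2 Orientation factor.
#' @param refractive_index Medium refractive index.
#' @param overlap_integral_J Overlap integral (M^-1 cm^-1 nm^4).
#' @param forster_radius_R0 Forster radius (nm); if `NULL` it is computed.
#' @return A list of class `fret_pair_spec`.
#' @export
fret_pair_spec <- function(donor_qy, kappa2 = 2 / 3, refractive_index = 1.33,
                           overlap_integral_J, forster_radius_R0 = NULL) {
  R0 <- forster_radius(overlap_integral_J, donor_qy, kappa2, refractive_index)
  if (!is.null(forster_radius_R0)) {
    if (abs(forster_radius_R0 - R0) > 1e-9 * R0) {
      stop("stated Forster radius inconsistent with (QY, kappa2, n, J)",
           call. = FALSE)
    }
    R0 <- forster_radius_R0
  }
  structure(list(donor_qy = donor_qy, kappa2 = kappa2,
                 refractive_index = refractive_index,
                 overlap_integral_J = overlap_integral_J,
                 forster_radius_R0 = R0),
            class = "fret_pair_spec")
}
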