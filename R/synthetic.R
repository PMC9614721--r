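#' Generate a noisy replicate-averaged titration series
#'
#' Evaluates the fixed-PQR binding model at each concentration, draws
#' `n_replicates` Gaussian-noise realizations per point (additive noise in
#' FRET-ratio units, emulating triplicate measurements), and returns the
#' replicate mean and SD per point together with the ground-truth record.
#'
#' @param Kd True dissociation constant (M).
#' @param Fmax True saturating FRET ratio.
#' @param pqr Protein:QD molar ratio.
#' @param concentrations Protein concentrations (M), strictly increasing.
#' @param noise_sd Per-replicate additive noise SD (FRET-ratio units).
#' @param n_replicates Replicates per concentration.
#' @param seed Integer RNG seed.
#' @param depletion `"ideal"` or `"mass_balance"` (see
#'   [simulate_fixed_pqr_titration()]).
#' @param temperature_K,lectin Metadata on the output series.
#' @return List with `series` (a [titration_series()]) and `truth` (all
#'   generator parameters, including the seed).
#' @export
gen_titration <- function(Kd, Fmax, pqr = 1, concentrations,
                          noise_sd = 0.05, n_replicates = 3, seed = 1,
                          depletion = c("ideal", "mass_balance"),
                          temperature_K = 298.15, lectin = "synthetic") {
  depletion <- match.arg(depletion)
  if (length(concentrations) == 0L) {
    stop("concentration list must be non-empty", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ideal <- simulate_fixed_pqr_titration(Kd, Fmax, pqr, concentrations,
                                        depletion = depletion,
                                        temperature_K = temperature_K,
                                        lectin = lectin)
  set.seed(seed)
  reps <- matrix(stats::rnorm(length(concentrations) * n_replicates,
                              mean = rep(ideal$fret_ratio,
                                         each = n_replicates),
                              sd = noise_sd),
                 nrow = n_replicates)
  series <- titration_series(
    concentrations,
    colMeans(reps),
    if (n_replicates > 1) apply(reps, 2, stats::sd) else 0,
    temperature_K = temperature_K, pqr = pqr, lectin = lectin
  )
  list(series = series,
       truth = list(Kd = Kd, Fmax = Fmax, pqr = pqr, noise_sd = noise_sd,
                    n_replicates = n_replicates, seed = seed,
                    depletion = depletion))
}

#' Generate an exact temperature-dependent Kd series
#'
#' Inverts the Van't Hoff relation: Kd(T) = exp(dH*1000/(R*T) - dS/R) with
#' dH in kJ/mol and dS in J/mol/K. Noise-free by design — refitting these
#' points recovers (dH, dS) exactly.
#'
#' @param dH Enthalpy change (kJ/mol).
#' @param dS Entropy change (J/mol/K).
#' @param temperatures_K Temperatures (K), > 0.
#' @return Data frame with `temperature_K` and `Kd` (M).
#' @export
gen_temperature_series <- function(dH, dS, temperatures_K) {
  if (any(temperatures_K <= 0)) stop("temperatures must be positive",
                                     call. = FALSE)
  data.frame(
    temperature_K = temperatures_K,
    Kd = exp(dH * 1000 / (GAS_CONSTANT * temperatures_K) - dS / GAS_CONSTANT)
  )
}

#' Generate raw stopped-flow channel pairs from a kinetic model
#'
#' Builds the noiseless FRET-ratio curve from the requested model, then
#' decomposes it into plausible donor (550 nm) and acceptor (628 nm)
#' channels — donor falling as acceptor rises, conserving the target ratio:
#' with bound fraction f(t) = ratio(t)/max ratio, donor = D0 (1 - phi f),
#' acceptor = ratio * donor. Additive Gaussian noise is applied per channel
#' and per replicate, and matching zero-mean background channel pairs are
#' emitted at the same noise level.
#'
#' @param direction `"association"` or `"dissociation"`.
#' @param params Named list of model parameters:
#'   association `y_max`, `k_on`, `a` (and optional `form`);
#'   dissociation `y_0`, `y_eq`, `k_off_prime`, `a`.
#' @param x0 Initial protein concentration (M).
#' @param duration_s Trace length (s).
#' @param dt_s Sampling interval (s).
#' @param noise_sd Additive channel noise SD (intensity units).
#' @param n_replicates Replicates per channel.
#' @param seed Integer RNG seed.
#' @param D0 Donor amplitude (intensity units).
#' @param phi Fraction of donor quenched at full binding (0-1).
#' @return List with `sample_channels`, `background_channels` (lists of
#'   [kinetic_channel()]) and `truth`.
#' @export
gen_kinetic_trace <- function(direction = c("association", "dissociation"),
                              params, x0 = 20e-9, duration_s = 60,
                              dt_s = 0.0125, noise_sd = 0, n_replicates = 3,
                              seed = 1, D0 = 100, phi = 0.6) {
  direction <- match.arg(direction)
  if (dt_s <= 0 || duration_s <= dt_s) stop("invalid time grid",
                                            call. = FALSE)
  t <- seq(0, duration_s, by = dt_s)
  ratio <- if (direction == "association") {
    association_model(t, params$y_max, params$k_on, x0, params$a,
                      form = if (is.null(params$form)) "exponential"
                             else params$form)
  } else {
    dissociation_model(t, params$y_0, params$y_eq, params$k_off_prime,
                       params$a)
  }
  # channel decomposition: donor falls with bound fraction, acceptor
  # carries the remainder so acceptor/donor reproduces the target ratio
  f <- ratio / max(abs(ratio), .Machine$double.eps)
  donor <- D0 * (1 - phi * pmin(pmax(f, 0), 1))
  acceptor <- ratio * donor

  set.seed(seed)
  mk <- function(base, nm, role) {
    lapply(seq_len(n_replicates), function(r) {
      kinetic_channel(t, base + stats::rnorm(length(t), 0, noise_sd),
                      emission_nm = nm, replicate_id = r, role = role)
    })
  }
  zero <- numeric(length(t))
  list(
    sample_channels = c(mk(donor, 550, "sample"),
                        mk(acceptor, 628, "sample")),
    background_channels = c(mk(zero, 550, "background"),
                            mk(zero, 628, "background")),
    truth = c(params, list(direction = direction, x0 = x0,
                           duration_s = duration_s, dt_s = dt_s,
                           noise_sd = noise_sd, n_replicates = n_replicates,
                           seed = seed, D0 = D0, phi = phi))
  )
}

#' Generate a synthetic particle field in a given dispersion state
#'
#' * `simultaneous` — hard-core point process: particles placed uniformly
#'   with a minimum pairwise spacing far above the linking distance, so
#'   essentially all particles are isolated.
#' * `cross_linking` — Thomas-like cluster process: parent points with
#'   Poisson-distributed offspring counts (mean `offspring_mean`, minimum
#'   2) scattered around each parent with SD `offspring_sd_nm`.
#' * `mixed` — a mixture targeting the intermediate dispersion pattern
#'   (roughly 40% isolated, 55% in 2-3 groupings, 5% in >= 4): isolated
#'   hard-core particles plus small clusters of size 2-3 plus a rare
#'   larger cluster.
#'
#' @param mode `"simultaneous"`, `"mixed"` or `"cross_linking"`.
#' @param n_particles Target particle count, > 0.
#' @param field_size `(width, height)` nm.
#' @param seed Integer RNG seed.
#' @param min_spacing_nm Hard-core minimum spacing (isolated particles).
#' @param offspring_mean,offspring_sd_nm Cluster process parameters.
#' @param mixed_weights Particle-number fractions `(isolated, 2-3, 4+)`
#'   targeted in mixed mode.
#' @return List with `field` (a [particle_field()]) and `truth`.
#' @export
gen_particle_field <- function(mode = c("simultaneous", "mixed",
                                        "cross_linking"),
                               n_particles = 200,
                               field_size = c(2000, 2000), seed = 1,
                               min_spacing_nm = 60,
                               offspring_mean = 6, offspring_sd_nm = 4,
                               mixed_weights = c(0.40, 0.55, 0.05)) {
  mode <- match.arg(mode)
  if (n_particles <= 0) stop("n_particles must be positive", call. = FALSE)
  set.seed(seed)

  place_hardcore <- function(k, existing = NULL) {
    pts <- existing
    tries <- 0L
    while ((if (is.null(pts)) 0L else nrow(pts)) <
           k + (if (is.null(existing)) 0L else nrow(existing))) {
      cand <- c(stats::runif(1, 0, field_size[1]),
                stats::runif(1, 0, field_size[2]))
      ok <- is.null(pts) ||
        all((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 >=
              min_spacing_nm^2)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
      if (tries > 1000L * k) {
        stop("retry limit: hard-core packing infeasible at this density",
             call. = FALSE)
      }
    }
    pts
  }
  jitter_cluster <- function(center, size) {
    cbind(stats::rnorm(size, center[1], offspring_sd_nm),
          stats::rnorm(size, center[2], offspring_sd_nm))
  }
  clamp <- function(p) {
    p[, 1] <- pmin(pmax(p[, 1], 0), field_size[1])
    p[, 2] <- pmin(pmax(p[, 2], 0), field_size[2])
    p
  }

  pts <- switch(mode,
    simultaneous = place_hardcore(n_particles),
    cross_linking = {
      acc <- NULL
      centers <- NULL
      while (is.null(acc) || nrow(acc) < n_particles) {
        centers <- place_hardcore(1, centers)
        ctr <- centers[nrow(centers), ]
        size <- max(2L, stats::rpois(1, offspring_mean))
        acc <- rbind(acc, jitter_cluster(ctr, size))
      }
      acc[seq_len(n_particles), , drop = FALSE]
    },
    mixed = {
      n_iso <- round(mixed_weights[1] * n_particles)
      n_small <- round(mixed_weights[2] * n_particles)
      n_large <- n_particles - n_iso - n_small
      centers <- place_hardcore(n_iso)
      acc <- centers
      got <- 0L
      while (got < n_small) {
        centers <- place_hardcore(1, centers)
        ctr <- centers[nrow(centers), ]
        size <- min(sample(2:3, 1), n_small - got)
        size <- max(size, 1L)
        acc <- rbind(acc, jitter_cluster(ctr, size))
        got <- got + size
      }
      while (n_large > 0) {
        centers <- place_hardcore(1, centers)
        ctr <- centers[nrow(centers), ]
        size <- min(max(4L, stats::rpois(1, 5)), n_large)
        acc <- rbind(acc, jitter_cluster(ctr, size))
        n_large <- n_large - size
      }
      acc
    }
  )
  pts <- clamp(pts)
  list(field = particle_field(pts[, 1], pts[, 2], field_size = field_size),
       truth = list(mode = mode, n_particles = nrow(pts),
                    field_size = field_size, seed = seed,
                    min_spacing_nm = min_spacing_nm,
                    offspring_mean = offspring_mean,
                    offspring_sd_nm = offspring_sd_nm))
}

#' Render a particle field as a synthetic spot image
#'
#' Draws one Gaussian spot per centroid on a pixel grid, for end-to-end
#' tests of [detect_particles()]. Purely synthetic; no electron-optics
#' modelling beyond optional additive Gaussian noise.
#'
#' @param field A [particle_field()].
#' @param pixel_size nm per pixel.
#' @param spot_sigma_px Gaussian spot SD in pixels.
#' @param amplitude Peak spot intensity.
#' @param noise_sd Additive background noise SD.
#' @param seed Seed for the noise.
#' @return Numeric matrix (rows = y, columns = x).
#' @export
gen_particle_image <- function(field, pixel_size = 4, spot_sigma_px = 1.5,
                               amplitude = 100, noise_sd = 0, seed = 1) {
  fs <- attr(field, "field_size")
  nc <- ceiling(fs[1] / pixel_size)
  nr <- ceiling(fs[2] / pixel_size)
  img <- matrix(0, nr, nc)
  half <- ceiling(5 * spot_sigma_px)  # spots rendered within +/- 5 sigma
  for (i in seq_len(nrow(field))) {
    px <- field$x_nm[i] / pixel_size
    py <- field$y_nm[i] / pixel_size
    ci <- max(1L, floor(px - half)):min(nc, ceiling(px + half))
    ri <- max(1L, floor(py - half)):min(nr, ceiling(py + half))
    img[ri, ci] <- img[ri, ci] + amplitude *
      exp(-(outer((ri - 0.5 - py)^2, (ci - 0.5 - px)^2, `+`)) /
            (2 * spot_sigma_px^2))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  img
}

#' Glycan valency per nanoparticle from a ligand mass balance
#'
#' (ligand added - ligand left unbound after cap exchange) / QD amount.
#'
#' @param ligand_added_mol,ligand_unbound_mol Ligand amounts (mol), with
#'   added >= unbound >= 0.
#' @param qd_mol QD amount (mol), > 0.
#' @return Mean glycans per QD.
#' @export
estimate_valency <- function(ligand_added_mol, ligand_unbound_mol, qd_mol) {
  if (qd_mol <= 0) stop("qd_mol must be positive", call. = FALSE)
  if (ligand_unbound_mol < 0 || ligand_unbound_mol > ligand_added_mol) {
    stop("measurement inconsistency: unbound ligand exceeds added ligand",
         call. = FALSE)
  }
  (ligand_added_mol - ligand_unbound_mol) / qd_mol
}

#' Mean inter-glycan distance on a spherical nanoparticle
#'
#' Divides the sphere surface (area pi * Dh^2) among `valency` ligands and
#' converts the per-ligand area A to a nearest-neighbour spacing:
#' hexagonal packing d = sqrt(2A/sqrt(3)), square packing d = sqrt(A).
#' A flat-packing estimate on a curved surface, so a lower bound on the
#' true spacing.
#'
#' @param Dh_nm Hydrodynamic diameter (nm).
#' @param valency Ligands per particle.
#' @param packing `"hexagonal"` or `"square"`.
#' @return Spacing in nm.
#' @export
estimate_inter_glycan_distance <- function(Dh_nm, valency,
                                           packing = c("hexagonal",
                                                       "square")) {
  packing <- match.arg(packing)
  if (Dh_nm <= 0 || valency <= 0) stop("inputs must be positive",
                                       call. = FALSE)
  A <- pi * Dh_nm^2 / valency
  if (packing == "hexagonal") sqrt(2 * A / sqrt(3)) else sqrt(A)
}

#' Synthetic two-peak emission spectrum
#'
#' Sum of Gaussian peaks on a regular wavelength grid; used to emulate
#' donor (~550 nm) and acceptor (~628 nm) emission in tests and examples.
#'
#' @param peaks Data frame with columns `center_nm`, `sigma_nm`, `amp`.
#' @param from_nm,to_nm,by_nm Wavelength grid (nm).
#' @param excitation_nm,label Spectrum metadata.
#' @return An [emission_spectrum()].
#' @export
gen_spectrum <- function(peaks, from_nm = 480, to_nm = 750, by_nm = 1,
                         excitation_nm = 450, label = "synthetic") {
  wl <- seq(from_nm, to_nm, by = by_nm)
  intensity <- rep(0, length(wl))
  for (i in seq_len(nrow(peaks))) {
    intensity <- intensity + peaks$amp[i] *
      exp(-(wl - peaks$center_nm[i])^2 / (2 * peaks$sigma_nm[i]^2))
  }
  emission_spectrum(wl, intensity, excitation_nm = excitation_nm,
                    label = label)
}
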