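#' Van't Hoff thermodynamic summary per lectin
#'
#' Runs [vant_hoff_fit()] on each lectin's (T, Kd) block of an affinity
#' table and assembles the standard-state summary: dH (kJ/mol), dS
#' (J/mol/K), dG and -T dS at `T_ref`, plus the driving-force label.
#'
#' @param affinity Data frame with columns `lectin`, `temperature_K`,
#'   `Kd`, optionally `Kd_sd` (see [affinity_temperature_table()]).
#' @param T_ref Reference temperature (K).
#' @param weighting Passed to [vant_hoff_fit()].
#' @return Data frame, one row per lectin: `lectin`, `dH_kJ_mol`,
#'   `dH_sd`, `dS_J_mol_K`, `dS_sd`, `dG_kJ_mol`, `minus_TdS_kJ_mol`,
#'   `driving_force`.
#' @export
thermodynamic_summary <- function(affinity, T_ref = 298.15,
                                  weighting = "none") {
  out <- lapply(split(affinity, affinity$lectin), function(blk) {
    fit <- vant_hoff_fit(blk$temperature_K, blk$Kd, blk$Kd_sd,
                         T_ref = T_ref, weighting = weighting)
    data.frame(lectin = blk$lectin[1],
               dH_kJ_mol = fit$dH, dH_sd = fit$dH_sd,
               dS_J_mol_K = fit$dS, dS_sd = fit$dS_sd,
               dG_kJ_mol = fit$dG_at_Tref,
               minus_TdS_kJ_mol = fit$minus_TdS_at_Tref,
               driving_force = classify_driving_force(fit))
  })
  res <- do.call(rbind, out[unique(affinity$lectin)])
  rownames(res) <- NULL
  res
}

#' Kinetic summary with half-lives and derived rates
#'
#' From per-lectin fitted rate constants, computes the association
#' half-life ln(2)/(x0 k_on), the dissociation half-life ln(2)/k_off', the
#' competition-implied Kd' = k_off'/k_on, and (when an equilibrium Kd is
#' supplied) the equilibrium-consistent natural k_off = k_on Kd.
#'
#' @param kinetics Data frame as returned by [kinetic_parameter_table()].
#' @param x0 Protein concentration of the association runs (M).
#' @param Kd_equilibrium Optional named vector of equilibrium Kd values
#'   (M) per lectin, for the natural off-rate.
#' @return Data frame, one row per lectin.
#' @export
kinetic_summary <- function(kinetics, x0 = 20e-9, Kd_equilibrium = NULL) {
  k_on <- kinetics$assoc_k_on_1e7 * 1e7
  k_off_prime <- kinetics$dissoc_k_off_prime
  res <- data.frame(
    lectin = kinetics$lectin,
    k_on_M_s = k_on,
    t_half_assoc_s = half_life_association(x0, k_on),
    k_off_prime_s = k_off_prime,
    t_half_dissoc_s = half_life_dissociation(k_off_prime),
    Kd_prime_M = k_off_prime / k_on,
    drift_class_assoc = ifelse(kinetics$assoc_a_1e3 < 0,
                               "secondary_association", "qd_dimming")
  )
  res$k_off_natural_s <- if (is.null(Kd_equilibrium)) NA_real_ else {
    unname(k_on * Kd_equilibrium[as.character(kinetics$lectin)])
  }
  res
}

#' Cluster-state summary per dispersion mode
#'
#' Groups each field with [cluster_particles()], summarizes the
#' per-particle size-class fractions, and classifies the binding mode.
#'
#' @param fields Named list of [particle_field()] objects.
#' @param link_distance Linking distance (nm).
#' @return Data frame: `sample`, `n_particles`, `f_isolated`, `f_2_3`,
#'   `f_4_plus`, `mode_label`.
#' @export
cluster_state_summary <- function(fields, link_distance) {
  out <- lapply(names(fields), function(nm) {
    sizes <- cluster_particles(fields[[nm]], link_distance)
    s <- summarize_clusters(sizes)
    data.frame(sample = nm, n_particles = s$n_particles,
               f_isolated = s$f_isolated, f_2_3 = s$f_2_3,
               f_4_plus = s$f_4_plus,
               mode_label = classify_binding_mode(s))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
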