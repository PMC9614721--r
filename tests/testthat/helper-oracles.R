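# Independent oracles used to cross-check the package's fitters and
# clustering. These deliberately use brute force / full enumeration and
# never call the code paths they check.

# single-linkage clustering by union-find over the full distance matrix
brute_force_cluster_sizes <- function(x, y, link_distance) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= link_distance) {
        a <- find(i); b <- find(j)
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(sort(tabulate(match(roots, unique(roots))), decreasing = TRUE))
}

# exhaustive 2-D grid search minimizing the same weighted Hill SSE
grid_search_hill <- function(series, Kd_range, Fmax_range, n_grid = 201) {
  Kd_grid <- exp(seq(log(Kd_range[1]), log(Kd_range[2]),
                     length.out = n_grid))
  Fmax_grid <- seq(Fmax_range[1], Fmax_range[2], length.out = n_grid)
  w <- if (all(series$fret_ratio_sd > 0)) 1 / series$fret_ratio_sd^2 else
    rep(1, nrow(series))
  best <- list(sse = Inf)
  for (Kd in Kd_grid) {
    pred_base <- series$conc_M / (Kd + series$conc_M)
    for (Fmax in Fmax_grid) {
      sse <- sum(w * (series$fret_ratio - Fmax * pred_base)^2)
      if (sse < best$sse) best <- list(sse = sse, Kd = Kd, Fmax = Fmax)
    }
  }
  best
}

# exhaustive 3-D grid search for the exponential association SSE
grid_search_association <- function(trace, x0, k_on_range, y_max_range,
                                    a_range, n_grid = 41) {
  kg <- exp(seq(log(k_on_range[1]), log(k_on_range[2]), length.out = n_grid))
  yg <- seq(y_max_range[1], y_max_range[2], length.out = n_grid)
  ag <- seq(a_range[1], a_range[2], length.out = n_grid)
  t <- trace$time_s; y <- trace$fret_ratio
  best <- list(sse = Inf)
  for (k in kg) {
    ek <- 1 - exp(-k * x0 * t)
    for (ym in yg) {
      base <- ym * ek
      for (a in ag) {
        sse <- sum((y - base + a * t)^2)
        if (sse < best$sse) best <- list(sse = sse, k_on = k, y_max = ym,
                                         a = a)
      }
    }
  }
  best
}

# shared synthetic two-peak donor/acceptor spectrum parameters
donor_peak <- data.frame(center_nm = 550, sigma_nm = 15, amp = 100)
acceptor_peak <- data.frame(center_nm = 628, sigma_nm = 20, amp = 40)
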