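#' Construct a particle field
#'
#' Nanoparticle centroid positions (nm) inside a rectangular field, as
#' extracted from (S/T)EM micrographs or generated synthetically.
#'
#' @param x_nm,y_nm Centroid coordinates (nm).
#' @param field_size Numeric length-2 `(width, height)` in nm.
#' @param pixel_size Optional nm/pixel provenance.
#' @return Data frame of class `particle_field` with attributes
#'   `field_size`, `pixel_size`.
#' @export
particle_field <- function(x_nm, y_nm, field_size, pixel_size = NA_real_) {
  if (length(x_nm) != length(y_nm)) stop("x and y lengths differ",
                                         call. = FALSE)
  if (length(x_nm) > 0 &&
      (any(x_nm < 0) || any(y_nm < 0) ||
       any(x_nm > field_size[1]) || any(y_nm > field_size[2]))) {
    stop("centroids outside field bounds", call. = FALSE)
  }
  structure(data.frame(x_nm = x_nm, y_nm = y_nm),
            field_size = field_size, pixel_size = pixel_size,
            class = c("particle_field", "data.frame"))
}

#' Group particles into clusters by single linkage
#'
#' Two particles closer than `link_distance` belong to the same cluster,
#' transitively (single-linkage agglomeration, cut at `link_distance`).
#' The reported size classes are computed downstream by
#' [summarize_clusters()].
#'
#' @param field A [particle_field()].
#' @param link_distance Linking distance (nm), > 0. A sensible default is
#'   1.5x the nominal particle diameter.
#' @return Integer vector of cluster sizes (multiset), one entry per
#'   cluster; empty for an empty field.
#' @export
cluster_particles <- function(field, link_distance) {
  if (link_distance <= 0) stop("link_distance must be positive",
                               call. = FALSE)
  n <- nrow(field)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::dist(cbind(field$x_nm, field$y_nm)),
                      method = "single")
  # cutree(h = d) merges links with height <= d; "within link_distance"
  membership <- stats::cutree(hc, h = link_distance)
  as.integer(sort(tabulate(membership), decreasing = TRUE))
}

#' Summarize cluster sizes into per-particle fractions
#'
#' Fractions are per particle (fraction of QDs), not per cluster: a
#' cluster of size k contributes k particles to its size class. Classes
#' follow the {1, 2-3, >=4} convention.
#'
#' @param cluster_sizes Integer multiset of cluster sizes.
#' @return List of class `cluster_summary`: `n_particles`, `n_clusters`,
#'   `cluster_sizes`, `f_isolated`, `f_2_3`, `f_4_plus`.
#' @export
summarize_clusters <- function(cluster_sizes) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (length(cluster_sizes) == 0L) {
    stop("undefined fractions: empty cluster-size multiset", call. = FALSE)
  }
  if (any(cluster_sizes < 1L)) stop("cluster sizes must be >= 1",
                                    call. = FALSE)
  N <- sum(cluster_sizes)
  structure(list(
    n_particles = N,
    n_clusters = length(cluster_sizes),
    cluster_sizes = cluster_sizes,
    f_isolated = sum(cluster_sizes[cluster_sizes == 1L]) / N,
    f_2_3 = sum(cluster_sizes[cluster_sizes %in% 2:3]) / N,
    f_4_plus = sum(cluster_sizes[cluster_sizes >= 4L]) / N
  ), class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(
    "<cluster_summary> %d particles in %d clusters: isolated %.1f%%, 2-3 %.1f%%, >=4 %.1f%%\n",
    x$n_particles, x$n_clusters, 100 * x$f_isolated, 100 * x$f_2_3,
    100 * x$f_4_plus))
  invisible(x)
}

#' Classify the multivalent binding mode from cluster fractions
#'
#' A tetrameric lectin engaging one nanoparticle with all binding domains
#' (simultaneous binding) leaves particles isolated; bridging several
#' particles (cross-linking) builds large assemblies. Defaults:
#' `simultaneous` when >= 90% of particles are isolated; `cross_linking`
#' when <= 30% are isolated and >= 15% sit in clusters of >= 4; `mixed`
#' otherwise.
#'
#' @param summary A [summarize_clusters()] result.
#' @param simultaneous_min_isolated,crosslink_max_isolated,crosslink_min_4plus
#'   Classification thresholds (fractions).
#' @return `"simultaneous"`, `"cross_linking"` or `"mixed"`.
#' @export
classify_binding_mode <- function(summary,
                                  simultaneous_min_isolated = 0.9,
                                  crosslink_max_isolated = 0.3,
                                  crosslink_min_4plus = 0.15) {
  stopifnot(inherits(summary, "cluster_summary"))
  if (summary$f_isolated >= simultaneous_min_isolated) return("simultaneous")
  if (summary$f_isolated <= crosslink_max_isolated &&
      summary$f_4_plus >= crosslink_min_4plus) return("cross_linking")
  "mixed"
}

# EBImage::bwlabel is 4-connected; union labels that touch diagonally to
# obtain 8-connectivity, then renumber densely.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  k <- max(lab)
  if (k == 0L || nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

#' Detect particles in a 2-D intensity image
#'
#' Binarizes at `threshold`, labels connected components (8-connectivity),
#' discards components smaller than `min_area_px`, and returns
#' intensity-weighted centroids scaled to nm. Spots that overlap closer
#' than a spot diameter merge into one component — a known limitation of
#' connectivity-based detection.
#'
#' @param image Numeric matrix of intensities (rows = y, columns = x).
#' @param threshold Binarization threshold (intensity units).
#' @param min_area_px Minimum component area in pixels.
#' @param pixel_size nm per pixel.
#' @return A [particle_field()] (possibly empty, with a warning).
#' @export
detect_particles <- function(image, threshold, min_area_px = 1,
                             pixel_size = 1) {
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  mask <- image > threshold
  if (!any(mask)) {
    warning("no components found above threshold", call. = FALSE)
    return(particle_field(numeric(0), numeric(0),
                          field_size = rev(dim(image)) * pixel_size,
                          pixel_size = pixel_size))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- merge_diagonal_labels(lab)
  labv <- as.integer(lab)
  keep <- which(tabulate(labv) >= min_area_px)
  nr <- nrow(image)
  idx <- which(labv > 0 & labv %in% keep)
  if (length(idx) == 0L) {
    warning("no components of sufficient area", call. = FALSE)
    return(particle_field(numeric(0), numeric(0),
                          field_size = rev(dim(image)) * pixel_size,
                          pixel_size = pixel_size))
  }
  comp <- labv[idx]
  wgt <- as.numeric(image)[idx]
  row_i <- ((idx - 1L) %% nr) + 1L   # y (row)
  col_i <- ((idx - 1L) %/% nr) + 1L  # x (column)
  cx <- tapply(wgt * col_i, comp, sum) / tapply(wgt, comp, sum)
  cy <- tapply(wgt * row_i, comp, sum) / tapply(wgt, comp, sum)
  particle_field((as.numeric(cx) - 0.5) * pixel_size,
                 (as.numeric(cy) - 0.5) * pixel_size,
                 field_size = c(ncol(image), nrow(image)) * pixel_size,
                 pixel_size = pixel_size)
}
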