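# Per-ROI peptide-site calling and pattern statistics.
#
# Each ROI's member localizations are rendered at the design's
# super-resolution oversampling, the image is normalized and Gaussian
# smoothed, and local maxima are taken as candidate site positions.
# Maxima closer than a fraction of the designed inter-site distance are
# merged, a single-linkage clustering keeps only the central cluster
# (rejecting maxima that belong to a neighboring structure or background),
# and per-ROI statistics (site count, mean nearest-neighbor distance) are
# accumulated into a pattern summary.

#' Site-calling parameters
#'
#' @param smoothing_sigma_px Gaussian smoothing SD in super-resolution
#'   pixels, so the physical smoothing scale follows the per-design
#'   oversampling.
#' @param merge_factor Maxima closer than `merge_factor * nominal_edge_nm`
#'   are merged (default 0.5).
#' @param cluster_link_factor Single-linkage cutoff as a fraction of the
#'   design edge. The default 2.1 exceeds the hexagon diameter (2 edges),
#'   so every subset of pattern vertices — including opposite vertices of
#'   a partially occupied hexagon — stays in one cluster, while maxima
#'   from neighboring structures (hundreds of nm away) are still cut off.
#' @param maxima_rel_threshold Minimum maxima intensity as a fraction of
#'   the smoothed-image maximum.
#' @return List of class `site_params`.
#' @export
site_params <- function(smoothing_sigma_px = 1.0, merge_factor = 0.5,
                        cluster_link_factor = 2.1,
                        maxima_rel_threshold = 0.2) {
  stopifnot(smoothing_sigma_px > 0, merge_factor > 0, merge_factor < 1,
            cluster_link_factor > 0, maxima_rel_threshold >= 0,
            maxima_rel_threshold <= 1)
  structure(
    list(smoothing_sigma_px = smoothing_sigma_px,
         merge_factor = merge_factor,
         cluster_link_factor = cluster_link_factor,
         maxima_rel_threshold = maxima_rel_threshold),
    class = "site_params"
  )
}

# strict 8-neighborhood local maxima at or above thr; returns index matrix
.local_maxima <- function(im, thr) {
  nr <- nrow(im); nc <- ncol(im)
  if (nr < 3 || nc < 3) return(matrix(numeric(0), 0, 2))
  core <- im[2:(nr - 1), 2:(nc - 1)]
  ok <- core >= thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & core > im[2:(nr - 1) + di, 2:(nc - 1) + dj, drop = FALSE]
  }
  w <- which(ok, arr.ind = TRUE)
  if (!nrow(w)) return(matrix(numeric(0), 0, 2))
  w + 1L  # back to full-image indices
}

# intensity-weighted 3x3 centroid refinement; returns fractional indices
.refine_maxima <- function(im, peaks) {
  t(apply(peaks, 1, function(p) {
    W <- im[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1)]
    W <- W - min(W)
    s <- sum(W)
    if (s <= 0) return(as.numeric(p))
    p + c(sum((-1:1) * rowSums(W)), sum((-1:1) * colSums(W))) / s
  }))
}

#' Merge nearby maxima
#'
#' Iteratively replaces the closest pair of points at distance below
#' `min_dist_nm` by its intensity-weighted centroid until all pairwise
#' distances are at least `min_dist_nm`.
#'
#' @param points_nm Numeric matrix (n x 2) of positions, nm.
#' @param min_dist_nm Merging threshold, nm (> 0).
#' @param weights Optional positive weights (e.g. peak intensities);
#'   equal weights when omitted.
#' @return Matrix of merged positions (all pairwise distances
#'   >= `min_dist_nm`).
#' @export
merge_maxima <- function(points_nm, min_dist_nm, weights = NULL) {
  stopifnot(min_dist_nm > 0)
  pts <- as.matrix(points_nm)
  if (!nrow(pts)) return(pts)
  w <- if (is.null(weights)) rep(1, nrow(pts)) else as.numeric(weights)
  stopifnot(length(w) == nrow(pts), all(w > 0))
  while (nrow(pts) > 1) {
    dm <- as.matrix(stats::dist(pts))
    dm[upper.tri(dm, diag = TRUE)] <- Inf
    m <- which.min(dm)
    if (dm[m] >= min_dist_nm) break
    ij <- arrayInd(m, dim(dm))
    i <- ij[1]; j <- ij[2]
    pts[j, ] <- (w[i] * pts[i, ] + w[j] * pts[j, ]) / (w[i] + w[j])
    w[j] <- w[i] + w[j]
    pts <- pts[-i, , drop = FALSE]
    w <- w[-i]
  }
  attr(pts, "weights") <- w
  pts
}

#' Keep the central cluster of maxima
#'
#' Single-linkage clustering with cutoff `link_dist_nm`; the cluster with
#' the most members is kept, ties broken by the smallest centroid distance
#' to `center`.
#'
#' @param points_nm Numeric matrix (n x 2), nm.
#' @param link_dist_nm Linkage cutoff, nm.
#' @param center Reference center (default origin of the ROI-local frame).
#' @return The retained points.
#' @export
select_central_cluster <- function(points_nm, link_dist_nm,
                                   center = c(0, 0)) {
  pts <- as.matrix(points_nm)
  if (nrow(pts) <= 1) return(pts)
  grp <- stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                       h = link_dist_nm)
  sizes <- tabulate(grp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    cdist <- vapply(best, function(g) {
      cen <- colMeans(pts[grp == g, , drop = FALSE])
      sqrt(sum((cen - center)^2))
    }, numeric(1))
    best <- best[which.min(cdist)]
  }
  pts[grp == best, , drop = FALSE]
}

#' Mean nearest-neighbor distance of a point set
#'
#' For each point, the distance to its nearest other point; returns the
#' mean. For a complete regular hexagon with edge `e` this equals `e`;
#' for three alternating vertices it equals `e * sqrt(3)`.
#'
#' @param points_nm Numeric matrix (n x 2) with n >= 2.
#' @return Mean nearest-neighbor distance (same units as input).
#' @export
mean_nnd <- function(points_nm) {
  pts <- as.matrix(points_nm)
  if (nrow(pts) < 2) {
    stop("mean_nnd is undefined for fewer than 2 points", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  mean(apply(dm, 1, min))
}

#' Call peptide sites in one origami ROI
#'
#' Renders the ROI's localizations at the design's oversampling in an
#' ROI-local nm frame, normalizes and Gaussian-smooths the image, detects
#' strict 8-neighborhood local maxima above `maxima_rel_threshold` times
#' the image maximum, refines them to sub-pixel positions, merges maxima
#' closer than `merge_factor` times the design edge, and keeps the central
#' cluster. The per-ROI mean nearest-neighbor distance is reported when at
#' least two sites survive (and is `NA` otherwise).
#'
#' @param roi_locs Data frame of the ROI's member localizations (columns
#'   `x`, `y` in camera pixels).
#' @param design A `design_spec` (see [get_design()]).
#' @param params [site_params()].
#' @param center_px ROI center `c(x, y)` in camera pixels; defaults to the
#'   member centroid.
#' @param half_width_px ROI half-width in camera pixels.
#' @param camera_pixel_nm Camera pixel size, nm (taken from the table
#'   metadata when `roi_locs` is a `loc_table`).
#' @param roi_id Identifier copied into the result.
#' @return A `site_detection`: list with `roi_id`, `site_coords_nm`
#'   (n x 2 matrix, ROI-local nm), `n_sites` and `mean_nnd_nm`.
#' @export
detect_sites <- function(roi_locs, design, params = site_params(),
                         center_px = NULL, half_width_px = 1.5,
                         camera_pixel_nm = NULL, roi_id = NA_integer_) {
  if (!inherits(design, "design_spec")) design <- get_design(design)
  if (!nrow(roi_locs)) stop("empty ROI", call. = FALSE)
  if (is.null(camera_pixel_nm)) {
    camera_pixel_nm <- attr(roi_locs, "camera_pixel_nm") %||% 87
  }
  if (is.null(center_px)) center_px <- c(mean(roi_locs$x), mean(roi_locs$y))
  x_nm <- (roi_locs$x - center_px[1]) * camera_pixel_nm
  y_nm <- (roi_locs$y - center_px[2]) * camera_pixel_nm
  ext <- half_width_px * camera_pixel_nm
  bin_nm <- camera_pixel_nm / design$oversampling
  im <- .hist2d(x_nm, y_nm, c(-ext, ext), c(-ext, ext), bin_nm)
  xlim <- attr(im, "xlim")
  ylim <- attr(im, "ylim")
  if (max(im) > 0) im <- im / max(im)
  im <- EBImage::gblur(im, sigma = params$smoothing_sigma_px)
  thr <- params$maxima_rel_threshold * max(im)
  peaks <- .local_maxima(im, thr)
  pts <- matrix(numeric(0), 0, 2)
  if (nrow(peaks)) {
    wts <- im[peaks]
    frac <- .refine_maxima(im, peaks)
    pts <- cbind(xlim[1] + (frac[, 1] - 0.5) * bin_nm,
                 ylim[1] + (frac[, 2] - 0.5) * bin_nm)
    pts <- merge_maxima(pts, params$merge_factor * design$nominal_edge_nm,
                        weights = wts)
    pts <- select_central_cluster(
      pts, params$cluster_link_factor * design$nominal_edge_nm
    )
  }
  structure(
    list(
      roi_id = roi_id,
      site_coords_nm = unname(pts[, , drop = FALSE]),
      n_sites = nrow(pts),
      mean_nnd_nm = if (nrow(pts) >= 2) mean_nnd(pts) else NA_real_
    ),
    class = "site_detection"
  )
}

#' Call sites in all QC-passing ROIs
#'
#' @param table The filtered [loc_table()] the ROIs were detected in.
#' @param roi_set Result of [detect_rois()].
#' @param design A `design_spec`.
#' @param params [site_params()].
#' @return List of `site_detection` objects (QC-passing ROIs only).
#' @export
quantify_rois <- function(table, roi_set, design, params = site_params()) {
  md <- loc_metadata(table)
  idx <- which(roi_set$rois$qc_pass)
  lapply(idx, function(k) {
    detect_sites(
      as.data.frame(table)[roi_set$members[[k]], , drop = FALSE],
      design, params,
      center_px = c(roi_set$rois$x_px[k], roi_set$rois$y_px[k]),
      half_width_px = roi_set$rois$half_width_px[k],
      camera_pixel_nm = md$camera_pixel_nm,
      roi_id = roi_set$rois$roi_id[k]
    )
  })
}

#' Summarize site detections of one design
#'
#' Aggregates per-ROI site counts into a sites-per-ROI histogram, an
#' occupancy estimate (`mean(min(n_sites, 6)) / 6`; counts above the 6
#' designed sites stay in the histogram but are capped for occupancy),
#' and the distribution of per-ROI mean nearest-neighbor distances.
#'
#' @param detections List of `site_detection` objects.
#' @param design The common `design_spec`.
#' @return A `pattern_summary`: list with `design`, `n_rois`,
#'   `sites_per_roi` (named count vector over 0..max), `occupancy_estimate`,
#'   `mean_nnd_values`, `mean_nnd_mean`, `mean_nnd_sd`.
#' @export
summarize_patterns <- function(detections, design) {
  if (!inherits(design, "design_spec")) design <- get_design(design)
  if (!length(detections)) {
    stop("no site detections to summarize", call. = FALSE)
  }
  counts <- vapply(detections, function(d) d$n_sites, numeric(1))
  nnd <- vapply(detections, function(d) d$mean_nnd_nm, numeric(1))
  nnd <- nnd[!is.na(nnd)]
  hist <- table(factor(counts, levels = 0:max(6, counts)))
  structure(
    list(
      design = design$name,
      n_rois = length(detections),
      sites_per_roi = hist,
      occupancy_estimate = mean(pmin(counts, 6)) / 6,
      mean_nnd_values = nnd,
      mean_nnd_mean = if (length(nnd)) mean(nnd) else NA_real_,
      mean_nnd_sd = if (length(nnd) > 1) stats::sd(nnd) else NA_real_
    ),
    class = "pattern_summary"
  )
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf(
    "<pattern_summary> %s: %d ROIs, occupancy estimate %.3f, mean NND %.2f nm (SD %.2f)\n",
    x$design, x$n_rois, x$occupancy_estimate, x$mean_nnd_mean, x$mean_nnd_sd
  ))
  cat("sites per ROI:\n")
  print(x$sites_per_roi)
  invisible(x)
}

#' Full analysis pipeline for one localization table
#'
#' Convenience wrapper: quality filtering, optional drift correction, ROI
#' detection, per-ROI site calling and pattern summary.
#'
#' @param table A [loc_table()].
#' @param design A `design_spec` or design name.
#' @param filter [filter_params()].
#' @param roi [roi_params()].
#' @param site [site_params()].
#' @param drift_correct Estimate and subtract drift before ROI detection?
#' @return List with `filter_report`, `drift_trace` (or `NULL`),
#'   `roi_set`, `detections` and `summary`.
#' @export
quantify_pattern <- function(table, design, filter = filter_params(),
                             roi = roi_params(), site = site_params(),
                             drift_correct = FALSE) {
  if (!inherits(design, "design_spec")) design <- get_design(design)
  flt <- filter_localizations(table, filter)
  trace <- NULL
  if (drift_correct) {
    trace <- estimate_drift(flt$locs, filter$drift_segment_frames)
    flt$locs <- apply_drift(flt$locs, trace)
  }
  rois <- detect_rois(flt$locs, roi)
  detections <- quantify_rois(flt$locs, rois, design, site)
  list(
    filter_report = flt$report,
    drift_trace = trace,
    roi_set = rois,
    detections = detections,
    summary = if (length(detections)) summarize_patterns(detections, design)
              else NULL
  )
}
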