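# Quality filtering and drift correction of localization tables.
#
# Filtering removes low-precision localizations (precision above a camera
# pixel threshold), asymmetric fits (ellipticity below a ratio threshold)
# and multi-emitter events (photon count above mean + z * SD). All three
# rules are evaluated simultaneously against the statistics of the input
# table. Drift is estimated with a redundant cross-correlation (RCC)
# scheme: the acquisition is split into temporal segments, every pair of
# segment renderings is cross-correlated, and the per-segment offsets are
# solved jointly by least squares.

#' Filtering parameters
#'
#' Defaults follow standard DNA-PAINT preprocessing: precision worse than
#' 0.03 camera pixels, ellipticity below 0.1 and photon counts more than
#' 2 SD above the mean are removed; drift is estimated on 200-frame
#' segments.
#'
#' @param precision_max_px Maximum localization precision, camera pixels.
#' @param ellipticity_min Minimum ellipticity (minor/major width ratio).
#' @param photon_z Photon-count outlier threshold in SD units above the mean.
#' @param drift_segment_frames Temporal segment length for drift estimation.
#' @return List of class `filter_params`.
#' @export
filter_params <- function(precision_max_px = 0.03, ellipticity_min = 0.1,
                          photon_z = 2, drift_segment_frames = 200L) {
  stopifnot(precision_max_px > 0, ellipticity_min > 0, photon_z > 0,
            drift_segment_frames >= 1)
  structure(
    list(precision_max_px = precision_max_px,
         ellipticity_min = ellipticity_min, photon_z = photon_z,
         drift_segment_frames = as.integer(drift_segment_frames)),
    class = "filter_params"
  )
}

#' Quality-filter a localization table
#'
#' Removes rows with `precision > precision_max_px`, rows with
#' `ellipticity < ellipticity_min`, and rows with
#' `photons > mean + photon_z * SD`, where the photon mean and (sample) SD
#' are computed over the full input table before any rule fires. Surviving
#' rows are returned unaltered and in their original order.
#'
#' @param table A [loc_table()].
#' @param params [filter_params()].
#' @param photon_stats Optional frozen `c(mean, sd)` of photon counts to
#'   use instead of recomputing them (makes filtering idempotent when the
#'   values from a previous report are reused).
#' @return List with `locs` (filtered table) and `report`
#'   (class `filter_report`): per-rule removal counts (a row violating
#'   several rules is counted under each), total removed/retained, and
#'   the photon statistics used.
#' @export
filter_localizations <- function(table, params = filter_params(),
                                 photon_stats = NULL) {
  md <- loc_metadata(table)
  n <- nrow(table)
  if (is.null(photon_stats)) {
    pm <- if (n) mean(table$photons) else NA_real_
    ps <- if (n > 1) stats::sd(table$photons) else 0
  } else {
    pm <- photon_stats[1]; ps <- photon_stats[2]
  }
  if (is.na(ps)) ps <- 0
  bad_prec <- table$precision > params$precision_max_px
  bad_ell <- table$ellipticity < params$ellipticity_min
  bad_phot <- if (n) table$photons > pm + params$photon_z * ps else logical(0)
  keep <- !(bad_prec | bad_ell | bad_phot)
  out <- loc_table(as.data.frame(table)[keep, , drop = FALSE],
                   camera_pixel_nm = md$camera_pixel_nm,
                   n_frames = md$n_frames, fov_px = NULL,
                   source = md$source, validate = FALSE)
  attr(out, "fov_px") <- md$fov_px
  report <- structure(
    list(n_input = n,
         n_removed_precision = sum(bad_prec),
         n_removed_ellipticity = sum(bad_ell),
         n_removed_photons = sum(bad_phot),
         n_removed = sum(!keep), n_retained = sum(keep),
         photon_mean = pm, photon_sd = ps,
         params = params),
    class = "filter_report"
  )
  list(locs = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    paste0("<filter_report> %d in, %d removed (%d precision, %d ellipticity, ",
           "%d photons), %d retained\n"),
    x$n_input, x$n_removed, x$n_removed_precision, x$n_removed_ellipticity,
    x$n_removed_photons, x$n_retained
  ))
  invisible(x)
}

#' Remove localizations near fiducial markers
#'
#' Masks out all localizations within `radius_px` of any of the given
#' fiducial positions (e.g. gold nanoparticles).
#'
#' @param table A [loc_table()].
#' @param centers_px Matrix (k x 2) or data frame of fiducial positions,
#'   camera pixels.
#' @param radius_px Exclusion radius, camera pixels.
#' @return The table without the masked rows; the number removed is
#'   available as `attr(, "n_fiducial_removed")`.
#' @export
exclude_fiducials <- function(table, centers_px, radius_px = 2) {
  centers_px <- as.matrix(centers_px)
  keep <- rep(TRUE, nrow(table))
  for (f in seq_len(nrow(centers_px))) {
    keep <- keep & ((table$x - centers_px[f, 1])^2 +
                      (table$y - centers_px[f, 2])^2 > radius_px^2)
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_fiducial_removed") <- sum(!keep)
  out
}

# --- RCC drift estimation ---------------------------------------------------

# cross-correlate two equally sized images (FFT); returns the sub-pixel
# displacement d (in bins) such that B is approximately A shifted by +d
.xcorr_shift <- function(A, B) {
  C <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  nr <- nrow(C); nc <- ncol(C)
  p <- arrayInd(which.max(C), dim(C))
  # 3x3 neighborhood with circular indexing, centroid refinement
  ri <- ((p[1] - 2):(p[1])) %% nr + 1L
  ci <- ((p[2] - 2):(p[2])) %% nc + 1L
  W <- C[ri, ci]
  W <- W - min(W)
  sw <- sum(W)
  off <- if (sw > 0) {
    c(sum((-1:1) * rowSums(W)), sum((-1:1) * colSums(W))) / sw
  } else c(0, 0)
  d <- c(p[1] - 1, p[2] - 1) + off
  d - ifelse(d > c(nr, nc) / 2, c(nr, nc), 0)
}

# separable Gaussian blur (zero padding) used to regularize sparse
# renderings before correlation
.gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(v) c(rep(0, r), v, rep(0, r))
  conv1 <- function(v) stats::convolve(pad(v), rev(k), type = "filter")
  m <- apply(m, 2, conv1)
  t(apply(t(m), 2, conv1))
}

#' Estimate drift by redundant cross-correlation
#'
#' Splits the acquisition into segments of `segment_frames` frames,
#' renders each segment as a super-resolved 2D histogram, estimates the
#' relative displacement of every segment pair from the sub-pixel peak of
#' their cross-correlation, solves all pairwise displacements jointly in
#' least squares, interpolates the per-segment offsets to per-frame
#' offsets (linear, knots at segment midpoints), and gauge-fixes the trace
#' to zero mean.
#'
#' @param table A [loc_table()]; needs at least `2 * segment_frames` frames.
#' @param segment_frames Segment length, frames.
#' @param oversampling Rendering oversampling for the correlation images
#'   (bins per camera pixel).
#' @param min_locs_per_segment Minimum localizations required per segment.
#' @return A `drift_trace`: data frame with columns `frame`, `dx`, `dy`
#'   (camera pixels, mean zero over frames), with the per-segment offsets
#'   and the least-squares residual RMS attached as attributes
#'   (`segment_offsets_px`, `residual_rms_px`).
#' @export
estimate_drift <- function(table, segment_frames = 200L, oversampling = 2,
                           min_locs_per_segment = 10L) {
  md <- loc_metadata(table)
  n_frames <- md$n_frames %||% (max(table$frame) + 1L)
  if (n_frames < 2 * segment_frames) {
    stop("need at least 2 * segment_frames frames to estimate drift",
         call. = FALSE)
  }
  n_seg <- n_frames %/% segment_frames
  seg <- pmin(table$frame %/% segment_frames, n_seg - 1L) + 1L
  counts <- tabulate(seg, n_seg)
  if (any(counts < min_locs_per_segment)) {
    stop("segment(s) with fewer than ", min_locs_per_segment,
         " localizations; use larger segment_frames", call. = FALSE)
  }
  pad <- 2
  xlim <- range(table$x) + c(-pad, pad)
  ylim <- range(table$y) + c(-pad, pad)
  imgs <- lapply(seq_len(n_seg), function(s) {
    rows <- seg == s
    im <- .hist2d(table$x[rows], table$y[rows], xlim, ylim, 1 / oversampling)
    .gauss_blur(im, 1)
  })
  pairs <- utils::combn(n_seg, 2)
  d <- t(apply(pairs, 2, function(p) .xcorr_shift(imgs[[p[1]]], imgs[[p[2]]])))
  A <- matrix(0, ncol(pairs) + 1L, n_seg)
  for (k in seq_len(ncol(pairs))) {
    A[k, pairs[1, k]] <- -1
    A[k, pairs[2, k]] <- 1
  }
  A[ncol(pairs) + 1L, ] <- 1  # gauge: offsets sum to zero
  sol <- qr.solve(A, rbind(d, 0))
  resid <- A[seq_len(ncol(pairs)), , drop = FALSE] %*% sol - d
  offsets_px <- sol / oversampling
  mids <- (seq_len(n_seg) - 0.5) * segment_frames
  mids[n_seg] <- (((n_seg - 1) * segment_frames) + n_frames) / 2
  fr <- 0:(n_frames - 1)
  # linear interpolation at segment midpoints, linear extrapolation at the
  # ends (slope of the first/last knot pair)
  interp <- function(o) {
    y <- stats::approx(mids, o, xout = fr, rule = 2)$y
    lo <- fr < mids[1]
    hi <- fr > mids[n_seg]
    y[lo] <- o[1] + (fr[lo] - mids[1]) * (o[2] - o[1]) / (mids[2] - mids[1])
    y[hi] <- o[n_seg] + (fr[hi] - mids[n_seg]) *
      (o[n_seg] - o[n_seg - 1]) / (mids[n_seg] - mids[n_seg - 1])
    y
  }
  dx <- interp(offsets_px[, 1])
  dy <- interp(offsets_px[, 2])
  trace <- data.frame(frame = fr, dx = dx - mean(dx), dy = dy - mean(dy))
  attr(trace, "segment_offsets_px") <- offsets_px
  attr(trace, "residual_rms_px") <- sqrt(mean(resid^2)) / oversampling
  class(trace) <- c("drift_trace", "data.frame")
  trace
}

#' Apply (subtract) a drift trace
#'
#' Shifts every localization by minus the trace offset of its frame.
#' Applying a trace and then its negation restores the original
#' coordinates.
#'
#' @param table A [loc_table()].
#' @param trace A `drift_trace` from [estimate_drift()] (or any data frame
#'   with columns `frame`, `dx`, `dy` covering all frames in the table).
#' @return The corrected table; metadata records the correction.
#' @export
apply_drift <- function(table, trace) {
  i <- match(table$frame, trace$frame)
  if (anyNA(i)) stop("drift trace does not cover all frames", call. = FALSE)
  table$x <- table$x - trace$dx[i]
  table$y <- table$y - trace$dy[i]
  attr(table, "source") <- paste0(attr(table, "source") %||% "",
                                  " [drift corrected]")
  table
}
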