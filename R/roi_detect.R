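# Detection of individual origami structures in a filtered localization
# table. Structures appear as compact clusters; the table is rendered as a
# low-resolution 2D histogram, connected blobs are extracted, and each blob
# becomes a square ROI centered on the localization-weighted centroid.
# ROIs are quality-controlled on localization count and temporal span:
# genuine docking sites blink throughout the acquisition while nonspecific
# stickers emit in short bursts.

# 2D histogram with half-open bins; matrix indexed [x, y]
.hist2d <- function(x, y, xlim, ylim, binsize) {
  nx <- max(1L, ceiling((xlim[2] - xlim[1]) / binsize))
  ny <- max(1L, ceiling((ylim[2] - ylim[1]) / binsize))
  ix <- floor((x - xlim[1]) / binsize) + 1L
  iy <- floor((y - ylim[1]) / binsize) + 1L
  ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
  m <- matrix(0, nx, ny)
  if (any(ok)) {
    tab <- table(factor(ix[ok], levels = seq_len(nx)),
                 factor(iy[ok], levels = seq_len(ny)))
    m <- matrix(as.numeric(tab), nx, ny)
  }
  attr(m, "xlim") <- xlim
  attr(m, "ylim") <- ylim
  attr(m, "binsize") <- binsize
  m
}

#' Render localizations as a super-resolved count image
#'
#' Bins localizations into a 2D histogram whose bin edge length is
#' `1 / oversampling` camera pixels. The sum over all pixels equals the
#' number of in-bounds localizations.
#'
#' @param table A [loc_table()] (or data frame with `x`, `y`).
#' @param oversampling Bins per camera pixel (>= 1).
#' @param bounds Numeric `c(xmin, xmax, ymin, ymax)` in camera pixels;
#'   defaults to the field of view from the metadata, else the data
#'   bounding box padded by one bin.
#' @return Numeric matrix indexed `[x, y]` with attributes `xlim`, `ylim`,
#'   `binsize`.
#' @export
render_image <- function(table, oversampling, bounds = NULL) {
  stopifnot(oversampling >= 1)
  if (is.null(bounds)) {
    fov <- attr(table, "fov_px")
    bounds <- if (!is.null(fov)) c(0, fov[1], 0, fov[2]) else {
      b <- 1 / oversampling
      c(range(table$x) + c(-b, b), range(table$y) + c(-b, b))
    }
  }
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    stop("empty rendering bounds", call. = FALSE)
  }
  .hist2d(table$x, table$y, bounds[1:2], bounds[3:4], 1 / oversampling)
}

#' ROI detection parameters
#'
#' `min_locs`/`max_locs` default to roughly 0.2x and 5x the localization
#' count expected from one fully occupied structure under the simulator's
#' default kinetics (~430 localizations); adjust them to the acquisition
#' at hand. `roi_half_width_px` follows the common 1.5 camera-pixel pick
#' scale.
#'
#' @param detect_oversampling Rendering oversampling for detection.
#' @param min_locs,max_locs Accepted localization count per ROI.
#' @param min_span_fraction Minimum temporal span of member localizations,
#'   as a fraction of the acquisition length.
#' @param roi_half_width_px Half-width of the square ROI, camera pixels.
#' @param min_component_locs Blobs with fewer member localizations than
#'   this are discarded before ROI construction (isolated nonspecific
#'   events rather than contours).
#' @return List of class `roi_params`.
#' @export
roi_params <- function(detect_oversampling = 20L, min_locs = 80L,
                       max_locs = 2500L, min_span_fraction = 0.5,
                       roi_half_width_px = 1.5, min_component_locs = 10L) {
  stopifnot(detect_oversampling >= 1, min_locs >= 1, max_locs >= min_locs,
            min_span_fraction > 0, min_span_fraction <= 1,
            roi_half_width_px > 0, min_component_locs >= 1)
  structure(
    list(detect_oversampling = as.integer(detect_oversampling),
         min_locs = min_locs, max_locs = max_locs,
         min_span_fraction = min_span_fraction,
         roi_half_width_px = roi_half_width_px,
         min_component_locs = as.integer(min_component_locs)),
    class = "roi_params"
  )
}

#' Detect origami ROIs in a localization table
#'
#' Renders the table at `detect_oversampling`, binarizes (count >= 1),
#' applies a 3x3 morphological closing, labels connected blobs, and turns
#' each blob into a square ROI centered on the localization-weighted
#' centroid of its member localizations. Centers closer than one ROI
#' half-width are merged. QC requires
#' `min_locs <= n_locs <= max_locs` and a temporal span of at least
#' `min_span_fraction * n_frames`. ROIs are ordered by descending
#' localization count.
#'
#' @param table A filtered [loc_table()].
#' @param params [roi_params()].
#' @return A `roi_set`: list with `rois` (data frame: `roi_id`, `x_px`,
#'   `y_px`, `half_width_px`, `n_locs`, `frame_first`, `frame_last`,
#'   `span_frames`, `qc_pass`) and `members` (list of row indices into
#'   `table`, parallel to `rois`).
#' @export
detect_rois <- function(table, params = roi_params()) {
  md <- loc_metadata(table)
  n_frames <- md$n_frames %||% (if (nrow(table)) max(table$frame) + 1L else 0L)
  empty <- list(
    rois = data.frame(roi_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), half_width_px = numeric(0),
                      n_locs = integer(0), frame_first = integer(0),
                      frame_last = integer(0), span_frames = integer(0),
                      qc_pass = logical(0)),
    members = list(), params = params, n_frames = n_frames
  )
  class(empty) <- "roi_set"
  if (!nrow(table)) return(empty)

  img <- render_image(table, params$detect_oversampling)
  bw <- (img >= 1) * 1
  closed <- EBImage::closing(bw, EBImage::makeBrush(3, "box"))
  lab <- EBImage::bwlabel(closed)
  # map localizations onto label image pixels
  bs <- attr(img, "binsize")
  ix <- pmin(pmax(floor((table$x - attr(img, "xlim")[1]) / bs) + 1L, 1L), nrow(lab))
  iy <- pmin(pmax(floor((table$y - attr(img, "ylim")[1]) / bs) + 1L, 1L), ncol(lab))
  loc_lab <- lab[cbind(ix, iy)]
  tab <- tabulate(loc_lab[loc_lab > 0], nbins = max(lab))
  labs <- which(tab >= params$min_component_locs)
  if (!length(labs)) return(empty)
  cx <- vapply(labs, function(l) mean(table$x[loc_lab == l]), numeric(1))
  cy <- vapply(labs, function(l) mean(table$y[loc_lab == l]), numeric(1))
  # merge duplicate centers (blob fragments) closer than one half-width
  centers <- cbind(cx, cy)
  if (nrow(centers) > 1) {
    grp <- stats::cutree(
      stats::hclust(stats::dist(centers), method = "single"),
      h = params$roi_half_width_px
    )
    centers <- cbind(
      vapply(split(cx, grp), mean, numeric(1)),
      vapply(split(cy, grp), mean, numeric(1))
    )
  }
  hw <- params$roi_half_width_px
  members <- lapply(seq_len(nrow(centers)), function(k) {
    which(abs(table$x - centers[k, 1]) <= hw &
            abs(table$y - centers[k, 2]) <= hw)
  })
  n_locs <- lengths(members)
  keep <- n_locs > 0
  centers <- centers[keep, , drop = FALSE]
  members <- members[keep]
  n_locs <- n_locs[keep]
  first <- vapply(members, function(m) min(table$frame[m]), numeric(1))
  last <- vapply(members, function(m) max(table$frame[m]), numeric(1))
  span <- last - first
  qc <- n_locs >= params$min_locs & n_locs <= params$max_locs &
    span >= params$min_span_fraction * n_frames
  ord <- order(-n_locs)
  out <- list(
    rois = data.frame(
      roi_id = seq_along(ord), x_px = centers[ord, 1], y_px = centers[ord, 2],
      half_width_px = hw, n_locs = as.integer(n_locs[ord]),
      frame_first = as.integer(first[ord]), frame_last = as.integer(last[ord]),
      span_frames = as.integer(span[ord]), qc_pass = qc[ord]
    ),
    members = members[ord], params = params, n_frames = n_frames
  )
  class(out) <- "roi_set"
  out
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs (%d passing QC)\n",
              nrow(x$rois), sum(x$rois$qc_pass)))
  invisible(x)
}
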