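# Localization-table container and I/O.
#
# Conventions (used throughout the package): coordinates are in camera
# pixels and refer to pixel centers; frame indices are 0-based; field-of-view
# bounds are half-open [0, fov). The physical pixel size is carried in the
# table metadata as `camera_pixel_nm` and conversions to nm happen only at
# analysis boundaries (site calling).

.loc_required_cols <- c("frame", "x", "y", "photons", "sx", "sy", "precision")

#' Construct a localization table
#'
#' A localization table is a `data.frame` with one row per localization
#' event and columns `frame` (0-based), `x`, `y` (camera pixels),
#' `photons`, `sx`, `sy` (fitted spot widths, pixels), `precision`
#' (localization precision, pixels) and `ellipticity` (minor/major width
#' ratio in (0, 1]); acquisition metadata travels as attributes.
#' If `ellipticity` is absent it is derived as `min(sx, sy) / max(sx, sy)`.
#'
#' @param df Data frame with at least the columns `frame`, `x`, `y`,
#'   `photons`, `sx`, `sy`, `precision`.
#' @param camera_pixel_nm Physical camera pixel size in nm (default 87).
#' @param n_frames Number of frames in the acquisition; defaults to
#'   `max(frame) + 1`.
#' @param fov_px Optional field-of-view `c(width, height)` in camera pixels.
#' @param source Free-text provenance string.
#' @param validate Check row invariants (positive photons/precision,
#'   ellipticity in (0, 1], frames in range)?
#' @return A `loc_table` (a classed `data.frame`).
#' @export
loc_table <- function(df, camera_pixel_nm = 87, n_frames = NULL,
                      fov_px = NULL, source = "", validate = TRUE) {
  missing <- setdiff(.loc_required_cols, names(df))
  if (length(missing)) {
    stop("localization table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)
  if (is.null(df$ellipticity)) {
    df$ellipticity <- ifelse(
      pmax(df$sx, df$sy) > 0, pmin(df$sx, df$sy) / pmax(df$sx, df$sy), 1
    )
  }
  if (is.null(n_frames)) {
    n_frames <- if (nrow(df)) max(df$frame) + 1L else 0L
  }
  if (validate && nrow(df)) {
    if (any(df$frame < 0) || any(df$frame >= n_frames)) {
      stop("frame indices must lie in [0, n_frames)", call. = FALSE)
    }
    if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
      stop("non-finite coordinates", call. = FALSE)
    }
    if (any(df$photons <= 0)) stop("photons must be positive", call. = FALSE)
    if (any(df$precision <= 0)) stop("precision must be positive", call. = FALSE)
    if (any(df$ellipticity <= 0 | df$ellipticity > 1)) {
      stop("ellipticity must lie in (0, 1]", call. = FALSE)
    }
    if (!is.null(fov_px) &&
        (any(df$x < 0 | df$x >= fov_px[1]) || any(df$y < 0 | df$y >= fov_px[2]))) {
      # drift-uncorrected tables may legitimately exceed the nominal FOV
      warning("some localizations fall outside the nominal field of view",
              call. = FALSE)
    }
  }
  attr(df, "camera_pixel_nm") <- camera_pixel_nm
  attr(df, "n_frames") <- as.integer(n_frames)
  attr(df, "fov_px") <- fov_px
  attr(df, "source") <- source
  class(df) <- c("loc_table", "data.frame")
  df
}

#' Metadata of a localization table
#'
#' @param table A `loc_table`.
#' @return Named list with `camera_pixel_nm`, `n_frames`, `fov_px`, `source`.
#' @export
loc_metadata <- function(table) {
  list(
    camera_pixel_nm = attr(table, "camera_pixel_nm") %||% 87,
    n_frames = attr(table, "n_frames"),
    fov_px = attr(table, "fov_px"),
    source = attr(table, "source") %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.loc_table <- function(x, ...) {
  md <- loc_metadata(x)
  cat(sprintf(
    "<loc_table> %d localizations, %d frames, %.4g nm/px%s\n",
    nrow(x), md$n_frames, md$camera_pixel_nm,
    if (!is.null(md$fov_px)) sprintf(", FOV %gx%g px", md$fov_px[1], md$fov_px[2]) else ""
  ))
  NextMethod()
}

.sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a localization table
#'
#' Reads the CSV dialect: a header row with the standard columns, plus a
#' YAML metadata sidecar at `<path>.yaml` (keys `camera_pixel_nm`,
#' `n_frames`, `fov_px`, `source`). If the sidecar is absent a warning is
#' emitted and defaults (87 nm camera pixels) are assumed. A missing
#' `ellipticity` column is derived from `sx`, `sy`.
#'
#' @param path Input file path.
#' @param format Only `"csv"` is available in this build; `"hdf5"` raises
#'   an informative error (convert Picasso HDF5 files to CSV first).
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5") {
    stop("HDF5 localization files are not supported by this build; ",
         "export the table to CSV and use format = \"csv\"", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  missing <- setdiff(.loc_required_cols, names(df))
  if (length(missing)) {
    stop("localization file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sp <- .sidecar_path(path)
  if (file.exists(sp)) {
    md <- yaml::read_yaml(sp)
  } else {
    warning("no metadata sidecar found at ", sp,
            "; assuming camera pixel size 87 nm", call. = FALSE)
    md <- list()
  }
  loc_table(
    df,
    camera_pixel_nm = md$camera_pixel_nm %||% 87,
    n_frames = md$n_frames,
    fov_px = if (!is.null(md$fov_px)) as.numeric(unlist(md$fov_px)) else NULL,
    source = md$source %||% ""
  )
}

#' Write a localization table
#'
#' Writes the table as CSV with a header row and its metadata as a YAML
#' sidecar at `<path>.yaml`. Output is stable for fixed input, and
#' `read_localizations()` round-trips both rows and metadata.
#'
#' @param table A [loc_table()].
#' @param path Output file path.
#' @param format Only `"csv"` is available in this build.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, format = "csv") {
  if (format != "csv") {
    stop("only format = \"csv\" is supported by this build", call. = FALSE)
  }
  md <- loc_metadata(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  out <- list(camera_pixel_nm = md$camera_pixel_nm, n_frames = md$n_frames,
              source = md$source)
  if (!is.null(md$fov_px)) out$fov_px <- as.numeric(md$fov_px)
  yaml::write_yaml(out, .sidecar_path(path))
  invisible(path)
}
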