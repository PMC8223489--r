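# Synthetic DNA-PAINT acquisition simulator.
#
# Emulates imaging of surface-immobilized origami structures with partial
# per-site peptide occupancy. Kinetics are frame-level: each docking site is
# a stationary two-state (dark/bright) Markov chain; every bright frame
# emits one localization at the site position plus isotropic Gaussian noise.
# The simulator produces a localization table plus a ground-truth record
# labeling every localization with its source.

#' Acquisition parameters
#'
#' Defaults reproduce the imaging conditions the pipeline is designed for:
#' 12000 frames at 300 ms exposure, 87 nm camera pixels, 10 nM imager.
#'
#' @param n_frames Number of camera frames.
#' @param exposure_s Exposure time per frame, seconds.
#' @param camera_pixel_nm Camera pixel size, nm.
#' @param fov_px Field of view `c(width, height)` in camera pixels.
#' @param imager_conc_nM Imager strand concentration, nM.
#' @return List of class `acquisition_params`.
#' @export
acquisition_params <- function(n_frames = 12000L, exposure_s = 0.3,
                               camera_pixel_nm = 87, fov_px = c(64, 64),
                               imager_conc_nM = 10) {
  stopifnot(n_frames >= 1, camera_pixel_nm > 0, exposure_s > 0,
            length(fov_px) == 2, all(fov_px > 0), imager_conc_nM >= 0)
  structure(
    list(n_frames = as.integer(n_frames), exposure_s = exposure_s,
         camera_pixel_nm = camera_pixel_nm, fov_px = fov_px,
         imager_conc_nM = imager_conc_nM),
    class = "acquisition_params"
  )
}

#' Blinking-kinetics and noise parameters
#'
#' The binding kinetics are an alternating renewal process: dark dwell
#' times are geometric with per-frame on-probability
#' `1 - exp(-dark_rate_per_nM_per_s * imager_conc_nM * exposure_s)` and
#' bright dwells are geometric with mean `mean_bright_frames`. These are
#' free parameters of the simulator (typical DNA-PAINT on-rates are
#' ~1e6 /M/s, i.e. 1e-3 /nM/s).
#'
#' @param mean_bright_frames Mean bright-state dwell, frames.
#' @param dark_rate_per_nM_per_s Site on-rate coefficient; the binding rate
#'   is this value times the imager concentration in nM.
#' @param loc_precision_nm Isotropic Gaussian localization noise SD, nm.
#' @param photon_mean,photon_sd Mean and SD of the (log-normal) photon-count
#'   distribution of genuine localizations.
#' @param bg_rate_per_um2_per_frame Density of nonspecific background
#'   localizations per square micron per frame.
#' @param drift_nm_per_frame 2D linear drift velocity `c(dx, dy)`, nm/frame,
#'   added cumulatively to all emitted positions.
#' @param n_fiducials Number of fiducial markers (emit every frame).
#' @param asym_frac Fraction of genuine localizations replaced by
#'   asymmetric "junk" fits (ellipticity well below 0.1), giving the
#'   ellipticity filter something to reject.
#' @return List of class `kinetics_params`.
#' @export
kinetics_params <- function(mean_bright_frames = 2,
                            dark_rate_per_nM_per_s = 1e-3,
                            loc_precision_nm = 1.0,
                            photon_mean = 2000, photon_sd = 400,
                            bg_rate_per_um2_per_frame = 0.01,
                            drift_nm_per_frame = c(0, 0),
                            n_fiducials = 0L,
                            asym_frac = 0.02) {
  stopifnot(mean_bright_frames >= 1, dark_rate_per_nM_per_s >= 0,
            loc_precision_nm >= 0, photon_mean > 0, photon_sd >= 0,
            bg_rate_per_um2_per_frame >= 0, length(drift_nm_per_frame) == 2,
            n_fiducials >= 0, asym_frac >= 0, asym_frac <= 1)
  structure(
    list(mean_bright_frames = mean_bright_frames,
         dark_rate_per_nM_per_s = dark_rate_per_nM_per_s,
         loc_precision_nm = loc_precision_nm,
         photon_mean = photon_mean, photon_sd = photon_sd,
         bg_rate_per_um2_per_frame = bg_rate_per_um2_per_frame,
         drift_nm_per_frame = drift_nm_per_frame,
         n_fiducials = as.integer(n_fiducials),
         asym_frac = asym_frac),
    class = "kinetics_params"
  )
}

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Place origami structures in the field of view
#'
#' Draws structure centers uniformly inside a margin-inset field of view
#' with i.i.d. uniform rotations, enforcing a minimum pairwise separation
#' by rejection sampling.
#'
#' @param n Number of structures.
#' @param fov_px Field of view `c(width, height)`, camera pixels.
#' @param min_sep_nm Minimum center-to-center distance, nm.
#' @param camera_pixel_nm Camera pixel size, nm.
#' @param margin_px Inset margin from the FOV edge, camera pixels.
#' @param seed Optional RNG seed (deterministic output per seed).
#' @param max_tries Rejection-sampling attempts per structure before
#'   declaring the packing infeasible.
#' @return Data frame with columns `x_px`, `y_px`, `rotation_rad`.
#' @export
place_structures <- function(n, fov_px, min_sep_nm, camera_pixel_nm = 87,
                             margin_px = 3, seed = NULL, max_tries = 5000) {
  stopifnot(n >= 0, length(fov_px) == 2, min_sep_nm >= 0)
  if (n == 0) {
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      rotation_rad = numeric(0)))
  }
  lo <- c(margin_px, margin_px)
  hi <- fov_px - margin_px
  if (any(hi <= lo)) stop("field of view too small for the margin", call. = FALSE)
  min_sep_px <- min_sep_nm / camera_pixel_nm
  .with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cx <- stats::runif(1, lo[1], hi[1])
        cy <- stats::runif(1, lo[2], hi[2])
        if (i == 1 ||
            all((xs[seq_len(i - 1)] - cx)^2 + (ys[seq_len(i - 1)] - cy)^2 >=
                min_sep_px^2)) {
          xs[i] <- cx; ys[i] <- cy; ok <- TRUE; break
        }
      }
      if (!ok) {
        stop("could not place ", n, " structures at min_sep_nm = ", min_sep_nm,
             " in the given field of view; enlarge fov_px or reduce n",
             call. = FALSE)
      }
    }
    data.frame(x_px = xs, y_px = ys,
               rotation_rad = stats::runif(n, 0, 2 * pi))
  })
}

# bright frames (0-based) of one site: stationary alternating geometric
# dark/bright chain over n_frames
.sim_bright_frames <- function(n_frames, p_on, p_off) {
  if (p_on <= 0) return(integer(0))
  rho <- p_on / (p_on + p_off)
  state <- stats::runif(1) < rho
  t <- 0L
  out <- vector("list", 64L); k <- 0L
  while (t < n_frames) {
    dur <- if (state) stats::rgeom(1, p_off) + 1L else stats::rgeom(1, p_on) + 1L
    if (state) {
      k <- k + 1L
      if (k > length(out)) out <- c(out, vector("list", length(out)))
      out[[k]] <- t + seq_len(min(dur, n_frames - t)) - 1L
    }
    t <- t + dur
    state <- !state
  }
  if (k == 0L) integer(0) else unlist(out[seq_len(k)])
}

#' Expected localization count of a single docking site
#'
#' Closed-form mean and variance of the number of bright frames of one
#' always-present site under the simulator's stationary two-state chain:
#' bright fraction `rho = p_on / (p_on + p_off)`, mean `n_frames * rho`,
#' and variance accounting for the chain's lag autocorrelation
#' `lambda = 1 - p_on - p_off`.
#'
#' @param acq [acquisition_params()].
#' @param kin [kinetics_params()].
#' @return List with `p_on`, `p_off`, `bright_fraction`, `mean`, `var`.
#' @export
expected_site_localizations <- function(acq = acquisition_params(),
                                        kin = kinetics_params()) {
  p_on <- 1 - exp(-kin$dark_rate_per_nM_per_s * acq$imager_conc_nM *
                    acq$exposure_s)
  p_off <- 1 / kin$mean_bright_frames
  rho <- p_on / (p_on + p_off)
  n <- acq$n_frames
  lambda <- 1 - p_on - p_off
  k <- seq_len(n - 1)
  v <- rho * (1 - rho) * (n + 2 * sum((n - k) * lambda^k))
  list(p_on = p_on, p_off = p_off, bright_fraction = rho,
       mean = n * rho, var = v)
}

.rlnorm_meansd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a DNA-PAINT acquisition
#'
#' Places `n_structures` copies of `design` in the field of view, marks
#' each of their 6 sites present independently with probability
#' `occupancy`, simulates per-site blinking, background and fiducial
#' localizations, applies cumulative drift, and returns the frame-sorted
#' localization table together with ground truth.
#'
#' @param design A `design_spec` from [get_design()].
#' @param n_structures Number of origami structures.
#' @param occupancy Per-site presence probability in \[0, 1\].
#' @param acq [acquisition_params()].
#' @param kin [kinetics_params()].
#' @param min_sep_nm Minimum structure separation, nm.
#' @param seed Optional RNG seed; the same seed reproduces the acquisition
#'   bit-for-bit.
#' @return List with elements `locs` (a [loc_table()]) and `truth`
#'   (class `paint_truth`): `truth$structures` is a data frame with the
#'   true pose and per-site presence of every structure,
#'   `truth$sources` labels each row of `locs` with its origin
#'   (`"site_<structure>_<site>"`, `"background"` or `"fiducial_<i>"`),
#'   and `truth$fiducials_px` holds fiducial positions.
#' @export
simulate_acquisition <- function(design, n_structures, occupancy = 1,
                                 acq = acquisition_params(),
                                 kin = kinetics_params(),
                                 min_sep_nm = 500, seed = NULL) {
  if (!inherits(design, "design_spec")) design <- get_design(design)
  if (!is.numeric(occupancy) || occupancy < 0 || occupancy > 1) {
    stop("`occupancy` must lie in [0, 1]", call. = FALSE)
  }
  .with_seed(seed, {
    pix <- acq$camera_pixel_nm
    poses <- place_structures(n_structures, acq$fov_px, min_sep_nm, pix)
    present <- matrix(stats::runif(n_structures * 6) < occupancy,
                      nrow = max(n_structures, 0), ncol = 6)
    ex <- expected_site_localizations(acq, kin)
    sigma_px <- kin$loc_precision_nm / pix
    drift_px <- kin$drift_nm_per_frame / pix

    frames <- list(); xs <- list(); ys <- list(); src <- list()
    idx <- 0L
    for (s in seq_len(n_structures)) {
      rot <- poses$rotation_rad[s]
      R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
      sites_px <- sweep(design$site_coords_nm %*% t(R) / pix, 2,
                        c(poses$x_px[s], poses$y_px[s]), `+`)
      for (j in 1:6) {
        if (!present[s, j]) next
        fr <- .sim_bright_frames(acq$n_frames, ex$p_on, ex$p_off)
        if (!length(fr)) next
        idx <- idx + 1L
        frames[[idx]] <- fr
        xs[[idx]] <- sites_px[j, 1] + stats::rnorm(length(fr), 0, sigma_px)
        ys[[idx]] <- sites_px[j, 2] + stats::rnorm(length(fr), 0, sigma_px)
        src[[idx]] <- rep(sprintf("site_%d_%d", s, j), length(fr))
      }
    }
    frame <- unlist(frames) %||% integer(0)
    x <- unlist(xs) %||% numeric(0)
    y <- unlist(ys) %||% numeric(0)
    source_lab <- unlist(src) %||% character(0)
    n_true <- length(frame)
    photons <- .rlnorm_meansd(n_true, kin$photon_mean, kin$photon_sd)
    sx <- 0.85 * exp(stats::rnorm(n_true, 0, 0.03))
    sy <- 0.85 * exp(stats::rnorm(n_true, 0, 0.03))
    if (kin$asym_frac > 0 && n_true > 0) {
      junk <- stats::runif(n_true) < kin$asym_frac
      sy[junk] <- sy[junk] * stats::runif(sum(junk), 12, 20)
    }

    # nonspecific background: Poisson in space-time over the FOV
    area_um2 <- prod(acq$fov_px) * (pix / 1000)^2
    n_bg <- stats::rpois(1, kin$bg_rate_per_um2_per_frame * area_um2 *
                           acq$n_frames)
    if (n_bg > 0) {
      frame <- c(frame, sample.int(acq$n_frames, n_bg, replace = TRUE) - 1L)
      x <- c(x, stats::runif(n_bg, 0, acq$fov_px[1]))
      y <- c(y, stats::runif(n_bg, 0, acq$fov_px[2]))
      photons <- c(photons, .rlnorm_meansd(n_bg, kin$photon_mean * 0.6,
                                           kin$photon_sd))
      sx <- c(sx, 0.9 * exp(stats::rnorm(n_bg, 0, 0.1)))
      sy <- c(sy, 0.9 * exp(stats::rnorm(n_bg, 0, 0.1)))
      source_lab <- c(source_lab, rep("background", n_bg))
    }

    # fiducials emit every frame with high photon counts and little jitter
    fid <- matrix(numeric(0), 0, 2)
    if (kin$n_fiducials > 0) {
      fid <- cbind(stats::runif(kin$n_fiducials, 2, acq$fov_px[1] - 2),
                   stats::runif(kin$n_fiducials, 2, acq$fov_px[2] - 2))
      for (f in seq_len(kin$n_fiducials)) {
        frame <- c(frame, 0:(acq$n_frames - 1L))
        x <- c(x, fid[f, 1] + stats::rnorm(acq$n_frames, 0, 0.002))
        y <- c(y, fid[f, 2] + stats::rnorm(acq$n_frames, 0, 0.002))
        photons <- c(photons, .rlnorm_meansd(acq$n_frames,
                                             kin$photon_mean * 5, kin$photon_sd))
        sx <- c(sx, 0.85 * exp(stats::rnorm(acq$n_frames, 0, 0.03)))
        sy <- c(sy, 0.85 * exp(stats::rnorm(acq$n_frames, 0, 0.03)))
        source_lab <- c(source_lab, rep(sprintf("fiducial_%d", f), acq$n_frames))
      }
    }

    # cumulative linear drift on all emitted positions
    if (any(drift_px != 0) && length(frame)) {
      x <- x + frame * drift_px[1]
      y <- y + frame * drift_px[2]
    }

    precision <- if (length(photons)) {
      pmax(sigma_px, 1e-4) * sqrt(kin$photon_mean / photons)
    } else numeric(0)

    ord <- order(frame)
    df <- data.frame(
      frame = as.integer(frame[ord]), x = x[ord], y = y[ord],
      photons = photons[ord], sx = sx[ord], sy = sy[ord],
      precision = precision[ord]
    )
    locs <- suppressWarnings(loc_table(
      df, camera_pixel_nm = pix, n_frames = acq$n_frames,
      fov_px = acq$fov_px,
      source = sprintf("hexpaint simulation, design %s, %d structures, occupancy %.3g",
                       design$name, n_structures, occupancy)
    ))
    structures <- cbind(
      data.frame(structure_id = seq_len(n_structures),
                 design = rep(design$name, n_structures)),
      poses,
      stats::setNames(as.data.frame(present),
                      paste0("site_present_", 1:6))
    )
    truth <- structure(
      list(structures = structures, sources = source_lab[ord],
           fiducials_px = fid, design = design$name,
           occupancy = occupancy, drift_px_per_frame = drift_px),
      class = "paint_truth"
    )
    list(locs = locs, truth = truth)
  })
}

#' Write simulator ground truth as a CSV sidecar
#'
#' Writes `truth$structures` (columns `structure_id`, `design`, `x_px`,
#' `y_px`, `rotation_rad`, `site_present_1` .. `site_present_6`) to `path`
#' and, optionally, the per-localization source labels to `sources_path`
#' (single column `source`, one row per localization-table row).
#'
#' @param truth A `paint_truth` object from [simulate_acquisition()].
#' @param path Output CSV path for the structure table.
#' @param sources_path Optional output CSV path for per-localization labels.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, sources_path = NULL) {
  stopifnot(inherits(truth, "paint_truth"))
  utils::write.csv(truth$structures, path, row.names = FALSE)
  if (!is.null(sources_path)) {
    utils::write.csv(data.frame(source = truth$sources), sources_path,
                     row.names = FALSE)
  }
  invisible(path)
}
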