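# Shared fixtures built in code.

# High-SNR benchmark scene: default acquisition (12000 frames, 300 ms,
# 87 nm pixels, 10 nM imager), 1 nm localization precision, no drift,
# low background.
high_snr_scene <- function(design, n_structures = 30, occupancy = 1,
                           seed = 1, fov_px = c(64, 64),
                           n_frames = 12000L, ...) {
  simulate_acquisition(
    design, n_structures, occupancy,
    acq = acquisition_params(n_frames = n_frames, fov_px = fov_px),
    kin = kinetics_params(...),
    seed = seed
  )
}

# Minimal hand-built localization table.
toy_loc_table <- function(n = 5, n_frames = 100L, ...) {
  df <- data.frame(
    frame = seq_len(n) - 1L, x = seq_len(n), y = rev(seq_len(n)),
    photons = rep(1000, n), sx = rep(0.9, n), sy = rep(0.9, n),
    precision = rep(0.01, n)
  )
  loc_table(df, n_frames = n_frames, ...)
}

# Gaussian localization cloud(s) for site-calling tests: one cluster of
# `n_each` localizations around every row of `centers_nm` (ROI-local nm),
# returned as camera-pixel coordinates around `center_px`.
site_cloud <- function(centers_nm, n_each = 80, sigma_nm = 1,
                       center_px = c(10, 10), camera_pixel_nm = 87,
                       seed = 99) {
  set.seed(seed)
  centers_nm <- rbind(centers_nm)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers_nm)), function(i) {
    cbind(stats::rnorm(n_each, centers_nm[i, 1], sigma_nm),
          stats::rnorm(n_each, centers_nm[i, 2], sigma_nm))
  }))
  n <- nrow(pts)
  data.frame(
    frame = sample.int(12000L, n, replace = TRUE) - 1L,
    x = center_px[1] + pts[, 1] / camera_pixel_nm,
    y = center_px[2] + pts[, 2] / camera_pixel_nm,
    photons = rep(2000, n), sx = rep(0.85, n), sy = rep(0.85, n),
    precision = rep(0.012, n), ellipticity = rep(1, n)
  )
}
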