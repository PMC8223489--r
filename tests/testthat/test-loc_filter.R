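# Hand-derived 5-row fixture: row 2 fails the ellipticity rule, row 3 the
# precision rule; photon mean 2080 and sample SD ~4427 put the photon
# threshold at ~10934, so the 10000-photon row survives.
five_row_fixture <- function() {
  loc_table(data.frame(
    frame = 0:4, x = 1:5, y = 1:5,
    photons = c(100, 100, 100, 100, 10000),
    sx = rep(0.9, 5), sy = rep(0.9, 5),
    precision = c(0.01, 0.01, 0.05, 0.01, 0.01),
    ellipticity = c(0.9, 0.05, 0.9, 0.9, 0.9)
  ), n_frames = 10L)
}

test_that("the three quality rules reproduce the hand-applied outcome", {
  res <- filter_localizations(five_row_fixture())
  expect_identical(res$locs$frame, c(0L, 3L, 4L))
  expect_identical(res$report$n_removed_precision, 1L)
  expect_identical(res$report$n_removed_ellipticity, 1L)
  expect_identical(res$report$n_removed_photons, 0L)
  expect_identical(res$report$n_removed, 2L)
  expect_identical(res$report$n_retained, 3L)
  expect_equal(res$report$photon_mean, 2080)
  expect_equal(res$report$photon_sd, stats::sd(c(100, 100, 100, 100, 10000)))
})

test_that("removed plus retained equals the input row count", {
  sim <- high_snr_scene("W16", 5, seed = 4, n_frames = 2000L)
  res <- filter_localizations(sim$locs)
  expect_identical(res$report$n_removed + res$report$n_retained,
                   res$report$n_input)
  expect_identical(res$report$n_retained, nrow(res$locs))
})

test_that("equal photon counts disable the photon rule (degenerate SD)", {
  tb <- toy_loc_table(6)
  res <- filter_localizations(tb)
  expect_identical(res$report$n_removed_photons, 0L)
  expect_identical(nrow(res$locs), 6L)
})

test_that("filtering preserves surviving rows verbatim and in order", {
  res <- filter_localizations(five_row_fixture())
  orig <- as.data.frame(five_row_fixture())[c(1, 4, 5), ]
  rownames(orig) <- NULL
  got <- as.data.frame(res$locs)
  rownames(got) <- NULL
  expect_identical(got, orig)
})

test_that("filtering is idempotent when photon statistics are frozen", {
  res1 <- filter_localizations(five_row_fixture())
  stats1 <- c(res1$report$photon_mean, res1$report$photon_sd)
  res2 <- filter_localizations(res1$locs, photon_stats = stats1)
  expect_identical(as.data.frame(res2$locs), as.data.frame(res1$locs))
  expect_identical(res2$report$n_removed, 0L)
})

test_that("an empty table filters to an empty table with a zero report", {
  res <- filter_localizations(toy_loc_table(0))
  expect_identical(nrow(res$locs), 0L)
  expect_identical(res$report$n_removed, 0L)
  expect_identical(res$report$n_retained, 0L)
})

test_that("fiducial localizations are removed by a radius mask", {
  sim <- simulate_acquisition("W16", 2, 1,
                              acq = acquisition_params(n_frames = 500L),
                              kin = kinetics_params(n_fiducials = 2),
                              seed = 21)
  out <- exclude_fiducials(sim$locs, sim$truth$fiducials_px, radius_px = 1)
  kept_src <- sim$truth$sources[sim$locs$x %in% out$x &
                                  sim$locs$y %in% out$y]
  expect_false(any(grepl("^fiducial", kept_src)))
  expect_identical(nrow(sim$locs) - nrow(out),
                   attr(out, "n_fiducial_removed"))
})

# --- drift ------------------------------------------------------------------

test_that("drift estimation needs enough frames and localizations", {
  tb <- toy_loc_table(50, n_frames = 100L)
  expect_error(estimate_drift(tb, segment_frames = 200), "2 \\* segment_frames")
  sparse <- toy_loc_table(4, n_frames = 1000L)
  expect_error(estimate_drift(sparse, segment_frames = 100), "larger")
})

test_that("the drift trace of a quiet acquisition is near zero and gauge-fixed", {
  sim <- high_snr_scene("W16", 15, seed = 9, n_frames = 3000L)
  flt <- filter_localizations(sim$locs)
  tr <- estimate_drift(flt$locs, 300)
  expect_equal(mean(tr$dx), 0, tolerance = 1e-9)
  expect_equal(mean(tr$dy), 0, tolerance = 1e-9)
  expect_lt(max(abs(c(tr$dx, tr$dy))), 0.1)
  expect_true(is.finite(attr(tr, "residual_rms_px")))
})

test_that("drift estimation is equivariant under a rigid translation schedule", {
  sim <- high_snr_scene("W16", 15, seed = 9, n_frames = 3000L)
  flt <- filter_localizations(sim$locs)
  tr0 <- estimate_drift(flt$locs, 300)
  slope <- 0.003
  shifted <- flt$locs
  shifted$x <- shifted$x + slope * shifted$frame
  tr1 <- estimate_drift(shifted, 300)
  sched <- slope * tr0$frame
  expect_lt(max(abs(tr1$dx - (tr0$dx + sched - mean(sched)))), 0.1)
  expect_lt(max(abs(tr1$dy - tr0$dy)), 0.1)
})

test_that("applying a zero trace is the identity; a trace and its negation cancel", {
  tb <- toy_loc_table(20, n_frames = 40L)
  zero <- data.frame(frame = 0:39, dx = 0, dy = 0)
  expect_equal(as.data.frame(apply_drift(tb, zero))[, c("x", "y")],
               as.data.frame(tb)[, c("x", "y")])
  tr <- data.frame(frame = 0:39, dx = sin(0:39 / 5), dy = cos(0:39 / 5))
  neg <- transform(tr, dx = -dx, dy = -dy)
  back <- apply_drift(apply_drift(tb, tr), neg)
  expect_equal(back$x, tb$x, tolerance = 1e-12)
  expect_equal(back$y, tb$y, tolerance = 1e-12)
})

test_that("frames not covered by the trace are an error", {
  tb <- toy_loc_table(5, n_frames = 10L)
  expect_error(apply_drift(tb, data.frame(frame = 0:2, dx = 0, dy = 0)),
               "cover")
})

test_that("drift correction tightens per-site localization spread", {
  kin <- kinetics_params(drift_nm_per_frame = c(0.15, -0.1))
  sim <- simulate_acquisition("W16", 12, 1,
                              acq = acquisition_params(n_frames = 4000L),
                              kin = kin, seed = 14)
  flt <- filter_localizations(sim$locs)
  tr <- estimate_drift(flt$locs, 400)
  cor <- apply_drift(flt$locs, tr)
  keep <- !(sim$locs$precision > 0.03 | sim$locs$ellipticity < 0.1 |
              sim$locs$photons > mean(sim$locs$photons) +
                2 * stats::sd(sim$locs$photons))
  src <- sim$truth$sources[keep]
  site_groups <- split(which(grepl("^site", src)), src[grepl("^site", src)])
  sd_of <- function(tab) {
    mean(unlist(lapply(site_groups, function(i) {
      if (length(i) < 10) return(NULL)
      sqrt(stats::var(tab$x[i]) + stats::var(tab$y[i]))
    })))
  }
  expect_lt(sd_of(cor), 0.5 * sd_of(flt$locs))
  # corrected spread approaches the localization precision (1 nm = 0.0115 px)
  expect_lt(sd_of(cor), 4 * sqrt(2) * 1 / 87)
})
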