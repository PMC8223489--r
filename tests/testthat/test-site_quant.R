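test_that("mean_nnd equals the all-pairs brute-force oracle exactly", {
  set.seed(123)
  for (rep in 1:20) {
    pts <- matrix(stats::runif(2 * sample(2:12, 1), 0, 50), ncol = 2)
    expect_identical(mean_nnd(pts), brute_mean_nnd(pts))
  }
})

test_that("hexagon nearest-neighbor closed forms hold", {
  e <- 15.8
  hexa <- hexagon_coords(e)
  expect_equal(mean_nnd(hexa), e, tolerance = 1e-9)
  expect_equal(mean_nnd(hexa[c(1, 3, 5), ]), e * sqrt(3), tolerance = 1e-9)
  expect_equal(mean_nnd(rbind(c(0, 0), c(3.2, 0))), 3.2, tolerance = 1e-12)
  expect_error(mean_nnd(rbind(c(0, 0))), "2 points")
})

test_that("merge_maxima leaves separated points alone and merges close pairs", {
  pts <- rbind(c(0, 0), c(10, 0), c(0, 10))
  expect_equal(merge_maxima(pts, 5), pts, ignore_attr = TRUE)
  # two equal-weight points 0.8 * threshold apart collapse to the midpoint
  two <- rbind(c(0, 0), c(4, 0))
  out <- merge_maxima(two, 5)
  expect_identical(nrow(out), 1L)
  expect_equal(out[1, ], c(2, 0), ignore_attr = TRUE)
})

test_that("collinear triple merges trace through the hand computation", {
  # spacing 0.6 * d: first merge the nearest pair (weight 2 at 0.3d),
  # then the remainder (distance 0.9d < d) to the weighted centroid 0.6d
  d <- 7
  pts <- rbind(c(0, 0), c(0.6 * d, 0), c(1.2 * d, 0))
  out <- merge_maxima(pts, d)
  expect_identical(nrow(out), 1L)
  expect_equal(out[1, ], c(0.6 * d, 0), ignore_attr = TRUE)
})

test_that("merged point sets never contain a pair below the threshold", {
  set.seed(7)
  for (rep in 1:25) {
    pts <- matrix(stats::runif(2 * sample(3:15, 1), 0, 20), ncol = 2)
    thr <- stats::runif(1, 1, 8)
    out <- merge_maxima(pts, thr, weights = stats::runif(nrow(pts), 0.5, 2))
    expect_lte(nrow(out), nrow(pts))
    if (nrow(out) > 1) expect_true(all(stats::dist(out) >= thr))
  }
})

test_that("the central cluster is selected with a count-first, centrality tie-break", {
  hexa <- hexagon_coords(10)
  all_close <- select_central_cluster(hexa, 21)
  expect_identical(nrow(all_close), 6L)
  # stray maximum five edges away is dropped
  with_stray <- rbind(hexa, c(50, 0))
  kept <- select_central_cluster(with_stray, 21)
  expect_identical(nrow(kept), 6L)
  expect_true(all(kept[, 1] < 20))
  # two singleton clusters: the one nearer the ROI center wins
  two <- rbind(c(1, 0), c(5, 0))
  expect_equal(select_central_cluster(two, 1, center = c(0, 0)),
               rbind(c(1, 0)), ignore_attr = TRUE)
})

test_that("planted site clouds are called at their positions", {
  d <- get_design("W16")
  locs <- site_cloud(d$site_coords_nm, n_each = 70, sigma_nm = 1, seed = 5)
  det <- detect_sites(locs, d, center_px = c(10, 10))
  expect_identical(det$n_sites, 6L)
  expect_equal(det$mean_nnd_nm, d$nominal_edge_nm, tolerance = 0.05)
  # a single site gives one call and an undefined mean NND
  one <- site_cloud(c(0, 0), n_each = 70, seed = 6)
  det1 <- detect_sites(one, d, center_px = c(10, 10))
  expect_identical(det1$n_sites, 1L)
  expect_true(is.na(det1$mean_nnd_nm))
})

test_that("two clouds below the merge distance are called as one site", {
  d <- get_design("W16")
  sep <- 0.4 * d$nominal_edge_nm
  locs <- site_cloud(rbind(c(-sep / 2, 0), c(sep / 2, 0)),
                     n_each = 80, sigma_nm = 0.8, seed = 8)
  det <- detect_sites(locs, d, center_px = c(10, 10))
  expect_identical(det$n_sites, 1L)
})

test_that("site calling is invariant to a whole-pixel ROI translation", {
  d <- get_design("W16")
  locs <- site_cloud(d$site_coords_nm, n_each = 70, seed = 11)
  a <- detect_sites(locs, d, center_px = c(10, 10))
  moved <- locs
  moved$x <- moved$x + 7
  moved$y <- moved$y - 3
  b <- detect_sites(moved, d, center_px = c(17, 7))
  expect_identical(b$n_sites, a$n_sites)
  expect_equal(b$site_coords_nm, a$site_coords_nm, tolerance = 1e-9)
})

test_that("empty ROIs are an error", {
  expect_error(detect_sites(data.frame(x = numeric(0), y = numeric(0)),
                            get_design("W6")), "empty")
})

test_that("pattern summaries aggregate counts, occupancy and NND", {
  mk <- function(n, nnd) structure(
    list(roi_id = 1L, site_coords_nm = matrix(0, n, 2), n_sites = n,
         mean_nnd_nm = nnd), class = "site_detection")
  dets <- list(mk(6, 15.5), mk(5, 16.0), mk(4, 15.0), mk(6, 16.1))
  s <- summarize_patterns(dets, get_design("W16"))
  expect_equal(s$occupancy_estimate, 21 / 24)
  expect_identical(sum(s$sites_per_roi), 4L)
  expect_equal(s$mean_nnd_mean, mean(c(15.5, 16, 15, 16.1)))
  all6 <- summarize_patterns(list(mk(6, 15.8), mk(6, 15.9)), "W16")
  expect_equal(all6$occupancy_estimate, 1)
  # counts above 6 stay in the histogram but cap for occupancy
  over <- summarize_patterns(list(mk(7, 15.8)), "W16")
  expect_equal(over$occupancy_estimate, 1)
  expect_identical(as.integer(over$sites_per_roi[["7"]]), 1L)
  expect_error(summarize_patterns(list(), "W16"), "no site detections")
})

test_that("detected site count never exceeds the raw maxima count", {
  d <- get_design("W9")
  locs <- site_cloud(d$site_coords_nm, n_each = 40, sigma_nm = 1.2, seed = 3)
  det <- detect_sites(locs, d, center_px = c(10, 10))
  expect_lte(det$n_sites, 6L + 2L)  # merging/selection only ever removes
  expect_gte(det$n_sites, 1L)
})
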