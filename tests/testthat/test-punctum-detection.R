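test_that("physical query sizes convert to pixels with round-half-up, floor 1", {
  g <- list(pixel_size_xy = 100, slice_thickness = 70)
  q <- punctum_query("c", c(0.2, 0.2), 0.14)
  px <- synscreen:::query_in_pixels(q, g)
  expect_identical(px$window, c(2L, 2L))   # 0.2 um -> 2 px
  expect_identical(px$span, 2L)            # 0.14 um -> 2 slices
  px1 <- synscreen:::query_in_pixels(punctum_query("c", 0.2, 0.07), g)
  expect_identical(px1$span, 1L)           # 0.07 um -> 1 slice
  px3 <- synscreen:::query_in_pixels(punctum_query("c", 0.2, 0.21), g)
  expect_identical(px3$span, 3L)           # 0.21 um -> 3 slices
  # round-half-up: 150 nm / 100 nm = 1.5 -> 2 px
  expect_identical(synscreen:::query_in_pixels(
    punctum_query("c", 0.15, 0.14), g)$window[1], 2L)
  # floors at 1: queries smaller than a voxel still span one
  expect_identical(synscreen:::query_in_pixels(
    punctum_query("c", 0.01, 0.01), g)$window[1], 1L)
})

test_that("punctum probability is high inside a planted blob, low in noise", {
  set.seed(31)
  a <- pmax(array(rnorm(6 * 48 * 48, 1000, 100), c(6, 48, 48)), 0)
  ctr <- c(3, 24, 24)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    a[ctr[1] + dz, ctr[2] + dy, ctr[3] + dx] <-
      a[ctr[1] + dz, ctr[2] + dy, ctr[3] + dx] + 1000  # 10 sd amplitude
  v <- make_volume(a)
  pr <- compute_punctum_probability(v, punctum_query("test"))
  expect_equal(pr$stage, "punctum3d")
  expect_gt(pr$values[ctr[1], ctr[2], ctr[3]], 0.9)
  # all-noise channel: essentially no voxel survives the 2x2x2 product
  vn <- noise_volume(6, 48, 48, seed = 32)
  prn <- compute_punctum_probability(vn, punctum_query("test"))
  expect_lte(mean(prn$values >= 0.9), 1e-3)
  # span longer than the stack errors
  expect_error(compute_punctum_probability(
    vn, punctum_query("test", min_span_z_um = 0.7)), "stack depth")
})

test_that("segmentation labels components consistently", {
  m <- array(0, c(4, 12, 12))
  m[1:2, 2:4, 2:4] <- 0.95                    # punctum 1, 18 voxels
  m[3:4, 8:10, 8:10] <- 0.99                  # punctum 2, 18 voxels
  ps <- segment_puncta(prob_map(m), 0.9, remediate = FALSE)
  expect_equal(nrow(ps$puncta), 2L)
  expect_setequal(ps$puncta$voxel_count, c(18L, 18L))
  # labels are consecutive and counts agree with the label volume
  expect_setequal(unique(as.vector(ps$label_volume)), c(0L, 1L, 2L))
  expect_equal(sum(ps$puncta$voxel_count), sum(ps$label_volume > 0))
  # centroids sit at the blob centers
  expect_equal(sort(ps$puncta$y), c(3, 9))
  # empty map
  expect_equal(nrow(segment_puncta(prob_map(array(0, c(2, 4, 4))))$puncta), 0L)
  expect_error(segment_puncta(prob_map(m), 1.5), "threshold")
})

test_that("a one-voxel split is healed by remediation", {
  # a 1-px-wide bar with a single sub-threshold voxel in the middle
  m <- array(0, c(1, 9, 9))
  m[1, 5, 3:7] <- 0.95
  m[1, 5, 5] <- 0.5
  raw <- segment_puncta(prob_map(m), 0.9, remediate = FALSE)
  healed <- segment_puncta(prob_map(m), 0.9, remediate = TRUE)
  expect_equal(nrow(raw$puncta), 2L)
  expect_equal(nrow(healed$puncta), 1L)
})

test_that("punctum volume statistics use the population SD", {
  fake <- function(volumes) {
    ps <- segment_puncta(prob_map(array(0, c(1, 4, 4))))
    ps$puncta <- data.frame(id = seq_along(volumes), voxel_count = volumes)
    ps
  }
  s1 <- punctum_volume_stats(fake(c(10, 10, 10)))
  expect_equal(s1$mean_volume, 10); expect_equal(s1$sd_volume, 0)
  s2 <- punctum_volume_stats(fake(c(4, 16)))
  expect_equal(s2$mean_volume, 10); expect_equal(s2$sd_volume, 6)
  s0 <- punctum_volume_stats(fake(integer(0)))
  expect_true(s0$empty)
  expect_equal(c(s0$mean_volume, s0$sd_volume), c(0, 0))
})

test_that("erratic labeling shows a much larger SD-to-mean volume ratio", {
  regular <- generate_dataset(synthetic_spec(
    shape = c(6, 160, 160), n_candidate = 30, seed = 41))
  erratic <- generate_dataset(synthetic_spec(
    shape = c(6, 160, 160), n_candidate = 25, n_giant_clusters = 3,
    seed = 42))
  stats_for <- function(ds) {
    pr <- compute_punctum_probability(ds$channels$candidate)
    punctum_volume_stats(segment_puncta(pr))
  }
  sr <- stats_for(regular); se <- stats_for(erratic)
  expect_gt((se$sd_volume / se$mean_volume) / (sr$sd_volume / sr$mean_volume),
            5)
})

test_that("punctum density is count over physical volume", {
  ps <- segment_puncta(prob_map(array(0, c(10, 512, 512))))
  # default geometry: one voxel = 0.1 * 0.1 * 0.07 = 7e-4 um^3
  expect_equal(voxel_volume_um3(ps), 7e-4)
  expect_equal(total_volume_um3(ps), 1835.008)
  expect_equal(punctum_density(ps), 0)     # no puncta -> density 0
  ps$puncta <- data.frame(id = 1:150)      # 150 puncta in ~1835 um^3
  expect_equal(punctum_density(ps), 150 / 1835.008)
  # and the printed example: 150 puncta in 1000 um^3 -> 0.15
  ps2 <- ps; ps2$pixel_size_xy <- 100; ps2$slice_thickness <- 1000 / (512^2 * 10 * 0.01) * 1000
  expect_equal(punctum_density(ps2), 0.15, tolerance = 1e-12)
})

test_that("punctum counts shrink monotonically with threshold and span", {
  ds <- generate_dataset(synthetic_spec(shape = c(6, 128, 128),
                                        n_candidate = 20, seed = 51))
  v <- ds$channels$candidate
  fg <- foreground_probability(v)
  b <- blob2d_probability(fg, c(2, 2))
  counts_thr <- vapply(c(0.5, 0.7, 0.9, 0.97),
                       function(t) nrow(segment_puncta(span_probability(b, 2),
                                                       t)$puncta), 0)
  expect_true(all(diff(counts_thr) <= 0))
  counts_span <- vapply(1:3, function(s)
    nrow(segment_puncta(span_probability(b, s))$puncta), 0)
  expect_true(all(diff(counts_span) <= 0))
})

test_that("well-separated high-SNR puncta are recovered exactly", {
  ds <- generate_dataset(synthetic_spec(shape = c(8, 192, 192),
                                        n_candidate = 30, seed = 61))
  pr <- compute_punctum_probability(ds$channels$candidate)
  ps <- segment_puncta(pr)
  sc <- score_against_truth(ps, ds$truth, match_radius = 2)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})
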