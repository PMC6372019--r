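test_that("a constant truth curve yields a constant ribbon", {
  prof <- matrix(0.4, 1000, 1, dimnames = list(NULL, "1"))
  sec <- make_section(prof, default_ribbon_geometry(96), noise_sd = 0)
  inside <- sec$label_map > 0
  expect_true(all(sec$image[inside] == 0.4))
  expect_true(all(sec$image[!inside] == 0))
  expect_true(all(sec$label_map %in% c(0L, 1L)))
})

test_that("curve length other than n_blocks is rejected", {
  expect_error(make_section(matrix(0.5, 999, 1)), "999")
})

test_that("pixel intensities agree with an independent depth-raycasting oracle", {
  # two regions with opposite step curves; noise-free
  hi_lo <- c(rep(0.8, 500), rep(0.2, 500))
  lo_hi <- rev(hi_lo)
  sec <- make_section(cbind(`1` = hi_lo, `2` = lo_hi),
                      default_ribbon_geometry(160), noise_sd = 0)
  inside <- which(sec$label_map > 0, arr.ind = TRUE)
  set.seed(42)
  pick <- inside[sample.int(nrow(inside), 200), ]
  for (i in seq_len(nrow(pick))) {
    y <- pick[i, 1]; x <- pick[i, 2]
    # oracle: depth from nearest points on the two boundary polylines
    dp <- min(sqrt((sec$pial_curve$x - x)^2 + (sec$pial_curve$y - y)^2))
    dw <- min(sqrt((sec$wm_curve$x - x)^2 + (sec$wm_curve$y - y)^2))
    d_oracle <- dp / (dp + dw)
    if (abs(d_oracle - 0.5) < 0.05) next  # skip pixels at the step edge
    truth <- sec$truth_profiles[min(max(floor(d_oracle * 1000) + 1, 1), 1000),
                                sec$label_map[y, x]]
    expect_equal(sec$image[y, x], unname(truth))
  }
})

test_that("section generation is deterministic under a fixed seed", {
  tp <- make_truth_profiles(3, seed = 5)
  s1 <- make_section(tp, default_ribbon_geometry(96), noise_sd = 0.05, seed = 7)
  s2 <- make_section(tp, default_ribbon_geometry(96), noise_sd = 0.05, seed = 7)
  expect_identical(s1$image, s2$image)
  s3 <- make_section(tp, default_ribbon_geometry(96), noise_sd = 0.05, seed = 8)
  expect_false(identical(s1$image, s3$image))
})

test_that("polarity flag inverts ribbon intensities", {
  prof <- matrix(0.3, 1000, 1, dimnames = list(NULL, "1"))
  g <- default_ribbon_geometry(96)
  a <- make_section(prof, g, polarity = 1)
  b <- make_section(prof, g, polarity = -1)
  inside <- a$label_map > 0
  expect_equal(b$image[inside], 1 - a$image[inside])
})

test_that("point pairs are radial, on-curve, grouped and deterministic", {
  sec <- tiny_section()
  pp <- sample_point_pairs(sec, 16, seed = 3)
  expect_equal(nrow(pp), 16L)
  expect_equal(unique(table(pp$group)), 4L)
  cen <- sec$geometry$center
  for (i in seq_len(nrow(pp))) {
    # membership: pial point on the pial curve within 0.5 px
    dp <- min(sqrt((sec$pial_curve$x - pp$pial_x[i])^2 +
                     (sec$pial_curve$y - pp$pial_y[i])^2))
    expect_lt(dp, 0.5)
    # perpendicularity: segment is radial (cross product with radius ~ 0)
    seg <- c(pp$pial_x[i] - pp$wm_x[i], pp$pial_y[i] - pp$wm_y[i])
    rad <- c(pp$pial_x[i] - cen[1], pp$pial_y[i] - cen[2])
    sin_ang <- abs(seg[1] * rad[2] - seg[2] * rad[1]) /
      (sqrt(sum(seg^2)) * sqrt(sum(rad^2)))
    expect_lt(sin_ang, 1e-9)
  }
  expect_identical(pp, sample_point_pairs(sec, 16, seed = 3))
  expect_error(sample_point_pairs(sec, 1e6), "exceeds")
})

test_that("orientation-field corridors carry the requested directions", {
  f <- make_orientation_field(
    list(list(start = c(3, 8, 4), length1 = 8, regions = c(1, 2))),
    c(16, 16, 8))
  for (i in 0:7) {
    expect_equal(f$dirs[3 + i, 8, 4, ], c(1, 0, 0))
    expect_equal(f$fa[3 + i, 8, 4], 0.8)
  }
  expect_equal(f$labels[3, 8, 4], 1L)
  expect_equal(f$labels[10, 8, 4], 2L)
  # unit norm wherever fa is above background
  nrm <- sqrt(apply(f$dirs^2, 1:3, sum))
  expect_true(all(abs(nrm - 1) < 1e-12))
})

test_that("corridor bend angle matches a dot-product oracle within 1 degree", {
  for (th in c(20, 37, 45, 58)) {
    f <- make_orientation_field(
      list(list(start = c(3, 3, 4), length1 = 8, length2 = 8,
                bend_angle = th, regions = c(1, 2))),
      c(24, 16, 8))
    d1 <- f$dirs[5, 3, 4, ]             # inside first segment
    lab2 <- which(f$labels == 2, arr.ind = TRUE)
    d2 <- f$dirs[lab2[1], lab2[2], lab2[3], ]  # inside second segment
    ang <- acos(pmin(1, sum(d1 * d2))) * 180 / pi
    expect_lt(abs(ang - th), 1)
  }
})

test_that("empty tract spec yields a background-only field and bad corridors error", {
  f <- make_orientation_field(list(), c(8, 8, 8))
  expect_true(all(f$fa == 0.05))
  expect_true(all(f$labels == 0L))
  expect_error(
    make_orientation_field(
      list(list(start = c(7, 4, 4), length1 = 10, regions = c(1, 2))),
      c(8, 8, 8)),
    "leaves the grid")
})

test_that("null coupling leaves similarity and mean streamline count unrelated", {
  # 64 regions -> 2016 pairs; average correlation over 20 seeds within +-0.05
  set.seed(1)
  simv <- runif(64 * 63 / 2, -1, 1)
  sim <- matrix(0, 64, 64)
  sim[upper.tri(sim)] <- simv
  sim <- sim + t(sim)
  cors <- vapply(1:20, function(s) {
    coh <- make_cohort(cohort_spec(n_subjects = 5, n_regions = 64,
                                   coupling_beta = 0, seed = s), sim)
    meanw <- Reduce(`+`, coh)[upper.tri(sim)] / length(coh)
    cor(simv, meanw)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("strong coupling makes edge presence monotone across similarity deciles", {
  set.seed(2)
  simv <- runif(40 * 39 / 2, -1, 1)
  sim <- matrix(0, 40, 40)
  sim[upper.tri(sim)] <- simv
  sim <- sim + t(sim)
  dec <- cut(simv, quantile(simv, seq(0, 1, 0.1)), include.lowest = TRUE,
             labels = FALSE)
  present <- matrix(0, length(simv), 50)
  for (s in 1:50) {
    coh <- make_cohort(cohort_spec(n_subjects = 2, n_regions = 40,
                                   coupling_beta = 5, seed = 100 + s), sim)
    present[, s] <- attr(coh, "group_indicator")[upper.tri(sim)]
  }
  freq <- tapply(rowMeans(present), dec, mean)
  expect_true(all(diff(freq) > 0))
})

test_that("near-unit base density saturates the group indicator", {
  sim <- diag(0, 6)
  coh <- make_cohort(cohort_spec(n_subjects = 2, n_regions = 6,
                                 coupling_beta = 0,
                                 base_density = 1 - 1e-12, seed = 1), sim)
  gi <- attr(coh, "group_indicator")
  expect_true(all(gi[upper.tri(gi)] == 1L))
})

test_that("cohorts are reproducible bit-for-bit under a fixed seed", {
  sim <- cor(make_truth_profiles(10, seed = 4))
  spec <- cohort_spec(n_subjects = 4, n_regions = 10, seed = 9)
  expect_identical(make_cohort(spec, sim), make_cohort(spec, sim))
  expect_error(make_cohort(spec, matrix(runif(100), 10, 10)), "symmetric")
})

test_that("region geometry respects hemispheres, support and determinism", {
  g <- make_region_geometry(4, seed = 2)
  expect_equal(table(g$hemisphere)[["left"]], 2L)
  expect_equal(table(g$hemisphere)[["right"]], 2L)
  g2 <- make_region_geometry(30, seed = 5)
  expect_true(all(g2$volume > 0))
  expect_true(all(g2$area > 0))
  expect_false(anyDuplicated(g2[, c("x", "y", "z")]) > 0)
  expect_identical(g2, make_region_geometry(30, seed = 5))
  expect_error(make_region_geometry(5), "even")
})
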