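test_that("nearest neighbours minimize midpoint distance with deterministic ties", {
  # collinear segments with midpoints at x = 0, 1, 5
  pairs <- dplyr::bind_rows(
    pair_row(1L, c(0, 0), c(0, 2)),
    pair_row(2L, c(1, 0), c(1, 2)),
    pair_row(3L, c(5, 0), c(5, 2))
  )
  nn <- nearest_neighbor_pairs(pairs)
  # exhaustive pairwise-distance oracle
  mids <- cbind((pairs$pial_x + pairs$wm_x) / 2, (pairs$pial_y + pairs$wm_y) / 2)
  dm <- as.matrix(dist(mids)); diag(dm) <- Inf
  expect_equal(nn$nn_pair_id, unname(apply(dm, 1, which.min)))
  expect_equal(nn$nn_pair_id, c(2L, 1L, 2L))

  two <- nearest_neighbor_pairs(pairs[1:2, ])
  expect_equal(two$nn_pair_id, c(2L, 1L))

  dup <- dplyr::bind_rows(
    pair_row(1L, c(0, 0), c(0, 2)),
    pair_row(2L, c(3, 0), c(3, 2)),
    pair_row(3L, c(3, 0), c(3, 2))  # duplicate midpoint of 2
  )
  nn2 <- nearest_neighbor_pairs(dup)
  expect_equal(nn2$nn_pair_id[1], 2L)  # tie between 2 and 3 -> lowest id
  expect_equal(nn2$nn_distance[2], 0)

  lone <- nearest_neighbor_pairs(pair_row(9L, c(0, 0), c(0, 2)))
  expect_true(is.na(lone$nn_pair_id))
})

test_that("profile extraction is constant on constant images and 1,000 long", {
  img <- matrix(0.4, 60, 60)
  p <- pair_row(1L, c(10, 5), c(10, 50))
  nb <- pair_row(2L, c(20, 5), c(20, 50))
  prof <- extract_profile(img, p, nb)
  expect_length(prof, 1000L)
  expect_true(all(prof == 0.4))
  expect_error(extract_profile(img, p, p), "degenerate")
  expect_error(extract_profile(img, p, NA), "no nearest-neighbour")
})

test_that("two-band images match a brute-force pixel-binning oracle", {
  img <- rbind(matrix(1, 20, 40), matrix(0, 20, 40))
  p <- pair_row(1L, c(5, 2), c(5, 38))
  nb <- pair_row(2L, c(10, 2), c(10, 38))
  prof <- extract_profile(img, p, nb, n_blocks = 10L)
  # oracle: bin pixel centers of the rectangle into depth strata
  oracle <- vapply(1:10, function(k) {
    lo <- 2 + (k - 1) * 3.6
    hi <- 2 + k * 3.6
    ys <- (ceiling(lo)):(floor(ifelse(k == 10, hi, hi - 1e-9)))
    mean(img[ys, 6:9])
  }, numeric(1))
  trans <- which(oracle > 0 & oracle < 1 |
                   abs(oracle - prof) > 1e-9)
  # all strata but the single pial->wm transition stratum agree exactly
  expect_lte(length(trans), 1L)
  expect_equal(prof[-trans], oracle[-trans])
  expect_true(prof[trans] >= 0 && prof[trans] <= 1)
  expect_true(all(prof[seq_len(min(trans) - 1)] == 1))
  expect_true(all(prof[seq.int(max(trans) + 1, 10)] == 0))
})

test_that("extraction is linear in image intensity", {
  set.seed(3)
  img <- matrix(runif(3600), 60, 60)
  p <- pair_row(1L, c(12, 6), c(14, 52))
  nb <- pair_row(2L, c(22, 7), c(24, 51))
  a <- extract_profile(img, p, nb, n_blocks = 50L)
  b <- extract_profile(img * 2.5, p, nb, n_blocks = 50L)
  expect_equal(b, 2.5 * a, tolerance = 1e-12)
})

test_that("profiles are depth-oriented: increasing stain with depth gives nondecreasing curves", {
  ramp <- matrix(seq(0.1, 0.9, length.out = 1000), 1000, 2)
  colnames(ramp) <- c("1", "2")
  sec <- make_section(ramp, default_ribbon_geometry(160), noise_sd = 0)
  pp <- sample_point_pairs(sec, 24, seed = 5)
  pf <- extract_profiles(sec$image, pp, sec$label_map, n_blocks = 200L)
  for (v in pf$values) {
    if (is.null(v)) next
    # outermost strata mix with background pixels across the ribbon boundary
    # under bilinear interpolation, so assess the interior of the ribbon
    expect_gt(v[190] - v[10], 0.5)
    expect_true(all(diff(v[10:190]) > -1e-3))
  }
})

test_that("region assignment matches an exhaustive-scan oracle and breaks ties low", {
  lm1 <- matrix(0L, 8, 8)
  lm1[4, 5] <- 3L  # pixel (x=5, y=4)
  res <- assign_region(c(5, 4), lm1)
  expect_equal(res$region, 3L)
  expect_equal(res$voxel_distance, 0)

  # midpoint equidistant from regions 7 (x=2) and 4 (x=6): lower id wins
  lm2 <- matrix(0L, 8, 8)
  lm2[4, 2] <- 7L
  lm2[4, 6] <- 4L
  expect_equal(assign_region(c(4, 4), lm2)$region, 4L)

  set.seed(11)
  for (rep in 1:100) {
    lm <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
    if (all(lm == 0)) next
    mid <- runif(2, 1, 12)
    got <- assign_region(mid, lm)
    # oracle: scan every pixel
    best <- Inf; breg <- Inf
    for (y in 1:12) for (x in 1:12) {
      if (lm[y, x] == 0) next
      d <- sqrt((x - mid[1])^2 + (y - mid[2])^2)
      if (d < best - 1e-12 || (abs(d - best) <= 1e-12 && lm[y, x] < breg)) {
        best <- d; breg <- lm[y, x]
      }
    }
    expect_equal(got$voxel_distance, best)
    expect_equal(got$region, breg)
  }
  expect_error(assign_region(c(1, 1), matrix(0L, 4, 4)), "no labeled")
})

make_qc_profiles <- function(dists, regions, nn_regions = regions) {
  n <- length(dists)
  tibble::tibble(
    pair_id = seq_len(n), section_id = 1L, region = regions,
    voxel_distance = dists, nn_pair_id = seq_len(n),
    nn_distance = 1, segment_length = 10,
    values = replicate(n, rep(0.5, 10), simplify = FALSE),
    nn_region = nn_regions,
    crosses_boundary = nn_regions != regions
  )
}

test_that("distance outliers beyond the upper IQR fence are excluded first", {
  pf <- make_qc_profiles(c(1, 1, 1, 1, 100), rep(2L, 5))
  # quartile oracle, quantile type 7: Q1 = Q3 = 1, fence = 1
  q <- quantile(pf$voxel_distance, c(0.25, 0.75), type = 7)
  expect_equal(unname(q[2] + 1.5 * diff(q)), 1)
  kept <- suppressMessages(qc_filter(pf))
  expect_equal(kept$pair_id, 1:4)
  excl <- attr(kept, "exclusions")
  expect_equal(excl$reason, "distance_outlier")

  same <- make_qc_profiles(rep(2, 6), rep(1L, 6))
  expect_equal(nrow(suppressMessages(qc_filter(same))), 6L)
})

test_that("boundary-crossing profiles are excluded after the distance rule", {
  pf <- make_qc_profiles(rep(1, 4), c(3L, 5L, 2L, 2L),
                         nn_regions = c(5L, 3L, 2L, 2L))
  kept <- suppressMessages(qc_filter(pf))
  expect_equal(kept$pair_id, 3:4)
  expect_equal(attr(kept, "exclusions")$reason,
               rep("boundary_crossing", 2))
  expect_warning(qc_filter(pf[0, ]), "empty")
})

test_that("regional aggregation averages members and applies the count filter", {
  pf <- make_qc_profiles(rep(1, 21), c(rep(1L, 19), 2L, 2L))
  pf$values <- c(replicate(19, rep(0.2, 10), simplify = FALSE),
                 list(rep(0, 10)), list(rep(1, 10)))
  reg <- regional_profiles(pf, min_count = 20)
  expect_false(reg$included[reg$region == 1])  # 19 < 20
  expect_equal(reg$mean_profile[[which(reg$region == 2)]], rep(0.5, 10))
  reg0 <- regional_profiles(pf, min_count = 0)
  expect_true(all(reg0$included))
  # two identical members -> mean equals either
  expect_equal(regional_profiles(pf[1:2, ], min_count = 0)$mean_profile[[1]],
               pf$values[[1]])
})

test_that("noise-free regional profiles recover the ground truth", {
  tp <- make_truth_profiles(6, seed = 13)
  sec <- make_section(tp, default_ribbon_geometry(400), noise_sd = 0)
  pp <- sample_point_pairs(sec, 200, seed = 2)
  pf <- extract_profiles(sec$image, pp, sec$label_map)
  reg <- regional_profiles(suppressMessages(qc_filter(pf)), min_count = 10)
  for (i in which(reg$included)) {
    r <- cor(reg$mean_profile[[i]], tp[, as.character(reg$region[i])])
    expect_gt(r, 0.99)
  }
})

test_that("layer step profiles follow cumulative thickness boundaries", {
  one <- ek_layer_table(1, 2, 3)
  expect_equal(ek_profile(one), rep(6, 1000))
  two <- ek_layer_table(c(0.3, 0.7), c(2, 1), c(5, 1))
  prof <- ek_profile(two)
  # cumulative-boundary oracle: steps at depths (k - 0.5)/1000 <= 0.3
  expect_equal(sum(prof == 10), 300L)
  expect_equal(sum(prof == 1), 700L)
  inc <- ek_layer_table(c(0.2, 0.3, 0.5), c(1, 2, 3), c(1, 2, 3))
  expect_true(all(diff(ek_profile(inc)) >= 0))
  bad <- ek_layer_table(c(0.3, 0.7), c(1, 1), c(1, 1))
  bad$thickness_fraction <- c(0.3, 0.6)
  expect_error(ek_profile(bad), "sum to 1")
})

test_that("profile comparison is plain Pearson correlation", {
  a <- seq_len(1000) / 10
  expect_equal(compare_profiles(a, a), 1.0)
  expect_equal(compare_profiles(a, -a), -1.0)
  b <- a^2
  # direct-formula oracle
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(compare_profiles(a, b), r_oracle, tolerance = 1e-12)
  expect_error(compare_profiles(a, rep(1, 1000)), "zero variance")
})
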