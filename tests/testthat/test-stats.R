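test_that("pooled-variance t test matches the closed-form oracle", {
  same <- ttest2(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  x <- c(1, 2, 3); y <- c(4, 5, 6)
  got <- ttest2(x, y)
  # direct-formula oracle
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), 4)
  expect_equal(got$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(got$df, 4)
  expect_equal(got$p, p_oracle, tolerance = 1e-10)

  swapped <- ttest2(y, x)
  expect_equal(swapped$statistic, -got$statistic)
  expect_equal(swapped$p, got$p)
  expect_error(ttest2(c(2, 2), c(2, 2)), "pooled variance")
  expect_error(ttest2(1, c(1, 2)), "n >= 2")
})

test_that("Pearson test handles exact and orthogonal cases", {
  x <- 1:10
  expect_equal(pearson_test(x, 2 * x + 1)$estimate, 1)
  xo <- c(1, -1, 1, -1); yo <- c(1, 1, -1, -1)
  got <- pearson_test(xo, yo)
  expect_equal(got$estimate, 0)
  expect_equal(got$p, 1)
  expect_error(pearson_test(x, rep(2, 10)), "constant")
})

test_that("Pearson p agrees with a permutation oracle", {
  set.seed(17)
  x <- rnorm(20)
  y <- 0.5 * x + rnorm(20)
  got <- pearson_test(x, y)
  r_obs <- abs(cor(x, y))
  nperm <- 1e5
  # vectorized permutation oracle
  xc <- scale(x)[, 1]
  ym <- vapply(seq_len(nperm), function(i) sample(y), numeric(20))
  rs <- abs(as.numeric(crossprod(xc, scale(ym))) / 19)
  p_perm <- (sum(rs >= r_obs - 1e-12) + 1) / (nperm + 1)
  expect_lt(abs(got$p - p_perm), 0.01)
})

test_that("partial correlation matches the recursive closed form", {
  set.seed(23)
  x <- rnorm(30); y <- rnorm(30); c1 <- rnorm(30)
  got <- partial_corr(x, y, cbind(c1))
  rxy <- cor(x, y); rxc <- cor(x, c1); ryc <- cor(y, c1)
  rho_oracle <- (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
  expect_equal(got$estimate, rho_oracle, tolerance = 1e-10)
  expect_equal(got$df, 27)

  none <- partial_corr(x, y, NULL)
  ref <- pearson_test(x, y, name = "partial")
  expect_equal(none, ref)
  expect_error(partial_corr(x, c1, cbind(c1)), "explained exactly")
  expect_error(partial_corr(x, y, cbind(c1, 2 * c1)), "collinear")
})

test_that("OLS recovers coefficients against the normal-equations oracle", {
  set.seed(29)
  X <- matrix(rnorm(100), 25, 4)
  beta <- c(2, -1, 0.5, 0, 3)
  y <- beta[1] + X %*% beta[-1] + rnorm(25, 0, 0.4)
  fit <- ols(as.numeric(y), X)
  Xd <- cbind(1, X)
  beta_oracle <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  expect_equal(tidy(fit)$estimate, as.numeric(beta_oracle), tolerance = 1e-8)
  # residual identities
  r <- resid(fit$fit)
  expect_equal(as.numeric(y), unname(fitted(fit$fit) + r))
  expect_lt(max(abs(t(Xd) %*% r)), 1e-8)

  exact <- ols(as.numeric(X %*% c(1, 2, 3, 4)), X)
  expect_equal(suppressWarnings(glance(exact))$r_squared, 1)
  expect_lt(max(abs(resid(exact$fit))), 1e-10)

  none <- ols(c(3, 5, 7, 9), matrix(numeric(0), 4, 0))
  expect_equal(tidy(none)$estimate, 6)  # intercept only -> mean(y)
  expect_error(ols(rnorm(10), cbind(1:10, 2 * (1:10))), "rank")
})

test_that("residualization centres and orthogonalizes", {
  set.seed(31)
  nuis <- cbind(runif(40, 1, 9), rnorm(40))
  planted <- 2 * nuis[, 1] + rnorm(40, 0, 0.3)
  r <- residualize(planted, nuis)
  expect_equal(mean(r), 0, tolerance = 1e-12)
  expect_lt(abs(cor(r, nuis[, 1])), 1e-8)
  expect_lt(abs(cor(r, nuis[, 2])), 1e-8)
  exact <- residualize(3 + nuis %*% c(1, -2), nuis)
  expect_lt(max(abs(exact)), 1e-10)
  indep <- rnorm(40)
  nuis_unrelated <- rnorm(40)
  r_ind <- residualize(indep, cbind(nuis_unrelated))
  expect_gt(cor(r_ind, indep - mean(indep)), 0.95)
  expect_equal(mean(r_ind), 0, tolerance = 1e-12)
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  ident <- anova1(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)

  set.seed(37)
  groups <- list(rnorm(15, 0), rnorm(15, 0.5), rnorm(15, 1))
  got <- anova1(groups)
  vals <- unlist(groups)
  gm <- mean(vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_oracle <- (ssb / 2) / (ssw / 42)
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(c(got$df, got$df2), c(2, 42))
  expect_error(anova1(list(c(1, 1), c(2, 2))), "zero within-group")
})

test_that("BH correction reproduces the step-up hand computation", {
  expect_equal(bh_fdr(0.03)$q, 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q, rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.5, 6))$q, rep(0.5, 6))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(41)
  p <- runif(50)
  res <- bh_fdr(p)
  expect_true(all(res$q >= res$p))
  ord <- order(p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))
})

test_that("centroid distances and distance bins behave deterministically", {
  geom <- tibble::tibble(region = 1:2, x = c(0, 3), y = c(0, 4), z = c(0, 0))
  d <- edge_distance(geom)
  expect_equal(d[1, 2], 5.0)
  expect_equal(diag(d), c(0, 0), ignore_attr = TRUE)

  set.seed(43)
  g10 <- make_region_geometry(10, seed = 3)
  d10 <- edge_distance(g10)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(d10[i, j],
                 sqrt(sum((g10[i, c("x", "y", "z")] -
                             g10[j, c("x", "y", "z")])^2)),
                 ignore_attr = TRUE)
  }

  bins8 <- bin_distances(c(5, 1, 8, 3, 9, 2, 7, 4))
  expect_equal(as.integer(table(bins8$category)), c(2L, 4L, 2L))
  expect_equal(bins8$category[bins8$distance %in% c(1, 2)],
               factor(c("short", "short"), levels = c("short", "mid", "long")))

  tied <- bin_distances(rep(2, 4))
  expect_equal(as.integer(table(tied$category)), c(1L, 2L, 1L))
  expect_equal(as.character(tied$category), c("short", "mid", "mid", "long"))

  set.seed(47)
  d100 <- runif(100)
  b100 <- bin_distances(d100)
  srt <- sort(d100)
  expect_true(all(d100[b100$category == "short"] <= srt[25]))
  expect_true(all(d100[b100$category == "long"] >= srt[76]))
  expect_error(bin_distances(c(1, 2, 3)), ">= 4")
})

test_that("hemisphere split partitions pairs completely", {
  geom <- tibble::tibble(region = 1:4,
                         hemisphere = c("left", "left", "right", "right"))
  pairs <- tidyr::expand_grid(region_i = 1:4, region_j = 1:4) %>%
    dplyr::filter(region_i < region_j)
  hs <- hemisphere_split(pairs, geom)
  expect_equal(as.integer(table(hs$hemi)), c(1L, 1L, 4L))

  allL <- tibble::tibble(region = 1:3, hemisphere = "left")
  pl <- tibble::tibble(region_i = c(1, 1, 2), region_j = c(2, 3, 3))
  expect_equal(as.integer(table(hemisphere_split(pl, allL)$hemi)),
               c(3L, 0L, 0L))

  g60 <- make_region_geometry(60, seed = 1)
  p60 <- tidyr::expand_grid(region_i = 1:60, region_j = 1:60) %>%
    dplyr::filter(region_i < region_j)
  h60 <- hemisphere_split(p60, g60)
  expect_equal(as.integer(table(h60$hemi)), c(435L, 435L, 900L))
  expect_equal(nrow(h60), choose(60, 2))
  expect_error(hemisphere_split(tibble::tibble(region_i = 1, region_j = 9),
                                geom), "missing hemisphere")
})

test_that("residualized values never correlate with their nuisance columns", {
  set.seed(53)
  for (rep in 1:5) {
    nuis <- matrix(rnorm(60), 20, 3)
    v <- rnorm(20, sd = 2)
    r <- residualize(v, nuis)
    for (k in 1:3) expect_lt(abs(cor(r, nuis[, k])), 1e-8)
  }
})
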