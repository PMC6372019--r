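# Statistical battery primitives. Each test returns a one-row tibble
# (name, statistic, df, df2, p, extra) so results stack into a family table
# that bh_fdr() then corrects as a unit.

stat_row <- function(name, statistic, df, p, df2 = NA_real_, estimate = NA_real_) {
  tibble(name = name, statistic = unname(statistic), df = unname(df),
         df2 = unname(df2), estimate = unname(estimate), p = unname(p))
}

#' Two-tailed two-sample pooled-variance t test
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, matching
#' integer-df reporting conventions for connected-versus-nonconnected
#' comparisons.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param name Label for the result row.
#' @return One-row tibble (`name`, `statistic`, `df`, `p`, ...).
#' @export
ttest2 <- function(x, y, name = "ttest2") {
  if (length(x) < 2L || length(y) < 2L) abort("each sample needs n >= 2.")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("zero pooled variance: t statistic undefined.")
  tt <- t.test(x, y, var.equal = TRUE)
  stat_row(name, tt$statistic, tt$parameter, tt$p.value,
           estimate = mean(x) - mean(y))
}

#' Pearson correlation test
#'
#' Pearson r with the two-tailed p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param x,y Numeric vectors of equal length >= 3, both nonconstant.
#' @param name Label for the result row.
#' @return One-row tibble; `estimate` carries r.
#' @export
pearson_test <- function(x, y, name = "pearson") {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need equal-length vectors with n >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  stat_row(name, ct$statistic, ct$parameter, ct$p.value,
           estimate = unname(ct$estimate))
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (with intercept); the p-value uses
#' `t = rho sqrt((n - 2 - k) / (1 - rho^2))` on `n - 2 - k` df. With no
#' covariates this reduces exactly to [pearson_test()].
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix (n x k), or `NULL` for none.
#' @param name Label for the result row.
#' @return One-row tibble; `estimate` carries rho.
#' @export
partial_corr <- function(x, y, covariates = NULL, name = "partial") {
  if (is.null(covariates) || NCOL(covariates) == 0L || length(covariates) == 0L) {
    return(pearson_test(x, y, name = name))
  }
  covariates <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(covariates)
  if (n <= k + 2L) abort("need n > k + 2 observations.")
  X <- cbind(1, covariates)
  if (qr(X)$rank < ncol(X)) abort("collinear covariates.")
  rx <- resid(lm.fit(X, x))
  ry <- resid(lm.fit(X, y))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    abort("degenerate partial correlation: a variable is explained exactly by the covariates.")
  }
  rho <- cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * pt(-abs(tval), df)
  stat_row(name, tval, df, p, estimate = rho)
}

#' Ordinary least squares regression
#'
#' Fits `y = b0 + b1 x1 + ... + bk xk + e` by least squares and returns a
#' fitted object with broom-style [tidy()] (coefficients, two-tailed
#' p-values) and [glance()] (R-squared and fit summaries) methods.
#'
#' @param y Response vector.
#' @param X Design matrix (n x k), intercept added automatically.
#' @return Object of class `cyto_ols` wrapping the `lm` fit.
#' @export
ols <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) <= ncol(X) + 1L) abort("need n > k + 1 observations.")
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    abort("rank-deficient design matrix.")
  }
  if (ncol(X) > 0L && is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  df <- if (ncol(X) > 0L) data.frame(y = y, X) else data.frame(y = y)
  fit <- lm(y ~ ., data = df)
  structure(list(fit = fit, response = y, design = X), class = "cyto_ols")
}

#' @export
print.cyto_ols <- function(x, ...) {
  cat("<cyto_ols>\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy coefficients of an OLS fit
#'
#' @param x A `cyto_ols`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`, `p`.
#' @export
tidy.cyto_ols <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p = unname(s[, 4]))
}

#' One-row fit summary of an OLS fit
#'
#' @param x A `cyto_ols`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `adj_r_squared`, `sigma`, `statistic`,
#'   `df`, `df_residual`, `p`, `n`.
#' @export
glance.cyto_ols <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble(
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]), df = unname(f[2]), df_residual = unname(f[3]),
    p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = length(x$response)
  )
}

#' Residualize a vector against nuisance regressors
#'
#' Returns the residuals of an intercept-including least-squares regression
#' of `values` on the nuisance design (e.g. interregional distance, mean
#' volume, mean surface area per region pair); residuals have mean zero and
#' are orthogonal to every nuisance column.
#'
#' @param values Numeric vector.
#' @param nuisance Numeric matrix or data frame of nuisance columns.
#' @return Numeric residual vector, same length as `values`.
#' @export
residualize <- function(values, nuisance) {
  nuisance <- as.matrix(nuisance)
  X <- cbind(1, nuisance)
  if (qr(X)$rank < ncol(X)) abort("rank-deficient nuisance design.")
  as.numeric(resid(lm.fit(X, values)))
}

#' One-way analysis of variance
#'
#' Classic equal-variance one-way ANOVA: F on `(k - 1, N - k)` df across the
#' supplied groups.
#'
#' @param groups Named list of >= 2 numeric samples, each n >= 2.
#' @param name Label for the result row.
#' @return One-row tibble with `statistic` (F), `df` (between), `df2`
#'   (within), `p`.
#' @export
anova1 <- function(groups, name = "anova") {
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    abort("need >= 2 groups, each with n >= 2.")
  }
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    abort("zero within-group variance everywhere: F undefined.")
  }
  ow <- oneway.test(vals ~ grp, var.equal = TRUE)
  stat_row(name, ow$statistic, ow$parameter[1], ow$p.value,
           df2 = ow$parameter[2])
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up q-values with monotonicity adjustment, plus significance flags at
#' `q < alpha`.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @param alpha Significance level on the q scale (default 0.05).
#' @return Tibble with `p`, `q`, `significant`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  q <- p.adjust(pvalues, method = "BH")
  tibble(p = pvalues, q = q, significant = q < alpha)
}

#' Interregional centroid distance matrix
#'
#' Euclidean distances between region centroids, symmetric with a zero
#' diagonal.
#'
#' @param geometry Tibble with `region`, `x`, `y`, `z`.
#' @return Symmetric matrix with region ids as dimnames.
#' @export
edge_distance <- function(geometry) {
  cen <- as.matrix(geometry[, c("x", "y", "z")])
  if (anyDuplicated(cen)) abort("region centroids must be distinct.")
  d <- as.matrix(dist(cen))
  dimnames(d) <- list(geometry$region, geometry$region)
  d
}

#' Bin connected pairs into short-, mid- and long-range categories
#'
#' Ranks the distances of the connected pairs; the shortest
#' `ceiling(0.25 E)` are "short", the longest `ceiling(0.25 E)` are "long",
#' the remainder "mid". Ties are resolved by stable input order, so category
#' sizes are deterministic.
#'
#' @param distances Numeric distances of connected pairs (length >= 4).
#' @param quantiles Lower/upper rank fractions (default `c(0.25, 0.75)`).
#' @return Tibble with `index`, `distance`, `category`
#'   (factor short/mid/long).
#' @export
bin_distances <- function(distances, quantiles = c(0.25, 0.75)) {
  E <- length(distances)
  if (E < 4L) abort("need >= 4 connected pairs.")
  n_tail <- ceiling((quantiles[1]) * E)
  ord <- order(distances)  # stable for ties
  category <- rep("mid", E)
  category[ord[seq_len(n_tail)]] <- "short"
  category[ord[seq.int(E - n_tail + 1L, E)]] <- "long"
  tibble(index = seq_len(E), distance = distances,
         category = factor(category, levels = c("short", "mid", "long")))
}

#' Split region pairs by hemisphere membership
#'
#' Partitions a pair table into within-left, within-right and
#' interhemispheric subsets; the three subsets are disjoint and cover all
#' pairs.
#'
#' @param pairs Tibble with `region_i`, `region_j`.
#' @param geometry Tibble with `region`, `hemisphere` (`"left"`/`"right"`).
#' @return The pair tibble with a `hemi` factor column
#'   (`"LH"`, `"RH"`, `"LH-RH"`).
#' @export
hemisphere_split <- function(pairs, geometry) {
  hemi <- setNames(geometry$hemisphere, geometry$region)
  hi <- hemi[as.character(pairs$region_i)]
  hj <- hemi[as.character(pairs$region_j)]
  if (any(is.na(hi)) || any(is.na(hj))) {
    abort("missing hemisphere label for a region.")
  }
  pairs$hemi <- factor(
    ifelse(hi == "left" & hj == "left", "LH",
           ifelse(hi == "right" & hj == "right", "RH", "LH-RH")),
    levels = c("LH", "RH", "LH-RH")
  )
  pairs
}
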