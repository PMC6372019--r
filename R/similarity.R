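#' Interregional profile-similarity matrix
#'
#' Computes the Pearson correlation between the regional mean laminar
#' profiles of every pair of regions. Regions flagged as excluded (too few
#' profiles) are kept in the matrix but masked: their rows and columns are
#' `NA` and they never enter downstream statistics. The diagonal is masked.
#'
#' @param regional Tibble from [regional_profiles()] (columns `region`,
#'   `mean_profile`, `included`, `n_profiles`).
#' @return Object of class `cyto_similarity`: list with `values` (symmetric
#'   matrix, region ids as dimnames), `included` (named logical),
#'   `n_profiles` (named integer) and `transform` (`"raw"`).
#' @export
similarity_matrix <- function(regional) {
  stopifnot(all(c("region", "mean_profile", "included") %in% names(regional)))
  inc <- regional$included
  if (sum(inc) < 2L) abort("need at least 2 included regions.")
  prof <- do.call(cbind, regional$mean_profile)
  colnames(prof) <- as.character(regional$region)
  sds <- apply(prof[, inc, drop = FALSE], 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant mean profile in region(s): %s",
                  paste(colnames(prof[, inc, drop = FALSE])[sds == 0],
                        collapse = ", ")))
  }
  vals <- suppressWarnings(cor(prof))
  vals[!inc, ] <- NA_real_
  vals[, !inc] <- NA_real_
  diag(vals) <- NA_real_
  structure(
    list(values = vals,
         included = setNames(inc, colnames(prof)),
         n_profiles = setNames(regional$n_profiles %||%
                                 rep(NA_integer_, nrow(regional)),
                               colnames(prof)),
         transform = "raw"),
    class = "cyto_similarity"
  )
}

#' Rank-matched Gaussianization of a vector
#'
#' Replaces values by standard-normal quantiles at plotting positions
#' `(rank - 0.5) / n` (average ranks for ties), then rescales affinely so the
#' output has sample mean exactly `target_mean` and sample SD exactly
#' `target_sd`. The map is monotone, so rank order is preserved; applying it
#' twice gives the same result as once.
#'
#' @param values Numeric vector (n >= 2, finite, not all identical).
#' @param target_mean,target_sd Target sample moments (defaults 1 and 0.2).
#' @return Transformed numeric vector.
#' @export
rank_gaussianize <- function(values, target_mean = 1, target_sd = 0.2) {
  if (length(values) < 2L || any(!is.finite(values))) {
    abort("`values` must be >= 2 finite numbers.")
  }
  if (max(values) == min(values)) {
    abort("transform undefined: all values identical.")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  z <- qnorm((r - 0.5) / n)
  if (sd(z) == 0) abort("transform undefined: degenerate rank distribution.")
  target_mean + (z - mean(z)) * target_sd / sd(z)
}

#' Apply the rank-matched normal transform to a similarity matrix
#'
#' Gaussianizes the vector of off-diagonal upper-triangle entries among
#' included regions to the target mean and SD, then mirrors the result back,
#' preserving symmetry and masking.
#'
#' @param sim A `cyto_similarity` with `transform == "raw"`.
#' @param target_mean,target_sd Targets (defaults 1 and 0.2).
#' @return A `cyto_similarity` with `transform == "gaussianized"`.
#' @export
gaussianize_similarity <- function(sim, target_mean = 1, target_sd = 0.2) {
  stopifnot(inherits(sim, "cyto_similarity"))
  v <- sim$values
  ut <- upper.tri(v) & !is.na(v)
  v[ut] <- rank_gaussianize(v[ut], target_mean, target_sd)
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  sim$values <- v
  sim$transform <- "gaussianized"
  sim
}

#' Regional mean similarity to the rest of the cortex
#'
#' Averages each included region's column of the similarity matrix over the
#' other included regions (diagonal and masked regions excluded), yielding
#' one value per region summarizing how cytoarchitectonically similar it is
#' to the rest of the brain.
#'
#' @param sim A `cyto_similarity`.
#' @return Tibble with `region`, `mean_similarity`, `n_profiles` for included
#'   regions only.
#' @export
regional_mean_similarity <- function(sim) {
  stopifnot(inherits(sim, "cyto_similarity"))
  inc <- names(sim$included)[sim$included]
  if (length(inc) < 2L) abort("need at least 2 included regions.")
  v <- sim$values[inc, inc, drop = FALSE]
  tibble(
    region = as.integer(inc),
    mean_similarity = colMeans(v, na.rm = TRUE),
    n_profiles = as.integer(sim$n_profiles[inc])
  )
}

#' @export
print.cyto_similarity <- function(x, ...) {
  cat(sprintf("<cyto_similarity> %d regions (%d included), transform=%s\n",
              nrow(x$values), sum(x$included), x$transform))
  invisible(x)
}

#' Tidy a similarity matrix into a long pair table
#'
#' @param x A `cyto_similarity`.
#' @param ... Unused.
#' @return Tibble with one row per unordered included region pair:
#'   `region_i`, `region_j`, `similarity`.
#' @export
tidy.cyto_similarity <- function(x, ...) {
  v <- x$values
  ids <- as.integer(rownames(v))
  ut <- which(upper.tri(v), arr.ind = TRUE)
  out <- tibble(
    region_i = ids[ut[, 1]],
    region_j = ids[ut[, 2]],
    similarity = v[ut]
  )
  out[!is.na(out$similarity), ]
}
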