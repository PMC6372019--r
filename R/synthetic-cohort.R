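#' Specification of a synthetic multi-subject cohort
#'
#' Bundles the parameters of the planted-effect connectome generator: a
#' group-level edge indicator is drawn once per region pair with probability
#' `plogis(qlogis(base_density) + coupling_beta * sim_ij)`; each subject then
#' expresses a group edge independently with probability `p_subject`, and
#' present edges receive a streamline count
#' `round(max(0, w0 + coupling_beta * sim_ij + N(0, noise_sd)))`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_regions Number of regions.
#' @param coupling_beta Effect size linking profile similarity to edge
#'   presence (log-odds per similarity unit) and weight (count units per
#'   similarity unit). 0 plants no effect.
#' @param base_density Baseline edge prevalence in (0, 1) at similarity 0.
#' @param noise_sd Subject-level SD of the weight noise (count units).
#' @param w0 Baseline mean streamline count for present edges.
#' @param p_subject Probability that a subject expresses a group-level edge.
#' @param seed Integer RNG seed; fixed seed gives bit-identical cohorts.
#' @return A list of class `cyto_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30L, n_regions = 60L, coupling_beta = 2,
                        base_density = 0.15, noise_sd = 3, w0 = 10,
                        p_subject = 0.8, seed = 1L) {
  stopifnot_scalar_count(n_subjects, "n_subjects", min = 2L)
  stopifnot_scalar_count(n_regions, "n_regions", min = 2L)
  if (base_density <= 0 || base_density >= 1) {
    abort("`base_density` must lie strictly in (0, 1).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  structure(
    list(n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
         coupling_beta = coupling_beta, base_density = base_density,
         noise_sd = noise_sd, w0 = w0, p_subject = p_subject,
         seed = as.integer(seed)),
    class = "cyto_cohort_spec"
  )
}

#' Generate a cohort of subject connectivity matrices with planted coupling
#'
#' Draws per-subject symmetric streamline-count (NOS) matrices in which the
#' chance of a connection, and its weight, increase with the cytoarchitectonic
#' similarity of the region pair (see [cohort_spec()] for the generative
#' model). The two-level structure (group indicator x per-subject expression)
#' makes the group consensus threshold nontrivial.
#'
#' @param spec A [cohort_spec()].
#' @param similarity Symmetric numeric `n_regions` x `n_regions` matrix of
#'   similarity values (e.g. Pearson correlations of regional laminar
#'   profiles); entries may be on any scale, the coupling acts linearly on
#'   the logit.
#' @return List of `n_subjects` symmetric integer matrices (zero diagonal),
#'   with attributes `group_indicator` (the latent group edge matrix) and
#'   `spec`.
#' @export
make_cohort <- function(spec, similarity) {
  stopifnot(inherits(spec, "cyto_cohort_spec"))
  if (!is_symmetric_num(similarity)) {
    abort("`similarity` must be a symmetric numeric matrix.")
  }
  R <- spec$n_regions
  if (nrow(similarity) != R) {
    abort(sprintf("`similarity` must be %d x %d to match `n_regions`.", R, R))
  }
  ut <- upper.tri(similarity)
  sim <- similarity[ut]
  n_pairs <- length(sim)
  with_seed(spec$seed, {
    p_edge <- stats::plogis(stats::qlogis(spec$base_density) +
                              spec$coupling_beta * sim)
    group_edge <- rbinom(n_pairs, 1L, p_edge)
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      expressed <- group_edge * rbinom(n_pairs, 1L, spec$p_subject)
      w <- spec$w0 + spec$coupling_beta * sim + rnorm(n_pairs, 0, spec$noise_sd)
      nos <- expressed * as.integer(round(pmax(0, w)))
      m <- matrix(0L, R, R)
      m[ut] <- as.integer(nos)
      m <- m + t(m)
      dimnames(m) <- dimnames(similarity)
      m
    })
    gi <- matrix(0L, R, R)
    gi[ut] <- group_edge
    gi <- gi + t(gi)
    attr(subjects, "group_indicator") <- gi
    attr(subjects, "spec") <- spec
    subjects
  })
}

#' Generate synthetic region geometry (centroids, volumes, areas)
#'
#' Places half of the regions in a left-hemisphere box and mirrors the other
#' half to the right (x negated), with log-normal cortical volumes and
#' surface areas on millimetre scales typical of atlas parcels.
#'
#' @param n_regions Even number of regions >= 4 (half per hemisphere).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `region`, `x`, `y`, `z`, `volume`, `area`,
#'   `hemisphere` (`"left"`/`"right"`).
#' @export
make_region_geometry <- function(n_regions, seed = 1L) {
  stopifnot_scalar_count(n_regions, "n_regions", min = 4L)
  if (n_regions %% 2L != 0L) {
    abort("`n_regions` must be even (half per hemisphere).")
  }
  half <- n_regions %/% 2L
  with_seed(seed, {
    x <- runif(half, 10, 65)
    y <- runif(half, -95, 65)
    z <- runif(half, -45, 70)
    volume <- rlnorm(n_regions, log(6000), 0.55)
    area <- rlnorm(n_regions, log(2400), 0.45)
    tibble(
      region = seq_len(n_regions),
      x = c(-x, x),
      y = rep(y, 2L) + rnorm(n_regions, 0, 2),
      z = rep(z, 2L) + rnorm(n_regions, 0, 2),
      volume = volume,
      area = area,
      hemisphere = rep(c("left", "right"), each = half)
    )
  })
}
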