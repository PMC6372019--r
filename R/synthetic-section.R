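#' Generate ground-truth laminar intensity profiles for a set of regions
#'
#' Builds one smooth 1,000-element laminar curve per region, modeled as a
#' stack of Gaussian layer bumps (six canonical layers from the pial to the
#' white-matter surface) whose amplitudes vary smoothly with the region's
#' position along the cortical ribbon. Neighbouring regions therefore have
#' similar curves while distant regions differ, producing a realistic spread
#' of interregional profile correlations.
#'
#' @param n_regions Number of regions (curves) to generate.
#' @param n_blocks Number of depth samples per curve (pial at index 1,
#'   white matter at index `n_blocks`).
#' @param seed Integer RNG seed; a fixed seed gives bit-identical output.
#' @param amp_variation Multiplicative spread of layer amplitudes across
#'   regions (log-scale SD of the smooth regional modulation).
#' @return A numeric matrix with `n_blocks` rows and `n_regions` columns,
#'   values in \[0, 1\]; column names are the region ids `1:n_regions`.
#' @export
make_truth_profiles <- function(n_regions, n_blocks = 1000L, seed = 1L,
                                amp_variation = 0.45) {
  stopifnot_scalar_count(n_regions, "n_regions", min = 2L)
  stopifnot_scalar_count(n_blocks, "n_blocks", min = 10L)
  with_seed(seed, {
    d <- (seq_len(n_blocks) - 0.5) / n_blocks
    # canonical layer centers/widths/base amplitudes (depth fractions)
    centers <- c(0.07, 0.22, 0.40, 0.55, 0.72, 0.90)
    widths  <- c(0.05, 0.07, 0.08, 0.06, 0.08, 0.07)
    base    <- c(0.35, 0.85, 0.70, 1.00, 0.60, 0.75)
    n_layers <- length(centers)
    pos <- (seq_len(n_regions) - 0.5) / n_regions
    # smooth low-order Fourier modulation of each layer's amplitude
    amps <- matrix(0, n_layers, n_regions)
    for (l in seq_len(n_layers)) {
      a1 <- rnorm(1); b1 <- rnorm(1); a2 <- rnorm(1); b2 <- rnorm(1)
      f <- a1 * sin(2 * pi * pos) + b1 * cos(2 * pi * pos) +
        0.5 * (a2 * sin(4 * pi * pos) + b2 * cos(4 * pi * pos))
      amps[l, ] <- base[l] * exp(amp_variation * f / sqrt(2.5))
    }
    bumps <- vapply(seq_len(n_layers), function(l) {
      exp(-((d - centers[l])^2) / (2 * widths[l]^2))
    }, numeric(n_blocks))
    profiles <- 0.12 + bumps %*% amps / 3
    profiles <- profiles / max(profiles) * 0.9
    colnames(profiles) <- as.character(seq_len(n_regions))
    profiles
  })
}

#' Default circular-annulus ribbon geometry for synthetic sections
#'
#' The pial surface is the outer circle (radius 45% of the image side) and
#' the white-matter surface the inner circle (30%), centred in the image;
#' boundary curves are sampled at 8,192 points.
#'
#' @param size Image side length in pixels (>= 32).
#' @param r_pial,r_wm Optional explicit radii in pixels.
#' @return List with `size`, `center`, `r_pial`, `r_wm`, `n_curve`.
#' @export
default_ribbon_geometry <- function(size = 400L, r_pial = NULL, r_wm = NULL) {
  size <- stopifnot_scalar_count(size, "size", min = 32L)
  list(
    size = size,
    center = c((size + 1) / 2, (size + 1) / 2),
    r_pial = r_pial %||% (0.45 * size),
    r_wm = r_wm %||% (0.30 * size),
    n_curve = 8192L
  )
}

#' Generate a synthetic cell-body-stained cortical section
#'
#' Emulates a digitized stained histology section as a circular annulus:
#' the pial surface is the outer circle, the white-matter surface the inner
#' circle, and regions are angular sectors. The pixel intensity at relative
#' cortical depth `d` inside region `r` equals the region's ground-truth
#' laminar curve evaluated at `d`, plus i.i.d. Gaussian noise. The closed-form
#' annulus makes perpendicular point pairs and per-pixel depths exact, so
#' extraction can be checked against analytic oracles.
#'
#' @param region_profiles Matrix (`n_blocks` x regions, as from
#'   [make_truth_profiles()]) or named list of equal-length numeric curves;
#'   every curve must have exactly 1,000 elements unless `n_blocks` says
#'   otherwise.
#' @param ribbon_geometry List with `size` (image side, px), `center`,
#'   `r_pial`, `r_wm`; see `default_ribbon_geometry()` defaults.
#' @param noise_sd Intensity-unit SD of additive Gaussian pixel noise (>= 0).
#' @param seed Integer RNG seed (noise only); fixed seed gives identical
#'   output.
#' @param polarity `1` records the curve as-is; `-1` inverts intensities
#'   (`1 - value`), since the stain digitization polarity is a convention,
#'   not a fact of the data.
#' @param n_blocks Required curve length (default 1,000).
#' @return An object of class `cyto_section`: a list with `image` (matrix in
#'   \[0,1\]), `label_map` (integer region id per pixel, 0 = background),
#'   `pial_curve` / `wm_curve` (tibbles `x`, `y`, `theta`), `truth_profiles`,
#'   and the annulus `geometry`.
#' @export
make_section <- function(region_profiles,
                         ribbon_geometry = default_ribbon_geometry(),
                         noise_sd = 0, seed = 1L, polarity = 1,
                         n_blocks = 1000L) {
  if (is.list(region_profiles) && !is.data.frame(region_profiles)) {
    region_profiles <- do.call(cbind, region_profiles)
  }
  region_profiles <- as.matrix(region_profiles)
  if (nrow(region_profiles) != n_blocks) {
    abort(sprintf("every region curve must have exactly %d elements, got %d.",
                  n_blocks, nrow(region_profiles)))
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!polarity %in% c(1, -1)) abort("`polarity` must be 1 or -1.")
  g <- ribbon_geometry
  if (is.null(colnames(region_profiles))) {
    colnames(region_profiles) <- as.character(seq_len(ncol(region_profiles)))
  }
  n_regions <- ncol(region_profiles)
  region_ids <- as.integer(colnames(region_profiles))

  sz <- g$size
  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # column coordinate
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row coordinate
  dx <- xs - g$center[1]
  dy <- ys - g$center[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) %% (2 * pi)
  inside <- r <= g$r_pial & r >= g$r_wm

  depth <- (g$r_pial - r) / (g$r_pial - g$r_wm)
  block <- clamp(floor(depth * n_blocks) + 1L, 1L, n_blocks)
  sector <- clamp(floor(theta / (2 * pi / n_regions)) + 1L, 1L, n_regions)

  label_map <- matrix(0L, sz, sz)
  label_map[inside] <- region_ids[sector[inside]]

  image <- matrix(0, sz, sz)
  idx <- cbind(block[inside], sector[inside])
  image[inside] <- region_profiles[idx]
  if (polarity == -1) image[inside] <- 1 - image[inside]
  if (noise_sd > 0) {
    image[inside] <- with_seed(seed, image[inside] + rnorm(sum(inside), 0, noise_sd))
  }
  image <- clamp(image, 0, 1)

  tcurve <- seq(0, 2 * pi, length.out = g$n_curve + 1L)[-(g$n_curve + 1L)]
  pial_curve <- tibble(
    theta = tcurve,
    x = g$center[1] + g$r_pial * cos(tcurve),
    y = g$center[2] + g$r_pial * sin(tcurve)
  )
  wm_curve <- tibble(
    theta = tcurve,
    x = g$center[1] + g$r_wm * cos(tcurve),
    y = g$center[2] + g$r_wm * sin(tcurve)
  )

  structure(
    list(
      image = image, label_map = label_map,
      pial_curve = pial_curve, wm_curve = wm_curve,
      truth_profiles = region_profiles, geometry = g,
      polarity = polarity, noise_sd = noise_sd, seed = seed
    ),
    class = "cyto_section"
  )
}

#' @export
print.cyto_section <- function(x, ...) {
  cat(sprintf(
    "<cyto_section> %dx%d px, %d regions, r_pial=%.1f, r_wm=%.1f, noise_sd=%g\n",
    nrow(x$image), ncol(x$image), ncol(x$truth_profiles),
    x$geometry$r_pial, x$geometry$r_wm, x$noise_sd
  ))
  invisible(x)
}

#' Sample pial/white-matter point pairs on a synthetic section
#'
#' Selects point pairs the way a manual annotator would: groups of four
#' closely spaced pairs at random positions along the ribbon, each pair
#' consisting of one point on the pial curve and one on the white-matter
#' curve joined by a segment perpendicular to both boundaries (exactly
#' radial on the annulus).
#'
#' @param section A `cyto_section`.
#' @param n_pairs Total number of pairs (>= 2); rounded up to a multiple of 4
#'   groups internally, then truncated to `n_pairs`.
#' @param seed Integer RNG seed; fixed seed gives an identical pair list.
#' @param group_spacing Spacing between pairs within a group, in curve
#'   samples (short intervals along the ribbon).
#' @return Tibble with columns `pair_id`, `section_id`, `group`,
#'   `pial_x`, `pial_y`, `wm_x`, `wm_y`, `theta`.
#' @export
sample_point_pairs <- function(section, n_pairs, seed = 1L, group_spacing = 2L) {
  stopifnot(inherits(section, "cyto_section"))
  stopifnot_scalar_count(n_pairs, "n_pairs", min = 2L)
  m <- nrow(section$pial_curve)
  if (n_pairs > m) {
    abort(sprintf("n_pairs (%d) exceeds available curve samples (%d).", n_pairs, m))
  }
  n_groups <- ceiling(n_pairs / 4)
  # groups occupy disjoint slots along the ribbon so no two pairs coincide
  slot_width <- 4L * group_spacing
  n_slots <- m %/% slot_width
  if (n_groups > n_slots) {
    abort(sprintf("n_pairs (%d) exceeds available curve samples (%d slots).",
                  n_pairs, n_slots))
  }
  with_seed(seed, {
    base_idx <- (sample.int(n_slots, n_groups, replace = FALSE) - 1L) *
      slot_width + 1L
    idx <- as.vector(vapply(base_idx, function(b) {
      ((b - 1L + group_spacing * (0:3)) %% m) + 1L
    }, integer(4)))
    idx <- idx[seq_len(n_pairs)]
    tibble(
      pair_id = seq_len(n_pairs),
      section_id = 1L,
      group = rep(seq_len(n_groups), each = 4L)[seq_len(n_pairs)],
      theta = section$pial_curve$theta[idx],
      pial_x = section$pial_curve$x[idx],
      pial_y = section$pial_curve$y[idx],
      wm_x = section$wm_curve$x[idx],
      wm_y = section$wm_curve$y[idx]
    )
  })
}
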