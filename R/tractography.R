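#' Deterministic streamline tractography with fiber-assignment rules
#'
#' Propagates streamlines through a voxel-wise principal-direction field in
#' the classical fiber-assignment-by-continuous-tracking style: eight seeds
#' are placed on a fixed 2x2x2 subvoxel grid (offsets of 1/4 voxel) in every
#' masked voxel with FA at or above `fa_stop`, and each seed is tracked in
#' both directions along the voxel's (sign-aligned, axial) direction. A step
#' into a new voxel is refused — terminating the streamline — when that voxel
#' lies outside the grid or mask (`exited_mask`), has `fa < fa_stop`
#' (`low_fa`), or when the angle between consecutive voxel directions exceeds
#' `angle_stop` degrees (`sharp_turn`).
#'
#' @param field A `cyto_field` from [make_orientation_field()].
#' @param seeds_per_voxel Number of seeds per voxel; must be 8 (the fixed
#'   subvoxel grid).
#' @param fa_stop FA termination threshold (default 0.1).
#' @param angle_stop Turning-angle threshold in degrees, strict (default 45:
#'   a 45-degree turn is traversed, anything larger terminates).
#' @param step_size Step length in voxels, in (0, 1] (default 0.5).
#' @param max_steps Maximum steps per half-track.
#' @return Object of class `cyto_streamlines`: list of streamlines, each a
#'   list with `points` (matrix of voxel coordinates, >= 2 rows) and
#'   `termination` (reasons at the two ends).
#' @export
track_fact <- function(field, seeds_per_voxel = 8L, fa_stop = 0.1,
                       angle_stop = 45, step_size = 0.5, max_steps = 200L) {
  stopifnot(inherits(field, "cyto_field"))
  if (step_size <= 0 || step_size > 1) {
    abort("`step_size` must be in (0, 1] voxels.")
  }
  if (seeds_per_voxel != 8L) {
    abort("`seeds_per_voxel` must be 8 (fixed 2x2x2 subvoxel grid).")
  }
  gs <- field$grid_shape
  cos_stop <- cos(angle_stop * pi / 180) - 1e-9  # strict: exactly angle_stop passes

  dir_at <- function(v) field$dirs[v[1], v[2], v[3], ]
  ok_voxel <- function(v) {
    all(v >= 1L) && all(v <= gs) && field$mask[v[1], v[2], v[3]]
  }

  half_track <- function(pos, travel) {
    pts <- list()
    reason <- "max_steps"
    v <- as.integer(round(pos))
    for (step in seq_len(max_steps)) {
      d <- dir_at(v)
      if (sum(d * travel) < 0) d <- -d
      newpos <- pos + step_size * d
      nv <- as.integer(round(newpos))
      if (!identical(nv, v)) {
        if (!ok_voxel(nv)) { reason <- "exited_mask"; break }
        if (field$fa[nv[1], nv[2], nv[3]] < fa_stop) { reason <- "low_fa"; break }
        nd <- dir_at(nv)
        if (sum(nd * d) < 0) nd <- -nd
        if (sum(nd * d) < cos_stop) { reason <- "sharp_turn"; break }
        v <- nv
      }
      pos <- newpos
      travel <- d
      pts[[length(pts) + 1L]] <- pos
    }
    list(points = pts, reason = reason)
  }

  offsets <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25),
                                   c(-0.25, 0.25)))
  seed_vox <- which(field$fa >= fa_stop & field$mask, arr.ind = TRUE)
  tracks <- list()
  for (i in seq_len(nrow(seed_vox))) {
    v0 <- as.integer(seed_vox[i, ])
    d0 <- dir_at(v0)
    for (s in seq_len(nrow(offsets))) {
      p0 <- v0 + offsets[s, ]
      fwd <- half_track(p0, d0)
      bwd <- half_track(p0, -d0)
      pts <- c(rev(bwd$points), list(p0), fwd$points)
      mat <- do.call(rbind, pts)
      if (nrow(mat) >= 2L) {
        tracks[[length(tracks) + 1L]] <- list(
          points = mat,
          termination = c(backward = bwd$reason, forward = fwd$reason)
        )
      }
    }
  }
  structure(tracks, class = "cyto_streamlines")
}

#' @export
print.cyto_streamlines <- function(x, ...) {
  cat(sprintf("<cyto_streamlines> %d streamlines\n", length(x)))
  invisible(x)
}

#' Count streamlines between labeled regions
#'
#' Builds a symmetric streamline-count (NOS) matrix: a streamline whose two
#' endpoints fall in voxels with distinct nonzero region labels increments
#' the corresponding entry; streamlines with an unlabeled endpoint, or both
#' endpoints in the same region, are discarded.
#'
#' @param tracks A `cyto_streamlines`.
#' @param labels 3-D integer array of region ids per voxel (0 = unlabeled).
#' @param regions Optional integer vector fixing the matrix row/column
#'   universe; defaults to the sorted nonzero labels present.
#' @return Symmetric integer matrix with zero diagonal and region ids as
#'   dimnames.
#' @export
count_streamlines <- function(tracks, labels, regions = NULL) {
  regions <- regions %||% sort(unique(labels[labels > 0L]))
  R <- length(regions)
  m <- matrix(0L, R, R, dimnames = list(regions, regions))
  lab_of <- function(p) {
    v <- as.integer(round(p))
    if (any(v < 1L) || any(v > dim(labels))) return(0L)
    labels[v[1], v[2], v[3]]
  }
  for (tr in tracks) {
    a <- lab_of(tr$points[1, ])
    b <- lab_of(tr$points[nrow(tr$points), ])
    if (a > 0L && b > 0L && a != b) {
      i <- match(a, regions)
      j <- match(b, regions)
      m[i, j] <- m[i, j] + 1L
      m[j, i] <- m[j, i] + 1L
    }
  }
  m
}

#' Streamline density: counts scaled by mean region volume
#'
#' Divides each streamline count by the mean cortical volume of the two
#' connected regions, `NOS(i, j) / ((volume_i + volume_j) / 2)`.
#'
#' @param nos Symmetric NOS matrix with region ids as dimnames.
#' @param geometry Region geometry tibble with `region` and `volume`.
#' @return Symmetric numeric density matrix.
#' @export
streamline_density <- function(nos, geometry) {
  ids <- as.integer(rownames(nos))
  vol <- geometry$volume[match(ids, geometry$region)]
  if (any(is.na(vol) & rowSums(nos != 0) > 0)) {
    abort("missing volume for a region with nonzero streamline count.")
  }
  if (any(vol <= 0, na.rm = TRUE)) abort("region volumes must be > 0.")
  denom <- outer(vol, vol, function(a, b) (a + b) / 2)
  out <- nos / denom
  diag(out) <- 0
  out
}

#' Group-consensus binary and weighted networks
#'
#' Forms the group binary network by placing an edge wherever strictly more
#' than `threshold` of the subjects have a nonzero weight (an edge present in
#' exactly half the subjects at the default 0.5 is therefore excluded), and
#' the group weighted network by averaging the nonzero subject weights of
#' each consensus edge.
#'
#' @param subjects List of >= 2 symmetric subject matrices with identical
#'   dimensions and dimnames.
#' @param threshold Consensus prevalence threshold in \[0, 1), strict
#'   (default 0.5).
#' @return Object of class `cyto_group_network`: list with `binary`,
#'   `weighted`, `prevalence` matrices and `threshold`, `n_subjects`.
#' @export
group_network <- function(subjects, threshold = 0.5) {
  if (length(subjects) < 2L) abort("need >= 2 subjects.")
  dims <- lapply(subjects, dim)
  if (length(unique(lapply(subjects, dimnames))) > 1L ||
      length(unique(dims)) > 1L) {
    abort("subject matrices must share dimensions and region sets.")
  }
  n <- length(subjects)
  present <- Reduce(`+`, lapply(subjects, function(m) (m != 0) * 1L))
  prevalence <- present / n
  binary <- (prevalence > threshold) * 1L
  wsum <- Reduce(`+`, subjects)
  weighted <- ifelse(present > 0, wsum / pmax(present, 1L), 0) * binary
  diag(binary) <- 0L
  diag(weighted) <- 0
  structure(
    list(binary = binary, weighted = weighted, prevalence = prevalence,
         threshold = threshold, n_subjects = n),
    class = "cyto_group_network"
  )
}

#' @export
print.cyto_group_network <- function(x, ...) {
  R <- nrow(x$binary)
  cat(sprintf(
    "<cyto_group_network> %d regions, %d edges (prevalence > %g over %d subjects)\n",
    R, sum(x$binary[upper.tri(x$binary)]), x$threshold, x$n_subjects
  ))
  invisible(x)
}

#' Tidy a group network into an edge table
#'
#' @param x A `cyto_group_network`.
#' @param ... Unused.
#' @return Tibble of all unordered region pairs with `region_i`, `region_j`,
#'   `connected`, `prevalence`, `weight`.
#' @export
tidy.cyto_group_network <- function(x, ...) {
  ids <- rownames(x$binary) %||% as.character(seq_len(nrow(x$binary)))
  ut <- which(upper.tri(x$binary), arr.ind = TRUE)
  tibble(
    region_i = as.integer(ids[ut[, 1]]),
    region_j = as.integer(ids[ut[, 2]]),
    connected = x$binary[ut] == 1L,
    prevalence = x$prevalence[ut],
    weight = x$weighted[ut]
  )
}
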