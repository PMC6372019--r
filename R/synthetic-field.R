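#' Generate a synthetic principal-diffusion orientation field
#'
#' Builds a voxel grid carrying a unit principal direction and a fractional
#' anisotropy (FA) value per voxel, with one or more high-FA "corridors"
#' emulating coherent white-matter tracts between labeled gray-matter
#' endpoints. Each corridor runs along +x for `length1` voxels and may then
#' bend in the x-y plane by `bend_angle` degrees for another `length2`
#' voxels, so turning-angle stopping rules can be probed with a known
#' geometry.
#'
#' @param tract_spec List of corridors; each corridor is a list with
#'   `start` (voxel coordinate, length-3 integer), `length1` (voxels along
#'   +x, >= 2), optional `length2` (voxels after the bend, default 0),
#'   optional `bend_angle` (degrees, default 0), `regions` (length-2 integer
#'   ids labeling the two endpoints), optional `width` (cross-section voxels
#'   in y, default 1). An empty list yields a background-only field.
#' @param grid_shape Integer length-3 voxel dimensions (each >= 8).
#' @param fa_tract FA inside corridors (default 0.8).
#' @param fa_background FA elsewhere (default 0.05).
#' @return An object of class `cyto_field`: list with `dirs` (4-D array
#'   `x,y,z,3` of unit vectors), `fa`, `labels`, `mask` (3-D arrays), and
#'   `grid_shape`.
#' @export
make_orientation_field <- function(tract_spec, grid_shape = c(16L, 16L, 8L),
                                   fa_tract = 0.8, fa_background = 0.05) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L)) {
    abort("`grid_shape` must be three integers, each >= 8.")
  }
  dirs <- array(0, c(grid_shape, 3L))
  dirs[, , , 1] <- 1  # background axis; inert because background FA is low
  fa <- array(fa_background, grid_shape)
  labels <- array(0L, grid_shape)
  mask <- array(TRUE, grid_shape)

  in_grid <- function(v) all(v >= 1L) && all(v <= grid_shape)
  set_dir <- function(v, d) {
    dirs[v[1], v[2], v[3], ] <<- d / sqrt(sum(d^2))
    fa[v[1], v[2], v[3]] <<- fa_tract
  }

  for (tr in tract_spec) {
    start <- as.integer(tr$start)
    l1 <- as.integer(tr$length1)
    l2 <- as.integer(tr$length2 %||% 0L)
    ang <- tr$bend_angle %||% 0
    w <- as.integer(tr$width %||% 1L)
    if (l1 < 2L) abort("corridor `length1` must be >= 2 voxels.")
    d1 <- c(1, 0, 0)
    d2 <- c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    seg1 <- lapply(0:(l1 - 1L), function(i) start + c(i, 0L, 0L))
    bend <- seg1[[l1]]
    seg2 <- list()
    if (l2 > 0L) {
      ts <- seq(0.5, l2, by = 0.25)
      pts <- unique(t(vapply(ts, function(t) as.integer(round(bend + t * d2)),
                             integer(3))))
      seg2 <- lapply(seq_len(nrow(pts)), function(i) pts[i, ])
      seg2 <- Filter(function(v) !identical(v, bend), seg2)
    }
    vox <- c(seg1, seg2)
    for (dyoff in 0:(w - 1L)) {
      for (k in seq_along(vox)) {
        v <- vox[[k]] + c(0L, dyoff, 0L)
        if (!in_grid(v)) {
          abort(sprintf("corridor leaves the grid at voxel (%s).",
                        paste(v, collapse = ",")))
        }
        set_dir(v, if (k <= l1) d1 else d2)
      }
      first <- seg1[[1]] + c(0L, dyoff, 0L)
      last <- vox[[length(vox)]] + c(0L, dyoff, 0L)
      labels[first[1], first[2], first[3]] <- as.integer(tr$regions[1])
      labels[last[1], last[2], last[3]] <- as.integer(tr$regions[2])
    }
  }

  structure(
    list(dirs = dirs, fa = fa, labels = labels, mask = mask,
         grid_shape = grid_shape),
    class = "cyto_field"
  )
}

#' @export
print.cyto_field <- function(x, ...) {
  cat(sprintf("<cyto_field> grid %s, %d tract voxels, %d labeled\n",
              paste(x$grid_shape, collapse = "x"),
              sum(x$fa >= 0.1), sum(x$labels > 0)))
  invisible(x)
}
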