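# Internal helpers shared across modules.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All generators funnel through this so that a fixed
# seed yields bit-identical output regardless of surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation of a matrix `img` at continuous coordinates
# (x = column, y = row); pixel centers sit at integer coordinates and values
# are clamped at the borders.
bilinear_at <- function(img, x, y) {
  nr <- nrow(img)
  nc <- ncol(img)
  x <- clamp(x, 1, nc)
  y <- clamp(y, 1, nr)
  x0 <- clamp(floor(x), 1, nc - 1L)
  y0 <- clamp(floor(y), 1, nr - 1L)
  fx <- x - x0
  fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1L)]
  i10 <- img[cbind(y0 + 1L, x0)]
  i11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

is_symmetric_num <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m)), na.rm = TRUE) <= tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
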