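#' Construct a layer table of classical cytoarchitectonic measurements
#'
#' Holds, per cortical layer, the relative thickness fraction (must sum to 1),
#' the neuron density (cells per unit volume) and the mean neuron size
#' (volume units), in the style of the classical layer-resolved atlases of
#' cortical cytoarchitecture.
#'
#' @param thickness_fraction Positive fractions summing to 1 (pial to
#'   white matter order).
#' @param neuron_density Positive densities, one per layer.
#' @param neuron_size Positive sizes, one per layer.
#' @param total_thickness Optional absolute cortical thickness (same units as
#'   profile segment lengths) for thickness-agreement analyses.
#' @return Tibble of class `cyto_ek_table` with one row per layer.
#' @export
ek_layer_table <- function(thickness_fraction, neuron_density, neuron_size,
                           total_thickness = NA_real_) {
  if (any(thickness_fraction <= 0)) abort("thickness fractions must be positive.")
  if (abs(sum(thickness_fraction) - 1) > 1e-9) {
    abort("thickness fractions must sum to 1 (within 1e-9).")
  }
  if (length(neuron_density) != length(thickness_fraction) ||
      length(neuron_size) != length(thickness_fraction)) {
    abort("all layer vectors must have the same length.")
  }
  out <- tibble(
    layer = seq_along(thickness_fraction),
    thickness_fraction = thickness_fraction,
    neuron_density = neuron_density,
    neuron_size = neuron_size
  )
  attr(out, "total_thickness") <- total_thickness
  class(out) <- c("cyto_ek_table", class(out))
  out
}

#' Build a step profile from a layer table
#'
#' Samples `n_steps` depth steps from the pial to the white-matter surface;
#' step `k` carries the (neuron density x neuron size) value of the layer
#' containing depth `(k - 0.5) / n_steps` under the cumulative thickness
#' fractions.
#'
#' @param layers A [ek_layer_table()].
#' @param n_steps Number of depth steps (default 1,000).
#' @return Numeric step profile of length `n_steps`.
#' @export
ek_profile <- function(layers, n_steps = 1000L) {
  stopifnot(inherits(layers, "cyto_ek_table"))
  n_steps <- stopifnot_scalar_count(n_steps, "n_steps", min = 1L)
  if (abs(sum(layers$thickness_fraction) - 1) > 1e-9) {
    abort("thickness fractions must sum to 1 (within 1e-9).")
  }
  bounds <- cumsum(layers$thickness_fraction)
  d <- (seq_len(n_steps) - 0.5) / n_steps
  layer_of <- findInterval(d, c(0, bounds), rightmost.closed = TRUE,
                           left.open = TRUE)
  layer_of <- clamp(layer_of, 1L, nrow(layers))
  (layers$neuron_density * layers$neuron_size)[layer_of]
}

#' Pearson similarity of two laminar profiles
#'
#' @param a,b Numeric vectors of equal length with nonzero variance.
#' @return Pearson product-moment correlation coefficient.
#' @export
compare_profiles <- function(a, b) {
  if (length(a) != length(b)) abort("profiles must have equal length.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("undefined correlation: a profile has zero variance.")
  }
  cor(a, b)
}

#' Derive layer tables from ground-truth laminar curves
#'
#' Summarizes each region's continuous truth curve into a layer table by
#' averaging the curve within each layer's depth band and storing the result
#' as the layer's (density x size) product, split arbitrarily between a unit
#' size and the band mean as density. Used to test profile/step-profile
#' agreement on synthetic data; files and objects produced this way are
#' synthetic stand-ins, not digitizations of the classical atlas.
#'
#' @param truth_profiles Matrix of truth curves (rows = depth, cols = regions).
#' @param fractions Layer thickness fractions summing to 1.
#' @param total_thickness Optional absolute thickness per region (recycled).
#' @return Named list of [ek_layer_table()] objects, one per column.
#' @export
make_ek_tables <- function(truth_profiles,
                           fractions = c(0.1, 0.12, 0.22, 0.1, 0.26, 0.2),
                           total_thickness = NA_real_) {
  truth_profiles <- as.matrix(truth_profiles)
  nb <- nrow(truth_profiles)
  bounds <- cumsum(fractions)
  d <- (seq_len(nb) - 0.5) / nb
  layer_of <- clamp(findInterval(d, c(0, bounds), rightmost.closed = TRUE,
                                 left.open = TRUE), 1L, length(fractions))
  tt <- rep_len(total_thickness, ncol(truth_profiles))
  out <- lapply(seq_len(ncol(truth_profiles)), function(j) {
    dens <- as.numeric(tapply(truth_profiles[, j], layer_of, mean))
    ek_layer_table(fractions, dens, rep(1, length(fractions)),
                   total_thickness = tt[j])
  })
  names(out) <- colnames(truth_profiles) %||% as.character(seq_along(out))
  out
}
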