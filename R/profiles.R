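#' Find the nearest-neighbour point pair for every pair
#'
#' For each pial/white-matter point pair, finds the distinct pair in the same
#' section minimizing the Euclidean distance between segment midpoints. The
#' neighbour relation need not be symmetric; ties are broken by the lowest
#' `pair_id` so results are deterministic.
#'
#' @param pairs Tibble of point pairs with columns `pair_id`, `section_id`,
#'   `pial_x`, `pial_y`, `wm_x`, `wm_y`.
#' @return The input tibble with `nn_pair_id` and `nn_distance` (px) added;
#'   a pair alone in its section gets `NA` for both (flagged unpaired).
#' @export
nearest_neighbor_pairs <- function(pairs) {
  stopifnot(all(c("pair_id", "section_id", "pial_x", "pial_y", "wm_x", "wm_y")
                %in% names(pairs)))
  pairs <- pairs %>%
    mutate(mid_x = (.data$pial_x + .data$wm_x) / 2,
           mid_y = (.data$pial_y + .data$wm_y) / 2)
  out <- pairs %>%
    group_by(.data$section_id) %>%
    group_modify_nn() %>%
    ungroup()
  out
}

# split-apply over sections without importing group_modify semantics
group_modify_nn <- function(grouped) {
  dplyr::group_modify(grouped, function(df, key) {
    n <- nrow(df)
    if (n < 2L) {
      df$nn_pair_id <- NA_integer_
      df$nn_distance <- NA_real_
      return(df)
    }
    dm <- as.matrix(dist(cbind(df$mid_x, df$mid_y)))
    diag(dm) <- Inf
    # tie-break by lowest pair_id: scan candidates in pair_id order
    ord <- order(df$pair_id)
    nn_idx <- vapply(seq_len(n), function(i) {
      best <- min(dm[i, ])
      cands <- which(dm[i, ] <= best + 0)
      cands[which.min(df$pair_id[cands])]
    }, integer(1))
    df$nn_pair_id <- df$pair_id[nn_idx]
    df$nn_distance <- dm[cbind(seq_len(n), nn_idx)]
    df
  })
}

#' Extract a 1,000-block laminar intensity profile from a section image
#'
#' Links a point pair with its nearest-neighbour pair to form a quadrilateral
#' (pair pial, neighbour pial, neighbour wm, pair wm) covering a small patch
#' of cortex, partitions it into `n_blocks` depth strata via the bilinear map
#' of the unit square onto the quadrilateral, and records the mean image
#' intensity of each stratum. Element 1 sits at the pial surface, element
#' `n_blocks` at the white-matter surface.
#'
#' Each stratum is sampled on a lattice of 4 points across the quadrilateral
#' by `m` points in depth (with `m` chosen so the full lattice resolves the
#' longer segment at pixel scale), using bilinear image interpolation.
#'
#' @param image Numeric intensity matrix (rows = y, columns = x).
#' @param pair,neighbor One-row data frames (or named lists) with `pial_x`,
#'   `pial_y`, `wm_x`, `wm_y`.
#' @param n_blocks Number of depth blocks (default 1,000).
#' @param samples_across Lattice points across the quadrilateral per stratum.
#' @return Numeric vector of length `n_blocks`.
#' @export
extract_profile <- function(image, pair, neighbor, n_blocks = 1000L,
                            samples_across = 4L) {
  if (is.null(neighbor) || (length(neighbor) == 1L && is.na(neighbor))) {
    abort("pair has no nearest-neighbour pair; cannot form a quadrilateral.")
  }
  n_blocks <- stopifnot_scalar_count(n_blocks, "n_blocks", min = 1L)
  pa <- c(pair$pial_x, pair$pial_y)
  pb <- c(neighbor$pial_x, neighbor$pial_y)
  wb <- c(neighbor$wm_x, neighbor$wm_y)
  wa <- c(pair$wm_x, pair$wm_y)
  corners <- rbind(pa, pb, wb, wa)
  area <- abs(sum(corners[, 1] * corners[c(2, 3, 4, 1), 2] -
                    corners[c(2, 3, 4, 1), 1] * corners[, 2])) / 2
  if (area <= 1e-9) abort("degenerate quadrilateral (area ~ 0).")

  len_a <- sqrt(sum((pa - wa)^2))
  len_b <- sqrt(sum((pb - wb)^2))
  m <- max(1L, ceiling(max(len_a, len_b) / n_blocks))
  ks <- rep(seq_len(n_blocks), each = m * samples_across)
  vs <- (rep(seq_len(n_blocks), each = m) - 1L +
           (rep(seq_len(m), times = n_blocks) - 0.5) / m) / n_blocks
  vs <- rep(vs, each = samples_across)
  us <- rep((seq_len(samples_across) - 0.5) / samples_across,
            times = n_blocks * m)

  # bilinear map of (u across, v depth) onto the quadrilateral
  px <- (1 - vs) * ((1 - us) * pa[1] + us * pb[1]) +
    vs * ((1 - us) * wa[1] + us * wb[1])
  py <- (1 - vs) * ((1 - us) * pa[2] + us * pb[2]) +
    vs * ((1 - us) * wa[2] + us * wb[2])
  vals <- bilinear_at(image, px, py)
  as.numeric(tapply(vals, ks, mean))
}

#' Assign a point pair to the atlas region of its nearest labeled pixel
#'
#' Returns the region id of the labeled (nonzero) pixel nearest to the
#' segment midpoint, together with the Euclidean distance to that pixel.
#' Distance ties are broken by the lowest region id, then by pixel order.
#'
#' @param pair One-row data frame or list with `pial_x`, `pial_y`, `wm_x`,
#'   `wm_y` (the midpoint is used), or a length-2 numeric `c(x, y)`.
#' @param label_map Integer matrix of region ids per pixel (0 = background).
#' @return List with `region` and `voxel_distance` (px).
#' @export
assign_region <- function(pair, label_map) {
  lab_idx <- which(label_map > 0L, arr.ind = TRUE)
  if (nrow(lab_idx) == 0L) abort("`label_map` contains no labeled pixel.")
  if (is.numeric(pair) && length(pair) == 2L) {
    mid <- pair
  } else {
    mid <- c((pair$pial_x + pair$wm_x) / 2, (pair$pial_y + pair$wm_y) / 2)
  }
  # pixel (row=y, col=x) centers at integer coordinates
  d2 <- (lab_idx[, 2] - mid[1])^2 + (lab_idx[, 1] - mid[2])^2
  best <- min(d2)
  cands <- which(d2 <= best)
  regions <- label_map[lab_idx[cands, , drop = FALSE]]
  pick <- cands[order(regions, cands)[1]]
  list(region = as.integer(label_map[lab_idx[pick, , drop = FALSE]]),
       voxel_distance = unname(sqrt(d2[pick])))
}

#' Extract, region-assign and annotate profiles for a table of point pairs
#'
#' Convenience wrapper running [nearest_neighbor_pairs()],
#' [extract_profile()] and [assign_region()] over a whole pair table.
#'
#' @param image Intensity matrix.
#' @param pairs Point-pair tibble (`pair_id`, `section_id`, `pial_*`, `wm_*`).
#' @param label_map Integer region-id matrix aligned with `image`.
#' @param n_blocks Depth blocks per profile (default 1,000).
#' @return Tibble with one row per pair: `pair_id`, `section_id`, `region`,
#'   `voxel_distance`, `nn_pair_id`, `nn_distance`, `nn_region`,
#'   `crosses_boundary`, `segment_length` (px), and list-column `values`
#'   (numeric `n_blocks`-vectors).
#' @export
extract_profiles <- function(image, pairs, label_map, n_blocks = 1000L) {
  pr <- nearest_neighbor_pairs(pairs)
  lab_idx <- which(label_map > 0L, arr.ind = TRUE)
  if (nrow(lab_idx) == 0L) abort("`label_map` contains no labeled pixel.")
  lx <- lab_idx[, 2]
  ly <- lab_idx[, 1]
  lr <- label_map[lab_idx]

  assign_fast <- function(mx, my) {
    d2 <- (lx - mx)^2 + (ly - my)^2
    best <- min(d2)
    cands <- which(d2 <= best)
    pick <- cands[order(lr[cands], cands)[1]]
    unname(c(lr[pick], sqrt(d2[pick])))
  }

  rows <- lapply(seq_len(nrow(pr)), function(i) {
    row <- pr[i, ]
    mid <- c((row$pial_x + row$wm_x) / 2, (row$pial_y + row$wm_y) / 2)
    ar <- assign_fast(mid[1], mid[2])
    vals <- if (!is.na(row$nn_pair_id)) {
      nb <- pr[pr$pair_id == row$nn_pair_id, ]
      # coincident pairs give a degenerate quadrilateral; drop the profile
      tryCatch(extract_profile(image, row, nb, n_blocks = n_blocks),
               error = function(e) NULL)
    } else {
      NULL
    }
    tibble(
      pair_id = row$pair_id, section_id = row$section_id,
      region = as.integer(ar[1]), voxel_distance = ar[2],
      nn_pair_id = row$nn_pair_id, nn_distance = row$nn_distance,
      segment_length = sqrt((row$pial_x - row$wm_x)^2 +
                              (row$pial_y - row$wm_y)^2),
      values = list(vals)
    )
  })
  out <- bind_rows(rows)
  nn_region <- out$region[match(out$nn_pair_id, out$pair_id)]
  out$nn_region <- as.integer(nn_region)
  out$crosses_boundary <- !is.na(out$nn_region) & out$nn_region != out$region
  out
}

#' Quality-control filter for extracted profiles
#'
#' Applies, in this fixed order, (1) a distance outlier rule: profiles whose
#' midpoint lies farther from the nearest labeled pixel than
#' `Q3 + iqr_factor * IQR` of the `voxel_distance` distribution (one-sided
#' upper fence, quartiles by linear interpolation / quantile type 7) are
#' excluded; then (2) a boundary rule: profiles whose nearest-neighbour pair
#' is assigned a different region are excluded. Profiles without a neighbour
#' are also excluded (no quadrilateral).
#'
#' @param profiles Tibble from [extract_profiles()].
#' @param iqr_factor Multiplier of the interquartile range (default 1.5).
#' @return Tibble of surviving profiles; attribute `exclusions` is a tibble
#'   (`pair_id`, `reason`) logging every removal, and a message reports the
#'   bookkeeping counts.
#' @export
qc_filter <- function(profiles, iqr_factor = 1.5) {
  if (nrow(profiles) == 0L) {
    warn("qc_filter(): empty input; returning empty output.")
    return(profiles)
  }
  q <- quantile(profiles$voxel_distance, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + iqr_factor * (q[2] - q[1])
  out1 <- profiles$voxel_distance > fence
  survivors <- profiles[!out1, , drop = FALSE]
  out2 <- survivors$crosses_boundary | is.na(survivors$nn_pair_id) |
    purrr::map_lgl(survivors$values, is.null)
  final <- survivors[!out2, , drop = FALSE]
  exclusions <- bind_rows(
    tibble(pair_id = profiles$pair_id[out1], reason = "distance_outlier"),
    tibble(pair_id = survivors$pair_id[out2], reason = "boundary_crossing")
  )
  message(sprintf(
    "qc_filter: %d profiles -> %d after distance outliers (-%d) -> %d after boundary crossings (-%d)",
    nrow(profiles), nrow(survivors), sum(out1), nrow(final), sum(out2)
  ))
  attr(final, "exclusions") <- exclusions
  final
}

#' Aggregate profiles to regional mean laminar profiles
#'
#' Averages profiles element-wise within each region and flags regions with
#' fewer than `min_count` profiles as excluded (they are retained in the
#' output for bookkeeping but must not enter similarity analyses).
#'
#' @param profiles QC-passed profile tibble (list-column `values`).
#' @param min_count Minimum profiles per region for inclusion (default 20;
#'   0 disables the filter).
#' @return Tibble with `region`, `n_profiles`, `mean_thickness` (px),
#'   `included`, and list-column `mean_profile`.
#' @export
regional_profiles <- function(profiles, min_count = 20L) {
  profiles %>%
    filter(!purrr::map_lgl(.data$values, is.null)) %>%
    group_by(.data$region) %>%
    summarise(
      n_profiles = dplyr::n(),
      mean_thickness = mean(.data$segment_length),
      mean_profile = list(Reduce(`+`, .data$values) / dplyr::n()),
      .groups = "drop"
    ) %>%
    mutate(included = .data$n_profiles >= min_count) %>%
    arrange(.data$region)
}
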