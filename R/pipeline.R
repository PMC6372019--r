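#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis, from profile
#' extraction through the statistical battery, together with the synthetic
#' generation settings. The full configuration is echoed into the report for
#' provenance.
#'
#' @param n_regions Number of atlas regions (even).
#' @param n_subjects Number of cohort subjects.
#' @param n_pairs Number of point pairs sampled on the section (default 40
#'   per region).
#' @param n_blocks Depth blocks per profile (default 1000).
#' @param min_count Minimum profiles per region for inclusion (default 20).
#' @param iqr_factor Distance-outlier fence multiplier (default 1.5).
#' @param consensus_threshold Group-network prevalence threshold, strict
#'   (default 0.5).
#' @param fa_stop,angle_stop,seeds_per_voxel Tracking rules echoed for
#'   provenance (defaults 0.1, 45 degrees, 8).
#' @param distance_quantiles Short/long distance rank fractions
#'   (default `c(0.25, 0.75)`).
#' @param transform_mean,transform_sd Rank-gaussianization targets
#'   (defaults 1 and 0.2).
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param coupling_beta,base_density,noise_sd,w0,p_subject Cohort generator
#'   settings (see [cohort_spec()]).
#' @param section_size Synthetic section side length in pixels.
#' @param section_noise_sd Pixel noise SD of the synthetic section.
#' @param seed Master RNG seed.
#' @return List of class `cyto_config`.
#' @export
pipeline_config <- function(n_regions = 60L, n_subjects = 30L,
                            n_pairs = 40L * n_regions, n_blocks = 1000L,
                            min_count = 20L, iqr_factor = 1.5,
                            consensus_threshold = 0.5, fa_stop = 0.1,
                            angle_stop = 45, seeds_per_voxel = 8L,
                            distance_quantiles = c(0.25, 0.75),
                            transform_mean = 1, transform_sd = 0.2,
                            fdr_alpha = 0.05, coupling_beta = 2,
                            base_density = 0.15, noise_sd = 3, w0 = 10,
                            p_subject = 0.8, section_size = 400L,
                            section_noise_sd = 0.02, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(consensus_threshold >= 0, consensus_threshold < 1,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(cfg, class = "cyto_config")
}

edge_table <- function(sim, net_nos, net_dens, geometry, transform_mean,
                       transform_sd) {
  edges <- tidy(sim) %>%
    rename(sim = "similarity") %>%
    left_join(tidy(net_nos) %>% rename(weight_nos = "weight"),
              by = c("region_i", "region_j")) %>%
    left_join(tidy(net_dens) %>%
                select("region_i", "region_j", weight_density = "weight"),
              by = c("region_i", "region_j"))
  dmat <- edge_distance(geometry)
  gi <- as.character(edges$region_i)
  gj <- as.character(edges$region_j)
  edges$distance <- dmat[cbind(gi, gj)]
  vol <- setNames(geometry$volume, geometry$region)
  area <- setNames(geometry$area, geometry$region)
  edges$mean_volume <- (vol[gi] + vol[gj]) / 2
  edges$mean_area <- (area[gi] + area[gj]) / 2
  edges <- hemisphere_split(edges, geometry)
  edges$nos_g <- NA_real_
  edges$dens_g <- NA_real_
  conn <- which(edges$connected)
  edges$nos_g[conn] <- rank_gaussianize(edges$weight_nos[conn],
                                        transform_mean, transform_sd)
  edges$dens_g[conn] <- rank_gaussianize(edges$weight_density[conn],
                                         transform_mean, transform_sd)
  edges
}

# Declared main-result test family: 28 named entries. The family is data, not
# code, so alternative family definitions can be corrected together.
#' Default declaration of the main statistical test family
#'
#' Twenty-eight named tests: the edge-level connected-versus-nonconnected
#' t test; similarity-weight correlations (streamline count and density); the
#' distance-category ANOVA with three post hoc t tests and three per-bin
#' correlations; the distance/size-residualized t test and correlation; three
#' hemisphere-subset t tests and three correlations; node-level
#' similarity-strength correlations (two weight kinds), the degree
#' correlation, two profile-count-controlled partial correlations, the
#' distance-residualized node-level correlation, three further graph-metric
#' correlations, and the strength coefficient of the joint regression.
#'
#' @return Character vector of 28 test names.
#' @export
default_test_family <- function() {
  c("edge_ttest", "cor_nos", "cor_density",
    "anova_distance", "ttest_short_mid", "ttest_short_long", "ttest_mid_long",
    "cor_short", "cor_mid", "cor_long",
    "resid_edge_ttest", "resid_edge_cor",
    "ttest_LH", "ttest_RH", "ttest_LHRH",
    "cor_LH", "cor_RH", "cor_LHRH",
    "cor_strength_nos", "cor_strength_density", "cor_degree",
    "partial_strength", "partial_degree", "resid_nodal_cor",
    "cor_betweenness", "cor_clustering", "cor_pathlength",
    "regression_strength")
}

nodal_strength_from_edges <- function(edges, col) {
  bind_rows(
    tibble(region = edges$region_i, w = edges[[col]]),
    tibble(region = edges$region_j, w = edges[[col]])
  ) %>%
    filter(!is.na(.data$w)) %>%
    group_by(.data$region) %>%
    summarise(strength = sum(.data$w), .groups = "drop")
}

run_battery <- function(edges, nodal, cfg) {
  conn <- edges[edges$connected, ]
  nonconn <- edges[!edges$connected, ]
  bins <- bin_distances(conn$distance, cfg$distance_quantiles)
  conn$category <- bins$category

  res <- list()
  res$edge_ttest <- ttest2(conn$sim, nonconn$sim, "edge_ttest")
  res$cor_nos <- pearson_test(conn$sim, conn$nos_g, "cor_nos")
  res$cor_density <- pearson_test(conn$sim, conn$dens_g, "cor_density")

  grp <- split(conn$sim, conn$category)
  res$anova_distance <- anova1(grp, "anova_distance")
  res$ttest_short_mid <- ttest2(grp$short, grp$mid, "ttest_short_mid")
  res$ttest_short_long <- ttest2(grp$short, grp$long, "ttest_short_long")
  res$ttest_mid_long <- ttest2(grp$mid, grp$long, "ttest_mid_long")
  for (cat in c("short", "mid", "long")) {
    sub <- conn[conn$category == cat, ]
    res[[paste0("cor_", cat)]] <-
      pearson_test(sub$sim, sub$nos_g, paste0("cor_", cat))
  }

  nuis <- as.matrix(edges[, c("distance", "mean_volume", "mean_area")])
  sim_res <- residualize(edges$sim, nuis)
  res$resid_edge_ttest <- ttest2(sim_res[edges$connected],
                                 sim_res[!edges$connected],
                                 "resid_edge_ttest")
  nuis_c <- as.matrix(conn[, c("distance", "mean_volume", "mean_area")])
  res$resid_edge_cor <- pearson_test(residualize(conn$sim, nuis_c),
                                     residualize(conn$nos_g, nuis_c),
                                     "resid_edge_cor")

  for (h in c("LH", "RH", "LH-RH")) {
    sub <- edges[edges$hemi == h, ]
    tag <- gsub("-", "", h)
    res[[paste0("ttest_", tag)]] <-
      ttest2(sub$sim[sub$connected], sub$sim[!sub$connected],
             paste0("ttest_", tag))
    subc <- sub[sub$connected, ]
    res[[paste0("cor_", tag)]] <-
      pearson_test(subc$sim, subc$nos_g, paste0("cor_", tag))
  }

  res$cor_strength_nos <- pearson_test(nodal$mean_similarity,
                                       nodal$strength_nos, "cor_strength_nos")
  res$cor_strength_density <- pearson_test(nodal$mean_similarity,
                                           nodal$strength_density,
                                           "cor_strength_density")
  res$cor_degree <- pearson_test(nodal$mean_similarity,
                                 as.numeric(nodal$degree), "cor_degree")
  res$partial_strength <- partial_corr(nodal$mean_similarity,
                                       nodal$strength_nos,
                                       cbind(nodal$n_profiles),
                                       "partial_strength")
  res$partial_degree <- partial_corr(nodal$mean_similarity,
                                     as.numeric(nodal$degree),
                                     cbind(nodal$n_profiles), "partial_degree")
  res$resid_nodal_cor <- pearson_test(
    residualize(nodal$mean_similarity, cbind(nodal$mean_distance)),
    residualize(nodal$strength_nos, cbind(nodal$mean_distance)),
    "resid_nodal_cor")
  res$cor_betweenness <- pearson_test(nodal$mean_similarity,
                                      nodal$log_betweenness, "cor_betweenness")
  res$cor_clustering <- pearson_test(nodal$mean_similarity,
                                     nodal$clustering, "cor_clustering")
  res$cor_pathlength <- pearson_test(nodal$mean_similarity,
                                     nodal$path_length, "cor_pathlength")

  fit <- ols(nodal$mean_similarity,
             as.matrix(nodal[, c("strength_nos", "log_betweenness",
                                 "clustering", "path_length")]))
  ct <- tidy(fit)
  strength_row <- ct[ct$term == "strength_nos", ]
  res$regression_strength <- stat_row("regression_strength",
                                      strength_row$statistic,
                                      fit$fit$df.residual, strength_row$p,
                                      estimate = strength_row$estimate)

  battery <- bind_rows(res)
  battery <- battery[match(default_test_family(), battery$name), ]
  battery$family <- "main"
  fdr <- bh_fdr(battery$p, cfg$fdr_alpha)
  battery$q <- fdr$q
  battery$significant <- fdr$significant
  list(battery = battery, regression = fit)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Generates a synthetic stained section with known laminar structure,
#' samples point pairs, extracts and quality-controls laminar profiles,
#' builds the rank-gaussianized interregional similarity matrix, simulates a
#' multi-subject cohort whose connectivity is coupled to the (ground-truth)
#' profile similarity, forms group-consensus networks and nodal graph
#' metrics, and runs the declared 28-test statistical family with
#' Benjamini-Hochberg correction. Fully deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `cyto_report`: list with `config`, `counts`,
#'   `regional`, `similarity` (gaussianized), `network`, `nodal` (metrics +
#'   regional similarity), `edges` (edge-level scatter data), `battery`
#'   (28-row stat family with q-values), `regression` (the joint fit) and
#'   `version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "cyto_config"))
  cfg <- config
  truth <- make_truth_profiles(cfg$n_regions, cfg$n_blocks, seed = cfg$seed)
  geometry <- make_region_geometry(cfg$n_regions, seed = cfg$seed + 1L)
  section <- make_section(truth,
                          default_ribbon_geometry(cfg$section_size),
                          noise_sd = cfg$section_noise_sd,
                          seed = cfg$seed + 2L, n_blocks = cfg$n_blocks)
  pairs <- sample_point_pairs(section, cfg$n_pairs, seed = cfg$seed + 3L)
  profiles <- extract_profiles(section$image, pairs, section$label_map,
                               n_blocks = cfg$n_blocks)
  kept <- qc_filter(profiles, cfg$iqr_factor)
  exclusions <- attr(kept, "exclusions")
  regional <- regional_profiles(kept, cfg$min_count)
  sim_raw <- similarity_matrix(regional)
  sim_g <- gaussianize_similarity(sim_raw, cfg$transform_mean,
                                  cfg$transform_sd)

  true_sim <- cor(truth)
  dimnames(true_sim) <- list(seq_len(cfg$n_regions), seq_len(cfg$n_regions))
  spec <- cohort_spec(cfg$n_subjects, cfg$n_regions, cfg$coupling_beta,
                      cfg$base_density, cfg$noise_sd, cfg$w0, cfg$p_subject,
                      seed = cfg$seed + 4L)
  cohort <- make_cohort(spec, true_sim)
  dens_cohort <- lapply(cohort, streamline_density, geometry = geometry)
  net_nos <- group_network(cohort, cfg$consensus_threshold)
  net_dens <- group_network(dens_cohort, cfg$consensus_threshold)

  inc <- names(sim_g$included)[sim_g$included]
  sub_net <- function(net) {
    net$binary <- net$binary[inc, inc]
    net$weighted <- net$weighted[inc, inc]
    net$prevalence <- net$prevalence[inc, inc]
    net
  }
  net_nos_inc <- sub_net(net_nos)
  net_dens_inc <- sub_net(net_dens)

  edges <- edge_table(sim_g, net_nos_inc, net_dens_inc, geometry,
                      cfg$transform_mean, cfg$transform_sd)
  metrics <- nodal_metrics(net_nos_inc)
  dmat <- edge_distance(geometry)
  nodal <- regional_mean_similarity(sim_g) %>%
    left_join(metrics, by = "region") %>%
    left_join(nodal_strength_from_edges(edges, "nos_g") %>%
                rename(strength_nos = "strength"), by = "region") %>%
    left_join(nodal_strength_from_edges(edges, "dens_g") %>%
                rename(strength_density = "strength"), by = "region")
  nodal$strength_nos[is.na(nodal$strength_nos)] <- 0
  nodal$strength_density[is.na(nodal$strength_density)] <- 0
  nodal$mean_distance <- vapply(nodal$region, function(r) {
    others <- setdiff(as.integer(inc), r)
    mean(dmat[as.character(r), as.character(others)])
  }, numeric(1))

  bat <- run_battery(edges, nodal, cfg)

  counts <- list(
    n_pairs = nrow(pairs),
    n_profiles_extracted = nrow(profiles),
    n_excluded_distance = sum(exclusions$reason == "distance_outlier"),
    n_excluded_boundary = sum(exclusions$reason == "boundary_crossing"),
    n_profiles_included = nrow(kept),
    n_regions = cfg$n_regions,
    n_regions_included = length(inc),
    n_edges = sum(edges$connected),
    n_nonedges = sum(!edges$connected),
    n_family_tests = nrow(bat$battery)
  )
  message(sprintf(
    "pipeline: %d profiles -> %d after QC; %d/%d regions included; %d consensus edges; %d family tests",
    counts$n_profiles_extracted, counts$n_profiles_included,
    counts$n_regions_included, counts$n_regions, counts$n_edges,
    counts$n_family_tests))

  structure(
    list(config = unclass(cfg), counts = counts,
         regional = regional[, c("region", "n_profiles", "mean_thickness",
                                 "included")],
         similarity = sim_g, network = net_nos, edges = edges, nodal = nodal,
         battery = bat$battery, regression = bat$regression,
         version = as.character(utils::packageVersion("cytoconn"))),
    class = "cyto_report"
  )
}

#' @export
print.cyto_report <- function(x, ...) {
  cat(sprintf("<cyto_report> %d regions (%d included), %d subjects, %d family tests (%d significant at q < %g)\n",
              x$counts$n_regions, x$counts$n_regions_included,
              x$config$n_subjects, nrow(x$battery),
              sum(x$battery$significant), x$config$fdr_alpha))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the config echo, bookkeeping counts, regional table, battery and
#' node-level tables as a deterministic JSON document (fixed digits, stable
#' key order), so identical config + seed runs produce byte-identical files.
#'
#' @param report A `cyto_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cyto_report"))
  payload <- list(
    version = report$version,
    config = report$config,
    counts = report$counts,
    regional = report$regional,
    battery = report$battery,
    nodal = report$nodal,
    edges = report$edges[, c("region_i", "region_j", "sim", "connected",
                             "weight_nos", "distance", "hemi")]
  )
  json <- jsonlite::toJSON(payload, digits = 10, auto_unbox = TRUE,
                           na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Validate regional profiles against classical layer-table step profiles
#'
#' For each mapped region, correlates the regional mean laminar profile with
#' the step profile generated from the region's layer table; across regions,
#' also correlates profile means, profile SDs, and mean segment length
#' (thickness proxy) against the layer tables' total thickness.
#'
#' @param regional Tibble from [regional_profiles()].
#' @param ek_tables Named list of [ek_layer_table()] objects (names = region
#'   ids).
#' @param mapping Optional two-column data frame (`region`, `ek`) mapping
#'   profile regions to table names; defaults to matching region ids.
#' @param n_steps Steps in the generated step profiles.
#' @return List with `per_region` (tibble `region`, `ek`, `r`) and
#'   `agreement` (tibble with `property`, `r`): correlations of means, SDs
#'   and thickness across regions.
#' @export
validate_ek <- function(regional, ek_tables, mapping = NULL, n_steps = 1000L) {
  if (is.null(mapping)) {
    mapping <- tibble(region = regional$region,
                      ek = as.character(regional$region))
  }
  mapping <- mapping[mapping$ek %in% names(ek_tables), ]
  if (nrow(mapping) < 2L) abort("mapping must cover >= 2 regions.")
  rows <- list()
  for (i in seq_len(nrow(mapping))) {
    reg <- mapping$region[i]
    prof <- regional$mean_profile[[match(reg, regional$region)]]
    if (is.null(prof)) next
    ekp <- ek_profile(ek_tables[[mapping$ek[i]]], n_steps)
    if (sd(ekp) == 0 || sd(prof) == 0) {
      warn(sprintf("region %s skipped: degenerate profile.", reg))
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      region = reg, ek = mapping$ek[i],
      r = compare_profiles(prof, ekp),
      profile_mean = mean(prof), profile_sd = sd(prof),
      ek_mean = mean(ekp), ek_sd = sd(ekp),
      thickness = regional$mean_thickness[match(reg, regional$region)],
      ek_thickness = attr(ek_tables[[mapping$ek[i]]], "total_thickness")
    )
  }
  per_region <- bind_rows(rows)
  safe_cor <- function(a, b) {
    if (any(!is.finite(a)) || any(!is.finite(b)) ||
        sd(a) == 0 || sd(b) == 0) {
      return(NA_real_)  # e.g. uniform-thickness synthetic ribbons
    }
    cor(a, b)
  }
  agreement <- tibble(
    property = c("mean", "sd", "thickness"),
    r = c(safe_cor(per_region$profile_mean, per_region$ek_mean),
          safe_cor(per_region$profile_sd, per_region$ek_sd),
          safe_cor(per_region$thickness, per_region$ek_thickness))
  )
  list(per_region = per_region, agreement = agreement)
}

#' Planted-effect recovery across replicate cohorts
#'
#' Runs the cohort-level portion of the pipeline many times: per replicate,
#' fresh ground-truth laminar profiles are generated, their raw Pearson
#' similarity drives the cohort generator, the group-consensus network is
#' formed, and two statistics are computed on the rank-gaussianized
#' similarity — the connected-versus-nonconnected two-sample t test and the
#' regional-similarity versus nodal-strength correlation — with
#' Benjamini-Hochberg correction across the two-test replicate family. Used
#' to verify that a planted similarity-connectivity coupling is recovered
#' and that the null (zero coupling) is calibrated.
#'
#' @param n_replicates Number of replicate cohorts.
#' @param coupling_beta Planted effect size (see [cohort_spec()]).
#' @param n_regions,n_subjects Cohort dimensions.
#' @param base_density,noise_sd,w0,p_subject Generator settings.
#' @param seed Master seed; replicate r uses `seed + r` offsets.
#' @return Tibble with one row per replicate: `t`, `p_t`, `q_t`,
#'   `r_strength`, `p_r`, `n_edges`.
#' @export
planted_recovery <- function(n_replicates, coupling_beta, n_regions = 60L,
                             n_subjects = 30L, base_density = 0.15,
                             noise_sd = 3, w0 = 10, p_subject = 0.8,
                             seed = 1L) {
  one <- function(r) {
    truth <- make_truth_profiles(n_regions, seed = seed + 2L * r)
    sim_raw <- cor(truth)
    dimnames(sim_raw) <- list(seq_len(n_regions), seq_len(n_regions))
    spec <- cohort_spec(n_subjects, n_regions, coupling_beta, base_density,
                        noise_sd, w0, p_subject, seed = seed + 2L * r + 1L)
    net <- group_network(make_cohort(spec, sim_raw))
    edges <- tidy(net)
    ut <- upper.tri(sim_raw)
    sim_g <- rank_gaussianize(sim_raw[ut])
    conn <- edges$connected
    tt <- ttest2(sim_g[conn], sim_g[!conn], "edge_ttest")
    # nodal strength on gaussianized consensus-edge weights
    w_g <- rep(NA_real_, nrow(edges))
    w_g[conn] <- rank_gaussianize(edges$weight[conn])
    strength <- vapply(seq_len(n_regions), function(v) {
      sum(w_g[conn & (edges$region_i == v | edges$region_j == v)])
    }, numeric(1))
    simmat_g <- sim_raw
    simmat_g[ut] <- sim_g
    simmat_g[lower.tri(simmat_g)] <- t(simmat_g)[lower.tri(simmat_g)]
    diag(simmat_g) <- NA
    mean_sim <- rowMeans(simmat_g, na.rm = TRUE)
    ct <- pearson_test(mean_sim, strength, "cor_strength")
    q <- p.adjust(c(tt$p, ct$p), method = "BH")
    tibble(t = tt$statistic, p_t = tt$p, q_t = q[1],
           r_strength = ct$estimate, p_r = ct$p, n_edges = sum(conn))
  }
  bind_rows(lapply(seq_len(n_replicates), one))
}
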