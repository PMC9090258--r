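DEFAULT_TARGETS <- c("CD68", "CD11c", "CD163", "CD11c_CD68", "CD11c_CD163",
                     "CD68_CD163", "CD11c_CD68_CD163")

#' Region-stratified dyad table (cross-type G AUCs)
#'
#' For every analysed region class and every reference -> target phenotype
#' pair, computes the empirical cross-type G-function on cells of that
#' region, its AUC at `r_cut` and the dichotomized interaction score.
#' Ambiguous cells and unassigned cells never enter.
#'
#' @param cells classified cell table with `region_class`, `phenotype`.
#' @param reference reference phenotype (default `"CD3"`, the T cell).
#' @param targets target phenotypes.
#' @param split_pstat3 if `TRUE`, each target is split into p-STAT3+ and
#'   p-STAT3- sub-populations.
#' @param r_max,r_step radius grid (um).
#' @param r_cut AUC cut-off (um).
#' @return data.frame: one row per region x target (x p-STAT3 stratum)
#'   with `n_ref`, `n_target`, `lambda_y`, `auc_15`, `auc_pct`, `score`.
#' @export
dyad_table <- function(cells, reference = "CD3", targets = DEFAULT_TARGETS,
                       split_pstat3 = FALSE, r_max = 50, r_step = 0.5,
                       r_cut = 15) {
  check_cell_table(cells, c("x_um", "y_um", "region_class", "phenotype"))
  cells <- cells[cells$phenotype != "ambiguous" &
                   !cells$region_class %in% c("unassigned", "excluded"), ]
  grid <- seq(0, r_max, by = r_step)
  rows <- list()
  for (rc in unique(cells$region_class)) {
    inreg <- cells[cells$region_class == rc, ]
    ref <- inreg[inreg$phenotype == reference, ]
    win <- tryCatch(observation_window(inreg), error = function(e) NULL)
    strata <- if (split_pstat3) c(FALSE, TRUE) else NA
    for (tg in targets) for (ps in strata) {
      tgt <- inreg[inreg$phenotype == tg, ]
      label <- tg
      if (!is.na(ps)) {
        tgt <- tgt[tgt$pstat3 == ps, ]
        label <- paste0(tg, if (ps) "_pSTAT3pos" else "_pSTAT3neg")
      }
      cur <- empirical_cross_g(ref, tgt, r_grid = grid, window = win)
      a <- g_auc(cur, r_cut = r_cut)
      rows[[length(rows) + 1L]] <- data.frame(
        region_class = rc, reference = reference, target = label,
        n_ref = nrow(ref), n_target = nrow(tgt),
        lambda_y = cur$lambda_y, auc_15 = a$auc, auc_pct = a$auc_pct,
        score = a$interaction_score, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(region_class = character(0), reference = character(0),
                      target = character(0), n_ref = integer(0),
                      n_target = integer(0), lambda_y = numeric(0),
                      auc_15 = numeric(0), auc_pct = numeric(0),
                      score = logical(0)))
  do.call(rbind, rows)
}

#' Region-stratified cluster table (cross pair counts)
#'
#' For every analysed region class and target phenotype, computes
#' radius-bounded cross pair counts around the reference cells and the
#' derived single-type cluster frequency (>= 2 partners within the
#' radius). The cluster criterion is recorded in the output.
#'
#' @inheritParams dyad_table
#' @param radius neighbourhood radius in um.
#' @return data.frame: one row per region x target with `n_ref`,
#'   `n_target`, `mean_count`, `cluster_freq`, `criterion`.
#' @export
cluster_table <- function(cells, reference = "CD3",
                          targets = DEFAULT_TARGETS, radius = 15) {
  check_cell_table(cells, c("x_um", "y_um", "region_class", "phenotype"))
  cells <- cells[cells$phenotype != "ambiguous" &
                   !cells$region_class %in% c("unassigned", "excluded"), ]
  rows <- list()
  for (rc in unique(cells$region_class)) {
    inreg <- cells[cells$region_class == rc, ]
    ref <- inreg[inreg$phenotype == reference, ]
    for (tg in targets) {
      tgt <- inreg[inreg$phenotype == tg, ]
      pc <- cross_pair_counts(ref, tgt, radius = radius)
      cf <- cluster_frequency(pc)
      rows[[length(rows) + 1L]] <- data.frame(
        region_class = rc, reference = reference, target = tg,
        n_ref = nrow(ref), n_target = nrow(tgt),
        mean_count = if (nrow(ref)) mean(pc$counts) else NA_real_,
        cluster_freq = cf$frequency, criterion = cf$criterion,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(region_class = character(0), reference = character(0),
                      target = character(0), n_ref = integer(0),
                      n_target = integer(0), mean_count = numeric(0),
                      cluster_freq = numeric(0), criterion = character(0)))
  do.call(rbind, rows)
}

#' Run the full single-specimen pipeline
#'
#' Executes gate -> region assignment -> composition -> dyads -> clusters
#' on one specimen and returns all tables plus a run manifest. The input
#' is either a simulation config (the specimen is generated) or a cell
#' table plus region annotations.
#'
#' @param input a [simulation_config()] or a cell table with marker
#'   measurement columns.
#' @param regions list of [region_annotation]; required when `input` is a
#'   cell table.
#' @param gates named list of [marker_gate()].
#' @param radius_um dyad/cluster radius (um).
#' @param r_max_um maximum G-function radius (um).
#' @param split_pstat3 split dyad targets by p-STAT3 status.
#' @param out_dir optional directory; when given, all tables, regions and
#'   the manifest are written there.
#' @return Object of class `interactome_result`: `cells`, `regions`,
#'   `composition`, `dyads`, `clusters`, `manifest`, `log`.
#' @export
run_pipeline <- function(input, regions = NULL, gates = default_gates(),
                         radius_um = 15, r_max_um = 50,
                         split_pstat3 = FALSE, out_dir = NULL) {
  seed <- NULL
  if (inherits(input, "sim_config")) {
    spec <- simulate_specimen(input)
    cells <- spec$cells; regions <- spec$regions
    gates <- input$gates
    seed <- input$seed
  } else {
    cells <- input
    stop_if(!is.data.frame(cells) || nrow(cells) == 0,
            "empty or invalid cell table")
    stop_if(is.null(regions), "regions required with a cell table input")
  }
  log <- c(sprintf("input: %d cells, %d regions", nrow(cells),
                   length(regions)))
  cells <- classify_cells(cells, gates)
  log <- c(log, sprintf("gated: %d ambiguous excluded",
                        sum(cells$phenotype == "ambiguous")))
  if (!"region_id" %in% names(cells))
    cells <- assign_regions(cells, regions)
  n_un <- sum(cells$region_id == "unassigned")
  log <- c(log, sprintf("region assignment: %d unassigned excluded", n_un))
  composition <- composition_summary(cells, regions)
  dyads <- dyad_table(cells, r_max = r_max_um, r_cut = radius_um,
                      split_pstat3 = split_pstat3)
  clusters <- cluster_table(cells, radius = radius_um)
  manifest <- list(
    package = "immunospat",
    version = as.character(utils::packageVersion("immunospat")),
    seed = seed,
    gates = lapply(gates, function(g)
      list(intensity = g$intensity_threshold,
           coverage = g$coverage_threshold)),
    radius_um = radius_um, r_max_um = r_max_um,
    cluster_criterion = ">=2 single-type / >=1+>=1 mixed within radius")
  res <- structure(list(cells = cells, regions = regions,
                        composition = composition, dyads = dyads,
                        clusters = clusters, manifest = manifest,
                        log = log),
                   class = "interactome_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cells_csv(cells, file.path(out_dir, "cells_classified.csv"))
    utils::write.csv(composition, file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
    utils::write.csv(dyads, file.path(out_dir, "dyads.csv"),
                     row.names = FALSE)
    utils::write.csv(clusters, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
    write_regions_geojson(regions, file.path(out_dir, "regions.geojson"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  }
  res
}

#' @export
print.interactome_result <- function(x, ...) {
  cat("Spatial immune interactome result\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat(sprintf("  composition rows: %d; dyad rows: %d; cluster rows: %d\n",
              nrow(x$composition), nrow(x$dyads), nrow(x$clusters)))
  pos <- x$dyads[x$dyads$score, ]
  if (nrow(pos) > 0) {
    cat("  positive dyad scores:\n")
    for (i in seq_len(nrow(pos)))
      cat(sprintf("    %s: %s -> %s (AUC %.2f um)\n", pos$region_class[i],
                  pos$reference[i], pos$target[i], pos$auc_15[i]))
  }
  invisible(x)
}

#' Compare two cohorts metric by metric
#'
#' Inferential layer over tidy per-specimen metrics: for every
#' region x metric present in both cohorts, an exact Wilcoxon rank-sum
#' test, with Benjamini-Hochberg adjustment applied within each
#' (metric-family x region) stratum (the `family` column, e.g. dyad AUCs
#' vs composition percentages, each stratified by region).
#'
#' @param tidy data.frame with columns `specimen`, `cohort` (two levels),
#'   `region`, `family`, `metric`, `value`.
#' @return data.frame with per-comparison group means, `p` and `p_adj`.
#' @export
compare_cohorts <- function(tidy) {
  need <- c("specimen", "cohort", "region", "family", "metric", "value")
  stop_if(!all(need %in% names(tidy)), "tidy table needs columns: ",
          paste(need, collapse = ", "))
  lev <- unique(tidy$cohort)
  stop_if(length(lev) != 2, "need exactly two cohorts")
  combos <- unique(tidy[c("region", "family", "metric")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- tidy$region == combos$region[i] &
      tidy$family == combos$family[i] & tidy$metric == combos$metric[i]
    a <- tidy$value[sel & tidy$cohort == lev[1]]
    b <- tidy$value[sel & tidy$cohort == lev[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0 || length(b) == 0)
      return(cbind(combos[i, ], mean_a = NA_real_, mean_b = NA_real_,
                   n_a = length(a), n_b = length(b), p = NA_real_))
    wt <- wilcoxon_exact(a, b)
    cbind(combos[i, ], mean_a = mean(a), mean_b = mean(b),
          n_a = length(a), n_b = length(b), p = wt$p.value)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$p_adj <- NA_real_
  for (s in unique(paste(out$family, out$region))) {
    idx <- paste(out$family, out$region) == s & !is.na(out$p)
    if (any(idx)) out$p_adj[idx] <- bh_fdr(out$p[idx])
  }
  names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
  attr(out, "cohorts") <- lev
  out
}

#' Synthetic two-cohort experiment
#'
#' Regenerates the study's analysis pattern on synthetic cohorts: `n_each`
#' specimens are generated per cohort (seeds derived from `seed`), the
#' single-specimen pipeline runs on each, and per-specimen dyad AUCs and
#' cluster frequencies are compared between cohorts with
#' [compare_cohorts()].
#'
#' @param config_a,config_b [simulation_config()] for the two cohorts
#'   (their `seed` fields are overridden per specimen).
#' @param n_each specimens per cohort.
#' @param seed base seed.
#' @param targets dyad/cluster target phenotypes to analyse.
#' @return List of class `cohort_experiment`: `metrics` (tidy
#'   per-specimen table) and `comparison` (from [compare_cohorts()]).
#' @export
cohort_experiment <- function(config_a, config_b, n_each = 10, seed = 1,
                              targets = c("CD68", "CD163")) {
  specimen_metrics <- function(config, cohort, i) {
    cfg <- config
    cfg$seed <- as.integer(seed + 7919 * (i + ifelse(cohort == "B",
                                                     n_each, 0)))
    res <- run_pipeline(cfg)
    dy <- res$dyads[res$dyads$target %in% targets, ]
    cl <- res$clusters[res$clusters$target %in% targets, ]
    rbind(
      data.frame(specimen = paste0(cohort, i), cohort = cohort,
                 region = dy$region_class, family = "dyad_auc",
                 metric = paste(dy$reference, dy$target, sep = "->"),
                 value = dy$auc_15, stringsAsFactors = FALSE),
      data.frame(specimen = paste0(cohort, i), cohort = cohort,
                 region = cl$region_class, family = "cluster_freq",
                 metric = paste(cl$reference, cl$target, sep = "->"),
                 value = cl$cluster_freq, stringsAsFactors = FALSE))
  }
  rows <- list()
  for (i in seq_len(n_each)) {
    rows[[length(rows) + 1L]] <- specimen_metrics(config_a, "A", i)
    rows[[length(rows) + 1L]] <- specimen_metrics(config_b, "B", i)
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics,
                 comparison = compare_cohorts(metrics)),
            class = "cohort_experiment")
}

#' @export
print.cohort_experiment <- function(x, ...) {
  cat("Two-cohort synthetic experiment\n")
  cmp <- x$comparison
  sig <- !is.na(cmp$p_adj) & cmp$p_adj < 0.05
  cat(sprintf("  %d comparisons, %d significant (adjusted p < 0.05)\n",
              nrow(cmp), sum(sig)))
  if (any(sig)) print(cmp[sig, c("region", "family", "metric", "p", "p_adj")])
  invisible(x)
}
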