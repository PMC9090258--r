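#' Simulation configuration for a synthetic specimen
#'
#' Bundles everything needed to generate one synthetic tissue wedge:
#' window geometry, per-region per-phenotype base intensities (homogeneous
#' Poisson, cells/um^2), cross-type attraction entries (parent-offspring
#' planting that creates ground-truth dyads/clusters), density-gradient
#' entries, per-phenotype nuclear p-STAT3 fractions, marker gates and the
#' intensity noise level. A seed is mandatory: identical config + seed give
#' bitwise-identical output.
#'
#' @param window_width,window_height window in um.
#' @param band_fractions proportions of the edge/tumor/necrosis bands.
#' @param densities named list, one element per region class
#'   (`edge`, `tumor`, `necrosis`), each a named numeric vector of
#'   intensities (cells/um^2) per phenotype.
#' @param attractions list of [attraction_entry()] objects.
#' @param gradients list of [gradient_entry()] objects.
#' @param pstat3_fraction named numeric in \[0, 1\] per phenotype: the
#'   probability a generated cell of that phenotype is p-STAT3 positive.
#' @param gates named list of [marker_gate()] objects (one per marker,
#'   including `pSTAT3`).
#' @param noise_sd relative intensity/coverage noise scale (0 = noiseless).
#' @param seed integer RNG seed (required).
#' @return Object of class `sim_config`.
#' @export
simulation_config <- function(window_width = 900, window_height = 600,
                              band_fractions = c(1, 1, 1) / 3,
                              densities = default_densities(),
                              attractions = list(),
                              gradients = list(),
                              pstat3_fraction = default_pstat3_fraction(),
                              gates = default_gates(),
                              noise_sd = 0,
                              seed) {
  stop_if(missing(seed), "`seed` is required")
  stop_if(window_width <= 0 || window_height <= 0,
          "window dimensions must be positive")
  densities <- lapply(densities, unlist)     # accept nested-list configs
  pstat3_fraction <- unlist(pstat3_fraction)
  for (reg in names(densities)) {
    lam <- densities[[reg]]
    stop_if(any(lam < 0) || any(!is.finite(lam)),
            "densities must be finite and >= 0")
    bad <- setdiff(names(lam), PHENOTYPES)
    stop_if(length(bad) > 0, "unknown phenotype in densities: ",
            paste(bad, collapse = ", "))
  }
  stop_if(any(pstat3_fraction < 0 | pstat3_fraction > 1),
          "pstat3_fraction values must lie in [0, 1]")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  for (a in attractions)
    stop_if(!inherits(a, "attraction_entry"), "invalid attraction entry")
  for (g in gradients)
    stop_if(!inherits(g, "gradient_entry"), "invalid gradient entry")
  structure(list(window_width = window_width, window_height = window_height,
                 band_fractions = band_fractions, densities = densities,
                 attractions = attractions, gradients = gradients,
                 pstat3_fraction = pstat3_fraction, gates = gates,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Cross-type attraction entry
#'
#' Describes planted attraction: each parent cell of the reference
#' phenotype inside the stated region class receives `k` offspring of the
#' target phenotype, placed uniformly in a disc of `radius` um around it
#' (clipped to the region). `k` is either fixed or Poisson-distributed.
#'
#' @param reference,target phenotype labels.
#' @param region_class region class the planting applies to.
#' @param k offspring per parent: fixed count if `k_type = "fixed"`,
#'   Poisson mean if `k_type = "poisson"`.
#' @param k_type `"poisson"` (default) or `"fixed"`.
#' @param radius offspring disc radius in um (> 0).
#' @export
attraction_entry <- function(reference, target, region_class,
                             k = 1, k_type = c("poisson", "fixed"),
                             radius = 10) {
  k_type <- match.arg(k_type)
  stop_if(radius <= 0, "offspring radius must be > 0")
  stop_if(k < 0, "offspring number must be >= 0")
  stop_if(!reference %in% PHENOTYPES || !target %in% PHENOTYPES,
          "unknown phenotype label")
  structure(list(reference = reference, target = target,
                 region_class = region_class, k = k, k_type = k_type,
                 radius = radius),
            class = "attraction_entry")
}

#' Density-gradient entry
#'
#' An inhomogeneous Poisson component whose intensity decays exponentially
#' with distance from the region border facing the tumor:
#' lambda(d) = lambda_far + (lambda_near - lambda_far) * exp(-d / decay).
#'
#' @param phenotype phenotype label.
#' @param region_class region class the gradient lives in.
#' @param lambda_near intensity at the tumor-facing border (cells/um^2).
#' @param lambda_far asymptotic intensity far from the border.
#' @param decay_length e-folding length in um.
#' @param from which side of the region's bounding box faces the tumor:
#'   `"xmin"`, `"xmax"`, `"ymin"` or `"ymax"`.
#' @export
gradient_entry <- function(phenotype, region_class, lambda_near, lambda_far,
                           decay_length, from = "xmax") {
  stop_if(lambda_near < lambda_far || lambda_far < 0,
          "need lambda_near >= lambda_far >= 0")
  stop_if(decay_length <= 0, "decay_length must be > 0")
  from <- match.arg(from, c("xmin", "xmax", "ymin", "ymax"))
  structure(list(phenotype = phenotype, region_class = region_class,
                 lambda_near = lambda_near, lambda_far = lambda_far,
                 decay_length = decay_length, from = from),
            class = "gradient_entry")
}

# Default per-region densities (cells/um^2). The source study publishes no
# numeric densities; these are chosen once to qualitatively mirror its
# composition pattern: macrophage (CD163) dominance overall, monocyte
# (CD68) enrichment within tumor, sparse necrosis, and rarer multi-marker
# phenotypes. See the methods vignette.
#' @rdname simulation_config
#' @export
default_densities <- function() {
  list(
    edge = c(CD3 = 6e-4, CD68 = 4e-4, CD11c = 2e-4, CD163 = 9e-4,
             CD11c_CD68 = 1.2e-4, CD11c_CD163 = 8e-5, CD68_CD163 = 8e-5,
             CD11c_CD68_CD163 = 5e-5, negative = 2e-3),
    tumor = c(CD3 = 6e-4, CD68 = 8e-4, CD11c = 2.5e-4, CD163 = 7e-4,
              CD11c_CD68 = 1e-4, CD11c_CD163 = 8e-5, CD68_CD163 = 8e-5,
              CD11c_CD68_CD163 = 6e-5, negative = 2.5e-3),
    necrosis = c(CD3 = 1.2e-4, CD68 = 1.5e-4, CD11c = 5e-5, CD163 = 3e-4,
                 CD11c_CD68 = 2e-5, CD11c_CD163 = 2e-5, CD68_CD163 = 2e-5,
                 CD11c_CD68_CD163 = 1e-5, negative = 8e-4))
}

#' @rdname simulation_config
#' @export
default_pstat3_fraction <- function() {
  c(CD3 = 0.25, CD68 = 0.3, CD11c = 0.25, CD163 = 0.35,
    CD11c_CD68 = 0.3, CD11c_CD163 = 0.3, CD68_CD163 = 0.3,
    CD11c_CD68_CD163 = 0.3, negative = 0.1)
}

# Uniform points inside a polygon, by rejection from the bounding box.
#' @noRd
runif_in_polygon <- function(n, polygon) {
  out <- matrix(NA_real_, 0, 2)
  if (n == 0L) return(out)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  need <- n
  while (need > 0) {
    m <- max(16L, ceiling(need * 1.6))
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, polygon)
    got <- cbind(px[keep], py[keep])
    if (nrow(got) > need) got <- got[seq_len(need), , drop = FALSE]
    out <- rbind(out, got)
    need <- n - nrow(out)
  }
  out
}

#' @noRd
new_cell_rows <- function(n, x, y, region_id, region_class, phenotype,
                          pstat3, interaction_id = NA_character_,
                          id_start = 1L) {
  data.frame(cell_id = sprintf("c%06d", seq.int(id_start, length.out = n)),
             x_um = x, y_um = y,
             region_id = region_id, region_class = region_class,
             phenotype_truth = phenotype, pstat3_truth = pstat3,
             interaction_id = interaction_id,
             stringsAsFactors = FALSE)
}

#' Simulate the homogeneous baseline point pattern
#'
#' For every region x phenotype with intensity lambda, draws
#' `N ~ Poisson(lambda * area)` cells uniformly in the region polygon
#' (complete spatial randomness within each region).
#'
#' @param regions list of [region_annotation].
#' @param config a [simulation_config()].
#' @return Cell table (data.frame) with truth columns `phenotype_truth`,
#'   `pstat3_truth`, `interaction_id`.
#' @export
simulate_cells <- function(regions, config) {
  stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  with_seed(config$seed, {
    rows <- list()
    next_id <- 1L
    for (r in regions) {
      lam <- config$densities[[r$region_class]]
      if (is.null(lam)) next
      area <- abs(polygon_area(r$polygon))
      for (ph in names(lam)) {
        if (lam[[ph]] <= 0) next
        n <- stats::rpois(1, lam[[ph]] * area)
        if (n == 0) next
        xy <- runif_in_polygon(n, r$polygon)
        pfrac <- config$pstat3_fraction[[ph]] %||% 0
        rows[[length(rows) + 1L]] <- new_cell_rows(
          n, xy[, 1], xy[, 2], r$region_id, r$region_class, ph,
          stats::runif(n) < pfrac, id_start = next_id)
        next_id <- next_id + n
      }
    }
    if (length(rows) == 0) return(empty_cell_table())
    do.call(rbind, rows)
  })
}

#' @noRd
empty_cell_table <- function() {
  new_cell_rows(0, numeric(0), numeric(0), character(0), character(0),
                character(0), logical(0), character(0))
}

#' Plant cross-type attraction (parent-offspring dyads/clusters)
#'
#' Every cell of the reference phenotype in the entry's region class
#' becomes a parent; `k` offspring of the target phenotype are placed
#' uniformly in a disc of the stated radius around it, clipped to the
#' parent's region. Offspring carry the parent's `cell_id` in
#' `interaction_id` as ground truth.
#'
#' @param cells cell table.
#' @param regions list of [region_annotation] (for clipping).
#' @param entry an [attraction_entry()].
#' @param seed RNG seed.
#' @param pstat3_fraction probability an offspring is p-STAT3 positive.
#' @return Cell table with offspring rows appended. If no parent exists the
#'   input is returned unchanged with a warning.
#' @export
plant_interactions <- function(cells, regions, entry, seed,
                               pstat3_fraction = 0) {
  stop_if(!inherits(entry, "attraction_entry"), "invalid attraction entry")
  check_cell_table(cells, c("cell_id", "x_um", "y_um", "region_id",
                            "phenotype_truth"))
  parents <- which(cells$phenotype_truth == entry$reference &
                     cells$region_class == entry$region_class)
  if (length(parents) == 0) {
    warning("no '", entry$reference, "' parents in region class '",
            entry$region_class, "'; table returned unchanged")
    return(cells)
  }
  polys <- stats::setNames(lapply(regions, `[[`, "polygon"),
                           vapply(regions, `[[`, "", "region_id"))
  with_seed(seed, {
    ks <- switch(entry$k_type,
                 fixed = rep(as.integer(round(entry$k)), length(parents)),
                 poisson = stats::rpois(length(parents), entry$k))
    total <- sum(ks)
    if (total == 0) return(cells)
    off <- vector("list", length(parents))
    for (i in seq_along(parents)) {
      if (ks[i] == 0) next
      p <- parents[i]
      poly <- polys[[cells$region_id[p]]]
      ox <- numeric(ks[i]); oy <- numeric(ks[i])
      for (j in seq_len(ks[i])) {
        ok <- FALSE
        for (try in 1:100) {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- entry$radius * sqrt(stats::runif(1))
          cand <- c(cells$x_um[p] + rad * cos(ang),
                    cells$y_um[p] + rad * sin(ang))
          if (is.null(poly) ||
              point_in_polygon(cand[1], cand[2], poly)) {
            ox[j] <- cand[1]; oy[j] <- cand[2]; ok <- TRUE; break
          }
        }
        # parent location is always in-region and within any radius
        if (!ok) { ox[j] <- cells$x_um[p]; oy[j] <- cells$y_um[p] }
      }
      off[[i]] <- new_cell_rows(ks[i], ox, oy, cells$region_id[p],
                                cells$region_class[p], entry$target,
                                stats::runif(ks[i]) < pstat3_fraction,
                                interaction_id = cells$cell_id[p])
    }
    off <- do.call(rbind, off)
    off$cell_id <- sprintf("p%06d", seq_len(nrow(off)) + nrow(cells))
    rbind(cells, off)
  })
}

#' Simulate a decaying density gradient
#'
#' Inhomogeneous Poisson draw inside one region with intensity
#' `lambda(d) = lambda_far + (lambda_near - lambda_far) * exp(-d / decay)`,
#' where `d` is distance from the region border facing the tumor.
#' Generated by thinning a homogeneous draw at `lambda_near`.
#'
#' @param region a [region_annotation].
#' @param entry a [gradient_entry()].
#' @param seed RNG seed.
#' @param pstat3_fraction probability a generated cell is p-STAT3 positive.
#' @return Cell table of the gradient component (may be empty).
#' @export
simulate_gradient <- function(region, entry, seed, pstat3_fraction = 0) {
  stop_if(!inherits(entry, "gradient_entry"), "invalid gradient entry")
  if (entry$lambda_near == 0) return(empty_cell_table())
  with_seed(seed, {
    poly <- region$polygon
    area <- abs(polygon_area(poly))
    n <- stats::rpois(1, entry$lambda_near * area)
    if (n == 0) return(empty_cell_table())
    xy <- runif_in_polygon(n, poly)
    d <- switch(entry$from,
                xmin = xy[, 1] - min(poly[, 1]),
                xmax = max(poly[, 1]) - xy[, 1],
                ymin = xy[, 2] - min(poly[, 2]),
                ymax = max(poly[, 2]) - xy[, 2])
    lam <- entry$lambda_far + (entry$lambda_near - entry$lambda_far) *
      exp(-d / entry$decay_length)
    keep <- stats::runif(n) < lam / entry$lambda_near
    m <- sum(keep)
    new_cell_rows(m, xy[keep, 1], xy[keep, 2], region$region_id,
                  region$region_class, entry$phenotype,
                  stats::runif(m) < pstat3_fraction)
  })
}

#' Simulate marker intensities and coverages from phenotype truth
#'
#' Gives each cell per-marker (intensity, percent-coverage) measurements
#' consistent with its true phenotype under the supplied gates: markers in
#' the phenotype draw from a truncated Gaussian kept above both gate
#' thresholds (so a true positive never falls below gate), markers outside
#' it draw from a low-signal Gaussian below the thresholds in expectation
#' (so false positives can occur under noise). At `noise_sd = 0` re-gating
#' reproduces the generating phenotype exactly.
#'
#' @param cells cell table with `phenotype_truth` and `pstat3_truth`.
#' @param gates named list of [marker_gate()] including `pSTAT3`.
#' @param noise_sd relative noise scale (>= 0).
#' @param seed RNG seed.
#' @return `cells` with `<marker>_intensity` and `<marker>_coverage`
#'   columns appended.
#' @export
simulate_intensities <- function(cells, gates, noise_sd, seed) {
  check_cell_table(cells, c("phenotype_truth", "pstat3_truth"))
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  bad <- setdiff(unique(cells$phenotype_truth), PHENOTYPES)
  stop_if(length(bad) > 0, "unknown phenotype label: ",
          paste(bad, collapse = ", "))
  n <- nrow(cells)
  pos_by_marker <- lapply(MARKERS, function(m)
    vapply(cells$phenotype_truth, function(ph) m %in% phenotype_markers(ph),
           logical(1), USE.NAMES = FALSE))
  names(pos_by_marker) <- MARKERS
  pos_by_marker$pSTAT3 <- as.logical(cells$pstat3_truth)
  with_seed(seed, {
    for (m in names(pos_by_marker)) {
      g <- gates[[m]]
      stop_if(is.null(g), "no gate supplied for marker ", m)
      pos <- pos_by_marker[[m]]
      it <- g$intensity_threshold; ct <- g$coverage_threshold
      intens <- numeric(n); cover <- numeric(n)
      np <- sum(pos); nn <- n - np
      intens[pos] <- rtruncnorm(np, mean = 2 * it, sd = noise_sd * it,
                                a = it)
      intens[!pos] <- rtruncnorm(nn, mean = 0.25 * it, sd = noise_sd * it,
                                 a = 0)
      cover[pos] <- rtruncnorm(np, mean = (ct + 1) / 2,
                               sd = noise_sd * (1 - ct) / 2, a = ct, b = 1)
      cover[!pos] <- rtruncnorm(nn, mean = 0.5 * ct, sd = noise_sd * ct,
                                a = 0, b = 1)
      cells[[paste0(m, "_intensity")]] <- intens
      cells[[paste0(m, "_coverage")]] <- cover
    }
    cells
  })
}

#' Simulate one complete synthetic specimen
#'
#' Runs the whole generator: wedge regions, homogeneous baseline pattern,
#' planted attractions, gradients, and marker intensities.
#'
#' @param config a [simulation_config()].
#' @return List with elements `cells`, `regions`, `config`.
#' @export
simulate_specimen <- function(config) {
  stop_if(!inherits(config, "sim_config"), "config must be a sim_config")
  regions <- generate_regions(config$window_width, config$window_height,
                              config$band_fractions)
  cells <- simulate_cells(regions, config)
  i <- 0L
  for (a in config$attractions) {
    i <- i + 1L
    pf <- config$pstat3_fraction[[a$target]] %||% 0
    cells <- plant_interactions(cells, regions, a, seed = config$seed + i,
                                pstat3_fraction = pf)
  }
  for (g in config$gradients) {
    i <- i + 1L
    reg <- Filter(function(r) r$region_class == g$region_class, regions)
    for (r in reg) {
      pf <- config$pstat3_fraction[[g$phenotype]] %||% 0
      extra <- simulate_gradient(r, g, seed = config$seed + i,
                                 pstat3_fraction = pf)
      if (nrow(extra) > 0) {
        extra$cell_id <- sprintf("g%06d", nrow(cells) + seq_len(nrow(extra)))
        cells <- rbind(cells, extra)
      }
    }
  }
  cells <- simulate_intensities(cells, config$gates, config$noise_sd,
                                seed = config$seed + i + 1L)
  list(cells = cells, regions = regions, config = config)
}

#' Read/write cell tables as CSV
#'
#' Plain CSV with one row per cell; all columns preserved.
#' @param cells cell table.
#' @param file path.
#' @export
write_cells_csv <- function(cells, file) {
  utils::write.csv(cells, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}
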