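#' Immune phenotype taxonomy
#'
#' The taxonomy covers the four lineage markers and their myeloid
#' combinations: `CD3` (T cell), `CD68` (monocyte-derived), `CD11c` (APC),
#' `CD163` (macrophage), the double positives `CD11c_CD68` (putative
#' microglia), `CD11c_CD163`, `CD68_CD163`, the triple positive
#' `CD11c_CD68_CD163`, plus `ambiguous` (CD3 co-occurring with a myeloid
#' marker — excluded from downstream statistics) and `negative` (no marker).
#' Nuclear p-STAT3 is carried as a binary modifier on every phenotype.
#'
#' @format Character vectors.
#' @name phenotypes
NULL

#' @rdname phenotypes
#' @export
MARKERS <- c("CD3", "CD68", "CD11c", "CD163")

# canonical marker order inside combination labels
MYELOID <- c("CD11c", "CD68", "CD163")

#' @rdname phenotypes
#' @export
PHENOTYPES <- c("CD3", "CD68", "CD11c", "CD163",
                "CD11c_CD68", "CD11c_CD163", "CD68_CD163",
                "CD11c_CD68_CD163", "ambiguous", "negative")

# markers implied positive by a phenotype label
#' @noRd
phenotype_markers <- function(phenotype) {
  stop_if(!phenotype %in% PHENOTYPES, "unknown phenotype: ", phenotype)
  if (phenotype %in% c("negative", "ambiguous")) return(character(0))
  strsplit(phenotype, "_", fixed = TRUE)[[1]]
}

#' Dual-threshold marker gate
#'
#' A cell is positive for a marker when both its mean signal intensity and
#' its percent coverage reach the marker's thresholds (inclusive). The two
#' parameters are controlled independently, mirroring manual gating on an
#' image-analysis platform.
#'
#' @param marker marker name.
#' @param intensity_threshold fluorescence-intensity threshold (>= 0,
#'   arbitrary units).
#' @param coverage_threshold coverage threshold as a fraction in \[0, 1\].
#' @return Object of class `marker_gate`.
#' @export
marker_gate <- function(marker, intensity_threshold, coverage_threshold) {
  stop_if(intensity_threshold < 0, "intensity_threshold must be >= 0")
  stop_if(coverage_threshold < 0 || coverage_threshold > 1,
          "coverage_threshold must lie in [0, 1]")
  structure(list(marker = marker,
                 intensity_threshold = intensity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "marker_gate")
}

#' Default gates used by the synthetic generator
#' @return Named list of [marker_gate()] for the four lineage markers and
#'   `pSTAT3`.
#' @export
default_gates <- function() {
  mk <- c(MARKERS, "pSTAT3")
  stats::setNames(lapply(mk, marker_gate,
                         intensity_threshold = 10, coverage_threshold = 0.3),
                  mk)
}

#' Apply one marker gate
#'
#' @param intensity,coverage numeric vectors (finite, >= 0).
#' @param gate a [marker_gate()].
#' @return Logical vector: positive iff `intensity >= intensity_threshold`
#'   AND `coverage >= coverage_threshold` (inclusive on both boundaries).
#' @export
gate_marker <- function(intensity, coverage, gate) {
  stop_if(!inherits(gate, "marker_gate"), "gate must be a marker_gate")
  stop_if(any(!is.finite(intensity)) || any(!is.finite(coverage)) ||
            any(intensity < 0) || any(coverage < 0),
          "intensity/coverage must be finite and >= 0")
  intensity >= gate$intensity_threshold & coverage >= gate$coverage_threshold
}

#' Map a marker-positivity vector to a phenotype
#'
#' CD3 alone gives `CD3`; any myeloid combination without CD3 gives the
#' exact combination label (markers in the canonical order CD11c, CD68,
#' CD163); CD3 together with any myeloid marker gives `ambiguous`; no
#' positive marker gives `negative`. p-STAT3 positivity is carried
#' alongside as a modifier, never entering the phenotype label.
#'
#' @param cd3,cd68,cd11c,cd163,pstat3 logical vectors (recycled to common
#'   length).
#' @return data.frame with `phenotype` and `pstat3` columns.
#' @export
assign_phenotype <- function(cd3, cd68, cd11c, cd163, pstat3 = FALSE) {
  args <- list(cd3, cd68, cd11c, cd163, pstat3)
  stop_if(!all(vapply(args, is.logical, logical(1))),
          "positivity inputs must be logical")
  n <- max(lengths(args))
  cd3 <- rep_len(cd3, n); cd68 <- rep_len(cd68, n)
  cd11c <- rep_len(cd11c, n); cd163 <- rep_len(cd163, n)
  pstat3 <- rep_len(pstat3, n)
  myeloid <- cbind(CD11c = cd11c, CD68 = cd68, CD163 = cd163)
  any_my <- rowSums(myeloid) > 0
  combo <- apply(myeloid, 1, function(v) paste(MYELOID[v], collapse = "_"))
  phenotype <- ifelse(cd3 & any_my, "ambiguous",
               ifelse(cd3, "CD3",
               ifelse(any_my, combo, "negative")))
  data.frame(phenotype = phenotype, pstat3 = pstat3,
             stringsAsFactors = FALSE)
}

#' Gate and phenotype a whole cell table
#'
#' Applies every marker gate to the table's `<marker>_intensity` /
#' `<marker>_coverage` columns and assigns the phenotype and p-STAT3
#' status. Deterministic and row-order independent.
#'
#' @param cells cell table carrying measurement columns for the four
#'   lineage markers and `pSTAT3`.
#' @param gates named list of [marker_gate()].
#' @return `cells` with `phenotype` and `pstat3` columns appended.
#' @export
classify_cells <- function(cells, gates = default_gates()) {
  pos <- lapply(c(MARKERS, "pSTAT3"), function(m) {
    ic <- paste0(m, "_intensity"); cc <- paste0(m, "_coverage")
    stop_if(!(ic %in% names(cells)) || !(cc %in% names(cells)),
            "missing measurement columns for marker ", m)
    gate_marker(cells[[ic]], cells[[cc]], gates[[m]])
  })
  names(pos) <- c(MARKERS, "pSTAT3")
  res <- assign_phenotype(pos$CD3, pos$CD68, pos$CD11c, pos$CD163,
                          pos$pSTAT3)
  cells$phenotype <- res$phenotype
  cells$pstat3 <- res$pstat3
  cells
}

#' Region-stratified phenotype composition
#'
#' Percentages of each phenotype x p-STAT3 class per region class, the
#' quantity plotted region by region in immune-composition dot plots.
#' The denominator is all classified, non-ambiguous cells in the region
#' (the `negative` class included); `ambiguous` cells are excluded.
#' A region class with zero classified cells yields `NA` percentages with
#' `empty_region = TRUE`, never a division error.
#'
#' @param cells classified cell table (from [classify_cells()]) with
#'   `region_class` assigned.
#' @param regions list of [region_annotation]; fixes the set of region
#'   classes reported.
#' @return data.frame with `region_class`, `phenotype`, `pstat3`, `n`,
#'   `percent`, `empty_region`.
#' @export
composition_summary <- function(cells, regions) {
  check_cell_table(cells, c("region_id", "region_class", "phenotype",
                            "pstat3"))
  known <- c(vapply(regions, `[[`, "", "region_id"), "unassigned")
  bad <- setdiff(unique(cells$region_id), known)
  stop_if(length(bad) > 0, "unknown region id(s): ",
          paste(bad, collapse = ", "))
  classes <- unique(vapply(regions, `[[`, "", "region_class"))
  classes <- setdiff(classes, "excluded")
  keep <- cells$phenotype != "ambiguous" & cells$region_class %in% classes
  cells <- cells[keep, , drop = FALSE]
  phen <- setdiff(PHENOTYPES, "ambiguous")
  grid <- expand.grid(region_class = classes, phenotype = phen,
                      pstat3 = c(FALSE, TRUE), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  key <- function(r, p, s) paste(r, p, s, sep = "\r")
  cnt <- table(key(cells$region_class, cells$phenotype, cells$pstat3))
  tot <- table(cells$region_class)
  grid$n <- as.integer(cnt[key(grid$region_class, grid$phenotype,
                               grid$pstat3)])
  grid$n[is.na(grid$n)] <- 0L
  denom <- as.integer(tot[grid$region_class])
  denom[is.na(denom)] <- 0L
  grid$percent <- ifelse(denom > 0, 100 * grid$n / denom, NA_real_)
  grid$empty_region <- denom == 0L
  grid[order(grid$region_class, grid$phenotype, grid$pstat3), ]
}
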