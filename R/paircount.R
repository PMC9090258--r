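#' Radius-bounded cross pair counts
#'
#' For each reference cell, counts the target cells lying within `radius`
#' um (inclusive boundary). When reference and target are the same
#' phenotype, self-pairs are excluded (a cell never counts itself);
#' identity is taken from matching `cell_id` values when both tables carry
#' them, or from row identity when the same object is passed twice.
#'
#' @param reference,target cell tables (`x_um`, `y_um`, optionally
#'   `cell_id`) or 2-column matrices.
#' @param radius neighbourhood radius in um (> 0); the study default is
#'   15 um.
#' @return Object of class `pair_counts`: integer `counts` (one per
#'   reference cell, in input order), `radius`, `n_ref`, `n_target`.
#' @export
cross_pair_counts <- function(reference, target, radius = 15) {
  stop_if(!is.numeric(radius) || radius <= 0, "radius must be > 0")
  ref <- as_xy(reference); tgt <- as_xy(target)
  ref_id <- if (is.data.frame(reference) && "cell_id" %in% names(reference))
    reference$cell_id else NULL
  tgt_id <- if (is.data.frame(target) && "cell_id" %in% names(target))
    target$cell_id else NULL
  same_set <- identical(reference, target)
  n <- nrow(ref)
  counts <- integer(n)
  if (n > 0 && nrow(tgt) > 0) {
    block <- 512L
    r2 <- radius^2
    for (s in seq(1L, n, by = block)) {
      e <- min(n, s + block - 1L)
      dx <- outer(ref[s:e, 1], tgt[, 1], "-")
      dy <- outer(ref[s:e, 2], tgt[, 2], "-")
      within <- (dx * dx + dy * dy) <= r2 + 1e-12
      cnt <- rowSums(within)
      # remove self-pairs
      if (!is.null(ref_id) && !is.null(tgt_id)) {
        selfm <- outer(ref_id[s:e], tgt_id, "==") & within
        cnt <- cnt - rowSums(selfm)
      } else if (same_set) {
        cnt <- cnt - 1L            # each point matches itself at distance 0
      }
      counts[s:e] <- as.integer(cnt)
    }
  }
  structure(list(counts = counts, radius = radius,
                 n_ref = n, n_target = nrow(tgt)),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("<pair counts: %d reference x %d target cells, r = %g um, mean %.2f>\n",
              x$n_ref, x$n_target, x$radius,
              if (x$n_ref) mean(x$counts) else NA_real_))
  invisible(x)
}

#' Cluster frequency from cross pair counts
#'
#' Operationalizes a "cluster interaction": with a single target type, a
#' reference cell is a cluster member when it has at least `min_single`
#' (default 2) target cells within the radius; with two target types, when
#' it has at least one of each. A single partner cell is a dyad-scale
#' contact, not a cluster. The frequency is the percentage of reference
#' cells that are cluster members. These thresholds are a package
#' convention and are recorded in all output metadata.
#'
#' @param counts a [cross_pair_counts()] result (single-type criterion).
#' @param counts2 optional second [cross_pair_counts()] over the same
#'   reference cells (two-type criterion).
#' @param min_single minimum partner count for the single-type criterion.
#' @return List of class `cluster_frequency`: `frequency` (percent, `NA`
#'   with `empty = TRUE` when there are no reference cells), `n_ref`,
#'   `n_members`, `criterion`.
#' @export
cluster_frequency <- function(counts, counts2 = NULL, min_single = 2) {
  stop_if(!inherits(counts, "pair_counts"), "counts must be pair_counts")
  if (!is.null(counts2)) {
    stop_if(!inherits(counts2, "pair_counts"), "counts2 must be pair_counts")
    stop_if(counts2$n_ref != counts$n_ref,
            "count sets cover different reference cells")
    stop_if(counts2$radius != counts$radius,
            "count sets computed at different radii")
    member <- counts$counts >= 1L & counts2$counts >= 1L
    criterion <- ">=1 of each of two target types"
  } else {
    member <- counts$counts >= min_single
    criterion <- sprintf(">=%d of one target type", min_single)
  }
  n <- counts$n_ref
  structure(list(
    frequency = if (n > 0) 100 * sum(member) / n else NA_real_,
    empty = n == 0,
    n_ref = n, n_members = sum(member),
    radius = counts$radius, criterion = criterion),
    class = "cluster_frequency")
}

#' @export
print.cluster_frequency <- function(x, ...) {
  cat(sprintf("<cluster frequency: %s%% (%d/%d refs, r = %g um, %s)>\n",
              if (x$empty) "NA" else sprintf("%.1f", x$frequency),
              x$n_members, x$n_ref, x$radius, x$criterion))
  invisible(x)
}
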