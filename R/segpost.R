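#' Isotropic label expansion
#'
#' Approximates cell boundaries from nucleus labels: every background pixel
#' whose centre lies within `radius` um of at least one labelled pixel is
#' assigned to the label owning the nearest such pixel (Euclidean distance
#' between pixel centres; the lower label id wins exact ties). Original
#' label pixels are never changed and labels never merge.
#'
#' @param mask a [label_mask()].
#' @param radius expansion radius in um (>= 0); the study default is 3 um.
#' @return The expanded [label_mask()].
#' @export
expand_labels <- function(mask, radius = 3) {
  stop_if(!inherits(mask, "label_mask"), "not a label_mask")
  stop_if(!is.numeric(radius) || radius < 0, "radius must be >= 0")
  lab <- mask$labels
  if (radius == 0 || all(lab == 0L)) return(mask)
  rpx <- radius / mask$pixel_size
  rmax <- floor(rpx + 1e-9)
  offs <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
  offs$d2 <- offs$dy^2 + offs$dx^2
  offs <- offs[offs$d2 <= rpx^2 + 1e-9 & offs$d2 > 0, ]
  offs <- offs[order(offs$d2), ]
  out <- lab
  ny <- nrow(lab); nx <- ncol(lab)
  # process offsets in shells of equal distance: a pixel is claimed at its
  # first shell containing any labelled pixel; min label within a shell
  for (d2 in unique(offs$d2)) {
    open <- out == 0L
    if (!any(open)) break
    shell <- offs[offs$d2 == d2, ]
    cand <- matrix(Inf, ny, nx)
    for (s in seq_len(nrow(shell))) {
      dy <- shell$dy[s]; dx <- shell$dx[s]
      src_i <- max(1L, 1L + dy):min(ny, ny + dy)
      dst_i <- src_i - dy
      src_j <- max(1L, 1L + dx):min(nx, nx + dx)
      dst_j <- src_j - dx
      sh <- matrix(Inf, ny, nx)
      sh[dst_i, dst_j] <- ifelse(lab[src_i, src_j] > 0L,
                                 lab[src_i, src_j], Inf)
      cand <- pmin(cand, sh)
    }
    claim <- open & is.finite(cand)
    out[claim] <- as.integer(cand[claim])
  }
  label_mask(out, mask$pixel_size)
}

#' Minimum-area label filter
#'
#' Removes labels whose pixel area (pixel count x pixel_size^2) is
#' strictly less than `min_area` um^2; surviving labels keep their ids.
#' The study default of 11 um^2 corresponds to a circular-equivalent
#' radius of about 2 um.
#'
#' @param mask a [label_mask()].
#' @param min_area area threshold in um^2 (>= 0).
#' @return Filtered [label_mask()].
#' @export
filter_small_labels <- function(mask, min_area = 11) {
  stop_if(!inherits(mask, "label_mask"), "not a label_mask")
  stop_if(min_area < 0, "min_area must be >= 0")
  lab <- mask$labels
  if (all(lab == 0L)) return(mask)
  counts <- tabulate(lab[lab > 0L])
  area <- counts * mask$pixel_size^2
  drop <- which(area < min_area & counts > 0L)
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_mask(lab, mask$pixel_size)
}

#' Label centroids and areas
#'
#' One row per surviving label: centroid as the mean of member pixel-centre
#' coordinates (in um) and pixel-count area in um^2. Feeds the spatial
#' statistics, which operate on centre x / centre y coordinates.
#'
#' @param mask a [label_mask()].
#' @return data.frame with `cell_id` (the integer label), `x_um`, `y_um`,
#'   `area_um2`; zero rows for an empty mask.
#' @export
centroids <- function(mask) {
  stop_if(!inherits(mask, "label_mask"), "not a label_mask")
  lab <- mask$labels
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0)))
  ps <- mask$pixel_size
  l <- lab[idx]
  x <- (idx[, "col"] - 0.5) * ps
  y <- (idx[, "row"] - 0.5) * ps
  agg <- rowsum(cbind(x = x, y = y, n = 1), group = l)
  ids <- as.integer(rownames(agg))
  data.frame(cell_id = ids,
             x_um = agg[, "x"] / agg[, "n"],
             y_um = agg[, "y"] / agg[, "n"],
             area_um2 = agg[, "n"] * ps^2,
             row.names = NULL)
}

#' Full nucleus-label post-processing chain
#'
#' Convenience wrapper: expand labels, drop sub-threshold objects, extract
#' centroids.
#'
#' @param mask a [label_mask()].
#' @param expand_um expansion radius (default 3 um).
#' @param min_area_um2 area filter (default 11 um^2).
#' @return Centroid table as from [centroids()].
#' @export
postprocess_labels <- function(mask, expand_um = 3, min_area_um2 = 11) {
  centroids(filter_small_labels(expand_labels(mask, expand_um),
                                min_area_um2))
}
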