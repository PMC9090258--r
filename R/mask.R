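#' Integer label masks
#'
#' A label mask is a 2-D integer grid: 0 is background, k > 0 marks the
#' pixels of cell k. Rows index y, columns index x; the centre of pixel
#' (row i, col j) sits at ((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)
#' in um.
#'
#' @param labels integer matrix (0 = background).
#' @param pixel_size pixel edge length in um/pixel (> 0).
#' @return Object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size) {
  stop_if(!is.matrix(labels), "labels must be a matrix")
  stop_if(pixel_size <= 0, "pixel_size must be > 0")
  storage.mode(labels) <- "integer"
  stop_if(any(labels < 0), "labels must be non-negative integers")
  structure(list(labels = labels, pixel_size = pixel_size),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask %d x %d px (%.3g um/px), %d labels>\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Rasterize cells into a label mask
#'
#' Each cell becomes a disc of the given radius: a pixel belongs to the
#' disc when its centre lies within `cell_radius` of the cell centroid.
#' Where discs overlap, the pixel goes to the nearest centroid (lowest row
#' index on exact ties). Label k corresponds to the k-th table row.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param pixel_size um per pixel.
#' @param cell_radius disc radius in um (must be >= `pixel_size` so every
#'   cell covers at least one pixel).
#' @param width,height raster extent in um; default covers all cells plus
#'   one radius of margin.
#' @return A [label_mask()].
#' @export
render_label_mask <- function(cells, pixel_size, cell_radius,
                              width = NULL, height = NULL) {
  check_cell_table(cells, c("x_um", "y_um"))
  stop_if(cell_radius < pixel_size, "cell_radius must be >= pixel_size")
  n <- nrow(cells)
  if (is.null(width))
    width <- if (n) max(cells$x_um) + cell_radius else pixel_size
  if (is.null(height))
    height <- if (n) max(cells$y_um) + cell_radius else pixel_size
  nx <- ceiling(width / pixel_size)
  ny <- ceiling(height / pixel_size)
  if (n > 0)
    stop_if(any(cells$x_um < 0 | cells$x_um > width |
                  cells$y_um < 0 | cells$y_um > height),
            "cells outside the raster extent")
  lab <- matrix(0L, ny, nx)
  if (n == 0) return(label_mask(lab, pixel_size))
  best <- matrix(Inf, ny, nx)
  rpx <- cell_radius / pixel_size
  for (k in seq_len(n)) {
    # pixel-centre coordinates in pixel units
    cx <- cells$x_um[k] / pixel_size
    cy <- cells$y_um[k] / pixel_size
    jr <- max(1L, floor(cx - rpx + 0.5)):min(nx, ceiling(cx + rpx + 0.5))
    ir <- max(1L, floor(cy - rpx + 0.5)):min(ny, ceiling(cy + rpx + 0.5))
    dx <- (jr - 0.5) - cx
    dy <- (ir - 0.5) - cy
    d2 <- outer(dy^2, dx^2, "+")
    hit <- d2 <= rpx^2 + 1e-12
    win <- hit & d2 < best[ir, jr]        # strict: earlier (lower) id wins ties
    if (any(win)) {
      sub <- lab[ir, jr]; sub[win] <- k
      lab[ir, jr] <- sub
      subb <- best[ir, jr]; subb[win] <- d2[win]
      best[ir, jr] <- subb
    }
  }
  label_mask(lab, pixel_size)
}

#' Write / read a label mask as single-plane TIFF
#'
#' Stored as 16-bit integers (at most 65535 labels); the pixel size is not
#' part of the TIFF payload and must be carried in the run configuration.
#'
#' @param mask a [label_mask()].
#' @param file path.
#' @export
write_label_mask <- function(mask, file) {
  stop_if(!inherits(mask, "label_mask"), "not a label_mask")
  mx <- max(mask$labels)
  stop_if(mx > 65535L, "more than 65535 labels; cannot store as 16-bit")
  tiff::writeTIFF(mask$labels / 65535, file, bits.per.sample = 16L)
  invisible(file)
}

#' @rdname write_label_mask
#' @param pixel_size um per pixel of the stored mask.
#' @export
read_label_mask <- function(file, pixel_size) {
  m <- tiff::readTIFF(file, as.is = TRUE)
  label_mask(m, pixel_size)
}
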