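#' Region annotations
#'
#' A region annotation is a labeled polygon compartment of a tissue section:
#' one of the classes `brain`, `edge`, `tumor`, `necrosis` (plus `excluded`
#' for masked-out areas such as bleeds). Polygons are simple (not
#' self-intersecting), with vertices in micrometres.
#'
#' @param region_id character scalar, unique within a specimen.
#' @param region_class one of `"brain"`, `"edge"`, `"tumor"`, `"necrosis"`,
#'   `"excluded"`.
#' @param polygon two-column numeric matrix of vertices (x, y) in um, open
#'   ring (first vertex not repeated).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(region_id, region_class, polygon) {
  region_class <- match.arg(region_class, REGION_CLASSES)
  polygon <- as.matrix(polygon)
  stop_if(ncol(polygon) != 2 || nrow(polygon) < 3 || !all(is.finite(polygon)),
          "polygon must be a finite n x 2 matrix with n >= 3")
  stop_if(abs(polygon_area(polygon)) <= 0,
          "polygon is degenerate (zero area)")
  structure(list(region_id = as.character(region_id),
                 region_class = region_class,
                 polygon = unname(polygon)),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region %s: %s, %d vertices, area %.1f um^2>\n",
              x$region_id, x$region_class, nrow(x$polygon),
              polygon_area(x$polygon)))
  invisible(x)
}

REGION_CLASSES <- c("brain", "edge", "tumor", "necrosis", "excluded")

#' Signed polygon area (shoelace), in um^2
#' @param polygon two-column vertex matrix, open ring.
#' @return Numeric scalar; positive for counter-clockwise rings.
#' @export
polygon_area <- function(polygon) {
  x <- polygon[, 1]; y <- polygon[, 2]
  j <- c(seq_len(nrow(polygon))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Point-in-polygon by ray casting; points exactly on an edge or vertex count
# as inside (the stated boundary convention). Vectorized over points.
#' @noRd
point_in_polygon <- function(px, py, polygon) {
  n <- nrow(polygon)
  vx <- polygon[, 1]; vy <- polygon[, 2]
  jx <- vx[c(2:n, 1)]; jy <- vy[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  eps <- 1e-9
  for (e in seq_len(n)) {
    x1 <- vx[e]; y1 <- vy[e]; x2 <- jx[e]; y2 <- jy[e]
    # on-segment test
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    dot <- (px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)
    on <- abs(cross) <= eps * (1 + sqrt(seglen2)) & dot >= -eps & dot <= seglen2 + eps
    boundary <- boundary | on
    # ray casting (horizontal ray to +x)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) / (y2 - y1) * (x2 - x1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | boundary
}

#' Generate the three-band wedge geometry
#'
#' Builds the study geometry of a resected tissue wedge: three abutting
#' rectangular bands spanning the window from the infiltrating edge through
#' tumor to the necrotic core, along the x axis.
#'
#' @param window_width,window_height window dimensions in um.
#' @param band_fractions three positive proportions (edge, tumor, necrosis)
#'   summing to 1.
#' @return List of three [region_annotation] objects covering the window.
#' @examples
#' regs <- generate_regions(300, 100)
#' sapply(regs, function(r) r$region_class)
#' @export
generate_regions <- function(window_width, window_height,
                             band_fractions = c(1, 1, 1) / 3) {
  stop_if(!is.numeric(window_width) || window_width <= 0 ||
            !is.numeric(window_height) || window_height <= 0,
          "window dimensions must be positive")
  stop_if(length(band_fractions) != 3 || any(band_fractions <= 0),
          "band_fractions must be 3 positive proportions")
  stop_if(abs(sum(band_fractions) - 1) > 1e-8,
          "band_fractions must sum to 1")
  xs <- c(0, cumsum(band_fractions)) * window_width
  classes <- c("edge", "tumor", "necrosis")
  lapply(1:3, function(i) {
    region_annotation(
      region_id = classes[i],
      region_class = classes[i],
      polygon = cbind(c(xs[i], xs[i + 1], xs[i + 1], xs[i]),
                      c(0, 0, window_height, window_height)))
  })
}

#' Assign each cell to a region
#'
#' Point-in-polygon assignment with the boundary counted inside; a point on
#' a shared border goes to the first-listed region (deterministic
#' tie-break). Cells falling in no region get region_id `"unassigned"` and
#' are excluded from downstream statistics.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param regions list of [region_annotation] objects; order matters for
#'   tie-breaking.
#' @return `cells` with a `region_id` and `region_class` column.
#' @export
assign_regions <- function(cells, regions) {
  check_cell_table(cells, c("x_um", "y_um"))
  stop_if(length(regions) == 0, "no regions supplied")
  for (r in regions)
    stop_if(!inherits(r, "region_annotation"), "invalid region annotation")
  region_id <- rep(NA_character_, nrow(cells))
  region_class <- rep(NA_character_, nrow(cells))
  for (r in regions) {
    open <- is.na(region_id)
    if (!any(open)) break
    hit <- point_in_polygon(cells$x_um[open], cells$y_um[open], r$polygon)
    region_id[open][hit] <- r$region_id
    region_class[open][hit] <- r$region_class
  }
  region_id[is.na(region_id)] <- "unassigned"
  region_class[is.na(region_class)] <- "unassigned"
  cells$region_id <- region_id
  cells$region_class <- region_class
  cells
}

#' Write regions to GeoJSON
#'
#' One Feature per region, `Polygon` geometry (closed ring), with
#' `region_id` and `region_class` properties.
#'
#' @param regions list of [region_annotation].
#' @param file output path.
#' @export
write_regions_geojson <- function(regions, file) {
  feats <- lapply(regions, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(region_id = r$region_id,
                           region_class = r$region_class),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) ring[i, ]))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Read regions from GeoJSON
#' @param file GeoJSON FeatureCollection path as written by
#'   [write_regions_geojson()] (or any Polygon features carrying a
#'   `region_class` property).
#' @return List of [region_annotation], in file order.
#' @export
read_regions_geojson <- function(file) {
  fc <- jsonlite::read_json(file)
  stop_if(!identical(fc$type, "FeatureCollection"), "not a FeatureCollection")
  lapply(seq_along(fc$features), function(i) {
    f <- fc$features[[i]]
    stop_if(!identical(f$geometry$type, "Polygon"),
            "feature ", i, " is not a Polygon")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(v) unlist(v)))
    # drop closing vertex
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    region_annotation(f$properties$region_id %||% paste0("region_", i),
                      f$properties$region_class, ring)
  })
}
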