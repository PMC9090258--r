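#' @noRd
as_xy <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x_um", "y_um") %in% names(points)))
      return(cbind(points$x_um, points$y_um))
    points <- as.matrix(points)
  }
  if (is.null(points)) return(matrix(numeric(0), 0, 2))
  points <- as.matrix(points)
  stop_if(ncol(points) < 2, "points must have x and y columns")
  stop_if(any(!is.finite(points[, 1:2])), "coordinates must be finite")
  points[, 1:2, drop = FALSE]
}

#' Convex-hull observation window
#'
#' The spatial domain for intensity estimation: the convex hull of the
#' cell coordinates of a specimen.
#'
#' @param points cell table (columns `x_um`, `y_um`) or 2-column matrix.
#' @return Object of class `spat_window`: hull `vertices`
#'   (counter-clockwise, open ring) and `area` in um^2.
#' @export
observation_window <- function(points) {
  xy <- as_xy(points)
  xy <- unique(xy)
  stop_if(nrow(xy) < 3, "need >= 3 distinct points for a window")
  h <- grDevices::chull(xy[, 1], xy[, 2])
  stop_if(length(h) < 3, "degenerate window: points are collinear")
  verts <- xy[rev(h), , drop = FALSE]           # counter-clockwise
  area <- polygon_area(verts)
  stop_if(abs(area) <= 0, "degenerate window: zero area")
  structure(list(vertices = verts, area = abs(area)), class = "spat_window")
}

#' @export
print.spat_window <- function(x, ...) {
  cat(sprintf("<observation window: %d hull vertices, area %.1f um^2>\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

#' Point-process intensity estimate
#'
#' Overall density of one cell type on the specimen:
#' `lambda = n / window area`.
#'
#' @param points target-type cells (table or matrix); may be empty.
#' @param window a [observation_window()] result.
#' @return Intensity in cells/um^2.
#' @export
estimate_intensity <- function(points, window) {
  stop_if(!inherits(window, "spat_window"), "window must be a spat_window")
  stop_if(window$area <= 0, "window has zero area")
  nrow(as_xy(points)) / window$area
}

#' Closed-form G-function under complete spatial randomness
#'
#' Probability of finding at least one type-y cell within distance r of a
#' type-x cell when type y is a homogeneous Poisson process of intensity
#' `lambda_y`: `G(r) = 1 - exp(-lambda_y * pi * r^2)`.
#'
#' @param lambda_y intensity of the target type (cells/um^2, >= 0).
#' @param r radius in um (>= 0); vectorized.
#' @return Probabilities in \[0, 1).
#' @export
theoretical_g <- function(lambda_y, r) {
  stop_if(any(lambda_y < 0) || any(r < 0), "lambda_y and r must be >= 0")
  1 - exp(-lambda_y * pi * r^2)
}

# nearest-neighbour distance from each ref point to the target set,
# blocked to bound memory; Inf where the target set is empty
#' @noRd
cross_nn_dist <- function(ref, tgt, block = 512L) {
  n <- nrow(ref)
  if (n == 0L) return(numeric(0))
  if (nrow(tgt) == 0L) return(rep(Inf, n))
  out <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    dx <- outer(ref[s:e, 1], tgt[, 1], "-")
    dy <- outer(ref[s:e, 2], tgt[, 2], "-")
    d2 <- dx * dx + dy * dy
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

# distance from points to polygon boundary (min over segments)
#' @noRd
dist_to_boundary <- function(xy, polygon) {
  n <- nrow(polygon)
  d <- rep(Inf, nrow(xy))
  for (e in seq_len(n)) {
    a <- polygon[e, ]; b <- polygon[if (e == n) 1L else e + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) /
      max(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d <- pmin(d, sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2))
  }
  d
}

#' Empirical cross-type G-function
#'
#' Empirical nearest-neighbour distance distribution from reference cells
#' (type x) to target cells (type y): for each radius on the grid, the
#' fraction of reference cells whose nearest target lies at distance <= r.
#' The default estimator applies no edge correction, matching the
#' uncorrected closed form used for interpretation; a reduced-sample
#' border correction is available for sensitivity analysis (it restricts,
#' at each r, to reference cells at least r from the window boundary).
#' If either point set is empty, G is identically 0 by convention.
#'
#' @param reference,target cell tables or 2-column matrices (um).
#' @param r_grid sorted radius grid starting at 0, in um; default 0 to
#'   50 um in 0.5 um steps.
#' @param correction `"none"` (default) or `"border"`.
#' @param window a [observation_window()]; required for the border
#'   correction, otherwise used only to record `lambda_y`. Computed from
#'   the union of both point sets when omitted and computable.
#' @return Object of class `gcurve`: `r`, `G`, `n_ref`, `n_target`,
#'   `lambda_y`, `reference`, `target`, `correction`.
#' @export
empirical_cross_g <- function(reference, target,
                              r_grid = seq(0, 50, by = 0.5),
                              correction = c("none", "border"),
                              window = NULL) {
  correction <- match.arg(correction)
  stop_if(is.unsorted(r_grid, strictly = TRUE) || r_grid[1] != 0,
          "r_grid must be strictly increasing and start at 0")
  ref <- as_xy(reference); tgt <- as_xy(target)
  if (is.null(window) && (nrow(ref) + nrow(tgt)) >= 3) {
    window <- tryCatch(observation_window(rbind(ref, tgt)),
                       error = function(e) NULL)
  }
  lambda_y <- if (!is.null(window)) estimate_intensity(tgt, window)
              else NA_real_
  if (nrow(ref) == 0L || nrow(tgt) == 0L) {
    G <- rep(0, length(r_grid))
  } else {
    d <- cross_nn_dist(ref, tgt)
    if (correction == "none") {
      G <- vapply(r_grid, function(r) mean(d <= r), numeric(1))
    } else {
      stop_if(is.null(window), "border correction needs a window")
      b <- dist_to_boundary(ref, window$vertices)
      G <- vapply(r_grid, function(r) {
        keep <- b >= r
        if (!any(keep)) return(NA_real_)
        mean(d[keep] <= r)
      }, numeric(1))
    }
  }
  structure(list(r = r_grid, G = G,
                 n_ref = nrow(ref), n_target = nrow(tgt),
                 lambda_y = lambda_y,
                 reference = attr(reference, "phenotype") %||% "x",
                 target = attr(target, "phenotype") %||% "y",
                 correction = correction),
            class = "gcurve")
}

#' @export
print.gcurve <- function(x, ...) {
  a <- tryCatch(g_auc(x)$auc, error = function(e) NA_real_)
  cat(sprintf(
    "<cross-type G: %s -> %s, n_ref %d, n_target %d, AUC(15um) %.3f>\n",
    x$reference, x$target, x$n_ref, x$n_target, a))
  invisible(x)
}

#' @export
plot.gcurve <- function(x, ..., csr = TRUE) {
  graphics::plot(x$r, x$G, type = "s", ylim = c(0, 1),
                 xlab = "r (um)", ylab = "G(r)",
                 main = sprintf("%s -> %s", x$reference, x$target), ...)
  if (csr && is.finite(x$lambda_y))
    graphics::lines(x$r, theoretical_g(x$lambda_y, x$r), lty = 2,
                    col = "grey40")
  invisible(x)
}

#' G-function AUC and dichotomized interaction score
#'
#' Trapezoidal integral of the empirical G over \[0, r_cut\] (default
#' 15 um), in um. Any positive AUC dichotomizes to a positive interaction
#' score; an AUC of exactly 0 (typically from absent or extremely sparse
#' cell types) scores negative.
#'
#' @param curve a [empirical_cross_g()] result.
#' @param r_cut integration cut-off in um; must lie within the grid.
#' @return List: `auc` (um), `auc_pct` (normalized, 100 * auc / r_cut),
#'   `interaction_score` (logical).
#' @export
g_auc <- function(curve, r_cut = 15) {
  stop_if(!inherits(curve, "gcurve"), "curve must be a gcurve")
  r <- curve$r; G <- curve$G
  stop_if(r_cut < r[1] || r_cut > r[length(r)],
          "r_cut lies outside the radius grid")
  keep <- r <= r_cut
  rr <- r[keep]; GG <- G[keep]
  if (rr[length(rr)] < r_cut) {      # interpolate the cut point
    i <- sum(keep)
    g_cut <- G[i] + (G[i + 1] - G[i]) * (r_cut - r[i]) / (r[i + 1] - r[i])
    rr <- c(rr, r_cut); GG <- c(GG, g_cut)
  }
  auc <- sum(diff(rr) * (utils::head(GG, -1) + utils::tail(GG, -1)) / 2)
  list(auc = auc, auc_pct = 100 * auc / r_cut,
       interaction_score = auc > 0)
}
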