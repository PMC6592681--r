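#' @title Interphase cell-shape morphometrics
#' @description Planimetric measurements on segmented basal-cell outlines:
#'   cross-sectional area, longest planar axis, height:width aspect ratio,
#'   elongation nematic, polygon class, packing density, proliferation rate
#'   and tissue thickness.
#' @name geometry
NULL

as_polygon <- function(polygon) {
  p <- as.matrix(polygon)
  if (ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
    stop("invalid-shape: polygon must be a finite n x 2 matrix with n >= 3",
         call. = FALSE)
  # drop a repeated closing vertex
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (nrow(p) < 3) stop("invalid-shape: fewer than 3 distinct vertices",
                        call. = FALSE)
  p
}

signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# O(n^2) proper-crossing test between non-adjacent edges
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

#' Polygon (cross-sectional) area
#'
#' Shoelace area of a simple polygon, independent of vertex orientation.
#'
#' @param polygon An n x 2 matrix of vertices (um), open or closed.
#' @param validate Check that the polygon is simple (non-self-intersecting);
#'   O(n^2), skip for trusted tessellation output.
#' @return Area in um^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' @export
polygon_area <- function(polygon, validate = TRUE) {
  p <- as_polygon(polygon)
  if (validate && !is_simple_polygon(p))
    stop("invalid-shape: polygon is self-intersecting", call. = FALSE)
  a <- abs(signed_area(p))
  if (a <= 0) stop("invalid-shape: polygon has zero area", call. = FALSE)
  a
}

#' Polygon centroid
#' @inheritParams polygon_area
#' @return Length-2 numeric `c(x, y)`.
#' @export
polygon_centroid <- function(polygon) {
  p <- as_polygon(polygon)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a == 0) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Apical-basal cell height
#'
#' Distance from the apical surface to the basement membrane.
#'
#' @param apical_z,basal_z z-coordinates (um), apical positive, membrane at 0.
#' @return Height in um; a zero height is returned with a warning.
#' @export
cell_height <- function(apical_z, basal_z = 0) {
  if (any(apical_z < basal_z))
    stop("negative cell extent: apical_z < basal_z", call. = FALSE)
  h <- apical_z - basal_z
  if (any(h == 0)) warning("degenerate zero-height cell")
  h
}

#' Longest planar axis of a cell outline
#'
#' The cell "width": the maximum chord between boundary vertices (equivalent
#' to the rotating-calipers diameter for convex outlines), together with its
#' axial orientation.  Ties are broken by the first maximal vertex pair in
#' scan order.
#'
#' @inheritParams polygon_area
#' @return List with `length` (um) and `orientation_deg` in \[0, 180).
#' @examples
#' longest_planar_axis(rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2)))
#' @export
longest_planar_axis <- function(polygon, validate = TRUE) {
  p <- as_polygon(polygon)
  if (validate && !is_simple_polygon(p))
    stop("invalid-shape: polygon is self-intersecting", call. = FALSE)
  d2 <- as.matrix(stats::dist(p))^2
  idx <- which(d2 == max(d2), arr.ind = TRUE)
  # first pair in row-major scan order, deterministic under ties
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  i <- idx[1, 1]; j <- idx[1, 2]
  v <- p[j, ] - p[i, ]
  ang <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  list(length = sqrt(d2[i, j]), orientation_deg = ang)
}

#' Height:width aspect ratio
#'
#' Apical-basal height divided by the longest planar axis of the interphase
#' outline (measured just before mitotic rounding when used with division
#' events).
#'
#' @param height Cell height (um).
#' @param polygon Interphase outline; alternatively pass `width` directly.
#' @param width Longest-planar-axis length (um), if precomputed.
#' @return Dimensionless ratio.
#' @export
height_width_ratio <- function(height, polygon = NULL, width = NULL) {
  if (is.null(width)) {
    if (is.null(polygon)) stop("supply polygon or width", call. = FALSE)
    width <- longest_planar_axis(polygon)$length
  }
  if (any(width <= 0)) stop("zero width", call. = FALSE)
  height / width
}

#' Elongation nematic of a cell outline
#'
#' From the area-normalized central second-moment tensor of the polygon
#' interior: magnitude `100 * (l1 - l2) / (l1 + l2)` (eigenvalues l1 >= l2)
#' and the principal-axis orientation.  A 2:1 ellipse gives magnitude 60;
#' the x100 scale puts typical epithelial values in the tens, the range in
#' which tissue-segmentation tools report elongation.
#'
#' @inheritParams polygon_area
#' @return List with `magnitude` (dimensionless, >= 0) and `axis_deg` in
#'   \[0, 180).
#' @export
elongation_nematic <- function(polygon, validate = TRUE) {
  p <- as_polygon(polygon)
  if (validate && !is_simple_polygon(p))
    stop("invalid-shape: polygon is self-intersecting", call. = FALSE)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (a == 0) stop("invalid-shape: degenerate polygon", call. = FALSE)
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  x <- x - cx; xn <- xn - cx; y <- y - cy; yn <- yn - cy
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12          # integral of x^2 dA
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  m <- matrix(c(ixx, ixy, ixy, iyy), 2) / a
  e <- eigen(m, symmetric = TRUE)
  l <- e$values
  mag <- 100 * (l[1] - l[2]) / (l[1] + l[2])
  v <- e$vectors[, 1]
  list(magnitude = mag, axis_deg = (atan2(v[2], v[1]) * 180 / pi) %% 180)
}

#' Polygon-class distribution
#'
#' Histogram of neighbor numbers (cell sidedness) over a field, the classic
#' epithelial-topology readout.  Boundary-clipped cells are excluded.
#'
#' @param field A `fov` object (see [generate_field()]), or a list of
#'   polygons.
#' @param classes Neighbor numbers to tabulate; larger counts are pooled
#'   into the last class.
#' @param tol Edge-snapping tolerance passed to [polygon_adjacency()].
#' @return Data frame with `class`, `count`, `proportion`.
#' @export
polygon_class_distribution <- function(field, classes = 4:8, tol = 0.1) {
  polys <- if (inherits(field, "fov")) field$polygons else field
  adj <- polygon_adjacency(polys, tol = tol)
  nc <- attr(adj, "neighbor_count")
  keep <- rep(TRUE, length(polys))
  if (inherits(field, "fov")) keep <- !field$cells$boundary
  nc <- nc[keep]
  ncp <- pmin(pmax(nc, min(classes)), max(classes))
  count <- vapply(classes, function(k) sum(ncp == k), integer(1))
  data.frame(class = classes, count = count,
             proportion = if (sum(count)) count / sum(count) else 0 * count)
}

#' Cell packing density
#'
#' Number of cells whose centroid lies within the field bounds, normalized
#' to a stated reference area.
#'
#' @param field A `fov` object.
#' @param reference_area Reference area in um^2 (default the 1200 um^2
#'   field-of-view convention).
#' @return Cells per `reference_area`.
#' @export
cell_density <- function(field, reference_area = 1200) {
  b <- field$bounds
  area <- (b[2] - b[1]) * (b[4] - b[3])
  if (area <= 0) stop("zero field area", call. = FALSE)
  cx <- field$cells$cx; cy <- field$cells$cy
  n_in <- sum(cx >= b[1] & cx <= b[2] & cy >= b[3] & cy <= b[4])
  n_in / area * reference_area
}

#' Proliferation rate
#'
#' Mitotic cells as a percentage of all cells in the field.
#'
#' @param field A `fov` object.
#' @return Percent in \[0, 100\].
#' @export
proliferation_rate <- function(field) {
  n <- nrow(field$cells)
  if (n == 0) stop("empty field", call. = FALSE)
  100 * length(field$mitotic_ids) / n
}

#' Tissue thickness from a cross-sectional mask
#'
#' Thickness measured as foreground area normalized to lateral extent:
#' `sum(mask) * px^2 / (ncol(mask) * px)`.  Rows are the apical-basal (z)
#' direction, columns the lateral direction.
#'
#' @param mask Logical or 0/1 matrix (an XZ or sagittal section).
#' @param px_size Pixel size in um.
#' @return Mean thickness in um.
#' @examples
#' tissue_thickness(matrix(1, 20, 100), px_size = 0.5)  # 10 um band
#' @export
tissue_thickness <- function(mask, px_size) {
  m <- as.matrix(mask)
  if (!length(m) || ncol(m) == 0) stop("empty mask", call. = FALSE)
  fg <- sum(m != 0)
  if (fg == 0) stop("empty mask: no foreground", call. = FALSE)
  fg * px_size^2 / (ncol(m) * px_size)
}

#' Axial difference between two orientations
#'
#' Smallest angle between two axes (period 180 degrees), in \[0, 90\].
#'
#' @param a,b Orientations in degrees.
#' @return Axial difference in degrees.
#' @export
axial_difference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Long-axis-rule alignment between interphase shape and division
#'
#' For each division event matched to the mother's interphase shape,
#' computes the axial difference between the in-plane division axis and the
#' longest planar axis (reported for planar divisions, where the in-plane
#' axis is well defined), the per-category height:width means, and the
#' Spearman rank correlation between H:W and division angle (one-sided:
#' taller-than-wide cells are expected to divide more perpendicularly).
#'
#' @param events Data frame of division events with columns `mother_id`,
#'   `angle_deg`, `category`, `xy_axis_deg` (see [analyze_divisions()]).
#' @param shapes Data frame with `cell_id`, `height`, and either a `polygon`
#'   list-column or precomputed `width`/`axis_deg` columns.
#' @return List: `per_event` data frame (`mother_id`, `angle_deg`,
#'   `category`, `hw_ratio`, `delta_xy_deg`), `hw_by_category`,
#'   `mean_delta_xy_planar`, `spearman_rho`, `spearman_p` (one-sided),
#'   `n_unmatched`.
#' @export
hertwig_alignment <- function(events, shapes) {
  if (!is.null(shapes$polygon) && is.null(shapes$width)) {
    ax <- lapply(shapes$polygon, longest_planar_axis, validate = FALSE)
    shapes$width <- vapply(ax, `[[`, numeric(1), "length")
    shapes$axis_deg <- vapply(ax, `[[`, numeric(1), "orientation_deg")
  }
  idx <- match(events$mother_id, shapes$cell_id)
  n_unmatched <- sum(is.na(idx))
  if (n_unmatched > 0)
    warning(sprintf("%d event(s) without a matching interphase shape, skipped",
                    n_unmatched))
  ok <- !is.na(idx)
  ev <- events[ok, , drop = FALSE]
  sh <- shapes[idx[ok], , drop = FALSE]
  per_event <- data.frame(
    mother_id = ev$mother_id,
    angle_deg = ev$angle_deg,
    category = ev$category,
    hw_ratio = sh$height / sh$width,
    delta_xy_deg = axial_difference(ev$xy_axis_deg, sh$axis_deg),
    stringsAsFactors = FALSE
  )
  hw_by_category <- tapply(per_event$hw_ratio,
                           factor(per_event$category,
                                  levels = c("planar", "oblique", "perpendicular")),
                           mean)
  planar <- per_event$category == "planar"
  mean_dxy <- if (any(planar)) mean(per_event$delta_xy_deg[planar]) else NA_real_
  if (nrow(per_event) >= 3 && stats::sd(per_event$hw_ratio) > 0 &&
      stats::sd(per_event$angle_deg) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(per_event$hw_ratio, per_event$angle_deg,
                      method = "spearman", alternative = "greater"))
    rho <- unname(ct$estimate); pv <- ct$p.value
  } else {
    rho <- NA_real_; pv <- NA_real_
  }
  list(per_event = per_event,
       hw_by_category = hw_by_category,
       mean_delta_xy_planar = mean_dxy,
       spearman_rho = rho, spearman_p = pv,
       n_unmatched = n_unmatched)
}
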