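#' Bounded Voronoi tessellation with optional Lloyd relaxation
#'
#' Tessellates a rectangle around a set of seed points, clipping every tile
#' to the rectangle.  With `lloyd > 0`, seed points are iteratively replaced
#' by their tile centroids (centroidal Voronoi relaxation), which regularizes
#' the packing toward the hexagon-dominated polygon-class distributions seen
#' in epithelia.
#'
#' @param points Two-column matrix of seed coordinates (um).
#' @param bounds Numeric length-4 rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param lloyd Number of Lloyd iterations (non-negative integer).
#' @return List with `polygons` (list of two-column vertex matrices, one per
#'   input point, in input order), `points` (the possibly relaxed seed
#'   coordinates) and `bounds`.
#' @examples
#' set.seed(1)
#' v <- bounded_voronoi(cbind(runif(20, 0, 30), runif(20, 0, 30)),
#'                      c(0, 30, 0, 30), lloyd = 2)
#' length(v$polygons)
#' @export
bounded_voronoi <- function(points, bounds, lloyd = 0) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 2, length(bounds) == 4,
            bounds[2] > bounds[1], bounds[4] > bounds[3])
  polys_of <- function(pts) {
    dd <- deldir::deldir(pts[, 1], pts[, 2], rw = bounds, suppressMsge = TRUE)
    assemble_tiles(dd, pts, bounds)
  }
  for (i in seq_len(lloyd)) {
    polys <- polys_of(points)
    points <- t(vapply(polys, polygon_centroid, numeric(2)))
  }
  list(polygons = polys_of(points), points = points, bounds = bounds)
}

# Build clipped Voronoi tile polygons from deldir's segment table.  Tiles
# are convex, so vertices sort angularly around their seed.  Rectangle
# corners belong to the tile of the nearest seed.
assemble_tiles <- function(dd, pts, bounds) {
  n <- nrow(pts)
  s <- dd$dirsgs
  tile <- c(s$ind1, s$ind1, s$ind2, s$ind2)
  vx <- c(s$x1, s$x2, s$x1, s$x2)
  vy <- c(s$y1, s$y2, s$y1, s$y2)
  corner_x <- bounds[c(1, 2, 1, 2)]
  corner_y <- bounds[c(3, 3, 4, 4)]
  for (k in 1:4) {
    d2 <- (pts[, 1] - corner_x[k])^2 + (pts[, 2] - corner_y[k])^2
    i <- which.min(d2)
    tile <- c(tile, i); vx <- c(vx, corner_x[k]); vy <- c(vy, corner_y[k])
  }
  o <- order(tile)
  tile <- tile[o]; vx <- vx[o]; vy <- vy[o]
  starts <- c(which(c(TRUE, tile[-1] != tile[-length(tile)])), length(tile) + 1L)
  polys <- vector("list", n)
  for (g in seq_len(length(starts) - 1L)) {
    idx <- starts[g]:(starts[g + 1L] - 1L)
    i <- tile[starts[g]]
    x <- vx[idx]; y <- vy[idx]
    key <- paste(round(x, 9), round(y, 9))
    keep <- !duplicated(key)
    x <- x[keep]; y <- y[keep]
    ang <- atan2(y - pts[i, 2], x - pts[i, 1])
    oo <- order(ang)
    polys[[i]] <- cbind(x = x[oo], y = y[oo])
  }
  polys
}

#' Cell adjacency from shared polygon edges
#'
#' Two cells are neighbors when their polygons share at least two vertices
#' after snapping coordinates to a tolerance grid, i.e. when they share an
#' edge.  Works both on exact Voronoi output and on segmented outlines with
#' small coordinate mismatch.
#'
#' @param polygons List of two-column vertex matrices.
#' @param tol Snapping tolerance (um); vertices closer than this are merged.
#' @return Integer matrix with columns `i`, `j` (i < j), one row per
#'   neighboring pair, plus a `neighbor_count` attribute (per-polygon counts).
#' @export
polygon_adjacency <- function(polygons, tol = 0.1) {
  n <- length(polygons)
  keys <- lapply(polygons, function(p) {
    unique(paste(round(p[, 1] / tol), round(p[, 2] / tol)))
  })
  vert <- data.frame(
    key = unlist(keys, use.names = FALSE),
    cell = rep.int(seq_len(n), lengths(keys)),
    stringsAsFactors = FALSE
  )
  pairs <- matrix(integer(0), ncol = 2)
  by_key <- split(vert$cell, vert$key)
  shared <- by_key[lengths(by_key) > 1]
  if (length(shared)) {
    pr <- do.call(rbind, lapply(shared, function(cells) {
      cells <- sort(unique(cells))
      if (length(cells) < 2) return(NULL)
      t(utils::combn(cells, 2))
    }))
    if (!is.null(pr) && nrow(pr)) {
      key2 <- paste(pr[, 1], pr[, 2])
      cnt <- table(key2)
      keep <- names(cnt)[cnt >= 2]
      if (length(keep)) {
        sp <- do.call(rbind, strsplit(keep, " "))
        pairs <- cbind(i = as.integer(sp[, 1]), j = as.integer(sp[, 2]))
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      }
    }
  }
  nc <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n)
  structure(pairs, neighbor_count = nc)
}

# Cells with a vertex on the bounding rectangle (within tol): their polygons
# are clipped, so shape statistics exclude them.
boundary_cells <- function(polygons, bounds, tol = 1e-6) {
  vapply(polygons, function(p) {
    any(p[, 1] < bounds[1] + tol | p[, 1] > bounds[2] - tol |
        p[, 2] < bounds[3] + tol | p[, 2] > bounds[4] - tol)
  }, logical(1))
}
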