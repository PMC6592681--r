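#' @title File formats
#' @description Plain-text interchange: tracks and division tables as CSV,
#'   cell polygons as JSON vertex tables, configurations as YAML, reports
#'   as JSON.  All lengths are um, times minutes, angles degrees; the image
#'   convention is y-down with origin at the top-left, matching label-mask
#'   practice.
#' @name io
NULL

TRACK_COLUMNS <- c("field_id", "cell_id", "frame", "t_min",
                   "x_um", "y_um", "z_um", "is_mitotic", "mother_id")

#' Write / read a nuclear track table
#'
#' @param tracks Data frame in the schema of [emit_tracks()].
#' @param path CSV path.
#' @return `read_tracks_csv` returns the track data frame.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(all(TRACK_COLUMNS %in% names(tracks)))
  utils::write.csv(tracks[, TRACK_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path))
    stop("tracks file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "character",
                                       mother_id = "character"))
  missing <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing))
    stop("tracks file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df$mother_id[is.na(df$mother_id)] <- ""
  df
}

#' Write / read a division-event table
#' @param events Data frame of division events (truth or analyzed).
#' @param path CSV path.
#' @export
write_divisions_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_divisions_csv
#' @export
read_divisions_csv <- function(path) {
  if (!file.exists(path))
    stop("divisions file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read cell polygons as a JSON vertex table
#'
#' One record per cell: `cell_id`, `height_um`, `vertices` (n x 2 array of
#' basal-plane um coordinates).
#'
#' @param field A `fov` object, or a list with `polygons` and `cells`.
#' @param path JSON path.
#' @return `read_polygons_json` returns a list with `polygons` (named list
#'   of matrices) and `heights` (named numeric).
#' @export
write_polygons_json <- function(field, path) {
  recs <- lapply(seq_along(field$polygons), function(i) {
    list(cell_id = field$cells$cell_id[i],
         height_um = field$cells$height[i],
         vertices = unname(field$polygons[[i]]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_json
#' @export
read_polygons_json <- function(path) {
  if (!file.exists(path))
    stop("polygons file not found: ", path, call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  polys <- lapply(recs, function(r) {
    v <- r$vertices
    if (is.list(v)) v <- do.call(rbind, v)
    matrix(as.numeric(v), ncol = 2,
           dimnames = list(NULL, c("x", "y")))
  })
  names(polys) <- vapply(recs, `[[`, character(1), "cell_id")
  heights <- vapply(recs, function(r) as.numeric(r$height_um), numeric(1))
  names(heights) <- names(polys)
  list(polygons = polys, heights = heights)
}

#' Write / read a simulation or pipeline configuration as YAML
#'
#' Files carry a `schema` tag (`epistrat-config/1`).
#'
#' @param config A [sim_config()] or pipeline configuration list.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  obj$angle_mixture <- as.list(obj$angle_mixture)
  obj$fate_given_angle <- as.list(obj$fate_given_angle)
  yaml::write_yaml(c(list(schema = "epistrat-config/1"), obj), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema, "epistrat-config/1"))
    stop("unrecognized config schema in ", path, call. = FALSE)
  obj$schema <- NULL
  obj$angle_mixture <- unlist(obj$angle_mixture)
  obj$fate_given_angle <- unlist(obj$fate_given_angle)
  do.call(sim_config, obj)
}

#' Validate a track table
#'
#' Checks the schema, strictly increasing frames per cell, finite
#' coordinates, positive frame interval and lineage consistency (a mother's
#' track must end before her daughters' begin).  Violations are returned,
#' not raised.
#'
#' @param tracks Track data frame or CSV path.
#' @return Data frame of violations with columns `type`, `cell_id`,
#'   `detail`; zero rows when the table is clean.
#' @export
validate_tracks <- function(tracks) {
  if (is.character(tracks)) tracks <- read_tracks_csv(tracks)
  v <- list()
  add <- function(type, cell_id, detail)
    v[[length(v) + 1]] <<- data.frame(type = type, cell_id = cell_id,
                                      detail = detail, stringsAsFactors = FALSE)
  missing <- setdiff(TRACK_COLUMNS, names(tracks))
  if (length(missing)) {
    add("schema", NA_character_,
        paste("missing columns:", paste(missing, collapse = ", ")))
    return(do.call(rbind, v))
  }
  for (col in c("x_um", "y_um", "z_um")) {
    bad <- !is.finite(tracks[[col]])
    if (any(bad))
      add("non_finite", paste(unique(tracks$cell_id[bad]), collapse = ","),
          sprintf("%d non-finite %s value(s)", sum(bad), col))
  }
  by_cell <- split(tracks$frame, tracks$cell_id)
  for (id in names(by_cell)) {
    f <- by_cell[[id]]
    if (any(diff(sort(f)) == 0))
      add("frame_monotonicity", id, "duplicated frame")
    else if (is.unsorted(f))
      add("frame_monotonicity", id, "frames not in increasing order")
  }
  has_mother <- !is.na(tracks$mother_id) & tracks$mother_id != ""
  if (any(has_mother)) {
    first_frame <- tapply(tracks$frame, tracks$cell_id, min)
    last_frame <- tapply(tracks$frame, tracks$cell_id, max)
    dpairs <- unique(tracks[has_mother, c("cell_id", "mother_id")])
    for (r in seq_len(nrow(dpairs))) {
      mid <- dpairs$mother_id[r]
      if (!mid %in% names(last_frame)) {
        add("lineage", dpairs$cell_id[r], sprintf("mother '%s' has no track", mid))
      } else if (last_frame[[mid]] >= first_frame[[dpairs$cell_id[r]]]) {
        add("lineage", dpairs$cell_id[r],
            sprintf("daughter starts at frame %d but mother '%s' persists to %d",
                    first_frame[[dpairs$cell_id[r]]], mid, last_frame[[mid]]))
      }
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(type = character(), cell_id = character(),
                  detail = character(), stringsAsFactors = FALSE)
}

#' Render a field as a label mask
#'
#' Rasterizes cell polygons into an integer label matrix (0 = background,
#' cell i = i), y-down with the origin at the top-left.  With the `tiff`
#' package the mask can be written as a 16-bit TIFF via
#' [write_label_mask_tiff()].
#'
#' @param field A `fov` object.
#' @param um_per_px Pixel size (um).
#' @return Integer matrix (rows = y, columns = x).
#' @export
render_label_mask <- function(field, um_per_px = 0.5) {
  b <- field$bounds
  nx <- ceiling((b[2] - b[1]) / um_per_px)
  ny <- ceiling((b[4] - b[3]) / um_per_px)
  px <- b[1] + (seq_len(nx) - 0.5) * um_per_px
  py <- b[3] + (seq_len(ny) - 0.5) * um_per_px
  mask <- matrix(0L, nrow = ny, ncol = nx)
  for (i in seq_along(field$polygons)) {
    p <- field$polygons[[i]]
    xr <- range(p[, 1]); yr <- range(p[, 2])
    cx <- which(px >= xr[1] & px <= xr[2])
    cy <- which(py >= yr[1] & py <= yr[2])
    if (!length(cx) || !length(cy)) next
    gx <- rep(px[cx], each = length(cy))
    gy <- rep(py[cy], times = length(cx))
    inside <- point_in_polygon(gx, gy, p)
    sel <- matrix(inside, nrow = length(cy))
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx)) {
      # y-down: image row 1 is the top of the field
      mask[cbind(ny + 1L - cy[idx[, 1]], cx[idx[, 2]])] <- i
    }
  }
  mask
}

# even-odd ray casting; boundary pixels resolve by strict crossing
point_in_polygon <- function(x, y, p) {
  n <- nrow(p)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @rdname render_label_mask
#' @param mask Integer label matrix.
#' @param path TIFF path.
#' @export
write_label_mask_tiff <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF masks", call. = FALSE)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname render_label_mask
#' @export
read_label_mask_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF masks", call. = FALSE)
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- tiff::readTIFF(path)
  round(m * 65535)
}

#' Label-mask centroids
#'
#' Centroids of each label as pixel means, returned in um in the y-up
#' basal-plane convention.
#'
#' @param mask Integer label matrix (y-down).
#' @param um_per_px Pixel size (um).
#' @return Data frame with `label`, `cx`, `cy`, `n_px`.
#' @export
mask_cell_centroids <- function(mask, um_per_px = 0.5) {
  labs <- sort(unique(mask[mask > 0]))
  ny <- nrow(mask)
  out <- lapply(labs, function(l) {
    idx <- which(mask == l, arr.ind = TRUE)
    data.frame(label = l,
               cx = (mean(idx[, 2]) - 0.5) * um_per_px,
               cy = (ny - mean(idx[, 1]) + 0.5) * um_per_px,
               n_px = nrow(idx))
  })
  do.call(rbind, out)
}

#' Extract cell outlines from a label mask
#'
#' Outer contours of each label, converted to um polygons (y-up).  Requires
#' the `EBImage` package.
#'
#' @param mask Integer label matrix (y-down).
#' @param um_per_px Pixel size (um).
#' @return Named list of polygon matrices.
#' @export
polygons_from_mask <- function(mask, um_per_px = 0.5) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("the 'EBImage' package is required to extract mask contours",
         call. = FALSE)
  ny <- nrow(mask)
  oc <- EBImage::ocontour(EBImage::Image(t(mask)))
  polys <- lapply(oc, function(ct) {
    cbind(x = (ct[, 1] + 0.5) * um_per_px,
          y = (ny - ct[, 2] - 0.5) * um_per_px)
  })
  names(polys) <- paste0("label", seq_along(polys))
  polys
}
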