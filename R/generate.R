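#' @title Synthetic basal-layer generator
#' @description Generates virtual fields of view of an embryonic basal
#'   layer with known ground truth: Lloyd-relaxed bounded Voronoi cell
#'   packing, nuclear tracks at a fixed frame interval, division events
#'   whose elevation angles follow either a configured category mixture or
#'   the cell's own 3D long axis, positional fates coupled to the angle,
#'   and junctional intensities carrying a configurable nematic polarity.
#'   Every stage of the analysis pipeline can be checked by parameter
#'   recovery against the emitted ground truth.
#' @name synthetic_data
NULL

reflect_into_0_90 <- function(a) {
  a <- abs(a) %% 180
  ifelse(a > 90, 180 - a, a)
}

category_bounds <- list(planar = c(0, 20), oblique = c(20, 70),
                        perpendicular = c(70, 90))

sample_within_bin <- function(cat_idx, within_bin) {
  lo <- c(0, 20, 70)[cat_idx]
  hi <- c(20, 70, 90)[cat_idx]
  u <- stats::runif(length(cat_idx))
  if (within_bin == "uniform") {
    lo + u * (hi - lo)
  } else {
    # density proportional to sin(theta) within the bin (3D-isotropic)
    cl <- cos(lo * pi / 180); ch <- cos(hi * pi / 180)
    acos(cl - u * (cl - ch)) * 180 / pi
  }
}

#' Sample division elevation angles
#'
#' Mixture mode draws a category from `config$angle_mixture` and an angle
#' within the category bin (planar \[0, 20\], oblique (20, 70\],
#' perpendicular (70, 90\]) under the configured within-bin law.  Hertwig
#' mode takes each cell's 3D long-axis elevation (90 degrees when the cell
#' is taller than its longest planar chord, 0 otherwise) plus Gaussian
#' noise of SD `config$hertwig_noise_sd`, reflected into \[0, 90\]; the
#' in-plane division axis follows the longest-planar-axis orientation with
#' the same noise.
#'
#' Draws come from the current RNG state; seed externally (or via
#' [generate_field()], which manages seeding) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param n Number of draws (ignored in hertwig mode, where one angle per
#'   row of `long_axes` is drawn).
#' @param long_axes Data frame with `elevation_deg` and `xy_deg` (required
#'   in hertwig mode).
#' @return Data frame with `angle_deg`, `category`, `xy_axis_deg`.
#' @export
sample_division_angles <- function(config, n = 1, long_axes = NULL) {
  if (config$hertwig_mode) {
    if (is.null(long_axes))
      stop("hertwig mode requires long_axes (elevation_deg, xy_deg)",
           call. = FALSE)
    m <- nrow(long_axes)
    ang <- reflect_into_0_90(long_axes$elevation_deg +
                               stats::rnorm(m, 0, config$hertwig_noise_sd))
    xy <- (long_axes$xy_deg + stats::rnorm(m, 0, config$hertwig_noise_sd)) %% 180
  } else {
    cat_idx <- sample.int(3, n, replace = TRUE, prob = config$angle_mixture)
    ang <- sample_within_bin(cat_idx, config$within_bin)
    xy <- stats::runif(n, 0, 180)
  }
  data.frame(angle_deg = ang, category = classify_angle(ang),
             xy_axis_deg = xy, stringsAsFactors = FALSE)
}

rtruncnorm_pos <- function(n, mean, sd, lower = 1) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic basal-layer field of view
#'
#' Cells are a Lloyd-relaxed Voronoi tessellation of uniform points at the
#' target density, clipped to the field rectangle.  Heights are drawn from
#' a truncated normal law.  Division events (mother cells, frames, true
#' angles, in-plane axes and fates) are sampled according to the
#' configuration, and per-cell polarity axes are jittered around the tissue
#' axis.  All randomness flows from `config$seed`; identical configurations
#' reproduce identical output.
#'
#' @param config A [sim_config()].
#' @return List with `field` (class `fov`: `field_id`, `bounds`,
#'   `polygons`, `cells` data frame, `mitotic_ids`) and `truth` (ground
#'   truth: `cells`, `divisions`, `tissue_polarity`).  `truth$divisions`
#'   records the true angle, category, fate and in-plane axis of every
#'   event; `truth$cells` records per-cell height, area, longest chord,
#'   elongation nematic and polarity (nematic scale m/2 at the jittered
#'   per-cell axis).
#' @examples
#' sim <- generate_field(sim_config(field_width = 40, field_height = 30,
#'                                  n_divisions = 5, seed = 3))
#' nrow(sim$field$cells)
#' @export
generate_field <- function(config) {
  validate_sim_config(config)
  area <- config$field_width * config$field_height
  n <- round(config$target_density * area / 100)
  if (n < 3) stop("invalid-config: fewer than 3 cells at this density",
                  call. = FALSE)
  w_frames <- round(90 / config$frame_interval)
  if (config$n_divisions > 0 && config$n_frames - w_frames < 2)
    stop("invalid-config: movie too short for the 1.5-h fate window",
         call. = FALSE)
  if (config$n_divisions > n)
    stop("invalid-config: more divisions than cells", call. = FALSE)
  bounds <- c(0, config$field_width, 0, config$field_height)
  withr::with_seed(config$seed, {
    pts <- cbind(stats::runif(n, bounds[1], bounds[2]),
                 stats::runif(n, bounds[3], bounds[4]))
    vor <- bounded_voronoi(pts, bounds, lloyd = config$lloyd_iterations)
    polys <- vor$polygons
    ids <- sprintf("c%04d", seq_len(n))
    names(polys) <- ids
    heights <- rtruncnorm_pos(n, config$height_mean, config$height_sd)
    cent <- t(vapply(polys, polygon_centroid, numeric(2)))
    areas <- vapply(polys, polygon_area, numeric(1), validate = FALSE)
    chords <- lapply(polys, longest_planar_axis, validate = FALSE)
    width <- vapply(chords, `[[`, numeric(1), "length")
    chord_axis <- vapply(chords, `[[`, numeric(1), "orientation_deg")
    elong <- lapply(polys, elongation_nematic, validate = FALSE)
    adj <- polygon_adjacency(polys, tol = 1e-6)
    pol_axis <- (config$polarity_axis +
                   stats::rnorm(n, 0, config$polarity_axis_noise_sd)) %% 180
    cells <- data.frame(
      cell_id = ids,
      cx = cent[, 1], cy = cent[, 2],
      height = heights,
      area = areas,
      width = width,
      axis_deg = chord_axis,
      elongation = vapply(elong, `[[`, numeric(1), "magnitude"),
      elongation_axis_deg = vapply(elong, `[[`, numeric(1), "axis_deg"),
      neighbor_count = attr(adj, "neighbor_count"),
      boundary = boundary_cells(polys, bounds),
      polarity_axis_deg = pol_axis,
      stringsAsFactors = FALSE
    )
    # division events
    nd <- config$n_divisions
    if (nd > 0) {
      mothers <- sort(sample(ids, nd))
      mrow <- match(mothers, ids)
      frames <- sample(seq(2L, config$n_frames - w_frames), nd, replace = TRUE)
      draws <- sample_division_angles(
        config, n = nd,
        long_axes = data.frame(
          elevation_deg = ifelse(heights[mrow] > width[mrow], 90, 0),
          xy_deg = chord_axis[mrow]))
      p_sym <- config$fate_given_angle[match(draws$category,
                                             c("planar", "oblique", "perpendicular"))]
      sym <- stats::runif(nd) < p_sym
      divisions <- data.frame(
        mother_id = mothers,
        daughter_a_id = paste0(mothers, "a"),
        daughter_b_id = paste0(mothers, "b"),
        division_frame = as.integer(frames),
        angle_deg = draws$angle_deg,
        category = draws$category,
        xy_axis_deg = draws$xy_axis_deg,
        fate = ifelse(sym, "symmetric", "asymmetric"),
        stringsAsFactors = FALSE
      )
    } else {
      divisions <- data.frame(mother_id = character(),
                              daughter_a_id = character(),
                              daughter_b_id = character(),
                              division_frame = integer(),
                              angle_deg = numeric(), category = character(),
                              xy_axis_deg = numeric(), fate = character(),
                              stringsAsFactors = FALSE)
    }
    field <- structure(list(field_id = config$field_id, bounds = bounds,
                            polygons = polys, cells = cells,
                            mitotic_ids = divisions$mother_id),
                       class = "fov")
    m2 <- config$polarity_magnitude / 2  # nematic scale of the Fourier-2 estimator
    ztis <- mean(m2 * exp(2i * cells$polarity_axis_deg * pi / 180))
    truth <- list(
      cells = cbind(cells[, c("cell_id", "height", "area", "width",
                              "axis_deg", "elongation",
                              "elongation_axis_deg", "neighbor_count",
                              "boundary", "polarity_axis_deg")],
                    polarity_nematic = m2),
      divisions = divisions,
      tissue_polarity = list(magnitude = Mod(ztis),
                             axis_deg = (Arg(ztis) / 2 * 180 / pi) %% 180)
    )
    list(field = field, truth = truth)
  })
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov '%s'> %d cells in %g x %g um, %d mitotic\n",
              x$field_id, nrow(x$cells), x$bounds[2] - x$bounds[1],
              x$bounds[4] - x$bounds[3], length(x$mitotic_ids)))
  invisible(x)
}

# Stationary AR(1) noise, one column per track (rows = frames).
ar1_noise_matrix <- function(n_frames, n_tracks, sd, rho) {
  if (sd == 0 || n_frames == 0 || n_tracks == 0)
    return(matrix(0, n_frames, n_tracks))
  innov <- matrix(stats::rnorm(n_frames * n_tracks, 0, sd * sqrt(1 - rho^2)),
                  n_frames, n_tracks)
  innov[1, ] <- stats::rnorm(n_tracks, 0, sd)
  e <- stats::filter(innov, rho, method = "recursive")
  matrix(as.numeric(e), n_frames, n_tracks)
}

#' Emit nuclear tracks for a synthetic field
#'
#' One row per nucleus per frame.  Mother tracks end at the division frame;
#' the two daughters begin the next frame, separated by
#' `config$daughter_separation` along the sampled 3D division axis (the
#' pair is shifted up as needed to keep both nuclei above the basement
#' membrane without distorting the angle).  Basal daughters relax to the
#' basal nuclear plane by the second post-division frame; the suprabasal
#' daughter of an asymmetric division crosses the basal threshold within 3
#' frames and plateaus at `config$z_suprabasal` through the rest of the
#' movie.  z-jitter is AR(1) with stationary SD `config$z_noise_sd`.  A
#' perpendicular-leaning symmetric division can place one daughter
#' transiently above the threshold at the telophase frame; the analyzer's
#' persistence rule is designed to score these correctly.
#'
#' @param field A `fov` from [generate_field()].
#' @param divisions Ground-truth division table
#'   (`generate_field(...)$truth$divisions`).
#' @param config The same [sim_config()].
#' @return Data frame with columns `field_id`, `cell_id`, `frame`, `t_min`,
#'   `x_um`, `y_um`, `z_um`, `is_mitotic`, `mother_id`.
#' @export
emit_tracks <- function(field, divisions, config) {
  w_frames <- round(90 / config$frame_interval)
  if (nrow(divisions) &&
      (any(divisions$division_frame < 1) ||
       any(divisions$division_frame > config$n_frames - w_frames)))
    stop(sprintf("division frame outside [1, %d]: the %g-min fate window must fit",
                 config$n_frames - w_frames, w_frames * config$frame_interval),
         call. = FALSE)
  if (nrow(divisions) && !all(divisions$mother_id %in% field$cells$cell_id))
    stop("divisions reference cells not in the field", call. = FALSE)
  nf <- config$n_frames
  nc <- nrow(field$cells)
  nd <- nrow(divisions)
  div_at <- divisions$division_frame[match(field$cells$cell_id,
                                           divisions$mother_id)]
  withr::with_seed(config$seed + 1L, {
    # --- resident cells (mothers end at their division frame)
    last <- ifelse(is.na(div_at), nf, div_at)
    xn <- matrix(stats::rnorm(nf * nc, 0, config$xy_noise_sd), nf, nc)
    yn <- matrix(stats::rnorm(nf * nc, 0, config$xy_noise_sd), nf, nc)
    zn <- ar1_noise_matrix(nf, nc, config$z_noise_sd, config$z_noise_rho)
    ci <- rep.int(seq_len(nc), last)
    fr <- sequence(last)
    at <- cbind(fr, ci)
    cell_part <- list(
      cell_id = field$cells$cell_id[ci], frame = fr,
      x_um = field$cells$cx[ci] + xn[at],
      y_um = field$cells$cy[ci] + yn[at],
      z_um = pmax(config$z_basal_mean + zn[at], 0.1),
      is_mitotic = !is.na(div_at[ci]) & fr == last[ci],
      mother_id = rep("", length(ci))
    )
    # --- daughters: two tracks per division, frames d+1 .. n_frames
    if (nd > 0) {
      i <- match(divisions$mother_id, field$cells$cell_id)
      theta <- divisions$angle_deg * pi / 180
      phi <- divisions$xy_axis_deg * pi / 180
      half <- config$daughter_separation / 2
      ox <- half * cos(theta) * cos(phi)
      oy <- half * cos(theta) * sin(phi)
      oz <- half * sin(theta)
      center_z <- pmax(config$z_basal_mean, 0.2 + abs(oz))
      # daughter "b" (the +z side) is the suprabasal one in asymmetric events
      dj <- rep(seq_len(nd), each = 2)           # division per daughter track
      sgn <- rep(c(-1, 1), nd)
      did <- as.vector(rbind(divisions$daughter_a_id, divisions$daughter_b_id))
      supra <- divisions$fate[dj] == "asymmetric" & sgn == 1
      ntr <- 2L * nd
      klen <- nf - divisions$division_frame[dj]
      xn2 <- matrix(stats::rnorm(nf * ntr, 0, config$xy_noise_sd), nf, ntr)
      yn2 <- matrix(stats::rnorm(nf * ntr, 0, config$xy_noise_sd), nf, ntr)
      zn2 <- ar1_noise_matrix(nf, ntr, config$z_noise_sd, config$z_noise_rho)
      ti <- rep.int(seq_len(ntr), klen)          # track index per row
      step <- sequence(klen)                     # frames past division
      fr2 <- divisions$division_frame[dj][ti] + step
      z0 <- center_z[dj] + sgn * oz[dj]
      zb <- ifelse(step == 1L, z0[ti],
            ifelse(supra[ti],
                   ifelse(step == 2L, (z0[ti] + config$z_suprabasal) / 2,
                          config$z_suprabasal),
                   config$z_basal_mean))
      at2 <- cbind(step, ti)
      dtr_part <- list(
        cell_id = did[ti], frame = fr2,
        x_um = field$cells$cx[i[dj]][ti] + (sgn * ox[dj])[ti] + xn2[at2],
        y_um = field$cells$cy[i[dj]][ti] + (sgn * oy[dj])[ti] + yn2[at2],
        z_um = pmax(zb + zn2[at2], 0.1),
        is_mitotic = rep(FALSE, length(ti)),
        mother_id = divisions$mother_id[dj][ti]
      )
      parts <- Map(c, cell_part, dtr_part)
    } else {
      parts <- cell_part
    }
    out <- data.frame(field_id = field$field_id, cell_id = parts$cell_id,
                      frame = parts$frame,
                      t_min = (parts$frame - 1) * config$frame_interval,
                      x_um = parts$x_um, y_um = parts$y_um, z_um = parts$z_um,
                      is_mitotic = parts$is_mitotic,
                      mother_id = parts$mother_id,
                      stringsAsFactors = FALSE)
    out <- out[order(out$cell_id, out$frame), ]
    rownames(out) <- NULL
    out
  })
}

#' Emit polarized junctional intensity samples
#'
#' For each cell, boundary intensity is sampled along every polygon edge at
#' `config$edge_sample_spacing` intervals.  A sample at outward-normal
#' angle `phi` has intensity `baseline * (1 + m * cos 2(phi - phi_c))` plus
#' Gaussian noise, where `phi_c` is the cell's ground-truth polarity axis
#' and `m = config$polarity_magnitude`.  The intensity-weighted Fourier-2
#' nematic of this profile has magnitude `m/2` at axis `phi_c`, which is
#' what `truth$cells$polarity_nematic` records.
#'
#' @inheritParams emit_tracks
#' @return Data frame with `cell_id`, `normal_angle_deg`, `intensity`.
#' @export
emit_edge_intensities <- function(field, config) {
  m <- config$polarity_magnitude
  withr::with_seed(config$seed + 2L, {
    out <- lapply(seq_len(nrow(field$cells)), function(i) {
      p <- field$polygons[[i]]
      if (signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      nv <- nrow(p)
      nxt <- c(2:nv, 1)
      ex <- p[nxt, 1] - p[, 1]
      ey <- p[nxt, 2] - p[, 2]
      len <- sqrt(ex^2 + ey^2)
      # outward normal of a CCW polygon edge
      phi_n <- (atan2(-ex, ey) * 180 / pi) %% 180
      reps <- pmax(1L, floor(len / config$edge_sample_spacing))
      phi <- rep(phi_n, reps)
      phic <- field$cells$polarity_axis_deg[i]
      base <- config$edge_baseline *
        (1 + m * cos(2 * (phi - phic) * pi / 180))
      intensity <- pmax(base + stats::rnorm(length(phi), 0, config$edge_noise_sd), 0)
      data.frame(cell_id = field$cells$cell_id[i],
                 normal_angle_deg = phi, intensity = intensity,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  })
}

#' Run the full generator
#'
#' Convenience wrapper: [generate_field()], [emit_tracks()] and
#' [emit_edge_intensities()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `field`, `truth`, `tracks`, `edges`, `config`.
#' @export
simulate_experiment <- function(config) {
  sim <- generate_field(config)
  tracks <- emit_tracks(sim$field, sim$truth$divisions, config)
  edges <- emit_edge_intensities(sim$field, config)
  list(field = sim$field, truth = sim$truth, tracks = tracks, edges = edges,
       config = config)
}
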