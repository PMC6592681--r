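#' Simulation configuration for the synthetic basal layer
#'
#' Bundles every parameter of the synthetic-epithelium generator into a
#' validated object.  Defaults describe an E14.5-like wildtype basal layer:
#' roughly isometric cells (height about 6.9 um, mean cross-sectional area
#' about 35 um^2, so height:width near 0.9), a division-angle mixture of
#' 51% planar / 29% oblique / 20% perpendicular, strong coupling between
#' orientation and positional fate (94% of planar divisions symmetric, 11%
#' of perpendicular), and 10-minute frames.
#'
#' @param field_width,field_height Field-of-view dimensions (um).
#' @param target_density Cells per 100 um^2.  The generated cell count is
#'   `round(target_density * area / 100)`.
#' @param height_mean,height_sd Mean and SD of apical-basal cell height (um);
#'   heights are drawn from a normal law truncated at 1 um.
#' @param angle_mixture Length-3 non-negative weights (planar, oblique,
#'   perpendicular) summing to 1; used when `hertwig_mode = FALSE`.
#' @param within_bin Law for the angle within its category bin: `"uniform"`
#'   or `"sine"` (3D-isotropic, density proportional to sin of the angle;
#'   useful for null simulations).
#' @param fate_given_angle Length-3 probabilities of a *symmetric* fate given
#'   category (planar, oblique, perpendicular).
#' @param hertwig_mode If `TRUE`, division angles follow each cell's 3D long
#'   axis (long-axis rule) instead of the mixture: the angle is the long-axis
#'   elevation (0 when the longest planar chord exceeds the height, 90 when
#'   the cell is taller than wide) plus Gaussian noise of SD
#'   `hertwig_noise_sd`, reflected into \[0, 90\].
#' @param hertwig_noise_sd Angular noise SD (degrees) for hertwig mode,
#'   applied to both the elevation and the in-plane division axis.
#' @param frame_interval Minutes between frames.
#' @param n_frames Number of frames in the movie.
#' @param n_divisions Number of division events to generate (at most one per
#'   cell).
#' @param daughter_separation Distance between daughter nuclear centroids at
#'   the first post-division frame (um).  The paper-scale movies show
#'   telophase nuclei several microns apart; 8 um is a plausible default and
#'   is flagged as such (no measured value exists to pin it).
#' @param z_basal_mean Mean nuclear z of basal cells (um above the basement
#'   membrane, apical positive).
#' @param z_suprabasal Plateau z of a daughter that moves suprabasally (um).
#' @param basal_threshold z above which a nucleus counts as suprabasal (um).
#'   Shared convention between generator and analyzer.
#' @param z_noise_sd Stationary SD (um) of the AR(1) z-jitter added to every
#'   track.  Default 0.3 um, the centroid quantization implied by 1-um
#'   z-steps (step / sqrt(12)).
#' @param z_noise_rho Per-frame autocorrelation of the z-jitter.  Nuclear
#'   wobble is slow relative to a 10-min frame interval, so jitter is
#'   modelled as AR(1) rather than white noise.
#' @param xy_noise_sd SD (um) of independent per-frame xy jitter.
#' @param polarity_magnitude Modulation depth m in \[0, 1\] of junctional
#'   intensity: `baseline * (1 + m * cos 2(phi - axis))`.  Note the standard
#'   intensity-weighted Fourier nematic of this profile has magnitude m/2;
#'   ground truth records that nematic scale.
#' @param polarity_axis Tissue polarity axis phi0 (degrees in \[0, 180)).
#' @param polarity_axis_noise_sd Per-cell SD (degrees) of the cell polarity
#'   axis around `polarity_axis`.
#' @param edge_baseline Baseline junctional intensity (arbitrary units).
#' @param edge_noise_sd Additive Gaussian noise SD on each boundary sample.
#' @param edge_sample_spacing Spacing (um) of intensity samples along cell
#'   boundaries.
#' @param lloyd_iterations Lloyd (centroidal Voronoi) relaxation iterations
#'   applied to the cell packing.
#' @param field_id Identifier written into all emitted tables.
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$angle_mixture
#' @export
sim_config <- function(field_width = 100,
                       field_height = 75,
                       target_density = 2.87,
                       height_mean = 6.9,
                       height_sd = 1.5,
                       angle_mixture = c(planar = 0.51, oblique = 0.29, perpendicular = 0.20),
                       within_bin = c("uniform", "sine"),
                       fate_given_angle = c(planar = 0.94, oblique = 0.41, perpendicular = 0.11),
                       hertwig_mode = FALSE,
                       hertwig_noise_sd = 10,
                       frame_interval = 10,
                       n_frames = 48,
                       n_divisions = 40,
                       daughter_separation = 8,
                       z_basal_mean = 3,
                       z_suprabasal = 10,
                       basal_threshold = 5.5,
                       z_noise_sd = 0.3,
                       z_noise_rho = 0.7,
                       xy_noise_sd = 0.1,
                       polarity_magnitude = 0.5,
                       polarity_axis = 30,
                       polarity_axis_noise_sd = 10,
                       edge_baseline = 100,
                       edge_noise_sd = 5,
                       edge_sample_spacing = 0.75,
                       lloyd_iterations = 2,
                       field_id = "sim1",
                       seed = 1L) {
  within_bin <- match.arg(within_bin)
  cfg <- list(
    field_width = field_width, field_height = field_height,
    target_density = target_density,
    height_mean = height_mean, height_sd = height_sd,
    angle_mixture = angle_mixture, within_bin = within_bin,
    fate_given_angle = fate_given_angle,
    hertwig_mode = isTRUE(hertwig_mode), hertwig_noise_sd = hertwig_noise_sd,
    frame_interval = frame_interval, n_frames = n_frames,
    n_divisions = n_divisions, daughter_separation = daughter_separation,
    z_basal_mean = z_basal_mean, z_suprabasal = z_suprabasal,
    basal_threshold = basal_threshold,
    z_noise_sd = z_noise_sd, z_noise_rho = z_noise_rho,
    xy_noise_sd = xy_noise_sd,
    polarity_magnitude = polarity_magnitude, polarity_axis = polarity_axis,
    polarity_axis_noise_sd = polarity_axis_noise_sd,
    edge_baseline = edge_baseline, edge_noise_sd = edge_noise_sd,
    edge_sample_spacing = edge_sample_spacing,
    lloyd_iterations = lloyd_iterations,
    field_id = field_id, seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` object (or plain list with the same fields).
#' @export
validate_sim_config <- function(cfg) {
  stop_cfg <- function(...) stop("invalid-config: ", sprintf(...), call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$field_width) || cfg$field_width <= 0 ||
      !num1(cfg$field_height) || cfg$field_height <= 0)
    stop_cfg("field dimensions must be positive (got %s x %s)",
             format(cfg$field_width), format(cfg$field_height))
  if (!num1(cfg$target_density) || cfg$target_density <= 0)
    stop_cfg("target_density must be > 0")
  if (!num1(cfg$height_mean) || cfg$height_mean <= 0 || cfg$height_sd < 0)
    stop_cfg("height_mean must be > 0 and height_sd >= 0")
  w <- cfg$angle_mixture
  if (length(w) != 3L || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-8)
    stop_cfg("angle_mixture must be 3 non-negative weights summing to 1")
  p <- cfg$fate_given_angle
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_cfg("fate_given_angle must be 3 probabilities in [0,1]")
  if (!num1(cfg$frame_interval) || cfg$frame_interval <= 0)
    stop_cfg("frame_interval must be > 0")
  if (cfg$n_frames < 1 || cfg$n_divisions < 0)
    stop_cfg("n_frames must be >= 1 and n_divisions >= 0")
  if (!num1(cfg$daughter_separation) || cfg$daughter_separation <= 0)
    stop_cfg("daughter_separation must be > 0")
  if (!num1(cfg$polarity_magnitude) ||
      cfg$polarity_magnitude < 0 || cfg$polarity_magnitude > 1)
    stop_cfg("polarity_magnitude must be in [0,1]")
  if (!num1(cfg$polarity_axis) || cfg$polarity_axis < 0 || cfg$polarity_axis >= 180)
    stop_cfg("polarity_axis must be in [0,180)")
  if (cfg$basal_threshold <= cfg$z_basal_mean ||
      cfg$z_suprabasal <= cfg$basal_threshold)
    stop_cfg("need z_basal_mean < basal_threshold < z_suprabasal")
  if (abs(cfg$z_noise_rho) >= 1) stop_cfg("z_noise_rho must be in (-1,1)")
  if (!num1(cfg$seed) || is.na(cfg$seed) || abs(cfg$seed) >= 2^31 - 10)
    stop_cfg("seed must be a finite integer below 2^31 - 10")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field: %g x %g um, %g cells/100um^2 (~%d cells)\n",
              x$field_width, x$field_height, x$target_density,
              round(x$target_density * x$field_width * x$field_height / 100)))
  if (x$hertwig_mode) {
    cat(sprintf("  angles: hertwig mode, noise sd %g deg\n", x$hertwig_noise_sd))
  } else {
    cat(sprintf("  angles: mixture %.2f/%.2f/%.2f (%s within bin)\n",
                x$angle_mixture[1], x$angle_mixture[2], x$angle_mixture[3],
                x$within_bin))
  }
  cat(sprintf("  movie: %d frames x %g min, %d divisions\n",
              x$n_frames, x$frame_interval, x$n_divisions))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
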