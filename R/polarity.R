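#' @title Junctional planar-cell-polarity nematics
#' @description Planar-polarized junctional signal (e.g. a PCP protein
#'   enriched on opposite cell edges) is quantified per cell as a nematic
#'   order parameter via the intensity-weighted second Fourier mode of
#'   boundary intensity, and summarized at tissue level by averaging
#'   per-cell nematics in the angle-doubled complex plane (period 180
#'   degrees).
#' @name polarity
NULL

#' Per-cell polarity nematic
#'
#' For boundary samples with outward-normal angles `phi_k` and intensities
#' `I_k`, the complex nematic is `z = sum(I_k exp(2i phi_k)) / sum(I_k)`;
#' magnitude `|z|`, axis `arg(z)/2 mod 180`.  For an intensity profile
#' `baseline (1 + m cos 2(phi - phi0))` sampled uniformly, `|z| = m/2` and
#' the axis is `phi0`.
#'
#' @param boundary_samples Data frame with columns `normal_angle_deg` and
#'   `intensity` (>= 3 samples, non-negative intensities, positive total).
#' @param cell_id Optional identifier carried through.
#' @param method `"moment"` (default): the intensity-weighted Fourier
#'   moment above, the simple estimator used for rose plots.
#'   `"harmonic"`: per-cell least-squares fit of
#'   `I = c0 + c2c cos 2 phi + c2s sin 2 phi`, returning magnitude
#'   `sqrt(c2c^2 + c2s^2) / (2 c0)` at the fitted axis.  The moment
#'   estimator inherits a small bias from the cell's own boundary-normal
#'   anisotropy (its second/fourth shape modes); the harmonic fit accounts
#'   for the sampling design and is unbiased whenever the boundary carries
#'   at least three distinct normal directions, so it is preferred for
#'   quantitative magnitude comparisons.
#' @return List of class `polarity_measure`: `cell_id`, `magnitude`,
#'   `axis_deg` (in \[0, 180)), `weight` (total intensity), `n_samples`.
#' @examples
#' phi <- seq(0, 179, by = 1)
#' cell_polarity(data.frame(normal_angle_deg = phi,
#'                          intensity = 1 + cos(2 * (phi - 30) * pi / 180)))
#' @export
cell_polarity <- function(boundary_samples, cell_id = NA_character_,
                          method = c("moment", "harmonic")) {
  method <- match.arg(method)
  s <- boundary_samples
  stopifnot(all(c("normal_angle_deg", "intensity") %in% names(s)))
  if (nrow(s) < 3) stop("need at least 3 boundary samples", call. = FALSE)
  if (any(s$intensity < 0)) stop("negative intensity", call. = FALSE)
  w <- sum(s$intensity)
  if (w <= 0) stop("undefined-polarity: zero total intensity", call. = FALSE)
  phi <- s$normal_angle_deg * pi / 180
  if (method == "moment") {
    z <- sum(s$intensity * exp(2i * phi)) / w
  } else {
    X <- cbind(1, cos(2 * phi), sin(2 * phi))
    fit <- stats::lm.fit(X, s$intensity)
    cf <- unname(fit$coefficients)
    if (any(is.na(cf)) || cf[1] <= 0) {
      # degenerate normal design (e.g. all edges parallel): fall back
      z <- sum(s$intensity * exp(2i * phi)) / w
    } else {
      z <- complex(real = cf[2], imaginary = cf[3]) / (2 * cf[1])
    }
  }
  structure(list(cell_id = cell_id, magnitude = Mod(z),
                 axis_deg = nematic_axis_deg(z),
                 weight = w, n_samples = nrow(s)),
            class = "polarity_measure")
}

# half-argument of a doubled-angle complex nematic, snapped into [0, 180)
nematic_axis_deg <- function(z) {
  ax <- (Arg(z) * 90 / pi) %% 180
  if (ax >= 180 - 1e-9) ax <- 0
  ax
}

#' Polarity of every cell in an edge-sample table
#'
#' @param edge_samples Data frame with `cell_id`, `normal_angle_deg`,
#'   `intensity`.
#' @param method Per-cell estimator, see [cell_polarity()].
#' @return Data frame with one row per cell: `cell_id`, `magnitude`,
#'   `axis_deg`, `weight`, `n_samples`.
#' @export
field_polarity <- function(edge_samples, method = c("moment", "harmonic")) {
  method <- match.arg(method)
  out <- lapply(split(edge_samples, edge_samples$cell_id), function(s) {
    pm <- cell_polarity(s, cell_id = s$cell_id[1], method = method)
    data.frame(cell_id = pm$cell_id, magnitude = pm$magnitude,
               axis_deg = pm$axis_deg, weight = pm$weight,
               n_samples = pm$n_samples, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Tissue-level average polarity
#'
#' Per-cell nematics `magnitude * exp(2i axis)` are averaged as complex
#' numbers (each cell one vote by default, or weighted by total boundary
#' intensity); the result's modulus and half-argument give the average
#' magnitude and direction drawn on rose plots.
#'
#' @param cells Data frame with `magnitude` and `axis_deg` columns (as from
#'   [field_polarity()]), and `weight` when intensity weighting is used.
#' @param weighting `"equal"` or `"intensity"`.
#' @return List: `magnitude`, `axis_deg` in \[0, 180), `n_cells`.
#' @export
tissue_polarity <- function(cells, weighting = c("equal", "intensity")) {
  weighting <- match.arg(weighting)
  if (nrow(cells) < 1) stop("empty input", call. = FALSE)
  w <- if (weighting == "intensity") cells$weight else rep(1, nrow(cells))
  z <- sum(w * cells$magnitude * exp(2i * cells$axis_deg * pi / 180)) / sum(w)
  list(magnitude = Mod(z), axis_deg = nematic_axis_deg(z),
       n_cells = nrow(cells))
}

#' Axial rose histogram of cell polarity
#'
#' Bins per-cell axes over \[0, 180) (axial data: 179.9 and 0.1 degrees fall
#' in adjacent wrap-around bins, not the same bin).
#'
#' @param cells Data frame with `axis_deg` (and `magnitude` when weighted).
#' @param bin_width_deg Bin width; must divide 180.
#' @param weighted If `TRUE`, bins sum per-cell magnitudes instead of
#'   counts.
#' @return Data frame with `bin_start`, `bin_end`, `weight`.
#' @export
rose_histogram <- function(cells, bin_width_deg = 15, weighted = FALSE) {
  if (bin_width_deg <= 0 || (180 %% bin_width_deg) != 0)
    stop("config error: bin_width_deg must divide 180", call. = FALSE)
  nb <- 180 / bin_width_deg
  ax <- cells$axis_deg %% 180
  idx <- floor(ax / bin_width_deg) + 1
  wt <- if (weighted) cells$magnitude else rep(1, length(ax))
  weight <- vapply(seq_len(nb), function(k) sum(wt[idx == k]), numeric(1))
  data.frame(bin_start = (seq_len(nb) - 1) * bin_width_deg,
             bin_end = seq_len(nb) * bin_width_deg,
             weight = weight)
}
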