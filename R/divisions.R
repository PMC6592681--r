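#' @title Division orientation and positional fate analysis
#' @description Division angles from daughter nuclear centroids at
#'   telophase, the planar/oblique/perpendicular classification, positional
#'   fate from post-division z-tracks, and angle/fate summary tables.
#' @name division_analysis
NULL

#' Division angle between daughter centroids
#'
#' Elevation of the axis joining the two daughter nuclear centroids relative
#' to the basal plane: `asin(|dz| / |d|)` in degrees, in \[0, 90\].
#' Symmetric in argument order and invariant to rigid in-plane motions.
#'
#' @param p_a,p_b Length-3 numeric xyz centroids (um), z measured from the
#'   basement membrane.
#' @return Angle in degrees.
#' @examples
#' division_angle(c(0, 0, 0), c(3, 0, 4))  # 53.13
#' @export
division_angle <- function(p_a, p_b) {
  stopifnot(length(p_a) == 3, length(p_b) == 3,
            is.finite(p_a), is.finite(p_b))
  d <- p_b - p_a
  nrm <- sqrt(sum(d^2))
  if (nrm == 0)
    stop("degenerate-geometry: coincident daughter centroids", call. = FALSE)
  asin(min(abs(d[3]) / nrm, 1)) * 180 / pi
}

#' Classify a division angle
#'
#' Planar for angles at or below 20 degrees, oblique above 20 and at or
#' below 70, perpendicular above 70 (boundaries inclusive on the lower
#' category).
#'
#' @param theta Angle(s) in degrees, each in \[0, 90\].
#' @return Character vector: `"planar"`, `"oblique"` or `"perpendicular"`.
#' @export
classify_angle <- function(theta) {
  if (any(!is.finite(theta) | theta < 0 | theta > 90))
    stop("angle out of [0, 90] range", call. = FALSE)
  ifelse(theta <= 20, "planar", ifelse(theta <= 70, "oblique", "perpendicular"))
}

#' Telophase measurement frame
#'
#' The division angle is measured at the first frame where both daughter
#' nuclei exist as separate objects (the telophase proxy; metaphase frames
#' are never used because spindles still rotate before anaphase).
#'
#' @param mother,daughter_a,daughter_b Track data frames with at least a
#'   `frame` column (see [read_tracks_csv()] for the schema).
#' @return The measurement frame (integer).
#' @export
select_measurement_frame <- function(mother, daughter_a, daughter_b) {
  if (nrow(daughter_a) == 0 || nrow(daughter_b) == 0)
    stop("incomplete-event: daughter track missing", call. = FALSE)
  common <- intersect(daughter_a$frame, daughter_b$frame)
  if (length(common) == 0)
    stop("incomplete-event: daughters never co-present", call. = FALSE)
  f <- min(common)
  if (!is.null(mother) && nrow(mother) > 0 && max(mother$frame) >= f)
    stop("inconsistent-lineage: mother persists past daughter appearance",
         call. = FALSE)
  f
}

suprabasal_label <- function(z, threshold) {
  up <- z > threshold
  if (!up[length(up)]) return(FALSE)
  r <- rle(up)
  any(r$values & r$lengths >= 2)
}

#' Assign a positional fate to a division
#'
#' A daughter is suprabasal at a frame when its nuclear z exceeds
#' `basal_threshold`.  Over the post-division window the daughter's label is
#' suprabasal when it shows a persistence run of at least 2 consecutive
#' suprabasal frames *and* is suprabasal at the window's final frame (the
#' persistence rule guards against z-jitter).  Symmetric: both daughters
#' basal; asymmetric: exactly one suprabasal; both suprabasal is reported as
#' its own flag and excluded from the dichotomy.  Incomplete windows give
#' `"indeterminate"`.
#'
#' @param daughter_a,daughter_b Track data frames with `frame` and `z_um`.
#' @param division_frame Last mother frame; the window covers the following
#'   `window_min / frame_interval` frames.
#' @param basal_threshold Suprabasal z cutoff (um); see
#'   [estimate_basal_threshold()].
#' @param window_min Tracking window in minutes (default 90, i.e. 1.5 h).
#' @param frame_interval Minutes per frame.
#' @return List with `fate` (`"symmetric"`, `"asymmetric"`,
#'   `"both_suprabasal"` or `"indeterminate"`) and `reason` (non-`NA` for
#'   indeterminate events).
#' @export
assign_fate <- function(daughter_a, daughter_b, division_frame,
                        basal_threshold, window_min = 90,
                        frame_interval = 10) {
  stopifnot(frame_interval > 0, window_min > 0)
  w <- round(window_min / frame_interval)
  frames <- division_frame + seq_len(w)
  za <- daughter_a$z_um[match(frames, daughter_a$frame)]
  zb <- daughter_b$z_um[match(frames, daughter_b$frame)]
  if (any(is.na(za)) || any(is.na(zb)))
    return(list(fate = "indeterminate",
                reason = sprintf("missing frames in %d-min window", w * frame_interval)))
  a_up <- suprabasal_label(za, basal_threshold)
  b_up <- suprabasal_label(zb, basal_threshold)
  fate <- if (a_up && b_up) "both_suprabasal"
          else if (a_up || b_up) "asymmetric" else "symmetric"
  list(fate = fate, reason = NA_character_)
}

#' Default suprabasal cutoff from the mother population
#'
#' The basal threshold defaults to the 75th percentile of mother-population
#' nuclear z plus one nuclear radius; the convention is configurable because
#' no numeric suprabasal criterion is standard.
#'
#' @param tracks Track data frame (schema of [read_tracks_csv()]).
#' @param nuclear_radius Nuclear radius in um.
#' @return Threshold z in um.
#' @export
estimate_basal_threshold <- function(tracks, nuclear_radius = 2.5) {
  mothers <- tracks$cell_id[!is.na(tracks$mother_id) & tracks$mother_id != ""]
  pop <- tracks[!(tracks$cell_id %in% mothers), , drop = FALSE]
  if (nrow(pop) == 0) pop <- tracks
  unname(stats::quantile(pop$z_um, 0.75)) + nuclear_radius
}

#' Extract and score all division events from a track table
#'
#' Groups daughters by `mother_id`, finds the telophase measurement frame,
#' computes the 3D division angle and in-plane axis, classifies the
#' orientation and assigns the positional fate.
#'
#' @param tracks Track data frame with columns `cell_id`, `frame`, `x_um`,
#'   `y_um`, `z_um`, `mother_id` (empty/`NA` for cells without a recorded
#'   mother) and optionally `field_id`, `t_min`.
#' @param frame_interval Minutes per frame.
#' @param basal_threshold Suprabasal cutoff (um); estimated via
#'   [estimate_basal_threshold()] when `NULL`.
#' @param window_min Fate-tracking window in minutes.
#' @return Data frame of events: `mother_id`, `daughter_a_id`,
#'   `daughter_b_id`, `division_frame`, `measurement_frame`, `angle_deg`,
#'   `xy_axis_deg`, `category`, `fate`, `fate_reason`.
#' @export
analyze_divisions <- function(tracks, frame_interval = 10,
                              basal_threshold = NULL, window_min = 90) {
  stopifnot(all(c("cell_id", "frame", "x_um", "y_um", "z_um", "mother_id")
                %in% names(tracks)))
  if (is.null(basal_threshold))
    basal_threshold <- estimate_basal_threshold(tracks)
  has_mother <- !is.na(tracks$mother_id) & tracks$mother_id != ""
  daughters <- unique(tracks[has_mother, c("cell_id", "mother_id")])
  fams <- split(daughters$cell_id, daughters$mother_id)
  fams <- fams[lengths(fams) == 2]
  ord <- order(tracks$cell_id, tracks$frame)
  frame_v <- tracks$frame[ord]
  x_v <- tracks$x_um[ord]; y_v <- tracks$y_um[ord]; z_v <- tracks$z_um[ord]
  idx_by_cell <- split(seq_along(ord), tracks$cell_id[ord])
  n_ev <- length(fams)
  mid_v <- names(fams)
  da_id <- db_id <- character(n_ev)
  divf_v <- mf_v <- integer(n_ev)
  ang_v <- xy_v <- numeric(n_ev)
  fate_v <- reason_v <- character(n_ev)
  for (e in seq_len(n_ev)) {
    ids <- sort(fams[[e]])
    da_id[e] <- ids[1]; db_id[e] <- ids[2]
    ia <- idx_by_cell[[ids[1]]]; ib <- idx_by_cell[[ids[2]]]
    im <- idx_by_cell[[mid_v[e]]]
    fa <- frame_v[ia]; fb <- frame_v[ib]
    common <- intersect(fa, fb)
    if (length(ia) == 0 || length(ib) == 0 || length(common) == 0)
      stop("incomplete-event: daughters never co-present (mother ",
           mid_v[e], ")", call. = FALSE)
    mf <- min(common)
    if (length(im) && max(frame_v[im]) >= mf)
      stop("inconsistent-lineage: mother ", mid_v[e],
           " persists past daughter appearance", call. = FALSE)
    ka <- ia[match(mf, fa)]; kb <- ib[match(mf, fb)]
    pa <- c(x_v[ka], y_v[ka], z_v[ka])
    pb <- c(x_v[kb], y_v[kb], z_v[kb])
    ang_v[e] <- division_angle(pa, pb)
    xy_v[e] <- (atan2(pb[2] - pa[2], pb[1] - pa[1]) * 180 / pi) %% 180
    divf_v[e] <- if (length(im)) max(frame_v[im]) else mf - 1L
    mf_v[e] <- mf
    ft <- assign_fate(list(frame = fa, z_um = z_v[ia]),
                      list(frame = fb, z_um = z_v[ib]),
                      divf_v[e], basal_threshold,
                      window_min = window_min, frame_interval = frame_interval)
    fate_v[e] <- ft$fate; reason_v[e] <- ft$reason
  }
  out <- data.frame(mother_id = mid_v, daughter_a_id = da_id,
                    daughter_b_id = db_id, division_frame = divf_v,
                    measurement_frame = mf_v, angle_deg = ang_v,
                    xy_axis_deg = xy_v,
                    category = if (n_ev) classify_angle(ang_v) else character(0),
                    fate = fate_v, fate_reason = reason_v,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "basal_threshold") <- basal_threshold
  out
}

#' Orientation-by-fate contingency table
#'
#' Counts of divisions per (category, fate) with row proportions.  Events
#' with indeterminate or both-suprabasal outcomes are tallied separately
#' and excluded from the symmetric/asymmetric dichotomy.
#'
#' @param events Event data frame from [analyze_divisions()], or any data
#'   frame with `category` and `fate` columns.
#' @return List: `counts` (3 x 2 matrix), `proportions` (row-wise),
#'   `n_excluded` (indeterminate + both-suprabasal).
#' @export
angle_fate_table <- function(events) {
  cats <- c("planar", "oblique", "perpendicular")
  fates <- c("symmetric", "asymmetric")
  counts <- matrix(0L, 3, 2, dimnames = list(category = cats, fate = fates))
  keep <- events$fate %in% fates
  if (any(keep)) {
    tab <- table(factor(events$category[keep], levels = cats),
                 factor(events$fate[keep], levels = fates))
    counts[] <- as.integer(tab)
  }
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = props,
       n_excluded = sum(!keep))
}

#' Angular histogram of division angles
#'
#' Counts per bin over \[0, 90\]: bins are left-closed, the last bin closed
#' on both ends so that 90 degrees is included.
#'
#' @param angles_deg Angles in degrees, each in \[0, 90\].
#' @param bin_width Bin width in degrees; must divide 90.
#' @return Data frame with `bin_start`, `bin_end`, `count`, `proportion`.
#' @export
angular_histogram <- function(angles_deg, bin_width = 10) {
  if (bin_width <= 0 || (90 %% bin_width) != 0)
    stop("config error: bin_width must divide 90", call. = FALSE)
  if (any(!is.finite(angles_deg) | angles_deg < 0 | angles_deg > 90))
    stop("angle out of [0, 90] range", call. = FALSE)
  nb <- 90 / bin_width
  idx <- pmin(floor(angles_deg / bin_width), nb - 1) + 1
  count <- tabulate(idx, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             count = count,
             proportion = if (length(angles_deg)) count / length(angles_deg)
                          else 0 * count)
}

#' Category proportions of an angle sample
#'
#' @param angles_deg Angles in degrees in \[0, 90\].
#' @return Named numeric of planar/oblique/perpendicular proportions.
#' @export
category_proportions <- function(angles_deg) {
  cats <- factor(classify_angle(angles_deg),
                 levels = c("planar", "oblique", "perpendicular"))
  prop.table(table(cats))
}
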