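# Independent brute-force oracles used across test files.

# Kuiper V by direct ECDF evaluation at every pooled value (O(n^2)).
brute_kuiper <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  fa <- vapply(ts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(ts, function(t) mean(b <= t), numeric(1))
  dp <- max(c(fa - fb, 0))
  dm <- max(c(fb - fa, 0))
  c(V = dp + dm, D_plus = dp, D_minus = dm)
}

# Polygon area by fan triangulation from the first vertex.
brute_area <- function(p) {
  a <- 0
  for (i in 2:(nrow(p) - 1)) {
    v1 <- p[i, ] - p[1, ]; v2 <- p[i + 1, ] - p[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  unname(abs(a))
}

# Longest chord by an explicit all-pairs loop.
brute_longest_chord <- function(p) {
  best <- 0
  for (i in 1:(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
    d <- sqrt(sum((p[i, ] - p[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# Elevation angle by direct trigonometry (atan2 form, independent of the
# arcsin implementation).
trig_angle <- function(pa, pb) {
  d <- pb - pa
  atan2(abs(d[3]), sqrt(d[1]^2 + d[2]^2)) * 180 / pi
}

regular_polygon <- function(n, r = 1, cx = 0, cy = 0, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

ellipse_polygon <- function(a, b, n = 64, angle_deg = 0, cx = 0, cy = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  x <- a * cos(th); y <- b * sin(th)
  ang <- angle_deg * pi / 180
  cbind(x = cx + x * cos(ang) - y * sin(ang),
        y = cy + x * sin(ang) + y * cos(ang))
}

rotate_polygon <- function(p, angle_deg, cx = 0, cy = 0) {
  ang <- angle_deg * pi / 180
  x <- p[, 1] - cx; y <- p[, 2] - cy
  cbind(x = cx + x * cos(ang) - y * sin(ang),
        y = cy + x * sin(ang) + y * cos(ang))
}

mixture_config <- function(w, n_divisions = 300, seed = 1, ...) {
  sim_config(field_width = 150, field_height = 105,
             angle_mixture = stats::setNames(w, c("planar", "oblique", "perpendicular")),
             n_divisions = n_divisions, n_frames = 14, seed = seed, ...)
}

# Small hand-built two-daughter track set around one division.
toy_division_tracks <- function(za, zb, division_frame = 3, n_frames = 12,
                                threshold = 5.5) {
  frames <- seq.int(division_frame + 1, division_frame + length(za))
  list(
    mother = data.frame(cell_id = "m", frame = 1:division_frame,
                        x_um = 0, y_um = 0, z_um = 3,
                        mother_id = "", stringsAsFactors = FALSE),
    a = data.frame(cell_id = "ma", frame = frames, x_um = 1, y_um = 0,
                   z_um = za, mother_id = "m", stringsAsFactors = FALSE),
    b = data.frame(cell_id = "mb", frame = frames, x_um = -1, y_um = 0,
                   z_um = zb, mother_id = "m", stringsAsFactors = FALSE)
  )
}

WT_MIX <- c(0.51, 0.29, 0.20)
MUT_MIX <- c(0.27, 0.39, 0.34)
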