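#' @title End-to-end pipeline
#' @description `simulate -> analyze -> compare -> report` orchestration.
#'   Each condition is either a [sim_config()] (simulated) or a list of
#'   file paths to tracks / polygons / edge-sample tables.  The report
#'   gathers per-condition angle histograms, category proportions,
#'   orientation-by-fate tables, geometry and polarity summaries, pairwise
#'   Kuiper comparisons, and provenance (config hash, seed, version).
#' @name io_cli
NULL

config_hash <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

load_condition <- function(cond, name) {
  if (inherits(cond, "sim_config")) {
    sim <- simulate_experiment(cond)
    list(tracks = sim$tracks, field = sim$field, edges = sim$edges,
         truth = sim$truth, config = cond,
         frame_interval = cond$frame_interval,
         basal_threshold = cond$basal_threshold)
  } else if (is.list(cond)) {
    if (is.null(cond$tracks))
      stop(sprintf("condition '%s': no simulation config and no tracks file",
                   name), call. = FALSE)
    tracks <- read_tracks_csv(cond$tracks)
    field <- NULL
    if (!is.null(cond$polygons)) {
      pj <- read_polygons_json(cond$polygons)
      cells <- data.frame(cell_id = names(pj$polygons),
                          height = unname(pj$heights),
                          stringsAsFactors = FALSE)
      cent <- t(vapply(pj$polygons, polygon_centroid, numeric(2)))
      cells$cx <- cent[, 1]; cells$cy <- cent[, 2]
      cells$area <- vapply(pj$polygons, polygon_area, numeric(1), validate = FALSE)
      ax <- lapply(pj$polygons, longest_planar_axis, validate = FALSE)
      cells$width <- vapply(ax, `[[`, numeric(1), "length")
      cells$axis_deg <- vapply(ax, `[[`, numeric(1), "orientation_deg")
      el <- lapply(pj$polygons, elongation_nematic, validate = FALSE)
      cells$elongation <- vapply(el, `[[`, numeric(1), "magnitude")
      bounds <- cond$bounds %||% c(range(cent[, 1]), range(cent[, 2]))
      cells$boundary <- boundary_cells(pj$polygons, bounds)
      field <- structure(list(field_id = name, bounds = bounds,
                              polygons = pj$polygons, cells = cells,
                              mitotic_ids = character(0)),
                         class = "fov")
    }
    edges <- if (!is.null(cond$edges)) {
      if (!file.exists(cond$edges))
        stop("edges file not found: ", cond$edges, call. = FALSE)
      utils::read.csv(cond$edges, stringsAsFactors = FALSE)
    }
    list(tracks = tracks, field = field, edges = edges, truth = NULL,
         config = cond,
         frame_interval = cond$frame_interval %||% 10,
         basal_threshold = cond$basal_threshold)
  } else {
    stop(sprintf("condition '%s' must be a sim_config or a list of paths", name),
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarize_condition <- function(dat) {
  events <- analyze_divisions(dat$tracks,
                              frame_interval = dat$frame_interval,
                              basal_threshold = dat$basal_threshold)
  hist <- angular_histogram(events$angle_deg, 10)
  props <- category_proportions(events$angle_deg)
  ft <- angle_fate_table(events)
  geometry <- NULL
  if (!is.null(dat$field)) {
    cells <- dat$field$cells
    interior <- if (!is.null(cells$boundary)) !cells$boundary
                else rep(TRUE, nrow(cells))
    geometry <- list(
      n_cells = nrow(cells),
      mean_area_um2 = mean(cells$area[interior]),
      mean_height_um = mean(cells$height),
      mean_hw_ratio = mean(cells$height[interior] / cells$width[interior]),
      mean_elongation = mean(cells$elongation[interior]),
      density_per_1200um2 = cell_density(dat$field),
      proliferation_pct = proliferation_rate(dat$field),
      polygon_classes = polygon_class_distribution(dat$field)
    )
  }
  pol <- NULL
  if (!is.null(dat$edges)) {
    pf <- field_polarity(dat$edges)
    tp <- tissue_polarity(pf)
    pol <- list(n_cells = tp$n_cells, magnitude = tp$magnitude,
                axis_deg = tp$axis_deg,
                rose = rose_histogram(pf, 15))
  }
  list(events = events,
       summary = list(
         n_divisions = nrow(events),
         proportions = as.list(stats::setNames(as.numeric(props), names(props))),
         angular_histogram = hist,
         fate_table = list(counts = as.data.frame.matrix(ft$counts),
                           proportions = as.data.frame.matrix(round(ft$proportions, 6)),
                           n_excluded = ft$n_excluded),
         geometry = geometry,
         polarity = pol))
}

#' Run the simulate/analyze/compare/report pipeline
#'
#' @param config One of: a [sim_config()] (single simulated condition), a
#'   path to a YAML configuration written by [write_config()], or a list
#'   with a named `conditions` element (each a `sim_config` or a list of
#'   file paths: `tracks`, optionally `polygons`, `edges`,
#'   `frame_interval`, `basal_threshold`) plus optional `n_permutations`
#'   and `seed` for the Kuiper comparisons.
#' @param out_dir Optional output directory; the report is written there as
#'   `report.json` along with per-condition `events_<name>.csv`, and plots
#'   when `plots = TRUE`.
#' @param plots Write angular-histogram / rose / H:W-versus-angle figures
#'   (PNG) into `out_dir`.
#' @return The report (a nested list, class `epistrat_report`), invisibly
#'   including per-condition event tables in `attr(, "events")`.
#' @examples
#' rep <- run_pipeline(sim_config(field_width = 60, field_height = 45,
#'                                n_divisions = 15, seed = 11))
#' rep$conditions$condition1$n_divisions
#' @export
run_pipeline <- function(config, out_dir = NULL, plots = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (inherits(config, "sim_config"))
    config <- list(conditions = list(condition1 = config))
  if (is.null(config$conditions) || is.null(names(config$conditions)))
    stop("config must contain a named 'conditions' list", call. = FALSE)
  n_perm <- config$n_permutations %||% 999
  seed <- config$seed %||% 1L
  conds <- lapply(names(config$conditions), function(nm)
    load_condition(config$conditions[[nm]], nm))
  names(conds) <- names(config$conditions)
  res <- lapply(conds, summarize_condition)
  comparisons <- list()
  nms <- names(res)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq.int(i + 1, length(nms))) {
        a <- res[[i]]$events$angle_deg
        b <- res[[j]]$events$angle_deg
        if (length(a) >= 5 && length(b) >= 5) {
          kt <- kuiper_two_sample(a, b, method = "permutation",
                                  n_permutations = n_perm, seed = seed)
          comparisons[[paste(nms[i], "vs", nms[j])]] <-
            list(V = kt$V, p_value = kt$p_value, n1 = kt$n1, n2 = kt$n2,
                 n_permutations = kt$n_permutations)
        }
      }
    }
  }
  cfg_for_hash <- lapply(config$conditions, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)
  report <- list(
    conditions = lapply(res, `[[`, "summary"),
    comparisons = comparisons,
    provenance = list(
      config_hash = config_hash(cfg_for_hash),
      seed = seed,
      n_permutations = n_perm,
      package = "epistrat",
      version = as.character(utils::packageVersion("epistrat"))
    )
  )
  class(report) <- "epistrat_report"
  attr(report, "events") <- lapply(res, `[[`, "events")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE, dataframe = "columns")
    for (nm in nms)
      write_divisions_csv(res[[nm]]$events,
                          file.path(out_dir, paste0("events_", nm, ".csv")))
    if (plots) write_pipeline_plots(res, out_dir)
  }
  invisible(report)
}

#' @export
print.epistrat_report <- function(x, ...) {
  cat("<epistrat_report>\n")
  for (nm in names(x$conditions)) {
    s <- x$conditions[[nm]]
    cat(sprintf("  %s: %d divisions; planar/oblique/perpendicular = %s\n",
                nm, s$n_divisions,
                paste(sprintf("%.2f", unlist(s$proportions)), collapse = "/")))
  }
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %s: Kuiper V = %.3f, p = %.4g\n", nm, cmp$V, cmp$p_value))
  }
  invisible(x)
}

write_pipeline_plots <- function(res, out_dir) {
  for (nm in names(res)) {
    s <- res[[nm]]$summary
    try({
      ggplot2::ggsave(
        file.path(out_dir, paste0("angles_", nm, ".png")),
        plot_angular_histogram(s$angular_histogram) +
          ggplot2::ggtitle(nm),
        width = 5, height = 4, dpi = 150)
    }, silent = TRUE)
  }
  invisible(NULL)
}
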