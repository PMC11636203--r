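#' Run configuration
#'
#' Aggregates everything a full analysis run needs: field of view,
#' segmentation parameters, colony allocation scheme, report cutoff, and
#' output directory. Defaults reproduce the standard field deployment: a
#' 60-second grouping window, an 800 x 320 px field of view with the hive on
#' the left, thousands-digit colony allocation, and a 2-hour trip-duration
#' cutoff in the report.
#'
#' @param fov A [fov()].
#' @param seg A [segmentation_config()].
#' @param scheme A [colony_scheme()].
#' @param cutoff_hours Trip-duration cutoff reported on (hours).
#' @param bin_minutes Histogram bin width (minutes).
#' @param out_dir Directory where [cmd_analyze()] writes its artifacts.
#' @param verbose Emit per-stage progress messages?
#' @return An object of class `run_config`.
#' @export
run_config <- function(fov = beegate::fov(), seg = segmentation_config(),
                       scheme = colony_scheme(), cutoff_hours = 2,
                       bin_minutes = 1, out_dir = ".", verbose = TRUE) {
  stopifnot(inherits(fov, "fov"), inherits(seg, "segmentation_config"))
  if (cutoff_hours <= 0) abort("`cutoff_hours` must be positive.")
  structure(list(fov = fov, seg = seg, scheme = scheme,
                 cutoff_hours = cutoff_hours, bin_minutes = bin_minutes,
                 out_dir = out_dir, verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: `fov_width`, `fov_height`, `hive_side`, `gap_seconds`,
#' `displacement_threshold_frac`, `min_detections_for_direction`,
#' `cutoff_hours`, `bin_minutes`, `out_dir`, and `colonies` (a mapping of
#' label to `[low, high]`). Missing keys keep their defaults; explicit
#' arguments to the `cmd_*` wrappers override file values.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  f <- fov(width = y$fov_width %||% 800, height = y$fov_height %||% 320,
           hive_side = y$hive_side %||% "left")
  seg <- segmentation_config(
    gap_seconds = y$gap_seconds %||% 60,
    displacement_threshold_frac = y$displacement_threshold_frac %||% 0.25,
    min_detections_for_direction = y$min_detections_for_direction %||% 2L)
  scheme <- if (!is.null(y$colonies)) {
    colony_scheme(labels = names(y$colonies),
                  id_low = vapply(y$colonies, function(r) r[[1]], 0),
                  id_high = vapply(y$colonies, function(r) r[[2]], 0))
  } else {
    colony_scheme()
  }
  run_config(fov = f, seg = seg, scheme = scheme,
             cutoff_hours = y$cutoff_hours %||% 2,
             bin_minutes = y$bin_minutes %||% 1,
             out_dir = y$out_dir %||% ".")
}

#' Run the full analysis pipeline on a detection table
#'
#' Chronological detections are grouped into events, the events classified
#' as enter/exit/unknown, trips extracted, and the colony report built.
#'
#' @param det A detection tibble.
#' @param config A [run_config()].
#' @return A list of class `colony_analysis`: `detections`, `events`,
#'   `trips`, `report`.
#' @export
analyze_colony <- function(det, config = run_config()) {
  events <- group_events(det, config$seg)
  events <- classify_events(events, config$fov, config$seg)
  trips <- extract_trips(events)
  report <- build_report(det, events, trips, scheme = config$scheme,
                         cutoff_hours = config$cutoff_hours,
                         bin_minutes = config$bin_minutes)
  structure(list(detections = det, events = events, trips = trips,
                 report = report),
            class = "colony_analysis")
}

#' @export
print.colony_analysis <- function(x, ...) {
  print(x$report)
  invisible(x)
}

say <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) inform(sprintf(fmt, ...))
}

#' Analyze detection logs and write all artifacts
#'
#' Front door of the pipeline: reads one or more detection-log files,
#' runs [analyze_colony()], and writes into `config$out_dir`:
#' `report.txt` and `report.json`, `Events_by_ID.csv` / `.xls`, and the two
#' histogram figures (`hist_per_id.png`, `hist_trip_durations.png`).
#' Each run logs its configuration echo, input checksums and per-stage
#' counts, so a run can be reproduced from its log alone.
#'
#' @param paths Detection-log file paths.
#' @param config A [run_config()].
#' @param strict Passed to [read_detection_log()].
#' @return The `colony_analysis`, invisibly.
#' @export
cmd_analyze <- function(paths, config = run_config(), strict = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say(config, "config: gap=%gs thr=%g%% fov=%dx%d hive=%s cutoff=%gh",
      config$seg$gap_seconds,
      100 * config$seg$displacement_threshold_frac,
      config$fov$width, config$fov$height, config$fov$hive_side,
      config$cutoff_hours)
  parts <- lapply(paths, function(p) {
    d <- read_detection_log(p, fov = config$fov, strict = strict)
    say(config, "input %s: %d detections, %d malformed line(s) [md5 %s]",
        p, nrow(d), nrow(detection_problems(d)),
        substr(unname(tools::md5sum(p)), 1, 8))
    d
  })
  det <- bind_rows(parts)
  det <- det[order(det$timestamp), , drop = FALSE]
  res <- analyze_colony(det, config)
  say(config, "stages: %d detections -> %d events -> %d trips",
      nrow(res$detections), nrow(res$events), nrow(res$trips))

  txt <- file.path(config$out_dir, "report.txt")
  con <- file(txt, "wb")
  writeLines(utils::capture.output(print(res$report)), con, sep = "\n")
  close(con)
  jsonlite::write_json(report_as_list(res$report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  write_events_spreadsheet(res$events,
                           file.path(config$out_dir, "Events_by_ID.csv"))
  if (nrow(res$events)) {
    save_plot(plot_activity_histogram(res$report),
              file.path(config$out_dir, "hist_per_id.png"))
  }
  if (nrow(res$trips)) {
    save_plot(plot_duration_histogram(res$report),
              file.path(config$out_dir, "hist_trip_durations.png"))
  }
  say(config, "artifacts written to %s", config$out_dir)
  invisible(res)
}

save_plot <- function(p, path, width = 8, height = 4.5) {
  ggsave(path, p, width = width, height = height, dpi = 120)
}

#' Per-ID activity histogram
#'
#' Grouped bars of detections, events and trips per tag ID.
#'
#' @param report A `colony_report`.
#' @param ids Optional subset of tag IDs to display.
#' @return A ggplot object.
#' @export
plot_activity_histogram <- function(report, ids = NULL) {
  d <- report$per_id
  if (!is.null(ids)) d <- d[d$tag_id %in% ids, , drop = FALSE]
  long <- pivot_longer(d[, c("tag_id", "detections", "events", "trips")],
                       -"tag_id", names_to = "measure", values_to = "count")
  long$measure <- factor(long$measure,
                         levels = c("detections", "events", "trips"))
  ggplot(long, aes(x = factor(.data$tag_id), y = .data$count,
                   fill = .data$measure)) +
    geom_col(position = "dodge") +
    labs(x = "tag ID", y = "count", fill = NULL,
         title = "Detections, events and trips per tag") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5))
}

#' Trip-duration histogram
#'
#' Trips per duration bin (minutes).
#'
#' @param report A `colony_report`.
#' @param max_minutes Truncate the display at this duration.
#' @return A ggplot object.
#' @export
plot_duration_histogram <- function(report, max_minutes = 120) {
  h <- report$duration_stats$histogram
  h <- h[h$bin_start_min < max_minutes, , drop = FALSE]
  sub <- if (!report$duration_stats$empty) {
    sprintf("n = %d | mean %s | median %s | mode %s",
            report$duration_stats$n, fmt_mmss(report$duration_stats$mean),
            fmt_mmss(report$duration_stats$median),
            fmt_mmss(report$duration_stats$mode))
  } else "no trips"
  ggplot(h, aes(x = .data$bin_start_min, y = .data$count)) +
    geom_col(fill = "goldenrod3") +
    labs(x = "trip duration (min)", y = "trips",
         title = "Trip duration distribution", subtitle = sub) +
    theme_minimal()
}

#' Plot the detections of events as trajectory vectors
#'
#' Draws each detection of an event as a position with an arrow showing the
#' recorded tag orientation, on a canvas matching the camera field of view,
#' annotated with the event category and time span. One figure per event.
#'
#' @param events A classified event tibble.
#' @param tag_id Tag to plot; must have events in `events`.
#' @param fov The field of view (canvas dimensions).
#' @return A list of ggplot objects, one per event of the tag.
#' @export
plot_event_trajectories <- function(events, tag_id,
                                    fov = beegate::fov()) {
  ev <- events[events$tag_id == tag_id, , drop = FALSE]
  if (nrow(ev) == 0L) {
    abort(sprintf("no events for tag %s; available IDs: %s", tag_id,
                  paste(sort(unique(events$tag_id)), collapse = ", ")))
  }
  arrow_len <- 0.04 * fov$width
  lapply(seq_len(nrow(ev)), function(i) {
    d <- ev$detections[[i]]
    d$xend <- d$x + arrow_len * cos(d$theta * pi / 180)
    d$yend <- d$y + arrow_len * sin(d$theta * pi / 180)
    ggplot(d, aes(x = .data$x, y = .data$y)) +
      geom_path(color = "grey60", linetype = 2) +
      geom_segment(aes(xend = .data$xend, yend = .data$yend),
                   arrow = grid::arrow(length = grid::unit(2, "mm")),
                   color = "steelblue") +
      geom_point(size = 1.5) +
      coord_fixed(xlim = c(0, fov$width), ylim = c(fov$height, 0),
                  expand = FALSE) +
      labs(title = sprintf("tag %d — %s event", tag_id, ev$category[i]),
           subtitle = sprintf("%s to %s (%d detections)",
                              format_ts(ev$t_start[i]),
                              format_ts(ev$t_end[i]),
                              ev$n_detections[i]),
           x = "x (px)", y = "y (px)") +
      theme_minimal()
  })
}

#' Simulate traffic and write the log and ground truth
#'
#' Thin wrapper over [simulate_traffic()]: writes the detection log as
#' canonical CSV and the ground truth as JSON.
#'
#' @param scenario A [traffic_scenario()].
#' @param out Path for the detection log.
#' @param truth_out Path for the ground-truth JSON.
#' @return The simulation result, invisibly.
#' @export
cmd_simulate <- function(scenario, out = "simulated_log.csv",
                         truth_out = "simulated_truth.json") {
  sim <- simulate_traffic(scenario)
  write_detection_log(sim$detections, out, fov = scenario$fov)
  tr <- sim$truth
  tr$t_leave <- format_ts(tr$t_leave)
  tr$t_return <- format_ts(tr$t_return)
  jsonlite::write_json(tr, truth_out, auto_unbox = TRUE, digits = NA)
  invisible(sim)
}

#' Render a printable tag sheet for a range of IDs
#'
#' @param ids Numeric codewords/IDs to render.
#' @param out Output path (`.svg` or `.pdf`).
#' @param ... Passed to [make_sheet()].
#' @return The `tag_sheet`, invisibly.
#' @export
cmd_render_tags <- function(ids, out = "tags.svg", ...) {
  sheet <- make_sheet(ids, ...)
  write_sheet(sheet, out)
  invisible(sheet)
}
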