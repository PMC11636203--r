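#' Pair classified events into foraging trips
#'
#' A trip is an exit event followed by the consecutive entry event of the
#' same tag. Unknown events are removed before pairing (they carry no
#' directional information and would otherwise break almost every pairing).
#' Within each tag's remaining chronological event sequence, each enter is
#' paired with the latest exit that precedes it; earlier unpaired exits are
#' discarded as failed exits, and enters without a preceding exit are
#' discarded as failed entries. Each event joins at most one trip and a
#' tag's trips never overlap in time.
#'
#' Trip duration is the time from the last sighting while leaving to the
#' first sighting on return: `enter.t_start - exit.t_end`. This is the best
#' log-derived approximation of time spent outside the hive. By
#' construction every duration exceeds the grouping window (one minute at
#' the default configuration).
#'
#' @param events A classified event tibble ([classify_events()]); every
#'   `category` must be set.
#' @return A trip tibble: `tag_id`, `exit_event_id`, `enter_event_id`,
#'   `t_exit` (end of the exit event), `t_enter` (start of the enter event),
#'   `duration_seconds`.
#' @export
extract_trips <- function(events) {
  if (nrow(events) && anyNA(events$category)) {
    abort("events carry unset categories; run classify_events() first.")
  }
  ev <- events |>
    filter(.data$category != "unknown") |>
    arrange(.data$tag_id, .data$t_start)
  trips <- list()
  for (id in unique(ev$tag_id)) {
    e <- ev[ev$tag_id == id, , drop = FALSE]
    pending_exit <- NULL
    for (i in seq_len(nrow(e))) {
      if (e$category[i] == "exit") {
        pending_exit <- e[i, ]          # later exits supersede failed ones
      } else if (!is.null(pending_exit)) {
        trips[[length(trips) + 1L]] <- tibble(
          tag_id = id,
          exit_event_id = pending_exit$event_id,
          enter_event_id = e$event_id[i],
          t_exit = pending_exit$t_end,
          t_enter = e$t_start[i],
          duration_seconds =
            as.numeric(e$t_start[i]) - as.numeric(pending_exit$t_end)
        )
        pending_exit <- NULL
      }                                  # enter with no pending exit: failed entry
    }
  }
  if (!length(trips)) return(empty_trips())
  bind_rows(trips) |> arrange(.data$t_exit, .data$tag_id)
}

empty_trips <- function() {
  tibble(tag_id = integer(0), exit_event_id = integer(0),
         enter_event_id = integer(0),
         t_exit = .POSIXct(numeric(0), tz = "UTC"),
         t_enter = .POSIXct(numeric(0), tz = "UTC"),
         duration_seconds = numeric(0))
}

#' Trip-duration statistics
#'
#' Mean and median over raw durations in seconds; the mode is the most
#' frequent duration after rounding to whole seconds (ties broken toward the
#' smallest value, matching the skew of foraging-trip distributions); the
#' histogram counts trips per duration bin in minutes.
#'
#' @param trips A trip tibble from [extract_trips()].
#' @param bin_minutes Histogram bin width in minutes (default 1).
#' @return An object of class `duration_stats`: list with `n`, `mean`,
#'   `median`, `mode` (all seconds; `NA` with `empty = TRUE` when there are
#'   no trips), and `histogram`, a tibble of `bin_start_min`, `bin_end_min`,
#'   `count`.
#' @export
trip_statistics <- function(trips, bin_minutes = 1) {
  if (bin_minutes <= 0) abort("`bin_minutes` must be positive.")
  dur <- trips$duration_seconds
  if (length(dur) == 0L) {
    return(structure(list(n = 0L, mean = NA_real_, median = NA_real_,
                          mode = NA_real_, empty = TRUE,
                          histogram = tibble(bin_start_min = numeric(0),
                                             bin_end_min = numeric(0),
                                             count = integer(0))),
                     class = "duration_stats"))
  }
  if (any(dur <= 0)) abort("all trip durations must be positive.")
  rounded <- round(dur)
  tab <- table(rounded)
  best <- as.numeric(names(tab))[tab == max(tab)]
  mode_s <- min(best)
  bin <- floor(dur / 60 / bin_minutes)
  counts <- table(bin)
  hist <- tibble(bin_start_min = as.numeric(names(counts)) * bin_minutes,
                 bin_end_min = (as.numeric(names(counts)) + 1) * bin_minutes,
                 count = as.integer(counts))
  structure(list(n = length(dur), mean = mean(dur), median = median(dur),
                 mode = mode_s, empty = FALSE, histogram = hist),
            class = "duration_stats")
}

#' @export
print.duration_stats <- function(x, ...) {
  if (x$empty) {
    cat("<duration_stats> no trips\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<duration_stats> n = %d | mean %s | median %s | mode %s\n",
    x$n, fmt_mmss(x$mean), fmt_mmss(x$median), fmt_mmss(x$mode)))
  invisible(x)
}

fmt_mmss <- function(s) {
  if (is.na(s)) return("-")
  sprintf("%d min %02d s", floor(s / 60), round(s %% 60))
}

#' Build a colony activity report
#'
#' Aggregates a colony's detections, events and trips into a single report:
#' totals, mean detections per event, the percentage of enter/exit/unknown
#' events, total trips and trips under a configurable duration cutoff,
#' trip-duration statistics, and per-ID tallies of detections, events and
#' trips.
#'
#' @param detections The detection tibble the events were built from.
#' @param events The classified event tibble.
#' @param trips The trip tibble.
#' @param scheme Colony allocation scheme used to label the data.
#' @param cutoff_hours Report the number of trips shorter than this many
#'   hours (default 2).
#' @param bin_minutes Histogram bin width passed to [trip_statistics()].
#' @return An object of class `colony_report` (a list; see Details), with a
#'   `print()` method rendering the plain-text report.
#' @details The inputs must be mutually consistent: the events must
#'   partition the detections and every trip must reference an existing
#'   event; violations raise an error naming the broken relation.
#' @export
build_report <- function(detections, events, trips,
                         scheme = colony_scheme(), cutoff_hours = 2,
                         bin_minutes = 1) {
  if (sum(events$n_detections) != nrow(detections)) {
    abort(paste0("inconsistent inputs: events cover ",
                 sum(events$n_detections), " detections but ",
                 nrow(detections), " were supplied ",
                 "(violated relation: events partition detections)"))
  }
  if (nrow(trips) &&
      !all(c(trips$exit_event_id, trips$enter_event_id) %in%
             events$event_id)) {
    abort(paste0("inconsistent inputs: trips reference unknown event ids ",
                 "(violated relation: trips reference events)"))
  }
  n_det <- nrow(detections)
  n_ev <- nrow(events)
  n_tr <- nrow(trips)
  cat_counts <- c(enter = sum(events$category == "enter"),
                  exit = sum(events$category == "exit"),
                  unknown = sum(events$category == "unknown"))
  pct <- if (n_ev > 0) 100 * cat_counts / n_ev else
    c(enter = NA_real_, exit = NA_real_, unknown = NA_real_)
  per_id <- tibble(tag_id = sort(unique(c(detections$tag_id,
                                          events$tag_id, trips$tag_id))))
  if (nrow(per_id)) {
    per_id <- per_id |>
      mutate(
        colony = colony_of(.data$tag_id, scheme),
        detections = vapply(.data$tag_id, function(i)
          sum(detections$tag_id == i), 0L),
        events = vapply(.data$tag_id, function(i)
          sum(events$tag_id == i), 0L),
        trips = vapply(.data$tag_id, function(i)
          sum(trips$tag_id == i), 0L)
      )
  } else {
    per_id <- tibble(tag_id = integer(0), colony = character(0),
                     detections = integer(0), events = integer(0),
                     trips = integer(0))
  }
  structure(list(
    n_detections = n_det,
    n_events = n_ev,
    mean_detections_per_event = if (n_ev > 0) n_det / n_ev else NA_real_,
    category_counts = cat_counts,
    category_pct = pct,
    n_trips = n_tr,
    cutoff_hours = cutoff_hours,
    n_trips_under_cutoff = sum(trips$duration_seconds < cutoff_hours * 3600),
    duration_stats = trip_statistics(trips, bin_minutes = bin_minutes),
    per_id = per_id
  ), class = "colony_report")
}

fmt_pct <- function(p) ifelse(is.na(p), "—", sprintf("%.2f%%", p))

#' @export
print.colony_report <- function(x, ...) {
  cat("Colony activity report\n")
  cat("----------------------\n")
  cat(sprintf("Detections:            %d\n", x$n_detections))
  cat(sprintf("Events:                %d\n", x$n_events))
  cat(sprintf("Detections per event:  %s\n",
              ifelse(is.na(x$mean_detections_per_event), "—",
                     sprintf("%.2f", x$mean_detections_per_event))))
  cat(sprintf("  enter:   %5d (%s)\n", x$category_counts[["enter"]],
              fmt_pct(x$category_pct[["enter"]])))
  cat(sprintf("  exit:    %5d (%s)\n", x$category_counts[["exit"]],
              fmt_pct(x$category_pct[["exit"]])))
  cat(sprintf("  unknown: %5d (%s)\n", x$category_counts[["unknown"]],
              fmt_pct(x$category_pct[["unknown"]])))
  cat(sprintf("Trips:                 %d\n", x$n_trips))
  cat(sprintf("Trips under %g h:      %d\n", x$cutoff_hours,
              x$n_trips_under_cutoff))
  print(x$duration_stats)
  invisible(x)
}

#' Serialise a colony report to JSON-ready structures
#'
#' @param x A `colony_report`.
#' @return A plain list mirroring the report, suitable for
#'   `jsonlite::write_json()`.
#' @export
report_as_list <- function(x) {
  list(
    n_detections = x$n_detections,
    n_events = x$n_events,
    mean_detections_per_event = x$mean_detections_per_event,
    category_counts = as.list(x$category_counts),
    category_pct = as.list(x$category_pct),
    n_trips = x$n_trips,
    cutoff_hours = x$cutoff_hours,
    n_trips_under_cutoff = x$n_trips_under_cutoff,
    duration_stats = list(
      n = x$duration_stats$n,
      mean = x$duration_stats$mean,
      median = x$duration_stats$median,
      mode = x$duration_stats$mode,
      histogram = as.list(x$duration_stats$histogram)
    ),
    per_id = as.list(x$per_id)
  )
}

# ---- event spreadsheet -------------------------------------------------

events_spreadsheet_rows <- function(events) {
  tibble(tag_id = events$tag_id,
         t_start = format_ts(events$t_start),
         t_end = format_ts(events$t_end),
         n_detections = events$n_detections,
         category = events$category,
         net_displacement = events$net_displacement)
}

#' Write the per-event spreadsheet
#'
#' Emits one row per event (tag ID, start, end, number of detections,
#' category, net displacement) as a CSV file and as an Excel-compatible
#' SpreadsheetML (`.xls`) file next to it.
#'
#' @param events A classified event tibble.
#' @param path Output CSV path (default `Events_by_ID.csv`); the `.xls` twin
#'   is written with the same stem.
#' @return Invisibly, the paths written.
#' @export
write_events_spreadsheet <- function(events, path = "Events_by_ID.csv") {
  rows <- events_spreadsheet_rows(events)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  xls <- sub("\\.csv$", ".xls", path)
  if (identical(xls, path)) xls <- paste0(path, ".xls")
  write_spreadsheetml(rows, xls, sheet = "Events_by_ID")
  invisible(c(csv = path, xls = xls))
}

# Minimal SpreadsheetML 2003 writer (single-file XML workbook that Excel and
# LibreOffice open natively); adequate for tabular event exports.
write_spreadsheetml <- function(df, path, sheet = "Sheet1") {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  cell <- function(v) {
    if (is.numeric(v) && !is.na(v)) {
      sprintf('<Cell><Data ss:Type="Number">%s</Data></Cell>',
              formatC(v, digits = 15, format = "g"))
    } else {
      sprintf('<Cell><Data ss:Type="String">%s</Data></Cell>',
              esc(as.character(v)))
    }
  }
  rows <- c(
    paste0("<Row>", paste0(vapply(names(df), cell, ""), collapse = ""),
           "</Row>"),
    vapply(seq_len(nrow(df)), function(i) {
      paste0("<Row>",
             paste0(vapply(seq_along(df), function(j) cell(df[[j]][i]), ""),
                    collapse = ""),
             "</Row>")
    }, "")
  )
  xml <- c(
    '<?xml version="1.0"?>',
    '<?mso-application progid="Excel.Sheet"?>',
    paste0('<Workbook xmlns="urn:schemas-microsoft-com:office:spreadsheet" ',
           'xmlns:ss="urn:schemas-microsoft-com:office:spreadsheet">'),
    sprintf('<Worksheet ss:Name="%s"><Table>', esc(sheet)),
    rows,
    "</Table></Worksheet></Workbook>"
  )
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}
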