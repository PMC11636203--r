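#' Segmentation configuration
#'
#' Parameters of the temporal-proximity grouping rule and the
#' displacement-based enter/exit classifier.
#'
#' Two consecutive detections of the same tag belong to the same event when
#' they are at most `gap_seconds` apart (the boundary is inclusive: a gap of
#' exactly `gap_seconds` does not split an event). This makes the shortest
#' resolvable trip duration equal to the grouping window, one minute at the
#' default, which separates genuine excursions from brief in-tunnel activity.
#'
#' Classification uses the net displacement of an event projected on the
#' tunnel's long axis: an event whose displacement toward the hive reaches
#' `displacement_threshold_frac` of the axis length is an `enter`, the
#' mirror image is an `exit`, everything else (including events with fewer
#' than `min_detections_for_direction` detections) is `unknown`.
#'
#' @param gap_seconds Grouping window in seconds (positive; default 60).
#' @param displacement_threshold_frac Fraction of the tunnel-axis length that
#'   the net displacement must reach for a directional label (default 0.25,
#'   i.e. 200 px on an 800 px axis).
#' @param min_detections_for_direction Minimum detections an event needs
#'   before a directional label is considered (default 2).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(gap_seconds = 60,
                                displacement_threshold_frac = 0.25,
                                min_detections_for_direction = 2L) {
  if (!is.numeric(gap_seconds) || gap_seconds <= 0) {
    abort("`gap_seconds` must be positive.")
  }
  if (displacement_threshold_frac <= 0 || displacement_threshold_frac > 1) {
    abort("`displacement_threshold_frac` must be in (0, 1].")
  }
  if (min_detections_for_direction < 1) {
    abort("`min_detections_for_direction` must be >= 1.")
  }
  structure(list(gap_seconds = gap_seconds,
                 displacement_threshold_frac = displacement_threshold_frac,
                 min_detections_for_direction =
                   as.integer(min_detections_for_direction)),
            class = "segmentation_config")
}

# the tunnel's long axis and its signed "toward hive" direction
tunnel_axis <- function(fov) {
  along_x <- fov$width >= fov$height
  list(
    coord = if (along_x) "x" else "y",
    length = if (along_x) fov$width else fov$height,
    # +1 when increasing coordinate moves toward the hive side
    toward_hive = if (fov$hive_side %in% c("left", "top")) -1 else 1
  )
}

#' Group detections into events by temporal proximity
#'
#' Splits each tag's chronological detection stream wherever the gap between
#' consecutive detections exceeds the grouping window; maximal runs within
#' the window become events. Detections of different tag IDs never interact.
#' A gap of exactly `gap_seconds` stays within one event (inclusive window).
#'
#' @param d A chronologically ordered detection tibble (as returned by
#'   [parse_detection_lines()] or [detections()]).
#' @param cfg A [segmentation_config()].
#' @return An event tibble, one row per event, ordered by start time:
#'   columns `event_id`, `tag_id`, `t_start`, `t_end`, `n_detections`,
#'   `x_first`, `y_first`, `x_last`, `y_last`, `category` (`NA` until
#'   [classify_events()] is applied), `net_displacement` (`NA` likewise), and
#'   a `detections` list-column holding each event's detection rows.
#' @export
group_events <- function(d, cfg = segmentation_config()) {
  if (nrow(d) == 0L) return(empty_events())
  tnum <- as.numeric(d$timestamp)
  if (is.unsorted(tnum)) {
    abort("detections must be chronologically ordered; parse/sort them first.")
  }
  ev_rows <- list()
  for (rows in split(seq_len(nrow(d)), d$tag_id)) {
    new_ev <- c(TRUE, diff(tnum[rows]) > cfg$gap_seconds)
    bounds <- c(which(new_ev), length(rows) + 1L)
    for (k in seq_len(length(bounds) - 1L)) {
      ev_rows[[length(ev_rows) + 1L]] <- rows[bounds[k]:(bounds[k + 1L] - 1L)]
    }
  }
  first <- vapply(ev_rows, function(r) r[1L], 0L)
  last <- vapply(ev_rows, function(r) r[length(r)], 0L)
  ord <- order(tnum[first], d$tag_id[first])
  ev_rows <- ev_rows[ord]
  first <- first[ord]
  last <- last[ord]
  n_ev <- length(ev_rows)
  new_tibble(list(
    event_id = seq_len(n_ev),
    tag_id = d$tag_id[first],
    t_start = d$timestamp[first],
    t_end = d$timestamp[last],
    n_detections = vapply(ev_rows, length, 0L),
    x_first = d$x[first], y_first = d$y[first],
    x_last = d$x[last], y_last = d$y[last],
    detections = lapply(ev_rows, function(r)
      new_tibble(list(timestamp = d$timestamp[r], x = d$x[r], y = d$y[r],
                      theta = d$theta[r]), nrow = length(r))),
    category = rep(NA_character_, n_ev),
    net_displacement = rep(NA_real_, n_ev)
  ), nrow = n_ev)
}

empty_events <- function() {
  tibble(event_id = integer(0), tag_id = integer(0),
         t_start = .POSIXct(numeric(0), tz = "UTC"),
         t_end = .POSIXct(numeric(0), tz = "UTC"),
         n_detections = integer(0),
         x_first = numeric(0), y_first = numeric(0),
         x_last = numeric(0), y_last = numeric(0),
         detections = list(),
         category = character(0), net_displacement = numeric(0))
}

#' Classify events as enter, exit or unknown
#'
#' Computes each event's net displacement — last minus first detection
#' position, projected on the tunnel's long axis and signed positive toward
#' the hive side — and labels the event `enter` when the displacement reaches
#' the configured threshold toward the hive, `exit` when it reaches the
#' threshold away from the hive, and `unknown` otherwise. Events with fewer
#' than `min_detections_for_direction` detections are always `unknown`.
#'
#' The classifier deliberately ignores the recorded tag orientation: a bee's
#' heading at the moment of a frame does not reliably indicate its direction
#' of travel, while the displacement across the tunnel does.
#'
#' @param events An event tibble from [group_events()].
#' @param fov The field of view (axis length and hive side).
#' @param cfg A [segmentation_config()].
#' @return The event tibble with `category` and `net_displacement` filled in.
#' @export
classify_events <- function(events, fov = beegate::fov(),
                            cfg = segmentation_config()) {
  axis <- tunnel_axis(fov)
  if (nrow(events) == 0L) return(events)
  first <- if (axis$coord == "x") events$x_first else events$y_first
  last <- if (axis$coord == "x") events$x_last else events$y_last
  disp <- (last - first) * axis$toward_hive
  thr <- cfg$displacement_threshold_frac * axis$length
  cat <- ifelse(disp >= thr, "enter", ifelse(disp <= -thr, "exit", "unknown"))
  cat[events$n_detections < cfg$min_detections_for_direction] <- "unknown"
  events$net_displacement <- disp
  events$category <- cat
  events
}
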