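base_time <- as.POSIXct("2024-06-01 08:00:00", tz = "UTC")

# detections from second-offsets relative to base_time
make_det <- function(t, id = 5059L, x = 100, y = 100, theta = 0,
                     cpu_temp = NA_real_) {
  detections(base_time + t, id, x, y, theta, cpu_temp)
}

# Brute-force grouping oracle: enumerate all 2^(n-1) segmentations of one
# tag's chronological times, keep those satisfying the event invariants
# (within-event gaps <= gap, across-boundary gaps > gap), assert uniqueness,
# and return the event sizes of the unique valid segmentation.
.split_masks <- new.env(parent = emptyenv())

all_split_masks <- function(k) {
  key <- as.character(k)
  if (is.null(.split_masks[[key]])) {
    .split_masks[[key]] <-
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  }
  .split_masks[[key]]
}

brute_force_group_sizes <- function(times, gap = 60) {
  n <- length(times)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  gaps <- diff(times)
  masks <- all_split_masks(n - 1L)
  # a segmentation is valid iff every unsplit gap is <= gap and every split
  # gap is > gap; test all 2^(n-1) of them
  want <- matrix(gaps > gap, nrow(masks), n - 1L, byrow = TRUE)
  ok <- rowSums(masks != want) == 0L
  stopifnot(sum(ok) == 1L)  # the valid segmentation must be unique
  split <- masks[which(ok), ]
  unname(diff(c(0L, which(split), n)))
}

# Independent excursion-to-trip matcher used as an oracle for
# recovery_rate(): for each detectable excursion, scan every trip.
brute_force_recovery <- function(truth, trips, tolerance_s,
                                 gap_seconds = 60, min_detections = 2L) {
  det <- truth[truth$exit_n >= min_detections &
                 truth$enter_n >= min_detections &
                 truth$duration_seconds > gap_seconds, , drop = FALSE]
  if (nrow(det) == 0L) return(NA_real_)
  hits <- 0L
  for (i in seq_len(nrow(det))) {
    found <- FALSE
    for (j in seq_len(nrow(trips))) {
      if (trips$tag_id[j] != det$tag_id[i]) next
      overlap <- as.numeric(trips$t_exit[j]) <= as.numeric(det$t_return[i]) &&
        as.numeric(trips$t_enter[j]) >= as.numeric(det$t_leave[i])
      if (overlap &&
          abs(trips$duration_seconds[j] - det$duration_seconds[i]) <=
            tolerance_s) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits / nrow(det)
}

# a trip table carrying just the given durations (for statistics tests)
empty_trips_for_test <- function(durations) {
  n <- length(durations)
  tibble::tibble(
    tag_id = rep(1L, n), exit_event_id = seq_len(n) * 2L - 1L,
    enter_event_id = seq_len(n) * 2L,
    t_exit = base_time + cumsum(rep(10000, n)),
    t_enter = base_time + cumsum(rep(10000, n)) + durations,
    duration_seconds = durations)
}

# quick classified-event row for trip-pairing tests (times in seconds)
make_event <- function(id, t_start, t_end, category, event_id = 1L) {
  ts0 <- base_time + t_start
  ts1 <- base_time + t_end
  tibble::tibble(
    event_id = event_id, tag_id = as.integer(id),
    t_start = ts0, t_end = ts1,
    n_detections = 2L, x_first = 0, y_first = 0, x_last = 0, y_last = 0,
    detections = list(tibble::tibble(timestamp = c(ts0, ts1),
                                     x = c(0, 0), y = c(0, 0),
                                     theta = c(0, 0))),
    category = category, net_displacement = 0)
}

make_events <- function(...) {
  evs <- list(...)
  for (i in seq_along(evs)) evs[[i]]$event_id <- i
  dplyr::bind_rows(evs)
}
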