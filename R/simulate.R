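#' Entrance-traffic scenario
#'
#' Describes a synthetic multi-day stream of tagged-bee traffic through the
#' entrance tunnel: how many bees, which ID block, what mixture of
#' behaviours they perform, how long excursions last, and how reliably the
#' camera reads a tag per frame.
#'
#' Behaviours:
#' * `foraging_trip` — full excursion; durations follow a log-normal whose
#'   default parameters (`meanlog = 6.27`, `sdlog = 1.22`) put the mode near
#'   2 min and the mean near 18-19 min, the heavy right skew typical of
#'   foraging; durations are truncated at `min_s` (default 61 s) because the
#'   grouping window makes shorter round-trips indistinguishable from
#'   in-tunnel activity.
#' * `cleansing_flight` — very short excursion (default 5-60 s).
#' * `orientation_flight` — learning flight, default 250-300 s.
#' * `failed_exit` / `failed_entry` — partial traversal that turns back;
#'   produces a low-net-displacement detection cluster and no excursion.
#' * `loiter` — lingering near the entrance; a diffuse cluster of
#'   detections with no net displacement.
#'
#' Detection failure has two layers: each frame in view is read with
#' probability `p_frame_detect`, and a whole traversal yields zero
#' detections with probability `p_traversal_missed` (a bee crawling
#' upside-down hides its tag for the entire pass).
#'
#' @param n_bees Number of tagged bees.
#' @param id_range Inclusive tag-ID range; the first `n_bees` IDs are used.
#' @param start Start date-time (naive local) of the scenario.
#' @param duration_days Days of traffic to generate.
#' @param behavior_mix Named probabilities over the six behaviours
#'   (must sum to 1).
#' @param trip_duration_model List: `family` (`"lognormal"`), `meanlog`,
#'   `sdlog`, `min_s`, `max_s`. Durations are truncated to `[min_s, max_s]`:
#'   the floor because the grouping window hides shorter round-trips, the
#'   ceiling (default 4 h) because foragers return the same day.
#' @param orientation_duration_range,cleansing_duration_range Seconds.
#' @param traversal_speed_px_s Walking speed along the tunnel axis.
#' @param frame_rate Camera frame rate, Hz (the field system tops out at 15).
#' @param p_frame_detect Per-frame tag-read probability while in view.
#' @param p_traversal_missed Probability an entire traversal goes undetected.
#' @param excursions_per_bee_day Poisson mean of excursion-or-other
#'   activities per bee per day.
#' @param exact_excursions_per_bee If set, each bee performs exactly this
#'   many activities (scheduled across days as needed) instead of a Poisson
#'   draw; useful for scenarios with a fixed ground-truth count.
#' @param activity_window Daily activity hours (bees fly in daylight).
#' @param dwell_mean_s Mean in-hive dwell between activities, seconds.
#' @param dwell_min_s Minimum dwell between activities (default 120 s): a
#'   returning bee does not re-exit within the grouping window, which would
#'   be unresolvable by any window-based segmentation.
#' @param cross_jitter_px Uniform cross-axis jitter around a traversal lane.
#' @param fov Field of view.
#' @param seed RNG seed; identical scenario + seed gives byte-identical logs.
#' @return An object of class `traffic_scenario`.
#' @export
traffic_scenario <- function(
    n_bees = 20L,
    id_range = c(5000L, 5999L),
    start = "2024-06-01 00:00:00",
    duration_days = 1,
    behavior_mix = c(foraging_trip = 0.55, cleansing_flight = 0.15,
                     orientation_flight = 0.10, failed_exit = 0.08,
                     failed_entry = 0.05, loiter = 0.07),
    trip_duration_model = list(family = "lognormal", meanlog = 6.27,
                               sdlog = 1.22, min_s = 61, max_s = 14400),
    orientation_duration_range = c(250, 300),
    cleansing_duration_range = c(5, 60),
    traversal_speed_px_s = 200,
    frame_rate = 15,
    p_frame_detect = 0.9,
    p_traversal_missed = 0.05,
    excursions_per_bee_day = 6,
    exact_excursions_per_bee = NULL,
    activity_window = c(7, 19),
    dwell_mean_s = 1800,
    dwell_min_s = 120,
    cross_jitter_px = 20,
    fov = beegate::fov(),
    seed = 1L) {
  behaviors <- c("foraging_trip", "cleansing_flight", "orientation_flight",
                 "failed_exit", "failed_entry", "loiter")
  mix <- setNames(rep(0, length(behaviors)), behaviors)
  if (is.null(names(behavior_mix)) ||
      !all(names(behavior_mix) %in% behaviors)) {
    abort(paste0("`behavior_mix` must be named with a subset of: ",
                 paste(behaviors, collapse = ", ")))
  }
  mix[names(behavior_mix)] <- behavior_mix
  if (any(mix < 0) || any(mix > 1) || abs(sum(mix) - 1) > 1e-9) {
    abort("`behavior_mix` entries must be probabilities summing to 1.")
  }
  if (p_frame_detect < 0 || p_frame_detect > 1 ||
      p_traversal_missed < 0 || p_traversal_missed > 1) {
    abort("detection probabilities must lie in [0, 1].")
  }
  if (frame_rate <= 0) abort("`frame_rate` must be positive.")
  if (traversal_speed_px_s <= 0) {
    abort("`traversal_speed_px_s` must be positive.")
  }
  n_ids <- id_range[2] - id_range[1] + 1L
  if (n_bees > n_ids) abort("`id_range` too small for `n_bees`.")
  structure(list(
    n_bees = as.integer(n_bees), id_range = as.integer(id_range),
    start = if (is.character(start))
      as.POSIXct(start, tz = "UTC") else start,
    duration_days = duration_days, behavior_mix = mix,
    trip_duration_model = trip_duration_model,
    orientation_duration_range = orientation_duration_range,
    cleansing_duration_range = cleansing_duration_range,
    traversal_speed_px_s = traversal_speed_px_s, frame_rate = frame_rate,
    p_frame_detect = p_frame_detect,
    p_traversal_missed = p_traversal_missed,
    excursions_per_bee_day = excursions_per_bee_day,
    exact_excursions_per_bee = exact_excursions_per_bee,
    activity_window = activity_window, dwell_mean_s = dwell_mean_s,
    dwell_min_s = dwell_min_s,
    cross_jitter_px = cross_jitter_px, fov = fov, seed = as.integer(seed)
  ), class = "traffic_scenario")
}

draw_dwell <- function(sc) {
  lo <- sc$dwell_min_s %||% 0
  lo + stats::rexp(1, 1 / max(sc$dwell_mean_s - lo, 1))
}

draw_duration <- function(sc, behavior) {
  switch(behavior,
    foraging_trip = {
      m <- sc$trip_duration_model
      lo <- m$min_s %||% 0
      hi <- m$max_s %||% Inf
      d <- rlnorm(1, m$meanlog, m$sdlog)
      tries <- 0L
      while ((d < lo || d > hi) && tries < 1000L) {
        d <- rlnorm(1, m$meanlog, m$sdlog)
        tries <- tries + 1L
      }
      min(max(d, lo), hi)
    },
    cleansing_flight = runif(1, sc$cleansing_duration_range[1],
                             sc$cleansing_duration_range[2]),
    orientation_flight = runif(1, sc$orientation_duration_range[1],
                               sc$orientation_duration_range[2])
  )
}

# map a 1-D tunnel-axis position (0 = hive end) + cross position to x/y/theta
axis_to_xy <- function(p, cross, fov, outbound) {
  ax <- tunnel_axis(fov)
  along <- if (ax$toward_hive < 0) p else ax$length - 1 - p
  if (ax$coord == "x") {
    list(x = along, y = cross,
         theta = if (xor(outbound, ax$toward_hive > 0)) 0 else 180)
  } else {
    list(x = cross, y = along,
         theta = if (xor(outbound, ax$toward_hive > 0)) 90 else 270)
  }
}

# one traversal of the full tunnel; returns detections + in-view endpoints
sim_traversal <- function(sc, tag_id, t0, outbound, partial = 1) {
  ax <- tunnel_axis(sc$fov)
  step <- sc$traversal_speed_px_s / sc$frame_rate
  span <- ax$length * partial
  k <- floor((span - 1e-9) / step)
  if (k < 1) {
    warn("traversal faster than the frame interval; no frames land in view")
    return(list(det = empty_detections(), n = 0L,
                t_first = t0, t_last = t0 + span / sc$traversal_speed_px_s))
  }
  pos <- (0:k) * step
  if (!outbound) pos <- rev(pos)
  times <- t0 + (0:k) / sc$frame_rate
  cross_lane <- runif(1, 0.3, 0.7) *
    (if (ax$coord == "x") sc$fov$height else sc$fov$width)
  cross <- pmin(pmax(cross_lane +
                       runif(k + 1, -sc$cross_jitter_px, sc$cross_jitter_px),
                     0),
                (if (ax$coord == "x") sc$fov$height else sc$fov$width) - 1)
  hit <- runif(k + 1) <= sc$p_frame_detect
  if (runif(1) <= sc$p_traversal_missed) hit[] <- FALSE
  xy <- axis_to_xy(pos, cross, sc$fov, outbound)
  det <- tibble(timestamp = ts_round_ms(.POSIXct(times, tz = "UTC")),
                tag_id = as.integer(tag_id),
                x = xy$x, y = xy$y,
                theta = rep(xy$theta, k + 1),
                cpu_temp = NA_real_)[hit, , drop = FALSE]
  list(det = det, n = sum(hit),
       t_first = times[1], t_last = times[k + 1])
}

# out-and-back partial traversal (failed exit/entry): one unknown-ish cluster
sim_turnaround <- function(sc, tag_id, t0, from_hive) {
  half <- sim_traversal(sc, tag_id, t0, outbound = from_hive, partial = 0.4)
  back <- sim_traversal(sc, tag_id, half$t_last + 1 / sc$frame_rate,
                        outbound = !from_hive, partial = 0.4)
  # mirror the back leg to start where the out leg stopped
  ax <- tunnel_axis(sc$fov)
  if (nrow(back$det)) {
    if (ax$coord == "x") {
      off <- if (ax$toward_hive < 0) 0.6 * ax$length else -0.6 * ax$length
      back$det$x <- pmin(pmax(back$det$x - off, 0), sc$fov$width - 1)
    } else {
      off <- if (ax$toward_hive < 0) 0.6 * ax$length else -0.6 * ax$length
      back$det$y <- pmin(pmax(back$det$y - off, 0), sc$fov$height - 1)
    }
  }
  list(det = bind_rows(half$det, back$det), t_end = back$t_last)
}

sim_loiter <- function(sc, tag_id, t0) {
  dur <- runif(1, 10, 60)
  n_frames <- max(1L, floor(dur * sc$frame_rate))
  times <- t0 + (seq_len(n_frames) - 1) / sc$frame_rate
  cx <- runif(1, 0.3, 0.7) * sc$fov$width
  cy <- runif(1, 0.3, 0.7) * sc$fov$height
  hit <- runif(n_frames) <= sc$p_frame_detect * 0.1
  det <- tibble(
    timestamp = ts_round_ms(.POSIXct(times, tz = "UTC")),
    tag_id = as.integer(tag_id),
    x = pmin(pmax(cx + cumsum(runif(n_frames, -3, 3)), 0), sc$fov$width - 1),
    y = pmin(pmax(cy + cumsum(runif(n_frames, -3, 3)), 0),
             sc$fov$height - 1),
    theta = runif(n_frames, 0, 360) %% 360,
    cpu_temp = NA_real_)[hit, , drop = FALSE]
  list(det = det, t_end = t0 + dur)
}

#' Simulate entrance traffic with ground truth
#'
#' Generates a detection log (valid input for the analysis pipeline) and the
#' ground truth behind it. Each excursion produces an outbound traversal
#' away from the hive side, an absence of the behaviour's duration, and a
#' return traversal; failed exits/entries and loitering produce detection
#' clusters without an excursion. Output is deterministic for a fixed
#' scenario and seed.
#'
#' @param scenario A [traffic_scenario()].
#' @return A list with
#'   * `detections`: chronological detection tibble,
#'   * `truth`: one row per true excursion — `tag_id`, `behavior`,
#'     `t_leave` (last moment in view on the way out), `t_return` (first
#'     moment in view on the way back), `duration_seconds`, `exit_n` /
#'     `enter_n` (detections recorded on each traversal).
#' @export
simulate_traffic <- function(scenario) {
  sc <- scenario
  with_seed(sc$seed, {
    det_parts <- list()
    truth_parts <- list()
    day0 <- as.numeric(sc$start)
    ids <- sc$id_range[1] + seq_len(sc$n_bees) - 1L
    for (b in seq_len(sc$n_bees)) {
      id <- ids[b]
      n_done <- 0L
      for (day in seq_len(ceiling(sc$duration_days))) {
        w_open <- day0 + (day - 1) * 86400 + sc$activity_window[1] * 3600
        w_close <- day0 + (day - 1) * 86400 + sc$activity_window[2] * 3600
        w_close <- min(w_close, day0 + sc$duration_days * 86400)
        if (w_open >= w_close) next
        n_today <- if (is.null(sc$exact_excursions_per_bee)) {
          rpois(1, sc$excursions_per_bee_day)
        } else {
          sc$exact_excursions_per_bee - n_done
        }
        t <- w_open + draw_dwell(sc)
        acts <- 0L
        while (acts < n_today && t < w_close) {
          behavior <- sample(names(sc$behavior_mix), 1,
                             prob = sc$behavior_mix)
          if (behavior %in% c("foraging_trip", "cleansing_flight",
                              "orientation_flight")) {
            dur <- draw_duration(sc, behavior)
            out <- sim_traversal(sc, id, t, outbound = TRUE)
            t_leave <- out$t_last
            t_return <- t_leave + dur
            inb <- sim_traversal(sc, id, t_return, outbound = FALSE)
            det_parts[[length(det_parts) + 1L]] <- out$det
            det_parts[[length(det_parts) + 1L]] <- inb$det
            dur_ms <- round(t_return * 1000) / 1000 -
              round(t_leave * 1000) / 1000
            truth_parts[[length(truth_parts) + 1L]] <- tibble(
              tag_id = id, behavior = behavior,
              t_leave = ts_round_ms(.POSIXct(t_leave, tz = "UTC")),
              t_return = ts_round_ms(.POSIXct(t_return, tz = "UTC")),
              duration_seconds = dur_ms,
              exit_n = out$n, enter_n = inb$n)
            t <- inb$t_last
            n_done <- n_done + 1L
          } else if (behavior %in% c("failed_exit", "failed_entry")) {
            res <- sim_turnaround(sc, id, t,
                                  from_hive = behavior == "failed_exit")
            det_parts[[length(det_parts) + 1L]] <- res$det
            t <- res$t_end
          } else {
            res <- sim_loiter(sc, id, t)
            det_parts[[length(det_parts) + 1L]] <- res$det
            t <- res$t_end
          }
          acts <- acts + 1L
          t <- t + draw_dwell(sc)
        }
        if (!is.null(sc$exact_excursions_per_bee) &&
            n_done >= sc$exact_excursions_per_bee) break
      }
    }
    det <- if (length(det_parts)) bind_rows(det_parts) else
      empty_detections()
    det <- det[order(det$timestamp), , drop = FALSE]
    truth <- if (length(truth_parts)) {
      bind_rows(truth_parts) |> arrange(.data$tag_id, .data$t_leave)
    } else {
      tibble(tag_id = integer(0), behavior = character(0),
             t_leave = .POSIXct(numeric(0), tz = "UTC"),
             t_return = .POSIXct(numeric(0), tz = "UTC"),
             duration_seconds = numeric(0), exit_n = integer(0),
             enter_n = integer(0))
    }
    list(detections = det, truth = truth)
  })
}

#' Trip recovery rate against simulator ground truth
#'
#' A true excursion counts as *detectable* when both its traversals yielded
#' enough detections for a directional label and its duration exceeds the
#' grouping window (shorter round-trips are unresolvable by design). A
#' detectable excursion is *recovered* when some extracted trip of the same
#' tag overlaps it in time and agrees with its duration within
#' `tolerance_s`.
#'
#' @param truth Ground-truth tibble from [simulate_traffic()].
#' @param trips Trip tibble from [extract_trips()] run on the simulated log.
#' @param tolerance_s Duration agreement tolerance, seconds.
#' @param gap_seconds Grouping window the pipeline used.
#' @param min_detections Detections each traversal needs to be directional.
#' @return List: `rate` (recovered / detectable; `NA` if none detectable),
#'   `n_detectable`, `n_recovered`, and `matches` — one row per detectable
#'   excursion with `matched` and `duration_error_s`.
#' @export
recovery_rate <- function(truth, trips, tolerance_s = 1,
                          gap_seconds = 60, min_detections = 2L) {
  detectable <- truth$exit_n >= min_detections &
    truth$enter_n >= min_detections &
    truth$duration_seconds > gap_seconds
  td <- truth[detectable, , drop = FALSE]
  if (nrow(td) == 0L) {
    return(list(rate = NA_real_, n_detectable = 0L, n_recovered = 0L,
                matches = tibble(tag_id = integer(0), matched = logical(0),
                                 duration_error_s = numeric(0))))
  }
  matched <- logical(nrow(td))
  err <- rep(NA_real_, nrow(td))
  for (i in seq_len(nrow(td))) {
    cand <- trips[trips$tag_id == td$tag_id[i] &
                    as.numeric(trips$t_exit) <= as.numeric(td$t_return[i]) &
                    as.numeric(trips$t_enter) >= as.numeric(td$t_leave[i]), ,
                  drop = FALSE]
    if (nrow(cand)) {
      e <- abs(cand$duration_seconds - td$duration_seconds[i])
      err[i] <- min(e)
      matched[i] <- any(e <= tolerance_s)
    }
  }
  list(rate = mean(matched), n_detectable = nrow(td),
       n_recovered = sum(matched),
       matches = tibble(tag_id = td$tag_id, matched = matched,
                        duration_error_s = err))
}
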