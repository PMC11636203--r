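test_that("an exit followed by an enter forms one trip", {
  ev <- make_events(make_event(5059, 0, 100, "exit"),
                    make_event(5059, 183, 200, "enter"))
  tr <- extract_trips(ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$duration_seconds, 83)
})

test_that("wrong order, lone events and empty inputs yield no trips", {
  expect_equal(nrow(extract_trips(make_events(
    make_event(1, 0, 10, "enter"), make_event(1, 100, 110, "exit")))), 0L)
  expect_equal(nrow(extract_trips(make_events(
    make_event(1, 0, 10, "exit")))), 0L)
  expect_equal(nrow(extract_trips(make_events(make_event(1, 0, 10, "exit"))[0, ])),
               0L)
})

test_that("the latest of several exits is paired; earlier ones are failed exits", {
  ev <- make_events(make_event(1, 0, 10, "exit"),
                    make_event(1, 100, 110, "exit"),
                    make_event(1, 300, 310, "enter"))
  tr <- extract_trips(ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$exit_event_id, 2L)
  expect_equal(tr$duration_seconds, 190)
})

test_that("unknown events are removed before pairing", {
  ev <- make_events(make_event(1, 0, 10, "exit"),
                    make_event(1, 50, 60, "unknown"),
                    make_event(1, 300, 310, "enter"))
  tr <- extract_trips(ev)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$duration_seconds, 290)
  # adding an isolated unknown event never decreases the trip count
  ev2 <- make_events(make_event(1, 0, 10, "exit"),
                     make_event(1, 300, 310, "enter"),
                     make_event(1, 500, 505, "unknown"))
  expect_gte(nrow(extract_trips(ev2)), nrow(tr))
})

test_that("unset categories are an error", {
  ev <- make_event(1, 0, 10, "exit")
  ev$category <- NA_character_
  expect_error(extract_trips(ev), "classify")
})

test_that("trips never share events and are disjoint in time per tag", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(4:14, 1)
      starts <- sort(sample(0:5000, n)) * 10
      evs <- lapply(seq_len(n), function(i) {
        make_event(sample(1:2, 1), starts[i], starts[i] + 5,
                   sample(c("exit", "enter", "unknown"), 1))
      })
      ev <- do.call(make_events, evs)
      tr <- extract_trips(ev)
      used <- c(tr$exit_event_id, tr$enter_event_id)
      expect_equal(anyDuplicated(used), 0L)
      for (id in unique(tr$tag_id)) {
        ti <- tr[tr$tag_id == id, ]
        if (nrow(ti) > 1L) {
          expect_true(all(diff(as.numeric(ti$t_exit)) > 0))
          expect_true(all(head(as.numeric(ti$t_enter), -1) <=
                            tail(as.numeric(ti$t_exit), -1)))
        }
      }
      expect_true(all(tr$duration_seconds > 0))
    }
  })
})

test_that("duration statistics match hand arithmetic", {
  tr <- empty_trips_for_test(c(118, 118, 1118))
  st <- trip_statistics(tr)
  expect_equal(st$mode, 118)
  expect_equal(st$median, 118)
  expect_equal(st$mean, mean(c(118, 118, 1118)), tolerance = 1e-12)
  expect_equal(round(st$mean, 2), 451.33)
  st1 <- trip_statistics(empty_trips_for_test(83))
  expect_equal(c(st1$mean, st1$median, st1$mode), c(83, 83, 83))
  # histogram counts sum to n
  expect_equal(sum(st$histogram$count), st$n)
})

test_that("empty trips produce a flagged, non-crashing summary", {
  st <- trip_statistics(extract_trips(make_event(1, 0, 1, "unknown")))
  expect_equal(st$n, 0L)
  expect_true(st$empty)
  expect_true(is.na(st$mean))
  expect_output(print(st), "no trips")
})

test_that("sample mean of simulated durations matches the mixture mean", {
  withr::with_seed(77, {
    n <- 10000
    pick <- runif(n) < 0.7
    dur <- ifelse(pick, rlnorm(n, 5, 0.5), runif(n, 250, 300))
    mix_mean <- 0.7 * exp(5 + 0.5^2 / 2) + 0.3 * 275
    mix_var <- 0.7 * ((exp(0.5^2) - 1) * exp(10 + 0.5^2) +
                        exp(5 + 0.5^2 / 2)^2) +
      0.3 * ((300 - 250)^2 / 12 + 275^2) - mix_mean^2
    st <- trip_statistics(empty_trips_for_test(dur))
    expect_lt(abs(st$mean - mix_mean), 3 * sqrt(mix_var / n))
  })
})

test_that("the report aggregates counts, percentages and tallies", {
  d <- detections(base_time + c(0, 5, 100, 105, 400, 405, 800, 805),
                  rep(c(1001L, 1002L), 4),
                  x = c(650, 100, 60, 650, 100, 650, 400, 410),
                  y = 100, theta = 0)
  ev <- classify_events(group_events(d))
  tr <- extract_trips(ev)
  rep_ <- build_report(d, ev, tr)
  expect_equal(rep_$n_detections, 8L)
  expect_equal(sum(rep_$category_counts), rep_$n_events)
  expect_equal(sum(rep_$category_pct), 100, tolerance = 1e-9)
  expect_equal(sum(rep_$per_id$detections), 8L)
  expect_equal(rep_$per_id$colony, c("worker01", "worker01"))
})

test_that("category percentages follow the labels exactly", {
  ev <- make_events(make_event(1, 0, 10, "enter"),
                    make_event(1, 100, 110, "exit"),
                    make_event(1, 200, 210, "unknown"),
                    make_event(1, 300, 310, "unknown"))
  d <- detections(base_time + c(0, 10, 100, 110, 200, 210, 300, 310),
                  1L, x = 1, y = 1, theta = 0)
  ev$n_detections <- 2L
  rep_ <- build_report(d, ev, extract_trips(ev))
  expect_equal(unname(rep_$category_pct), c(25, 25, 50))
})

test_that("an all-zero report prints em dashes rather than NaN", {
  rep_ <- build_report(make_det(0)[0, ], group_events(make_det(0)[0, ]),
                       extract_trips(group_events(make_det(0)[0, ])))
  expect_equal(rep_$n_detections, 0L)
  out <- paste(utils::capture.output(print(rep_)), collapse = "\n")
  expect_match(out, "—")
})

test_that("inconsistent report inputs raise a named error", {
  d <- make_det(c(0, 5))
  ev <- classify_events(group_events(d))
  expect_error(build_report(d[1, ], ev, extract_trips(ev)), "partition")
  tr <- tibble::tibble(tag_id = 1L, exit_event_id = 99L,
                       enter_event_id = 100L, t_exit = base_time,
                       t_enter = base_time + 100, duration_seconds = 100)
  expect_error(build_report(d, ev, tr), "reference")
})

test_that("the events spreadsheet mirrors the event table", {
  d <- detections(base_time + c(0, 5, 100, 105), 5059L,
                  x = c(650, 60, 60, 650), y = 100, theta = 0)
  ev <- classify_events(group_events(d))
  csv <- withr::local_tempfile(fileext = ".csv")
  paths <- write_events_spreadsheet(ev, csv)
  rows <- utils::read.csv(csv)
  expect_equal(nrow(rows), nrow(ev))
  expect_equal(rows$tag_id, ev$tag_id)
  expect_equal(rows$category, ev$category)
  expect_true(file.exists(paths[["xls"]]))
  expect_match(readLines(paths[["xls"]], n = 3)[3], "Workbook")
  # zero events: header-only CSV
  empty_csv <- withr::local_tempfile(fileext = ".csv")
  write_events_spreadsheet(ev[0, ], empty_csv)
  expect_equal(length(readLines(empty_csv)), 1L)
})
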