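test_that("identical scenario and seed give byte-identical logs", {
  sc <- traffic_scenario(n_bees = 4, duration_days = 0.5, seed = 3)
  a <- simulate_traffic(sc)
  b <- simulate_traffic(sc)
  expect_identical(write_detection_log(a$detections),
                   write_detection_log(b$detections))
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
  # a different seed gives a different stream
  sc2 <- traffic_scenario(n_bees = 4, duration_days = 0.5, seed = 4)
  c <- simulate_traffic(sc2)
  expect_false(identical(write_detection_log(a$detections),
                         write_detection_log(c$detections)))
})

test_that("degenerate scenarios behave", {
  empty <- simulate_traffic(traffic_scenario(n_bees = 0, seed = 1))
  expect_equal(nrow(empty$detections), 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(traffic_scenario(behavior_mix = c(foraging_trip = 0.5)),
               "summing to 1")
  expect_error(traffic_scenario(p_frame_detect = 1.2), "\\[0, 1\\]")
  expect_error(traffic_scenario(n_bees = 10, id_range = c(1, 5)),
               "id_range")
})

test_that("a traversal faster than the frame interval warns", {
  sc <- traffic_scenario(n_bees = 1, exact_excursions_per_bee = 1,
                         behavior_mix = c(foraging_trip = 1),
                         traversal_speed_px_s = 1e6, seed = 2)
  w <- testthat::capture_warnings(simulate_traffic(sc))
  expect_true(any(grepl("frame", w)))
})

test_that("perfect detection writes every traversal to the log", {
  sc <- traffic_scenario(n_bees = 10, exact_excursions_per_bee = 2,
                         duration_days = 2,
                         behavior_mix = c(foraging_trip = 1),
                         p_frame_detect = 1, p_traversal_missed = 0,
                         seed = 5)
  sim <- simulate_traffic(sc)
  expect_equal(nrow(sim$truth), 20L)
  expect_true(all(sim$truth$exit_n >= 2))
  expect_true(all(sim$truth$enter_n >= 2))
  # the log parses and validates under the scenario's field of view
  lines <- write_detection_log(sim$detections, fov = sc$fov)
  reparsed <- parse_detection_lines(lines, fov = sc$fov)
  expect_equal(nrow(reparsed), nrow(sim$detections))
})

test_that("excursion durations respect the configured ranges", {
  sc <- traffic_scenario(n_bees = 12, duration_days = 1,
                         behavior_mix = c(cleansing_flight = 0.5,
                                          orientation_flight = 0.5),
                         seed = 6)
  sim <- simulate_traffic(sc)
  cl <- sim$truth[sim$truth$behavior == "cleansing_flight", ]
  or <- sim$truth[sim$truth$behavior == "orientation_flight", ]
  expect_gt(nrow(cl), 0L)
  expect_gt(nrow(or), 0L)
  expect_true(all(cl$duration_seconds >= 5 - 1e-6 &
                    cl$duration_seconds <= 60 + 1e-6))
  expect_true(all(or$duration_seconds >= 250 - 1e-6 &
                    or$duration_seconds <= 300 + 1e-6))
  # excursions per bee are time-ordered and non-overlapping
  for (id in unique(sim$truth$tag_id)) {
    tr <- sim$truth[sim$truth$tag_id == id, ]
    if (nrow(tr) > 1L) {
      expect_true(all(head(as.numeric(tr$t_return), -1) <=
                        tail(as.numeric(tr$t_leave), -1)))
    }
  }
})

test_that("whole-traversal misses occur at the configured rate", {
  sc <- traffic_scenario(n_bees = 25, exact_excursions_per_bee = 20,
                         duration_days = 4,
                         behavior_mix = c(foraging_trip = 1),
                         trip_duration_model = list(
                           family = "lognormal", meanlog = 4.8,
                           sdlog = 0.3, min_s = 61, max_s = 600),
                         p_frame_detect = 1, p_traversal_missed = 0.5,
                         dwell_mean_s = 120, seed = 8)
  sim <- simulate_traffic(sc)
  n_trav <- 2L * nrow(sim$truth)
  expect_gte(n_trav, 900L)
  missed <- sum(sim$truth$exit_n == 0) + sum(sim$truth$enter_n == 0)
  ci <- qbinom(c(0.005, 0.995), n_trav, 0.5)
  expect_gte(missed, ci[1])
  expect_lte(missed, ci[2])
})

test_that("recovery on a perfect scenario is total, on an empty one zero", {
  sc <- traffic_scenario(n_bees = 6, exact_excursions_per_bee = 3,
                         duration_days = 2,
                         behavior_mix = c(foraging_trip = 1),
                         p_frame_detect = 1, p_traversal_missed = 0,
                         seed = 9)
  sim <- simulate_traffic(sc)
  res <- analyze_colony(sim$detections, run_config(fov = sc$fov,
                                                   verbose = FALSE))
  rr <- recovery_rate(sim$truth, res$trips, tolerance_s = 2 / sc$frame_rate)
  expect_equal(rr$rate, 1)
  expect_equal(rr$n_detectable, 18L)
  # with every traversal missed nothing can be recovered
  rr0 <- recovery_rate(sim$truth, res$trips[0, ], tolerance_s = 1)
  expect_equal(rr0$rate, 0)
})

test_that("recovery_rate agrees with a brute-force matcher", {
  sc <- traffic_scenario(n_bees = 8, duration_days = 1,
                         p_frame_detect = 0.6, p_traversal_missed = 0.15,
                         seed = 10)
  sim <- simulate_traffic(sc)
  res <- analyze_colony(sim$detections, run_config(fov = sc$fov,
                                                   verbose = FALSE))
  for (tol in c(0.5, 5, 30)) {
    rr <- recovery_rate(sim$truth, res$trips, tolerance_s = tol)
    expect_equal(rr$rate,
                 brute_force_recovery(sim$truth, res$trips, tol))
  }
})
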