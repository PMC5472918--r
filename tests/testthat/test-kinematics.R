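test_that("segmentation yields floor((n-1)/20) windows of 20 sub-segments", {
  pos <- cbind(rep(25, 101), rep(75, 101))
  expect_length(segment_track(fly_track("a", pos)), 5L)
  expect_length(segment_track(fly_track("a", pos[1:25, ])), 1L)
  # a full 6-h session: 86,400 sub-segments -> 4,320 segments
  pos6h <- cbind(rep(25, 86401), rep(75, 86401))
  segs <- segment_track(fly_track("a", pos6h))
  expect_length(segs, 4320L)
  expect_true(all(vapply(segs, function(s) nrow(s$disp), integer(1)) == 20L))
  expect_error(segment_track(fly_track("a", pos[1:21, ], dt = 0.5)),
               "0.25")
})

test_that("speed is total path over 5 s", {
  expect_equal(compute_speed(segment_from_disp(matrix(0, 20, 2))), 0)
  line <- cbind(rep(1, 20), rep(0, 20))
  expect_equal(compute_speed(segment_from_disp(line)), 4)
  set.seed(1)
  d <- matrix(rnorm(40, 0, 0.5), 20, 2)
  expect_equal(compute_speed(segment_from_disp(d)),
               sum(sqrt(rowSums(d^2))) / 5)
})

test_that("acceleration is the mean absolute speed difference per 0.25 s", {
  line <- cbind(rep(1, 20), rep(0, 20))
  expect_equal(compute_acceleration(segment_from_disp(line)), 0)
  # v alternating 0 and 1 mm/s: every consecutive pair differs by 1 mm/s
  alt <- cbind(rep(c(0, 0.25), 10), 0)
  expect_equal(compute_acceleration(segment_from_disp(alt)), 4)
  set.seed(2)
  d <- matrix(rnorm(40, 0, 0.5), 20, 2)
  v <- sqrt(rowSums(d^2)) / 0.25
  expect_equal(compute_acceleration(segment_from_disp(d)),
               mean(abs(diff(v))) / 0.25)
})

test_that("stop duration counts sub-segments strictly below 0.1 mm", {
  expect_equal(compute_stop_duration(
    segment_from_disp(cbind(rep(0.05, 20), 0))), 5)
  # exactly 0.1 mm is movement (strict inequality)
  expect_equal(compute_stop_duration(
    segment_from_disp(cbind(rep(0.1, 20), 0))), 0)
  d <- cbind(c(rep(0.01, 7), rep(0.5, 13)), 0)
  expect_equal(compute_stop_duration(segment_from_disp(d)), 1.75)
})

test_that("locomotory rate excludes stop time and dominates speed", {
  # 2 mm traveled in 1 s of movement, 4 s stopped
  d <- cbind(c(rep(0.5, 4), rep(0, 16)), 0)
  seg <- segment_from_disp(d)
  expect_equal(compute_speed(seg), 0.4)
  expect_equal(compute_locomotory_rate(seg), 2)
  # never stops: locomotory rate equals speed
  line <- segment_from_disp(cbind(rep(1, 20), 0))
  expect_equal(compute_locomotory_rate(line), compute_speed(line))
  # fully stopped: undefined
  expect_true(is.na(compute_locomotory_rate(
    segment_from_disp(matrix(0, 20, 2)))))
})

test_that("meander is zero on a line and ~1/r on a circular arc", {
  expect_equal(compute_meander(segment_from_disp(cbind(rep(1, 20), 0))), 0)
  r <- 10
  theta <- 0.1
  ang <- (0:20) * theta
  pos <- cbind(25 + r * cos(ang), 75 + r * sin(ang))
  seg <- segment_track(fly_track("arc", pos))[[1]]
  # exact value of the discrete estimator on a regular arc:
  # 19 heading changes of theta over 20 chords of 2 r sin(theta/2)
  expect_equal(compute_meander(seg), 19 * theta / (20 * 2 * r * sin(theta / 2)),
               tolerance = 1e-10)
  expect_equal(compute_meander(seg), 1 / r, tolerance = 0.06)
  expect_true(is.na(compute_meander(segment_from_disp(matrix(0, 20, 2)))))
})

test_that("slip events are maximal runs of steep downward sub-segments", {
  up <- cbind(0, rep(1, 20))
  expect_equal(count_slips(segment_from_disp(up)), 0)
  d <- cbind(0, rep(0.5, 20))
  d[8:10, 2] <- -4               # one 3-step downward run counts once
  expect_equal(count_slips(segment_from_disp(d, start = c(25, 100))), 1)
  d[15, 2] <- -3                 # a separate run is a second event
  expect_equal(count_slips(segment_from_disp(d, start = c(25, 100))), 2)
  # threshold is strict: exactly -2 mm does not trigger
  expect_equal(count_slips(segment_from_disp(cbind(0, rep(-2, 20)),
                                             start = c(25, 140))), 0)
})

test_that("the detector recovers the simulator's injected slips", {
  p <- test_preset(slip_rate = 1.2)
  cfg <- simulation_config(duration = 1800, n_individuals = 1, seed = 6)
  detected <- injected <- 0
  for (i in 1:5) {
    tr <- generate_track(p, cfg, individual_seed = i)
    injected <- injected + nrow(attr(tr, "slip_events"))
    detected <- detected + sum(extract_features(tr)$slipping_number)
  }
  expect_gte(detected / injected, 0.95)
  expect_lte(detected / injected, 1.1)
})

test_that("zone occupancy conserves time and follows the track", {
  pos <- cbind(rep(25, 241), rep(145, 241))  # 60 s pinned in the top band
  occ <- zone_occupancy(fly_track("t", pos))
  expect_equal(occ$top, c(30, 30))
  expect_equal(occ$bottom + occ$food + occ$middle, c(0, 0))
  overall <- attr(occ, "overall")
  expect_equal(unname(overall[["top"]]), 60)
  # windows always sum to the window length (last may be shorter)
  pos2 <- cbind(runif(175, 0, 50), runif(175, 0, 150))
  occ2 <- zone_occupancy(fly_track("u", pos2))
  expect_equal(rowSums(occ2[, zone_levels()]), c(30, 13.5))
})

test_that("a drift-free walk splits its time roughly evenly top vs bottom", {
  p <- test_preset(geotaxis_drift = 0, slip_rate = 0, move_speed_mean = 5,
                   p_stop_entry = 0.05, p_stop_exit = 0.9, turn_sd = 0.3)
  cfg <- simulation_config(duration = 1800, n_individuals = 1, seed = 2)
  tot <- c(top = 0, bottom = 0)
  for (i in 1:8) {
    ov <- attr(zone_occupancy(generate_track(p, cfg, individual_seed = i)),
               "overall")
    tot <- tot + ov[c("top", "bottom")]
  }
  expect_lt(abs(tot[["top"]] - tot[["bottom"]]) / sum(tot), 0.25)
})

test_that("extract_features matches the per-segment operations", {
  p <- test_preset()
  cfg <- simulation_config(duration = 120, n_individuals = 1, seed = 8)
  tr <- generate_track(p, cfg, individual_seed = 3)
  f <- extract_features(tr)
  segs <- segment_track(tr)
  expect_equal(nrow(f), length(segs))
  expect_true(all(feature_names() %in% names(f)))
  for (i in seq_along(segs)) {
    expect_equal(f$speed[i], compute_speed(segs[[i]]))
    expect_equal(f$acceleration[i], compute_acceleration(segs[[i]]))
    expect_equal(f$locomotory_rate[i], compute_locomotory_rate(segs[[i]]))
    expect_equal(f$meander[i], compute_meander(segs[[i]]))
    expect_equal(f$stop_duration[i], compute_stop_duration(segs[[i]]))
    expect_equal(f$slipping_number[i], count_slips(segs[[i]]))
  }
})

test_that("per-segment invariants hold on simulated data", {
  p <- test_preset(slip_rate = 0.8)
  cfg <- simulation_config(duration = 600, n_individuals = 1, seed = 10)
  f <- extract_features(generate_track(p, cfg, individual_seed = 2))
  ok <- !is.na(f$locomotory_rate)
  expect_true(all(f$locomotory_rate[ok] >= f$speed[ok] - 1e-12))
  expect_true(all(f$stop_duration >= 0 & f$stop_duration <= 5))
  expect_true(all(f$speed >= 0))
})
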