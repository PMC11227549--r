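# Trajectory from a per-step speed-magnitude profile: the path zigzags along
# x inside the arena so only the speed series matters.
traj_from_speeds <- function(v, dt = 0.1) {
  x <- 0.1
  dirn <- 1
  xs <- x
  for (s in v) {
    step <- s * dt
    if (x + dirn * step > 0.95 || x + dirn * step < 0.05) dirn <- -dirn
    x <- x + dirn * step
    xs <- c(xs, x)
  }
  make_traj(t = seq_along(xs) * dt - dt, cx = xs, cy = rep(0.5, length(xs)))
}

test_that("choice classification applies the inside-at-deadline rule", {
  geom <- arena_geometry()
  trial <- make_trial(quadrant = 1L)

  parked <- make_traj(t = seq(0, 10.5, 0.1),
                      cx = rep(0.2, 106), cy = rep(0.2, 106))
  res <- classify_choice(trial, parked, geom)
  expect_equal(res$outcome, "accept")
  expect_equal(res$t_zone_entry, 4)   # first sample of the approach window

  far <- make_traj(t = seq(0, 10.5, 0.1),
                   cx = rep(0.8, 106), cy = rep(0.8, 106))
  expect_equal(classify_choice(trial, far, geom)$outcome, "reject")

  # enter 3 s after cue, leave 5 s after cue: outside at the deadline
  t <- seq(0, 10.5, 0.1)
  cx <- ifelse(t >= 7 & t < 9, 0.2, 0.6)
  cy <- ifelse(t >= 7 & t < 9, 0.2, 0.6)
  dip <- classify_choice(trial, make_traj(t, cx, cy), geom)
  expect_equal(dip$outcome, "reject")
  expect_equal(dip$t_zone_entry, 7)

  # coverage gap over the deadline -> unscorable
  gap <- parked[parked$t < 8, ]
  expect_equal(classify_choice(trial, gap, geom)$outcome, "unscorable")
})

test_that("distance traveled matches a brute-force step sum", {
  still <- make_traj(t = seq(0, 1, 0.1), cx = rep(0.4, 11), cy = rep(0.4, 11))
  expect_equal(distance_traveled(still), 0)

  tri <- make_traj(t = c(0, 0.1), cx = c(0, 0.3), cy = c(0, 0.4))
  expect_equal(distance_traveled(tri), 0.5)   # 3-4-5 triangle

  set.seed(99)
  walk <- make_traj(
    t = seq(0, 19.9, 0.1),
    cx = pmin(pmax(cumsum(rnorm(200, 0, 0.01)) + 0.5, 0), 1),
    cy = pmin(pmax(cumsum(rnorm(200, 0, 0.01)) + 0.5, 0), 1)
  )
  brute <- 0
  for (i in 2:nrow(walk)) {
    brute <- brute + sqrt((walk$cx[i] - walk$cx[i - 1])^2 +
                            (walk$cy[i] - walk$cy[i - 1])^2)
  }
  expect_equal(distance_traveled(walk), brute)
  # path length dominates net displacement
  expect_gte(distance_traveled(walk),
             sqrt((walk$cx[200] - walk$cx[1])^2 + (walk$cy[200] - walk$cy[1])^2))

  expect_true(is.na(distance_traveled(walk[1, ])))
})

test_that("travel pixels counts distinct cells including crossed ones", {
  still <- make_traj(t = c(0, 0.1), cx = c(0.5, 0.5), cy = c(0.5, 0.5))
  expect_equal(travel_pixels(still, grid_n = 8), 1)
  expect_equal(travel_pixels(still, grid_n = 1), 1)

  diag8 <- line_traj(c(0, 0), c(1, 1), duration = 1)
  expect_equal(travel_pixels(diag8, grid_n = 8), 8)
  expect_equal(travel_pixels(diag8, grid_n = 1), 1)

  # a sparse two-sample horizontal hop still counts the cells in between
  hop <- make_traj(t = c(0, 0.1), cx = c(0.05, 0.95), cy = c(0.5, 0.5))
  expect_equal(travel_pixels(hop, grid_n = 8), 8)
})

test_that("high-speed runs count maximal acceleration-outlier runs", {
  const <- traj_from_speeds(rep(0.15, 60))
  expect_equal(high_speed_runs(const)$n_runs, 0)

  one_step <- traj_from_speeds(c(rep(0.1, 30), rep(0.6, 30)))
  expect_equal(high_speed_runs(one_step)$n_runs, 1)

  two_steps <- traj_from_speeds(
    c(rep(0.1, 20), rep(0.6, 20), rep(0.6, 1), rep(0.1, 19))
  )
  hs <- high_speed_runs(two_steps)
  expect_equal(hs$n_runs, 2)
  expect_gte(hs$n_outliers, hs$n_runs)
  expect_equal(hs$per_unit_travel,
               hs$n_runs / distance_traveled(two_steps))
})

test_that("stopping points merge overlapping stationary windows", {
  still10 <- make_traj(t = seq(0, 10, 0.1), cx = rep(0.3, 101),
                       cy = rep(0.3, 101))
  expect_equal(stopping_points(still10), 1)

  run <- traj_from_speeds(rep(0.2, 100))
  expect_equal(stopping_points(run), 0)

  # two 4-s stationary bouts separated by a 5-s run
  t <- seq(0, 13, 0.1)
  cx <- c(rep(0.2, 41), 0.2 + 0.15 * seq(0.1, 5, 0.1), rep(0.95, 40))
  two <- make_traj(t, cx, rep(0.5, length(t)))
  expect_equal(stopping_points(two), 2)

  # brute-force window scan agrees on a seeded mixed trajectory
  set.seed(7)
  v <- rep(0.2, 120)
  v[31:70] <- 0        # one 4-s stop
  mixed <- traj_from_speeds(v)
  brute <- function(traj, eps = 0.1, window = 3) {
    n <- nrow(traj)
    flags <- logical(n)
    for (i in seq_len(n)) {
      idx <- which(traj$t >= traj$t[i] - 1e-9 &
                     traj$t <= traj$t[i] + window + 1e-9)
      if (max(traj$t[idx]) < traj$t[i] + window - 1e-9) next
      flags[i] <- diff(range(traj$cx[idx])) < eps &&
        diff(range(traj$cy[idx])) < eps
    }
    sum(rle(flags)$values)
  }
  expect_equal(stopping_points(mixed), brute(mixed))
  expect_equal(stopping_points(mixed), 1)
})

test_that("rotation points detect >180 degree sweeps within 1.5 s", {
  t <- seq(0, 5, 0.1)
  heading_traj <- function(theta) {
    make_traj(t, cx = rep(0.5, length(t)), cy = rep(0.5, length(t)),
              hx = 0.5 + 0.05 * cos(theta), hy = 0.5 + 0.05 * sin(theta))
  }

  expect_equal(rotation_points(heading_traj(rep(0.3, length(t)))), 0)

  sweep200 <- ifelse(t <= 1, t * 200 * pi / 180, 200 * pi / 180)
  expect_equal(rotation_points(heading_traj(sweep200)), 1)

  # +-90 degree slow oscillation never accumulates 180 within a window
  osc <- (pi / 2) * (1 - abs((t %% 3) - 1.5) / 1.5)
  expect_equal(rotation_points(heading_traj(osc)), 0)

  nohead <- make_traj(t, rep(0.5, length(t)), rep(0.5, length(t)),
                      hx = rep(NA_real_, length(t)),
                      hy = rep(NA_real_, length(t)))
  expect_true(is.na(rotation_points(nohead)))
})

test_that("approach and reaction times follow their definitions", {
  trial <- make_trial(outcome = "accept", t_zone_entry = 2.3)
  still <- make_traj(t = seq(0, 10, 0.1), cx = rep(0.5, 101),
                     cy = rep(0.5, 101))
  at <- approach_and_reaction_time(trial, still)
  expect_equal(at$approach_time, 2.3)

  rej <- make_trial(outcome = "reject")
  expect_true(is.na(approach_and_reaction_time(rej, still)$approach_time))

  # scripted 0.8 s hold before moving at 0.25 units/s
  t <- seq(0, 5, 0.1)
  cx <- ifelse(t <= 0.8, 0.2, pmin(0.2 + 0.25 * (t - 0.8), 0.95))
  lat <- approach_and_reaction_time(make_trial(), make_traj(t, cx, rep(0.5, 51)),
                                    eps_move = 0.02)
  expect_equal(lat$reaction_time, 0.8)
})

test_that("zone-occupancy fraction counts samples outside all four zones", {
  geom <- arena_geometry()
  inside <- make_traj(t = seq(0, 1, 0.1), cx = rep(0.2, 11), cy = rep(0.2, 11))
  expect_equal(prop_outside_reward_zones(inside, geom), 0)

  centre <- make_traj(t = seq(0, 1, 0.1), cx = rep(0.5, 11), cy = rep(0.5, 11))
  expect_equal(prop_outside_reward_zones(centre, geom), 1)

  half <- make_traj(t = seq(0, 1.9, 0.1),
                    cx = c(rep(0.2, 10), rep(0.5, 10)),
                    cy = c(rep(0.2, 10), rep(0.5, 10)))
  expect_equal(prop_outside_reward_zones(half, geom), 0.5)
})

test_that("approach-rate map reports exact per-cell fractions, empty cells absent", {
  feats <- tibble::tibble(
    reward_level = c(1, 1, 1, 2, 2, 4),
    cost_lux = c(15, 15, 320, 15, 15, 15),
    choice = c("accept", "reject", "reject", "accept", "accept", "accept")
  )
  m <- approach_rate_map(feats)
  expect_equal(m$p_accept[m$reward_level == 1 & m$cost_lux == 15], 0.5)
  expect_equal(m$p_accept[m$reward_level == 1 & m$cost_lux == 320], 0)
  expect_equal(m$p_accept[m$reward_level == 2 & m$cost_lux == 15], 1)
  # reward 3 was never offered: no row, not a zero
  expect_equal(nrow(m[m$reward_level == 3, ]), 0)
  expect_equal(sum(m$n_offered), 6)
})

test_that("extractor counts equal the simulator event log with noise off", {
  for (seed in c(3, 17)) {
    sim <- quiet_session(seed = seed, n_trials = 10,
                         speed_sd = 0, heading_sd = 0)
    feats <- extract_features(sim$session)
    truth <- sim$truth$per_trial
    expect_equal(feats$n_stops, truth$n_stops)
    expect_equal(feats$n_rotations, truth$n_rotations)
    expect_equal(feats$choice, truth$outcome)
    expect_equal(feats$t_zone_entry, truth$t_zone_entry)
    expect_equal(nrow(feats), nrow(sim$session$trials))
  }
})

test_that("features are invariant to uniform time shifts", {
  sim <- quiet_session(seed = 23, n_trials = 3)
  sl <- trial_tracking(sim$session, 2)
  shifted <- dplyr::mutate(sl, t = .data$t + 137.4)
  expect_equal(distance_traveled(sl), distance_traveled(shifted))
  expect_equal(travel_pixels(sl), travel_pixels(shifted))
  expect_equal(stopping_points(sl), stopping_points(shifted))
  expect_equal(rotation_points(sl), rotation_points(shifted))
  expect_equal(high_speed_runs(sl)$n_runs, high_speed_runs(shifted)$n_runs)
})
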