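# Shared fixtures built in code.

# A tracking tibble from explicit vectors; head defaults to facing +x.
make_traj <- function(t, cx, cy, hx = NULL, hy = NULL, head_offset = 0.05) {
  if (is.null(hx)) hx <- cx + head_offset
  if (is.null(hy)) hy <- cy
  tibble::tibble(t = t, cx = cx, cy = cy,
                 hx = pmin(pmax(hx, 0), 1), hy = pmin(pmax(hy, 0), 1))
}

# A straight constant-speed path between two points sampled at dt.
line_traj <- function(from, to, duration, dt = 0.1, t0 = 0) {
  t <- seq(t0, t0 + duration, by = dt)
  s <- (t - t0) / duration
  make_traj(t, from[1] + s * (to[1] - from[1]), from[2] + s * (to[2] - from[2]))
}

# One-row trial record with standard timing (tone at t0, cue +4 s, 6 s window).
make_trial <- function(trial_idx = 1L, quadrant = 1L, reward_level = 1L,
                       t0 = 0, outcome = "reject", t_zone_entry = NA_real_) {
  tibble::tibble(
    trial_idx = trial_idx, reward_level = reward_level,
    sucrose_pct = c(0.5, 2, 5, 9)[reward_level], cost_lux = 15,
    offered_quadrant = quadrant, outcome = outcome,
    t_tone = t0, t_cue = t0 + 4, t_decision = t0 + 10,
    t_zone_entry = t_zone_entry
  )
}

# Quiet small simulated session for IO/feature tests.
quiet_session <- function(seed = 11, n_trials = 8, tracking = TRUE, ...) {
  simulate_session(
    policy = decision_policy(a_R = 2, b_R = 3, a_C = 1, b_C = -1),
    kinematics = kinematics_config(...),
    schedule = task_schedule(n_trials = n_trials),
    seed = seed, tracking = tracking
  )
}

expect_tbl_equal <- function(a, b, tol = 0) {
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "class", "row.names")]
    x
  }
  expect_equal(strip(a), strip(b), tolerance = tol)
}
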