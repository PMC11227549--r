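#' Kinematics configuration for the simulated forager
#'
#' Controls the agent's locomotion and the rates of scripted behavioral
#' events. The agent moves by waypoint pursuit (straight legs between random
#' waypoints, toward the cued feeder on accepted trials); the head-direction
#' process is independent of locomotion and changes only during scripted
#' rotation events plus optional per-sample noise. With all noise terms at 0
#' the generated event logs (stops, rotations, zone entries) are exact ground
#' truth for the feature extractors.
#'
#' @param mean_speed Mean locomotion speed, normalised units / s.
#' @param speed_sd Per-leg speed jitter SD (0 = deterministic speed).
#' @param stop_rate Scripted complete stops per minute of inter-trial wander.
#' @param stop_duration Duration of each scripted stop, s (> 3 s so each is
#'   detectable by the 3-s stop window).
#' @param rotation_rate Scripted full-turn head rotations per minute.
#' @param heading_sd Per-sample head-direction noise SD, radians.
#' @param reaction_latency Hold time after the trial-start tone before the
#'   agent moves, s.
#' @param dt Sampling interval, s.
#' @param head Simulate the head point? If `FALSE`, `hx`/`hy` are missing and
#'   the rotation feature is unavailable.
#' @param head_offset Centre-to-head distance, normalised units.
#' @return A `kinematics_config` object.
#' @export
kinematics_config <- function(mean_speed = 0.25, speed_sd = 0,
                              stop_rate = 2, stop_duration = 4,
                              rotation_rate = 2, heading_sd = 0,
                              reaction_latency = 0, dt = 0.1,
                              head = TRUE, head_offset = 0.05) {
  stopifnot(mean_speed > 0, speed_sd >= 0, stop_rate >= 0, rotation_rate >= 0,
            heading_sd >= 0, dt > 0, stop_duration > 0, reaction_latency >= 0)
  structure(
    list(mean_speed = mean_speed, speed_sd = speed_sd, stop_rate = stop_rate,
         stop_duration = stop_duration, rotation_rate = rotation_rate,
         heading_sd = heading_sd, reaction_latency = reaction_latency,
         dt = dt, head = head, head_offset = head_offset),
    class = "kinematics_config"
  )
}

#' Task schedule: trial counts, offer sets and timing
#'
#' Defaults reproduce the standard daily battery: 40 trials, four sucrose
#' concentrations (0.5/2/5/9%), a 4-s trial-start tone, a 6-s approach window
#' after the cue, 7 s of consumption and a 28-s inter-trial interval. The
#' low-cost variant presents 15 lx only; the high-cost variant mixes 15 and
#' 320 lx at 50/50 (proportions overridable).
#'
#' @param n_trials Trials per session.
#' @param sucrose_pct Sucrose concentration (%) at reward levels 1-4.
#' @param cost_lux Illuminance levels offered (lx).
#' @param cost_probs Mixing proportions over `cost_lux` (must sum to 1).
#' @param cost_ordinal Ordinal cost level of each `cost_lux` entry, the scale
#'   the decision policy operates on (15 lx = level 1, 320 lx = level 3 by
#'   convention).
#' @param tone_duration,approach_window,consume_duration,iti Stage durations, s.
#' @param association_mode If `TRUE`, reward is delivered regardless of
#'   approach (training schedule); recorded in the session metadata.
#' @return A `task_schedule` object.
#' @export
task_schedule <- function(n_trials = 40,
                          sucrose_pct = c(0.5, 2, 5, 9),
                          cost_lux = c(15, 320),
                          cost_probs = NULL,
                          cost_ordinal = NULL,
                          tone_duration = 4, approach_window = 6,
                          consume_duration = 7, iti = 28,
                          association_mode = FALSE) {
  if (is.null(cost_probs)) cost_probs <- rep(1 / length(cost_lux), length(cost_lux))
  if (is.null(cost_ordinal)) {
    default_map <- c("15" = 1, "320" = 3)
    cost_ordinal <- unname(default_map[as.character(cost_lux)])
    cost_ordinal[is.na(cost_ordinal)] <- rank(cost_lux)[is.na(cost_ordinal)]
  }
  stopifnot(n_trials >= 1, length(sucrose_pct) == 4,
            length(cost_probs) == length(cost_lux),
            length(cost_ordinal) == length(cost_lux),
            tone_duration > 0, approach_window > 0, consume_duration > 0,
            iti > 0)
  if (abs(sum(cost_probs) - 1) > 1e-9) stopf("`cost_probs` must sum to 1")
  structure(
    list(n_trials = as.integer(n_trials), sucrose_pct = sucrose_pct,
         cost_lux = cost_lux, cost_probs = cost_probs,
         cost_ordinal = cost_ordinal, tone_duration = tone_duration,
         approach_window = approach_window,
         consume_duration = consume_duration, iti = iti,
         association_mode = isTRUE(association_mode)),
    class = "task_schedule"
  )
}

trial_length <- function(sch) {
  sch$tone_duration + sch$approach_window + sch$consume_duration + sch$iti
}

#' Simulate one behavioral session with known ground truth
#'
#' Runs the trial engine (tone, cue, approach window, consumption,
#' inter-trial interval) with a stochastic agent whose accept/reject choices
#' are Bernoulli draws from the two-factor logistic policy, and whose
#' trajectory is generated by waypoint pursuit. Returns both the assembled
#' session and a ground-truth record (per-trial acceptance probabilities and
#' draws, scripted stop/rotation event logs, zone entry times).
#'
#' @param policy A [decision_policy()].
#' @param kinematics A [kinematics_config()].
#' @param schedule A [task_schedule()].
#' @param geometry An [arena_geometry()].
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param rat_id,sex,condition,session_idx Session metadata. The RNG stream is
#'   keyed by `(seed, rat_id, session_idx)` so cohorts are reproducible
#'   trial-by-trial.
#' @param tracking If `FALSE`, skip trajectory generation (trial log only;
#'   much faster when only choices are needed).
#' @return A list with elements `session` (a `forage_session`) and `truth`.
#' @export
simulate_session <- function(policy = decision_policy(),
                             kinematics = kinematics_config(),
                             schedule = task_schedule(),
                             geometry = arena_geometry(),
                             seed = 1,
                             rat_id = "rat01", sex = "F",
                             condition = "baseline", session_idx = 1,
                             tracking = TRUE) {
  stopifnot(inherits(policy, "decision_policy"),
            inherits(kinematics, "kinematics_config"),
            inherits(schedule, "task_schedule"),
            inherits(geometry, "arena_geometry"))
  # feasibility: worst-case distance to a feeder must be coverable in time
  max_dist <- max(vapply(1:4, function(q) {
    f <- geometry$feeders[q, ]
    max(sqrt((c(0, 1, 0, 1) - f$x)^2 + (c(0, 0, 1, 1) - f$y)^2))
  }, numeric(1)))
  if (kinematics$mean_speed * schedule$approach_window < max_dist) {
    stopf(paste0("infeasible kinematics: mean speed %.3g cannot cover %.3g ",
                 "units within the %g s approach window"),
          kinematics$mean_speed, max_dist, schedule$approach_window,
      class = "foragedm_config_error")
  }

  stream <- derive_seed(seed, rat_id, session_idx)
  with_seed(stream, {
    sch <- schedule
    kin <- kinematics
    tl <- trial_length(sch)
    n <- sch$n_trials

    offered_quadrant <- sample.int(4L, n, replace = TRUE)
    cost_i <- sample.int(length(sch$cost_lux), n, replace = TRUE,
                         prob = sch$cost_probs)
    reward_level <- geometry$reward_map[offered_quadrant]
    R_ord <- reward_level
    C_ord <- sch$cost_ordinal[cost_i]
    p <- choice_prob(R_ord, C_ord, policy$a_R, policy$b_R,
                     policy$a_C, policy$b_C, policy$curvature)
    draw <- runif(n)
    outcome <- ifelse(draw < p, "accept", "reject")
    hesitate <- outcome == "reject" & runif(n) < policy$hesitation

    t_tone <- canon_num((seq_len(n) - 1) * tl, 3)
    t_cue <- canon_num(t_tone + sch$tone_duration, 3)
    t_decision <- canon_num(t_cue + sch$approach_window, 3)

    trials <- tibble::tibble(
      trial_idx = seq_len(n),
      reward_level = as.integer(reward_level),
      sucrose_pct = canon_num(sch$sucrose_pct[reward_level], 2),
      cost_lux = canon_num(sch$cost_lux[cost_i], 1),
      offered_quadrant = as.integer(offered_quadrant),
      outcome = outcome,
      t_tone = t_tone, t_cue = t_cue, t_decision = t_decision,
      t_zone_entry = NA_real_
    )

    truth_per_trial <- tibble::tibble(
      trial_idx = seq_len(n), R = R_ord, C = C_ord, p = p, draw = draw,
      outcome = outcome, hesitation = hesitate,
      n_stops = 0L, n_rotations = 0L,
      t_zone_entry = NA_real_, reaction_time = NA_real_
    )

    if (!tracking) {
      # trial log only: set zone entry for accepted trials at a nominal time
      ae <- outcome == "accept"
      trials$t_zone_entry[ae] <- canon_num(t_cue[ae] + 2, 3)
      truth_per_trial$t_zone_entry[ae] <- trials$t_zone_entry[ae]
      sess <- assemble_session(
        trials, empty_tracking(), geometry,
        meta = list(rat_id = rat_id, sex = sex, condition = condition,
                    session = session_idx,
                    association_mode = sch$association_mode),
        strict = FALSE
      )
      return(list(session = sess,
                  truth = list(policy = policy, kinematics = kin,
                               schedule = sch, seed = stream,
                               per_trial = truth_per_trial,
                               stops = empty_events(), rotations = empty_events())))
    }

    state <- list(pos = c(0.5, 0.5), heading = runif(1, 0, 2 * pi))
    samples <- vector("list", n)
    stop_log <- list()
    rot_log <- list()

    for (i in seq_len(n)) {
      tr <- simulate_trial_path(
        trial = trials[i, ], outcome = outcome[i], hesitate = hesitate[i],
        kin = kin, sch = sch, geometry = geometry, state = state
      )
      state <- tr$state
      samples[[i]] <- tr$samples
      stop_log[[i]] <- tr$stops
      rot_log[[i]] <- tr$rotations
      truth_per_trial$n_stops[i] <- nrow(tr$stops)
      truth_per_trial$n_rotations[i] <- nrow(tr$rotations)
      truth_per_trial$t_zone_entry[i] <- tr$t_zone_entry
      truth_per_trial$reaction_time[i] <- tr$reaction_time
      trials$t_zone_entry[i] <- tr$t_zone_entry
    }

    tracking_tbl <- dplyr::bind_rows(samples)
    tracking_tbl <- tibble::tibble(
      t = canon_num(tracking_tbl$t, 3),
      cx = canon_num(tracking_tbl$cx, 6), cy = canon_num(tracking_tbl$cy, 6),
      hx = canon_num(tracking_tbl$hx, 6), hy = canon_num(tracking_tbl$hy, 6)
    )
    trials$t_zone_entry <- canon_num(trials$t_zone_entry, 3)
    truth_per_trial$t_zone_entry <- trials$t_zone_entry

    sess <- assemble_session(
      trials, tracking_tbl, geometry,
      meta = list(rat_id = rat_id, sex = sex, condition = condition,
                  session = session_idx,
                  association_mode = sch$association_mode),
      strict = FALSE
    )
    list(
      session = sess,
      truth = list(
        policy = policy, kinematics = kin, schedule = sch, seed = stream,
        per_trial = truth_per_trial,
        stops = dplyr::bind_rows(stop_log) %||% empty_events(),
        rotations = dplyr::bind_rows(rot_log) %||% empty_events()
      )
    )
  })
}

empty_tracking <- function() {
  tibble::tibble(t = numeric(0), cx = numeric(0), cy = numeric(0),
                 hx = numeric(0), hy = numeric(0))
}

empty_events <- function() {
  tibble::tibble(trial_idx = integer(0), t_start = numeric(0),
                 t_end = numeric(0))
}

leg_speed <- function(kin) {
  max(0.15, rnorm(1, kin$mean_speed, kin$speed_sd))
}

# Random waypoint respecting an optional exclusion disc.
draw_waypoint <- function(from, avoid = NULL, avoid_r = 0) {
  for (k in 1:200) {
    w <- runif(2, 0.08, 0.92)
    if (sqrt(sum((w - from)^2)) < 0.35) next
    if (!is.null(avoid) && sqrt(sum((w - avoid)^2)) < avoid_r) next
    return(w)
  }
  c(0.5, 0.5)
}

# Piecewise-linear wander knots from t0 to t1 starting at p0. `holds` is a
# matrix of scripted stop intervals (start, end) inside [t0, t1].
wander_knots <- function(t0, t1, p0, kin, avoid = NULL, avoid_r = 0,
                         holds = NULL) {
  kt <- t0; kx <- p0[1]; ky <- p0[2]
  tcur <- t0; pcur <- p0
  hold_i <- 1L
  n_holds <- if (is.null(holds)) 0L else nrow(holds)
  while (tcur < t1) {
    if (hold_i <= n_holds && tcur >= holds[hold_i, 1] - 1e-9) {
      hend <- min(holds[hold_i, 2], t1)
      kt <- c(kt, hend); kx <- c(kx, pcur[1]); ky <- c(ky, pcur[2])
      tcur <- hend
      hold_i <- hold_i + 1L
      next
    }
    tmax <- if (hold_i <= n_holds) holds[hold_i, 1] else t1
    w <- draw_waypoint(pcur, avoid, avoid_r)
    sp <- leg_speed(kin)
    dur <- sqrt(sum((w - pcur)^2)) / sp
    if (tcur + dur > tmax) {
      # cut the leg at the boundary
      frac <- (tmax - tcur) / dur
      w <- pcur + frac * (w - pcur)
      dur <- tmax - tcur
    }
    tcur <- tcur + dur
    pcur <- w
    kt <- c(kt, tcur); kx <- c(kx, pcur[1]); ky <- c(ky, pcur[2])
  }
  list(t = kt, x = kx, y = ky, pos = pcur)
}

# Schedule `rate`/min Poisson events of length `dur` in [t0, t1], pairwise
# separated by >= gap and clear of the window edges.
schedule_events <- function(t0, t1, rate, dur, gap) {
  span <- t1 - t0
  if (span <= dur + 2 || rate <= 0) return(numeric(0))
  k <- rpois(1, rate * span / 60)
  if (k == 0) return(numeric(0))
  starts <- numeric(0)
  cand <- sort(runif(4 * k, t0 + 1, t1 - dur - 1))
  for (s in cand) {
    if (length(starts) >= k) break
    if (!length(starts) || s - tail(starts, 1) >= dur + gap) {
      starts <- c(starts, s)
    }
  }
  starts
}

# Build one trial's tracking samples plus its scripted-event log.
simulate_trial_path <- function(trial, outcome, hesitate, kin, sch, geometry,
                                state) {
  dt <- kin$dt
  t_tone <- trial$t_tone
  t_cue <- trial$t_cue
  t_dec <- trial$t_decision
  t_consume_end <- t_dec + sch$consume_duration
  t_end <- t_tone + trial_length(sch)
  feeder <- as.numeric(
    geometry$feeders[geometry$feeders$quadrant == trial$offered_quadrant,
                     c("x", "y")]
  )
  zone_r <- if (geometry$zone_mode == "disc") geometry$zone_radius else 0.2

  pos <- state$pos
  knots_t <- numeric(0); knots_x <- numeric(0); knots_y <- numeric(0)
  push <- function(k) {
    knots_t <<- c(knots_t, k$t); knots_x <<- c(knots_x, k$x)
    knots_y <<- c(knots_y, k$y)
  }

  # tone phase: optional reaction hold, then wander
  t_move <- min(t_tone + kin$reaction_latency, t_cue)
  if (t_move > t_tone) {
    push(list(t = c(t_tone, t_move), x = rep(pos[1], 2), y = rep(pos[2], 2)))
  } else {
    push(list(t = t_tone, x = pos[1], y = pos[2]))
  }
  wk <- wander_knots(t_move, t_cue, pos, kin)
  push(list(t = wk$t[-1], x = wk$x[-1], y = wk$y[-1]))
  pos <- wk$pos

  stops <- empty_events()
  if (outcome == "accept") {
    # approach the rim of a small circle around the feeder, then orbit it
    orbit_r <- 0.12
    dir0 <- pos - feeder
    if (sqrt(sum(dir0^2)) < 1e-6) dir0 <- c(1, 0)
    rim <- feeder + orbit_r * dir0 / sqrt(sum(dir0^2))
    dist <- sqrt(sum((rim - pos)^2))
    sp <- max(leg_speed(kin), dist / (t_dec - t_cue - 0.4))
    t_arr <- t_cue + dist / sp
    push(list(t = t_arr, x = rim[1], y = rim[2]))
    # orbit: knots every 0.2 s
    phi0 <- atan2(rim[2] - feeder[2], rim[1] - feeder[1])
    omega <- kin$mean_speed / orbit_r
    ts <- seq(t_arr, t_consume_end, by = 0.2)
    ts <- unique(c(ts[-1], t_consume_end))
    if (length(ts)) {
      phi <- phi0 + omega * (ts - t_arr)
      push(list(t = ts, x = feeder[1] + orbit_r * cos(phi),
                y = feeder[2] + orbit_r * sin(phi)))
      pos <- c(feeder[1] + orbit_r * cos(phi[length(phi)]),
               feeder[2] + orbit_r * sin(phi[length(phi)]))
    } else pos <- rim
    wander_start <- t_consume_end
  } else {
    if (hesitate) {
      # partial approach: to just outside the zone, then retreat
      rim <- feeder + (zone_r + 0.06) * (pos - feeder) /
        max(sqrt(sum((pos - feeder)^2)), 1e-6)
      sp <- leg_speed(kin)
      t_arr <- min(t_cue + sqrt(sum((rim - pos)^2)) / sp, t_dec - 0.5)
      push(list(t = t_arr, x = rim[1], y = rim[2]))
      pos <- rim
      wk <- wander_knots(t_arr, t_dec, pos, kin, avoid = feeder,
                         avoid_r = zone_r + 0.07)
    } else {
      wk <- wander_knots(t_cue, t_dec, pos, kin, avoid = feeder,
                         avoid_r = zone_r + 0.07)
    }
    push(list(t = wk$t[-1], x = wk$x[-1], y = wk$y[-1]))
    pos <- wk$pos
    wander_start <- t_dec
  }

  # inter-trial wander with scripted stops
  stop_starts <- schedule_events(wander_start + 1.5, t_end,
                                 kin$stop_rate, kin$stop_duration, gap = 8)
  holds <- if (length(stop_starts)) {
    cbind(stop_starts, stop_starts + kin$stop_duration)
  } else NULL
  wk <- wander_knots(wander_start, t_end, pos, kin, holds = holds)
  push(list(t = wk$t[-1], x = wk$x[-1], y = wk$y[-1]))

  # sample the piecewise-linear path on the global 0.1 s grid
  i0 <- ceiling(round(t_tone / dt, 6))
  i1 <- ceiling(round(t_end / dt, 6)) - 1L
  tg <- (i0:i1) * dt
  ord <- order(knots_t)
  knots_t <- knots_t[ord]; knots_x <- knots_x[ord]; knots_y <- knots_y[ord]
  keep <- !duplicated(round(knots_t, 9))
  cx <- stats::approx(knots_t[keep], knots_x[keep], xout = tg, rule = 2)$y
  cy <- stats::approx(knots_t[keep], knots_y[keep], xout = tg, rule = 2)$y
  cx <- pmin(pmax(cx, 0.02), 0.98)
  cy <- pmin(pmax(cy, 0.02), 0.98)

  # reject trials never enter the offered zone during the approach window:
  # push any straggler samples radially out of the zone
  if (outcome == "reject") {
    win <- tg >= t_cue - 1e-9 & tg <= t_dec + 1e-9
    d <- sqrt((cx - feeder[1])^2 + (cy - feeder[2])^2)
    bad <- win & d <= zone_r + 0.02
    if (any(bad)) {
      scl <- (zone_r + 0.03) / pmax(d[bad], 1e-6)
      cx[bad] <- feeder[1] + (cx[bad] - feeder[1]) * scl
      cy[bad] <- feeder[2] + (cy[bad] - feeder[2]) * scl
    }
  }

  # head direction: constant except scripted full rotations (+ noise)
  rot_starts <- schedule_events(t_tone + 0.5, t_end - 2,
                                kin$rotation_rate, dur = 1, gap = 4)
  heading <- rep(state$heading, length(tg))
  spin_dur <- 1
  for (s in rot_starts) {
    inw <- tg >= s & tg <= s + spin_dur
    heading[inw] <- heading[inw] +
      2 * pi * (tg[inw] - s) / spin_dur
    heading[tg > s + spin_dur] <- heading[tg > s + spin_dur] + 2 * pi
  }
  if (kin$heading_sd > 0) {
    heading <- heading + cumsum(rnorm(length(tg), 0, kin$heading_sd))
  }
  if (kin$head) {
    hx <- pmin(pmax(cx + kin$head_offset * cos(heading), 0), 1)
    hy <- pmin(pmax(cy + kin$head_offset * sin(heading), 0), 1)
  } else {
    hx <- rep(NA_real_, length(tg)); hy <- rep(NA_real_, length(tg))
  }

  # zone entry from the generated samples themselves
  win <- tg >= t_cue - 1e-9 & tg <= t_dec + 1e-9
  inz <- in_reward_zone(cx, cy, trial$offered_quadrant, geometry)
  entry <- which(win & inz)
  t_zone_entry <- if (length(entry)) tg[entry[1]] else NA_real_

  # movement onset: last sample at the tone position before displacement
  reaction_time <- if (kin$reaction_latency > 0) kin$reaction_latency else 0

  list(
    samples = tibble::tibble(t = tg, cx = cx, cy = cy, hx = hx, hy = hy),
    stops = if (length(stop_starts)) {
      tibble::tibble(trial_idx = trial$trial_idx, t_start = stop_starts,
                     t_end = stop_starts + kin$stop_duration)
    } else empty_events(),
    rotations = if (length(rot_starts)) {
      tibble::tibble(trial_idx = trial$trial_idx, t_start = rot_starts,
                     t_end = rot_starts + spin_dur)
    } else empty_events(),
    t_zone_entry = t_zone_entry,
    reaction_time = reaction_time,
    state = list(pos = c(cx[length(cx)], cy[length(cy)]),
                 heading = heading[length(heading)] %% (2 * pi))
  )
}

#' Simulate the trajectory of a single trial
#'
#' Thin wrapper over the trial engine for scripted, single-trial tests: given
#' a trial record and a forced outcome, generate the tracking samples spanning
#' the trial period together with the scripted event log.
#'
#' @param outcome `"accept"` or `"reject"`.
#' @param trial One-row trial tibble (see [read_trials()]).
#' @param kinematics A [kinematics_config()].
#' @param geometry An [arena_geometry()].
#' @param schedule A [task_schedule()] (timing only).
#' @param seed Integer seed.
#' @param start Starting centre position.
#' @return A list: `samples`, `stops`, `rotations`, `t_zone_entry`,
#'   `reaction_time`.
#' @export
simulate_trajectory <- function(outcome, trial,
                                kinematics = kinematics_config(),
                                geometry = arena_geometry(),
                                schedule = task_schedule(), seed = 1,
                                start = c(0.5, 0.5)) {
  with_seed(derive_seed(seed, "trajectory", trial$trial_idx), {
    simulate_trial_path(trial, outcome, hesitate = FALSE, kin = kinematics,
                        sch = schedule, geometry = geometry,
                        state = list(pos = start, heading = 0))
  })
}

#' Simulate a multi-rat, multi-condition cohort
#'
#' @param rats Character vector of rat ids.
#' @param conditions Named list: condition label -> list with elements
#'   `policy`, and optionally `kinematics`, `schedule`.
#' @param n_sessions Sessions per rat per condition.
#' @param geometry An [arena_geometry()].
#' @param seed Global seed; each session's stream is keyed by
#'   `(seed, rat_id, condition, session)`.
#' @param tracking Generate trajectories? (`FALSE` = trial logs only.)
#' @return A tibble with one row per session: `rat_id`, `condition`,
#'   `session`, and list-columns `session_obj`, `truth`.
#' @export
simulate_cohort <- function(rats, conditions, n_sessions = 10,
                            geometry = arena_geometry(), seed = 1,
                            tracking = FALSE) {
  grid <- tidyr::expand_grid(
    rat_id = rats, condition = names(conditions), session = seq_len(n_sessions)
  )
  out <- purrr::pmap(grid, function(rat_id, condition, session) {
    cfg <- conditions[[condition]]
    simulate_session(
      policy = cfg$policy,
      kinematics = cfg$kinematics %||% kinematics_config(),
      schedule = cfg$schedule %||% task_schedule(),
      geometry = geometry,
      seed = derive_seed(seed, condition),
      rat_id = rat_id, condition = condition, session_idx = session,
      tracking = tracking
    )
  })
  grid$session_obj <- purrr::map(out, "session")
  grid$truth <- purrr::map(out, "truth")
  grid
}
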