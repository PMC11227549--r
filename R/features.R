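#' Classify the choice on one trial from tracking
#'
#' A trial counts as an accept when the animal's centre point is inside the
#' offered reward zone at the decision deadline (cue time + approach window);
#' the first crossing time into the zone during the approach window is
#' recorded either way.
#'
#' @param trial One-row trial tibble.
#' @param tracking_slice Tracking samples covering the trial.
#' @param geometry An [arena_geometry()].
#' @return List: `outcome` (`"accept"`/`"reject"`/`"unscorable"`),
#'   `t_zone_entry` (NA when the zone was never entered).
#' @export
classify_choice <- function(trial, tracking_slice, geometry = arena_geometry()) {
  tr <- tracking_slice
  win <- tr$t >= trial$t_cue - 1e-9 & tr$t <= trial$t_decision + 1e-9
  if (!any(win)) {
    return(list(outcome = "unscorable", t_zone_entry = NA_real_))
  }
  tw <- tr[win, ]
  # sample at (or latest before) the deadline
  dead <- max(which(tw$t <= trial$t_decision + 1e-9))
  if (tw$t[dead] < trial$t_decision - 0.5) {
    return(list(outcome = "unscorable", t_zone_entry = NA_real_))
  }
  inz <- in_reward_zone(tw$cx, tw$cy, trial$offered_quadrant, geometry)
  entry <- which(inz)
  list(
    outcome = if (inz[dead]) "accept" else "reject",
    t_zone_entry = if (length(entry)) tw$t[entry[1]] else NA_real_
  )
}

#' Euclidean path length of a trajectory
#'
#' Sum of straight-line distances between consecutive centre points, in
#' normalised arena units.
#'
#' @param traj Tracking tibble (columns `t, cx, cy`).
#' @return Length (numeric), or `NA` with an `undefined` attribute when fewer
#'   than 2 samples are available.
#' @export
distance_traveled <- function(traj) {
  if (nrow(traj) < 2) {
    return(structure(NA_real_, undefined = "fewer than 2 samples"))
  }
  sum(sqrt(diff(traj$cx)^2 + diff(traj$cy)^2))
}

#' Number of grid cells visited ("travel pixels")
#'
#' The unit square is divided into `grid_n` x `grid_n` cells; the count is the
#' number of distinct cells the centre point visits, including cells crossed
#' between consecutive samples (segments are rasterised).
#'
#' @param traj Tracking tibble.
#' @param grid_n Cells per axis (default 64, emulating a coarse camera grid).
#' @return Integer count (>= 1 for any non-empty trajectory).
#' @export
travel_pixels <- function(traj, grid_n = 64) {
  if (nrow(traj) == 0) return(0L)
  cell <- function(x, y) {
    cx <- pmin(floor(x * grid_n), grid_n - 1L)
    cy <- pmin(floor(y * grid_n), grid_n - 1L)
    cx + grid_n * cy
  }
  cells <- cell(traj$cx, traj$cy)
  if (nrow(traj) > 1) {
    # supersample each segment finely enough to cross no cell unseen
    x0 <- traj$cx[-nrow(traj)]; y0 <- traj$cy[-nrow(traj)]
    x1 <- traj$cx[-1]; y1 <- traj$cy[-1]
    len <- pmax(abs(x1 - x0), abs(y1 - y0))
    nstep <- pmax(1L, ceiling(len * grid_n * 2))
    seg_cells <- unlist(lapply(which(nstep > 1), function(i) {
      s <- seq(0, 1, length.out = nstep[i] + 1)
      cell(x0[i] + s * (x1[i] - x0[i]), y0[i] + s * (y1[i] - y0[i]))
    }))
    cells <- c(cells, seg_cells)
  }
  length(unique(cells))
}

#' High-speed runs: acceleration outliers per trial
#'
#' Speed is computed by forward differences of the centre point; acceleration
#' by central differences of the speed series (actual sample spacing is used
#' throughout, so irregular sampling is handled). A sample is an outlier when
#' its acceleration magnitude exceeds `median + k_sd * SD` of the trial's
#' series. Consecutive outlier samples form one "run"; the headline count is
#' the number of runs (the raw outlier count is also returned), and the count
#' is normalised by the distance traveled.
#'
#' @param traj Tracking tibble.
#' @param k_sd Outlier multiplier (default 2).
#' @return List: `n_runs`, `n_outliers`, `per_unit_travel` (runs / distance;
#'   `NA` when distance is 0).
#' @export
high_speed_runs <- function(traj, k_sd = 2) {
  if (nrow(traj) < 4) {
    return(list(n_runs = NA_integer_, n_outliers = NA_integer_,
                per_unit_travel = NA_real_))
  }
  dt <- diff(traj$t)
  v <- sqrt(diff(traj$cx)^2 + diff(traj$cy)^2) / dt
  tv <- traj$t[-length(traj$t)] + dt / 2   # speed timestamps (midpoints)
  n <- length(v)
  acc <- abs((v[-(1:2)] - v[1:(n - 2)]) / (tv[-(1:2)] - tv[1:(n - 2)]))
  thr <- median(acc) + k_sd * sd(acc)
  # strict exceedance with a relative guard so float jitter on a
  # constant-speed path never counts as an outlier
  tol <- 1e-9 * max(1, max(acc[is.finite(acc)]))
  out <- is.finite(acc) & acc > thr + tol
  runs <- rle(out)
  n_runs <- sum(runs$values)
  dist <- distance_traveled(traj)
  list(
    n_runs = as.integer(n_runs),
    n_outliers = as.integer(sum(out)),
    per_unit_travel = if (isTRUE(dist > 0)) n_runs / dist else NA_real_
  )
}

#' Stopping points: merged stationary windows
#'
#' A sliding window of length `window` seconds is "stopped" when the centre
#' point's displacement range stays below `eps` in both x and y across the
#' whole window. Overlapping and adjacent stopped windows merge into a single
#' stop event; the count of merged events is returned.
#'
#' @param traj Tracking tibble.
#' @param eps Displacement threshold, normalised units (default 0.1).
#' @param window Window length, s (default 3).
#' @return Integer event count.
#' @export
stopping_points <- function(traj, eps = 0.1, window = 3) {
  n <- nrow(traj)
  if (n < 2) return(0L)
  t <- traj$t
  stopped <- rep(FALSE, n)
  j <- 1L
  for (i in seq_len(n)) {
    if (t[i] + window > t[n] + 1e-9) break
    if (j < i) j <- i
    while (j < n && t[j + 1] <= t[i] + window + 1e-9) j <- j + 1L
    idx <- i:j
    if (diff(range(traj$cx[idx])) < eps && diff(range(traj$cy[idx])) < eps) {
      stopped[i] <- TRUE
    }
  }
  # merge overlapping/adjacent stopped windows: consecutive stopped starts
  # belong to one event
  runs <- rle(stopped)
  as.integer(sum(runs$values))
}

#' Rotation points from head direction
#'
#' Head direction is the angle of the centre-to-head vector, unwrapped over
#' time. A rotation event is a window of `window` seconds within which the
#' cumulative absolute heading change exceeds `angle_thresh`; after each
#' detection the scan restarts beyond the detected window so one physical turn
#' is counted once.
#'
#' @param traj Tracking tibble with head columns `hx`, `hy`.
#' @param angle_thresh Threshold in degrees (default 180).
#' @param window Window length, s (default 1.5).
#' @return Integer count, or `NA` (feature unavailable) when head points are
#'   missing.
#' @export
rotation_points <- function(traj, angle_thresh = 180, window = 1.5) {
  if (nrow(traj) < 3 || anyNA(traj$hx) || anyNA(traj$hy)) {
    return(NA_integer_)
  }
  theta <- atan2(traj$hy - traj$cy, traj$hx - traj$cx)
  dth <- diff(theta)
  dth <- (dth + pi) %% (2 * pi) - pi   # wrap steps into (-pi, pi]
  cum <- c(0, cumsum(abs(dth)))
  t <- traj$t
  thr <- angle_thresh * pi / 180
  n <- nrow(traj)
  count <- 0L
  i <- 1L
  while (i < n) {
    jmax <- i
    while (jmax < n && t[jmax + 1] <= t[i] + window + 1e-9) jmax <- jmax + 1L
    if (cum[jmax] - cum[i] > thr) {
      count <- count + 1L
      i <- jmax + 1L
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Approach and reaction time of one trial
#'
#' Approach time is the latency from the trial-start tone to the first entry
#' into the offered reward zone (absent on rejected trials). Reaction time is
#' the latency from the tone to movement onset: the time of the last sample
#' still within `eps_move` of the position held at tone onset, before the
#' first sample exceeding it.
#'
#' @param trial One-row trial tibble (with `t_zone_entry` set).
#' @param tracking_slice Tracking samples covering the trial.
#' @param eps_move Movement-onset displacement threshold (default 0.05).
#' @return List: `approach_time`, `reaction_time` (s, `NA` when undefined).
#' @export
approach_and_reaction_time <- function(trial, tracking_slice,
                                       eps_move = 0.05) {
  approach <- if (!is.na(trial$t_zone_entry)) {
    trial$t_zone_entry - trial$t_tone
  } else NA_real_
  tr <- tracking_slice[tracking_slice$t >= trial$t_tone - 1e-9, ]
  reaction <- NA_real_
  if (nrow(tr) >= 2) {
    disp <- sqrt((tr$cx - tr$cx[1])^2 + (tr$cy - tr$cy[1])^2)
    first <- which(disp > eps_move)
    if (length(first)) {
      onset <- tr$t[max(first[1] - 1L, 1L)]
      reaction <- onset - trial$t_tone
    }
  }
  list(approach_time = approach, reaction_time = reaction)
}

#' Proportion of a trial spent outside all reward zones
#'
#' Fraction of the trial's tracking samples whose centre point lies outside
#' every one of the four reward zones. The session-level mean of this per-trial
#' fraction is the session summary used downstream.
#'
#' @param tracking_slice Tracking samples of the trial.
#' @param geometry An [arena_geometry()].
#' @return Fraction in \[0, 1\] (`NA` for an empty slice).
#' @export
prop_outside_reward_zones <- function(tracking_slice,
                                      geometry = arena_geometry()) {
  if (nrow(tracking_slice) == 0) return(NA_real_)
  inz <- in_reward_zone(tracking_slice$cx, tracking_slice$cy,
                        quadrant = NULL, geometry = geometry)
  mean(!inz)
}

#' Extract the per-trial feature table of a session
#'
#' One row per trial with every spatiotemporal feature, the tracking-derived
#' choice, and the trial's offer (reward level, sucrose %, cost). No trial is
#' ever dropped: trials whose tracking is unusable keep their row with `NA`
#' features and an `unscorable` flag.
#'
#' @param session A `forage_session`.
#' @param k_sd,stop_eps,stop_window,rot_window,grid_n,eps_move Feature
#'   parameters (see the individual feature functions).
#' @return A tibble keyed by `(rat_id, condition, session, trial_idx)`.
#' @export
extract_features <- function(session, k_sd = 2, stop_eps = 0.1,
                             stop_window = 3, rot_window = 1.5,
                             grid_n = 64, eps_move = 0.05) {
  stopifnot(inherits(session, "forage_session"))
  trials <- session$trials
  geometry <- session$geometry
  rows <- purrr::map(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    sl <- trial_tracking(session, i)
    ch <- classify_choice(tr, sl, geometry)
    hs <- high_speed_runs(sl, k_sd = k_sd)
    at <- approach_and_reaction_time(
      dplyr::mutate(tr, t_zone_entry = ch$t_zone_entry), sl,
      eps_move = eps_move
    )
    tibble::tibble(
      trial_idx = tr$trial_idx,
      reward_level = tr$reward_level,
      sucrose_pct = tr$sucrose_pct,
      cost_lux = tr$cost_lux,
      choice = ch$outcome,
      unscorable = ch$outcome == "unscorable",
      t_zone_entry = ch$t_zone_entry,
      distance_traveled = as.numeric(distance_traveled(sl)),
      travel_pixels = travel_pixels(sl, grid_n = grid_n),
      n_high_speed_runs = hs$n_runs,
      high_speed_runs_per_unit_travel = hs$per_unit_travel,
      n_stops = stopping_points(sl, eps = stop_eps, window = stop_window),
      n_rotations = rotation_points(sl, window = rot_window),
      approach_time = at$approach_time,
      reaction_time = at$reaction_time,
      prop_outside_reward_zones = prop_outside_reward_zones(sl, geometry)
    )
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(nrow(out) == nrow(trials))  # never drop a trial
  dplyr::bind_cols(
    tibble::tibble(
      rat_id = session$meta$rat_id %||% NA_character_,
      condition = session$meta$condition %||% NA_character_,
      session = session$meta$session %||% NA_integer_
    )[rep(1, nrow(out)), ],
    out
  )
}

#' Minimal feature table from a trial log alone
#'
#' Uses the logged outcome as the choice column, for sessions without
#' tracking (e.g. choice-only simulations). Spatiotemporal features are
#' absent.
#'
#' @param session A `forage_session`.
#' @return A tibble with the keying columns, offer columns and `choice`.
#' @export
trials_as_features <- function(session) {
  stopifnot(inherits(session, "forage_session"))
  tr <- session$trials
  meta <- session$meta
  tibble::tibble(
    rat_id = meta$rat_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    session = meta$session %||% NA_integer_,
    trial_idx = tr$trial_idx,
    reward_level = tr$reward_level,
    sucrose_pct = tr$sucrose_pct,
    cost_lux = tr$cost_lux,
    choice = tr$outcome
  )
}

#' Acceptance fractions over the reward x cost grid
#'
#' Cell (r, c) holds accepted / offered for reward level r and cost level c.
#' Cells with no offers are absent from the long table (never reported as 0).
#'
#' @param features A feature table ([extract_features()]) or any tibble with
#'   `reward_level`, `cost_lux` and `choice` columns. When the table carries a
#'   trial log's `outcome` instead of a tracking-derived `choice`, pass it
#'   renamed.
#' @return A tibble `reward_level, cost_lux, n_offered, n_accepted, p_accept`.
#' @export
approach_rate_map <- function(features) {
  stopifnot(all(c("reward_level", "cost_lux", "choice") %in% names(features)))
  features |>
    dplyr::filter(.data$choice %in% c("accept", "reject")) |>
    dplyr::group_by(.data$reward_level, .data$cost_lux) |>
    dplyr::summarise(
      n_offered = dplyr::n(),
      n_accepted = sum(.data$choice == "accept"),
      p_accept = .data$n_accepted / .data$n_offered,
      .groups = "drop"
    )
}

#' Build a psychometric curve from a feature table
#'
#' Per-level acceptance fractions (for `feature = "choice"`) or feature means,
#' against reward level (default) or cost.
#'
#' @param features A feature table.
#' @param feature Column to summarise; `"choice"` gives acceptance fractions.
#' @param axis `"reward"` or `"cost"`.
#' @return A `psych_curve` tibble: `x`, `y`, `n`, with attributes `axis` and
#'   `feature`.
#' @export
psych_curve <- function(features, feature = "choice",
                        axis = c("reward", "cost")) {
  axis <- match.arg(axis)
  key <- if (axis == "reward") "reward_level" else "cost_lux"
  df <- dplyr::filter(features, !(.data$choice %in% "unscorable"))
  out <- if (feature == "choice") {
    df |>
      dplyr::group_by(x = .data[[key]]) |>
      dplyr::summarise(y = mean(.data$choice == "accept"), n = dplyr::n(),
                       .groups = "drop")
  } else {
    df |>
      dplyr::group_by(x = .data[[key]]) |>
      dplyr::summarise(y = mean(.data[[feature]], na.rm = TRUE),
                       n = sum(!is.na(.data[[feature]])), .groups = "drop")
  }
  out <- dplyr::arrange(out, .data$x)
  structure(out, axis = axis, feature = feature,
            class = c("psych_curve", class(out)))
}
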