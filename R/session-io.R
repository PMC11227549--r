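#' Read a tracking stream
#'
#' Tracking files are comma-separated UTF-8 text with a mandatory header
#' `t,cx,cy,hx,hy`: time in seconds from session start, animal centre point and
#' (optional) head point in normalised arena units. The nominal sampling
#' interval is 0.1 s; gaps longer than `gap_factor` times the nominal interval
#' are flagged (not an error: cameras drop frames).
#'
#' @param path Path to a tracking CSV.
#' @param nominal_dt Nominal sampling interval in seconds.
#' @param gap_factor Gaps longer than `gap_factor * nominal_dt` are flagged.
#' @return A tibble with columns `t, cx, cy, hx, hy`, sorted by `t`, with
#'   attributes `n_gaps` (count) and `gaps` (tibble of flagged intervals).
#' @export
read_tracking <- function(path, nominal_dt = 0.1, gap_factor = 3) {
  df <- read_checked(path, c("t", "cx", "cy", "hx", "hy"))
  for (col in c("t", "cx", "cy")) {
    if (anyNA(df[[col]])) {
      stopf("%s: missing/malformed values in required column '%s' (first at data row %d)",
            path, col, which(is.na(df[[col]]))[1], class = "foragedm_parse_error")
    }
  }
  validate_tracking(df, where = path)
  df <- dplyr::arrange(df, .data$t)
  dt <- diff(df$t)
  gap <- which(dt > gap_factor * nominal_dt)
  attr(df, "gaps") <- tibble::tibble(
    after_t = df$t[gap], dt = dt[gap]
  )
  attr(df, "n_gaps") <- length(gap)
  df
}

validate_tracking <- function(df, where = "tracking") {
  if (nrow(df) == 0) return(invisible(df))
  if (is.unsorted(df$t, strictly = TRUE)) {
    bad <- which(diff(df$t) <= 0)[1] + 1L
    stopf("%s: time not strictly increasing at sample %d (t = %g)",
          where, bad, df$t[bad], class = "foragedm_validation_error")
  }
  coords <- c(df$cx, df$cy, df$hx, df$hy)
  coords <- coords[!is.na(coords)]
  if (length(coords) && (min(coords) < 0 || max(coords) > 1)) {
    stopf("%s: coordinates outside [0, 1]", where,
          class = "foragedm_validation_error")
  }
  invisible(df)
}

#' Write a tracking stream
#'
#' Numeric formatting is fixed (t to ms, coordinates to 1e-6) so that
#' write-read round trips are byte-stable.
#'
#' @param tracking Tibble with columns `t, cx, cy, hx, hy`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(tracking, path) {
  validate_tracking(tracking)
  lines <- c(
    "t,cx,cy,hx,hy",
    paste(
      fmt_num(tracking$t, 3), fmt_num(tracking$cx, 6), fmt_num(tracking$cy, 6),
      fmt_num(tracking$hx, 6), fmt_num(tracking$hy, 6),
      sep = ","
    )
  )
  writeLines(lines, path)
  invisible(path)
}

trial_cols <- c("trial_idx", "reward_level", "sucrose_pct", "cost_lux",
                "offered_quadrant", "outcome", "t_tone", "t_cue",
                "t_decision", "t_zone_entry")

#' Read a trial log
#'
#' Trial logs are comma-separated UTF-8 text with header columns
#' `trial_idx,reward_level,sucrose_pct,cost_lux,offered_quadrant,outcome,
#' t_tone,t_cue,t_decision,t_zone_entry`. `t_zone_entry` may be empty
#' (rejected trials). Event-time invariants (tone before cue, cue before the
#' decision deadline, zone entry present and no later than the deadline on
#' accepted trials) are enforced.
#'
#' @param path Path to a trial CSV.
#' @param approach_window Expected deadline, seconds after cue; `NULL` skips
#'   the check.
#' @return A tibble of trials.
#' @export
read_trials <- function(path, approach_window = 6) {
  df <- read_checked(path, trial_cols)
  if (nrow(df) == 0) return(df)
  df$trial_idx <- as.integer(df$trial_idx)
  df$reward_level <- as.integer(df$reward_level)
  df$offered_quadrant <- as.integer(df$offered_quadrant)
  validate_trials(df, approach_window = approach_window, where = path)
  df
}

validate_trials <- function(df, approach_window = 6, where = "trials") {
  fail <- function(i, msg) {
    stopf("%s: trial %s: %s", where, df$trial_idx[i], msg,
          class = "foragedm_validation_error")
  }
  if (!all(df$outcome %in% c("accept", "reject"))) {
    fail(which(!df$outcome %in% c("accept", "reject"))[1],
         "outcome must be 'accept' or 'reject'")
  }
  bad <- which(!(df$t_tone < df$t_cue & df$t_cue <= df$t_decision))
  if (length(bad)) fail(bad[1], "event times must satisfy t_tone < t_cue <= t_decision")
  if (!is.null(approach_window)) {
    bad <- which(abs(df$t_decision - df$t_cue - approach_window) > 1e-6)
    if (length(bad)) {
      fail(bad[1], sprintf("t_decision - t_cue must equal the approach window (%g s)",
                           approach_window))
    }
  }
  bad <- which(df$outcome == "accept" &
                 (is.na(df$t_zone_entry) | df$t_zone_entry > df$t_decision + 1e-9))
  if (length(bad)) fail(bad[1], "accepted trial requires t_zone_entry <= t_decision")
  bad <- which(!df$reward_level %in% 1:4 | !df$offered_quadrant %in% 1:4)
  if (length(bad)) fail(bad[1], "reward_level and offered_quadrant must be in 1-4")
  invisible(df)
}

#' Write a trial log
#'
#' @param trials Tibble of trials (see [read_trials()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  lines <- c(
    paste(trial_cols, collapse = ","),
    paste(
      trials$trial_idx, trials$reward_level, fmt_num(trials$sucrose_pct, 2),
      fmt_num(trials$cost_lux, 1), trials$offered_quadrant, trials$outcome,
      fmt_num(trials$t_tone, 3), fmt_num(trials$t_cue, 3),
      fmt_num(trials$t_decision, 3), fmt_num(trials$t_zone_entry, 3),
      sep = ","
    )
  )
  writeLines(lines, path)
  invisible(path)
}

read_checked <- function(path, expected) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(hdr), expected)) {
    stopf("%s: header is '%s', expected '%s'", path,
          paste(hdr, collapse = ","), paste(expected, collapse = ","),
          class = "foragedm_parse_error")
  }
  raw <- readLines(path)[-1]
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) {
    return(tibble::as_tibble(setNames(
      lapply(expected, function(x) numeric(0)), expected
    )))
  }
  parts <- strsplit(raw, ",", fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty fields are dropped by strsplit; pad
  parts <- lapply(parts, function(p) c(p, rep("", length(expected) - length(p))))
  bad <- which(nf > length(expected))
  if (length(bad)) {
    stopf("%s: line %d has %d fields, expected %d", path, bad[1] + 1L,
          nf[bad[1]], length(expected), class = "foragedm_parse_error")
  }
  mat <- do.call(rbind, parts)
  out <- setNames(vector("list", length(expected)), expected)
  for (j in seq_along(expected)) {
    col <- trimws(mat[, j])
    if (expected[j] == "outcome") {
      out[[j]] <- col
    } else {
      num <- suppressWarnings(as.numeric(col))
      blank <- !nzchar(col)
      if (any(is.na(num) & !blank)) {
        bad <- which(is.na(num) & !blank)[1]
        stopf("%s: line %d: cannot parse '%s' in column '%s'", path, bad + 1L,
              col[bad], expected[j], class = "foragedm_parse_error")
      }
      out[[j]] <- num
    }
  }
  tibble::as_tibble(out)
}

#' Assemble a validated session from trials, tracking and geometry
#'
#' Combines a trial log and a tracking stream into one session object,
#' running the full consistency report: unique/contiguous trial indices,
#' tracking coverage of every trial interval, coordinate range, strictly
#' increasing timestamps, and agreement between the logged outcome and the
#' outcome re-derived from tracking ([classify_choice()]). Outcome
#' disagreements are reported as warnings (the tracking-derived outcome is
#' authoritative for features); all other failed checks are errors.
#'
#' @param trials Tibble of trials ([read_trials()]).
#' @param tracking Tibble of tracking samples ([read_tracking()]).
#' @param geometry An [arena_geometry()].
#' @param meta Named list of session metadata (`rat_id`, `sex`, `condition`,
#'   `session`); free-form extra fields are kept.
#' @param strict If `TRUE` (default), any error-level consistency failure
#'   aborts with a condition carrying the full report (`data$report`); if
#'   `FALSE` the session is returned with the report attached.
#' @return A `forage_session` object: list with `trials`, `tracking`,
#'   `geometry`, `meta`, `slices` (per-trial tracking row ranges) and
#'   `report` (tibble: `check`, `level`, `detail`).
#' @export
assemble_session <- function(trials, tracking, geometry = arena_geometry(),
                             meta = list(), strict = TRUE) {
  checks <- list()
  note <- function(check, level, detail) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, level = level, detail = detail
    )
  }

  if (anyDuplicated(trials$trial_idx)) {
    dup <- unique(trials$trial_idx[duplicated(trials$trial_idx)])
    note("duplicate_index", "error",
         paste("duplicated trial_idx:", paste(dup, collapse = ", ")))
  } else if (nrow(trials) &&
             !identical(sort(trials$trial_idx), seq_len(nrow(trials)))) {
    note("contiguous_index", "error",
         "trial indices are not contiguous starting at 1")
  }

  if (nrow(tracking) == 0) {
    note("coverage", "error", "tracking stream is empty")
  } else {
    if (is.unsorted(tracking$t, strictly = TRUE)) {
      note("monotonic_time", "error", "tracking time not strictly increasing")
    }
    coords <- c(tracking$cx, tracking$cy, tracking$hx, tracking$hy)
    coords <- coords[!is.na(coords)]
    if (length(coords) && (min(coords) < 0 || max(coords) > 1)) {
      note("coordinate_range", "error", "coordinates outside [0, 1]")
    }
  }

  slices <- vector("list", nrow(trials))
  trial_end <- trial_end_times(trials)
  for (i in seq_len(nrow(trials))) {
    if (nrow(tracking) == 0) break
    lo <- trials$t_tone[i]
    hi <- trial_end[i]
    rows <- which(tracking$t >= lo - 1e-9 & tracking$t <= hi + 1e-9)
    slices[[i]] <- if (length(rows)) range(rows) else c(NA_integer_, NA_integer_)
    if (!length(rows) || min(tracking$t[rows]) > lo + 0.5 ||
        max(tracking$t[rows]) < trials$t_decision[i] - 1e-9) {
      note("coverage", "error",
           sprintf("trial %d interval [%0.3f, %0.3f] not covered by tracking",
                   trials$trial_idx[i], lo, hi))
    }
  }

  report <- if (length(checks)) dplyr::bind_rows(checks) else
    tibble::tibble(check = character(), level = character(), detail = character())

  session <- structure(
    list(trials = trials, tracking = tracking, geometry = geometry,
         meta = meta, slices = slices, report = report),
    class = "forage_session"
  )

  # re-derive outcomes from tracking where coverage allows (warning level)
  if (!any(report$level == "error")) {
    derived <- derive_outcomes(session)
    bad <- which(derived != trials$outcome)
    if (length(bad)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        check = "outcome_mismatch", level = "warning",
        detail = sprintf("trial %d: logged '%s', tracking-derived '%s'",
                         trials$trial_idx[bad], trials$outcome[bad],
                         derived[bad])
      ))
      session$report <- report
    }
  }

  if (strict && any(report$level == "error")) {
    msgs <- report$detail[report$level == "error"]
    abort(
      paste0("session consistency check failed (", length(msgs), " issue(s)):\n",
             paste0("- ", report$check[report$level == "error"], ": ", msgs,
                    collapse = "\n")),
      class = "foragedm_consistency_error",
      data = list(report = report)
    )
  }
  session
}

trial_end_times <- function(trials) {
  # end of each trial period = next trial's tone; the last trial keeps the
  # same period length as its predecessors (fixed trial cadence), or a 1 s
  # tail after the deadline when there is only one trial
  n <- nrow(trials)
  if (n == 0) return(numeric(0))
  last_end <- if (n >= 2) {
    trials$t_tone[n] + median(diff(trials$t_tone))
  } else {
    trials$t_decision[n] + 1
  }
  c(trials$t_tone[-1], last_end)
}

derive_outcomes <- function(session) {
  vapply(seq_len(nrow(session$trials)), function(i) {
    classify_choice(session$trials[i, ], trial_tracking(session, i),
                    session$geometry)$outcome
  }, character(1))
}

#' Extract the tracking slice of one trial
#'
#' @param session A `forage_session`.
#' @param i Trial row index.
#' @return Tibble of tracking samples spanning the trial period.
#' @export
trial_tracking <- function(session, i) {
  sl <- session$slices[[i]]
  if (is.null(sl) || anyNA(sl)) return(session$tracking[0, ])
  session$tracking[sl[1]:sl[2], ]
}

#' @export
print.forage_session <- function(x, ...) {
  cat(sprintf("<forage_session> %s / %s / session %s: %d trials, %d samples\n",
              x$meta$rat_id %||% "?", x$meta$condition %||% "?",
              x$meta$session %||% "?", nrow(x$trials), nrow(x$tracking)))
  nerr <- sum(x$report$level == "error")
  nwarn <- sum(x$report$level == "warning")
  cat(sprintf("  consistency: %d error(s), %d warning(s)\n", nerr, nwarn))
  invisible(x)
}

#' Write a session to a directory
#'
#' Writes `tracking.csv`, `trials.csv` and `meta.json` (metadata + geometry).
#'
#' @param session A `forage_session`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tracking(session$tracking, file.path(dir, "tracking.csv"))
  write_trials(session$trials, file.path(dir, "trials.csv"))
  jsonlite::write_json(
    c(session$meta, list(geometry = geometry_to_list(session$geometry))),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @param strict Passed to [assemble_session()].
#' @return A `forage_session`.
#' @export
read_session <- function(dir, strict = TRUE) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  geometry <- geometry_from_list(meta$geometry)
  meta$geometry <- NULL
  assemble_session(
    trials = read_trials(file.path(dir, "trials.csv")),
    tracking = read_tracking(file.path(dir, "tracking.csv")),
    geometry = geometry, meta = meta, strict = strict
  )
}
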