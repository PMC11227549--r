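test_that("tracking files round-trip byte-stably and flag gaps", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tracking.csv")

  tr <- make_traj(t = c(0, 0.1, 0.2), cx = c(0.5, 0.51, 0.52),
                  cy = c(0.5, 0.5, 0.5))
  write_tracking(tr, p)
  back <- read_tracking(p)
  expect_equal(nrow(back), 3)
  expect_equal(attr(back, "n_gaps"), 0)

  # write(read(x)) is the identity on the file
  p2 <- file.path(dir, "tracking2.csv")
  write_tracking(back, p2)
  expect_identical(readLines(p), readLines(p2))

  # gap flagging: > 3x nominal interval
  tr_gap <- make_traj(t = c(0, 0.1, 0.9), cx = rep(0.5, 3), cy = rep(0.5, 3))
  write_tracking(tr_gap, p)
  expect_equal(attr(read_tracking(p), "n_gaps"), 1)
})

test_that("tracking validation rejects bad files with located errors", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.csv")

  writeLines(c("t,cx,cy,hx,hy", "0.0,0.5,0.5,,", "0.1,0.5,0.5,,",
               "0.1,0.5,0.5,,"), p)
  expect_error(read_tracking(p), "strictly increasing",
               class = "foragedm_validation_error")

  writeLines(c("t,cx,cy,hx,hy", "0.0,oops,0.5,,"), p)
  expect_error(read_tracking(p), "line 2", class = "foragedm_parse_error")

  writeLines(c("time,x,y", "0,0.5,0.5"), p)
  expect_error(read_tracking(p), "header", class = "foragedm_parse_error")

  writeLines(c("t,cx,cy,hx,hy", "0.0,1.5,0.5,,"), p)
  expect_error(read_tracking(p), "\\[0, 1\\]",
               class = "foragedm_validation_error")
})

test_that("trial logs round-trip and enforce event-time invariants", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "trials.csv")

  writeLines(paste("trial_idx,reward_level,sucrose_pct,cost_lux,",
                   "offered_quadrant,outcome,t_tone,t_cue,t_decision,",
                   "t_zone_entry", sep = ""), p)
  expect_equal(nrow(read_trials(p)), 0)

  # accept without zone entry violates the invariant
  bad <- make_trial(outcome = "accept", t_zone_entry = NA_real_)
  write_trials(bad, p)
  expect_error(read_trials(p), "t_zone_entry",
               class = "foragedm_validation_error")

  # a full simulated log round-trips losslessly
  sim <- quiet_session(seed = 4, n_trials = 40)
  write_trials(sim$session$trials, p)
  back <- read_trials(p)
  expect_tbl_equal(back, sim$session$trials)
  p2 <- file.path(dir, "trials2.csv")
  write_trials(back, p2)
  expect_identical(readLines(p), readLines(p2))
})

test_that("session directories round-trip through write_session/read_session", {
  dir <- withr::local_tempdir()
  sim <- quiet_session(seed = 21, n_trials = 6)
  write_session(sim$session, dir)
  back <- read_session(dir)
  expect_tbl_equal(back$trials, sim$session$trials)
  expect_tbl_equal(back$tracking, sim$session$tracking)
  expect_equal(back$meta$rat_id, "rat01")
  expect_equal(back$geometry$zone_radius, sim$session$geometry$zone_radius)
})

test_that("assemble_session reports all consistency failures, not the first", {
  sim <- quiet_session(seed = 31, n_trials = 5)
  trials <- sim$session$trials
  tracking <- sim$session$tracking

  ok <- assemble_session(trials, tracking)
  expect_equal(sum(ok$report$level == "error"), 0)
  expect_equal(nrow(ok$trials), nrow(trials))

  # truncate tracking before the last trial -> coverage failure naming it
  cut <- tracking[tracking$t < trials$t_cue[5], ]
  err <- tryCatch(assemble_session(trials, cut),
                  foragedm_consistency_error = function(e) e)
  rep <- err$data$report
  expect_true(any(rep$check == "coverage" & grepl("trial 5", rep$detail)))

  # duplicated index AND truncated coverage are both listed
  dup <- trials
  dup$trial_idx[2] <- 1L
  err2 <- tryCatch(assemble_session(dup, cut),
                   foragedm_consistency_error = function(e) e)
  expect_true(any(err2$data$report$check == "duplicate_index"))
  expect_true(any(err2$data$report$check == "coverage"))

  # non-strict mode returns the session with the report attached
  s <- assemble_session(dup, cut, strict = FALSE)
  expect_s3_class(s, "forage_session")
  expect_gt(sum(s$report$level == "error"), 0)
})

test_that("logged-vs-derived outcome disagreements are reported as warnings", {
  sim <- quiet_session(seed = 41, n_trials = 5)
  trials <- sim$session$trials
  flip <- which(trials$outcome == "reject")[1]
  expect_false(is.na(flip))
  trials$outcome[flip] <- "accept"
  trials$t_zone_entry[flip] <- trials$t_decision[flip]
  s <- assemble_session(trials, sim$session$tracking,
                        geometry = sim$session$geometry, strict = FALSE)
  expect_true(any(s$report$check == "outcome_mismatch" &
                    grepl(paste("trial", flip), s$report$detail)))
})
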