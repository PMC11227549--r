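two_clouds <- function(n = 100, sd = 0.1, seed = 1) {
  set.seed(seed)
  rbind(
    cbind(rnorm(n, 0, sd), rnorm(n, 0, sd)),
    cbind(rnorm(n, 10, sd), rnorm(n, 10, sd))
  )
}

test_that("fuzzy c-means recovers well-separated cloud centres", {
  X <- two_clouds()
  fit <- fuzzy_cmeans(X, c = 2, seed = 3)
  means <- rbind(colMeans(X[1:100, ]), colMeans(X[101:200, ]))
  # match clusters to clouds by nearest centre
  d <- as.matrix(dist(rbind(fit$centers, means)))[1:2, 3:4]
  perm <- if (d[1, 1] + d[2, 2] <= d[1, 2] + d[2, 1]) c(1, 2) else c(2, 1)
  expect_lt(max(d[cbind(1:2, perm)]), 0.1)
  expect_true(all(apply(fit$membership, 1, max) > 0.99))
  expect_equal(rowSums(fit$membership), rep(1, 200), tolerance = 1e-12)
})

test_that("the FCM objective is non-increasing and memberships stay stochastic", {
  X <- two_clouds(sd = 2, seed = 9)   # overlapping: many iterations
  fit <- fuzzy_cmeans(X, c = 3, seed = 2)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
  expect_true(all(fit$membership >= 0 & fit$membership <= 1))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  X <- two_clouds(sd = 0.5, seed = 4)
  fit <- fuzzy_cmeans(X, c = 2, seed = 1, standardize = FALSE)
  ref <- e1071::cmeans(X, centers = 2, m = 2, iter.max = 300)
  d <- as.matrix(dist(rbind(fit$centers, ref$centers)))[1:2, 3:4]
  perm <- if (d[1, 1] + d[2, 2] <= d[1, 2] + d[2, 1]) c(1, 2) else c(2, 1)
  expect_lt(max(d[cbind(1:2, perm)]), 1e-3)
  # same objective value at the optimum
  D2 <- as.matrix(dist(rbind(X, fit$centers)))^2
  expect_equal(fit$objective,
               sum(ref$membership[, perm]^2 *
                     D2[1:nrow(X), nrow(X) + 1:2]),
               tolerance = 1e-4)
})

test_that("MPC matches hand arithmetic and its extremes", {
  U <- rbind(c(0.8, 0.2), c(0.6, 0.4), c(0.9, 0.1))
  pc <- mean(rowSums(U^2))
  expect_equal(pc, 0.6733333, tolerance = 1e-6)
  expect_equal(mpc(U), 0.3466667, tolerance = 1e-6)

  crisp <- diag(3)[rep(1:3, 4), ]
  expect_equal(mpc(crisp), 1)

  uniform <- matrix(1 / 4, nrow = 10, ncol = 4)
  expect_equal(mpc(uniform), 0)
})

test_that("MPC is invariant to relabeling and rigid motions of the data", {
  X <- two_clouds(sd = 0.3, seed = 6)
  fit <- fuzzy_cmeans(X, c = 2, seed = 5, standardize = FALSE)
  expect_equal(mpc(fit$membership), mpc(fit$membership[, 2:1]))

  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Xr <- X %*% Rot + matrix(c(3, -1), nrow(X), 2, byrow = TRUE)
  fit_r <- fuzzy_cmeans(Xr, c = 2, seed = 5, standardize = FALSE)
  expect_equal(fit$mpc, fit_r$mpc, tolerance = 1e-9)
})

test_that("MPC model selection finds the generative cluster count", {
  set.seed(12)
  X3 <- rbind(
    cbind(rnorm(80, 0, 0.3), rnorm(80, 0, 0.3)),
    cbind(rnorm(80, 5, 0.3), rnorm(80, 0, 0.3)),
    cbind(rnorm(80, 0, 0.3), rnorm(80, 5, 0.3))
  )
  best <- select_cluster_count(X3, c_range = 2:6, seed = 7)
  expect_equal(best$c, 3)
  expect_true(best$structure)
  again <- select_cluster_count(X3, c_range = 2:6, seed = 7)
  expect_identical(best$mpc_table, again$mpc_table)

  # a single blob: MPC low everywhere, flagged structureless
  set.seed(13)
  blob <- cbind(rnorm(150), rnorm(150))
  b <- select_cluster_count(blob, c_range = 2:5, seed = 7)
  expect_false(b$structure)
  expect_lt(max(b$mpc_table$mpc), 0.5)
})

test_that("degenerate inputs are rejected with informative errors", {
  X <- two_clouds()
  expect_error(fuzzy_cmeans(X, c = 201), "c <= n")
  expect_error(fuzzy_cmeans(X, c = 2, m = 1), "m must be")
  expect_error(fuzzy_cmeans(rbind(X, c(NA, 1)), c = 2), "finite")
  expect_error(select_cluster_count(X, c_range = integer(0)), "non-empty")
  # a point coincident with a centre gets a clean membership-1 split
  Xc <- rbind(matrix(0, 3, 2), matrix(5, 4, 2))
  fit <- fuzzy_cmeans(Xc, c = 2, seed = 1, standardize = FALSE)
  expect_equal(rowSums(fit$membership), rep(1, 7), tolerance = 1e-12)
  expect_equal(fit$mpc, 1, tolerance = 1e-6)
})

test_that("strategy profiles count sessions per cluster per rat", {
  model <- structure(list(c = 2, m = 2, cluster = c(rep(1L, 7), rep(2L, 3)),
                          membership = diag(2)[c(rep(1, 7), rep(2, 3)), ]),
                     class = "fcm_fit")
  keys <- tibble::tibble(rat_id = rep("r1", 10))
  prof <- strategy_profiles(list(distance = model), list(distance = keys))
  expect_equal(prof$probability, c(0.7, 0.3))
  expect_equal(sum(prof$probability), 1)

  v <- foragedm:::profile_vector(prof, "r1")
  expect_equal(unname(v), c(0.7, 0.3))
})

test_that("Euclidean shift distances follow the l2 norm on concatenations", {
  a <- c(f1.1 = 1, f1.2 = 0, f1.3 = 0)
  b <- c(f1.1 = 0, f1.2 = 1, f1.3 = 0)
  expect_equal(euclidean_shift(a, a), 0)
  expect_equal(euclidean_shift(a, b), sqrt(2))

  # two-feature concatenation: sqrt(d1^2 + d2^2)
  a2 <- c(a, g.1 = 0.5, g.2 = 0.5)
  b2 <- c(b, g.1 = 1, g.2 = 0)
  d1 <- sqrt(2); d2 <- sqrt(0.25 + 0.25)
  expect_equal(euclidean_shift(a2, b2), sqrt(d1^2 + d2^2))
})

test_that("the KS shift test matches the reference implementation", {
  expect_equal(population_shift_test(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(population_shift_test(c(1, 2), c(5, 6))$statistic, 1)

  set.seed(14)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  mine <- population_shift_test(x, y)
  ref <- ks.test(x, y)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  x2 <- rnorm(200); y2 <- rnorm(250)
  mine2 <- population_shift_test(x2, y2)
  ref2 <- ks.test(x2, y2)
  expect_equal(mine2$statistic, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-5)
})

test_that("cluster migration tests decompose into per-cluster 2x2 tables", {
  same <- cluster_migration_test(c(30, 20, 10), c(30, 20, 10))
  expect_equal(same$statistic, rep(0, 3))
  expect_equal(same$p_value, rep(1, 3))

  # 2x2 table (50,50 / 90,10): chi-squared = 38.095 (formula oracle:
  # N (ad - bc)^2 / (row1 row2 col1 col2) = 200 * 4000^2 / (100*100*140*60))
  m <- cluster_migration_test(c(50, 50), c(90, 10))
  expect_equal(m$statistic[1], 200 * 4000^2 / (100 * 100 * 140 * 60),
               tolerance = 1e-10)
  expect_equal(m$statistic[1], 38.0952381, tolerance = 1e-6)

  # bookkeeping: in + out always reproduces the condition totals
  expect_true(all(m$a_in + m$a_out == 100))
  expect_true(all(m$b_in + m$b_out == 100))
  expect_error(cluster_migration_test(c(0.5, 1), c(1, 1)), "integer")
})

test_that("cluster mean curves average member sessions pointwise", {
  cv <- function(y) tibble::tibble(x = 1:4, y = y)
  curves <- list(cv(c(0, 0, 1, 1)), cv(c(0, 0, 1, 1)), cv(c(0, 1, 1, 1)),
                 cv(c(1, 0, 0, 0)))
  out <- cluster_mean_curves(c(1, 1, 1, 2), curves)
  c1 <- out[out$cluster == 1, ]
  expect_equal(c1$y_mean, c(0, 1 / 3, 1, 1))
  expect_equal(c1$n_sessions, rep(3, 4))
  c2 <- out[out$cluster == 2, ]
  expect_equal(c2$y_mean, c(1, 0, 0, 0))
  expect_equal(c2$y_sem, rep(0, 4))   # single member

  twin <- cluster_mean_curves(c(1, 1), curves[1:2])
  expect_equal(twin$y_sem, rep(0, 4))  # identical members
})
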