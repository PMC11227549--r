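# Coarse grid-search oracle for the 1D logistic SSE surface.
grid_oracle_1d <- function(x, y, axis = "reward",
                           a_grid = exp(seq(log(0.02), log(20), length.out = 250)),
                           b_grid = seq(-12, 12, length.out = 250)) {
  best <- Inf
  for (a in a_grid) {
    for (b in b_grid) {
      p <- if (axis == "reward") plogis(a * x - b) else plogis(-(a * x + b))
      sse <- sum((y - p)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

test_that("noise-free 1D logistic curves are inverted exactly", {
  x <- 1:4
  y <- plogis(1.5 * x - 3)
  fit <- fit_logistic_1d(tibble::tibble(x = x, y = y), n_boot = 0)
  expect_equal(fit$a, 1.5, tolerance = 1e-6)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # cost axis: falling curve
  yc <- plogis(-(0.8 * x - 1))
  fc <- fit_logistic_1d(tibble::tibble(x = x, y = yc), axis = "cost",
                        n_boot = 0)
  expect_equal(fc$a, 0.8, tolerance = 1e-5)
  expect_equal(fc$b, -1, tolerance = 1e-5)
})

test_that("degenerate flat curves are flagged rather than silently fit", {
  fit <- fit_logistic_1d(tibble::tibble(x = 1:4, y = rep(1, 4)), n_boot = 0)
  expect_true(fit$degenerate)
})

test_that("the optimizer matches a dense grid-search oracle on rough data", {
  set.seed(5)
  for (rep in 1:3) {
    y <- runif(4, 0.05, 0.95)
    fit <- fit_logistic_1d(tibble::tibble(x = 1:4, y = sort(y)), n_boot = 0)
    oracle <- grid_oracle_1d(1:4, sort(y))
    expect_lte(fit$sse, oracle + 1e-3)
  }
})

test_that("the 2D choice surface recovers exact generating parameters", {
  cells <- tidyr::expand_grid(R = 1:4, C = c(1, 3))
  cells$p <- choice_prob(cells$R, cells$C, 2, 3, 1, -1)
  fit <- fit_logistic_2d(cells, n_boot = 0)
  expect_equal(fit$a_R, 2, tolerance = 1e-6)
  expect_equal(fit$b_R, 3, tolerance = 1e-6)
  expect_equal(fit$a_C, 1, tolerance = 1e-6)
  expect_equal(fit$b_C, -1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("a constant 0.5 grid yields a flagged flat surface", {
  cells <- tidyr::expand_grid(R = 1:4, C = c(1, 3))
  cells$p <- 0.5
  fit <- fit_logistic_2d(cells, n_boot = 0)
  expect_true(fit$flat)
})

test_that("single-cost grids fall back to the 1D fit with a warning", {
  cells <- tidyr::expand_grid(R = 1:4, C = 1)
  cells$p <- plogis(1.2 * cells$R - 2.5)
  expect_warning(fit <- fit_logistic_2d(cells, n_boot = 0), "single cost")
  expect_s3_class(fit, "logistic1d_fit")
})

test_that("bootstrap CIs cover the generating parameters at roughly 80%", {
  truth <- c(a_R = 2, b_R = 3, a_C = 1, b_C = -1)
  n_cell <- 200
  hits <- matrix(NA, 40, 4)
  for (r in 1:40) {
    set.seed(1000 + r)
    cells <- tidyr::expand_grid(R = 1:4, C = c(1, 3))
    p <- choice_prob(cells$R, cells$C, truth[1], truth[2], truth[3], truth[4])
    cells$p <- rbinom(nrow(cells), n_cell, p) / n_cell
    cells$n <- n_cell
    fit <- fit_logistic_2d(cells, n_boot = 150, seed = r)
    hits[r, ] <- truth >= fit$ci$conf.low & truth <= fit$ci$conf.high
  }
  # each parameter inside its 80% CI in at least 70% of replicates
  expect_true(all(colMeans(hits) >= 0.7))
})

test_that("the decision boundary is the exact half-maximum locus", {
  # hand-algebra case: a_R=1, b_R=0, a_C=1, b_C=0 at C=-ln 3 -> R*=ln 2
  bd <- decision_boundary(list(a_R = 1, b_R = 0, a_C = 1, b_C = 0),
                          cost_grid = c(-log(3), 1))
  expect_equal(bd$R_star[1], log(2), tolerance = 1e-12)
  expect_true(bd$exists[1])
  # at C=1 the cost logistic is already below 0.5: no boundary
  expect_false(bd$exists[2])
  expect_true(is.na(bd$R_star[2]))

  # defining property over random parameter draws
  set.seed(42)
  for (k in 1:25) {
    par <- list(a_R = runif(1, 0.5, 3), b_R = runif(1, -3, 3),
                a_C = runif(1, 0.5, 3), b_C = runif(1, -3, 3))
    Cs <- seq(-2, 4, length.out = 13)
    bd <- decision_boundary(par, Cs)
    ex <- bd$exists
    if (!any(ex)) next
    f <- choice_prob(bd$R_star[ex], bd$C[ex],
                     par$a_R, par$b_R, par$a_C, par$b_C)
    expect_true(all(abs(f - 0.5) < 1e-9))
  }
  expect_error(decision_boundary(list(a_R = 0, b_R = 0, a_C = 1, b_C = 0), 1),
               class = "foragedm_no_boundary")
})

test_that("utility curvature nests the linear model and is recoverable", {
  x <- 1:4
  # c = 0 data: free-c fit must collapse onto the linear fit
  y0 <- plogis(1.5 * x - 3)
  u0 <- fit_marginal_utility(tibble::tibble(x = x, y = y0), n_boot = 0)
  expect_lt(abs(u0$c), 1e-4)
  expect_equal(u0$sse, u0$sse_linear, tolerance = 1e-10)

  # structural constraints of g
  expect_equal(utility_g(0, -0.3), 0)
  eps <- 1e-7
  expect_equal((utility_g(eps, -0.3) - utility_g(0, -0.3)) / eps, 1,
               tolerance = 1e-6)

  # diminishing-returns data: curvature recovered, free fit beats linear
  yc <- plogis(2 * utility_g(x, -0.15) - 3)
  uc <- fit_marginal_utility(tibble::tibble(x = x, y = yc), n_boot = 100,
                             seed = 2)
  expect_equal(uc$c, -0.15, tolerance = 1e-4)
  expect_lte(uc$sse, uc$sse_linear)
  expect_true(uc$improves)
})

test_that("valuation, elasticity and sensitivity behave as defined", {
  x <- 1:4
  y <- plogis(1 * x - 2)   # midpoint at 2
  fit <- fit_logistic_1d(tibble::tibble(x = x, y = y, n = rep(50, 4)),
                         n_boot = 80, seed = 3)
  nf <- neuroecon_features(fit)
  expect_equal(nf$valuation, 2, tolerance = 1e-3)
  expect_equal(nf$elasticity, 1 / 4, tolerance = 1e-3)  # max slope a/4

  # steeper curve -> larger elasticity
  fit2 <- fit_logistic_1d(tibble::tibble(x = x, y = plogis(3 * x - 6)),
                          n_boot = 0)
  expect_gt(neuroecon_features(fit2)$elasticity, nf$elasticity)

  # doubling observation noise inflates the fit MSE (seeded)
  set.seed(8)
  noise <- rnorm(4)
  ylo <- pmin(pmax(y + 0.02 * noise, 0), 1)
  yhi <- pmin(pmax(y + 0.12 * noise, 0), 1)
  mse_lo <- neuroecon_features(
    fit_logistic_1d(tibble::tibble(x = x, y = ylo), n_boot = 0))$mse
  mse_hi <- neuroecon_features(
    fit_logistic_1d(tibble::tibble(x = x, y = yhi), n_boot = 0))$mse
  expect_gt(mse_hi, mse_lo)
})
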