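# Deterministic multistart bounded least squares used by every fitter.
# Starts are a fixed lattice (plus model-specific heuristics); each start is
# polished with nlminb at tight tolerances and the best SSE wins.
ls_multistart <- function(sse, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      nlminb(s, sse, lower = lower, upper = upper,
             control = list(abs.tol = 1e-14, rel.tol = 1e-12,
                            x.tol = 1e-12, iter.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stopf("all optimizer starts failed")
  # one Nelder-Mead polish from the winner guards against box-edge stalls
  pol <- tryCatch(
    optim(best$par, sse, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (!is.null(pol) && pol$value < best$objective &&
      all(pol$par >= lower & pol$par <= upper)) {
    best <- list(par = pol$par, objective = pol$value,
                 convergence = pol$convergence)
  }
  best$par <- unname(best$par)
  best
}

r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - yhat)^2)
  if (sst < 1e-300) return(if (sse < 1e-12) 1 else NA_real_)
  1 - sse / sst
}

curve_xyn <- function(curve) {
  stopifnot(all(c("x", "y") %in% names(curve)))
  list(x = curve$x, y = curve$y,
       n = if ("n" %in% names(curve)) curve$n else rep(NA_real_, nrow(curve)))
}

#' Fit a one-dimensional logistic choice function
#'
#' Least-squares fit of the acceptance probability against reward
#' (`f(x) = 1 / (1 + exp(-(a x - b)))`, rising) or cost
#' (`f(x) = 1 / (1 + exp(a x + b))`, falling) on per-level choice proportions.
#' Optimised from a deterministic multistart lattice; 80% parameter
#' confidence intervals by seeded parametric bootstrap (binomial when
#' per-level trial counts are available, Gaussian residual otherwise).
#'
#' @param curve A data frame with columns `x`, `y` (and optionally `n`), e.g.
#'   a [psych_curve()].
#' @param axis `"reward"` (rising) or `"cost"` (falling).
#' @param n_boot Bootstrap draws for the CIs (0 skips them).
#' @param level Confidence level (default 0.8).
#' @param seed Bootstrap seed.
#' @return A `logistic1d_fit` object: parameters `a`, `b`, `r_squared`,
#'   `sse`, CI tibble, bootstrap parameter draws, `degenerate` flag.
#' @export
fit_logistic_1d <- function(curve, axis = c("reward", "cost"),
                            n_boot = 200, level = 0.8, seed = 1) {
  axis <- match.arg(axis)
  d <- curve_xyn(curve)
  if (length(d$x) < 3) stopf("need at least 3 levels to fit")
  if (any(d$y < -1e-9 | d$y > 1 + 1e-9)) stopf("acceptance values must be in [0, 1]")
  # reward: plogis(a x - b); cost: plogis(-(a x + b))
  pred <- function(par, x) {
    if (axis == "reward") plogis(par[1] * x - par[2]) else
      plogis(-(par[1] * x + par[2]))
  }
  sse_fn <- function(par) sum((d$y - pred(par, d$x))^2)

  degenerate <- diff(range(d$y)) < 1e-9
  lower <- c(1e-6, -60); upper <- c(60, 60)
  starts <- c(
    lapply(exp(seq(log(0.05), log(10), length.out = 4)), function(a) {
      lapply(seq(-6, 6, length.out = 4), function(b) c(a, b))
    }) |> unlist(recursive = FALSE),
    list(heuristic_logistic_start(d$x, d$y, axis))
  )
  best <- ls_multistart(sse_fn, starts, lower, upper)
  yhat <- pred(best$par, d$x)

  boot <- NULL
  ci <- NULL
  if (n_boot > 0 && !degenerate) {
    boot <- boot_refit(d, pred, best$par, lower, upper, n_boot, seed)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- tibble::tibble(
      term = c("a", "b"),
      conf.low = apply(boot, 2, quantile, qs[1]),
      conf.high = apply(boot, 2, quantile, qs[2])
    )
  }
  structure(
    list(axis = axis, a = best$par[1], b = best$par[2],
         r_squared = r_squared(d$y, yhat), sse = best$objective,
         fitted = yhat, curve = tibble::tibble(x = d$x, y = d$y, n = d$n),
         ci = ci, boot = boot, level = level,
         degenerate = degenerate,
         predict = function(x) pred(best$par, x)),
    class = "logistic1d_fit"
  )
}

heuristic_logistic_start <- function(x, y, axis) {
  z <- qlogis(pmin(pmax(y, 0.02), 0.98))
  if (axis == "cost") z <- -z
  co <- tryCatch(coef(lm(z ~ x)), error = function(e) c(0, 1))
  a <- max(co[2], 0.05)
  b <- if (axis == "reward") -co[1] else co[1]
  c(a, b)
}

# Seeded parametric bootstrap refits; returns matrix of parameter draws.
boot_refit <- function(d, pred, par_hat, lower, upper, n_boot, seed) {
  p_hat <- pred(par_hat, d$x)
  res_sd <- sqrt(mean((d$y - p_hat)^2))
  binom <- all(!is.na(d$n)) && all(d$n >= 1) &&
    all(d$y >= 0 & d$y <= 1)
  with_seed(derive_seed(seed, "boot"), {
    draws <- matrix(NA_real_, n_boot, length(par_hat))
    for (b in seq_len(n_boot)) {
      ystar <- if (binom) {
        rbinom(length(p_hat), round(d$n), p_hat) / round(d$n)
      } else {
        pmin(pmax(p_hat + rnorm(length(p_hat), 0, res_sd), 0), 1)
      }
      sse_b <- function(par) sum((ystar - pred(par, d$x))^2)
      fit <- ls_multistart(sse_b, list(par_hat), lower, upper)
      draws[b, ] <- fit$par
    }
    draws
  })
}

#' Fit the two-factor logistic choice surface
#'
#' Least squares of the product-of-logistics surface
#' `f(R, C) = plogis(a_R R - b_R) * plogis(-(a_C C + b_C))` on the grid of
#' per-cell acceptance proportions. With a single cost level the surface is
#' unidentifiable and the fit falls back to [fit_logistic_1d()] with a
#' warning.
#'
#' @param cells A data frame with columns `R`, `C`, `p` (and optionally `n`),
#'   one row per (reward level, cost level) cell with offers.
#' @param n_boot,level,seed Bootstrap controls as in [fit_logistic_1d()].
#' @return A `logistic2d_fit` object (or a `logistic1d_fit` on fallback).
#' @export
fit_logistic_2d <- function(cells, n_boot = 200, level = 0.8, seed = 1) {
  stopifnot(all(c("R", "C", "p") %in% names(cells)))
  if (length(unique(cells$C)) < 2) {
    warn("single cost level: falling back to a 1D reward logistic fit")
    curve <- dplyr::summarise(
      dplyr::group_by(cells, x = .data$R),
      y = mean(.data$p),
      n = if ("n" %in% names(cells)) sum(.data$n) else NA_real_,
      .groups = "drop")
    return(fit_logistic_1d(curve, axis = "reward", n_boot = n_boot,
                           level = level, seed = seed))
  }
  if (length(unique(cells$R)) < 2) stopf("need at least 2 reward levels")
  n <- if ("n" %in% names(cells)) cells$n else rep(NA_real_, nrow(cells))
  d <- list(x = seq_len(nrow(cells)), y = cells$p, n = n)
  pred <- function(par, idx) {
    choice_prob(cells$R[idx], cells$C[idx], par[1], par[2], par[3], par[4])
  }
  sse_fn <- function(par) sum((d$y - pred(par, d$x))^2)
  lower <- c(1e-6, -60, 1e-6, -60); upper <- c(60, 60, 60, 60)
  lat <- expand.grid(a_R = c(0.5, 3), b_R = c(-2, 3),
                     a_C = c(0.5, 3), b_C = c(-3, 1))
  starts <- c(
    lapply(seq_len(nrow(lat)), function(i) as.numeric(lat[i, ])),
    list(c(heuristic_logistic_start(cells$R, pmin(cells$p * 2, 0.98), "reward"),
           1, -2))
  )
  best <- ls_multistart(sse_fn, starts, lower, upper)
  yhat <- pred(best$par, d$x)
  flat <- best$par[1] < 0.02 & best$par[3] < 0.02

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    boot <- boot_refit(d, pred, best$par, lower, upper, n_boot, seed)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- tibble::tibble(
      term = c("a_R", "b_R", "a_C", "b_C"),
      conf.low = apply(boot, 2, quantile, qs[1]),
      conf.high = apply(boot, 2, quantile, qs[2])
    )
  }
  structure(
    list(a_R = best$par[1], b_R = best$par[2],
         a_C = best$par[3], b_C = best$par[4],
         r_squared = r_squared(d$y, yhat), sse = best$objective,
         residuals = tibble::tibble(R = cells$R, C = cells$C, p = cells$p,
                                    fitted = yhat,
                                    residual = cells$p - yhat),
         ci = ci, boot = boot, level = level, flat = flat,
         predict = function(R, C) choice_prob(R, C, best$par[1], best$par[2],
                                              best$par[3], best$par[4])),
    class = "logistic2d_fit"
  )
}

#' Decision boundary of a fitted choice surface
#'
#' Solves `f(R, C) = 0.5` for reward as a function of cost. Writing
#' `S_R = 0.5 (1 + exp(a_C C + b_C))` for the reward-side probability needed
#' at cost C, the boundary is `R*(C) = (b_R - ln(1/S_R - 1)) / a_R`; where
#' `S_R >= 1` (the cost factor alone pushes acceptance below 0.5) no boundary
#' exists and the cell is flagged.
#'
#' @param fit A `logistic2d_fit`, or a list/vector with `a_R, b_R, a_C, b_C`.
#' @param cost_grid Cost values at which to evaluate the boundary.
#' @return A tibble `C`, `R_star`, `exists`.
#' @export
decision_boundary <- function(fit, cost_grid) {
  p <- if (inherits(fit, "logistic2d_fit")) fit else as.list(fit)
  if (p$a_R <= 0) {
    stopf("a_R must be > 0 for a decision boundary to exist",
          class = "foragedm_no_boundary")
  }
  S_R <- 0.5 * (1 + exp(p$a_C * cost_grid + p$b_C))
  exists <- S_R < 1
  R_star <- rep(NA_real_, length(cost_grid))
  R_star[exists] <- (p$b_R - log(1 / S_R[exists] - 1)) / p$a_R
  tibble::tibble(C = cost_grid, R_star = R_star, exists = exists)
}

#' Fit the marginal-utility choice model
#'
#' Replaces reward with its subjective utility in the reward logistic:
#' `f(R) = plogis(a_R g(R) - b_R)` with `g(R) = c R^2/2 + R` ([utility_g()];
#' `g(0) = 0`, `g'(0) = 1` by construction). `c = 0` reduces exactly to the
#' linear-reward logistic, so the free-curvature fit nests it; both SSEs are
#' reported.
#'
#' @param curve Reward-axis curve (`x`, `y`, optional `n`).
#' @param n_boot,level,seed Bootstrap controls.
#' @return A `utility_fit` object with `a`, `b`, `c`, both SSEs and an
#'   `improves` flag.
#' @export
fit_marginal_utility <- function(curve, n_boot = 200, level = 0.8, seed = 1) {
  d <- curve_xyn(curve)
  if (length(d$x) < 3) stopf("need at least 3 levels to fit")
  pred <- function(par, x) plogis(par[1] * utility_g(x, par[3]) - par[2])
  sse_fn <- function(par) sum((d$y - pred(par, d$x))^2)
  lower <- c(1e-6, -60, -2); upper <- c(60, 60, 2)
  lin <- fit_logistic_1d(curve, axis = "reward", n_boot = 0)
  starts <- c(
    lapply(c(-0.5, -0.15, 0, 0.15), function(cc) c(lin$a, lin$b, cc)),
    lapply(exp(seq(log(0.1), log(8), length.out = 4)), function(a) {
      c(a, 0, -0.2)
    })
  )
  best <- ls_multistart(sse_fn, starts, lower, upper)
  yhat <- pred(best$par, d$x)

  boot <- NULL; ci <- NULL
  if (n_boot > 0) {
    boot <- boot_refit(d, pred, best$par, lower, upper, n_boot, seed)
    qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- tibble::tibble(
      term = c("a", "b", "c"),
      conf.low = apply(boot, 2, quantile, qs[1]),
      conf.high = apply(boot, 2, quantile, qs[2])
    )
  }
  structure(
    list(a = best$par[1], b = best$par[2], c = best$par[3],
         r_squared = r_squared(d$y, yhat), sse = best$objective,
         sse_linear = lin$sse, improves = best$objective < lin$sse - 1e-12,
         linear_fit = lin, ci = ci, boot = boot, level = level,
         curve = tibble::tibble(x = d$x, y = d$y, n = d$n),
         g = function(R) utility_g(R, best$par[3]),
         predict = function(x) pred(best$par, x)),
    class = "utility_fit"
  )
}

#' Neuroeconomic summaries of a fitted psychometric function
#'
#' Valuation is the location where the fitted curve crosses half maximum;
#' elasticity is the maximum slope of the fitted curve; sensitivity is the
#' residual mean squared error plus the width of the bootstrap confidence
#' band of fitted values at the valuation point.
#'
#' @param fit A `logistic1d_fit` or `utility_fit`.
#' @param x_range Range over which to locate the half-maximum crossing and
#'   maximum slope; the default extends the fitted levels far enough that a
#'   logistic effectively reaches both asymptotes.
#' @return A tibble with `valuation`, `elasticity`, `mse`, `ci_band_width`.
#' @export
neuroecon_features <- function(fit, x_range = NULL) {
  stopifnot(inherits(fit, c("logistic1d_fit", "utility_fit")))
  xs <- fit$curve$x
  if (is.null(x_range)) x_range <- range(xs) + c(-3, 3) * diff(range(xs))
  grid <- seq(x_range[1], x_range[2], length.out = 2001)
  fx <- fit$predict(grid)
  half <- (max(fx) + min(fx)) / 2
  # half-maximum crossing by sign change of f - half
  s <- sign(fx - half)
  cross <- which(diff(s) != 0)
  valuation <- if (length(cross)) {
    i <- cross[1]
    x0 <- grid[i]; x1 <- grid[i + 1]
    f0 <- fx[i]; f1 <- fx[i + 1]
    x0 + (half - f0) / (f1 - f0) * (x1 - x0)
  } else NA_real_
  slope <- abs(diff(fx) / diff(grid))
  elasticity <- max(slope)
  mse <- fit$sse / nrow(fit$curve)
  band <- NA_real_
  if (!is.null(fit$boot) && !is.na(valuation)) {
    pv <- apply(fit$boot, 1, function(par) {
      if (inherits(fit, "utility_fit")) {
        plogis(par[1] * utility_g(valuation, par[3]) - par[2])
      } else if (fit$axis == "reward") {
        plogis(par[1] * valuation - par[2])
      } else {
        plogis(-(par[1] * valuation + par[2]))
      }
    })
    qs <- c((1 - fit$level) / 2, 1 - (1 - fit$level) / 2)
    band <- diff(quantile(pv, qs))
  }
  tibble::tibble(valuation = valuation, elasticity = elasticity,
                 mse = mse, ci_band_width = as.numeric(band))
}

#' @export
print.logistic1d_fit <- function(x, ...) {
  cat(sprintf("<logistic1d_fit> axis=%s a=%.4g b=%.4g R^2=%.4f%s\n",
              x$axis, x$a, x$b, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
print.logistic2d_fit <- function(x, ...) {
  cat(sprintf("<logistic2d_fit> a_R=%.4g b_R=%.4g a_C=%.4g b_C=%.4g R^2=%.4f%s\n",
              x$a_R, x$b_R, x$a_C, x$b_C, x$r_squared,
              if (isTRUE(x$flat)) " [flat]" else ""))
  invisible(x)
}

#' @export
print.utility_fit <- function(x, ...) {
  cat(sprintf("<utility_fit> a=%.4g b=%.4g c=%.4g R^2=%.4f (SSE %.3g vs linear %.3g)\n",
              x$a, x$b, x$c, x$r_squared, x$sse, x$sse_linear))
  invisible(x)
}
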