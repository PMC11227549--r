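#' Fit the four candidate shape models to a psychometric function
#'
#' Candidates are three sigmoid variants and a parabola:
#' \itemize{
#'   \item `sig2p`: `f(x) = 1 / (1 + b e^{-c x})`
#'   \item `sig3p`: `f(x) = a / (1 + b e^{-c x})`
#'   \item `sig4p`: `f(x) = a / (1 + b e^{-c (x - d)})`
#'   \item `parabola`: `f(x) = a (x - b)^2 + c`
#' }
#' Sigmoids are fit by deterministic multistart least squares; the parabola is
#' an exact linear least-squares fit. Each candidate reports its parameters
#' and R-squared.
#'
#' @param curve A data frame with `x` and `y` columns ([psych_curve()]).
#' @return A named list of `shape_candidate` objects
#'   (`sig2p`, `sig3p`, `sig4p`, `parabola`).
#' @export
fit_shape_models <- function(curve) {
  d <- curve_xyn(curve)
  if (any(!is.finite(d$y))) stopf("non-finite y values in curve")
  n <- length(d$x)
  if (n < 3) stopf("need at least 3 points")
  out <- list(
    sig2p = fit_sigmoid(d, n_par = 2),
    sig3p = fit_sigmoid(d, n_par = 3)
  )
  out$sig4p <- if (n >= 4) fit_sigmoid(d, n_par = 4) else NULL
  out$parabola <- fit_parabola(d)
  out[!vapply(out, is.null, logical(1))]
}

sig_pred <- function(par, x, n_par) {
  a <- if (n_par >= 3) par[1] else 1
  b <- par[n_par - 1]
  c <- par[n_par]
  d <- if (n_par == 4) par[2] else 0
  a / (1 + b * exp(-c * (x - d)))
}

fit_sigmoid <- function(d, n_par) {
  # parameter layout: sig2p (b, c); sig3p (a, b, c); sig4p (a, d, b, c)
  sse_fn <- function(par) sum((d$y - sig_pred(par, d$x, n_par))^2)
  b_lat <- exp(seq(log(0.1), log(100), length.out = 4))
  c_lat <- c(-4, -1, 1, 4)
  base <- expand.grid(b = b_lat, c = c_lat)
  ymax <- max(max(d$y), 1e-3)
  starts <- lapply(seq_len(nrow(base)), function(i) {
    bc <- as.numeric(base[i, ])
    switch(as.character(n_par),
           "2" = bc,
           "3" = c(ymax, bc),
           "4" = c(ymax, mean(d$x), bc))
  })
  lower <- switch(as.character(n_par),
                  "2" = c(1e-8, -50),
                  "3" = c(1e-6, 1e-8, -50),
                  "4" = c(1e-6, min(d$x) - 10, 1e-8, -50))
  # identifiability guard: a sigmoid plateau far above every observation is
  # unidentifiable from the data, so the height is bounded near the data range
  a_max <- max(3 * max(abs(d$y)), 1e-3)
  upper <- switch(as.character(n_par),
                  "2" = c(1e8, 50),
                  "3" = c(a_max, 1e8, 50),
                  "4" = c(a_max, max(d$x) + 10, 1e8, 50))
  best <- ls_multistart(sse_fn, starts, lower, upper)
  par <- best$par
  a <- if (n_par >= 3) par[1] else 1
  dd <- if (n_par == 4) par[2] else 0
  b <- switch(as.character(n_par), "2" = par[1], "3" = par[2], "4" = par[3])
  c <- switch(as.character(n_par), "2" = par[2], "3" = par[3], "4" = par[4])
  yhat <- sig_pred(par, d$x, n_par)
  structure(
    list(model = paste0("sig", n_par, "p"),
         a = a, b = b, c = c, d = dd,
         r_squared = r_squared(d$y, yhat), sse = best$objective,
         fitted = yhat,
         predict = function(x) sig_pred(par, x, n_par)),
    class = "shape_candidate"
  )
}

reorder_par <- function(par, n_par) par

fit_parabola <- function(d) {
  fit <- lm(d$y ~ d$x + I(d$x^2))
  co <- coef(fit)
  A <- co[3]; B <- co[2]; C0 <- co[1]
  if (!is.finite(A) || abs(A) < 1e-12) {
    # degenerate to a line; vertex undefined
    a <- 0; b <- NA_real_; cc <- NA_real_
  } else {
    a <- unname(A)
    b <- unname(-B / (2 * A))
    cc <- unname(C0 - B^2 / (4 * A))
  }
  yhat <- fitted(fit)
  structure(
    list(model = "parabola", a = a, b = b, c = cc,
         r_squared = r_squared(d$y, yhat), sse = sum((d$y - yhat)^2),
         fitted = as.numeric(yhat),
         predict = function(x) {
           if (is.na(b)) co[1] + co[2] * x else a * (x - b)^2 + cc
         }),
    class = "shape_candidate"
  )
}

#' Classify the shape of a psychometric function
#'
#' Applies the R-squared rule: the function is `sigmoidal` when any sigmoid
#' candidate reaches `r_squared >= threshold` (when more than one qualifies
#' the three-parameter sigmoid is the reported model); otherwise `parabolic`
#' when the parabola reaches the threshold; otherwise `undefined`. Shape
#' descriptors: for sigmoids, shift (x at half maximum,
#' `d + ln(b)/c`), slope (maximum derivative, `a c / 4`) and max (`a`); for
#' parabolas, shift (`b`, vertex location) and max (`c`, vertex value).
#' Upward-opening parabolas (`a > 0`) are flagged invalid (no interior
#' maximum) and are excluded from strategy clustering downstream.
#'
#' @param curve A data frame with `x`, `y`, or the output of
#'   [fit_shape_models()].
#' @param threshold R-squared acceptance threshold (default 0.4).
#' @return A `shape_fit` object: `label` (`sigmoidal` / `parabolic` /
#'   `undefined`), chosen `model`, parameters, `r_squared`, descriptor fields
#'   `shift`, `slope`, `max`, `valid`, `identified` (sigmoid midpoint inside
#'   the sampled range, i.e. the descriptors are measured rather than
#'   extrapolated), and the full candidate list.
#' @export
classify_shape <- function(curve, threshold = 0.4) {
  cands <- if (is.list(curve) && all(vapply(curve, inherits, logical(1),
                                            "shape_candidate"))) {
    curve
  } else {
    fit_shape_models(curve)
  }
  sig_names <- intersect(c("sig2p", "sig3p", "sig4p"), names(cands))
  sig_r2 <- vapply(cands[sig_names], function(f) f$r_squared, numeric(1))
  par_r2 <- cands$parabola$r_squared

  pick <- NULL; label <- "undefined"
  ok <- sig_names[!is.na(sig_r2) & sig_r2 >= threshold]
  if (length(ok) > 1) {
    label <- "sigmoidal"; pick <- cands$sig3p
  } else if (length(ok) == 1) {
    label <- "sigmoidal"; pick <- cands[[ok]]
  } else if (!is.na(par_r2) && par_r2 >= threshold) {
    label <- "parabolic"; pick <- cands$parabola
  }

  shift <- slope <- mx <- NA_real_
  valid <- TRUE
  identified <- TRUE
  if (label == "sigmoidal") {
    shift <- pick$d + log(pick$b) / pick$c
    slope <- pick$a * pick$c / 4
    mx <- pick$a
    # a midpoint outside the sampled level range means the plateau was never
    # observed: shift and max are extrapolations, not measurements
    xr <- range(curve_x(curve, cands))
    identified <- is.finite(shift) && shift >= xr[1] && shift <= xr[2]
  } else if (label == "parabolic") {
    shift <- pick$b
    mx <- pick$c
    valid <- is.finite(pick$a) && pick$a < 0
  }
  structure(
    list(label = label,
         model = if (is.null(pick)) NA_character_ else pick$model,
         r_squared = if (is.null(pick)) NA_real_ else pick$r_squared,
         shift = shift, slope = slope, max = mx, valid = valid,
         identified = identified,
         threshold = threshold, candidates = cands,
         fit = pick),
    class = "shape_fit"
  )
}

curve_x <- function(curve, cands) {
  if (is.data.frame(curve) && "x" %in% names(curve)) return(curve$x)
  # classification from pre-computed candidates: infer the sampled range
  # from the fitted values' length (ordinal levels 1..k)
  seq_along(cands[[1]]$fitted)
}

#' @export
print.shape_fit <- function(x, ...) {
  cat(sprintf("<shape_fit> %s (%s, R^2=%s) shift=%.3g slope=%.3g max=%.3g\n",
              x$label, x$model %||% "-",
              if (is.na(x$r_squared)) "-" else sprintf("%.3f", x$r_squared),
              x$shift, x$slope, x$max))
  invisible(x)
}

#' Shape-classify every session of a feature table
#'
#' For each `(rat_id, condition, session)` and one feature, builds the
#' per-level psychometric curve and classifies its shape.
#'
#' @param features A feature table ([extract_features()] rows, possibly many
#'   sessions).
#' @param feature Feature column (or `"choice"` for acceptance).
#' @param threshold R-squared threshold.
#' @return A tibble with keys, `label`, `model`, `r_squared`, `shift`,
#'   `slope`, `max`, `valid`.
#' @export
classify_sessions <- function(features, feature = "choice", threshold = 0.4) {
  features |>
    dplyr::group_by(.data$rat_id, .data$condition, .data$session) |>
    dplyr::group_modify(function(df, key) {
      cv <- psych_curve(df, feature = feature)
      if (nrow(cv) < 3 || any(!is.finite(cv$y))) {
        return(tibble::tibble(label = "undefined", model = NA_character_,
                              r_squared = NA_real_, shift = NA_real_,
                              slope = NA_real_, max = NA_real_, valid = FALSE,
                              identified = FALSE))
      }
      sf <- classify_shape(cv, threshold = threshold)
      tibble::tibble(label = sf$label, model = sf$model,
                     r_squared = sf$r_squared, shift = sf$shift,
                     slope = sf$slope, max = sf$max, valid = sf$valid,
                     identified = sf$identified)
    }) |>
    dplyr::ungroup()
}
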