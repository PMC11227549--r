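# broom-style tidiers for the fitted objects.

#' @exportS3Method generics::tidy
tidy.logistic1d_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' @exportS3Method generics::glance
glance.logistic1d_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sse = x$sse,
                 nobs = nrow(x$curve), axis = x$axis,
                 degenerate = x$degenerate)
}

#' @exportS3Method generics::tidy
tidy.logistic2d_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("a_R", "b_R", "a_C", "b_C"),
                        estimate = c(x$a_R, x$b_R, x$a_C, x$b_C))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' @exportS3Method generics::glance
glance.logistic2d_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sse = x$sse,
                 nobs = nrow(x$residuals), flat = isTRUE(x$flat))
}

#' @exportS3Method generics::tidy
tidy.utility_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("a", "b", "c"),
                        estimate = c(x$a, x$b, x$c))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' @exportS3Method generics::glance
glance.utility_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sse = x$sse,
                 sse_linear = x$sse_linear, improves = x$improves,
                 nobs = nrow(x$curve))
}

#' @exportS3Method generics::tidy
tidy.shape_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  keep <- switch(x$fit$model,
                 sig2p = c("b", "c"), sig3p = c("a", "b", "c"),
                 sig4p = c("a", "b", "c", "d"), parabola = c("a", "b", "c"))
  tibble::tibble(term = keep,
                 estimate = unlist(x$fit[keep], use.names = FALSE))
}

#' @exportS3Method generics::glance
glance.shape_fit <- function(x, ...) {
  tibble::tibble(label = x$label, model = x$model %||% NA_character_,
                 r.squared = x$r_squared, shift = x$shift, slope = x$slope,
                 max = x$max, valid = x$valid)
}

#' @exportS3Method generics::tidy
tidy.fcm_fit <- function(x, ...) {
  ctr <- tibble::as_tibble(as.data.frame(x$centers))
  ctr$cluster <- seq_len(x$c)
  dplyr::select(ctr, "cluster", dplyr::everything())
}

#' @exportS3Method generics::glance
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(c = x$c, m = x$m, pc = x$pc, mpc = x$mpc,
                 objective = x$objective, iterations = x$iterations,
                 converged = x$converged)
}
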