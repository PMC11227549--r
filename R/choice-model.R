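# Core two-factor logistic choice model shared by the simulator and fitters.
#
# Acceptance probability of an offer at reward level R and cost level C:
#   f(R, C) = 1 / (1 + exp(-a_R * R + b_R)) * 1 / (1 + exp(a_C * C + b_C))
# i.e. a reward logistic rising in R times a cost logistic falling in C.
# With a utility curvature c, R is replaced by g(R) = c * R^2 / 2 + R
# (g(0) = 0, g'(0) = 1; c < 0 gives diminishing marginal utility).

logistic_reward <- function(R, a, b) plogis(a * R - b)
logistic_cost   <- function(C, a, b) plogis(-(a * C + b))

#' Subjective utility of reward with curvature
#'
#' `g(R) = c * R^2 / 2 + R`, normalised so utility is 0 at zero reward and
#' initially grows one-for-one with reward (`g(0) = 0`, `g'(0) = 1`).
#' Negative curvature models diminishing marginal returns.
#'
#' @param R Reward level(s).
#' @param c Curvature (0 = linear utility).
#' @return Numeric vector of utilities.
#' @export
utility_g <- function(R, c = 0) c * R^2 / 2 + R

#' Two-factor logistic acceptance probability
#'
#' @param R,C Reward and cost levels (ordinal scale by convention).
#' @param a_R,b_R Reward slope (> 0 for approach-with-reward) and shift.
#' @param a_C,b_C Cost slope (> 0 for avoid-with-cost) and shift.
#' @param curvature Utility curvature `c` applied to `R` via [utility_g()].
#' @return Acceptance probabilities in (0, 1).
#' @export
choice_prob <- function(R, C, a_R, b_R, a_C, b_C, curvature = 0) {
  logistic_reward(utility_g(R, curvature), a_R, b_R) * logistic_cost(C, a_C, b_C)
}

#' Define a stochastic decision policy for the simulator
#'
#' The policy accepts an offer at (reward level, cost level) with the
#' two-factor logistic probability of [choice_prob()].
#'
#' @inheritParams choice_prob
#' @param hesitation Probability that a rejected trial still contains a
#'   partial approach toward the offered feeder before retreating.
#' @return A `decision_policy` object.
#' @export
decision_policy <- function(a_R = 2, b_R = 3, a_C = 1, b_C = -1,
                            curvature = 0, hesitation = 0.3) {
  if (a_R <= 0 || a_C <= 0) {
    stopf("a_R and a_C must be > 0 (approach reward / avoid cost regime)")
  }
  if (hesitation < 0 || hesitation > 1) stopf("`hesitation` must be in [0, 1]")
  structure(
    list(a_R = a_R, b_R = b_R, a_C = a_C, b_C = b_C,
         curvature = curvature, hesitation = hesitation),
    class = "decision_policy"
  )
}

#' @export
print.decision_policy <- function(x, ...) {
  cat(sprintf(
    "<decision_policy> a_R=%g b_R=%g a_C=%g b_C=%g curvature=%g\n",
    x$a_R, x$b_R, x$a_C, x$b_C, x$curvature))
  invisible(x)
}
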