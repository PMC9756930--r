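#' Recency/antiquity observation weights
#'
#' Per-observation error weights mixing a "new data matter" ramp with an
#' "old data matter" ramp:
#' \deqn{w_i = \lambda \frac{i}{n(n+1)/2} +
#'       (1-\lambda) \frac{n - (i - 1)}{n(n+1)/2},}
#' which always sums to one.  `lambda = 0` weights the oldest observations
#' most, `lambda = 1` the newest, and `lambda = 0.5` makes every weight
#' exactly `1/n`.
#'
#' @param lambda mixing factor in `[0, 1]`.
#' @param n number of observations, `n >= 1`.
#' @return numeric vector of length `n` summing to 1.
#' @examples
#' observation_weights(0, 3)    # 3/6, 2/6, 1/6
#' observation_weights(0.5, 21) # uniform 1/21
#' @export
observation_weights <- function(lambda, n) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_invalid("`lambda` must be a single number in [0, 1]")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop_invalid("`n` must be an integer >= 1")
  i <- seq_len(n)
  denom <- n * (n + 1) / 2
  lambda * i / denom + (1 - lambda) * (n - (i - 1)) / denom
}

#' Confidence-scaled dispersion multiplier
#'
#' The coefficient multiplying the cross-scenario dispersion term in the
#' RRMAD objective: `(1 - beta) * sqrt(-2 * log(alpha))`.  It is zero at
#' `beta = 1` (pure mean-absolute-deviation fit), grows as the confidence
#' level `alpha` shrinks, and is always nonnegative.
#'
#' @param alpha confidence level in `(0, 1)`.
#' @param beta conservativity coefficient in `[0, 1]`.
#' @return nonnegative scalar.
#' @examples
#' risk_coefficient(0.05, 0.95)      # ~ 0.122387
#' risk_coefficient(exp(-1/2), 0.5)  # exactly 0.5
#' @export
risk_coefficient <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop_invalid("`alpha` must be a single number strictly inside (0, 1)")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1)
    stop_invalid("`beta` must be a single number in [0, 1]")
  (1 - beta) * sqrt(-2 * log(alpha))
}

#' Tightness condition of the split-variable linearization
#'
#' The LP linearization represents each absolute value as a sum of two
#' nonnegative variables; at the optimum that sum equals the absolute value
#' whenever the mean-deviation cost dominates the dispersion cost, i.e. when
#' `beta > 2 * risk_coefficient(alpha, beta) * max(1 - p)`.  When this fails
#' the LP is a relaxation and the recomputed diagnostics are authoritative.
#'
#' @inheritParams risk_coefficient
#' @param p scenario probability vector.
#' @return `TRUE` if the condition holds.
#' @export
tightness_holds <- function(alpha, beta, p) {
  beta > 2 * risk_coefficient(alpha, beta) * max(1 - p)
}
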