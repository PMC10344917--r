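#' Target ubiquitination initial rate (rapid-equilibrium model)
#'
#' Initial rate of target ubiquitination for a ternary-complex-forming
#' degrader under rapid binding equilibrium:
#' \deqn{v = V_{max} / [(1 - K_{LPT}/K_{LP}) +
#'       (1 + [P]_t/K_{LP}) \cdot 2K_{LPT}/D]}
#' where \eqn{D = ([P]_t+[T]_t+K_{TP}) - \sqrt{([P]_t+[T]_t+K_{TP})^2 -
#' 4[P]_t[T]_t}} is twice the binary target-PROTAC complex concentration.
#' \code{v_max} is the product of the ternary-complex breakdown rate
#' constant and total ligase concentration. \code{D} is evaluated through
#' [binary_complex()]'s cancellation-free quadratic root so the saturation
#' regime at very large \code{p_total} keeps full precision.
#'
#' @param p_total,t_total Total PROTAC and target (nM), >= 0. Vectorised.
#'   A zero total returns the analytic limit 0.
#' @param k_lp,k_tp Binary dissociation constants (nM), > 0.
#' @param k_lpt Ternary dissociation constant (nM), > 0.
#' @param v_max Maximal rate (arbitrary rate units), > 0.
#' @return Rate \code{v} in the units of \code{v_max}; strictly below
#'   \code{v_max} for finite inputs.
#' @seealso [normalized_rate()] for the algebraically identical
#'   cooperativity form.
#' @export
ubiquitination_rate <- function(p_total, t_total, k_lp, k_tp, k_lpt, v_max) {
  if (any(!is.finite(v_max)) || any(v_max <= 0)) stop("`v_max` must be > 0")
  if (any(k_lp <= 0) || any(k_tp <= 0) || any(k_lpt <= 0))
    stop("dissociation constants must be strictly positive")
  if (any(!is.finite(p_total)) || any(p_total < 0) ||
      any(!is.finite(t_total)) || any(t_total < 0))
    stop("totals must be non-negative and finite")
  d <- 2 * binary_complex(p_total, t_total, k_tp)
  out <- ifelse(d == 0, 0,
                v_max / ((1 - k_lpt / k_lp) +
                           (1 + p_total / k_lp) * 2 * k_lpt / d))
  unname(out)
}

#' Normalised ubiquitination rate in terms of cooperativity
#'
#' The same rapid-equilibrium rate law written with cooperativity
#' \eqn{\alpha = K_{LP}/K_{LPT}} in place of the ternary affinity:
#' \deqn{v/V_{max} = \alpha / [\alpha + (2(K_{LP}+[P]_t)/D - 1)]}
#' with \eqn{D} as in [ubiquitination_rate()]. The curve rises linearly in
#' \code{p_total} at low PROTAC and saturates (then slowly declines) at
#' high PROTAC; higher cooperativity raises the whole curve.
#'
#' @param p_total,t_total Totals (nM), >= 0. Vectorised; zero returns 0.
#' @param k_lp,k_tp Binary dissociation constants (nM), > 0.
#' @param alpha Cooperativity, > 0.
#' @return \code{v/V_max} in \[0, 1).
#' @export
normalized_rate <- function(p_total, t_total, k_lp, k_tp, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("`alpha` must be > 0")
  if (any(k_lp <= 0) || any(k_tp <= 0))
    stop("dissociation constants must be strictly positive")
  if (any(!is.finite(p_total)) || any(p_total < 0) ||
      any(!is.finite(t_total)) || any(t_total < 0))
    stop("totals must be non-negative and finite")
  d <- 2 * binary_complex(p_total, t_total, k_tp)
  out <- ifelse(d == 0, 0,
                alpha / (alpha + (2 * (k_lp + p_total) / d - 1)))
  unname(out)
}

#' Linear-regime approximation of the ubiquitination rate
#'
#' For PROTAC well below the target, \code{K_LP} and \code{K_TP} scales the
#' rate law reduces to \code{v/V_max ~ [P]_t / (2 K_LPT)}: in the linear
#' regime the rate is set by ternary-complex affinity and PROTAC dose.
#'
#' @param p_total Total PROTAC (nM), > 0. Vectorised.
#' @param k_lpt Ternary dissociation constant (nM), > 0.
#' @return Approximate \code{v/V_max}.
#' @export
linear_rate <- function(p_total, k_lpt) {
  if (any(!is.finite(p_total)) || any(p_total <= 0) ||
      any(!is.finite(k_lpt)) || any(k_lpt <= 0))
    stop("inputs must be strictly positive and finite")
  p_total / (2 * k_lpt)
}

#' Saturation-regime approximation of the ubiquitination rate
#'
#' For PROTAC far above the target, \code{K_LP} and \code{K_TP} scales the
#' rate law reduces to \code{v/V_max ~ alpha [T]_t / (2 [P]_t)}: at
#' saturating dose the rate is governed by cooperativity (and decays as the
#' hook effect sequesters the proteins in binary complexes). The expression
#' is implemented exactly as stated; note that the exact large-dose limit
#' of [normalized_rate()] is \code{alpha [T]_t / [P]_t}, a factor 2 larger
#' (see the package vignette).
#'
#' @param alpha Cooperativity, > 0.
#' @param t_total Total target (nM), > 0.
#' @param p_total Total PROTAC (nM), > 0. Vectorised.
#' @return Approximate \code{v/V_max}.
#' @export
saturation_rate <- function(alpha, t_total, p_total) {
  if (any(!is.finite(alpha)) || any(alpha <= 0) ||
      any(!is.finite(t_total)) || any(t_total <= 0) ||
      any(!is.finite(p_total)) || any(p_total <= 0))
    stop("inputs must be strictly positive and finite")
  alpha * t_total / (2 * p_total)
}
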