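#' Binding parameters of a ligase/PROTAC/target system
#'
#' Bundles the dissociation constants and derived dimensionless factors that
#' govern heterobifunctional three-body binding. All affinities are in nM.
#' Cooperativity \code{alpha = K_LP / K_LPT} compares the PROTAC's binary
#' affinity for the ligase with its ternary-complex affinity; \code{alpha > 1}
#' indicates favourable protein-protein contacts in the ternary complex.
#' The binary-affinity factor \code{beta} (see [beta_factor()]) enters the
#' closed-form maximal ternary-complex fraction \code{alpha / (alpha + beta)}.
#'
#' Either \code{k_lpt} or \code{alpha} may be supplied; the other is derived.
#' If both are given they must agree to relative 1e-9.
#'
#' @param k_lp Ligase-PROTAC dissociation constant (nM), > 0.
#' @param k_tp Target-PROTAC dissociation constant (nM), > 0.
#' @param k_lpt Ternary dissociation constant (nM), > 0; optional if
#'   \code{alpha} is given.
#' @param alpha Cooperativity (dimensionless), > 0; optional if \code{k_lpt}
#'   is given.
#' @param t_excess Target excess factor over \code{k_tp} assumed when the
#'   binary complex is maintained on a sensor surface; enters \code{beta}.
#'   Default 25.
#' @return An object of class \code{eq_params}: a list with elements
#'   \code{k_lp}, \code{k_tp}, \code{k_lpt}, \code{alpha}, \code{beta},
#'   \code{t_excess}.
#' @examples
#' eq_params(k_lp = 60, k_tp = 60, k_lpt = 4.7)
#' @export
eq_params <- function(k_lp, k_tp, k_lpt = NULL, alpha = NULL, t_excess = 25) {
  stopifnot(is.numeric(k_lp), length(k_lp) == 1L,
            is.numeric(k_tp), length(k_tp) == 1L)
  if (!is.finite(k_lp) || k_lp <= 0 || !is.finite(k_tp) || k_tp <= 0)
    stop("dissociation constants must be strictly positive and finite")
  if (is.null(k_lpt) && is.null(alpha))
    stop("supply at least one of `k_lpt` or `alpha`")
  if (is.null(alpha)) {
    if (k_lpt <= 0) stop("`k_lpt` must be strictly positive")
    alpha <- k_lp / k_lpt
  } else if (is.null(k_lpt)) {
    if (alpha <= 0) stop("`alpha` must be strictly positive")
    k_lpt <- k_lp / alpha
  } else {
    if (k_lpt <= 0 || alpha <= 0) stop("`k_lpt` and `alpha` must be positive")
    if (abs(alpha - k_lp / k_lpt) > 1e-9 * abs(alpha))
      stop("inconsistent parameters: alpha != k_lp / k_lpt")
  }
  structure(
    list(k_lp = k_lp, k_tp = k_tp, k_lpt = k_lpt, alpha = alpha,
         beta = beta_factor(k_lp, k_tp, t_excess), t_excess = t_excess),
    class = "eq_params")
}

#' @export
print.eq_params <- function(x, ...) {
  cat("Ternary binding parameters (nM)\n")
  cat(sprintf("  K_LP  = %g\n  K_TP  = %g\n  K_LPT = %g\n", x$k_lp, x$k_tp, x$k_lpt))
  cat(sprintf("  alpha = %.4g   beta = %.4g (target excess %g x K_TP)\n",
              x$alpha, x$beta, x$t_excess))
  invisible(x)
}

#' Cooperativity of ternary-complex formation
#'
#' The ratio of binary ligase-PROTAC affinity to ternary-complex affinity,
#' \code{alpha = K_LP / K_LPT}. Values above 1 mean the target's presence
#' strengthens PROTAC-ligase engagement.
#'
#' @param k_lp Ligase-PROTAC dissociation constant (nM), > 0. Vectorised.
#' @param k_lpt Ternary dissociation constant (nM), > 0. Vectorised.
#' @return Dimensionless cooperativity, same length as the inputs.
#' @examples
#' cooperativity(60, 4.7)    # ~12.8
#' cooperativity(20.5, 1.5)  # ~13.7
#' @export
cooperativity <- function(k_lp, k_lpt) {
  if (any(!is.finite(k_lp)) || any(!is.finite(k_lpt)) ||
      any(k_lp <= 0) || any(k_lpt <= 0))
    stop("`k_lp` and `k_lpt` must be strictly positive and finite")
  k_lp / k_lpt
}

#' Binary-affinity factor entering the maximal ternary fraction
#'
#' \code{beta = (sqrt(K_LP / K_TP) + 1)^2 / excess}, where \code{excess} is
#' the assumed fold-excess of total target over \code{K_TP} that maintains
#' the binary target-PROTAC complex in a surface assay (default 25). Together
#' with cooperativity it bounds the attainable ternary-complex fraction at
#' \code{alpha / (alpha + beta)}.
#'
#' @param k_lp,k_tp Binary dissociation constants (nM), > 0. Vectorised.
#' @param excess Target excess factor, > 0. Default 25.
#' @return Dimensionless factor.
#' @examples
#' beta_factor(100, 100)  # matched affinities: 4/25 = 0.16
#' @export
beta_factor <- function(k_lp, k_tp, excess = 25) {
  if (any(!is.finite(k_lp)) || any(!is.finite(k_tp)) ||
      any(k_lp <= 0) || any(k_tp <= 0))
    stop("`k_lp` and `k_tp` must be strictly positive and finite")
  if (!is.numeric(excess) || any(excess <= 0)) stop("`excess` must be > 0")
  (sqrt(k_lp / k_tp) + 1)^2 / excess
}

#' Equilibrium surface occupancy by ternary complex
#'
#' Fraction of immobilised ligase engaged in ternary complex when titrated
#' with PROTAC in the presence of excess target:
#' \code{[LPT]/[L]_t = [P]_t / ([P]_t + K_LPT)}. Half the ligase is engaged
#' at \code{[P]_t = K_LPT}, which is how the ternary affinity is read off a
#' steady-state binding isotherm.
#'
#' @param p_total Total PROTAC concentration (nM), >= 0. Vectorised.
#' @param k_lpt Ternary dissociation constant (nM), > 0.
#' @return Occupancy fraction in \[0, 1).
#' @examples
#' spr_occupancy(20, 20)  # 0.5
#' @export
spr_occupancy <- function(p_total, k_lpt) {
  if (any(!is.finite(p_total)) || any(p_total < 0))
    stop("`p_total` must be non-negative and finite")
  if (any(!is.finite(k_lpt)) || any(k_lpt <= 0))
    stop("`k_lpt` must be strictly positive and finite")
  p_total / (p_total + k_lpt)
}

#' Maximal ternary-complex fraction
#'
#' Closed-form upper bound on the fraction of ligase drawn into ternary
#' complex over a PROTAC titration, \code{alpha / (alpha + beta)}. For
#' matched binary affinities (\code{beta} near 0.2 with the default 25-fold
#' target excess) the fraction already exceeds 0.9 at cooperativity 2.
#'
#' @param alpha Cooperativity, > 0. Vectorised.
#' @param beta Binary-affinity factor, > 0. Vectorised.
#' @return Fraction in (0, 1); increasing in \code{alpha}, decreasing in
#'   \code{beta}.
#' @examples
#' max_ternary_fraction(2, 0.2)  # ~0.909
#' @export
max_ternary_fraction <- function(alpha, beta) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("`alpha` must be strictly positive and finite")
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("`beta` must be strictly positive and finite")
  alpha / (alpha + beta)
}

#' Binary target-PROTAC complex concentration (tight-binding quadratic)
#'
#' Exact \code{[TP]} for a two-component equilibrium at totals
#' \code{p_total}, \code{t_total} and dissociation constant \code{k_tp}:
#' the smaller root of the binding quadratic,
#' \code{([P]_t + [T]_t + K_TP - sqrt((...)^2 - 4 [P]_t [T]_t)) / 2},
#' evaluated in the cancellation-free form
#' \code{2 [P]_t [T]_t / (S + sqrt(S^2 - 4 [P]_t [T]_t))} so the value stays
#' accurate when one total dwarfs the other.
#'
#' @param p_total,t_total Total concentrations (nM), >= 0. Vectorised.
#' @param k_tp Dissociation constant (nM), > 0.
#' @return \code{[TP]} in nM, bounded by \code{min(p_total, t_total)}.
#' @export
binary_complex <- function(p_total, t_total, k_tp) {
  if (any(!is.finite(p_total)) || any(p_total < 0) ||
      any(!is.finite(t_total)) || any(t_total < 0))
    stop("totals must be non-negative and finite")
  if (any(!is.finite(k_tp)) || any(k_tp <= 0))
    stop("`k_tp` must be strictly positive and finite")
  s <- p_total + t_total + k_tp
  disc <- s^2 - 4 * p_total * t_total
  # disc >= k_tp^2 > 0 analytically; guard rounding
  2 * p_total * t_total / (s + sqrt(pmax(disc, 0)))
}

# Free L and T at a given free PROTAC concentration p, from the two protein
# conservation laws with mass-action complexes LP = L p / K_LP,
# TP = T p / K_TP, LPT = alpha L T p / (K_LP K_TP). T solves a quadratic;
# the stable root form is picked by the sign of the linear coefficient.
free_proteins_at_p <- function(p, l_total, t_total, params) {
  a <- p / params$k_lp
  b <- p / params$k_tp
  g <- params$alpha * p / (params$k_lp * params$k_tp)
  if (g == 0) {
    return(list(L = l_total / (1 + a), T = t_total / (1 + b)))
  }
  A <- g * (1 + b)
  B <- (1 + a) * (1 + b) + g * (l_total - t_total)
  C0 <- t_total * (1 + a)                      # -C of the quadratic
  disc <- sqrt(B^2 + 4 * A * C0)
  Tfree <- if (B >= 0) 2 * C0 / (B + disc) else (disc - B) / (2 * A)
  Lfree <- l_total / (1 + a + g * Tfree)
  list(L = Lfree, T = Tfree)
}

#' Exact three-body binding equilibrium
#'
#' Solves the coupled mass-action equilibrium of ligase (L), PROTAC (P) and
#' target (T) with complexes LP, TP and LPT, where
#' \code{LPT = alpha L T P / (K_LP K_TP)}. The ternary polynomial has no
#' useful closed form for a cooperative system, so the solver reduces it to
#' a scalar root problem in free PROTAC: for any trial free \code{P} the two
#' protein conservation laws give free \code{L} and \code{T} in closed form
#' (a quadratic), and the remaining PROTAC-conservation residual is strictly
#' increasing in free \code{P} on \code{[0, P_t]}. Brent bracketing on that
#' interval (absolute tolerance \code{1e-12 * P_t}) yields the unique root.
#'
#' Degenerate totals short-circuit to the closed-form binary or empty
#' solutions, avoiding 0/0 in the mass-action ratios.
#'
#' @param l_total,t_total,p_total Total concentrations (nM), >= 0.
#' @param params An [eq_params()] object.
#' @return An object of class \code{species_state}: list with totals and the
#'   equilibrium concentrations \code{L, T, P, LP, TP, LPT} (nM), plus the
#'   conservation residual of the root solve.
#' @examples
#' p <- eq_params(k_lp = 100, k_tp = 100, alpha = 1)
#' solve_ternary(100, 100, 100, p)
#' @export
solve_ternary <- function(l_total, t_total, p_total, params) {
  stopifnot(inherits(params, "eq_params"))
  tot <- c(l_total, t_total, p_total)
  if (any(!is.finite(tot)) || any(tot < 0))
    stop("totals must be non-negative and finite")

  mk <- function(L, T, P, LP, TP, LPT, residual = 0) {
    structure(list(l_total = l_total, t_total = t_total, p_total = p_total,
                   L = L, T = T, P = P, LP = LP, TP = TP, LPT = LPT,
                   residual = residual),
              class = "species_state")
  }

  if (p_total == 0)
    return(mk(l_total, t_total, 0, 0, 0, 0))
  if (l_total == 0 && t_total == 0)
    return(mk(0, 0, p_total, 0, 0, 0))
  if (l_total == 0) {
    tp <- binary_complex(p_total, t_total, params$k_tp)
    return(mk(0, t_total - tp, p_total - tp, 0, tp, 0))
  }
  if (t_total == 0) {
    lp <- binary_complex(p_total, l_total, params$k_lp)
    return(mk(l_total - lp, 0, p_total - lp, lp, 0, 0))
  }

  resid <- function(p) {
    ft <- free_proteins_at_p(p, l_total, t_total, params)
    p * (1 + ft$L / params$k_lp + ft$T / params$k_tp +
           params$alpha * ft$L * ft$T / (params$k_lp * params$k_tp)) - p_total
  }
  # bracketing bisection driven to machine precision: the residual is
  # strictly increasing in free P, so [0, P_t] always brackets the root,
  # and ~60 halvings reach the floating-point floor regardless of how
  # stiff the conservation residual is
  lo <- 0; hi <- p_total
  f_root <- resid(hi)
  for (it in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (mid <= lo || mid >= hi) break
    fm <- resid(mid)
    if (fm < 0) lo <- mid else { hi <- mid; f_root <- fm }
  }
  p <- hi
  ft <- free_proteins_at_p(p, l_total, t_total, params)
  lp <- ft$L * p / params$k_lp
  tp <- ft$T * p / params$k_tp
  lpt <- params$alpha * ft$L * ft$T * p / (params$k_lp * params$k_tp)
  out <- mk(ft$L, ft$T, p, lp, tp, lpt, residual = f_root)
  # conservation check (relative 1e-8) as a convergence diagnostic
  rel <- max(abs(ft$L + lp + lpt - l_total) / max(l_total, 1e-300),
             abs(ft$T + tp + lpt - t_total) / max(t_total, 1e-300),
             abs(p + lp + tp + lpt - p_total) / p_total)
  if (!is.finite(rel) || rel > 1e-8)
    stop(sprintf("equilibrium solve did not converge (conservation residual %.3g)", rel))
  out
}

#' @export
print.species_state <- function(x, ...) {
  cat("Three-body equilibrium (nM)\n")
  cat(sprintf("  totals: L_t %g, T_t %g, P_t %g\n", x$l_total, x$t_total, x$p_total))
  cat(sprintf("  free:   L %.6g, T %.6g, P %.6g\n", x$L, x$T, x$P))
  cat(sprintf("  bound:  LP %.6g, TP %.6g, LPT %.6g\n", x$LP, x$TP, x$LPT))
  invisible(x)
}

#' Ternary-complex formation across a PROTAC titration (hook curve)
#'
#' Evaluates the exact equilibrium over a grid of total PROTAC
#' concentrations. The ternary complex rises with PROTAC, peaks, and then
#' collapses as excess PROTAC saturates both proteins in unproductive binary
#' complexes -- the hook effect.
#'
#' @param l_total,t_total Total ligase and target (nM).
#' @param p_grid Sorted positive vector of total PROTAC concentrations (nM).
#' @param params An [eq_params()] object.
#' @return A data.frame with columns \code{p_total, L, T, P, LP, TP, LPT}.
#' @examples
#' p <- eq_params(k_lp = 100, k_tp = 100, alpha = 10)
#' hc <- hook_curve(0.01, 2500, 10^seq(-2, 6, length.out = 25), p)
#' hc$p_total[which.max(hc$LPT)]
#' @export
hook_curve <- function(l_total, t_total, p_grid, params) {
  if (any(!is.finite(p_grid)) || any(p_grid <= 0) || is.unsorted(p_grid))
    stop("`p_grid` must be positive, finite and sorted increasing")
  rows <- lapply(p_grid, function(p) {
    st <- solve_ternary(l_total, t_total, p, params)
    data.frame(p_total = p, L = st$L, T = st$T, P = st$P,
               LP = st$LP, TP = st$TP, LPT = st$LPT)
  })
  do.call(rbind, rows)
}
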