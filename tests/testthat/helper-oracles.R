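# Independent oracles used to cross-check the package's numerics. These are
# deliberately naive (fixed-point iteration, bisection, quadratic scans,
# full enumeration) and share no code with the implementation under test.

# Three-body equilibrium by bisection on free PROTAC; free L and T at each
# trial p come from damped fixed-point iteration of the conservation laws.
oracle_ternary_lpt <- function(l_t, t_t, p_t, k_lp, k_tp, alpha,
                               n_bisect = 90L) {
  free_lt <- function(p) {
    L <- l_t; T <- t_t
    for (i in 1:400) {
      Ln <- l_t / (1 + p / k_lp + alpha * T * p / (k_lp * k_tp))
      Tn <- t_t / (1 + p / k_tp + alpha * Ln * p / (k_lp * k_tp))
      if (abs(Ln - L) < 1e-15 * (L + 1e-300) &&
          abs(Tn - T) < 1e-15 * (T + 1e-300)) { L <- Ln; T <- Tn; break }
      L <- Ln; T <- Tn
    }
    c(L = L, T = T)
  }
  resid <- function(p) {
    ft <- free_lt(p)
    p * (1 + ft["L"] / k_lp + ft["T"] / k_tp +
           alpha * ft["L"] * ft["T"] / (k_lp * k_tp)) - p_t
  }
  lo <- 0; hi <- p_t
  for (i in seq_len(n_bisect)) {
    mid <- (lo + hi) / 2
    if (resid(mid) < 0) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2
  ft <- free_lt(p)
  unname(alpha * ft["L"] * ft["T"] * p / (k_lp * k_tp))
}

# All-pairs quadratic clash scan.
oracle_clashes <- function(a, b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    if (sqrt(sum((a[i, ] - b[j, ])^2)) < cutoff) n <- n + 1L
  n
}

# Exact two-tailed permutation p-value by full enumeration (small n).
oracle_perm_p <- function(x, y, method = "pearson") {
  n <- length(y)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  obs <- abs(cor(x, y, method = method))
  stats <- vapply(perms(y), function(yy) abs(cor(x, yy, method = method)),
                  numeric(1L))
  mean(stats >= obs - 1e-12)
}

# Spherical-cap closed forms for overlapping equal spheres of expanded
# radius R at centre distance d (< 2R): per-sphere exposed area and the
# two-sphere buried area.
cap_exposed <- function(R, d) 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
cap_buried_pair <- function(R, d) 2 * 2 * pi * R * (R - d / 2)

# One unit in the last printed decimal place of a tabulated value.
printed_ulp <- function(x) {
  shown <- vapply(x, function(v) as.character(v), character(1L))
  dec <- ifelse(grepl("\\.", shown, fixed = FALSE),
                nchar(sub("^[^.]*\\.", "", shown)), 0L)
  10^(-dec)
}

# Interval of ratios consistent with numerator/denominator each printed at
# its own rounding precision.
rounded_ratio_interval <- function(num, den) {
  un <- printed_ulp(num) / 2; ud <- printed_ulp(den) / 2
  cbind(lo = (num - un) / (den + ud), hi = (num + un) / (den - ud))
}

# Rigid transform with a seeded random rotation + translation.
random_rigid <- function(m, seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  tr <- rnorm(3, sd = 10)
  sweep(as.matrix(m) %*% t(q), 2L, tr, `+`)
}
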