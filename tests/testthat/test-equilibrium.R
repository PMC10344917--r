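test_that("cooperativity is the binary/ternary affinity ratio", {
  expect_equal(cooperativity(60, 4.7), 60 / 4.7, tolerance = 1e-12)
  expect_equal(round(cooperativity(60, 4.7), 1), 12.8)
  expect_equal(round(cooperativity(20.5, 1.5), 1), 13.7)
  for (k in c(0.3, 7, 500)) expect_equal(cooperativity(k, k), 1)
  expect_error(cooperativity(-1, 5), "positive")
  expect_error(cooperativity(5, 0), "positive")
})

test_that("binary-affinity factor follows the matched-excess closed form", {
  k <- 42
  expect_equal(beta_factor(k, k), 4 / 25)
  expect_equal(beta_factor(9 * k, k), 16 / 25)
  expect_equal(beta_factor(100 * k, k), 121 / 25)
  # excess factor is configurable; default 25-fold target over K_TP
  expect_equal(beta_factor(k, k, excess = 10), 4 / 10)
  expect_error(beta_factor(0, 1), "positive")
})

test_that("surface occupancy is the PROTAC saturation isotherm", {
  expect_equal(spr_occupancy(20, 20), 0.5)
  expect_equal(spr_occupancy(0, 20), 0)
  expect_equal(spr_occupancy(9 * 20, 20), 0.9)
  expect_error(spr_occupancy(-1, 20), "non-negative")
})

test_that("maximal ternary fraction is alpha/(alpha+beta) with the right limits", {
  expect_equal(max_ternary_fraction(2, 0.2), 2 / 2.2, tolerance = 1e-12)
  expect_equal(max_ternary_fraction(1, 1), 0.5)
  expect_gt(max_ternary_fraction(1e6, 0.2), 1 - 1e-5)
  # monotone increasing in alpha, decreasing in beta
  a <- 10^seq(-2, 3, length.out = 40)
  expect_true(all(diff(max_ternary_fraction(a, 0.3)) > 0))
  expect_true(all(diff(max_ternary_fraction(2, a)) < 0))
  expect_error(max_ternary_fraction(0, 1), "positive")
})

test_that("binary complex equals the tight-binding quadratic root", {
  # independent evaluation of the textbook root
  root <- function(p, t, k) ((p + t + k) - sqrt((p + t + k)^2 - 4 * p * t)) / 2
  expect_equal(binary_complex(0.01, 100, 100), root(0.01, 100, 100),
               tolerance = 1e-9)
  # weak-binding limit P T/(T + K)
  expect_equal(binary_complex(0.01, 100, 100), 0.01 * 100 / 200,
               tolerance = 1e-4)
  # infinitely tight binding gives min of the totals
  expect_equal(binary_complex(3, 10, 1e-9), 3, tolerance = 1e-6)
  expect_equal(binary_complex(10, 3, 1e-9), 3, tolerance = 1e-6)
  expect_equal(binary_complex(0, 50, 10), 0)
  expect_error(binary_complex(-1, 1, 1), "non-negative")
})

test_that("eq_params derives and validates alpha, K_LPT and beta", {
  p <- eq_params(k_lp = 60, k_tp = 60, k_lpt = 4.7)
  expect_equal(p$alpha, 60 / 4.7)
  expect_equal(p$beta, beta_factor(60, 60))
  p2 <- eq_params(k_lp = 60, k_tp = 10, alpha = 5)
  expect_equal(p2$k_lpt, 12)
  expect_error(eq_params(60, 60, k_lpt = 10, alpha = 3), "inconsistent")
  expect_error(eq_params(-1, 60, alpha = 1), "positive")
  expect_error(eq_params(60, 60), "at least one")
})

test_that("exact solver handles degenerate totals in closed form", {
  p <- eq_params(k_lp = 100, k_tp = 50, alpha = 3)
  st <- solve_ternary(80, 60, 0, p)
  expect_equal(st$LPT, 0)
  expect_equal(st$L, 80)
  expect_equal(st$T, 60)
  st2 <- solve_ternary(0, 60, 10, p)
  expect_equal(st2$LPT, 0)
  expect_equal(st2$TP, binary_complex(10, 60, 50))
  st3 <- solve_ternary(80, 0, 10, p)
  expect_equal(st3$LP, binary_complex(10, 80, 100))
})

test_that("exact solver matches the bisection oracle on random systems", {
  set.seed(101)
  for (i in 1:100) {
    k_lp <- 10^runif(1, -1, 3); k_tp <- 10^runif(1, -1, 3)
    alpha <- 10^runif(1, -1, 2)
    l_t <- 10^runif(1, -1, 3); t_t <- 10^runif(1, -1, 3)
    p_t <- 10^runif(1, -1, 4)
    st <- solve_ternary(l_t, t_t, p_t, eq_params(k_lp, k_tp, alpha = alpha))
    lpt_o <- oracle_ternary_lpt(l_t, t_t, p_t, k_lp, k_tp, alpha)
    expect_equal(st$LPT, lpt_o, tolerance = 1e-8)
  }
  # named spec-style case
  st <- solve_ternary(100, 100, 100, eq_params(100, 100, alpha = 1))
  expect_equal(st$LPT, oracle_ternary_lpt(100, 100, 100, 100, 100, 1),
               tolerance = 1e-8)
})

test_that("solver output conserves mass and stays non-negative", {
  set.seed(202)
  for (i in 1:1000) {
    k_lp <- 10^runif(1, -1, 3); k_tp <- 10^runif(1, -1, 3)
    alpha <- 10^runif(1, -2, 2)
    l_t <- 10^runif(1, -2, 4); t_t <- 10^runif(1, -2, 4)
    p_t <- 10^runif(1, -2, 5)
    st <- solve_ternary(l_t, t_t, p_t, eq_params(k_lp, k_tp, alpha = alpha))
    sp <- unlist(st[c("L", "T", "P", "LP", "TP", "LPT")])
    expect_true(all(sp >= 0))
    expect_equal(st$L + st$LP + st$LPT, l_t, tolerance = 1e-8)
    expect_equal(st$T + st$TP + st$LPT, t_t, tolerance = 1e-8)
    expect_equal(st$P + st$LP + st$TP + st$LPT, p_t, tolerance = 1e-8)
  }
})

test_that("excess PROTAC collapses the ternary complex (hook effect)", {
  p <- eq_params(k_lp = 100, k_tp = 100, alpha = 1)
  grid <- 10^seq(-2, 7, length.out = 60)
  hc <- hook_curve(100, 100, grid, p)
  peak <- max(hc$LPT)
  expect_lt(solve_ternary(100, 100, 1e7, p)$LPT, 0.01 * peak)
  # unimodal: rises then falls around the single maximum
  i <- which.max(hc$LPT)
  expect_true(all(diff(hc$LPT[1:i]) >= 0))
  expect_true(all(diff(hc$LPT[i:length(grid)]) <= 0))
})

test_that("hook curve is zero without target and grows with cooperativity", {
  p <- eq_params(k_lp = 100, k_tp = 100, alpha = 2)
  grid <- 10^seq(-1, 5, length.out = 20)
  expect_true(all(hook_curve(100, 0, grid, p)$LPT == 0))
  p2 <- eq_params(k_lp = 100, k_tp = 100, alpha = 4)
  m1 <- max(hook_curve(10, 100, grid, p)$LPT)
  m2 <- max(hook_curve(10, 100, grid, p2)$LPT)
  expect_gt(m2, m1)
})

test_that("hook-curve maximum reproduces the closed-form fraction in the surface limit", {
  # immobilised-ligase limit: L_t tiny, T_t = 25 x K_TP
  set.seed(303)
  for (i in 1:12) {
    alpha <- 10^runif(1, -1, 2)
    k_tp <- 10^runif(1, 0, 2)
    k_lp <- k_tp * 10^runif(1, -1, 1)
    p <- eq_params(k_lp, k_tp, alpha = alpha)
    l_t <- 1e-4 * min(k_lp, p$k_lpt)
    grid <- 10^seq(log10(p$k_lpt) - 4, log10(max(k_lp, k_tp)) + 5,
                   length.out = 160)
    frac <- max(hook_curve(l_t, 25 * k_tp, grid, p)$LPT) / l_t
    expect_equal(frac, max_ternary_fraction(alpha, p$beta), tolerance = 0.05)
  }
})
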