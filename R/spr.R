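#' SPR sensorgram container
#'
#' Holds a resonance-unit time trace together with its injection schedule.
#' Time is per cycle (each cycle starts at 0). In multi-cycle format every
#' analyte concentration is run as its own cycle starting from a bare
#' surface; in single-cycle format injections run sequentially within one
#' cycle without regeneration, each association starting from the response
#' left by the previous phase.
#'
#' @param data data.frame with columns \code{time_s}, \code{response_ru},
#'   \code{conc_nM}, \code{cycle}, \code{phase} (\code{"assoc"} or
#'   \code{"dissoc"}).
#' @param injections data.frame with columns \code{start_s}, \code{stop_s},
#'   \code{conc_nM}, \code{cycle}; non-overlapping within a cycle.
#' @param mode \code{"multi-cycle"} or \code{"single-cycle"}.
#' @return An object of class \code{sensorgram}.
#' @export
sensorgram <- function(data, injections, mode = c("multi-cycle", "single-cycle")) {
  mode <- match.arg(mode)
  need <- c("time_s", "response_ru", "conc_nM", "cycle", "phase")
  if (!all(need %in% names(data)))
    stop("`data` must have columns: ", paste(need, collapse = ", "))
  need_i <- c("start_s", "stop_s", "conc_nM", "cycle")
  if (!all(need_i %in% names(injections)))
    stop("`injections` must have columns: ", paste(need_i, collapse = ", "))
  for (cy in unique(data$cycle)) {
    tt <- data$time_s[data$cycle == cy]
    if (is.unsorted(tt, strictly = TRUE))
      stop("time must be strictly increasing within cycle ", cy)
    inj <- injections[injections$cycle == cy, , drop = FALSE]
    inj <- inj[order(inj$start_s), , drop = FALSE]
    if (nrow(inj)) {
      if (any(inj$stop_s <= inj$start_s))
        stop("injection stop must exceed start (cycle ", cy, ")")
      if (nrow(inj) > 1L && any(inj$start_s[-1L] < inj$stop_s[-nrow(inj)]))
        stop("overlapping injections in cycle ", cy)
      if (min(inj$start_s) < min(tt) || max(inj$stop_s) > max(tt))
        stop("injections outside the recorded time range (cycle ", cy, ")")
    }
  }
  structure(list(data = data, injections = injections, mode = mode),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("SPR sensorgram (%s): %d points, %d cycle(s), %d injection(s)\n",
              x$mode, nrow(x$data), length(unique(x$data$cycle)),
              nrow(x$injections)))
  invisible(x)
}

# Closed-form 1:1 response for one cycle at the given times.
# Association toward Req = C Rmax/(C + KD) with rate kobs = kon C + koff;
# dissociation is a bare exponential in koff. The response at each segment
# boundary becomes the next segment's initial condition (no regeneration).
predict_cycle_1to1 <- function(times, inj, kon, koff, rmax) {
  kd <- koff / kon
  bounds <- sort(unique(c(min(times), inj$start_s, inj$stop_s, max(times))))
  conc_of <- function(t0) {
    hit <- inj$start_s <= t0 & t0 < inj$stop_s
    if (any(hit)) inj$conc_nM[which(hit)[1L]] else 0
  }
  resp <- numeric(length(times))
  r0 <- 0
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    sel <- times >= t0 & (times < t1 | (k == length(bounds) - 1L & times <= t1))
    cc <- conc_of(t0)
    if (cc > 0) {
      req <- cc * rmax / (cc + kd)
      kobs <- kon * cc + koff
      if (any(sel)) resp[sel] <- req + (r0 - req) * exp(-kobs * (times[sel] - t0))
      r0 <- req + (r0 - req) * exp(-kobs * (t1 - t0))
    } else {
      if (any(sel)) resp[sel] <- r0 * exp(-koff * (times[sel] - t0))
      r0 <- r0 * exp(-koff * (t1 - t0))
    }
  }
  resp
}

predict_sensorgram <- function(sg, kon, koff, rmax) {
  out <- numeric(nrow(sg$data))
  for (cy in unique(sg$data$cycle)) {
    sel <- sg$data$cycle == cy
    inj <- sg$injections[sg$injections$cycle == cy, , drop = FALSE]
    inj <- inj[order(inj$start_s), , drop = FALSE]
    out[sel] <- predict_cycle_1to1(sg$data$time_s[sel], inj, kon, koff, rmax)
  }
  out
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Generates a sensorgram from the closed-form 1:1 binding model with
#' optional Gaussian noise. In multi-cycle mode each concentration is a
#' separate cycle (association for \code{contact_s}, dissociation for
#' \code{dissoc_s}); in single-cycle mode the concentrations are injected
#' sequentially without regeneration, separated by \code{inter_s} of
#' dissociation, with a final dissociation of \code{dissoc_s}.
#'
#' @param kon Association rate constant, 1/(nM s), > 0.
#' @param koff Dissociation rate constant, 1/s, > 0.
#' @param rmax Saturating response, RU, > 0.
#' @param conc Analyte concentrations (nM), one injection each.
#' @param contact_s Association (contact) time per injection, s.
#' @param dissoc_s Final dissociation time, s.
#' @param inter_s Dissociation between sequential injections
#'   (single-cycle only), s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed Optional integer seed; a fixed seed reproduces the trace
#'   exactly. The caller's RNG state is left untouched.
#' @param mode Assay format.
#' @return A [sensorgram()] object.
#' @examples
#' sg <- simulate_sensorgram(1e-3, 5e-3, 100, conc = c(4, 20, 100),
#'                           noise_sd = 0)
#' @export
simulate_sensorgram <- function(kon, koff, rmax, conc,
                                contact_s = 60, dissoc_s = 120, inter_s = 30,
                                dt = 0.5, noise_sd = 0, seed = NULL,
                                mode = c("multi-cycle", "single-cycle")) {
  mode <- match.arg(mode)
  if (kon <= 0 || koff <= 0 || rmax <= 0)
    stop("`kon`, `koff` and `rmax` must be strictly positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (mode == "multi-cycle") {
    inj <- data.frame(start_s = 0, stop_s = contact_s, conc_nM = conc,
                      cycle = seq_along(conc))
    dat <- do.call(rbind, lapply(seq_along(conc), function(i) {
      tt <- seq(0, contact_s + dissoc_s, by = dt)
      data.frame(time_s = tt, response_ru = 0, conc_nM = conc[i], cycle = i,
                 phase = ifelse(tt <= contact_s, "assoc", "dissoc"))
    }))
  } else {
    starts <- (seq_along(conc) - 1L) * (contact_s + inter_s)
    inj <- data.frame(start_s = starts, stop_s = starts + contact_s,
                      conc_nM = conc, cycle = 1L)
    t_end <- max(inj$stop_s) + dissoc_s
    tt <- seq(0, t_end, by = dt)
    in_assoc <- vapply(tt, function(t0)
      any(inj$start_s <= t0 & t0 < inj$stop_s), logical(1L))
    cc <- vapply(tt, function(t0) {
      hit <- inj$start_s <= t0 & t0 < inj$stop_s
      if (any(hit)) inj$conc_nM[which(hit)[1L]] else 0
    }, numeric(1L))
    dat <- data.frame(time_s = tt, response_ru = 0, conc_nM = cc, cycle = 1L,
                      phase = ifelse(in_assoc, "assoc", "dissoc"))
  }
  sg <- sensorgram(dat, inj, mode)
  resp <- predict_sensorgram(sg, kon, koff, rmax)
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(resp), sd = noise_sd))
    resp <- resp + noise
  }
  sg$data$response_ru <- resp
  sg
}

#' Fit a 1:1 Langmuir interaction model to a sensorgram
#'
#' Least-squares estimation of \code{kon}, \code{koff} and \code{Rmax}
#' (log-parameterised for positivity) against the closed-form piecewise
#' binding model, honouring the sensorgram's injection schedule and mode.
#' The complex half-life is \code{t_half = ln(2)/koff} and
#' \code{KD = koff/kon}, both exact by construction from the fitted rates.
#'
#' @param sg A [sensorgram()] with at least two distinct analyte
#'   concentrations (multi-cycle) or sequential injections (single-cycle).
#' @return An object of class \code{kinetic_fit}: list with \code{ok},
#'   \code{kon} (1/(nM s)), \code{koff} (1/s), \code{kd} (nM), \code{rmax}
#'   (RU), \code{t_half} (s), \code{rmse} (RU); on failure \code{ok = FALSE}
#'   with a \code{reason}, never an error.
#' @export
fit_langmuir <- function(sg) {
  stopifnot(inherits(sg, "sensorgram"))
  fail <- function(reason) structure(
    list(ok = FALSE, reason = reason, kon = NA_real_, koff = NA_real_,
         kd = NA_real_, rmax = NA_real_, t_half = NA_real_, rmse = NA_real_),
    class = "kinetic_fit")
  concs <- unique(sg$injections$conc_nM[sg$injections$conc_nM > 0])
  if (length(concs) < 2L && nrow(sg$injections) < 2L)
    return(fail("need >= 2 analyte concentrations or sequential injections"))
  y <- sg$data$response_ru
  if (stats::sd(y) < 1e-9 * (abs(mean(y)) + 1))
    return(fail("flat trace: kinetics not identifiable"))

  # start values: koff from the log-linear tail of the final dissociation,
  # KD guess at the median tested concentration
  koff0 <- local({
    last_cy <- max(sg$data$cycle)
    last_stop <- max(sg$injections$stop_s[sg$injections$cycle == last_cy])
    d <- sg$data[sg$data$cycle == last_cy & sg$data$time_s > last_stop, ]
    d <- d[d$response_ru > max(y) * 0.01, ]
    if (nrow(d) >= 5L) {
      sl <- stats::coef(stats::lm(log(d$response_ru) ~ d$time_s))[2L]
      max(1e-5, -as.numeric(sl))
    } else 1e-2
  })
  kd0 <- stats::median(concs)
  start <- log(c(kon = koff0 / kd0, koff = koff0, rmax = max(y) * 1.2))

  res_fun <- function(par) {
    p <- exp(par)
    y - predict_sensorgram(sg, p[1L], p[2L], p[3L])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = res_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance))
    return(fail("nonlinear least squares did not converge"))
  p <- exp(fit$par)
  structure(list(ok = TRUE, reason = NULL,
                 kon = unname(p[1L]), koff = unname(p[2L]),
                 kd = unname(p[2L] / p[1L]), rmax = unname(p[3L]),
                 t_half = log(2) / unname(p[2L]),
                 rmse = sqrt(mean(res_fun(fit$par)^2))),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$ok) {
    cat("1:1 Langmuir fit FAILED:", x$reason, "\n")
  } else {
    cat(sprintf(paste0("1:1 Langmuir fit\n  kon  = %.4g 1/(nM s)\n",
                       "  koff = %.4g 1/s\n  KD   = %.4g nM\n",
                       "  Rmax = %.4g RU\n  t1/2 = %.4g s\n  RMSE = %.3g RU\n"),
                x$kon, x$koff, x$kd, x$rmax, x$t_half, x$rmse))
  }
  invisible(x)
}

#' Steady-state affinity from equilibrium responses
#'
#' Fits the binding isotherm \code{R = Rmax C / (C + K)} to equilibrium
#' responses at a series of analyte concentrations; \code{K} is the
#' concentration at half-maximal response. For ternary-complex titrations
#' (PROTAC in preformed excess-target mix) \code{K} is the ternary
#' dissociation constant.
#'
#' @param conc Analyte concentrations (nM), >= 4 points spanning the
#'   inflection.
#' @param r_eq Equilibrium responses (RU).
#' @return List with \code{ok}, \code{k} (nM), \code{rmax} (RU),
#'   \code{rmse}; on failure \code{ok = FALSE} with a \code{reason}.
#' @export
fit_steady_state <- function(conc, r_eq) {
  if (length(conc) != length(r_eq)) stop("lengths differ")
  if (length(conc) < 4L) stop("need >= 4 concentration points")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  fail <- function(reason) list(ok = FALSE, reason = reason,
                                k = NA_real_, rmax = NA_real_, rmse = NA_real_)
  if (max(abs(r_eq)) < 1e-12 || stats::sd(r_eq) < 1e-9 * (abs(mean(r_eq)) + 1))
    return(fail("no curvature: responses are flat"))
  rmax0 <- max(r_eq) * 1.2
  half <- max(r_eq) / 2
  k0 <- tryCatch(stats::approx(r_eq, conc, xout = half, ties = mean)$y,
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- stats::median(conc[conc > 0])
  df <- data.frame(conc = conc, r = r_eq)
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ rmax * conc / (conc + k), data = df,
                      start = list(rmax = rmax0, k = k0),
                      lower = c(0, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("steady-state fit did not converge"))
  cf <- stats::coef(fit)
  list(ok = TRUE, reason = NULL, k = unname(cf["k"]), rmax = unname(cf["rmax"]),
       rmse = sqrt(mean(stats::residuals(fit)^2)))
}

#' Reference-subtract a sensorgram
#'
#' Pointwise subtraction of a reference-channel trace from a raw trace
#' (single-pass reference subtraction). Both sensorgrams must share the
#' same time grid and cycle structure.
#'
#' @param raw,reference [sensorgram()] objects on identical grids.
#' @return The corrected sensorgram, with attribute
#'   \code{reference_subtracted = TRUE}.
#' @export
reference_subtract <- function(raw, reference) {
  stopifnot(inherits(raw, "sensorgram"), inherits(reference, "sensorgram"))
  if (nrow(raw$data) != nrow(reference$data) ||
      any(raw$data$time_s != reference$data$time_s) ||
      any(raw$data$cycle != reference$data$cycle))
    stop("time grids differ: cannot align raw and reference traces")
  out <- raw
  out$data$response_ru <- raw$data$response_ru - reference$data$response_ru
  attr(out, "reference_subtracted") <- TRUE
  out
}
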