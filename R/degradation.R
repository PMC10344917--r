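#' Percent-of-control normalisation
#'
#' Converts a raw assay signal to percent of control (POC):
#' \code{100 * (signal - background) / (vehicle - background)}, where
#' background is the mean signal of lysis-buffer-only wells and vehicle is
#' the mean signal of vehicle-treated wells. 100 POC means no degradation;
#' 0 POC means complete loss of target signal.
#'
#' @param signal Raw assay signal(s), vectorised.
#' @param background Background signal (same units).
#' @param vehicle Vehicle-control signal; must exceed \code{background}.
#' @return POC values.
#' @examples
#' normalize_poc(550, 50, 1050)  # 50
#' @export
normalize_poc <- function(signal, background, vehicle) {
  if (any(!is.finite(signal)) || !is.finite(background) || !is.finite(vehicle))
    stop("inputs must be finite")
  if (vehicle <= background)
    stop("vehicle signal must exceed background: cannot normalise")
  100 * (signal - background) / (vehicle - background)
}

#' Trapezoid area under a dose-response curve
#'
#' Area under the POC-versus-dose-index curve with unit spacing between
#' adjacent doses: the sum over adjacent pairs of \code{0.5 * (b1 + b2)}.
#' Because spacing is the dose index, not concentration, the value is a
#' rank-scale summary: a 10-point curve pinned at 100 POC (no degradation)
#' scores 900, and deeper or earlier degradation lowers the area. The value
#' is unchanged if the dose order is reversed.
#'
#' @param poc POC values ordered by dose (ascending or descending), >= 2
#'   finite points.
#' @return The trapezoid area (POC x index units).
#' @examples
#' auc_trapezoid(rep(100, 10))  # 900
#' @export
auc_trapezoid <- function(poc) {
  if (length(poc) < 2L) stop("need at least 2 points")
  if (any(!is.finite(poc))) stop("POC values must be finite")
  n <- length(poc)
  sum(0.5 * (poc[-1L] + poc[-n]))
}

#' Four-parameter logistic dose-response fit
#'
#' Fits the variable-slope four-parameter logistic (4PL) model on log10
#' concentration,
#' \deqn{POC = bottom + (top - bottom) / (1 + 10^{hill (x - \log_{10} EC_{50})}),}
#' and reduces it to degradation metrics: \code{dc50}, the concentration at
#' which the fitted curve crosses 50 POC (censored as greater than the top
#' tested dose when the curve never reaches 50 within the tested range);
#' \code{dmax = 100 - fitted bottom} (clamped to \[0, 100\]), with the
#' observed counterpart \code{dmax_observed = 100 - min(poc)} also reported;
#' and the trapezoid \code{auc} of the observed POC.
#'
#' Hook-effect-distorted curves can mask the top \code{mask_top} doses from
#' the 4PL fit; masked points still count toward the AUC.
#'
#' @param conc Concentrations (nM), strictly monotone, > 0; >= 5 points.
#' @param poc POC values, same length.
#' @param mask_top Number of highest doses to exclude from the 4PL fit
#'   (default 0).
#' @return An object of class \code{dose_response_fit}: list with
#'   \code{ok}, \code{dc50}, \code{dc50_censored}, \code{dc50_label},
#'   \code{dmax}, \code{dmax_observed}, \code{top}, \code{bottom},
#'   \code{hill}, \code{auc}, \code{rmse}; non-convergence yields a
#'   censored fit with diagnostics, never an error.
#' @export
fit_dose_response <- function(conc, poc, mask_top = 0L) {
  if (length(conc) != length(poc)) stop("lengths differ")
  if (length(conc) < 5L) stop("need >= 5 dose points")
  if (any(conc <= 0) || any(!is.finite(conc))) stop("concentrations must be > 0")
  if (any(!is.finite(poc))) stop("POC values must be finite")
  dconc <- diff(conc)
  if (!(all(dconc > 0) || all(dconc < 0))) stop("`conc` must be strictly monotone")

  # work in ascending dose
  ord <- order(conc)
  conc <- conc[ord]; poc <- poc[ord]
  auc <- auc_trapezoid(poc)
  top_conc <- max(conc)
  cens_label <- paste0("> ", format(top_conc, scientific = FALSE, trim = TRUE))

  keep <- seq_len(length(conc) - as.integer(mask_top))
  cf_fit <- conc[keep]; pf_fit <- poc[keep]

  censored_out <- function(reason) {
    mp <- mean(pf_fit)
    structure(list(ok = FALSE, reason = reason,
                   dc50 = NA_real_, dc50_censored = TRUE,
                   dc50_label = cens_label,
                   dmax = max(0, min(100, 100 - mp)),
                   dmax_observed = 100 - min(poc),
                   top = mp, bottom = mp, hill = NA_real_,
                   auc = auc, rmse = NA_real_),
              class = "dose_response_fit")
  }
  if (stats::sd(pf_fit) < 1e-6) return(censored_out("flat curve: no dose response"))

  x <- log10(cf_fit)
  le0 <- x[which.min(abs(pf_fit - (max(pf_fit) + min(pf_fit)) / 2))]
  df <- data.frame(x = x, poc = pf_fit)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      poc ~ bottom + (top - bottom) / (1 + 10^(hill * (x - le))),
      data = df,
      start = list(bottom = min(pf_fit), top = max(pf_fit), hill = 1, le = le0),
      lower = c(-50, 0, 0.05, min(x) - 3),
      upper = c(120, 200, 10, max(x) + 3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(censored_out("4PL fit did not converge"))
  cf <- as.list(stats::coef(fit))

  # fitted-curve crossing of 50 POC
  dc50 <- NA_real_; censored <- TRUE
  if (cf$bottom < 50 && cf$top > 50) {
    x50 <- cf$le + log10((cf$top - 50) / (50 - cf$bottom)) / cf$hill
    d <- 10^x50
    if (d <= top_conc) { dc50 <- d; censored <- FALSE }
  }
  structure(list(ok = TRUE, reason = NULL,
                 dc50 = dc50, dc50_censored = censored,
                 dc50_label = if (censored) cens_label else
                   format(dc50, digits = 4),
                 dmax = max(0, min(100, 100 - cf$bottom)),
                 dmax_observed = 100 - min(poc),
                 top = cf$top, bottom = cf$bottom, hill = cf$hill,
                 auc = auc, rmse = sqrt(mean(stats::residuals(fit)^2))),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit\n")
  cat(sprintf("  DC50 = %s nM   Dmax = %.1f%% (observed %.1f%%)\n",
              x$dc50_label, x$dmax, x$dmax_observed))
  cat(sprintf("  top/bottom = %.1f/%.1f POC   hill = %s   AUC = %.1f\n",
              x$top, x$bottom,
              if (is.na(x$hill)) "NA" else sprintf("%.2f", x$hill), x$auc))
  invisible(x)
}

#' One-phase decay fit of a degradation time course
#'
#' Fits \code{POC(t) = plateau + (start - plateau) exp(-k t)} to a
#' fixed-dose time course, then interpolates the fitted curve (closed form)
#' for the time at which it crosses 50 POC. The degradation half-life
#' \code{t_half} is that crossing time; the rate constant
#' \code{tau = 0.693 / t_half} (1/min) and the initial degradation rate
#' \code{100 * tau} (percent/min) follow. When the fitted plateau stays at
#' or above 50 POC the curve never crosses 50 and the half-life and initial
#' rate are censored with a reason.
#'
#' @param time Times (min), >= 4 points, first near 100 POC.
#' @param poc POC values, same length.
#' @return An object of class \code{time_course_fit}: list with \code{ok},
#'   \code{k} (1/min), \code{start}, \code{plateau} (POC), \code{t_half}
#'   (min), \code{tau} (1/min), \code{initial_rate} (percent/min),
#'   \code{censored}, \code{reason}, \code{rmse}.
#' @examples
#' t <- seq(0, 240, by = 20)
#' fit_time_course(t, 5 + 95 * exp(-0.02 * t))
#' @export
fit_time_course <- function(time, poc) {
  if (length(time) != length(poc)) stop("lengths differ")
  if (length(time) < 4L) stop("need >= 4 time points")
  if (any(!is.finite(time)) || any(!is.finite(poc))) stop("inputs must be finite")
  ord <- order(time)
  time <- time[ord]; poc <- poc[ord]

  k0 <- local({
    drop <- poc[1L] - poc
    pos <- drop > 0 & time > 0
    if (any(pos)) {
      span <- max(poc[1L] - min(poc), 1e-6)
      frac <- pmin(drop[pos] / (span * 1.05), 0.999)
      stats::median(-log(1 - frac) / time[pos])
    } else 0.01
  })
  df <- data.frame(t = time, poc = poc)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      poc ~ plateau + (start - plateau) * exp(-k * t), data = df,
      start = list(start = poc[1L], plateau = min(poc), k = max(k0, 1e-4)),
      lower = c(-50, -50, 1e-6), upper = c(200, 150, 10),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  fail <- function(reason) structure(
    list(ok = FALSE, reason = reason, k = NA_real_, start = NA_real_,
         plateau = NA_real_, t_half = NA_real_, tau = NA_real_,
         initial_rate = NA_real_, censored = TRUE, rmse = NA_real_),
    class = "time_course_fit")
  if (is.null(fit)) return(fail("one-phase decay fit did not converge"))
  cf <- as.list(stats::coef(fit))
  rmse <- sqrt(mean(stats::residuals(fit)^2))

  if (cf$plateau >= 50 || cf$start <= 50) {
    return(structure(
      list(ok = TRUE, reason = "fitted curve never crosses 50 POC",
           k = cf$k, start = cf$start, plateau = cf$plateau,
           t_half = NA_real_, tau = NA_real_, initial_rate = NA_real_,
           censored = TRUE, rmse = rmse),
      class = "time_course_fit"))
  }
  t_half <- log((cf$start - cf$plateau) / (50 - cf$plateau)) / cf$k
  tau <- 0.693 / t_half
  structure(list(ok = TRUE, reason = NULL,
                 k = cf$k, start = cf$start, plateau = cf$plateau,
                 t_half = t_half, tau = tau, initial_rate = 100 * tau,
                 censored = FALSE, rmse = rmse),
            class = "time_course_fit")
}

#' @export
print.time_course_fit <- function(x, ...) {
  cat("One-phase decay fit\n")
  if (x$censored) {
    cat("  t1/2 censored:", if (!is.null(x$reason)) x$reason else "fit failed", "\n")
  } else {
    cat(sprintf("  t1/2 = %.1f min   initial rate = %.2f %%/min   plateau = %.1f POC\n",
                x$t_half, x$initial_rate, x$plateau))
  }
  invisible(x)
}
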