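#' Correlation between a biophysical and a cellular parameter
#'
#' Pearson product-moment or Spearman rank correlation with explicit scale
#' handling: either variable may be log10-transformed before a Pearson
#' analysis (log scale requires positive values; it is a no-op for ranks).
#' Two-tailed significance comes from the t statistic with n - 2 degrees of
#' freedom (Pearson) or the exact/AS89 null (Spearman), via
#' \code{stats::cor.test}; a seeded Monte-Carlo permutation p-value is
#' available for small samples.
#'
#' Pairs with missing values are dropped. Zero variance in either variable
#' leaves the coefficient undefined and is an error.
#'
#' @param x,y Numeric vectors.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param x_scale,y_scale \code{"linear"} or \code{"log10"}.
#' @param p_method \code{"asymptotic"} (default) or \code{"permutation"}.
#' @param n_perm Number of permutations when \code{p_method =
#'   "permutation"}.
#' @param seed Seed for the permutation draw.
#' @return An object of class \code{sar_cor}: list with
#'   \code{coefficient}, \code{p_value}, \code{n}, \code{method},
#'   \code{x_scale}, \code{y_scale}.
#' @examples
#' sar_cor(c(6, 10, 26.5, 39, 49, 1.5),
#'         c(1.38, 0.76, 0.46, 0.21, 0.08, 1.95))  # r ~ -0.90
#' @export
sar_cor <- function(x, y, method = c("pearson", "spearman"),
                    x_scale = c("linear", "log10"),
                    y_scale = c("linear", "log10"),
                    p_method = c("asymptotic", "permutation"),
                    n_perm = 1e4L, seed = NULL) {
  method <- match.arg(method)
  x_scale <- match.arg(x_scale)
  y_scale <- match.arg(y_scale)
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  if (method == "pearson") {
    if (x_scale == "log10") {
      if (any(x <= 0)) stop("log10 scale requires positive x values")
      x <- log10(x)
    }
    if (y_scale == "log10") {
      if (any(y <= 0)) stop("log10 scale requires positive y values")
      y <- log10(y)
    }
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")

  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = (method == "spearman" && n <= 10)))
  coef <- unname(ct$estimate)
  p <- ct$p.value
  if (p_method == "permutation") {
    stat <- function(yy) suppressWarnings(stats::cor(x, yy, method = method))
    obs <- abs(stat(y))
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm),
                 function(i) abs(stat(sample(y))) >= obs - 1e-12,
                 logical(1L)))
    })
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(coefficient = coef, p_value = p, n = n, method = method,
                 x_scale = x_scale, y_scale = y_scale),
            class = "sar_cor")
}

#' @export
print.sar_cor <- function(x, ...) {
  sym <- if (x$method == "pearson") "r" else "rho"
  cat(sprintf("%s = %.2f (n = %d, two-tailed p = %.3g) [x: %s, y: %s]\n",
              sym, x$coefficient, x$n, x$p_value, x$x_scale, x$y_scale))
  invisible(x)
}

#' Default correlation panel configuration
#'
#' The pairs of compound-level parameters correlated in the packaged SAR
#' analysis, with the scale convention per pair. Affinity and cooperativity
#' axes are displayed log-scaled in degradation SAR work, but the scale on
#' which a printed coefficient is reproducible differs by panel; the
#' configuration records one choice per pair and can be edited.
#'
#' @return data.frame with columns \code{x}, \code{y}, \code{x_scale},
#'   \code{y_scale}, \code{method}.
#' @export
default_sar_pairs <- function() {
  data.frame(
    x = c("k_lpt", "k_lpt", "alpha", "k_lpt", "t_half_spr"),
    y = c("auc", "dc50", "initial_rate", "initial_rate", "initial_rate"),
    x_scale = c("linear", "log10", "log10", "linear", "log10"),
    y_scale = c("linear", "log10", "linear", "linear", "linear"),
    method = "pearson",
    stringsAsFactors = FALSE)
}

#' Correlation table over a compound record set
#'
#' Computes the configured correlations per target domain from a
#' compound-level table of biophysical and cellular parameters. Censored
#' DC50 values (reported only as greater than the top tested dose) are
#' excluded by default; \code{include_censored = TRUE} substitutes the
#' censoring bound instead, for sensitivity analysis. Pairs with fewer
#' than 3 usable records are skipped with a logged reason.
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{target_domain}, and the parameter columns named in
#'   \code{pairs} (e.g. \code{k_lp}, \code{k_lpt}, \code{alpha},
#'   \code{auc}, \code{dc50}, \code{dc50_censored}, \code{initial_rate},
#'   optionally \code{t_half_spr}). See [compound_table()].
#' @param pairs Pair configuration as from [default_sar_pairs()].
#' @param include_censored Include censored DC50 at the censoring bound.
#' @return data.frame with one row per (domain, pair): columns
#'   \code{target_domain}, \code{x}, \code{y}, \code{x_scale},
#'   \code{y_scale}, \code{method}, \code{coefficient}, \code{p_value},
#'   \code{n}, \code{note}.
#' @export
build_sar_table <- function(records, pairs = default_sar_pairs(),
                            include_censored = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- pairs[0, , drop = FALSE]
    out$target_domain <- character(0)
    out$coefficient <- numeric(0); out$p_value <- numeric(0)
    out$n <- integer(0); out$note <- character(0)
    return(out)
  }
  rows <- list()
  for (dom in unique(records$target_domain)) {
    rec <- records[records$target_domain == dom, , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      pr <- pairs[i, ]
      note <- ""
      row <- data.frame(target_domain = dom, pr,
                        coefficient = NA_real_, p_value = NA_real_,
                        n = NA_integer_, note = "",
                        stringsAsFactors = FALSE)
      if (!all(c(pr$x, pr$y) %in% names(rec))) {
        row$note <- "skipped: column missing"
        rows[[length(rows) + 1L]] <- row
        next
      }
      xv <- rec[[pr$x]]; yv <- rec[[pr$y]]
      drop_cens <- function(v, col) {
        cc <- paste0(col, "_censored")
        if (!include_censored && cc %in% names(rec))
          v[which(rec[[cc]])] <- NA_real_
        v
      }
      xv <- drop_cens(xv, pr$x); yv <- drop_cens(yv, pr$y)
      usable <- sum(is.finite(xv) & is.finite(yv))
      if (usable < 3L) {
        row$note <- sprintf("skipped: %d usable records (< 3)", usable)
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- sar_cor(xv, yv, method = pr$method,
                     x_scale = pr$x_scale, y_scale = pr$y_scale)
      row$coefficient <- res$coefficient
      row$p_value <- res$p_value
      row$n <- res$n
      row$note <- note
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged compound tables (binding and degradation parameters)
#'
#' Loads the packaged fixture tables of per-compound binding affinities
#' (K_LP, K_LPT), cooperativity, dose-response metrics (DC50, Dmax, AUC)
#' and initial degradation rates for the SMARCA2 bromodomain series (11
#' VHL PROTACs) and the BRD4 series measured against each bromodomain
#' (BD1 and BD2, 6 PROTACs each). Values were transcribed once and are
#' verified against a checksum manifest at load time; a mismatch is an
#' integrity error. DC50 entries censored at the top tested dose carry
#' \code{dc50_censored = TRUE} with \code{dc50} at the bound (10000 nM);
#' the SMARCA2 compound 3 row has no measurable degradation AUC/rate and
#' its ternary affinity is an approximate estimate (~500 nM).
#'
#' @param target \code{"smarca2"}, \code{"brd4_bd1"}, \code{"brd4_bd2"} or
#'   \code{"all"}.
#' @return data.frame with columns \code{compound_id},
#'   \code{target_domain}, \code{k_lp}, \code{k_lp_sem}, \code{k_lpt},
#'   \code{k_lpt_sem}, \code{alpha}, \code{auc}, \code{initial_rate},
#'   \code{dc50}, \code{dc50_censored}, \code{dmax}.
#' @export
compound_table <- function(target = c("all", "smarca2", "brd4_bd1", "brd4_bd2")) {
  target <- match.arg(target)
  files <- c(smarca2 = "table_smarca2.csv",
             brd4_bd1 = "table_brd4_bd1.csv",
             brd4_bd2 = "table_brd4_bd2.csv")
  if (target != "all") files <- files[target]
  dir <- system.file("extdata", package = "ternarySAR")
  manifest <- utils::read.csv(file.path(dir, "MANIFEST.csv"),
                              stringsAsFactors = FALSE)
  out <- lapply(unname(files), function(f) {
    path <- file.path(dir, f)
    want <- manifest$md5[manifest$file == f]
    have <- unname(tools::md5sum(path))
    if (length(want) != 1L || !identical(have, want))
      stop("fixture integrity error: checksum mismatch for ", f)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$dc50_censored <- as.logical(df$dc50_censored)
    df
  })
  do.call(rbind, out)
}
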