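# Augmented Dickey-Fuller screening of per-taxon series.
#
# No unit-root test ships with the package's dependencies, so the
# Dickey-Fuller regression, AIC lag selection and MacKinnon (1994)
# approximate asymptotic p-values are implemented here directly.

# MacKinnon (1994) response-surface polynomials for the univariate tau
# distribution; p = pnorm(polynomial(tau)).
MACKINNON <- list(
  constant = list(
    star = -1.61, min = -18.83, max = 2.74,
    smallp = c(2.1659, 1.4412, 0.038269),
    largep = c(1.7339, 0.93202, -0.12745, -0.010368)),
  constant_trend = list(
    star = -2.89, min = -16.18, max = 0.7,
    smallp = c(3.2512, 1.6047, 0.049588),
    largep = c(2.5261, 0.61654, -0.37956, -0.060285)))

mackinnon_p <- function(stat, regression) {
  tab <- MACKINNON[[regression]]
  if (stat > tab$max) return(1)
  if (stat < tab$min) return(0)
  coefs <- if (stat <= tab$star) tab$smallp else tab$largep
  stats::pnorm(sum(coefs * stat^(seq_along(coefs) - 1)))
}

# design matrix and t-statistic of the level coefficient for one lag order
adf_fit <- function(y, p, regression, n_used = NULL) {
  dy <- diff(y)
  n <- length(dy)
  if (is.null(n_used)) n_used <- n - p
  idx <- (n - n_used + 1):n            # last n_used differences
  X <- cbind(level = y[idx])           # y_{t-1}
  if (p > 0)
    for (i in seq_len(p))
      X <- cbind(X, dy[idx - i])
  X <- cbind(X, const = 1)
  if (regression == "constant_trend") X <- cbind(X, trend = seq_len(n_used))
  yy <- dy[idx]
  fit <- stats::lm.fit(X, yy)
  rss <- sum(fit$residuals^2)
  k <- ncol(X)
  df <- n_used - k
  if (df < 1 || !is.finite(rss) || rss <= 0 || any(is.na(fit$coefficients)))
    return(NULL)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(XtX_inv)) return(NULL)
  se <- sqrt(rss / df * XtX_inv[1, 1])
  list(tstat = fit$coefficients[1] / se,
       aic = n_used * log(rss / n_used) + 2 * k,
       rss = rss, n_used = n_used, k = k)
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Fits the Dickey-Fuller regression of the differenced series on its lagged
#' level, lagged differences, and deterministic terms, and tests the lagged
#' level coefficient against the unit-root null. More negative statistics
#' reject the null (non-stationarity) more strongly. P-values use the
#' MacKinnon (1994) asymptotic approximation.
#'
#' @param series numeric vector, length >= 10 after lagging, not constant.
#' @param max_lag maximum augmentation lag for AIC selection; `NULL` uses
#'   `trunc((n - 1)^(1/3))`. Candidates 0..max_lag are compared by AIC on a
#'   common sample, then the chosen order is refit on the full sample.
#' @param regression deterministic terms: `"constant"` (default) or
#'   `"constant_trend"`.
#' @param alpha significance level for the stationarity call.
#' @return a list of class `adf_result`: `statistic`, `p_value`, `n_lags`,
#'   `n_used`, `stationary` (`p_value < alpha`), `regression`, `alpha`.
#' @export
adf_test <- function(series, max_lag = NULL,
                     regression = c("constant", "constant_trend"),
                     alpha = 0.05) {
  regression <- match.arg(regression)
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  n <- length(series)
  if (stats::var(series) == 0)
    stop("constant series: unit-root test undefined (untestable, not ",
         "stationary)", call. = FALSE)
  if (is.null(max_lag)) max_lag <- trunc((n - 1)^(1/3))
  max_lag <- as.integer(max_lag)
  if (n - 1 - max_lag < 10)
    stop("series too short: need >= 10 usable observations after lagging",
         call. = FALSE)
  # AIC over 0..max_lag on the common (shortest) sample
  common <- n - 1 - max_lag
  fits <- lapply(0:max_lag, adf_fit, y = series, regression = regression,
                 n_used = common)
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
  if (all(!is.finite(aics)))
    stop("degenerate series: Dickey-Fuller regression is singular",
         call. = FALSE)
  p <- which.min(aics) - 1L
  fit <- adf_fit(series, p, regression)     # refit on full sample
  stat <- unname(fit$tstat)
  pval <- mackinnon_p(stat, regression)
  structure(list(statistic = stat, p_value = pval, n_lags = p,
                 n_used = fit$n_used, stationary = pval < alpha,
                 regression = regression, alpha = alpha),
            class = "adf_result")
}

#' @export
print.adf_result <- function(x, ...) {
  cat(sprintf(paste0("Augmented Dickey-Fuller test (%s)\n",
                     "  tau = %.4f, lags = %d, n = %d, p-value = %.4g\n",
                     "  call at alpha = %g: %s\n"),
              x$regression, x$statistic, x$n_lags, x$n_used, x$p_value,
              x$alpha,
              if (x$stationary) "stationary (unit root rejected)"
              else "non-stationary (unit root not rejected)"))
  invisible(x)
}

#' Stationarity screen across all taxa
#'
#' Applies [adf_test()] to every taxon surviving the rare-taxa filter.
#' Raw p-values drive the stationary/non-stationary call (one decision per
#' taxon); a Benjamini-Hochberg adjusted column is emitted alongside for
#' cautious interpretation. Untestable taxa (constant or too short) are
#' recorded with `NA` statistics rather than dropped.
#'
#' @param dataset an `mbtime_dataset`.
#' @param alpha significance level for calls (default 0.05).
#' @param rare_cutoff prevalence cutoff applied first via
#'   [filter_rare_taxa()] (default 0: keep all).
#' @param max_lag,regression passed to [adf_test()].
#' @param transform `"none"` tests the abundances as given; `"log10"`
#'   tests `log10(x + pseudocount)` via [log_scale()], recommended for
#'   heavy-tailed abundance data (the Dickey-Fuller regression is linear
#'   and the test is invariant to affine, not multiplicative, changes).
#' @return a `data.frame` with columns `taxon`, `statistic`, `p_value`,
#'   `adjusted_p`, `n_lags`, `stationary`, `note`.
#' @export
stationarity_report <- function(dataset, alpha = 0.05, rare_cutoff = 0,
                                max_lag = NULL,
                                regression = c("constant",
                                               "constant_trend"),
                                transform = c("none", "log10")) {
  regression <- match.arg(regression)
  transform <- match.arg(transform)
  stopifnot_dataset(dataset)
  dataset <- filter_rare_taxa(dataset, rare_cutoff)
  A <- if (transform == "log10") log_scale(dataset) else dataset$abundance
  k <- nrow(A)
  out <- data.frame(taxon = dataset$taxa,
                    statistic = rep(NA_real_, k),
                    p_value = rep(NA_real_, k),
                    adjusted_p = rep(NA_real_, k),
                    n_lags = rep(NA_integer_, k),
                    stationary = rep(NA, k), note = rep("", k),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (k == 0) return(out)
  for (i in seq_len(k)) {
    res <- tryCatch(
      adf_test(A[i, ], max_lag = max_lag,
               regression = regression, alpha = alpha),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note[i] <- res
    } else {
      out$statistic[i] <- res$statistic
      out$p_value[i] <- res$p_value
      out$n_lags[i] <- res$n_lags
      out$stationary[i] <- res$stationary
    }
  }
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "alpha") <- alpha
  attr(out, "normalization") <- dataset$normalization
  out
}
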