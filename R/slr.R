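## Segmental linear regression with AICc model selection.
##
## The two-segment model is continuous at the breakpoint x0:
##   y = a + b1 * x                      for x <= x0
##   y = a + b1 * x0 + b2 * (x - x0)     for x >  x0
## For fixed x0 this is ordinary least squares on [1, x, (x - x0)+]; the
## breakpoint is profiled out by a quantile grid search refined by
## golden-section minimization of the RSS.

.slr_rss <- function(x, y, x0) {
  X <- cbind(1, x, pmax(x - x0, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

.aicc_ls <- function(n, rss, k) {
  # least-squares AICc; k counts all estimated parameters incl. sigma
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a continuous two-segment (segmental) linear regression
#'
#' Fits both a broken-stick model and a single straight line to (x, y) and
#' selects between them by the small-sample corrected Akaike criterion,
#' AICc = n ln(RSS/n) + 2K + 2K(K+1)/(n-K-1), with K = 5 parameters for the
#' segmental model (intercept, two slopes, breakpoint, residual sd) and
#' K = 3 for the line. The breakpoint is located by conditional least
#' squares over a 101-point grid of x-quantiles between 5% and 95%,
#' then refined by golden-section search between the neighbouring grid
#' points. Candidate breakpoints must leave at least 3 distinct x values on
#' each side.
#'
#' @param x predictor (e.g. log10 pre-capture CPM).
#' @param y response (e.g. log2 enrichment factor).
#' @param grid_span quantile span searched for the breakpoint.
#' @param n_grid number of grid candidates.
#' @param min_side minimum distinct x values required on each side of a
#'   candidate breakpoint.
#' @return object of class `slr_fit`: breakpoint, intercept, slope_left,
#'   slope_right, rss, rss_linear, aicc_slr, aicc_linear, selected_model
#'   (`"segmental"` or `"linear"`), n.
#' @export
fit_segmental_linear <- function(x, y, grid_span = c(0.05, 0.95),
                                 n_grid = 101, min_side = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 8) stop("segmental fit requires at least 8 points")
  ux <- sort(unique(x))
  if (length(ux) < 2) stop("degenerate predictor: all x values equal")
  # numerical-zero floor: residual sums below it are indistinguishable from
  # a perfect fit, so exact fits tie on RSS and parsimony decides
  rss_floor <- max(1e-300, 1e-20 * n * mean(y^2))
  # linear model
  lin <- stats::lm.fit(cbind(1, x), y)
  rss_lin <- sum(lin$residuals^2)
  aicc_lin <- .aicc_ls(n, max(rss_lin, rss_floor), 3)
  # candidate breakpoints on the quantile grid
  cand <- unique(stats::quantile(x, probs = seq(grid_span[1], grid_span[2],
                                                length.out = n_grid),
                                 names = FALSE, type = 7))
  feasible <- vapply(cand, function(b) {
    sum(ux <= b) >= min_side && sum(ux > b) >= min_side
  }, logical(1))
  cand <- cand[feasible]
  if (!length(cand)) {
    stop("no feasible breakpoint: fewer than ", min_side,
         " distinct x values on one side throughout the grid")
  }
  rss_grid <- vapply(cand, function(b) .slr_rss(x, y, b), numeric(1))
  i <- which.min(rss_grid)
  lo <- if (i > 1) cand[i - 1] else cand[i]
  hi <- if (i < length(cand)) cand[i + 1] else cand[i]
  if (hi > lo) {
    opt <- stats::optimize(function(b) .slr_rss(x, y, b),
                           interval = c(lo, hi))
    x0 <- opt$minimum
    rss_seg <- opt$objective
    if (rss_grid[i] < rss_seg) {  # guard: grid point can beat the refine
      x0 <- cand[i]
      rss_seg <- rss_grid[i]
    }
  } else {
    x0 <- cand[i]
    rss_seg <- rss_grid[i]
  }
  coefs <- stats::lm.fit(cbind(1, x, pmax(x - x0, 0)), y)$coefficients
  aicc_seg <- .aicc_ls(n, max(rss_seg, rss_floor), 5)
  structure(
    list(
      breakpoint = unname(x0),
      intercept = unname(coefs[1]),
      slope_left = unname(coefs[2]),
      slope_right = unname(coefs[2] + coefs[3]),
      rss = rss_seg,
      rss_linear = rss_lin,
      aicc_slr = aicc_seg,
      aicc_linear = aicc_lin,
      selected_model = if (aicc_seg < aicc_lin) "segmental" else "linear",
      n = n
    ),
    class = "slr_fit"
  )
}

#' @export
print.slr_fit <- function(x, ...) {
  cat("slr_fit (n = ", x$n, "): selected ", x$selected_model,
      "; breakpoint = ", signif(x$breakpoint, 4),
      ", slopes ", signif(x$slope_left, 4), " / ",
      signif(x$slope_right, 4),
      "; AICc segmental ", signif(x$aicc_slr, 6),
      " vs linear ", signif(x$aicc_linear, 6), "\n", sep = "")
  invisible(x)
}

#' Predict from a segmental fit
#' @param object `slr_fit`.
#' @param newdata numeric x values.
#' @param ... unused.
#' @return fitted y values.
#' @export
predict.slr_fit <- function(object, newdata, ...) {
  object$intercept + object$slope_left * pmin(newdata, object$breakpoint) +
    object$slope_right * pmax(newdata - object$breakpoint, 0)
}

#' Expression cut-off below which enrichment estimates are unstable
#'
#' Fits the segmental model to per-gene log2 enrichment versus log10
#' pre-capture mean CPM (genes detected pre-capture only). When the
#' segmental model is selected by AICc the breakpoint, back-transformed to
#' CPM, is the expression cut-off; when the straight line wins no cut-off
#' exists and `NA` is returned.
#'
#' @param enrichment data.frame from [gene_enrichment()].
#' @return list: `threshold_cpm` (10^breakpoint or `NA`), `fit` (`slr_fit`).
#' @export
expression_threshold <- function(enrichment) {
  keep <- enrichment$pre_mean > 0 & is.finite(enrichment$ef_log)
  x <- log10(enrichment$pre_mean[keep])
  y <- enrichment$ef_log[keep]
  fit <- fit_segmental_linear(x, y)
  list(
    threshold_cpm = if (fit$selected_model == "segmental")
      10^fit$breakpoint else NA_real_,
    fit = fit
  )
}
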