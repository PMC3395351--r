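#' Table of paired replicate measurements
#'
#' Holds one quantity measured twice per subject (a second segmentation of the
#' same acquisition, or a second rater), as used for test-retest and
#' inter-rater reproducibility.
#'
#' @param m1,m2 Numeric vectors of equal length (>= 3), all finite.
#' @param id Optional subject identifiers.
#' @return A `replicate_table` (data.frame with columns `id`, `m1`, `m2`).
#' @export
replicate_table <- function(m1, m2, id = NULL) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  if (length(m1) != length(m2))
    stop("m1 and m2 must have equal length", call. = FALSE)
  if (length(m1) < 3L)
    stop("at least 3 subjects are required", call. = FALSE)
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("all measurements must be finite", call. = FALSE)
  if (is.null(id)) id <- seq_along(m1)
  structure(data.frame(id = id, m1 = m1, m2 = m2),
            class = c("replicate_table", "data.frame"))
}

as_replicate_table <- function(x) {
  if (inherits(x, "replicate_table")) return(x)
  if (is.data.frame(x) && all(c("m1", "m2") %in% names(x)))
    return(replicate_table(x$m1, x$m2, x$id))
  stop("expected a replicate_table or a data.frame with columns m1, m2",
       call. = FALSE)
}

#' Paired coefficient of variation (percent)
#'
#' Test-retest variability of paired measurements, expressed relative to the
#' grand mean:
#'
#' `CV = 100 * mean(|m1 - m2|) / (sqrt(2) * grand mean)`
#'
#' where the grand mean is taken over all `2n` values. The `sqrt(2)` converts
#' the mean absolute difference of two replicates to the scale of a
#' single-measurement standard deviation.
#'
#' @param table A [replicate_table()] (grand mean must be > 0).
#' @return CV in percent.
#' @examples
#' paired_cv(replicate_table(c(10, 12, 14), c(11, 11, 15)))
#' @export
paired_cv <- function(table) {
  tab <- as_replicate_table(table)
  gm <- mean(c(tab$m1, tab$m2))
  if (gm <= 0)
    stop("paired CV undefined: grand mean must be > 0", call. = FALSE)
  100 * mean(abs(tab$m1 - tab$m2)) / (sqrt(2) * gm)
}

#' Paired CV from summary statistics
#'
#' Same formula as [paired_cv()], evaluated from a printed grand mean and mean
#' absolute difference (as tabulated in published reproducibility tables).
#'
#' @param mean_value Grand mean of the measurements (> 0).
#' @param mean_abs_diff Mean absolute difference between the replicates.
#' @return CV in percent.
#' @export
paired_cv_from_summary <- function(mean_value, mean_abs_diff) {
  if (!is.numeric(mean_value) || any(mean_value <= 0))
    stop("mean_value must be > 0", call. = FALSE)
  100 * mean_abs_diff / (sqrt(2) * mean_value)
}

#' Intraclass correlation coefficient for paired replicates
#'
#' Single-measure ICC from the two-way ANOVA decomposition of an n-subject by
#' k-rater table (here k = 2), with a 95% F-based confidence interval:
#'
#' * `two_way_random_absolute` — absolute agreement, ICC(2,1):
#'   `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' * `two_way_mixed_consistency` — consistency, ICC(3,1):
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`
#'
#' `MSR`, `MSC`, `MSE` are the between-subject, between-rater and residual
#' mean squares. Confidence limits follow the F-distribution constructions of
#' McGraw & Wong (ICC(2,1) via the Satterthwaite degrees of freedom).
#' ANOVA-based ICCs can be negative (observed for poorly reproducible
#' quantities); degenerate tables with zero between-subject variance are
#' flagged as undefined.
#'
#' @param table A [replicate_table()] with n >= 3 subjects.
#' @param model `"two_way_random_absolute"` (default) or
#'   `"two_way_mixed_consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci` (length-2 vector), `model`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @examples
#' tab <- replicate_table(c(10, 12, 14, 16), c(11, 13, 15, 17))
#' icc(tab, "two_way_mixed_consistency")$icc   # exactly 1
#' icc(tab, "two_way_random_absolute")$icc     # ~0.9302
#' @export
icc <- function(table, model = c("two_way_random_absolute",
                                 "two_way_mixed_consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  tab <- as_replicate_table(table)
  n <- nrow(tab); k <- 2
  y <- cbind(tab$m1, tab$m2)
  grand <- mean(y)
  row_means <- rowMeans(y)
  col_means <- colMeans(y)

  ssr <- k * sum((row_means - grand)^2)           # between subjects
  ssc <- n * sum((col_means - grand)^2)           # between raters
  sse <- sum((y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    warning("zero between-subject variance: ICC undefined", call. = FALSE)
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), model = model,
                msr = msr, msc = msc, mse = mse))
  }

  alpha <- 1 - conf_level
  if (model == "two_way_mixed_consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      ci <- c(est, est)  # perfect fit: interval collapses
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Satterthwaite df for the MSC/MSE mixture under absolute agreement
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    denom <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    if (!is.finite(denom) || denom <= 0) {
      ci <- c(est, est)
    } else {
      v <- (a * msc + b * mse)^2 / denom
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(lower, upper)
    }
  }
  list(icc = est, ci = pmin(pmax(ci, -1), 1), model = model,
       msr = msr, msc = msc, mse = mse)
}

#' One-sample t-test of the absolute differences
#'
#' Tests whether the mean absolute difference between the two replicate
#' measurements differs from zero (one-sample t on `|m1 - m2|`, n-1 df).
#' With absolute differences bounded away from zero this is essentially
#' always significant; it quantifies the magnitude of disagreement rather
#' than bias.
#'
#' @param table A [replicate_table()].
#' @return List with `t`, `df`, `p_value`, `mean_abs_diff`, `sd_abs_diff`.
#' @export
abs_diff_ttest <- function(table) {
  tab <- as_replicate_table(table)
  d <- abs(tab$m1 - tab$m2)
  if (stats::sd(d) == 0)
    stop("absolute differences have zero variance: t-test degenerate",
         call. = FALSE)
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_abs_diff = mean(d), sd_abs_diff = stats::sd(d))
}

#' Pearson or Spearman correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), nonzero variance.
#' @param method `"pearson"` or `"spearman"`. Spearman p-values are exact
#'   (permutation-free AS 89) for n <= 10 and t-approximated above.
#' @return List with `r`, `p_value`, `method`, `n`.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  ct <- if (method == "spearman")
    stats::cor.test(x, y, method = "spearman", exact = length(x) <= 10)
  else stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, method = method,
       n = length(x))
}

#' Ordinary least-squares fit with per-predictor coefficients and R^2
#'
#' Thin wrapper around [stats::lm()] returning the regression summary in the
#' form used for reporting: per-predictor coefficient `B`, classical standard
#' error `se`, p-value, and the total model fit `R^2`.
#'
#' @param y Numeric response.
#' @param predictors data.frame (or named list) of numeric predictor columns.
#' @return List with `coefficients` (data.frame: term, B, se, p_value),
#'   `r_squared` and the underlying `lm` fit.
#' @export
ols_fit <- function(y, predictors) {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) > 0 && length(y) != nrow(predictors))
    stop("y and predictors must have matching length", call. = FALSE)
  dat <- if (ncol(predictors) == 0) data.frame(.y = y)
         else cbind(data.frame(.y = y), predictors)
  fit <- if (ncol(predictors) == 0) stats::lm(.y ~ 1, data = dat)
         else stats::lm(.y ~ ., data = dat)
  if (fit$rank < length(stats::coef(fit)))
    stop("rank-deficient design: drop collinear predictors", call. = FALSE)
  # a numerically perfect fit triggers a harmless precision note in summary()
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  list(coefficients = data.frame(term = rownames(co), B = co[, 1],
                                 se = co[, 2], p_value = co[, 4],
                                 row.names = NULL),
       r_squared = sm$r.squared, fit = fit)
}

#' Forward-stepwise predictor selection by p-value
#'
#' Classical stepwise multivariable regression: at each step the candidate
#' whose addition has the smallest partial p-value enters if p < `p_enter`;
#' after each entry, included predictors with p > `p_remove` are dropped
#' (worst first). Iterates until stable. May select the empty model.
#'
#' @param y Numeric response.
#' @param candidates data.frame of named candidate predictor columns.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10).
#' @return List with `selected` (character vector of chosen predictors) and
#'   `model` (the [ols_fit()] of the final model).
#' @export
stepwise_select <- function(y, candidates, p_enter = 0.05, p_remove = 0.10) {
  candidates <- as.data.frame(candidates)
  stopifnot(p_enter > 0, p_remove >= p_enter)
  included <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # guard against entry/removal cycling
    changed <- FALSE
    # forward step: best candidate not yet included (skip once the fit is
    # already numerically perfect — partial p-values are then meaningless)
    pool <- setdiff(names(candidates), included)
    if (length(included) > 0 &&
        ols_fit(y, candidates[, included, drop = FALSE])$r_squared >
          1 - 1e-12)
      pool <- character(0)
    if (length(pool) > 0) {
      pvals <- vapply(pool, function(nm) {
        f <- ols_fit(y, candidates[, c(included, nm), drop = FALSE])
        co <- f$coefficients
        co$p_value[co$term == nm]
      }, numeric(1))
      best <- names(which.min(pvals))
      if (pvals[best] < p_enter) {
        included <- c(included, best)
        changed <- TRUE
      }
    }
    # backward step: drop worst included predictor above p_remove
    repeat {
      if (length(included) == 0) break
      f <- ols_fit(y, candidates[, included, drop = FALSE])
      co <- f$coefficients[f$coefficients$term != "(Intercept)", ]
      worst <- co$term[which.max(co$p_value)]
      if (max(co$p_value) > p_remove) {
        included <- setdiff(included, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  list(selected = included,
       model = ols_fit(y, candidates[, included, drop = FALSE]))
}

#' Full agreement summary for one quantity
#'
#' Combines the reproducibility statistics reported per quantity: grand mean,
#' mean and SD of the absolute differences, paired CV, ICC with 95% CI, and
#' the one-sample t-test p-value of the absolute differences.
#'
#' @param table A [replicate_table()].
#' @param icc_model ICC variant, see [icc()].
#' @return An object of class `agreement_result`.
#' @export
agreement_summary <- function(table, icc_model = "two_way_random_absolute") {
  tab <- as_replicate_table(table)
  d <- abs(tab$m1 - tab$m2)
  ic <- tryCatch(icc(tab, icc_model),
                 warning = function(w) list(icc = NA_real_,
                                            ci = c(NA_real_, NA_real_)))
  tp <- tryCatch(abs_diff_ttest(tab)$p_value, error = function(e) NA_real_)
  cv <- tryCatch(paired_cv(tab), error = function(e) NA_real_)
  structure(list(mean = mean(c(tab$m1, tab$m2)), mean_abs_diff = mean(d),
                 sd_abs_diff = stats::sd(d), cv_percent = cv,
                 icc = ic$icc, icc_ci95 = ic$ci, t_p_value = tp,
                 n = nrow(tab)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (n = %d): mean %.3g, |diff| %.3g +/- %.3g, CV %.1f%%, ICC %.2f (%.2f-%.2f), t-test p %.3g\n",
              x$n, x$mean, x$mean_abs_diff, x$sd_abs_diff, x$cv_percent,
              x$icc, x$icc_ci95[1], x$icc_ci95[2], x$t_p_value))
  invisible(x)
}
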