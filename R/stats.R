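# Data-masked column access that also accepts a character column name, so
# the same verbs work programmatically (e.g. over pairs of columns).
resolve_col <- function(q, data) {
  v <- eval_tidy(q, data)
  if (is.character(v) && length(v) == 1L && v %in% names(data)) {
    data[[v]]
  } else {
    v
  }
}

#' Bland-Altman agreement between two measurement methods
#'
#' Computes the mean paired difference `x - y`, its sample standard
#' deviation, and the limits of agreement (mean +/- `loa_multiplier` * SD,
#' conventionally 1.96 for 95% limits), together with a one-sample t-test
#' of zero mean difference (the conventional reading of a "Bland-Altman
#' test" with a p-value).
#'
#' @param data A data frame with one row per subject.
#' @param x,y Unquoted column names of the two methods' measurements.
#' @param loa_multiplier SD multiplier for the limits of agreement.
#' @return An object of class `fp_bland_altman` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, `statistic`, `p_value`, plus
#'   the per-subject means and differences for plotting.
#' @export
bland_altman <- function(data, x, y, loa_multiplier = 1.96) {
  xv <- resolve_col(enquo(x), data)
  yv <- resolve_col(enquo(y), data)
  keep <- stats::complete.cases(xv, yv)
  if (sum(!keep) > 0L) {
    inform(sprintf("Dropped %d row(s) with missing values.", sum(!keep)))
  }
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) {
    abort("At least 3 complete pairs are required.",
          class = "fpquant_insufficient_data_error")
  }
  d <- xv - yv
  m <- mean(d)
  s <- sd(d)
  stat <- if (s > 0) m / (s / sqrt(n)) else NA_real_
  structure(
    list(
      mean_diff = m,
      sd_diff = s,
      loa_low = m - loa_multiplier * s,
      loa_high = m + loa_multiplier * s,
      loa_multiplier = loa_multiplier,
      n = n,
      statistic = stat,
      p_value = if (is.na(stat)) NA_real_ else 2 * pt(-abs(stat), n - 1L),
      means = (xv + yv) / 2,
      diffs = d
    ),
    class = "fp_bland_altman"
  )
}

#' @export
print.fp_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.3f (SD %.3f), %g%% LoA [%.3f, %.3f]\n",
    x$n, x$mean_diff, x$sd_diff,
    round(100 * (2 * stats::pnorm(x$loa_multiplier) - 1)),
    x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
tidy.fp_bland_altman <- function(x, ...) {
  tibble(
    estimate = c(x$mean_diff, x$loa_low, x$loa_high),
    term = c("mean_diff", "loa_low", "loa_high")
  )[, c("term", "estimate")]
}

#' @export
glance.fp_bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         statistic = x$statistic, p.value = x$p_value, nobs = x$n)
}

#' @export
autoplot.fp_bland_altman <- function(object, ...) {
  df <- tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "indianred") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (x - y)",
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Two-way random-effects intraclass correlation, absolute agreement
#'
#' ICC(2,1) (single measures) and ICC(2,k) (average measures) from the
#' two-way ANOVA mean squares of a complete subjects-by-raters matrix:
#'
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' \deqn{ICC(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#'
#' where `MS_R`, `MS_C`, `MS_E` are the row (subject), column (rater) and
#' residual mean squares.  Average measures is what reliability of a mean
#' over k raters/replicate images refers to.
#'
#' @param ratings Numeric matrix or data frame, `n` subjects x `k` raters,
#'   complete.
#' @return An object of class `fp_icc` with `icc_single`, `icc_average`,
#'   the mean squares, `n` and `k`.
#' @export
icc_twoway_random <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m)) {
    abort("`ratings` must be a complete numeric matrix.",
          class = "fpquant_format_error")
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort("Need at least 2 subjects and 2 raters.",
          class = "fpquant_insufficient_data_error")
  }
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0) {
    abort("All ratings are identical; ICC is undefined.",
          class = "fpquant_degenerate_error")
  }
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  structure(
    list(icc_single = icc1, icc_average = icck,
         ms_rows = msr, ms_cols = msc, ms_error = mse, n = n, k = k),
    class = "fp_icc"
  )
}

#' @export
print.fp_icc <- function(x, ...) {
  cat(sprintf(
    "ICC two-way random, absolute agreement (n = %d, k = %d):\n  single %.4f, average %.4f\n",
    x$n, x$k, x$icc_single, x$icc_average))
  invisible(x)
}

#' @export
glance.fp_icc <- function(x, ...) {
  tibble(icc_single = x$icc_single, icc_average = x$icc_average,
         ms_rows = x$ms_rows, ms_cols = x$ms_cols, ms_error = x$ms_error,
         nobs = x$n, k = x$k)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with a
#' p-value from the t approximation on `n - 2` degrees of freedom.  For
#' very small samples (`n <= 8`) an exact permutation p-value can be
#' requested instead.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact If `TRUE` and `n <= 8`, enumerate all permutations for the
#'   p-value.
#' @return An object of class `fp_spearman` with `estimate`, `statistic`,
#'   `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(data, x, y, alternative = c("two.sided", "greater", "less"),
                         exact = FALSE) {
  alternative <- match.arg(alternative)
  xv <- resolve_col(enquo(x), data)
  yv <- resolve_col(enquo(y), data)
  keep <- stats::complete.cases(xv, yv)
  if (sum(!keep) > 0L) {
    inform(sprintf("Dropped %d row(s) with missing values.", sum(!keep)))
  }
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) {
    abort("At least 3 complete pairs are required.",
          class = "fpquant_insufficient_data_error")
  }
  rx <- rank(xv); ry <- rank(yv)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Zero rank variance; Spearman correlation is undefined.",
          class = "fpquant_degenerate_error")
  }
  r <- cor(rx, ry)

  if (exact && n <= 8L) {
    perms <- permutations(n)
    robs <- r
    rs <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p_val <- switch(alternative,
      two.sided = mean(abs(rs) >= abs(robs) - 1e-12),
      greater = mean(rs >= robs - 1e-12),
      less = mean(rs <= robs + 1e-12))
    stat <- NA_real_
    method <- "exact permutation"
  } else {
    if (exact) {
      warn("Exact permutation is only available for n <= 8; using the t approximation.")
    }
    if (abs(r) >= 1) {
      stat <- sign(r) * Inf
      p_one <- 0
    } else {
      stat <- r * sqrt((n - 2) / (1 - r^2))
      p_one <- pt(abs(stat), n - 2L, lower.tail = FALSE)
    }
    p_val <- switch(alternative,
      two.sided = 2 * p_one,
      greater = if (stat >= 0) p_one else 1 - p_one,
      less = if (stat <= 0) p_one else 1 - p_one)
    method <- "t approximation"
  }
  structure(
    list(estimate = r, statistic = stat, p_value = min(p_val, 1),
         n = n, alternative = alternative, method = method),
    class = "fp_spearman"
  )
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' @export
print.fp_spearman <- function(x, ...) {
  cat(sprintf("Spearman r = %.4f (n = %d, p = %.3g, %s)\n",
              x$estimate, x$n, x$p_value, x$method))
  invisible(x)
}

#' @export
glance.fp_spearman <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         p.value = x$p_value, nobs = x$n, method = x$method)
}

#' Forward stepwise regression of total count on regional counts
#'
#' Forward selection: starting from the intercept-only model, at each step
#' the candidate predictor giving the largest increase in R-squared is
#' added if its partial-F p-value is below `p_enter`; selection stops when
#' no candidate qualifies.  This mirrors how incremental regional-predictor
#' models of a total papilla count are built.  Exactly collinear candidates
#' tie-break deterministically by column order (a message reports this).
#'
#' @param data A data frame containing response and predictors.
#' @param response Unquoted column name of the response.
#' @param predictors Character vector of candidate predictor names
#'   (default: every other numeric column).
#' @param p_enter Partial-F entry threshold (default 0.05).
#' @return An object of class `fp_stepwise`: `steps` tibble (one row per
#'   entered predictor with `term`, `r_squared`, `f_statistic`, `p_value`),
#'   `model` (the final [lm] fit), `p_enter`.
#' @export
stepwise_forward <- function(data, response, predictors = NULL,
                             p_enter = 0.05) {
  resp <- rlang::as_name(enquo(response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                          resp)
  }
  y <- data[[resp]]
  n <- length(y)
  selected <- character(0)
  steps <- list()
  rss0 <- sum((y - mean(y))^2)
  tss <- rss0

  repeat {
    cand <- setdiff(predictors, selected)
    if (length(cand) == 0L) break
    if (rss0 <= tss * 1e-12) break  # response already fitted exactly
    p1 <- length(selected) + 1L  # parameters in the augmented model
    df2 <- n - p1 - 1L
    if (df2 < 1L) break
    rss <- vapply(cand, function(v) {
      fit <- stats::lm.fit(cbind(1, as.matrix(data[c(selected, v)])), y)
      sum(fit$residuals^2)
    }, numeric(1))
    if (any(duplicated(signif(rss, 12)))) {
      inform("Tied candidate predictors; breaking ties by column order.")
    }
    best <- which.min(rss)  # first minimum = column-order tie-break
    f <- (rss0 - rss[best]) / (rss[best] / df2)
    pval <- pf(f, 1, df2, lower.tail = FALSE)
    if (is.na(pval) || pval >= p_enter) break
    selected <- c(selected, cand[best])
    rss0 <- unname(rss[best])
    steps[[length(steps) + 1L]] <- tibble(
      step = length(selected), term = cand[best],
      r_squared = 1 - rss0 / tss, f_statistic = f, p_value = pval
    )
  }

  model <- if (length(selected) > 0L) {
    stats::lm(stats::reformulate(selected, response = resp), data = data)
  } else {
    stats::lm(stats::reformulate("1", response = resp), data = data)
  }
  structure(
    list(steps = dplyr::bind_rows(steps), model = model, p_enter = p_enter,
         response = resp),
    class = "fp_stepwise"
  )
}

#' @export
print.fp_stepwise <- function(x, ...) {
  cat(sprintf("Forward stepwise model for '%s' (p_enter = %g):\n",
              x$response, x$p_enter))
  if (nrow(x$steps) == 0L) {
    cat("  no predictor entered\n")
  } else {
    print(as.data.frame(x$steps), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.fp_stepwise <- function(x, ...) {
  co <- stats::coef(x$model)
  tibble(term = names(co), estimate = unname(co))
}

#' @export
glance.fp_stepwise <- function(x, ...) {
  s <- summary(x$model)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         n_selected = nrow(x$steps), nobs = length(x$model$residuals))
}
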