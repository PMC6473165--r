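#' Estimated prevalence with a Wilson 95% confidence interval
#'
#' Prevalence is the percentage of virus-positive individuals over
#' individuals tested.  The percentage is rounded half-up to one decimal
#' (so 13/16 prints as 81.3).  The interval is the Wilson score interval,
#' whose lower bound is 0 when `k = 0`.
#'
#' @param k Number of positive individuals.
#' @param n Number of individuals tested (>= 1).
#' @return An object of class `prevalence_estimate`: `k`, `n`, `pct`,
#'   `ci95 = c(lo, hi)` (percent).
#' @examples
#' prevalence(5, 51)   # 9.8%
#' prevalence(13, 16)  # 81.3%
#' @export
prevalence <- function(k, n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (k < 0L || k > n) stop("k must be in [0, n]", call. = FALSE)
  p <- k / n
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(
    list(k = k, n = n, pct = round_half_up(100 * p, 1),
         ci95 = c(lo = max(0, 100 * (centre - half)),
                  hi = min(100, 100 * (centre + half)))),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%d/%d positive (%.1f%%, 95%% CI %.1f-%.1f)\n",
              x$k, x$n, x$pct, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Read a cohort table
#'
#' Tab-separated with a header; expected columns: `individual`, categorical
#' covariates (e.g. `species`, `age`, `sex`, `season`, `location`) and
#' `status` (`positive`/`negative`).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"status" %in% names(df)) stop("cohort table needs a 'status' column", call. = FALSE)
  bad <- setdiff(unique(df$status), c("positive", "negative"))
  if (length(bad)) stop("invalid status value: ", bad[1], call. = FALSE)
  df
}

#' Collapse repeated samples to one row per individual
#'
#' The unit of analysis is the individual, not the sample: an individual is
#' positive if any of its samples is positive.  Covariates are taken from
#' the individual's first row.
#'
#' @param cohort Data frame with `individual` and `status` columns.
#' @return One row per individual.
#' @export
collapse_samples <- function(cohort) {
  if (!"individual" %in% names(cohort)) {
    stop("cohort table needs an 'individual' column", call. = FALSE)
  }
  parts <- split(cohort, cohort$individual)
  out <- do.call(rbind, lapply(parts, function(p) {
    r <- p[1, , drop = FALSE]
    r$status <- if (any(p$status == "positive")) "positive" else "negative"
    r
  }))
  rownames(out) <- NULL
  out[order(match(out$individual, unique(cohort$individual))), , drop = FALSE]
}

# Aggregate either an individual-level cohort or a k/n count table into
# (level, k, n)
aggregate_counts <- function(x, factor = NULL) {
  if (all(c("k", "n") %in% names(x))) {
    lev_col <- factor %||% setdiff(names(x), c("k", "n"))[1]
    return(data.frame(level = as.character(x[[lev_col]]), k = x$k, n = x$n,
                      stringsAsFactors = FALSE))
  }
  if (is.null(factor)) stop("factor must be named for a cohort table", call. = FALSE)
  if (!factor %in% names(x)) stop("no column '", factor, "'", call. = FALSE)
  lv <- as.character(x[[factor]])
  k <- tapply(x$status == "positive", lv, sum)
  n <- tapply(lv, lv, length)
  data.frame(level = names(k), k = as.integer(k), n = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Fit a binomial GLM of status on one categorical predictor
#'
#' Logit-link binomial GLM fitted by iteratively reweighted least squares
#' (via [stats::glm()]).  With a single categorical predictor the model is
#' saturated in levels, so the fitted proportion in each level equals the
#' observed `k/n`; levels with `k = 0` or `k = n` sit on the boundary of
#' the parameter space (the fitted proportion is still the observed one,
#' but the coefficient is flagged).
#'
#' @param x Either an individual-level cohort data frame (with `status`)
#'   or an aggregated count table with columns `k`, `n` and a level column.
#' @param factor Name of the categorical predictor (required for cohort
#'   input; for count tables, defaults to the first non-`k`/`n` column).
#' @return A list: `fit` (the `glm` object), `levels`, `fitted_prop`,
#'   `observed_prop`, `boundary` (logical per level), `deviance`,
#'   `null_deviance`.
#' @export
fit_binomial_glm <- function(x, factor = NULL) {
  tab <- aggregate_counts(x, factor)
  if (nrow(tab) < 2L) stop("need at least 2 levels", call. = FALSE)
  if (any(tab$n < 1L)) stop("every level needs n >= 1", call. = FALSE)
  tab$level <- stats::relevel(base::factor(tab$level), ref = tab$level[1])
  fit <- stats::glm(cbind(k, n - k) ~ level, family = stats::binomial(),
                    data = tab)
  list(
    fit = fit,
    levels = as.character(tab$level),
    fitted_prop = unname(stats::fitted(fit)),
    observed_prop = tab$k / tab$n,
    boundary = tab$k == 0L | tab$k == tab$n,
    deviance = stats::deviance(fit),
    null_deviance = fit$null.deviance
  )
}

#' Deviance (likelihood-ratio) chi-square test for a categorical predictor
#'
#' The test statistic is the drop in deviance from the intercept-only
#' binomial GLM to the model with the predictor, which for a single
#' categorical factor equals the G statistic
#' \eqn{2 \sum o \log(o/e)} over the level-by-status table; zero-count
#' cells contribute 0.  Degrees of freedom are the number of levels minus
#' one; the p-value is the upper chi-square tail.
#'
#' @inheritParams fit_binomial_glm
#' @return An object of class `glm_test_result`: `df`, `chi2`, `p`,
#'   `method = "deviance_lr"`.
#' @examples
#' # seasonal contrast from printed counts
#' lr_test(data.frame(season = c("spring", "fall"), k = c(23, 9), n = c(41, 72)))
#' @export
lr_test <- function(x, factor = NULL) {
  f <- fit_binomial_glm(x, factor)
  chi2 <- f$null_deviance - f$deviance
  df <- length(f$levels) - 1L
  structure(
    list(df = df, chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
         method = "deviance_lr"),
    class = "glm_test_result"
  )
}

#' @export
print.glm_test_result <- function(x, ...) {
  p_txt <- if (x$p < 0.001) "p < 0.001" else sprintf("p = %.2f", x$p)
  cat(sprintf("deviance LR test: df = %d, chi2 = %.2f, %s\n", x$df, x$chi2, p_txt))
  invisible(x)
}

#' Prevalence by group
#'
#' @inheritParams fit_binomial_glm
#' @return Data frame with `level`, `k`, `n`, `pct`, `ci_lo`, `ci_hi`.
#' @export
prevalence_table <- function(x, factor = NULL) {
  tab <- aggregate_counts(x, factor)
  est <- lapply(seq_len(nrow(tab)), function(i) prevalence(tab$k[i], tab$n[i]))
  data.frame(
    level = tab$level, k = tab$k, n = tab$n,
    pct = vapply(est, `[[`, numeric(1), "pct"),
    ci_lo = vapply(est, function(e) e$ci95[["lo"]], numeric(1)),
    ci_hi = vapply(est, function(e) e$ci95[["hi"]], numeric(1)),
    stringsAsFactors = FALSE
  )
}
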