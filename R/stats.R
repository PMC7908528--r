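#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation; the two-sided p-value comes from
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) against Student's t with n - 2
#' degrees of freedom, and the confidence interval from [fisher_ci()].
#'
#' @param x,y Numeric vectors of equal length, n >= 4, each with non-zero
#'   variance.
#' @param level Confidence level for the interval.
#' @return Object of class `correlation_result`: `r`, `n`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
pearson <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pearson: need at least 4 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson: correlation undefined, an input has zero variance")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) < 1) {
    p <- correlation_p(r, n)
    ci <- fisher_ci(r, n, level)
  } else {
    p <- 0
    ci <- c(r, r)
  }
  structure(list(r = r, n = n, ci_low = ci[1L], ci_high = ci[2L], p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.2f (%.2f-%.2f), n = %d, p = %.4g%s\n",
              x$r, x$ci_low, x$ci_high, x$n, x$p, significance_stars(x$p)))
  invisible(x)
}

#' Two-sided p-value of a correlation coefficient
#'
#' From t = r * sqrt(n - 2) / sqrt(1 - r^2) against Student's t with n - 2
#' degrees of freedom; the test behind the significance stars when only r
#' and n are known.
#'
#' @param r Correlation, |r| < 1.
#' @param n Sample size, > 2.
#' @return Two-sided p-value.
#' @export
correlation_p <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1) stop("correlation_p: need |r| < 1")
  if (n <= 2) stop("correlation_p: need n > 2")
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Fisher-z confidence interval for a correlation
#'
#' z = atanh(r) is approximately normal with SE 1/sqrt(n - 3); the interval
#' is tanh(z -/+ z_crit/sqrt(n - 3)).
#'
#' @param r Correlation, |r| < 1.
#' @param n Sample size, >= 4.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' round(fisher_ci(0.78, 12), 2)  # 0.37 0.94
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("fisher_ci: degenerate interval, |r| must be < 1")
  }
  if (n < 4L) stop("fisher_ci: need n >= 4")
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Dependent-samples (paired) t test
#'
#' t = mean(d) / (sd(d)/sqrt(n)) on the paired differences d = x - y, with
#' n - 1 degrees of freedom, two-sided.
#'
#' @param x,y Paired numeric vectors of equal length, n >= 2; the
#'   differences must have non-zero variance.
#' @return Object of class `paired_comparison`: `mean_diff`, `t`, `df`, `p`,
#'   `n`, `sd_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2L) stop("paired_t: need at least 2 complete pairs")
  s <- stats::sd(d)
  # treat float-level residual spread of a constant shift as zero variance
  if (s <= 1e-12 * max(1, abs(mean(d)))) {
    stop("paired_t: degenerate comparison, paired differences have zero variance")
  }
  tval <- mean(d) / (s / sqrt(n))
  structure(
    list(mean_diff = mean(d), t = tval, df = n - 1L,
         p = 2 * stats::pt(-abs(tval), df = n - 1), n = n, sd_diff = s),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired t> mean diff = %.3f, t(%d) = %.3f, p = %.4g\n",
              x$mean_diff, x$df, x$t, x$p))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation of the W statistic and its p-value (the standard
#' published algorithm, as implemented in [stats::shapiro.test()]).
#'
#' @param x Numeric vector, 3 <= n <= 5000, with non-zero variance.
#' @return A list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) {
    stop("shapiro_wilk: sample size must be in [3, 5000] (got ", n, ")")
  }
  if (stats::sd(x) == 0) stop("shapiro_wilk: zero variance")
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p = res$p.value)
}

#' Average a set of correlation coefficients
#'
#' Arithmetic mean of the magnitudes |r| by default (so coefficients of
#' opposite sign do not cancel); set `use_magnitude = FALSE` for the mean of
#' the raw coefficients. Reports round to 2 decimals.
#'
#' @param rs Numeric vector of correlations, each |r| <= 1, non-empty.
#' @param use_magnitude Average |r| (default) or raw r.
#' @return The (unrounded) mean.
#' @export
average_correlations <- function(rs, use_magnitude = TRUE) {
  if (length(rs) == 0L) stop("average_correlations: empty input")
  if (any(!is.finite(rs)) || any(abs(rs) > 1)) {
    stop("average_correlations: correlations must be finite with |r| <= 1")
  }
  if (use_magnitude) mean(abs(rs)) else mean(rs)
}

#' Significance stars
#'
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise (vectorised).
#'
#' @param p P-value(s).
#' @return Character vector of flags.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Assemble the cross-test comparison tables
#'
#' Builds the generalizability table (per variable F and P, per test pair,
#' per method: Pearson r with Fisher-z 95% CI and significance flags), the
#' per-test concurrent-validity summary (standard-test mean and SD vs
#' two-point mean and SD, their correlation, and the dependent-samples t
#' test of the difference), using pairwise-complete subjects.
#'
#' @param profiles_by_test Named list (`jump`, `cycling`, `isokinetic`) of
#'   data.frames with columns `subject_id`, `F0`, `P0`.
#' @param standard_by_test Named list of data.frames with columns
#'   `subject_id`, `Fmax`, `Pmax`.
#' @param require_complete If `TRUE`, error (listing the missing IDs) when
#'   the tests do not share an identical subject set; if `FALSE` (default),
#'   use pairwise-complete subjects per cell.
#' @return A list of three data.frames: `table1` (variable x pair x method
#'   correlations), `figure3` (per test x variable means, SDs, validity r,
#'   paired difference), `comparisons` (the paired t tests).
#' @export
build_comparison_table <- function(profiles_by_test, standard_by_test,
                                   require_complete = FALSE) {
  tests <- c("jump", "cycling", "isokinetic")
  if (!all(tests %in% names(profiles_by_test)) ||
      !all(tests %in% names(standard_by_test))) {
    stop("build_comparison_table: need entries for tests ",
         paste(tests, collapse = ", "))
  }
  ids <- lapply(tests, function(tst) {
    intersect(profiles_by_test[[tst]]$subject_id,
              standard_by_test[[tst]]$subject_id)
  })
  names(ids) <- tests
  if (require_complete) {
    all_ids <- Reduce(union, ids)
    common <- Reduce(intersect, ids)
    if (length(setdiff(all_ids, common)) > 0L) {
      stop("build_comparison_table: subject mismatch, missing from some tests: ",
           paste(sort(setdiff(all_ids, common)), collapse = ", "))
    }
  }

  value_of <- function(tst, variable, method, subject_ids) {
    src <- if (method == "two_point") profiles_by_test[[tst]] else standard_by_test[[tst]]
    col <- if (method == "two_point") {
      if (variable == "F") "F0" else "P0"
    } else {
      if (variable == "F") "Fmax" else "Pmax"
    }
    src[[col]][match(subject_ids, src$subject_id)]
  }

  pairs <- list(c("jump", "cycling"), c("jump", "isokinetic"),
                c("cycling", "isokinetic"))
  t1 <- list()
  for (variable in c("F", "P")) {
    for (pp in pairs) {
      for (method in c("standard", "two_point")) {
        shared <- intersect(ids[[pp[1L]]], ids[[pp[2L]]])
        cr <- pearson(value_of(pp[1L], variable, method, shared),
                      value_of(pp[2L], variable, method, shared))
        t1[[length(t1) + 1L]] <- data.frame(
          variable = variable,
          pair = paste0(toupper(pp[1L]), "-", toupper(pp[2L])),
          method = method, r = cr$r, ci_low = cr$ci_low, ci_high = cr$ci_high,
          p = cr$p, n = cr$n, stars = significance_stars(cr$p),
          stringsAsFactors = FALSE)
      }
    }
  }
  table1 <- do.call(rbind, t1)

  f3 <- list(); cmp <- list()
  for (tst in tests) {
    for (variable in c("F", "P")) {
      shared <- ids[[tst]]
      std <- value_of(tst, variable, "standard", shared)
      twp <- value_of(tst, variable, "two_point", shared)
      cr <- pearson(std, twp)
      pt <- paired_t(twp, std)
      f3[[length(f3) + 1L]] <- data.frame(
        test = toupper(tst), variable = variable,
        standard_mean = mean(std), standard_sd = stats::sd(std),
        two_point_mean = mean(twp), two_point_sd = stats::sd(twp),
        r = cr$r, r_p = cr$p, r_stars = significance_stars(cr$p),
        diff_p = pt$p, diff_stars = significance_stars(pt$p), n = pt$n,
        stringsAsFactors = FALSE)
      cmp[[length(cmp) + 1L]] <- data.frame(
        test = toupper(tst), variable = variable, mean_diff = pt$mean_diff,
        t = pt$t, df = pt$df, p = pt$p, n = pt$n,
        stars = significance_stars(pt$p), stringsAsFactors = FALSE)
    }
  }
  list(table1 = table1, figure3 = do.call(rbind, f3),
       comparisons = do.call(rbind, cmp))
}
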