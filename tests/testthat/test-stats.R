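test_that("pearson handles perfect, inverse and degenerate relationships", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- pearson(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  rm1 <- pearson(x, -x)
  expect_equal(rm1$r, -1)
  expect_error(pearson(x, rep(3, 5)), "zero variance")
  expect_error(pearson(1:3, 3:1), "at least 4")
})

test_that("pearson agrees with the cor.test oracle", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    mine <- pearson(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    expect_equal(c(mine$ci_low, mine$ci_high), as.numeric(ref$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("pearson is affine-invariant and flips sign under negation", {
  set.seed(22)
  x <- rnorm(15); y <- rnorm(15) + 0.4 * x
  base <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 7, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson(x, 0.1 * y - 2)$r, base, tolerance = 1e-12)
  expect_equal(pearson(-x, y)$r, -base, tolerance = 1e-12)
})

test_that("fisher_ci matches hand-checked intervals and is symmetric at r = 0", {
  expect_equal(round(fisher_ci(0.78, 12), 2), c(0.37, 0.94))
  expect_equal(round(fisher_ci(0.72, 12), 2), c(0.25, 0.92))
  ci0 <- fisher_ci(0, 1000)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-12)
  expect_error(fisher_ci(1, 12), "degenerate")
  expect_error(fisher_ci(0.5, 3), "n >= 4")
})

test_that("correlation significance matches the t reference and is monotone in |r|", {
  # independently verified through the t CDF
  expect_equal(correlation_p(0.66, 12),
               2 * pt(-0.66 * sqrt(10) / sqrt(1 - 0.66^2), 10), tolerance = 1e-12)
  ps <- vapply(seq(0.05, 0.95, by = 0.05), correlation_p, numeric(1), n = 12)
  expect_true(all(diff(ps) < 0))
  expect_identical(significance_stars(c(0.001, 0.03, 0.2)), c("**", "*", ""))
})

test_that("paired_t matches t.test, is antisymmetric, and errors on zero variance", {
  set.seed(23)
  x <- rnorm(12, 10, 2); y <- rnorm(12, 9, 2)
  mine <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(paired_t(y, x)$t, -mine$t, tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x + 5), "zero variance")  # constant shift
})

test_that("paired t has the expected power at n = 12 for a 1.2 SD effect", {
  # Monte-Carlo power check (reduced to 2000 reps for runtime; analytic
  # power at d = 1.2, n = 12, alpha = 0.05 is 0.956)
  set.seed(24)
  reps <- 2000
  hits <- 0L
  for (i in seq_len(reps)) {
    d <- rnorm(12, 1.2, 1)
    if (paired_t(d, rep(0, 12))$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.90)
})

test_that("shapiro_wilk level and power behave as a 0.05-level test", {
  # null rate of p > 0.05 is 95% by construction; binomial band at 400 seeds
  set.seed(25)
  null_keep <- mean(vapply(1:400, function(i) {
    shapiro_wilk(rnorm(50))$p > 0.05
  }, logical(1)))
  expect_gt(null_keep, 0.92)
  # strongly skewed data are rejected essentially always
  set.seed(26)
  rej <- mean(vapply(1:400, function(i) {
    shapiro_wilk(rexp(50))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.95)
  expect_error(shapiro_wilk(c(1, 2)), "3, 5000")
  expect_error(shapiro_wilk(rep(1, 10)), "zero variance")
})

test_that("average_correlations uses magnitudes by default", {
  expect_equal(average_correlations(c(0.5, -0.5)), 0.5)
  expect_equal(average_correlations(c(0.5, -0.5), use_magnitude = FALSE), 0)
  expect_equal(average_correlations(0.5), 0.5)
  expect_error(average_correlations(numeric(0)), "empty")
  expect_error(average_correlations(c(0.2, 1.4)), "<= 1")
})

test_that("build_comparison_table recovers a known between-test correlation", {
  set.seed(27)
  n <- 200
  shared <- rnorm(n)
  mk <- function(scale) {
    F0 <- exp(5 + 0.2 * (sqrt(0.8) * shared + sqrt(0.2) * rnorm(n))) * scale
    P0 <- F0 * exp(rnorm(n, 0, 0.05))
    data.frame(subject_id = sprintf("S%03d", 1:n), F0 = F0, P0 = P0)
  }
  profs <- list(jump = mk(3), cycling = mk(1), isokinetic = mk(0.8))
  stds <- lapply(profs, function(df) {
    data.frame(subject_id = df$subject_id, Fmax = df$F0 * 0.8,
               Pmax = df$P0 * 0.75)
  })
  out <- build_comparison_table(profs, stds)
  expect_equal(nrow(out$table1), 12L)   # 2 variables x 3 pairs x 2 methods
  cell <- out$table1[out$table1$variable == "F" &
                       out$table1$pair == "JUMP-CYCLING" &
                       out$table1$method == "two_point", ]
  half_width <- (cell$ci_high - cell$ci_low) / 2
  expect_lt(abs(cell$r - 0.8), half_width)
})

test_that("independent tests give correlations inside the null band", {
  set.seed(28)
  rs <- replicate(30, {
    n <- 20
    profs <- lapply(1:3, function(i) {
      data.frame(subject_id = sprintf("S%03d", 1:n),
                 F0 = exp(rnorm(n, 5, 0.2)), P0 = exp(rnorm(n, 6, 0.2)))
    })
    names(profs) <- c("jump", "cycling", "isokinetic")
    stds <- lapply(profs, function(df) {
      data.frame(subject_id = df$subject_id,
                 Fmax = df$F0 * exp(rnorm(n, -0.2, 0.05)),
                 Pmax = df$P0 * exp(rnorm(n, -0.2, 0.05)))
    })
    out <- build_comparison_table(profs, stds)
    mean(abs(out$table1$r))
  })
  # E|r| under the null at n = 20 is about sqrt(2/(pi*(n-1))) ~ 0.18
  expect_lt(mean(rs), 0.30)
  expect_gt(mean(rs), 0.05)
})

test_that("subject mismatch is reported with the missing ids", {
  profs <- lapply(1:3, function(i) {
    data.frame(subject_id = sprintf("S%02d", 1:8), F0 = rnorm(8, 1000, 50),
               P0 = rnorm(8, 1500, 80))
  })
  names(profs) <- c("jump", "cycling", "isokinetic")
  set.seed(29)
  stds <- lapply(profs, function(df) {
    data.frame(subject_id = df$subject_id, Fmax = df$F0 - rnorm(8, 100, 10),
               Pmax = df$P0 - rnorm(8, 100, 10))
  })
  stds$cycling <- stds$cycling[stds$cycling$subject_id != "S03", ]
  expect_error(build_comparison_table(profs, stds, require_complete = TRUE),
               "S03")
  # pairwise-complete mode drops S03 only where cycling is involved
  out <- build_comparison_table(profs, stds)
  expect_equal(unique(out$table1$n[out$table1$pair == "JUMP-ISOKINETIC"]), 8L)
  expect_equal(unique(out$table1$n[out$table1$pair == "JUMP-CYCLING"]), 7L)
})
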