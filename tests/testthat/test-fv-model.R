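test_that("fit_two_point recovers the hand-computed line and parameters", {
  prof <- fit_two_point(fv_point(1500, 1.0, "heavy"), fv_point(500, 3.0, "light"))
  expect_equal(prof$F0, 2000)
  expect_equal(prof$V0, 4.0)
  expect_equal(prof$slope_a, 500)
  expect_equal(prof$P0, 2000)
  # the fitted line passes exactly through both inputs
  expect_equal(predict_force(prof, 1.0), 1500)
  expect_equal(predict_force(prof, 3.0), 500)
})

test_that("degenerate and invalid two-point inputs raise the named errors", {
  p <- fv_point(1000, 2)
  expect_error(fit_two_point(p, fv_point(900, 2)), "equal velocities")
  expect_error(fit_two_point(fv_point(500, 1), fv_point(1500, 3)),
               "does not decrease")
  expect_error(fv_point(-10, 1), "force")
  expect_error(fv_point(100, 0), "velocity")
  expect_error(fv_point(Inf, 1), "force")
})

test_that("fit_two_point equals the least-squares oracle on n = 2", {
  set.seed(101)
  for (i in 1:200) {
    F0 <- runif(1, 500, 3000); V0 <- runif(1, 1, 6)
    v <- sort(runif(2, 0.05, V0 * 0.95))
    f <- F0 * (1 - v / V0)
    prof <- fit_two_point(fv_point(f[1], v[1]), fv_point(f[2], v[2]))
    beta <- ols2_oracle(v, f)
    expect_equal(prof$F0, unname(beta["intercept"]), tolerance = 1e-12)
    expect_equal(-prof$slope_a, unname(beta["slope"]), tolerance = 1e-12)
  }
})

test_that("fit_linear: n = 2 equivalence, exact collinearity, noisy recovery", {
  pts <- list(fv_point(1500, 1.0), fv_point(500, 3.0))
  expect_equal(unclass(fit_linear(pts)), unclass(fit_two_point(pts[[1]], pts[[2]])),
               tolerance = 1e-12)

  col3 <- lapply(c(0.5, 2, 3.5), function(v) fv_point(2000 - 500 * v, v))
  prof <- fit_linear(col3)
  expect_equal(prof$F0, 2000, tolerance = 1e-9)
  expect_equal(prof$V0, 4, tolerance = 1e-9)

  set.seed(202)
  v <- runif(10, 0.5, 3.5)
  f <- 2000 - 500 * v + rnorm(10, 0, 30)
  prof <- fit_linear(Map(fv_point, f, v))
  beta <- ols_oracle(v, f)
  expect_equal(prof$F0, unname(beta["intercept"]), tolerance = 1e-9)
  expect_equal(-prof$slope_a, unname(beta["slope"]), tolerance = 1e-9)

  expect_error(fit_linear(list(fv_point(1, 1), fv_point(2, 1))), "degenerate")
})

test_that("predict_force and apex_power match hand values and the grid oracle", {
  prof <- fv_profile(2000, 4)
  expect_equal(predict_force(prof, 0), 2000)
  expect_equal(predict_force(prof, 4), 0)
  expect_equal(predict_force(prof, 2), 1000)
  expect_error(predict_force(prof, -1), ">= 0")

  expect_equal(apex_power(prof), list(velocity = 2, Pmax = 2000))
  expect_equal(apex_power(fv_profile(1, 1)), list(velocity = 0.5, Pmax = 0.25))

  # brute-force grid search over the power parabola
  set.seed(303)
  for (i in 1:3) {
    p <- fv_profile(runif(1, 500, 3000), runif(1, 1, 8))
    v <- seq(0, p$V0, length.out = 1e6)
    expect_equal(apex_power(p)$Pmax, max(v * predict_force(p, v)),
                 tolerance = 1e-6)
  }
})

test_that("exact interpolation and scale equivariance hold for random pairs", {
  set.seed(404)
  for (i in 1:100) {
    f1 <- runif(1, 800, 2500); v1 <- runif(1, 0.3, 1.5)
    f2 <- runif(1, 100, f1 - 50); v2 <- v1 + runif(1, 0.3, 3)
    prof <- suppressWarnings(fit_two_point(fv_point(f1, v1), fv_point(f2, v2)))
    expect_equal(predict_force(prof, v1), f1, tolerance = 1e-9)
    expect_equal(predict_force(prof, v2), f2, tolerance = 1e-9)
    k <- runif(1, 0.5, 3)
    scaled <- suppressWarnings(
      fit_two_point(fv_point(k * f1, v1), fv_point(k * f2, v2)))
    expect_equal(scaled$F0, k * prof$F0, tolerance = 1e-9)
    expect_equal(scaled$slope_a, k * prof$slope_a, tolerance = 1e-9)
    expect_equal(scaled$P0, k * prof$P0, tolerance = 1e-9)
    expect_equal(scaled$V0, prof$V0, tolerance = 1e-9)
  }
})

test_that("profile invariants and range warnings", {
  prof <- fv_profile(1234.5, 3.21)
  expect_equal(prof$slope_a, prof$F0 / prof$V0, tolerance = 1e-12)
  expect_equal(prof$P0, prof$F0 * prof$V0 / 4, tolerance = 1e-12)
  expect_warning(fv_profile(1000, 25), "20 m/s")
  expect_warning(fv_profile(20000, 5, body_mass = 60), "20 body weights")
  expect_silent(fv_profile(2000, 4, body_mass = 70))
})

test_that("profiles serialize to and from CSV losslessly", {
  profs <- list(
    S01 = list(jump = fv_profile(1800, 4.2), cycling = fv_profile(600, 3.3)),
    S02 = list(jump = fv_profile(1500, 3.9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, path)
  df <- read_profiles(path)
  expect_equal(names(df),
               c("subject_id", "test", "F0_N", "V0_mps", "slope_Nspm", "P0_W"))
  expect_equal(nrow(df), 3L)
  expect_equal(df$F0_N[df$subject_id == "S01" & df$test == "jump"], 1800)
  expect_equal(df$P0_W[df$subject_id == "S02"], 1500 * 3.9 / 4)
})
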