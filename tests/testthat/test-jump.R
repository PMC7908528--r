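# constructs a simple analytic jump-like trace: quiet standing at weight W,
# sinusoidal dip (net zero impulse), constant push, then flight at 0 N
analytic_jump_trace <- function(M = 70, rate = 1000, quiet = 1.2, dip = 0.6,
                                push_F = 1500, push_t = 0.25, depth = 0.2) {
  g <- 9.81; W <- M * g
  A <- 2 * pi * M * depth / dip^2
  td <- seq_len(round(dip * rate)) / rate
  f <- c(rep(W, round(quiet * rate)),
         W - A * sin(2 * pi * td / dip),
         rep(push_F, round(push_t * rate)),
         rep(0, round(0.25 * rate)))
  list(trace = force_trace(f, rate, body_mass = M),
       onset = round(quiet * rate) + 1L,
       lowest = round(quiet * rate) + round(dip * rate),
       takeoff = round(quiet * rate) + round(dip * rate) + round(push_t * rate) + 1L,
       W = W, M = M)
}

test_that("detect_phases finds onset, lowest position and takeoff within 5 ms", {
  fx <- analytic_jump_trace()
  ph <- detect_phases(fx$trace)
  expect_lte(abs(ph$onset_index - fx$onset), 5L)
  expect_lte(abs(ph$lowest_com_index - fx$lowest), 5L)
  expect_lte(abs(ph$takeoff_index - fx$takeoff), 5L)
  expect_equal(ph$system_weight, fx$W, tolerance = 1e-6)
})

test_that("detect_phases raises no-movement and no-takeoff errors", {
  quiet <- force_trace(rep(686.7, 3000) + rnorm(3000, 0, 1), 1000)
  expect_error(detect_phases(quiet), "no movement")

  fx <- analytic_jump_trace()
  grounded <- fx$trace
  n <- length(grounded$samples)
  grounded$samples[grounded$samples < 50] <- fx$W  # never leaves the ground
  expect_error(detect_phases(grounded), "no takeoff")
})

test_that("impulse-momentum kinematics match closed forms", {
  M <- 70; g <- 9.81; W <- M * g; rate <- 1000
  # constant net surplus of 140 N for 0.5 s (500 intervals) -> v = 1.0 m/s
  f <- c(rep(W, 1100), rep(W + 140, 501))
  tr <- force_trace(f, rate, body_mass = M)
  ph <- jump_phases(1101, 1102, 1601, system_weight = W)
  kin <- compute_kinematics(tr, ph)
  expect_equal(kin$velocity_mps[nrow(kin)], 1.0, tolerance = 1e-9)

  # equilibrium: F = W everywhere -> v and position identically zero
  tr0 <- force_trace(rep(W, 2000), rate, body_mass = M)
  kin0 <- compute_kinematics(tr0, jump_phases(1001, 1002, 2000, system_weight = W))
  expect_equal(kin0$velocity_mps, rep(0, nrow(kin0)))
  expect_equal(kin0$position_m, rep(0, nrow(kin0)))

  # quadratic-in-time surplus: F = W + c*t^2 -> v = c t^3 / (3 M)
  c2 <- 2000
  tt <- 0:500 / rate
  f <- c(rep(W, 1100), W + c2 * tt^2)
  kin2 <- compute_kinematics(force_trace(f, rate, body_mass = M),
                             jump_phases(1101, 1102, 1601, system_weight = W))
  expect_equal(kin2$velocity_mps[nrow(kin2)], c2 * 0.5^3 / (3 * M),
               tolerance = 1e-4)
})

test_that("impulse-momentum closure: v(takeoff) equals trapezoid net impulse over M", {
  tr <- simulate_jump_trace(nominal_truth(), added_load = 1, noise_sd = 3, seed = 5)
  filt <- lowpass_jump(tr)
  ph <- detect_phases(filt)
  kin <- compute_kinematics(filt, ph)
  v_to <- kin$velocity_mps[kin$index == ph$takeoff_index]
  seg <- filt$samples[ph$onset_index:ph$takeoff_index] - ph$system_weight
  M <- ph$system_weight / tr$gravity
  imp <- sum((seg[-1] + seg[-length(seg)]) / 2) / tr$rate / M
  expect_equal(v_to, imp, tolerance = 1e-9)
})

test_that("flight-phase acceleration equals -g within 0.05 m/s^2", {
  tr <- simulate_jump_trace(nominal_truth(), added_load = 1, noise_sd = 0, seed = 1)
  filt <- lowpass_jump(tr)
  ph <- detect_phases(filt)
  kin <- compute_kinematics(filt, ph)
  # skip 80 ms after takeoff: the causal filter is still decaying there
  fl <- kin$index > ph$takeoff_index + 80 & kin$index < length(filt$samples) - 10
  expect_true(all(abs(kin$accel_mps2[fl] + tr$gravity) < 0.05))
})

test_that("extract_jump_metrics recovers simulator ground truth within 2%", {
  tru <- nominal_truth()
  for (load in c(1, 24)) {
    tr <- simulate_jump_trace(tru, added_load = load, noise_sd = 0, seed = 2)
    tt <- attr(tr, "truth")
    m <- extract_jump_metrics(tr)
    expect_equal(m$Fmax, tt$Fmax, tolerance = 0.02)
    expect_equal(m$Vmax, tt$Vmax, tolerance = 0.02)
    expect_equal(m$Pmax, tt$Pmax, tolerance = 0.02)
  }
})

test_that("jump metrics are deterministic and concentric Pmax is the pointwise product max", {
  tr <- simulate_jump_trace(nominal_truth(), added_load = 24, noise_sd = 4, seed = 9)
  m1 <- extract_jump_metrics(tr)
  m2 <- extract_jump_metrics(tr)
  expect_identical(m1, m2)

  filt <- lowpass_jump(tr)
  ph <- detect_phases(filt)
  kin <- compute_kinematics(filt, ph)
  con <- kin$index >= ph$lowest_com_index & kin$index <= ph$takeoff_index
  expect_equal(m1$Pmax, max(kin$force_N[con] * kin$velocity_mps[con]))
})

test_that("heavier load lowers Vmax and raises Fmax across simulated subjects", {
  set.seed(77)
  for (i in 1:3) {
    tru <- subject_truth(
      paste0("T", i),
      profiles = list(jump = fv_profile(runif(1, 1500, 2000), runif(1, 3.8, 5)),
                      cycling = fv_profile(600, 3.4),
                      isokinetic = fv_profile(520, 2.6)),
      body_mass = runif(1, 55, 80))
    m1 <- extract_jump_metrics(simulate_jump_trace(tru, 1, noise_sd = 0))
    m24 <- extract_jump_metrics(simulate_jump_trace(tru, 24, noise_sd = 0))
    expect_lt(m24$Vmax, m1$Vmax)
    expect_gt(m24$Fmax, m1$Fmax)
    # negative-slope precondition of the two-point fit holds
    expect_s3_class(fit_two_point(fv_point(m24$Fmax, m24$Vmax),
                                  fv_point(m1$Fmax, m1$Vmax)), "fv_profile")
  }
})

test_that("select_best_trial picks highest Pmax with first-occurrence ties", {
  a <- trial_metrics(1000, 2, 1800, "a")
  b <- trial_metrics(1100, 2, 2000, "b")
  b2 <- trial_metrics(1090, 2, 2000, "b2")
  expect_identical(select_best_trial(list(a, b)), b)
  expect_identical(select_best_trial(list(a)), a)
  expect_identical(select_best_trial(list(b, b2)), b)  # tie -> first
  expect_error(select_best_trial(list()), "non-empty")
})

test_that("jump CSV round trip preserves the trace", {
  tr <- simulate_jump_trace(nominal_truth(), 1, noise_sd = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_jump_csv(tr, path)
  back <- read_jump_csv(path, body_mass = 67.4, added_load = 1)
  expect_equal(back$rate, tr$rate, tolerance = 1e-6)
  expect_equal(back$samples, tr$samples, tolerance = 1e-4)
  expect_equal(unclass(extract_jump_metrics(back))[c("Fmax", "Vmax", "Pmax")],
               unclass(extract_jump_metrics(tr))[c("Fmax", "Vmax", "Pmax")],
               tolerance = 1e-4)
})
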