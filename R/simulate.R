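#' Ground-truth description of one simulated subject
#'
#' Holds the true force-velocity profile of each test plus the
#' anthropometric metadata the pipelines need. This is the ground truth a
#' real study cannot observe; every simulated trial is generated from it,
#' so end-to-end recovery can be checked exactly.
#'
#' @param id Subject identifier.
#' @param profiles Named list of [fv_profile()] for `jump`, `cycling`,
#'   `isokinetic`.
#' @param body_mass Body mass, kg, in (40, 120).
#' @param lever_arm Isokinetic lever-arm length, m.
#' @param crank_length Ergometer crank length, m.
#' @param latent_ability Latent between-test ability factor (dimensionless).
#' @return Object of class `subject_truth`.
#' @export
subject_truth <- function(id, profiles, body_mass, lever_arm = 0.28,
                          crank_length = 0.170, latent_ability = 0) {
  stopifnot(all(c("jump", "cycling", "isokinetic") %in% names(profiles)))
  for (p in profiles) stopifnot(inherits(p, "fv_profile"))
  if (!is.finite(body_mass) || body_mass <= 40 || body_mass >= 120) {
    stop("subject_truth: body_mass must lie in (40, 120) kg")
  }
  structure(
    list(id = as.character(id), profiles = profiles,
         body_mass = as.numeric(body_mass), lever_arm = as.numeric(lever_arm),
         crank_length = as.numeric(crank_length),
         latent_ability = as.numeric(latent_ability)),
    class = "subject_truth"
  )
}

# run expr under a local RNG stream; global .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed %% 2147483647)
  expr
}

#' Simulate one countermovement-jump force trace
#'
#' Quiet standing, a prescribed smooth (sinusoidal) unweighting-braking dip
#' to a given countermovement depth, then a concentric push-off whose
#' plateau force F* and peak velocity v* are the self-consistent solution
#' of the subject's linear F-V law and the push-off dynamics over the dip
#' depth d: F* = F0 - a v* with v* = sqrt(2 d (F* - Mg)/M). Force rises to
#' the plateau and decays to takeoff along half-cosine ramps (so the 10 Hz
#' measurement filter can track the signal), with the hold duration chosen
#' so the concentric velocity peaks exactly at v*: the measured concentric
#' maxima (F*, v*) lie on the truth line, which is what makes end-to-end
#' recovery of F0 and V0 well-defined. Flight follows at zero force;
#' Gaussian sensor noise is added throughout. The attached truth metadata
#' reports the concentric maxima of the noiseless profile computed by the
#' same trapezoidal impulse-momentum integration the pipeline uses.
#'
#' A profile too weak to leave the ground under the load (F0 <= Mg) returns
#' a no-jump trace flagged `no_takeoff` in the attached truth metadata.
#'
#' @param truth A [subject_truth()].
#' @param added_load Vest/belt load, kg.
#' @param noise_sd Force sensor noise SD, newtons.
#' @param seed RNG seed for this trial (NULL = use current RNG state).
#' @param rate Sampling rate, Hz.
#' @param depth Countermovement depth, m.
#' @param dip_duration Duration of the unweighting-braking dip, s.
#' @param quiet_s Quiet-standing lead-in, s (>= 1 for onset detection).
#' @param flight_s Flight segment recorded after takeoff, s.
#' @param rise_s,decay_s Half-cosine ramp durations of the concentric force
#'   plateau, s.
#' @return A [force_trace()] with attribute `truth`: a list with the true
#'   event times (`onset_s`, `lowest_s`, `takeoff_s`), true concentric peaks
#'   (`Fmax`, `Vmax`, `Pmax`), and `no_takeoff`.
#' @export
simulate_jump_trace <- function(truth, added_load = 1, noise_sd = 5,
                                seed = NULL, rate = 1000, depth = 0.25,
                                dip_duration = 0.8, quiet_s = 1.5,
                                flight_s = 0.3, rise_s = 0.10, decay_s = 0.15) {
  stopifnot(inherits(truth, "subject_truth"))
  prof <- truth$profiles$jump
  g <- 9.81
  M <- truth$body_mass + added_load
  W <- M * g
  dt <- 1 / rate

  n_q <- round(quiet_s * rate)
  t_dip <- seq_len(round(dip_duration * rate)) * dt
  A <- 2 * pi * M * depth / dip_duration^2   # dip force amplitude for depth d
  dip <- W - A * sin(2 * pi * t_dip / dip_duration)

  no_takeoff <- prof$F0 <= W * (1 + 1e-6)
  if (!no_takeoff) {
    a <- prof$slope_a
    # (M/2d) v^2 + a v + (W - F0) = 0, positive root
    v_star <- (-a + sqrt(a^2 + 2 * M * (prof$F0 - W) / depth)) * depth / M
    F_star <- prof$F0 - a * v_star
    acc <- (F_star - W) / M
    # velocity gained on the half-cosine rise W -> F*
    gain_rise <- (F_star - W) * rise_s / (2 * M)
    # velocity gained on the decay F* -> 0 until F crosses W (peak velocity)
    t_w <- decay_s / pi * acos(2 * W / F_star - 1)
    gain_decay <- (F_star / 2 * (t_w + decay_s / pi * sin(pi * t_w / decay_s)) -
                     W * t_w) / M
    t_hold <- max((v_star - gain_decay - gain_rise) / acc, 0)
    t_rise <- seq_len(round(rise_s * rate)) * dt
    t_dec <- seq_len(round(decay_s * rate)) * dt
    con <- c(W + (F_star - W) * (1 - cos(pi * t_rise / rise_s)) / 2,
             rep(F_star, round(t_hold * rate)),
             F_star * (1 + cos(pi * t_dec / decay_s)) / 2)
    fly <- rep(0, round(flight_s * rate))
    f <- c(rep(W, n_q), dip, con, fly)
    # bookkeeping: concentric maxima of the noiseless profile via the same
    # trapezoidal impulse-momentum integration the pipeline applies
    onset_i <- n_q + 1L
    lowest_i <- n_q + length(t_dip)
    takeoff_i <- lowest_i + length(con)
    vel <- cumtrapz((f[onset_i:takeoff_i] - W) / M, dt)
    con_i <- (lowest_i - onset_i + 1L):(takeoff_i - onset_i + 1L)
    fcon <- f[onset_i:takeoff_i][con_i]
    truth_meta <- list(
      no_takeoff = FALSE, onset_s = quiet_s,
      lowest_s = quiet_s + dip_duration,
      takeoff_s = (takeoff_i - 1) * dt,
      Fmax = max(fcon), Vmax = max(vel[con_i]),
      Pmax = max(fcon * vel[con_i]),
      F_star = F_star, v_star = v_star,
      added_load = added_load, system_weight = W)
  } else {
    # push at F0 (below weight): dips and stands back up, never flies
    con <- rep(min(prof$F0, W), round(0.5 * rate))
    f <- c(rep(W, n_q), dip, con, rep(W, round(0.5 * rate)))
    truth_meta <- list(no_takeoff = TRUE, onset_s = quiet_s,
                       lowest_s = quiet_s + dip_duration, takeoff_s = NA_real_,
                       Fmax = NA_real_, Vmax = NA_real_, Pmax = NA_real_,
                       added_load = added_load, system_weight = W)
  }
  if (noise_sd > 0) {
    f <- f + with_local_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  }
  tr <- force_trace(f, rate = rate, body_mass = truth$body_mass,
                    added_load = added_load)
  attr(tr, "truth") <- truth_meta
  tr
}

#' Simulate one maximal cycle-ergometer sprint
#'
#' Pedal velocity rises with first-order dynamics, v(t) = v_p (1 -
#' exp(-t/tau)), to a load-dependent plateau v_p(load) = (V0/2) * L_ref /
#' (L_ref + load): heavier flywheel load gives a lower plateau velocity and
#' a higher plateau force, and v_p never exceeds the optimal velocity V0/2,
#' so power is monotone along the trajectory and peaks at the plateau.
#' (A pure Coulomb-friction flywheel model cannot keep both the 2 kg and
#' the 10 kg plateau below V0/2 at a 5:1 load ratio, so the load-velocity
#' coupling is modelled directly; see the package vignette.)
#' At every instant the rider force follows the F-V law, and recorded power
#' is F(v) * v at the (noisy) cadence, so P = F v pointwise.
#'
#' @param truth A [subject_truth()].
#' @param flywheel_load Friction load, kg.
#' @param duration Sprint duration, s.
#' @param seed RNG seed for this trial.
#' @param cadence_cv Multiplicative cadence noise CV (device quantisation).
#' @param tau Velocity rise time constant, s.
#' @param load_ref Load half-saturation constant of the plateau mapping, kg.
#' @param rate Sampling rate of the device record, Hz.
#' @return A [cycling_record()] with attribute `truth`: plateau values
#'   (`Fmax`, `Vmax`, `Pmax`, `cadence_rpm`).
#' @export
simulate_cycling_sprint <- function(truth, flywheel_load = 6, duration = 6,
                                    seed = NULL, cadence_cv = 0.02, tau = 1.0,
                                    load_ref = 6, rate = 50) {
  stopifnot(inherits(truth, "subject_truth"))
  prof <- truth$profiles$cycling
  L <- truth$crank_length
  v_p <- (prof$V0 / 2) * load_ref / (load_ref + flywheel_load)
  tt <- seq(0, duration, by = 1 / rate)
  v <- v_p * (1 - exp(-tt / tau))
  if (cadence_cv > 0) {
    v <- v * (1 + with_local_seed(seed, stats::rnorm(length(tt), 0, cadence_cv)))
    v <- pmax(v, 0)
  }
  cad <- v * 60 / (2 * pi * L)
  pw <- pmax(predict_force(prof, v), 0) * v
  rec <- cycling_record(tt, pw, cad, flywheel_load = flywheel_load,
                        crank_length = L)
  attr(rec, "truth") <- list(
    Vmax = v_p, Fmax = predict_force(prof, v_p),
    Pmax = predict_force(prof, v_p) * v_p,
    cadence_rpm = v_p * 60 / (2 * pi * L), flywheel_load = flywheel_load)
  rec
}

#' Simulate one isokinetic knee-extension trial
#'
#' Force ramps linearly (default 0.3 s) to the plateau the F-V law predicts
#' at the device velocity, F = F(omega * pi/180 * lever_arm), holds, then
#' ramps down, with Gaussian sensor noise. A device velocity at or beyond
#' V0 is infeasible (the law predicts non-positive force).
#'
#' @param truth A [subject_truth()].
#' @param omega Device angular velocity, deg/s.
#' @param seed RNG seed for this trial.
#' @param noise_sd Force sensor noise SD, newtons.
#' @param rate Sampling rate, Hz.
#' @param rise_s Ramp-up (and ramp-down) duration, s.
#' @param plateau_s Plateau duration, s.
#' @param pad_s Zero-force padding at each end, s.
#' @return An [isokinetic_trace()] with attribute `truth` (`Fmax`, `Vmax`,
#'   `Pmax`).
#' @export
simulate_isokinetic_trial <- function(truth, omega = 60, seed = NULL,
                                      noise_sd = 8, rate = 500, rise_s = 0.3,
                                      plateau_s = 1.5, pad_s = 0.2) {
  stopifnot(inherits(truth, "subject_truth"))
  prof <- truth$profiles$isokinetic
  v <- angular_to_linear(omega, truth$lever_arm)
  if (v >= prof$V0) {
    stop("simulate_isokinetic_trial: infeasible velocity, ", omega,
         " deg/s maps to ", signif(v, 4), " m/s >= V0 = ",
         signif(prof$V0, 4), " m/s")
  }
  Fp <- predict_force(prof, v)
  n_pad <- round(pad_s * rate); n_rise <- round(rise_s * rate)
  ramp <- Fp * (1 - cos(pi * seq_len(n_rise) / n_rise)) / 2  # smooth corners
  f <- c(rep(0, n_pad), ramp, rep(Fp, round(plateau_s * rate)),
         rev(ramp), rep(0, n_pad))
  if (noise_sd > 0) {
    f <- f + with_local_seed(seed, stats::rnorm(length(f), 0, noise_sd))
  }
  tr <- isokinetic_trace(f, rate = rate, angular_velocity = omega,
                         lever_arm = truth$lever_arm)
  attr(tr, "truth") <- list(Fmax = Fp, Vmax = v, Pmax = Fp * v, omega = omega)
  tr
}

#' Cohort generator configuration
#'
#' The default cohort emulates the study population the package targets:
#' n = 12 physically active women, body mass 67.4 +/- 6.2 kg, jump loads
#' {1, 24} kg (vest unloaded vs loaded) with 2 trials each, cycling sprints
#' at {2, 10} kg (two-point) plus the standard 6 kg load with 1 trial each,
#' and isokinetic trials at {60, 180} deg/s with 2 trials each. Between-test
#' structure is imposed on log F0 and log P0 via equicorrelated Gaussian
#' latents; see the vignette for the induced log V0 correlation.
#'
#' @param n_subjects Number of subjects.
#' @param seed Master seed; all trial-level streams derive from it.
#' @param r_F0,r_P0 Target between-test correlations of log F0 and log P0.
#' @param cv_F0,cv_V0 Between-subject coefficients of variation of the true
#'   F0 and V0 (log-normal).
#' @param body_mass_mean,body_mass_sd Body mass distribution, kg.
#' @param profile_means Named list per test of `c(F0 = , V0 = )` population
#'   means.
#' @param jump_loads,cycling_loads,iso_omegas Two-point conditions per test.
#' @param cycling_standard_load Standard-test flywheel load, kg.
#' @param n_jump_trials,n_iso_trials Trials per condition.
#' @param jump_noise_sd,iso_noise_sd Force noise SDs, N.
#' @param cadence_cv Cycling cadence noise CV.
#' @param lever_arm_mean,lever_arm_sd Lever-arm distribution, m.
#' @param crank_length Crank length, m.
#' @param jump_depth Countermovement depth, m.
#' @param min_loaded_takeoff_mps Screening threshold: a drawn subject whose
#'   predicted takeoff velocity under the heaviest jump load falls below
#'   this value is redrawn, emulating the study-entry requirement that every
#'   participant can actually jump with the loaded vest (0.6 m/s is a
#'   2 cm rise of the centre of mass -- barely leaving the ground).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 12, seed = 42, r_F0 = 0.6, r_P0 = 0.7,
                          cv_F0 = 0.15, cv_V0 = 0.15,
                          body_mass_mean = 67.4, body_mass_sd = 6.2,
                          profile_means = list(
                            jump = c(F0 = 1700, V0 = 4.5),
                            cycling = c(F0 = 600, V0 = 3.4),
                            isokinetic = c(F0 = 520, V0 = 2.6)),
                          jump_loads = c(1, 24), cycling_loads = c(2, 10),
                          cycling_standard_load = 6, iso_omegas = c(60, 180),
                          n_jump_trials = 2, n_iso_trials = 2,
                          jump_noise_sd = 5, iso_noise_sd = 8,
                          cadence_cv = 0.02,
                          lever_arm_mean = 0.28, lever_arm_sd = 0.02,
                          crank_length = 0.170, jump_depth = 0.25,
                          min_loaded_takeoff_mps = 0.6) {
  if (abs(r_F0) > 1 || abs(r_P0) > 1) {
    stop("cohort_config: correlation targets must lie in [-1, 1]")
  }
  cfg <- as.list(environment())
  # log V0 correlation implied by the F0 and P0 targets (equal CVs assumed
  # in the inversion; exact when cv_F0 == cv_V0)
  s2F <- log(1 + cv_F0^2); s2V <- log(1 + cv_V0^2)
  cfg$r_V0 <- (r_P0 * (s2F + s2V) - r_F0 * s2F) / s2V
  for (rho in c(cfg$r_F0, cfg$r_V0)) {
    if (rho < -0.5 || rho > 1) {
      stop("cohort_config: infeasible correlation targets, the implied ",
           "3-test equicorrelation matrix is not positive semi-definite ",
           "(log V0 correlation = ", signif(cfg$r_V0, 3), ")")
    }
  }
  class(cfg) <- "cohort_config"
  cfg
}

# equicorrelated standard-normal triple via one shared + independent parts;
# chol fallback handles negative rho in [-0.5, 0)
req_triple <- function(rho) {
  if (rho >= 0) {
    gshare <- stats::rnorm(1)
    sqrt(rho) * gshare + sqrt(1 - rho) * stats::rnorm(3)
  } else {
    S <- matrix(rho, 3, 3); diag(S) <- 1
    drop(chol(S) %*% stats::rnorm(3))   # upper-tri crossprod form
  }
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject ground-truth F-V profiles from a log-normal
#' between-subject model with the requested between-test correlation
#' structure, then forward-simulates every trial of every test and load
#' condition. All randomness flows from `config$seed` through per-trial
#' streams, so any single trial is reproducible in isolation.
#'
#' @param config A [cohort_config()].
#' @return A list of class `fv_cohort` with elements `config`, `subjects`
#'   (list of [subject_truth()]), `truth` (data.frame registry of true
#'   F0/V0/P0 per subject x test) and `trials` (list; each element has
#'   `subject_id`, `test`, `condition_label`, `role` -- `"two_point"`,
#'   `"standard"` or `"both"` -- the condition value, and the simulated
#'   trace/record carrying its own truth attribute).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  tests <- c("jump", "cycling", "isokinetic")

  # predicted loaded takeoff velocity of the push-off dynamics (see
  # simulate_jump_trace); used to screen out subjects the study design
  # would not have admitted
  loaded_takeoff <- function(prof, body_mass) {
    M <- body_mass + max(cfg$jump_loads)
    W <- M * 9.81
    if (prof$F0 <= W) return(0)
    a <- prof$slope_a; d <- cfg$jump_depth
    (-a + sqrt(a^2 + 2 * M * (prof$F0 - W) / d)) * d / M
  }

  subjects <- with_local_seed(cfg$seed, {
    lapply(seq_len(cfg$n_subjects), function(i) {
      for (attempt in 1:100) {
        zF <- req_triple(cfg$r_F0)
        zV <- req_triple(cfg$r_V0)
        sF <- sqrt(log(1 + cfg$cv_F0^2)); sV <- sqrt(log(1 + cfg$cv_V0^2))
        profs <- list()
        for (k in seq_along(tests)) {
          mu <- cfg$profile_means[[tests[k]]]
          F0 <- exp(log(mu[["F0"]]) - sF^2 / 2 + sF * zF[k])
          V0 <- exp(log(mu[["V0"]]) - sV^2 / 2 + sV * zV[k])
          profs[[tests[k]]] <- fv_profile(F0, V0)
        }
        bm <- min(max(stats::rnorm(1, cfg$body_mass_mean, cfg$body_mass_sd),
                      40.5), 119.5)
        if (loaded_takeoff(profs$jump, bm) >= cfg$min_loaded_takeoff_mps) break
      }
      la <- min(max(stats::rnorm(1, cfg$lever_arm_mean, cfg$lever_arm_sd),
                    0.2), 0.4)
      subject_truth(sprintf("S%02d", i), profs, body_mass = bm,
                    lever_arm = la, crank_length = cfg$crank_length,
                    latent_ability = mean(zF))
    })
  })

  truth <- do.call(rbind, lapply(subjects, function(s) {
    do.call(rbind, lapply(tests, function(tst) {
      p <- s$profiles[[tst]]
      data.frame(subject_id = s$id, test = tst, F0 = p$F0, V0 = p$V0,
                 slope_a = p$slope_a, P0 = p$P0, body_mass = s$body_mass,
                 stringsAsFactors = FALSE)
    }))
  }))

  trials <- list()
  ctr <- 0L
  tseed <- function() {
    ctr <<- ctr + 1L
    (cfg$seed * 7919 + ctr) %% 2147483647
  }
  add <- function(entry) trials[[length(trials) + 1L]] <<- entry

  for (s in subjects) {
    for (load in sort(cfg$jump_loads)) {
      role <- if (load == min(cfg$jump_loads)) "both" else "two_point"
      for (k in seq_len(cfg$n_jump_trials)) {
        tr <- simulate_jump_trace(s, added_load = load,
                                  noise_sd = cfg$jump_noise_sd, seed = tseed(),
                                  depth = cfg$jump_depth)
        add(list(subject_id = s$id, test = "jump",
                 condition_label = sprintf("load %g kg", load), role = role,
                 condition = load, trial = k, object = tr))
      }
    }
    cyc_loads <- sort(unique(c(cfg$cycling_loads, cfg$cycling_standard_load)))
    for (load in cyc_loads) {
      role <- if (load %in% cfg$cycling_loads && load == cfg$cycling_standard_load) {
        "both"
      } else if (load %in% cfg$cycling_loads) "two_point" else "standard"
      rec <- simulate_cycling_sprint(s, flywheel_load = load, seed = tseed(),
                                     cadence_cv = cfg$cadence_cv)
      add(list(subject_id = s$id, test = "cycling",
               condition_label = sprintf("load %g kg", load), role = role,
               condition = load, trial = 1L, object = rec))
    }
    for (omega in sort(cfg$iso_omegas)) {
      for (k in seq_len(cfg$n_iso_trials)) {
        tr <- simulate_isokinetic_trial(s, omega = omega, seed = tseed(),
                                        noise_sd = cfg$iso_noise_sd)
        add(list(subject_id = s$id, test = "isokinetic",
                 condition_label = sprintf("%g deg/s", omega), role = "both",
                 condition = omega, trial = k, object = tr))
      }
    }
  }

  structure(list(config = cfg, subjects = subjects, truth = truth,
                 trials = trials),
            class = "fv_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits per-trial CSVs in the formats the pipeline readers expect, plus
#' `subjects.csv`, `trials.csv` (the manifest) and `truth.csv` (the
#' ground-truth registry).
#'
#' @param cohort An `fv_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trials"), showWarnings = FALSE)

  subj <- do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$id, body_mass = s$body_mass,
               lever_arm = s$lever_arm, crank_length = s$crank_length,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)

  rows <- lapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]
    fname <- sprintf("trials/%s_%s_%g_t%d.csv", tr$subject_id, tr$test,
                     tr$condition, tr$trial)
    path <- file.path(dir, fname)
    switch(tr$test,
           jump = write_jump_csv(tr$object, path),
           cycling = write_cycling_csv(tr$object, path),
           isokinetic = write_isokinetic_csv(tr$object, path))
    data.frame(subject_id = tr$subject_id, test = tr$test,
               condition_label = tr$condition_label, role = tr$role,
               condition = tr$condition, trial = tr$trial, file = fname,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "trials.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
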