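#' Vertical ground-reaction force record of one jump trial
#'
#' Uniformly sampled vertical GRF with the metadata needed for
#' impulse-momentum processing. At least one second of quiet standing must
#' precede the movement so that system weight and the onset threshold can be
#' estimated from the signal itself.
#'
#' @param samples Vertical GRF, newtons.
#' @param rate Sampling rate, Hz (jump convention: 1000).
#' @param body_mass Body mass, kg (metadata; dynamics use plate-derived mass).
#' @param added_load Vest/belt load, kg.
#' @param gravity Gravitational acceleration, m/s^2.
#' @return Object of class `force_trace`.
#' @export
force_trace <- function(samples, rate, body_mass = NA_real_, added_load = 0,
                        gravity = 9.81) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("force_trace: samples must be finite")
  if (!is.finite(rate) || rate <= 0) stop("force_trace: rate must be > 0")
  structure(
    list(samples = samples, rate = as.numeric(rate),
         body_mass = as.numeric(body_mass), added_load = as.numeric(added_load),
         gravity = as.numeric(gravity)),
    class = "force_trace"
  )
}

#' Low-pass filter a jump force trace
#'
#' Causal (single-pass recursive) second-order Butterworth at 10 Hz, the
#' force-plate jump convention. The small group delay of the causal pass is
#' accepted; compare [lowpass_zero_phase()] used for isokinetic records.
#'
#' @param trace A [force_trace()].
#' @param cutoff_hz Cutoff, Hz.
#' @return A filtered [force_trace()].
#' @export
lowpass_jump <- function(trace, cutoff_hz = 10) {
  stopifnot(inherits(trace, "force_trace"))
  out <- trace
  out$samples <- lowpass_causal(trace$samples, trace$rate, cutoff_hz)
  out
}

#' Jump phase boundaries
#'
#' @param onset_index First sample where the force leaves quiet standing.
#' @param lowest_com_index Sample of the lowest centre-of-mass position
#'   (start of the concentric phase).
#' @param takeoff_index First flight sample (start of the flight phase).
#' @param system_weight Quiet-standing force, newtons (plate-derived).
#' @return Object of class `jump_phases`.
#' @export
jump_phases <- function(onset_index, lowest_com_index, takeoff_index,
                        system_weight = NA_real_) {
  idx <- c(onset_index, lowest_com_index, takeoff_index)
  if (any(!is.finite(idx)) || any(idx < 1)) stop("jump_phases: invalid indices")
  if (!(onset_index < lowest_com_index && lowest_com_index < takeoff_index)) {
    stop("jump_phases: need onset < lowest_com < takeoff (got ",
         paste(idx, collapse = " < "), ")")
  }
  structure(list(onset_index = as.integer(onset_index),
                 lowest_com_index = as.integer(lowest_com_index),
                 takeoff_index = as.integer(takeoff_index),
                 system_weight = system_weight),
            class = "jump_phases")
}

#' Detect movement onset, lowest position and takeoff
#'
#' System weight W and its noise SD are estimated from the first
#' `quiet_window_s` of quiet standing. Onset is the first sample where
#' |F - W| exceeds `max(onset_sd * SD, min_onset_N)`, backtracked to the
#' last sample inside 1 SD of W. Takeoff is the first later sample with
#' F below `flight_threshold_N`. The lowest centre-of-mass position is the
#' minimum of twice-integrated net force between onset and takeoff.
#'
#' @param trace A (filtered) [force_trace()].
#' @param onset_sd Onset threshold in quiet-standing SDs.
#' @param flight_threshold_N Flight threshold, newtons.
#' @param quiet_window_s Length of the quiet-standing window, seconds.
#' @param min_onset_N Floor of the onset threshold, newtons.
#' @return A [jump_phases()].
#' @export
detect_phases <- function(trace, onset_sd = 5, flight_threshold_N = 10,
                          quiet_window_s = 1, min_onset_N = 10) {
  stopifnot(inherits(trace, "force_trace"))
  f <- trace$samples
  n <- length(f)
  qn <- round(quiet_window_s * trace$rate)
  if (qn < 2L || qn >= n) stop("detect_phases: trace too short for the quiet window")
  W <- mean(f[1:qn])
  s <- stats::sd(f[1:qn])
  thr <- max(onset_sd * s, min_onset_N)

  dev <- abs(f - W)
  cand <- which(dev[(qn + 1L):n] > thr)
  if (length(cand) == 0L) {
    stop("detect_phases: no movement found (|F - W| never exceeded ",
         signif(thr, 4), " N)")
  }
  onset <- qn + cand[1L]
  # backtrack to the last crossing of 1 SD before the threshold crossing
  while (onset > 2L && dev[onset - 1L] > s) onset <- onset - 1L

  after <- which(f[(onset + 1L):n] < flight_threshold_N)
  if (length(after) == 0L) {
    stop("detect_phases: no takeoff found (force never fell below ",
         flight_threshold_N, " N)")
  }
  takeoff <- onset + after[1L]

  # lowest position: double integral of (F - W)/M from onset
  M <- W / trace$gravity
  dt <- 1 / trace$rate
  seg <- onset:takeoff
  acc <- (f[seg] - W) / M
  vel <- cumtrapz(acc, dt)
  pos <- cumtrapz(vel, dt)
  lowest <- seg[which.min(pos)]
  if (!(onset < lowest && lowest < takeoff)) {
    stop("detect_phases: inconsistent phases (onset ", onset, ", lowest ",
         lowest, ", takeoff ", takeoff, ")")
  }
  jump_phases(onset, lowest, takeoff, system_weight = W)
}

# cumulative trapezoidal integral with y[1] = 0
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((y[-1L] + y[-n]) / 2) * dt)
}

#' Impulse-momentum kinematics of a jump trace
#'
#' Acceleration a(t) = (F(t) - W)/M with plate-derived system weight
#' W (quiet-standing mean) and M = W/g; velocity and position by cumulative
#' trapezoidal integration from onset (v(onset) = 0); power P(t) = F(t)v(t).
#'
#' @param trace A (filtered) [force_trace()].
#' @param phases A [jump_phases()] from [detect_phases()].
#' @return A data.frame over samples `onset_index:length(trace)` with
#'   columns `index`, `time_s`, `force_N`, `accel_mps2`, `velocity_mps`,
#'   `position_m`, `power_W`.
#' @export
compute_kinematics <- function(trace, phases) {
  stopifnot(inherits(trace, "force_trace"), inherits(phases, "jump_phases"))
  f <- trace$samples
  W <- phases$system_weight
  if (!is.finite(W)) W <- mean(f[1:round(trace$rate)])
  M <- W / trace$gravity
  dt <- 1 / trace$rate
  idx <- phases$onset_index:length(f)
  acc <- (f[idx] - W) / M
  vel <- cumtrapz(acc, dt)
  pos <- cumtrapz(vel, dt)
  data.frame(index = idx, time_s = (idx - 1) * dt, force_N = f[idx],
             accel_mps2 = acc, velocity_mps = vel, position_m = pos,
             power_W = f[idx] * vel)
}

#' Extract concentric-phase maxima from a jump trial
#'
#' Runs the whole jump chain: 10 Hz causal low-pass, phase detection,
#' impulse-momentum integration, then the maxima of force, velocity and
#' power taken *independently* over the concentric phase (lowest position to
#' takeoff). Note the three maxima need not occur at the same sample.
#'
#' @param trace A raw [force_trace()].
#' @param cutoff_hz Jump filter cutoff, Hz.
#' @param onset_sd,flight_threshold_N,quiet_window_s See [detect_phases()].
#' @param condition_label Label stored in the result (defaults to the added
#'   load).
#' @return A [trial_metrics()] with extra fields `takeoff_velocity_mps` and
#'   `phases`.
#' @export
extract_jump_metrics <- function(trace, cutoff_hz = 10, onset_sd = 5,
                                 flight_threshold_N = 10, quiet_window_s = 1,
                                 condition_label = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  filt <- lowpass_jump(trace, cutoff_hz)
  phases <- detect_phases(filt, onset_sd = onset_sd,
                          flight_threshold_N = flight_threshold_N,
                          quiet_window_s = quiet_window_s)
  kin <- compute_kinematics(filt, phases)
  con <- kin$index >= phases$lowest_com_index & kin$index <= phases$takeoff_index
  if (is.null(condition_label)) {
    condition_label <- sprintf("load %g kg", trace$added_load)
  }
  trial_metrics(
    Fmax = max(kin$force_N[con]),
    Vmax = max(kin$velocity_mps[con]),
    Pmax = max(kin$power_W[con]),
    condition_label = condition_label,
    extra = list(
      takeoff_velocity_mps = kin$velocity_mps[kin$index == phases$takeoff_index],
      phases = phases)
  )
}

#' Read a jump trial CSV
#'
#' Expects a header with columns `time_s` and `force_N`; time must be
#' uniform and increasing. The sampling rate is inferred from the time
#' column.
#'
#' @param path CSV path.
#' @param body_mass,added_load,gravity Metadata passed to [force_trace()].
#' @return A [force_trace()].
#' @export
read_jump_csv <- function(path, body_mass = NA_real_, added_load = 0,
                          gravity = 9.81) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "force_N") %in% names(df))) {
    stop("read_jump_csv: ", path, " must have columns time_s, force_N")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6) {
    stop("read_jump_csv: time_s must be uniform and increasing")
  }
  force_trace(df$force_N, rate = 1 / mean(dt), body_mass = body_mass,
              added_load = added_load, gravity = gravity)
}

#' @rdname read_jump_csv
#' @param trace A [force_trace()] to write.
#' @export
write_jump_csv <- function(trace, path) {
  n <- length(trace$samples)
  df <- data.frame(time_s = round((seq_len(n) - 1) / trace$rate, 6),
                   force_N = round(trace$samples, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
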