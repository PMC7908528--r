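#' Isokinetic knee-extension force record
#'
#' Force-time record from an isokinetic dynamometer at a fixed angular
#' velocity. Velocity is device-constrained and treated as constant within
#' a trial; the lever-arm length converts it to a linear velocity so that
#' results are comparable with the other tests.
#'
#' @param samples Force, newtons.
#' @param rate Sampling rate, Hz (convention: 500).
#' @param angular_velocity Device angular velocity, deg/s (> 0).
#' @param lever_arm Individual lever-arm length, metres, in (0.15, 0.6).
#' @return Object of class `isokinetic_trace`.
#' @export
isokinetic_trace <- function(samples, rate = 500, angular_velocity, lever_arm) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("isokinetic_trace: samples must be finite")
  if (!is.finite(rate) || rate <= 0) stop("isokinetic_trace: rate must be > 0")
  if (!is.finite(angular_velocity) || angular_velocity <= 0) {
    stop("isokinetic_trace: angular_velocity must be > 0")
  }
  if (!is.finite(lever_arm) || lever_arm <= 0.15 || lever_arm >= 0.6) {
    stop("isokinetic_trace: lever_arm must lie in (0.15, 0.6) m")
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         angular_velocity = as.numeric(angular_velocity),
         lever_arm = as.numeric(lever_arm)),
    class = "isokinetic_trace"
  )
}

#' Zero-phase low-pass of an isokinetic trace
#'
#' Second-order Butterworth at 5 Hz applied forward then backward (zero net
#' phase), with one second of reflective padding at each end so the edges do
#' not ring.
#'
#' @param trace An [isokinetic_trace()].
#' @param cutoff_hz Cutoff, Hz.
#' @return A filtered [isokinetic_trace()].
#' @export
zero_phase_lowpass <- function(trace, cutoff_hz = 5) {
  stopifnot(inherits(trace, "isokinetic_trace"))
  out <- trace
  out$samples <- lowpass_zero_phase(trace$samples, trace$rate, cutoff_hz)
  out
}

#' Angular to linear velocity
#'
#' v = omega (in rad/s) * lever_arm, i.e. `angular_deg_s * pi/180 * lever_arm`.
#'
#' @param angular_deg_s Angular velocity, deg/s (> 0).
#' @param lever_arm Lever-arm length, metres (> 0).
#' @return Linear velocity, m/s.
#' @examples
#' angular_to_linear(180, 0.30)  # 0.9425 m/s
#' @export
angular_to_linear <- function(angular_deg_s, lever_arm) {
  if (any(angular_deg_s <= 0)) stop("angular_to_linear: angular velocity must be > 0")
  if (any(lever_arm <= 0)) stop("angular_to_linear: lever arm must be > 0")
  angular_deg_s * pi / 180 * lever_arm
}

#' Extract maxima from an isokinetic trial
#'
#' Filters the trace (5 Hz zero-phase), then takes the peak force over the
#' central part of the record: the first and last `exclusion_fraction` of
#' samples are excluded because the dynamometer accelerates/decelerates
#' there and the constant-velocity assumption does not hold. Vmax is the
#' constant device velocity converted to m/s; Pmax = Fmax * Vmax.
#'
#' @param trace An [isokinetic_trace()].
#' @param cutoff_hz Filter cutoff, Hz.
#' @param exclusion_fraction Fraction of samples dropped at each end of the
#'   peak search (0 disables).
#' @param condition_label Label; defaults to the angular velocity.
#' @return A [trial_metrics()].
#' @export
extract_isokinetic_metrics <- function(trace, cutoff_hz = 5,
                                       exclusion_fraction = 0.1,
                                       condition_label = NULL) {
  stopifnot(inherits(trace, "isokinetic_trace"))
  n <- length(trace$samples)
  if (n < 8L) stop("extract_isokinetic_metrics: trace too short")
  filt <- zero_phase_lowpass(trace, cutoff_hz)
  drop <- floor(n * exclusion_fraction)
  lo <- max(1L, drop + 1L)
  hi <- min(n, n - drop)
  Fmax <- max(filt$samples[lo:hi])
  Vmax <- angular_to_linear(trace$angular_velocity, trace$lever_arm)
  if (is.null(condition_label)) {
    condition_label <- sprintf("%g deg/s", trace$angular_velocity)
  }
  trial_metrics(Fmax = Fmax, Vmax = Vmax, Pmax = Fmax * Vmax,
                condition_label = condition_label)
}

#' Read / write an isokinetic trial CSV
#'
#' Columns: `time_s`, `force_N`; angular velocity and lever arm come from
#' trial metadata.
#'
#' @param path CSV path.
#' @param angular_velocity,lever_arm Metadata for [isokinetic_trace()].
#' @return An [isokinetic_trace()].
#' @export
read_isokinetic_csv <- function(path, angular_velocity, lever_arm) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "force_N") %in% names(df))) {
    stop("read_isokinetic_csv: ", path, " must have columns time_s, force_N")
  }
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("read_isokinetic_csv: time_s must be increasing")
  isokinetic_trace(df$force_N, rate = 1 / mean(dt),
                   angular_velocity = angular_velocity, lever_arm = lever_arm)
}

#' @rdname read_isokinetic_csv
#' @param trace An [isokinetic_trace()] to write.
#' @export
write_isokinetic_csv <- function(trace, path) {
  n <- length(trace$samples)
  df <- data.frame(time_s = round((seq_len(n) - 1) / trace$rate, 6),
                   force_N = round(trace$samples, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
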