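#' Cycle-ergometer sprint record
#'
#' Per-sample power and cadence from the ergometer software during a
#' maximal sprint against a friction-loaded flywheel, plus the crank length
#' needed to convert cadence to linear pedal velocity.
#'
#' @param time_s Sample times, seconds, increasing.
#' @param power_W Power, watts (>= 0).
#' @param cadence_rpm Cadence, revolutions per minute (>= 0).
#' @param flywheel_load Friction load, kg.
#' @param crank_length Crank length, metres, in (0.1, 0.25).
#' @return Object of class `cycling_record`.
#' @export
cycling_record <- function(time_s, power_W, cadence_rpm, flywheel_load = NA_real_,
                           crank_length = 0.170) {
  n <- length(time_s)
  stopifnot(length(power_W) == n, length(cadence_rpm) == n, n >= 1L)
  if (any(power_W < 0)) stop("cycling_record: power must be >= 0")
  if (any(cadence_rpm < 0)) stop("cycling_record: cadence must be >= 0")
  if (!is.finite(crank_length) || crank_length <= 0.1 || crank_length >= 0.25) {
    stop("cycling_record: crank_length must lie in (0.1, 0.25) m")
  }
  structure(
    list(time_s = as.numeric(time_s), power_W = as.numeric(power_W),
         cadence_rpm = as.numeric(cadence_rpm),
         flywheel_load = as.numeric(flywheel_load),
         crank_length = as.numeric(crank_length)),
    class = "cycling_record"
  )
}

#' Linear pedal velocity from cadence
#'
#' v = 2 * pi * crank_length * cadence / 60: the tangential speed of the
#' pedal at the given revolution frequency.
#'
#' @param cadence_rpm Cadence, rev/min (vectorised, >= 0).
#' @param crank_length Crank length, metres.
#' @return Pedal velocity, m/s.
#' @examples
#' pedal_velocity(120, 0.17)  # 2.136 m/s
#' @export
pedal_velocity <- function(cadence_rpm, crank_length) {
  if (any(cadence_rpm < 0)) stop("pedal_velocity: cadence must be >= 0")
  2 * pi * crank_length * cadence_rpm / 60
}

#' Force from power and velocity
#'
#' F = P / v, the tangential pedal force equivalent of the recorded power.
#'
#' @param power_W Power, watts (vectorised).
#' @param velocity_mps Velocity, m/s; must be strictly positive.
#' @return Force, newtons.
#' @export
force_from_power <- function(power_W, velocity_mps) {
  if (any(velocity_mps <= 0)) {
    stop("force_from_power: force is undefined at velocity <= 0")
  }
  power_W / velocity_mps
}

#' Extract sprint maxima from a cycling record
#'
#' Cadence is smoothed with a centred moving average (device cadence is
#' quantised per revolution) before peak picking. Pmax is the maximum of
#' the raw power channel; Vmax the pedal velocity at the (smoothed) cadence
#' maximum; Fmax is power over velocity *at the sample of maximal power* --
#' not max(P/V), which rewards near-zero-velocity start-up samples. The
#' velocity at the peak-power instant is also reported (`V_at_Pmax`).
#'
#' @param record A [cycling_record()].
#' @param smooth_window_s Moving-average window, seconds (0 disables).
#' @param condition_label Label; defaults to the flywheel load.
#' @return A [trial_metrics()] with extra field `V_at_Pmax`.
#' @export
extract_cycling_metrics <- function(record, smooth_window_s = 0.5,
                                    condition_label = NULL) {
  stopifnot(inherits(record, "cycling_record"))
  if (all(record$cadence_rpm == 0)) {
    stop("extract_cycling_metrics: cadence is zero throughout the record")
  }
  n <- length(record$time_s)
  cad <- record$cadence_rpm
  if (smooth_window_s > 0 && n > 2L) {
    dt <- if (n > 1L) stats::median(diff(record$time_s)) else smooth_window_s
    w <- max(1L, round(smooth_window_s / dt))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L && w < n) {
      half <- (w - 1L) %/% 2L
      cs <- cumsum(c(0, cad))
      lo <- pmax(seq_len(n) - half, 1L)
      hi <- pmin(seq_len(n) + half, n)
      cad <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
  }
  i_p <- which.max(record$power_W)
  v_at_p <- pedal_velocity(cad[i_p], record$crank_length)
  if (v_at_p <= 0) {
    stop("extract_cycling_metrics: zero velocity at the peak-power sample")
  }
  if (is.null(condition_label)) {
    condition_label <- sprintf("load %g kg", record$flywheel_load)
  }
  trial_metrics(
    Fmax = force_from_power(record$power_W[i_p], v_at_p),
    Vmax = pedal_velocity(max(cad), record$crank_length),
    Pmax = record$power_W[i_p],
    condition_label = condition_label,
    extra = list(V_at_Pmax = v_at_p)
  )
}

#' Read / write a cycling sprint CSV
#'
#' Columns: `time_s`, `power_W`, `cadence_rpm`.
#'
#' @param path CSV path.
#' @param flywheel_load,crank_length Metadata for [cycling_record()].
#' @return A [cycling_record()].
#' @export
read_cycling_csv <- function(path, flywheel_load = NA_real_, crank_length = 0.170) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "power_W", "cadence_rpm")
  if (!all(need %in% names(df))) {
    stop("read_cycling_csv: ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  cycling_record(df$time_s, df$power_W, df$cadence_rpm,
                 flywheel_load = flywheel_load, crank_length = crank_length)
}

#' @rdname read_cycling_csv
#' @param record A [cycling_record()] to write.
#' @export
write_cycling_csv <- function(record, path) {
  df <- data.frame(time_s = round(record$time_s, 6),
                   power_W = round(record$power_W, 4),
                   cadence_rpm = round(record$cadence_rpm, 4))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
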