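#' Maximal force, velocity and power of one trial
#'
#' The Fmax / Vmax / Pmax triple extracted from a single maximal-effort
#' trial under one load condition. For the jump these are independent maxima
#' over the concentric phase; for cycling, trace maxima; for isokinetic
#' trials Vmax is the device velocity and Pmax = Fmax * Vmax.
#'
#' @param Fmax Peak force, newtons.
#' @param Vmax Peak velocity, m/s.
#' @param Pmax Peak power, watts. Must not exceed `Fmax * Vmax`.
#' @param condition_label Load-condition label.
#' @param extra Optional named list of auxiliary values (e.g. `V_at_Pmax`).
#' @return Object of class `trial_metrics`.
#' @export
trial_metrics <- function(Fmax, Vmax, Pmax, condition_label = "", extra = list()) {
  vals <- c(Fmax, Vmax, Pmax)
  if (!all(is.finite(vals))) stop("trial_metrics: Fmax, Vmax, Pmax must be finite")
  if (Pmax > Fmax * Vmax * (1 + 1e-9)) {
    stop("trial_metrics: Pmax (", signif(Pmax, 6), " W) exceeds Fmax*Vmax (",
         signif(Fmax * Vmax, 6), " W)")
  }
  structure(
    c(list(Fmax = as.numeric(Fmax), Vmax = as.numeric(Vmax),
           Pmax = as.numeric(Pmax),
           condition_label = as.character(condition_label)),
      extra),
    class = "trial_metrics"
  )
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf("<trial_metrics %s> Fmax = %.1f N, Vmax = %.3f m/s, Pmax = %.1f W\n",
              x$condition_label, x$Fmax, x$Vmax, x$Pmax))
  invisible(x)
}

#' Pick the best of repeated trials
#'
#' The trial with the highest peak power is kept for analysis (jump and
#' cycling convention); set `by = "Fmax"` for the isokinetic convention
#' (highest peak force). Ties keep the first occurrence.
#'
#' @param metrics_list Non-empty list of [trial_metrics()] from the same
#'   load condition.
#' @param by `"Pmax"` (default) or `"Fmax"`.
#' @return The selected [trial_metrics()].
#' @export
select_best_trial <- function(metrics_list, by = c("Pmax", "Fmax")) {
  by <- match.arg(by)
  if (!is.list(metrics_list) || length(metrics_list) == 0L) {
    stop("select_best_trial: need a non-empty list of trial_metrics")
  }
  ok <- vapply(metrics_list, inherits, logical(1), what = "trial_metrics")
  if (!all(ok)) stop("select_best_trial: all elements must be trial_metrics")
  vals <- vapply(metrics_list, function(m) m[[by]], numeric(1))
  metrics_list[[which.max(vals)]]  # which.max keeps the first tie
}
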