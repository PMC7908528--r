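#' One (force, velocity) observation from a single load condition
#'
#' A maximal-effort test performed under one external load (or one angular
#' velocity) yields a single point on the subject's force-velocity line:
#' the peak force and peak velocity reached in that condition.
#'
#' @param force Peak force in newtons; finite and strictly positive.
#' @param velocity Peak velocity in metres per second; finite and strictly
#'   positive.
#' @param condition_label Free-text label of the load condition, e.g.
#'   `"load 24 kg"` or `"180 deg/s"`.
#' @return An object of class `fv_point`.
#' @examples
#' fv_point(1500, 1.0, "load 24 kg")
#' @export
fv_point <- function(force, velocity, condition_label = "") {
  stopifnot(length(force) == 1L, length(velocity) == 1L)
  if (!is.finite(force) || force <= 0) {
    stop("fv_point: force must be finite and > 0 (got ", force, ")")
  }
  if (!is.finite(velocity) || velocity <= 0) {
    stop("fv_point: velocity must be finite and > 0 (got ", velocity, ")")
  }
  structure(
    list(force = as.numeric(force), velocity = as.numeric(velocity),
         condition_label = as.character(condition_label)),
    class = "fv_point"
  )
}

#' Linear force-velocity profile (F0, V0, slope a, P0)
#'
#' The linear F-V model F(v) = F0 - a * v with a = F0 / V0. F0 is the
#' force-axis intercept (theoretical maximal isometric-equivalent force), V0
#' the velocity-axis intercept (theoretical maximal unloaded velocity), and
#' P0 = F0 * V0 / 4 the apex of the parabolic power-velocity curve.
#'
#' The slope is stored as a positive magnitude `slope_a = F0 / V0`; the
#' fitted regression coefficient of force on velocity is its negation.
#'
#' @param F0 Force intercept, newtons (> 0).
#' @param V0 Velocity intercept, m/s (> 0).
#' @param body_mass Optional body mass in kg used only for a physiological
#'   range warning on F0.
#' @return An object of class `fv_profile` with fields `F0`, `V0`,
#'   `slope_a`, `P0`.
#' @examples
#' p <- fv_profile(2000, 4)
#' p$P0   # 2000 W
#' @export
fv_profile <- function(F0, V0, body_mass = NULL) {
  if (!is.finite(F0) || F0 <= 0) stop("fv_profile: F0 must be finite and > 0")
  if (!is.finite(V0) || V0 <= 0) stop("fv_profile: V0 must be finite and > 0")
  prof <- structure(
    list(F0 = as.numeric(F0), V0 = as.numeric(V0),
         slope_a = as.numeric(F0) / as.numeric(V0),
         P0 = as.numeric(F0) * as.numeric(V0) / 4),
    class = "fv_profile"
  )
  # extrapolation far beyond physiological range: warn, never error
  if (prof$V0 > 20) {
    warning("fv_profile: V0 = ", signif(prof$V0, 4),
            " m/s exceeds 20 m/s; extrapolation far beyond physiological range")
  }
  if (!is.null(body_mass) && is.finite(body_mass) && body_mass > 0 &&
      prof$F0 > 20 * body_mass * 9.81) {
    warning("fvtp_profile: F0 = ", signif(prof$F0, 4),
            " N exceeds 20 body weights; extrapolation far beyond physiological range")
  }
  prof
}

#' @export
print.fv_profile <- function(x, ...) {
  cat(sprintf(
    "<fv_profile> F0 = %.1f N, V0 = %.3f m/s, a = %.1f N.s/m, P0 = %.1f W\n",
    x$F0, x$V0, x$slope_a, x$P0))
  invisible(x)
}

#' Fit the two-point force-velocity model
#'
#' Draws the straight line through the (peak force, peak velocity) points of
#' two load conditions and extrapolates it to both axes: F0 is the force
#' intercept, V0 the velocity intercept, a = F0/V0 the (positive) slope
#' magnitude and P0 = F0*V0/4 the maximal power.
#'
#' @param p1,p2 [fv_point()] observations at two distinct velocities.
#' @param body_mass Optional body mass (kg) for range warnings.
#' @return An [fv_profile()].
#' @examples
#' fit_two_point(fv_point(1500, 1), fv_point(500, 3))  # F0 2000 N, V0 4 m/s
#' @export
fit_two_point <- function(p1, p2, body_mass = NULL) {
  stopifnot(inherits(p1, "fv_point"), inherits(p2, "fv_point"))
  dv <- p2$velocity - p1$velocity
  if (dv == 0) {
    stop("fit_two_point: degenerate fit, the two points have equal velocities (",
         p1$velocity, " m/s)")
  }
  slope <- (p2$force - p1$force) / dv      # regression coefficient, must be < 0
  if (slope >= 0) {
    stop("fit_two_point: invalid profile, force does not decrease with velocity ",
         "(slope = ", signif(slope, 4), " N.s/m >= 0)")
  }
  F0 <- p1$force - slope * p1$velocity
  V0 <- -F0 / slope
  if (F0 <= 0) stop("fit_two_point: invalid profile, force intercept F0 <= 0")
  if (V0 <= 0) stop("fit_two_point: invalid profile, velocity intercept V0 <= 0")
  fv_profile(F0, V0, body_mass = body_mass)
}

#' Fit the linear force-velocity model to two or more points
#'
#' Ordinary least squares of force on velocity. With exactly two points this
#' is identical to [fit_two_point()]; with more points it is the multi-load
#' regression model that the two-point method approximates.
#'
#' @param points A list of [fv_point()] objects, length >= 2, with at least
#'   two distinct velocities.
#' @param body_mass Optional body mass (kg) for range warnings.
#' @return An [fv_profile()].
#' @export
fit_linear <- function(points, body_mass = NULL) {
  stopifnot(is.list(points), length(points) >= 2L)
  ok <- vapply(points, inherits, logical(1), what = "fv_point")
  if (!all(ok)) stop("fit_linear: all elements must be fv_point objects")
  v <- vapply(points, function(p) p$velocity, numeric(1))
  f <- vapply(points, function(p) p$force, numeric(1))
  if (length(unique(v)) < 2L) {
    stop("fit_two_point: degenerate fit, need at least two distinct velocities")
  }
  if (length(v) == 2L) {
    # closed-form normal equations collapse to the exact two-point line
    return(fit_two_point(points[[1L]], points[[2L]], body_mass = body_mass))
  }
  fit <- stats::lm.fit(cbind(intercept = 1, velocity = v), f)
  F0 <- unname(fit$coefficients[1L])
  slope <- unname(fit$coefficients[2L])
  if (slope >= 0) {
    stop("fit_linear: invalid profile, fitted force-on-velocity slope >= 0")
  }
  if (F0 <= 0) stop("fit_linear: invalid profile, force intercept F0 <= 0")
  fv_profile(F0, -F0 / slope, body_mass = body_mass)
}

#' Evaluate the force-velocity line
#'
#' @param profile An [fv_profile()].
#' @param velocity Velocity in m/s, >= 0 (vectorised). Values beyond V0
#'   return negative force (the line is extrapolated as-is).
#' @return Predicted force in newtons.
#' @export
predict_force <- function(profile, velocity) {
  stopifnot(inherits(profile, "fv_profile"))
  if (any(velocity < 0)) stop("predict_force: velocity must be >= 0")
  profile$F0 - profile$slope_a * velocity
}

#' Apex of the power-velocity parabola
#'
#' Power along the F-V line is P(v) = v * (F0 - a v), a downward parabola
#' maximised at v = V0/2 where it equals P0 = F0*V0/4.
#'
#' @param profile An [fv_profile()].
#' @return A list with `velocity` (= V0/2, m/s) and `Pmax` (= P0, watts).
#' @export
apex_power <- function(profile) {
  stopifnot(inherits(profile, "fv_profile"))
  list(velocity = profile$V0 / 2, Pmax = profile$P0)
}

#' Write / read force-velocity profiles as CSV
#'
#' Serialises a set of per-subject, per-test profiles with columns
#' `subject_id, test, F0_N, V0_mps, slope_Nspm, P0_W`.
#'
#' @param profiles A data.frame with columns `subject_id`, `test` and a
#'   list-column `profile` of [fv_profile()] objects, or a named list of
#'   named lists (`profiles[[subject]][[test]]`).
#' @param path File path.
#' @return `write_profiles`: the data.frame written, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  df <- profiles_to_df(profiles)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' @rdname write_profiles
#' @return `read_profiles`: a data.frame with one row per subject x test and
#'   the serialised columns.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "test", "F0_N", "V0_mps", "slope_Nspm", "P0_W")
  if (!all(need %in% names(df))) {
    stop("read_profiles: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

profiles_to_df <- function(profiles) {
  if (is.data.frame(profiles)) {
    rows <- lapply(seq_len(nrow(profiles)), function(i) {
      pr <- profiles$profile[[i]]
      data.frame(subject_id = profiles$subject_id[i], test = profiles$test[i],
                 F0_N = pr$F0, V0_mps = pr$V0, slope_Nspm = pr$slope_a,
                 P0_W = pr$P0, stringsAsFactors = FALSE)
    })
  } else {
    rows <- list()
    for (sid in names(profiles)) {
      for (test in names(profiles[[sid]])) {
        pr <- profiles[[sid]][[test]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, test = test, F0_N = pr$F0, V0_mps = pr$V0,
          slope_Nspm = pr$slope_a, P0_W = pr$P0, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
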