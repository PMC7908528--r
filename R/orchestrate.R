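#' Default analysis configuration
#'
#' Nested list of every tunable processing parameter with the package
#' defaults: `jump$cutoff_hz` 10, `jump$onset_sd` 5,
#' `jump$flight_threshold_N` 10, `jump$quiet_window_s` 1,
#' `cycling$crank_length_m` 0.17, `cycling$smooth_window_s` 0.5,
#' `iso$cutoff_hz` 5, `iso$exclusion_fraction` 0.1.
#'
#' @return A nested list of class `fvtp_config`.
#' @export
fvtp_config <- function() {
  structure(list(
    jump = list(cutoff_hz = 10, onset_sd = 5, flight_threshold_N = 10,
                quiet_window_s = 1),
    cycling = list(crank_length_m = 0.170, smooth_window_s = 0.5),
    iso = list(cutoff_hz = 5, exclusion_fraction = 0.1)
  ), class = "fvtp_config")
}

#' Load a YAML configuration file over the defaults
#'
#' Keys present in the file override the matching defaults of
#' [fvtp_config()]; everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return An `fvtp_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- fvtp_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in intersect(names(user), names(cfg))) {
    for (key in intersect(names(user[[section]]), names(cfg[[section]]))) {
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  cfg
}

# extract trial metrics from an in-memory trial entry (see generate_cohort)
extract_trial_entry <- function(entry, config = fvtp_config()) {
  switch(entry$test,
    jump = extract_jump_metrics(
      entry$object, cutoff_hz = config$jump$cutoff_hz,
      onset_sd = config$jump$onset_sd,
      flight_threshold_N = config$jump$flight_threshold_N,
      quiet_window_s = config$jump$quiet_window_s,
      condition_label = entry$condition_label),
    cycling = extract_cycling_metrics(
      entry$object, smooth_window_s = config$cycling$smooth_window_s,
      condition_label = entry$condition_label),
    isokinetic = extract_isokinetic_metrics(
      entry$object, cutoff_hz = config$iso$cutoff_hz,
      exclusion_fraction = config$iso$exclusion_fraction,
      condition_label = entry$condition_label),
    stop("unknown test: ", entry$test))
}

#' Per-condition best-trial metrics for a whole cohort
#'
#' Runs the per-test pipeline on every trial and keeps, per subject x test
#' x condition, the best repeated trial: highest peak power for jump and
#' cycling, highest peak force for isokinetic trials.
#'
#' @param cohort An `fv_cohort` from [generate_cohort()], or a list with a
#'   compatible `trials` element.
#' @param config An [fvtp_config()].
#' @param log_fun Optional callback `function(line)` receiving structured
#'   log lines for failed trials.
#' @return A data.frame: `subject_id`, `test`, `condition_label`, `role`,
#'   `condition`, `Fmax`, `Vmax`, `Pmax`, `n_trials`.
#' @export
cohort_metrics <- function(cohort, config = fvtp_config(), log_fun = NULL) {
  say <- function(...) if (!is.null(log_fun)) log_fun(paste0(...))
  groups <- list()
  for (entry in cohort$trials) {
    key <- paste(entry$subject_id, entry$test, entry$condition_label, sep = "|")
    m <- tryCatch(extract_trial_entry(entry, config), error = function(e) e)
    if (inherits(m, "error")) {
      say("WARN subject=", entry$subject_id, " test=", entry$test,
          " condition=", entry$condition_label, " stage=metrics event=excluded",
          " reason=", conditionMessage(m))
      next
    }
    groups[[key]] <- c(groups[[key]] %||% list(),
                       list(list(entry = entry, metrics = m)))
  }
  rows <- lapply(groups, function(grp) {
    by <- if (grp[[1L]]$entry$test == "isokinetic") "Fmax" else "Pmax"
    best <- select_best_trial(lapply(grp, `[[`, "metrics"), by = by)
    e <- grp[[1L]]$entry
    data.frame(subject_id = e$subject_id, test = e$test,
               condition_label = e$condition_label, role = e$role,
               condition = e$condition, Fmax = best$Fmax, Vmax = best$Vmax,
               Pmax = best$Pmax, n_trials = length(grp),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$subject_id, df$test, df$condition), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-point profiles and standard-test metrics from cohort metrics
#'
#' For each subject x test, fits [fit_two_point()] through the
#' lowest-velocity and highest-velocity two-point conditions, and collects
#' the standard-test Fmax/Pmax: the jump standard condition is the unloaded
#' (lightest) jump, the cycling standard its flagged standard load, and the
#' isokinetic standard takes Fmax from the 60 deg/s trial and Pmax from the
#' 180 deg/s trial.
#'
#' @param metrics A data.frame from [cohort_metrics()].
#' @param log_fun Optional logging callback.
#' @return A list: `profiles` (data.frame subject_id, test, F0, V0, slope_a,
#'   P0), `profiles_by_test` and `standard_by_test` (named lists of
#'   data.frames as [build_comparison_table()] expects).
#' @export
fit_cohort_profiles <- function(metrics, log_fun = NULL) {
  say <- function(...) if (!is.null(log_fun)) log_fun(paste0(...))
  tests <- c("jump", "cycling", "isokinetic")
  prof_rows <- list(); std_rows <- list()
  for (sid in unique(metrics$subject_id)) {
    for (tst in tests) {
      sub <- metrics[metrics$subject_id == sid & metrics$test == tst, ]
      if (nrow(sub) == 0L) {
        say("WARN subject=", sid, " test=", tst,
            " stage=fit event=excluded reason=no usable trials")
        next
      }
      tp <- sub[sub$role %in% c("two_point", "both"), ]
      if (nrow(tp) >= 2L && length(unique(tp$Vmax)) >= 2L) {
        lo <- tp[which.min(tp$Vmax), ]; hi <- tp[which.max(tp$Vmax), ]
        prof <- tryCatch(
          fit_two_point(
            fv_point(lo$Fmax, lo$Vmax, lo$condition_label),
            fv_point(hi$Fmax, hi$Vmax, hi$condition_label)),
          error = function(e) e)
        if (inherits(prof, "error")) {
          say("WARN subject=", sid, " test=", tst,
              " stage=fit event=excluded reason=", conditionMessage(prof))
        } else {
          prof_rows[[length(prof_rows) + 1L]] <- data.frame(
            subject_id = sid, test = tst, F0 = prof$F0, V0 = prof$V0,
            slope_a = prof$slope_a, P0 = prof$P0, stringsAsFactors = FALSE)
        }
      } else {
        say("WARN subject=", sid, " test=", tst,
            " stage=fit event=excluded reason=fewer than 2 usable conditions")
      }
      # standard-test metrics
      if (tst == "isokinetic") {
        f60 <- sub[grepl("^60 ", sub$condition_label), ]
        f180 <- sub[grepl("^180 ", sub$condition_label), ]
        if (nrow(f60) == 1L && nrow(f180) == 1L) {
          std_rows[[length(std_rows) + 1L]] <- data.frame(
            subject_id = sid, test = tst, Fmax = f60$Fmax, Pmax = f180$Pmax,
            stringsAsFactors = FALSE)
        } else {
          say("WARN subject=", sid, " test=isokinetic stage=standard ",
              "event=excluded reason=missing 60 or 180 deg/s condition")
        }
      } else {
        std <- sub[sub$role %in% c("standard", "both"), ]
        if (tst == "jump" && nrow(std) > 1L) std <- std[which.min(std$condition), ]
        if (nrow(std) == 1L) {
          std_rows[[length(std_rows) + 1L]] <- data.frame(
            subject_id = sid, test = tst, Fmax = std$Fmax, Pmax = std$Pmax,
            stringsAsFactors = FALSE)
        } else {
          say("WARN subject=", sid, " test=", tst,
              " stage=standard event=excluded reason=no standard condition")
        }
      }
    }
  }
  profiles <- do.call(rbind, prof_rows)
  standard <- do.call(rbind, std_rows)
  split_by <- function(df) {
    out <- lapply(tests, function(tst) df[df$test == tst, , drop = FALSE])
    names(out) <- tests
    out
  }
  list(profiles = profiles,
       profiles_by_test = split_by(profiles),
       standard_by_test = split_by(standard))
}

#' Read a cohort manifest directory into trial entries
#'
#' Expects `subjects.csv` (subject_id, body_mass, lever_arm, crank_length)
#' and `trials.csv` (subject_id, test, condition_label, role, condition,
#' trial, file) as written by [write_cohort()]. Trial files are loaded with
#' the per-test readers. Trials referencing unknown subjects are an error;
#' unreadable files are skipped with a log line.
#'
#' @param dir Manifest directory.
#' @param log_fun Optional logging callback.
#' @return A list with `subjects` (data.frame) and `trials` (list of
#'   entries compatible with [cohort_metrics()]).
#' @export
read_manifest <- function(dir, log_fun = NULL) {
  say <- function(...) if (!is.null(log_fun)) log_fun(paste0(...))
  subj <- utils::read.csv(file.path(dir, "subjects.csv"),
                          stringsAsFactors = FALSE)
  man <- utils::read.csv(file.path(dir, "trials.csv"),
                         stringsAsFactors = FALSE)
  missing <- setdiff(unique(man$subject_id), subj$subject_id)
  if (length(missing) > 0L) {
    stop("read_manifest: trials reference unknown subjects: ",
         paste(missing, collapse = ", "))
  }
  trials <- list()
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    meta <- subj[subj$subject_id == row$subject_id, ]
    obj <- tryCatch(switch(
      row$test,
      jump = read_jump_csv(file.path(dir, row$file),
                           body_mass = meta$body_mass,
                           added_load = row$condition),
      cycling = read_cycling_csv(file.path(dir, row$file),
                                 flywheel_load = row$condition,
                                 crank_length = meta$crank_length),
      isokinetic = read_isokinetic_csv(file.path(dir, row$file),
                                       angular_velocity = row$condition,
                                       lever_arm = meta$lever_arm),
      stop("unknown test '", row$test, "'")), error = function(e) e)
    if (inherits(obj, "error")) {
      say("WARN subject=", row$subject_id, " test=", row$test,
          " stage=read event=excluded file=", row$file,
          " reason=", conditionMessage(obj))
      next
    }
    trials[[length(trials) + 1L]] <- list(
      subject_id = row$subject_id, test = row$test,
      condition_label = row$condition_label, role = row$role,
      condition = row$condition, trial = row$trial, object = obj)
  }
  list(subjects = subj, trials = trials)
}

#' Run the full two-point profiling study
#'
#' Ingests a cohort manifest (directory of trial CSVs, as written by
#' [write_cohort()]) or an in-memory `fv_cohort`, runs all three per-test
#' pipelines, keeps the best trial per condition, fits the two-point
#' profiles, collects standard-test maxima, and computes the
#' cross-test/concurrent-validity statistics. Deterministic given inputs.
#'
#' @param manifest A directory path or an `fv_cohort` object.
#' @param config An [fvtp_config()] (or path to a YAML overriding it).
#' @param out_dir If non-NULL, write `profiles.csv`, `metrics.csv`,
#'   `table1.csv`, `figure3.csv`, `comparisons.csv`, `run.log` and
#'   `effective_config.yaml` there.
#' @return A list: `metrics`, `profiles`, `standard`, `table1`, `figure3`,
#'   `comparisons`, `log` (character vector of structured lines).
#' @export
run_study <- function(manifest, config = fvtp_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  log_lines <- character()
  log_fun <- function(line) log_lines <<- c(log_lines, line)

  if (is.character(manifest)) {
    cohort <- read_manifest(manifest, log_fun = log_fun)
  } else {
    cohort <- manifest
  }
  metrics <- cohort_metrics(cohort, config, log_fun = log_fun)
  fitted <- fit_cohort_profiles(metrics, log_fun = log_fun)
  stats_out <- build_comparison_table(fitted$profiles_by_test,
                                      fitted$standard_by_test)
  log_fun(paste0("INFO stage=stats event=done subjects=",
                 length(unique(metrics$subject_id)),
                 " excluded_lines=", sum(grepl("^WARN", log_lines))))

  res <- list(metrics = metrics, profiles = fitted$profiles,
              standard = do.call(rbind, fitted$standard_by_test),
              table1 = stats_out$table1, figure3 = stats_out$figure3,
              comparisons = stats_out$comparisons, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) round(x, 6))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
    }
    wr(res$metrics, "metrics.csv")
    prof_df <- res$profiles
    names(prof_df) <- c("subject_id", "test", "F0_N", "V0_mps", "slope_Nspm",
                        "P0_W")
    wr(prof_df, "profiles.csv")
    wr(res$table1, "table1.csv")
    wr(res$figure3, "figure3.csv")
    wr(res$comparisons, "comparisons.csv")
    writeLines(res$log, file.path(out_dir, "run.log"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "effective_config.yaml"))
  }
  res
}
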