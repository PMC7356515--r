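#' Write a trajectory to CSV
#'
#' Tidy CSV with one row per output day and header
#' `time_day,x1_mm3,x2_mm3,total_mm3,x3,xe3,x4,xe4,x5,xe5,E,Et_a,Et_i,Et_r`.
#' Floats are printed at 10 significant digits so files diff cleanly across
#' runs.
#'
#' @param trajectory a `pkpd_trajectory` from [simulate_combined()] (or any
#'   data.frame with those columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  cols <- c("time", "x1", "x2", "total", "x3", "xe3", "x4", "xe4",
            "x5", "xe5", "E", "Et_a", "Et_i", "Et_r")
  header <- c("time_day", "x1_mm3", "x2_mm3", "total_mm3", "x3", "xe3",
              "x4", "xe4", "x5", "xe5", "E", "Et_a", "Et_i", "Et_r")
  if (!all(cols %in% names(trajectory)))
    stop("write_trajectory: trajectory lacks required columns")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  for (i in seq_len(nrow(trajectory))) {
    vals <- vapply(cols, function(cl)
      format(trajectory[[cl]][i], digits = 10, scientific = FALSE,
             trim = TRUE), character(1))
    writeLines(paste(vals, collapse = ","), con)
  }
  invisible(path)
}

#' Read back a trajectory CSV
#'
#' Inverse of [write_trajectory()]; returns a data.frame with the package's
#' internal column names.
#'
#' @param path CSV file written by [write_trajectory()].
#' @return A data.frame.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path)
  names(tab) <- sub("^time_day$", "time", names(tab))
  names(tab) <- sub("_mm3$", "", names(tab))
  tab
}

#' Write a run summary with provenance
#'
#' JSON summary of an experiment: the summary metrics, every effective
#' model coefficient, the simulation settings, and a digest of each dosing
#' schedule (channel, event days and amounts), so a run can be reproduced
#' exactly from its summary file.
#'
#' @param summary an experiment summary data.frame (from [run_control()],
#'   [run_protocol()] or a sweep) with a `trajectory` attribute, or a
#'   `pkpd_trajectory`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  traj <- if (inherits(summary, "pkpd_trajectory")) summary
          else attr(summary, "trajectory")
  doc <- list()
  if (is.data.frame(summary) && !inherits(summary, "pkpd_trajectory"))
    doc$summary <- summary
  if (!is.null(traj)) {
    p <- attr(traj, "params")
    doc$provenance <- list(
      parameters = unclass(p),
      horizon = attr(traj, "horizon"),
      step = attr(traj, "step"),
      schedules = lapply(attr(traj, "schedules"), function(s)
        list(channel = s$channel, day = s$events$day,
             amount = s$events$amount, horizon = s$horizon))
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Rebuild a simulation from a summary's provenance block
#'
#' Re-runs [simulate_combined()] with the parameters, schedules, horizon
#' and step recorded by [write_summary()]; with the same package version
#' the trajectory reproduces bit-for-bit.
#'
#' @param path JSON summary path.
#' @return A `pkpd_trajectory`.
#' @export
replay_summary <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- doc$provenance
  if (is.null(prov)) stop("replay_summary: no provenance block in ", path)
  schedules <- lapply(prov$schedules, function(s)
    dose_schedule(s$channel, days = s$day, amounts = s$amount,
                  horizon = s$horizon))
  simulate_combined(do.call(combined_parameters, as.list(prov$parameters)),
                    schedules = schedules, horizon = prov$horizon,
                    step = prov$step)
}
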