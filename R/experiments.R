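#' Standard drug co-therapy schedules of the protocol study
#'
#' The protocol-comparison experiments hold the drug channels fixed:
#' antiangiogenic drug 0.171 mg/mL once weekly and immunotherapy 0.2 mg/mL
#' once weekly, both starting on day 1 together with radiotherapy.
#'
#' @param horizon schedule horizon in days.
#' @param ag_dose,im_dose weekly doses, mg/mL.
#' @return Named list with `AG` and `IM` [dose_schedule()] entries.
#' @export
standard_drug_schedules <- function(horizon = 30, ag_dose = 0.171,
                                    im_dose = 0.2) {
  list(AG = weekly_schedule("AG", ag_dose, horizon),
       IM = weekly_schedule("IM", im_dose, horizon))
}

.summarize_run <- function(label, traj, reference_total = NA_real_) {
  last <- traj[nrow(traj), ]
  data.frame(
    label = label,
    end_total_volume = last$total,
    end_active_volume = last$x1,
    end_necrotic_volume = last$x2,
    relative_difference_vs_reference =
      if (is.na(reference_total)) NA_real_ else
        100 * (last$total - reference_total) / reference_total,
    stringsAsFactors = FALSE
  )
}

#' Untreated control experiment
#'
#' Simulates tumor growth with all therapy inputs zero. Without treatment
#' the proliferating volume grows exponentially at rate `a - n` and the
#' necrotic volume integrates `n x1`, so the day-`T` closed forms are
#' `x1(T) = V0 exp((a - n) T)` and `x2(T) = n / (a - n) (x1(T) - V0)`.
#'
#' @param params a [combined_parameters()] object.
#' @param horizon,step passed to [simulate_combined()].
#' @return A one-row experiment summary data.frame with the day-`horizon`
#'   volumes and the trajectory attached as attribute `trajectory`.
#' @export
run_control <- function(params = combined_parameters(), horizon = 30,
                        step = 0.01) {
  tr <- simulate_combined(params, schedules = list(), horizon = horizon,
                          step = step)
  out <- .summarize_run("control", tr)
  attr(out, "trajectory") <- tr
  out
}

#' Combined-therapy protocol experiment
#'
#' Simulates the combined model under one of the three radiotherapy
#' protocols (see [rt_protocol()]) with the standard weekly drug co-therapy
#' held fixed.
#'
#' @param protocol_id 1, 2 or 3.
#' @param params a [combined_parameters()] object.
#' @param horizon,step passed to [simulate_combined()].
#' @param ... further arguments to [rt_protocol()] or
#'   [simulate_combined()] (e.g. `small_fraction_days`, `rt_lq_weight`).
#' @return A one-row experiment summary data.frame (see [run_control()]).
#' @export
run_protocol <- function(protocol_id, params = combined_parameters(),
                         horizon = 30, step = 0.01, ...) {
  dots <- list(...)
  rt_args <- dots[names(dots) %in% c("small_fraction_days")]
  sim_args <- dots[names(dots) %in% c("rt_lq_weight", "lq")]
  schedules <- standard_drug_schedules(horizon)
  schedules$RT <- do.call(rt_protocol,
                          c(list(protocol_id, horizon = horizon), rt_args))
  tr <- do.call(simulate_combined,
                c(list(params, schedules = schedules, horizon = horizon,
                       step = step), sim_args))
  out <- .summarize_run(paste0("protocol_", protocol_id), tr)
  attr(out, "trajectory") <- tr
  out
}

#' Relative end-volume difference between two runs
#'
#' Percent difference of total tumor end-volume, `100 * (B - A) / A`, with
#' run A as the reference.
#'
#' @param summary_b,summary_a experiment summaries from [run_control()],
#'   [run_protocol()] or sweep rows.
#' @return Signed percent difference.
#' @export
relative_difference <- function(summary_b, summary_a) {
  a <- summary_a$end_total_volume[1]
  b <- summary_b$end_total_volume[1]
  if (!is.finite(a) || a <= 0)
    stop("relative_difference: reference end volume must be > 0")
  100 * (b - a) / a
}

#' Synergy sweep
#'
#' Re-runs a protocol experiment over a grid of synergy coefficients
#' `sigma`, everything else fixed, and reports the end-volume fold change
#' between the extreme `sigma` values (low-synergy volume over
#' high-synergy volume).
#'
#' @param params a [combined_parameters()] object (its `sigma` is swept).
#' @param protocol_id radiotherapy protocol used for every run.
#' @param sigma_values nonnegative sweep grid.
#' @param horizon,step passed to [simulate_combined()].
#' @return A data.frame with one summary row per `sigma`, with the fold
#'   change attached as attribute `fold_change`.
#' @export
synergy_sweep <- function(params = combined_parameters(), protocol_id = 3,
                          sigma_values = c(1, 2, 4, 6, 8), horizon = 30,
                          step = 0.01) {
  if (!length(sigma_values) || any(sigma_values < 0))
    stop("synergy_sweep: sigma_values must be nonnegative and nonempty")
  rows <- lapply(sigma_values, function(s) {
    p <- params
    p$sigma <- s
    r <- run_protocol(protocol_id, validate_combined_parameters(p),
                      horizon = horizon, step = step)
    r$sigma <- s
    r
  })
  out <- do.call(rbind, rows)
  lo <- which.min(sigma_values); hi <- which.max(sigma_values)
  attr(out, "fold_change") <-
    out$end_total_volume[lo] / out$end_total_volume[hi]
  out
}

#' Resistance sweep
#'
#' Re-runs a protocol experiment over a grid of patient-response exponents
#' `gamma` at fixed nominal synergy, and reports the percent increase of
#' the end volume at the largest `gamma` (most resistant) relative to the
#' smallest (most responsive).
#'
#' @param params a [combined_parameters()] object (its `gamma` is swept).
#' @param protocol_id radiotherapy protocol used for every run.
#' @param gamma_values positive sweep grid.
#' @param sigma synergy coefficient held fixed during the sweep.
#' @param horizon,step passed to [simulate_combined()].
#' @return A data.frame with one summary row per `gamma`, with the percent
#'   increase attached as attribute `percent_increase`.
#' @export
resistance_sweep <- function(params = combined_parameters(), protocol_id = 3,
                             gamma_values = c(1, 2.5, 4, 8), sigma = 4,
                             horizon = 30, step = 0.01) {
  if (!length(gamma_values) || any(gamma_values <= 0))
    stop("resistance_sweep: gamma_values must be positive and nonempty")
  rows <- lapply(gamma_values, function(g) {
    p <- params
    p$gamma <- g
    p$sigma <- sigma
    r <- run_protocol(protocol_id, validate_combined_parameters(p),
                      horizon = horizon, step = step)
    r$gamma <- g
    r
  })
  out <- do.call(rbind, rows)
  lo <- which.min(gamma_values); hi <- which.max(gamma_values)
  attr(out, "percent_increase") <-
    100 * (out$end_total_volume[hi] - out$end_total_volume[lo]) /
      out$end_total_volume[lo]
  out
}
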