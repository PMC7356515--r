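#' State vector of the combined model
#'
#' The eight states are: `x1` proliferating tumor volume (mm^3), `x2`
#' necrotic tumor volume (mm^3), `x3`/`xe3` antiangiogenic serum and
#' effect-site levels (mg/mL), `x4`/`xe4` immunotherapy serum and
#' effect-site levels (mg/mL), `x5`/`xe5` radiotherapy drive and effect-site
#' levels (Gy/day-equivalent).
#'
#' @param x named numeric vector or list carrying the eight state fields.
#' @return A named numeric vector in canonical order.
#' @export
as_state_vector <- function(x) {
  fields <- c("x1", "x2", "x3", "xe3", "x4", "xe4", "x5", "xe5")
  x <- unlist(x)
  if (!all(fields %in% names(x)))
    stop("state vector needs fields: ", paste(fields, collapse = ", "))
  out <- as.numeric(x[fields])
  names(out) <- fields
  out
}

#' Initial state of a simulation
#'
#' Tumor at its initial volume, no necrotic tissue, all drug compartments
#' empty.
#'
#' @param params a [combined_parameters()] object (supplies `V0`).
#' @return A named state vector.
#' @export
initial_state <- function(params = combined_parameters())
  c(x1 = params$V0, x2 = 0, x3 = 0, xe3 = 0, x4 = 0, xe4 = 0, x5 = 0, xe5 = 0)

# Scalar Hill curve; saturates to 1 when i^g overflows.
.h <- function(i, g) {
  if (i <= 0) return(0)
  ig <- i^g
  if (!is.finite(ig)) return(1)
  ig / (1 + ig)
}

# Effect terms at one state; lean numeric core shared by combined_effect()
# and the ODE right-hand side. Returns a named numeric vector.
.effect_terms <- function(x1, xe3, xe4, xe5, p) {
  unt <- (100 * x1 / p$V0) / p$C50_t
  una <- xe3 / p$C50_a
  uni <- xe4 / p$C50_i
  unr <- xe5 / p$C50_r
  g <- p$gamma; s <- p$sigma
  h_t  <- .h(unt, g)
  s_ta <- p$Emax_a * .h(unt + una + s * unt * una, g)
  s_ti <- p$Emax_i * .h(unt + uni + s * unt * uni, g)
  s_tr <- p$Emax_r * .h(unt + unr + s * unt * unr, g)
  et_a <- max(s_ta - p$Emax_a * h_t, 0)
  et_i <- max(s_ti - p$Emax_i * h_t, 0)
  et_r <- max(s_tr - p$Emax_r * h_t, 0)
  e_ai <- max((p$Emax_a + p$Emax_i) / 2 * (.h(una + uni + s * una * uni, g) - .h(una + uni, g)), 0)
  e_ar <- max((p$Emax_a + p$Emax_r) / 2 * (.h(una + unr + s * una * unr, g) - .h(una + unr, g)), 0)
  e_ir <- max((p$Emax_i + p$Emax_r) / 2 * (.h(uni + unr + s * uni * unr, g) - .h(uni + unr, g)), 0)
  et_all <- (et_a + et_i + et_r) / 3
  ed_all <- (e_ai + e_ar + e_ir) / 3
  c(unt = unt, una = una, uni = uni, unr = unr,
    s_ta = s_ta, s_ti = s_ti, s_tr = s_tr,
    Et_a = et_a, Et_i = et_i, Et_r = et_r,
    E_ai = e_ai, E_ar = e_ar, E_ir = e_ir,
    Et_all = et_all, Ed_all = ed_all, E = (et_all + ed_all) / 2)
}

#' Right-hand side of the combined-therapy ODE system
#'
#' Implements the eight coupled state derivatives: net tumor growth
#' `(a - n) x1` minus the treatment kill `E x1` (killed volume moves to the
#' necrotic compartment, so total volume grows at `a x1`); first-order
#' serum kinetics with external dose-rate inputs; and effect-site
#' compartments driven by the serum level modulated by the full tumor-drug
#' Hill surface. The kill rate is the aggregated combined effect from
#' [combined_effect()] scaled by `unit_rate`. Negative state components
#' (integration undershoot) are clipped to zero before evaluation.
#'
#' @param t time in days.
#' @param state named state vector (see [as_state_vector()]).
#' @param params a [combined_parameters()] object.
#' @param schedules named list with `AG`, `IM`, `RT` [dose_schedule()]
#'   entries (missing channels mean no dosing).
#' @return Named vector of derivatives.
#' @export
combined_rhs <- function(t, state, params, schedules = list()) {
  x <- pmax(as_state_vector(state), 0)
  rate_of <- function(ch) {
    s <- schedules[[ch]]
    if (is.null(s)) 0 else dose_rate(s, min(t, s$horizon))
  }
  d <- .combined_deriv(t, x, params,
                       ua = rate_of("AG"), ui = rate_of("IM"), ur = rate_of("RT"))
  names(d) <- names(x)
  d
}

# derivative core: inputs already resolved to scalar rates
.combined_deriv <- function(t, x, p, ua, ui, ur) {
  ef <- .effect_terms(x[[1]], x[[4]], x[[6]], x[[8]], p)
  E <- ef[["E"]] * p$unit_rate
  kill <- E * x[[1]]
  c((p$a - p$n) * x[[1]] - kill,
    p$n * x[[1]] + kill,
    -p$c_a * x[[3]] + ua,
    -p$c_a * x[[4]] + ef[["s_ta"]] * x[[3]],
    -p$c_i * x[[5]] + ui,
    -p$c_i * x[[6]] + ef[["s_ti"]] * x[[5]],
    -p$c_r * x[[7]] + ur,
    -p$c_r * x[[8]] + ef[["s_tr"]] * x[[7]])
}

#' Right-hand side of the single-agent antiangiogenic model
#'
#' Three-state legacy model: proliferating volume inhibited by a saturable
#' drug effect `b_a x1 x3 / (ED50_a + x3)`, necrotic volume collecting
#' natural necrosis plus the inhibited volume, and serum level with
#' Michaelis-Menten clearance `c_a x3 / (K_Ba + x3)` and a saturable
#' tumor-mediated consumption term `b_ak x1 x3 / (ED50_a + x3)`.
#'
#' @param t time in days.
#' @param state named vector with `x1`, `x2`, `x3`.
#' @param params a [legacy_ag_parameters()] object.
#' @param u_a scalar inhibitor dose rate at time `t` (mg/(mL day)), or a
#'   function of `t`.
#' @return Named vector of derivatives.
#' @export
legacy_rhs <- function(t, state, params, u_a = 0) {
  x <- pmax(unlist(state)[c("x1", "x2", "x3")], 0)
  if (is.function(u_a)) u_a <- u_a(t)
  inhib <- params$b_a * x[[1]] * x[[3]] / (params$ED50_a + x[[3]])
  c(x1 = (params$a - params$n_a) * x[[1]] - inhib,
    x2 = params$n_a * x[[1]] + inhib,
    x3 = -params$c_a * x[[3]] / (params$K_Ba + x[[3]]) -
      params$b_ak * x[[1]] * x[[3]] / (params$ED50_a + x[[3]]) + u_a)
}

#' Simulate the combined-therapy model
#'
#' Fixed-step fourth-order Runge-Kutta integration of the combined model
#' from the standard initial state (tumor at `V0`, drug compartments empty),
#' with piecewise-constant dose-rate inputs aligned to day boundaries.
#' Fixed-step integration keeps runs bit-for-bit reproducible and places
#' integration nodes exactly on the input discontinuities. Output is
#' sampled on the daily grid and augmented with the effect breakdown at
#' each sampled state.
#'
#' @param params a [combined_parameters()] object.
#' @param schedules named list of [dose_schedule()] objects (`AG`, `IM`,
#'   `RT`); omitted channels are undosed.
#' @param horizon simulation length in days.
#' @param step integration step in days; must divide 1 and be at most 0.05.
#' @param rt_lq_weight logical; weight the daily radiotherapy drive by the
#'   incomplete-repair LQ effect (see [daily_rt_drive()]). Off by default.
#' @param lq [lq_parameters()] used when `rt_lq_weight = TRUE`.
#' @return An object of class `pkpd_trajectory`: a data.frame with columns
#'   `time`, the eight states, `total` (`x1 + x2`) and the effect columns
#'   `E`, `Et_a`, `Et_i`, `Et_r`, with the simulation settings attached as
#'   attributes.
#' @examples
#' tr <- simulate_combined(combined_parameters(), horizon = 5)
#' tail(tr$total, 1)
#' @export
simulate_combined <- function(params = combined_parameters(),
                              schedules = list(), horizon = 30, step = 0.01,
                              rt_lq_weight = FALSE, lq = lq_parameters()) {
  params <- validate_combined_parameters(params)
  if (horizon <= 0 || horizon != round(horizon))
    stop("simulate_combined: horizon must be a positive whole number of days")
  if (step > 0.05) stop("simulate_combined: step must be <= 0.05 day")
  n_sub <- round(1 / step)
  if (abs(n_sub * step - 1) > 1e-9)
    stop("simulate_combined: step must divide 1 day evenly")
  for (ch in names(schedules)) {
    s <- schedules[[ch]]
    if (!inherits(s, "dose_schedule") || s$channel != ch)
      stop("simulate_combined: schedules must be named dose_schedule objects ",
           "matching their channel (AG, IM, RT)")
  }
  tab <- function(ch) {
    s <- schedules[[ch]]
    if (is.null(s)) return(numeric(horizon))
    r <- numeric(horizon)
    r[seq_len(min(s$horizon, horizon))] <- .rate_table(s)[seq_len(min(s$horizon, horizon))]
    r
  }
  ua <- tab("AG"); ui <- tab("IM")
  ur <- if (is.null(schedules$RT)) numeric(horizon) else
    daily_rt_drive(schedules$RT, seq_len(horizon), lq_weight = rt_lq_weight, lq = lq)

  # The inputs are constant over each day, so integrate day by day and
  # restart at the boundaries: every segment is smooth and classical RK4
  # keeps its full convergence order. The derivative closure below inlines
  # the effect algebra of .effect_terms() for speed; a cross-check test
  # keeps the two in step.
  a_n <- params$a - params$n; n_ <- params$n
  c_a <- params$c_a; c_i <- params$c_i; c_r <- params$c_r
  iC50a <- 1 / params$C50_a; iC50i <- 1 / params$C50_i; iC50r <- 1 / params$C50_r
  tnorm <- 100 / (params$V0 * params$C50_t)
  ema <- params$Emax_a; emi <- params$Emax_i; emr <- params$Emax_r
  e_ai_max <- (ema + emi) / 2; e_ar_max <- (ema + emr) / 2
  e_ir_max <- (emi + emr) / 2
  g <- params$gamma; s <- params$sigma; urate <- params$unit_rate
  hh <- function(i) {
    if (i <= 0) return(0)
    v <- i^g
    if (is.finite(v)) v / (1 + v) else 1
  }
  clipped <- FALSE
  rhs <- function(t, y, parms) {
    if (any(y < 0)) { clipped <<- TRUE; y <- pmax(y, 0) }
    unt <- y[[1]] * tnorm
    una <- y[[4]] * iC50a; uni <- y[[6]] * iC50i; unr <- y[[8]] * iC50r
    h0 <- hh(unt)
    s_ta <- ema * hh(unt + una + s * unt * una)
    s_ti <- emi * hh(unt + uni + s * unt * uni)
    s_tr <- emr * hh(unt + unr + s * unt * unr)
    et <- max(s_ta - ema * h0, 0) + max(s_ti - emi * h0, 0) +
      max(s_tr - emr * h0, 0)
    ed <- max(e_ai_max * (hh(una + uni + s * una * uni) - hh(una + uni)), 0) +
      max(e_ar_max * (hh(una + unr + s * una * unr) - hh(una + unr)), 0) +
      max(e_ir_max * (hh(uni + unr + s * uni * unr) - hh(uni + unr)), 0)
    kill <- (et + ed) / 6 * urate * y[[1]]
    list(c(a_n * y[[1]] - kill,
           n_ * y[[1]] + kill,
           -c_a * y[[3]] + parms[[1]],
           -c_a * y[[4]] + s_ta * y[[3]],
           -c_i * y[[5]] + parms[[2]],
           -c_i * y[[6]] + s_ti * y[[5]],
           -c_r * y[[7]] + parms[[3]],
           -c_r * y[[8]] + s_tr * y[[7]]))
  }
  y <- initial_state(params)
  daily <- matrix(NA_real_, nrow = horizon + 1, ncol = 9,
                  dimnames = list(NULL, c("time", names(y))))
  daily[1, ] <- c(0, y)
  for (k in seq_len(horizon)) {
    seg <- deSolve::ode(y = y, times = (k - 1) + (0:n_sub) * step, func = rhs,
                        parms = c(ua[k], ui[k], ur[k]), method = "rk4")
    if (any(!is.finite(seg)))
      stop("simulate_combined: non-finite state at t = ",
           signif(seg[which(!is.finite(rowSums(seg)))[1], 1], 6))
    y <- seg[nrow(seg), -1]
    daily[k + 1, ] <- c(k, y)
  }
  if (clipped)
    warning("simulate_combined: negative state undershoot clipped to 0")
  out <- as.data.frame(daily)
  out$total <- out$x1 + out$x2
  ef <- t(vapply(seq_len(nrow(out)), function(i)
    .effect_terms(out$x1[i], out$xe3[i], out$xe4[i], out$xe5[i], params),
    numeric(16)))
  out$E <- ef[, "E"] * params$unit_rate
  out$Et_a <- ef[, "Et_a"]; out$Et_i <- ef[, "Et_i"]; out$Et_r <- ef[, "Et_r"]
  out$time <- round(out$time)
  out <- out[, c("time", "x1", "x2", "total", "x3", "xe3", "x4", "xe4",
                 "x5", "xe5", "E", "Et_a", "Et_i", "Et_r")]
  structure(out, class = c("pkpd_trajectory", "data.frame"),
            params = params, schedules = schedules,
            step = step, horizon = horizon)
}

#' Simulate the single-agent antiangiogenic model
#'
#' Fixed-step RK4 integration of the legacy three-state model.
#'
#' @param params a [legacy_ag_parameters()] object.
#' @param schedule an AG [dose_schedule()] or `NULL` for no dosing.
#' @param v0 initial proliferating volume, mm^3.
#' @param horizon,step as in [simulate_combined()].
#' @return A data.frame with columns `time`, `x1`, `x2`, `x3`, `total`.
#' @export
simulate_legacy <- function(params = legacy_ag_parameters(), schedule = NULL,
                            v0 = 1000, horizon = 30, step = 0.01) {
  if (step > 0.05) stop("simulate_legacy: step must be <= 0.05 day")
  n_sub <- round(1 / step)
  rate <- if (is.null(schedule)) numeric(horizon) else {
    if (schedule$channel != "AG") stop("simulate_legacy: schedule must be AG")
    .rate_table(schedule)
  }
  rhs <- function(t, y, parms)
    list(legacy_rhs(t, pmax(y, 0), params, u_a = parms))
  y <- c(x1 = v0, x2 = 0, x3 = 0)
  daily <- matrix(NA_real_, nrow = horizon + 1, ncol = 4,
                  dimnames = list(NULL, c("time", names(y))))
  daily[1, ] <- c(0, y)
  for (k in seq_len(horizon)) {
    seg <- deSolve::ode(y = y, times = (k - 1) + (0:n_sub) * step, func = rhs,
                        parms = rate[k], method = "rk4")
    y <- seg[nrow(seg), -1]
    daily[k + 1, ] <- c(k, y)
  }
  out <- as.data.frame(daily)
  out$total <- out$x1 + out$x2
  out
}

#' @export
print.pkpd_trajectory <- function(x, ...) {
  h <- attr(x, "horizon")
  last <- x[nrow(x), ]
  cat(sprintf("Combined-therapy trajectory: %d days, step %g day\n",
              h, attr(x, "step")))
  cat(sprintf("  day %d: active %.1f mm^3, necrotic %.1f mm^3, total %.1f mm^3\n",
              last$time, last$x1, last$x2, last$total))
  invisible(x)
}
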