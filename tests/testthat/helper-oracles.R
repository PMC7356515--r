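# Independent oracles used across the suite. The Euler integrator below
# re-derives the model equations from their mathematical statement rather
# than calling the package's right-hand side, so it can serve as an
# integration cross-check.

# Closed-form untreated growth: exponential active volume, integrated
# necrosis.
control_closed_form <- function(p, t) {
  x1 <- p$V0 * exp((p$a - p$n) * t)
  list(x1 = x1, x2 = p$n / (p$a - p$n) * (x1 - p$V0))
}

# Scalar Hill curve written independently (log-space power).
oracle_hill <- function(i, g) {
  if (i <= 0) return(0)
  v <- exp(g * log(i))
  if (!is.finite(v)) return(1)
  v / (1 + v)
}

# Brute-force explicit-Euler integration of the combined model with
# piecewise-constant daily inputs. rates: list of numeric day-rate vectors
# ua, ui, ur of length `horizon`.
oracle_euler <- function(p, rates, horizon = 30, step = 1e-4) {
  n <- round(horizon / step)
  x <- c(p$V0, 0, 0, 0, 0, 0, 0, 0)
  g <- p$gamma; s <- p$sigma
  ema <- p$Emax_a; emi <- p$Emax_i; emr <- p$Emax_r
  for (k in seq_len(n)) {
    t <- (k - 1) * step
    d <- min(floor(t) + 1, horizon)
    unt <- (100 * x[1] / p$V0) / p$C50_t
    una <- x[4] / p$C50_a; uni <- x[6] / p$C50_i; unr <- x[8] / p$C50_r
    h0 <- oracle_hill(unt, g)
    sta <- ema * oracle_hill(unt + una + s * unt * una, g)
    sti <- emi * oracle_hill(unt + uni + s * unt * uni, g)
    str <- emr * oracle_hill(unt + unr + s * unt * unr, g)
    et <- (max(sta - ema * h0, 0) + max(sti - emi * h0, 0) +
           max(str - emr * h0, 0)) / 3
    ed <- (max((ema + emi) / 2 * (oracle_hill(una + uni + s * una * uni, g) -
                                  oracle_hill(una + uni, g)), 0) +
           max((ema + emr) / 2 * (oracle_hill(una + unr + s * una * unr, g) -
                                  oracle_hill(una + unr, g)), 0) +
           max((emi + emr) / 2 * (oracle_hill(uni + unr + s * uni * unr, g) -
                                  oracle_hill(uni + unr, g)), 0)) / 3
    E <- (et + ed) / 2 * p$unit_rate
    dx <- c((p$a - p$n) * x[1] - E * x[1],
            p$n * x[1] + E * x[1],
            -p$c_a * x[3] + rates$ua[d],
            -p$c_a * x[4] + sta * x[3],
            -p$c_i * x[5] + rates$ui[d],
            -p$c_i * x[6] + sti * x[5],
            -p$c_r * x[7] + rates$ur[d],
            -p$c_r * x[8] + str * x[7])
    x <- pmax(x + step * dx, 0)
  }
  x
}

# Day-rate vector of a schedule, built from its event table.
day_rates <- function(schedule, horizon = 30) {
  r <- numeric(horizon)
  if (!is.null(schedule))
    for (i in seq_len(nrow(schedule$events)))
      r[schedule$events$day[i]] <- r[schedule$events$day[i]] +
        schedule$events$amount[i]
  r
}
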