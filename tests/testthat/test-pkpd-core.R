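test_that("combined RHS reduces to pure growth/necrosis without drugs", {
  p <- combined_parameters()
  d <- combined_rhs(0, initial_state(p), p)
  expect_equal(d[["x1"]], (p$a - p$n) * p$V0)
  expect_equal(d[["x2"]], p$n * p$V0)
  expect_equal(unname(d[c("x3", "xe3", "x4", "xe4", "x5", "xe5")]), rep(0, 6))
})

test_that("total volume always grows at a * x1 (kill flux moves to necrosis)", {
  p <- combined_parameters()
  set.seed(42)
  for (k in 1:20) {
    st <- c(x1 = runif(1, 1, 5e4), x2 = runif(1, 0, 5e4),
            x3 = runif(1, 0, 0.5), xe3 = runif(1, 0, 0.5),
            x4 = runif(1, 0, 0.3), xe4 = runif(1, 0, 0.3),
            x5 = runif(1, 0, 15), xe5 = runif(1, 0, 15))
    d <- combined_rhs(0, st, p)
    expect_equal(d[["x1"]] + d[["x2"]], p$a * st[["x1"]], tolerance = 1e-12)
  }
})

test_that("the effect-site drive equals the tumor-drug Hill surface", {
  p <- combined_parameters()
  st <- initial_state(p)
  st["x3"] <- 0.44; st["xe3"] <- 0.22
  eb <- combined_effect(st, p)
  manual <- hill_surface(interaction_index(2, 0.22 / 0.44, p$sigma),
                         p$gamma, p$Emax_a)
  expect_equal(eb$uptake_a, manual)
  # and the xe3 derivative is the surface times the serum level (no uptake loss)
  d <- combined_rhs(0, st, p)
  expect_equal(d[["xe3"]], -p$c_a * 0.22 + manual * 0.44)
})

test_that("legacy model limits: zero drug, saturation, half-effect inhibition", {
  p <- legacy_ag_parameters()
  d0 <- legacy_rhs(0, c(x1 = 1000, x2 = 0, x3 = 0), p, u_a = 0.171)
  expect_equal(d0[["x1"]], (p$a - p$n_a) * 1000)
  expect_equal(d0[["x3"]], 0.171)
  # saturable inhibition at x3 = ED50: half of b_a * x1
  dh <- legacy_rhs(0, c(x1 = 1000, x2 = 0, x3 = p$ED50_a), p)
  expect_equal(dh[["x2"]] - p$n_a * 1000, 84.25)
  # x3 -> infinity: inhibition tends to b_a * x1
  db <- legacy_rhs(0, c(x1 = 1000, x2 = 0, x3 = 1e9), p)
  expect_equal(db[["x2"]] - p$n_a * 1000, p$b_a * 1000, tolerance = 1e-6)
})

test_that("untreated simulation matches the exponential closed form", {
  p <- combined_parameters()
  tr <- simulate_combined(p, horizon = 30, step = 0.01)
  cf <- control_closed_form(p, 30)
  expect_equal(tr$x1[31], cf$x1, tolerance = 1e-6)
  expect_equal(tr$x2[31], cf$x2, tolerance = 1e-6)
  expect_equal(tr$total, tr$x1 + tr$x2)
  expect_equal(tr$time, 0:30)
})

test_that("RK4 is converged: halving the step barely moves the endpoint", {
  p <- combined_parameters()
  a0 <- simulate_combined(p, horizon = 10, step = 0.01)
  b0 <- simulate_combined(p, horizon = 10, step = 0.005)
  expect_equal(a0$x1[11], b0$x1[11], tolerance = 1e-6)
  sch <- c(standard_drug_schedules(), list(RT = rt_protocol(2)))
  a <- simulate_combined(p, sch, horizon = 10, step = 0.01)
  b <- simulate_combined(p, sch, horizon = 10, step = 0.005)
  # treated runs have fast effect transients; step error is ~3e-6 there
  expect_equal(a$x1[11], b$x1[11], tolerance = 1e-5)
  expect_equal(a$x2[11], b$x2[11], tolerance = 1e-5)
})

test_that("the fast integration path matches direct integration of combined_rhs", {
  p <- combined_parameters()
  sch <- c(standard_drug_schedules(4), list(RT = rt_protocol(2, horizon = 4)))
  tr <- simulate_combined(p, sch, horizon = 4, step = 0.02)
  # re-integrate day by day through the exported RHS, holding each day's
  # dose rate constant via an all-days schedule to avoid boundary lookups
  y <- initial_state(p)
  for (k in 1:4) {
    const_sch <- lapply(sch, function(s)
      dose_schedule(s$channel, days = 1:4,
                    amounts = dose_rate(s, k - 0.5), horizon = 4))
    seg <- deSolve::ode(y = y, times = (k - 1) + (0:50) * 0.02,
                        func = function(t, y, parms)
                          list(combined_rhs(t, y, p, const_sch)),
                        parms = NULL, method = "rk4")
    y <- seg[nrow(seg), -1]
    expect_equal(unname(unlist(tr[k + 1, c("x1", "x2", "x3", "xe3", "x4",
                                           "xe4", "x5", "xe5")])),
                 unname(y), tolerance = 1e-12, info = paste("day", k))
  }
})

test_that("repeated runs are bit-for-bit identical", {
  p <- combined_parameters()
  sch <- c(standard_drug_schedules(), list(RT = rt_protocol(3)))
  a <- simulate_combined(p, sch)
  b <- simulate_combined(p, sch)
  expect_identical(a, b)
})

test_that("all states stay nonnegative under every protocol", {
  p <- combined_parameters()
  for (id in 1:3) {
    sch <- c(standard_drug_schedules(), list(RT = rt_protocol(id)))
    tr <- simulate_combined(p, sch)
    expect_true(all(as.matrix(tr[, c("x1", "x2", "x3", "xe3", "x4", "xe4",
                                     "x5", "xe5")]) >= 0), info = id)
  }
})

test_that("treated active volume never exceeds the control pointwise", {
  p <- combined_parameters()
  ctrl <- simulate_combined(p)
  for (id in 1:3) {
    sch <- c(standard_drug_schedules(), list(RT = rt_protocol(id)))
    tr <- simulate_combined(p, sch)
    expect_true(all(tr$x1 <= ctrl$x1 + 1e-9), info = id)
  }
})

test_that("total volume growth matches the integral of a * x1", {
  p <- combined_parameters()
  sch <- c(standard_drug_schedules(), list(RT = rt_protocol(1)))
  tr <- simulate_combined(p, sch)
  # trapezoid on the daily grid; discretization dominates the tolerance
  integral <- sum((tr$x1[-1] + tr$x1[-31]) / 2)
  expect_equal(tr$total[31] - p$V0, p$a * integral, tolerance = 5e-3)
})

test_that("RK4 agrees with a brute-force fine-step Euler oracle", {
  p <- combined_parameters()
  sch <- c(standard_drug_schedules(), list(RT = rt_protocol(3)))
  tr <- simulate_combined(p, sch, horizon = 30, step = 0.01)
  rates <- list(ua = day_rates(sch$AG), ui = day_rates(sch$IM),
                ur = day_rates(sch$RT))
  x_euler <- oracle_euler(p, rates, horizon = 30, step = 1e-4)
  expect_equal(tr$x1[31], x_euler[1], tolerance = 1e-3)
  expect_equal(tr$x2[31], x_euler[2], tolerance = 1e-3)
  expect_equal(tr$xe3[31], x_euler[4], tolerance = 1e-3)
})

test_that("simulation settings are validated", {
  p <- combined_parameters()
  expect_error(simulate_combined(p, step = 0.1), "0.05")
  expect_error(simulate_combined(p, step = 0.03), "divide 1 day")
  expect_error(simulate_combined(p, horizon = 0), "horizon")
  expect_error(simulate_combined(p, schedules = list(AG = rt_protocol(1))),
               "matching their channel")
})

test_that("legacy simulation retards growth relative to its own control", {
  ctrl <- simulate_legacy(horizon = 20)
  trt <- simulate_legacy(schedule = weekly_schedule("AG", 0.171, 20),
                         horizon = 20)
  expect_true(all(trt$x1 <= ctrl$x1 + 1e-9))
  expect_gt(trt$x3[2], 0)
})
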