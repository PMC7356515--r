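test_that("interaction index combines normalized levels with a synergy product", {
  expect_equal(interaction_index(1, 0, 4), 1)
  expect_equal(interaction_index(1, 1, 4), 6)
  expect_equal(interaction_index(0, 0, 8), 0)
  expect_equal(interaction_index(0.5, 0.25, 2), 0.5 + 0.25 + 2 * 0.5 * 0.25)
  expect_error(interaction_index(-1, 0, 4), "must be >= 0")
  expect_error(interaction_index(1, 1, -1), "sigma")
})

test_that("interaction index is symmetric in its two agents", {
  set.seed(11)
  for (k in 1:25) {
    a <- runif(1, 0, 5); b <- runif(1, 0, 5); s <- runif(1, 0, 10)
    expect_equal(interaction_index(a, b, s), interaction_index(b, a, s))
  }
})

test_that("Hill surface passes through half effect at unit index for every gamma", {
  for (g in c(0.5, 1, 2.5, 8)) {
    expect_equal(hill_surface(1, g, 1), 0.5, info = paste("gamma", g))
    expect_equal(hill_surface(1, g, 0.43), 0.215, info = paste("gamma", g))
  }
  expect_equal(hill_surface(0, 2.5, 0.7), 0)
  expect_equal(hill_surface(6, 2.5, 1), 0.988786928522, tolerance = 1e-8)
})

test_that("Hill surface stays within [0, emax] and saturates for huge indices", {
  x <- c(0, 1e-8, 0.5, 1, 10, 1e6, 1e300)
  v <- hill_surface(x, 8, 0.7)
  expect_true(all(v >= 0 & v <= 0.7))
  expect_equal(v[length(v)], 0.7)
})

test_that("effect is nondecreasing in each level and in sigma", {
  grid <- seq(0, 3, by = 0.25)
  for (s in c(0, 1, 4, 8)) {
    eff <- hill_surface(interaction_index(grid, 0.7, s), 2.5, 1)
    expect_true(all(diff(eff) >= 0), info = paste("sigma", s))
  }
  for (ua in c(0.2, 1, 2.5)) for (ub in c(0.1, 0.9)) {
    by_sigma <- sapply(c(0, 1, 4, 8), function(s)
      hill_surface(interaction_index(ua, ub, s), 2.5, 1))
    expect_true(all(diff(by_sigma) >= 0))
  }
})

test_that("with one agent absent the surface collapses to the 1-D Hill curve", {
  u <- seq(0, 4, by = 0.5)
  ref <- hill_surface(u, 2.5, 0.7)
  for (s in c(0, 4, 8))
    expect_equal(hill_surface(interaction_index(u, 0, s), 2.5, 0.7), ref)
})

test_that("state normalization divides each level by its potency", {
  p <- combined_parameters()
  st <- initial_state(p)
  un <- normalize_levels(st, p)
  expect_equal(un$tumor, 2)      # 100% of initial volume over C50_t = 50
  expect_equal(un$AG, 0); expect_equal(un$IM, 0); expect_equal(un$RT, 0)
  st["xe3"] <- 0.44; st["xe4"] <- 32e-6; st["xe5"] <- 20
  un <- normalize_levels(st, p)
  expect_equal(un$AG, 1); expect_equal(un$IM, 1); expect_equal(un$RT, 1)
})

test_that("combined effect vanishes without treatment and aggregates by means", {
  p <- combined_parameters()
  eb0 <- combined_effect(initial_state(p), p)
  for (f in c("Et_a", "Et_i", "Et_r", "E_ai", "E_ar", "E_ir",
              "Et_all", "Ed_all", "E"))
    expect_equal(eb0[[f]], 0, info = f)

  st <- initial_state(p)
  st[c("xe3", "xe4", "xe5")] <- c(0.3, 40e-6, 6)
  eb <- combined_effect(st, p)
  expect_equal(eb$Et_all, mean(c(eb$Et_a, eb$Et_i, eb$Et_r)))
  expect_equal(eb$Ed_all, mean(c(eb$E_ai, eb$E_ar, eb$E_ir)))
  expect_equal(eb$E, (eb$Et_all + eb$Ed_all) / 2)
  comps <- unlist(eb[c("Et_a", "Et_i", "Et_r", "E_ai", "E_ar", "E_ir",
                       "Et_all", "Ed_all", "E")])
  expect_true(all(comps >= 0 & comps <= 1))
  expect_gt(eb$E, 0)
})

test_that("combined effect grows with the synergy coefficient at a fixed state", {
  st <- initial_state(combined_parameters())
  st[c("xe3", "xe4", "xe5")] <- c(0.25, 20e-6, 4)
  e_by_sigma <- sapply(c(1, 2, 4, 8), function(s)
    combined_effect(st, combined_parameters(sigma = s))$E)
  expect_true(all(diff(e_by_sigma) >= 0))
  expect_gt(e_by_sigma[4], e_by_sigma[1])
})

test_that("surface grid export tabulates the isobole surface", {
  g <- surface_grid(un_a = c(0, 1), un_b = c(0, 1), sigma = 4, gamma = 2.5)
  expect_named(g, c("Un_A", "Un_B", "Effect"))
  expect_equal(nrow(g), 4)
  expect_equal(g$Effect[g$Un_A == 0 & g$Un_B == 0], 0)
  expect_equal(g$Effect[g$Un_A == 1 & g$Un_B == 1],
               hill_surface(6, 2.5, 1))
})
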