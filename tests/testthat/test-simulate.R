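test_that("an empty community does not move", {
  m <- make_competitive(mu = 1, beta = 0.3)
  m$species <- list()
  traj <- integrate_to_depletion(m)
  expect_equal(traj$times, 0)
  expect_equal(traj$termination_reason, "growth_arrested")
  expect_equal(unname(traj$terminal), unname(model_state0(m)))
  expect_equal(community_function(traj, m), 0)
})

test_that("a single competitor converts the whole budget at its yield", {
  m <- make_competitive(mu = 1, beta = 0.4, Y = 0.5, x0 = 0.01, C0 = 10)
  traj <- integrate_to_depletion(m)
  expect_equal(traj$termination_reason, "resource_depleted")
  expect_equal(traj$terminal[["x.s1"]], 5.01, tolerance = 1e-7)
  expect_equal(community_function(traj, m), 4, tolerance = 1e-7)
  # residual carbon is negligible relative to the budget
  expect_lt(traj$terminal[["C"]], 1e-6 * 10)
})

test_that("the nitrogen budget caps biomass exactly", {
  # carbon budget YC*C0 = 2.5 exceeds nitrogen budget YN*N0 = 2
  m <- make_ssmc(YC = 0.5, C0s = 5, N_budget = 2, x0 = 0.01)
  traj <- integrate_to_depletion(m)
  expect_equal(traj$terminal[["x"]], 0.01 + 2, tolerance = 1e-6)
  # the budget identity x - x0 = YN*(N0 - N) is linear, hence exact
  np <- m$nitrogen
  expect_equal(traj$terminal[["x"]] - 0.01,
               np$YN * (np$N0 - traj$terminal[["N"]]), tolerance = 1e-9)
  # carbon keeps draining under nitrogen arrest
  expect_lt(traj$terminal[["C1"]], 5 - 2 / 0.5)
})

test_that("symmetric communities split the pie equally", {
  m <- make_competitive(mu = c(1, 1), beta = c(0.2, 0.6))
  traj <- integrate_to_depletion(m)
  expect_equal(community_function(traj, m), 10 * mean(c(0.2, 0.6)),
               tolerance = 1e-7)
  expect_equal(traj$terminal[["x.s1"]], traj$terminal[["x.s2"]],
               tolerance = 1e-9)
})

test_that("byproduct bookkeeping holds along heterogeneous trajectories", {
  for (seed in 1:5) {
    m <- random_competitive(seed, n = 10)
    traj <- integrate_to_depletion(m)
    xinf <- traj$terminal[paste0("x.", species_ids(m))]
    x0 <- vapply(m$species, `[[`, 0, "x0")
    Y <- vapply(m$species, `[[`, 0, "Y")
    beta <- vapply(m$species, `[[`, 0, "beta")
    consumed <- (xinf - x0) / Y
    expect_equal(community_function(traj, m), sum(beta * consumed),
                 tolerance = 1e-7)
    # mass balance against the pool
    expect_equal(sum(consumed), 10 - traj$terminal[["C"]], tolerance = 1e-6)
  }
})

test_that("terminal states match the closed-form depletion oracle", {
  m <- random_competitive(17, n = 6)
  traj <- integrate_to_depletion(m, rel_tol = 1e-10, abs_tol = 1e-12)
  orc <- oracle_competitive(
    vapply(m$species, `[[`, 0, "mu"), vapply(m$species, `[[`, 0, "Y"),
    vapply(m$species, `[[`, 0, "x0"), model_C0(m),
    vapply(m$species, `[[`, 0, "beta"))
  expect_equal(unname(traj$terminal[paste0("x.", species_ids(m))]),
               unname(orc$xinf), tolerance = 1e-7)
  expect_equal(community_function(traj, m), orc$B, tolerance = 1e-7)

  mcf <- random_crossfeeding(23, np = 3, nk = 4)
  tcf <- integrate_to_depletion(mcf, rel_tol = 1e-10, abs_tol = 1e-12)
  expect_equal(community_function(tcf, mcf), oracle_crossfeeding(mcf)$B,
               tolerance = 1e-7)
})

test_that("cross-fed carbon is bounded by leaked primary carbon", {
  m <- make_crossfeeding(mu_p = 1, beta_p = 0.3, mu_k = 0.9, beta_k = 0.7,
                         pp = 0.6)
  traj <- integrate_to_depletion(m, rel_tol = 1e-10, abs_tol = 1e-12)
  # all primary carbon consumed, so total Ccf produced = pp * C0; the
  # consumer in turn ate all of it
  x0 <- 0.01
  consumed_k <- (traj$terminal[["x.c1"]] - x0) / 0.5
  expect_equal(consumed_k, 0.6 * 10, tolerance = 1e-6)
  expect_lt(traj$terminal[["Ccf"]], 1e-6)
})

test_that("F converges as tolerances tighten and ignores t_max when finished", {
  m <- random_competitive(9, n = 5)
  F_loose <- community_function(
    integrate_to_depletion(m, rel_tol = 1e-6, abs_tol = 1e-8), m)
  F_tight <- community_function(
    integrate_to_depletion(m, rel_tol = 1e-7, abs_tol = 1e-9), m)
  expect_lt(abs(F_loose - F_tight), 10 * 1e-6 * F_tight)

  F_a <- community_function(integrate_to_depletion(m, t_max = 1e3), m)
  F_b <- community_function(integrate_to_depletion(m, t_max = 1e4), m)
  expect_equal(F_a, F_b, tolerance = 1e-10)
})

test_that("hitting t_max is flagged and blocks the function value", {
  m <- make_competitive(mu = 0.1, beta = 0.3, x0 = 1e-3)
  traj <- integrate_to_depletion(m, t_max = 1)
  expect_equal(traj$termination_reason, "max_time")
  expect_error(community_function(traj, m), "t_max")
  expect_silent(community_function(traj, m, allow_max_time = TRUE))
})

test_that("the literal transcription variant scales byproduct by the yield", {
  m <- make_competitive(mu = c(1, 0.8), beta = c(0.4, 0.7), Y = 0.5)
  m$eq6_literal <- TRUE
  traj <- integrate_to_depletion(m)
  xinf <- traj$terminal[paste0("x.", species_ids(m))]
  dx <- xinf - 0.01
  # dB = beta * Y * dx/dt integrates to beta * Y * (x_inf - x0)
  expect_equal(community_function(traj, m),
               sum(c(0.4, 0.7) * 0.5 * dx), tolerance = 1e-7)
})

test_that("trajectories export as tidy long tables", {
  m <- make_competitive(mu = 1, beta = 0.3)
  traj <- integrate_to_depletion(m, times = seq(0, 100, length.out = 21))
  df <- as.data.frame(traj)
  expect_named(df, c("time", "variable", "value"))
  expect_setequal(unique(df$variable), c("x.s1", "C", "B"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  expect_equal(utils::read.csv(path), df, tolerance = 1e-12)
})
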