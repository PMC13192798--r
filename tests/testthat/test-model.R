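test_that("build_model constructs validated models and fills defaults", {
  m <- build_model(list(
    family = "competitive", C0 = 10, KM = 0.5,
    species = list(list(id = "a", mu = 1), list(id = "b", mu = 1.2),
                   list(id = "c", mu = 0.8))))
  expect_s3_class(m, "community_model")
  expect_length(m$species, 3)
  expect_length(m$carbons, 1)
  expect_equal(model_C0(m), 10)
  # shared KM filled into species without their own K
  expect_equal(vapply(m$species, `[[`, 0, "K"), rep(0.5, 3))
  expect_equal(vapply(m$species, `[[`, 0, "pp"), rep(0, 3))

  m2 <- build_model(list(
    family = "single_species_multicarbon",
    species = list(list(id = "sp", mu = 1)),
    carbons = lapply(1:10, function(i) list(id = paste0("C", i), C0 = 1)),
    nitrogen = list(N0 = 5)))
  expect_length(model_state0(m2), 12)  # x + 10 carbons + N
})

test_that("validation errors name the offending field or rule", {
  expect_error(species_phenotype("a", mu = -1), "mu")
  expect_error(species_phenotype("a", mu = 1, Y = 0), "Y")
  expect_error(species_phenotype("a", mu = 1, beta = -0.1), "beta")
  expect_error(species_phenotype("a", mu = 1, pp = 1, guild = "producer"),
               "pp")
  expect_error(species_phenotype("a", mu = 1, pp = 0.2), "producer")
  expect_error(carbon_source("C", C0 = -1), "C0")
  expect_error(build_model(list(family = "competitive", C0 = 10,
                                species = list(list(id = "a")))), "mu")
  # crossfeeding without both guilds is a composition error
  expect_error(make_crossfeeding(mu_p = 1, beta_p = 0.3, mu_k = numeric(0),
                                 beta_k = numeric(0), pp = 0.3),
               "producer and one consumer")
  # duplicate ids
  expect_error(make_competitive(mu = c(1, 1), beta = 0.3, ids = c("a", "a")),
               "unique")
  # niche partitioning needs two pools and the two guilds
  expect_error(community_model(
    "niche_partitioned",
    species = list(species_phenotype("a", mu = 1, guild = "groupA")),
    carbons = list(carbon_source("C1", 5))), "two carbon pools")
})

test_that("single-species rhs follows Liebig's minimum and drains carbon", {
  # one carbon at half saturation with YC*rC = 2, nitrogen in huge excess
  m <- make_ssmc(YC = 2, C0s = 1, rC = 1, KC = 1, N_budget = 1e6, YN = 1,
                 rN = 1e3)
  st <- model_state0(m)
  st[["x"]] <- 1; st[["C1"]] <- 1
  d <- model_rhs(m, st)
  expect_equal(d[["x"]], 1.0)              # 1 * min(2 * 0.5, huge)
  expect_equal(d[["C1"]], -0.5)            # -x * r * C/(K+C)

  # nitrogen exhausted: growth stops, carbon still drains
  st[["N"]] <- 0
  d <- model_rhs(m, st)
  expect_equal(d[["x"]], 0)
  expect_equal(d[["N"]], 0)
  expect_lt(d[["C1"]], 0)

  # no carbon anywhere: no growth even with nitrogen present
  st[["N"]] <- 10; st[["C1"]] <- 0
  d <- model_rhs(m, st)
  expect_equal(d[["x"]], 0)
})

test_that("competitive rhs: Monod growth, yield-scaled drain, per-carbon byproduct", {
  m <- make_competitive(mu = 1, beta = 0.4, Y = 0.5, KM = 1)
  st <- model_state0(m)
  st[["x.s1"]] <- 1; st[["C"]] <- 1   # C = KM
  d <- model_rhs(m, st)
  expect_equal(d[["x.s1"]], 0.5)
  expect_equal(d[["C"]], -1.0)
  expect_equal(d[["B"]], 0.4)         # beta per unit carbon consumed

  # exchange symmetry of identical species
  m2 <- make_competitive(mu = c(1, 1), beta = c(0.3, 0.3), x0 = 0.02)
  st2 <- model_state0(m2)
  d2 <- model_rhs(m2, st2)
  expect_equal(d2[["x.s1"]], d2[["x.s2"]])

  # exhausted pool: everything is zero
  st2[["C"]] <- 0
  expect_equal(unname(model_rhs(m2, st2)), rep(0, length(st2)))

  expect_error(model_rhs(m, replace(st, 2, -1)), "negative")
})

test_that("crossfeeding rhs reduces to competitive when leakage is zero", {
  mcf <- make_crossfeeding(mu_p = c(1, 0.8), beta_p = c(0.3, 0.5),
                           mu_k = 0.9, beta_k = 0.7, pp = 0)
  st <- model_state0(mcf)
  st[["C"]] <- 2
  d <- model_rhs(mcf, st)
  # producers behave exactly like competitors
  mcmp <- make_competitive(mu = c(1, 0.8), beta = c(0.3, 0.5), ids = c("p1", "p2"))
  stc <- model_state0(mcmp); stc[["C"]] <- 2
  dc <- model_rhs(mcmp, stc)
  expect_equal(d[["x.p1"]], dc[["x.p1"]])
  expect_equal(d[["C"]], dc[["C"]])
  expect_equal(d[["B"]], dc[["B"]])
  # consumers are inert: no cross-fed carbon ever appears
  expect_equal(d[["Ccf"]], 0)
  expect_equal(d[["x.c1"]], 0)
})

test_that("leaked carbon is bookkept: producer consumption splits into biomass and Ccf", {
  m <- make_crossfeeding(mu_p = 1, beta_p = 0.3, mu_k = 0.9, beta_k = 0.7,
                         pp = 0.4, Y = 0.5)
  st <- model_state0(m)
  st[["x.p1"]] <- 1; st[["C"]] <- 1  # half saturation
  d <- model_rhs(m, st)
  g <- 0.5                       # mu * C/(KM+C) * x
  q <- g / ((1 - 0.4) * 0.5)     # consumption with yield on retained carbon
  expect_equal(d[["x.p1"]], g)
  expect_equal(d[["C"]], -q)
  expect_equal(d[["Ccf"]], 0.4 * q)
  # byproduct counts retained carbon: beta * (1-pp) * q = beta * g / Y
  expect_equal(d[["B"]], 0.3 * (1 - 0.4) * q)
  expect_equal(d[["B"]], 0.3 * g / 0.5)

  # the total-carbon comparison variant counts the leaked fraction too
  mt <- m; mt$producer_beta_total <- TRUE
  expect_equal(model_rhs(mt, st)[["B"]], 0.3 * q)
})

test_that("reference R derivatives agree with the compiled integrator path", {
  # integrate the same model with the pure-R rhs through a generic solver
  # and with the package's compiled path; terminal states must agree
  for (seed in c(2, 5)) {
    m <- random_crossfeeding(seed, np = 2, nk = 3)
    traj <- integrate_to_depletion(m, rel_tol = 1e-10, abs_tol = 1e-12)
    rfun <- function(t, y, p) {
      names(y) <- names(model_state0(m))
      list(unname(model_rhs(m, pmax(y, 0))))
    }
    out <- deSolve::lsoda(model_state0(m), times = c(0, 60), func = rfun,
                          rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(traj$terminal), unname(out[2, -1]), tolerance = 1e-7)
  }
})

test_that("facilitation multiplies the beta of present targets only", {
  sp <- list(
    species_phenotype("helper", mu = 1, beta = 0.1,
                      facilitation_targets = list(list(id = "star",
                                                       multiplier = 3))),
    species_phenotype("star", mu = 1, beta = 0.3))
  m <- community_model("facilitation", sp,
                       list(carbon_source("C", 10, Y = 1, K = 1)), KM = 1)
  expect_equal(unname(beta_effective(m)), c(0.1, 0.9))
  # absent helper: no boost
  expect_equal(unname(beta_effective(subset_model(m, "star"))), 0.3)
})

test_that("subset_model removes species from the state entirely", {
  m <- make_competitive(mu = c(1, 1.2, 0.8), beta = 0.3)
  s <- subset_model(m, c("s1", "s3"))
  expect_equal(species_ids(s), c("s1", "s3"))
  expect_named(model_state0(s), c("x.s1", "x.s3", "C", "B"))
  expect_error(subset_model(m, "nope"), "unknown species")
})
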