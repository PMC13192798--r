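test_that("ols_fit recovers lines and rejects degenerate inputs", {
  pts <- data.frame(F = c(1, 2, 3), deltaF = c(3, 2, 1))
  expect_equal(ols_fit(pts), c(slope = -1, intercept = 4))
  flat <- data.frame(F = c(1, 2, 3), deltaF = c(0.7, 0.7, 0.7))
  expect_equal(ols_fit(flat), c(slope = 0, intercept = 0.7))
  expect_error(ols_fit(data.frame(F = c(2, 2), deltaF = c(1, 3))),
               "degenerate")
})

test_that("ols slope matches the symmetry closed form", {
  # symmetric community, backgrounds restricted to a common size s:
  # every point sits on the line with slope -1/(s+1)
  for (n_pool in 3:5) {
    m <- make_competitive(mu = rep(1, n_pool + 1),
                          beta = seq(0.2, 0.9, length.out = n_pool + 1))
    scan <- scan_focal_species(m, paste0("s", n_pool + 1))
    sizes <- nchar(gsub("0", "", scan$points$background))
    s <- n_pool - 1                      # choose(n_pool, s) >= 3 subsets
    sub <- scan$points[sizes == s, , drop = FALSE]
    fit_sub <- ols_fit(sub)
    expect_equal(fit_sub[["slope"]], -1 / (s + 1), tolerance = 1e-6)
  }
})

test_that("weighted correlation is exact on lines and matches a brute-force oracle", {
  up <- data.frame(F = 1:10, deltaF = 2 * (1:10) + 3)
  dn <- data.frame(F = 1:10, deltaF = -0.5 * (1:10) + 1)
  expect_equal(weighted_correlation(up, 5), 1, tolerance = 1e-12)
  expect_equal(weighted_correlation(dn, 5), -1, tolerance = 1e-12)

  # curved cloud: compare against the one-line weighted-Pearson formula
  set.seed(42)
  F <- sort(runif(200, 0, 10))
  dF <- (F - 5)^2 + rnorm(200, 0, 0.5)
  pts <- data.frame(F = F, deltaF = dF)
  n_bins <- 20
  edges <- seq(min(F), max(F), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(F, edges, rightmost.closed = TRUE), 1),
              n_bins)
  w <- 1 / tabulate(bin, n_bins)[bin]
  mw <- function(v) sum(w * v) / sum(w)
  rho_oracle <- (mw(F * dF) - mw(F) * mw(dF)) /
    sqrt((mw(F^2) - mw(F)^2) * (mw(dF^2) - mw(dF)^2))
  expect_equal(weighted_correlation(pts, n_bins), rho_oracle,
               tolerance = 1e-10)
  expect_lt(abs(weighted_correlation(pts, n_bins)), 1)
})

test_that("uniform weights reduce to plain Pearson and affine invariance holds", {
  set.seed(7)
  pts <- data.frame(F = runif(50), deltaF = runif(50))
  expect_equal(weighted_correlation(pts, n_bins = 1),
               cor(pts$F, pts$deltaF), tolerance = 1e-12)
  r0 <- weighted_correlation(pts, 10)
  shifted <- data.frame(F = 3 * pts$F + 2, deltaF = 0.1 * pts$deltaF - 4)
  expect_equal(weighted_correlation(shifted, 10), r0, tolerance = 1e-12)
  flipped <- data.frame(F = -pts$F, deltaF = pts$deltaF)
  expect_equal(weighted_correlation(flipped, 10), -r0, tolerance = 1e-12)
})

test_that("degenerate clouds are flagged, not silently zero", {
  pts <- data.frame(F = 1:10, deltaF = rep(0, 10))
  expect_warning(r <- weighted_correlation(pts, 5), "degenerate")
  expect_true(is.na(r))
  expect_true(attr(r, "degenerate"))
})

test_that("alpha estimation matches exchange symmetry and the consumption oracle", {
  # sole consumer takes (C0 - C_inf)/C0 which tends to 1
  m1 <- make_competitive(mu = 1, beta = 0.3)
  expect_equal(estimate_alpha(m1, character(0), "s1"), 1, tolerance = 1e-6)

  # symmetric (n+1)-species community: alpha = 1/(n+1)
  m3 <- make_competitive(mu = rep(1, 3), beta = c(0.2, 0.6, 0.9))
  expect_equal(estimate_alpha(m3, c("s1", "s2"), "s3"), 1 / 3,
               tolerance = 1e-6)

  # heterogeneous community: match the closed-form consumption share
  m <- random_competitive(31, n = 10)
  orc <- oracle_competitive(
    vapply(m$species, `[[`, 0, "mu"), vapply(m$species, `[[`, 0, "Y"),
    vapply(m$species, `[[`, 0, "x0"), model_C0(m),
    vapply(m$species, `[[`, 0, "beta"))
  a <- estimate_alpha(m, species_ids(m)[1:9], species_ids(m)[10],
                      rel_tol = 1e-10, abs_tol = 1e-12)
  expect_equal(a, orc$consumed[10] / 10, tolerance = 1e-6)
})

test_that("the analytic line is plain substitution in alpha, C0, beta_j", {
  expect_equal(eq7_prediction(1 / 3, 10, 0.9),
               c(analytic_slope = -1 / 3, analytic_intercept = 3))
  expect_equal(eq7_prediction(0, 10, 0.5),
               c(analytic_slope = 0, analytic_intercept = 0))
  p <- eq7_prediction(0.4, 10, 0)
  expect_equal(p[["analytic_intercept"]], 0)
  expect_lt(p[["analytic_slope"]], 0)
  expect_error(eq7_prediction(1.2, 10, 0.5))
})

test_that("fit_scan agrees with the analytic line under symmetry", {
  m <- make_competitive(mu = rep(1, 4), beta = c(0.2, 0.4, 0.6, 0.9))
  scan <- scan_focal_species(m, "s4")
  # restrict to full-size backgrounds where the reference alpha applies
  sizes <- nchar(gsub("0", "", scan$points$background))
  scan$points <- scan$points[sizes == 3, , drop = FALSE]
  # need >= 2 distinct F: sizes-3 has only one subset; use sizes 2 and 3
  scan2 <- scan_focal_species(m, "s4")
  fit <- fit_scan(scan2, m)
  expect_equal(fit$alpha, 1 / 4, tolerance = 1e-6)
  expect_equal(fit$analytic_slope, -fit$alpha)
  expect_equal(fit$analytic_intercept, fit$alpha * 10 * 0.9, tolerance = 1e-6)
  # under symmetry the consumption-weighted mean efficiency is arithmetic
  expect_equal(fit$beta_mean_background, mean(c(0.2, 0.4, 0.6)),
               tolerance = 1e-6)
})

test_that("growth-rate heterogeneity biases measured below analytic", {
  set.seed(12)
  m <- make_competitive(mu = runif(8, 0.6, 1.4), beta = runif(8, 0.1, 0.9))
  # focal with a fast growth rate so the scan is informative
  m$species[[8]]$mu <- 1.45
  scan <- scan_focal_species(m, "s8")
  fit <- fit_scan(scan, m)
  expect_lt(fit$slope, fit$analytic_slope)
  expect_gt(fit$intercept, fit$analytic_intercept)
})

test_that("the average-efficiency identity F = C0 * <beta>_S holds", {
  for (seed in c(4, 8)) {
    m <- random_competitive(seed, n = 6)
    traj <- integrate_to_depletion(m)
    xinf <- traj$terminal[paste0("x.", species_ids(m))]
    x0 <- vapply(m$species, `[[`, 0, "x0")
    Y <- vapply(m$species, `[[`, 0, "Y")
    beta <- vapply(m$species, `[[`, 0, "beta")
    f <- ((xinf - x0) / Y) / 10          # consumption fractions
    expect_equal(sum(f), 1, tolerance = 1e-6)
    expect_equal(community_function(traj, m), 10 * sum(f * beta),
                 tolerance = 1e-6)
  }
})
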