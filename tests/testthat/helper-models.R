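# model builders shared across the test files

make_competitive <- function(mu, beta, Y = 0.5, x0 = 0.01, C0 = 10, KM = 1,
                             family = "competitive", ids = NULL) {
  n <- length(mu)
  if (length(beta) == 1) beta <- rep(beta, n)
  if (length(Y) == 1) Y <- rep(Y, n)
  if (length(x0) == 1) x0 <- rep(x0, n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  community_model(
    family = family,
    species = lapply(seq_len(n), function(i)
      species_phenotype(id = ids[i], mu = mu[i], Y = Y[i], beta = beta[i],
                        x0 = x0[i])),
    carbons = list(carbon_source("C", C0 = C0, Y = 1, K = KM)),
    KM = KM)
}

make_crossfeeding <- function(mu_p, beta_p, mu_k, beta_k, pp, Y = 0.5,
                              x0 = 0.01, C0 = 10, KM = 1) {
  np <- length(mu_p); nk <- length(mu_k)
  sp <- c(
    lapply(seq_len(np), function(i)
      species_phenotype(id = paste0("p", i), mu = mu_p[i], Y = Y,
                        beta = beta_p[i], x0 = x0, guild = "producer",
                        pp = pp)),
    lapply(seq_len(nk), function(i)
      species_phenotype(id = paste0("c", i), mu = mu_k[i], Y = Y,
                        beta = beta_k[i], x0 = x0, guild = "consumer")))
  community_model("crossfeeding", sp,
                  list(carbon_source("C", C0 = C0, Y = 1, K = KM)), KM = KM)
}

# rN defaults fast so that nitrogen limits through its budget, not its
# uptake rate: with slow nitrogen uptake the Liebig minimum throttles growth
# while carbon drains unconverted, and the budget arithmetic no longer holds
make_ssmc <- function(YC, C0s, rC = NULL, x0 = 0.01, N_budget = NULL,
                      YN = 0.8, rN = 30, KC = 0.1, KN = 0.01) {
  m <- length(YC)
  if (is.null(rC)) rC <- rep(1, m)
  carbons <- lapply(seq_len(m), function(i)
    carbon_source(paste0("C", i), C0 = C0s[i], r = rC[i], Y = YC[i], K = KC))
  nitrogen <- if (!is.null(N_budget))
    nitrogen_pool(N0 = N_budget / YN, rN = rN, YN = YN, KN = KN)
  community_model(
    "single_species_multicarbon",
    species = list(species_phenotype("sp", mu = 1, Y = 1, x0 = x0)),
    carbons = carbons, nitrogen = nitrogen)
}

# deterministic 10-carbon template used by the resource-landscape tests:
# per-source budgets YC*C0 spread over ~0.37..1.4, total about 8.4
make_ssmc_template <- function(N_budget = NULL) {
  i <- 1:10
  make_ssmc(YC = 0.3 + 0.04 * i, C0s = 1 + 0.1 * i, rC = 0.8 + 0.05 * i,
            N_budget = N_budget)
}

random_competitive <- function(seed, n = 8, C0 = 10) {
  set.seed(seed)
  make_competitive(mu = runif(n, 0.5, 1.5), beta = runif(n, 0.05, 0.95),
                   Y = runif(n, 0.3, 0.7), x0 = 10^runif(n, -3, -1.5),
                   C0 = C0, KM = runif(1, 0.5, 2))
}

random_crossfeeding <- function(seed, np = 3, nk = 4, pp = NULL) {
  set.seed(seed)
  if (is.null(pp)) pp <- runif(1, 0.05, 0.9)
  make_crossfeeding(mu_p = runif(np, 0.5, 1.5), beta_p = runif(np, 0.05, 0.95),
                    mu_k = runif(nk, 0.5, 1.5), beta_k = runif(nk, 0.05, 0.95),
                    pp = pp, x0 = 0.01)
}
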