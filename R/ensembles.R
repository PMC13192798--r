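#' Configuration for random-community ensembles
#'
#' Sampling law and experiment sizes for the two ensemble experiments:
#' measured-vs-analytic slopes and intercepts under growth-rate heterogeneity
#' (competitive family), and the guild-averaged density-weighted correlation
#' across a leakage sweep (cross-feeding family). Growth rates are sampled
#' uniformly in `mu_center * (1 - mu_spread, 1 + mu_spread)`, byproduct
#' yields uniformly in `beta_range`; yields, inocula and half-saturations
#' are fixed (`Y_fixed`, `x0 = 1e-3 * C0`, `KM = 0.1 * C0` by default).
#' Everything downstream is a pure function of this config, including `seed`.
#'
#' @param n_species Community size.
#' @param n_producers Number of producer species (cross-feeding family;
#'   0 means purely competitive). Producers are the first `n_producers`
#'   species; the rest are consumers.
#' @param mu_center,mu_spread Center and relative half-width of the uniform
#'   growth-rate band (spread 0 gives identical rates).
#' @param beta_range Length-2 range for byproduct yields.
#' @param beta_range_producers,beta_range_consumers Optional guild-specific
#'   overrides of `beta_range` (cross-feeding family).
#' @param Y_fixed Growth yield shared by all species.
#' @param C0 Initial carbon budget.
#' @param x0 Initial biomass per species.
#' @param KM Community-wide half-saturation.
#' @param leakage_grid Leakage fractions pp for [leakage_sweep()].
#' @param n_communities Number of replicate community parameterizations.
#' @param background_mode `"auto"` (exhaustive below pool size 12, else
#'   subsample), `"exhaustive"`, or `"subsample"`.
#' @param n_sample Subsets per focal in subsample mode.
#' @param n_bins Bins for the density-weighted correlation.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_species = 10, n_producers = 0,
                            mu_center = 1, mu_spread = 0.3,
                            beta_range = c(0.05, 0.95),
                            beta_range_producers = NULL,
                            beta_range_consumers = NULL,
                            Y_fixed = 0.5, C0 = 10, x0 = 1e-3 * C0,
                            KM = 0.1 * C0,
                            leakage_grid = c(0.05, 0.1, 0.2, 0.4, 0.6, 0.8),
                            n_communities = 10,
                            background_mode = c("auto", "exhaustive",
                                                "subsample"),
                            n_sample = 200, n_bins = 20, seed = 1) {
  background_mode <- match.arg(background_mode)
  stopifnot(n_species >= 1, n_producers >= 0, n_producers < n_species,
            mu_center > 0, mu_spread >= 0, mu_spread < 1,
            length(beta_range) == 2, beta_range[1] >= 0,
            diff(beta_range) >= 0, Y_fixed > 0, C0 > 0, x0 > 0, KM > 0,
            all(leakage_grid >= 0), all(leakage_grid < 1),
            n_communities >= 1, n_sample >= 2, n_bins >= 1,
            is.numeric(seed), length(seed) == 1)
  structure(list(
    n_species = n_species, n_producers = n_producers,
    mu_center = mu_center, mu_spread = mu_spread,
    beta_range = beta_range,
    beta_range_producers = beta_range_producers,
    beta_range_consumers = beta_range_consumers,
    Y_fixed = Y_fixed, C0 = C0, x0 = x0, KM = KM,
    leakage_grid = leakage_grid, n_communities = n_communities,
    background_mode = background_mode, n_sample = n_sample,
    n_bins = n_bins, seed = as.integer(seed)), class = "ensemble_config")
}

#' Draw one random community from an ensemble configuration
#'
#' Deterministic in `(config$seed, replicate_index)`. Guilds are assigned by
#' index: species `p1 ... p<Np>` are producers, the rest (`c...`) consumers;
#' with `n_producers = 0` all species are competitors (`s...`). Producer
#' leakage is left at 0 here; [set_leakage()] applies a pp value.
#'
#' @param config An [ensemble_config()].
#' @param replicate_index Positive integer.
#' @return A `community_model`.
#' @export
sample_community <- function(config, replicate_index) {
  stopifnot(inherits(config, "ensemble_config"), replicate_index >= 1)
  n <- config$n_species
  np <- config$n_producers
  draws <- .with_seed(.sub_seed(config$seed, replicate_index), {
    mu <- stats::runif(n, config$mu_center * (1 - config$mu_spread),
                       config$mu_center * (1 + config$mu_spread))
    br_p <- config$beta_range_producers %||% config$beta_range
    br_c <- config$beta_range_consumers %||% config$beta_range
    beta <- if (np > 0) {
      c(stats::runif(np, br_p[1], br_p[2]),
        stats::runif(n - np, br_c[1], br_c[2]))
    } else stats::runif(n, config$beta_range[1], config$beta_range[2])
    list(mu = mu, beta = beta)
  })
  guild <- if (np > 0) c(rep("producer", np), rep("consumer", n - np))
           else rep("competitor", n)
  ids <- if (np > 0) c(paste0("p", seq_len(np)), paste0("c", seq_len(n - np)))
         else paste0("s", seq_len(n))
  species <- lapply(seq_len(n), function(i)
    species_phenotype(id = ids[i], mu = draws$mu[i], Y = config$Y_fixed,
                      beta = draws$beta[i], x0 = config$x0,
                      guild = guild[i], pp = 0))
  community_model(
    family = if (np > 0) "crossfeeding" else "competitive",
    species = species,
    carbons = list(carbon_source(id = "C", C0 = config$C0, Y = 1,
                                 K = config$KM)),
    KM = config$KM)
}

#' Set the leakage fraction of all producers
#'
#' @param model A cross-feeding `community_model`.
#' @param pp Leakage fraction in `[0, 1)`.
#' @return The model with every producer's `pp` replaced.
#' @export
set_leakage <- function(model, pp) {
  stopifnot(pp >= 0, pp < 1)
  model$species <- lapply(model$species, function(s) {
    if (s$guild == "producer") s$pp <- pp
    s
  })
  model
}

#' Measured versus analytic slopes and intercepts across an ensemble
#'
#' For every community replicate and every focal species: scan the focal
#' over background subsets, fit the measured OLS line, and compute the
#' analytic slope/intercept from the simulated carbon share on the full
#' background. With `mu_spread = 0` measured and analytic coincide; with
#' growth-rate heterogeneity the measured slopes are systematically more
#' negative and the intercepts higher.
#'
#' @param config An [ensemble_config()] (competitive family,
#'   `n_producers = 0`).
#' @param rel_tol,abs_tol Solver tolerances (scan workloads default looser
#'   than single-trajectory work; see the methods vignette).
#' @return A data.frame with one row per (replicate, focal): measured
#'   `slope`/`intercept`, `analytic_slope`/`analytic_intercept`, `alpha`,
#'   `rho_w`, `beta_j`, `n_points`.
#' @export
slope_intercept_experiment <- function(config, rel_tol = 1e-8,
                                       abs_tol = 1e-10) {
  stopifnot(inherits(config, "ensemble_config"), config$n_producers == 0)
  out <- list()
  for (rep_i in seq_len(config$n_communities)) {
    model <- sample_community(config, rep_i)
    ids <- species_ids(model)
    beta <- beta_effective(model)
    for (fi in seq_along(ids)) {
      bgs <- .ensemble_backgrounds(config, length(ids) - 1L, rep_i, fi)
      scan <- scan_focal_species(model, ids[fi], bgs,
                                 rel_tol = rel_tol, abs_tol = abs_tol)
      fit <- fit_scan(scan, model, n_bins = config$n_bins,
                      rel_tol = rel_tol, abs_tol = abs_tol)
      out[[length(out) + 1L]] <- data.frame(
        replicate = rep_i, focal = ids[fi],
        slope = fit$slope, intercept = fit$intercept,
        analytic_slope = fit$analytic_slope,
        analytic_intercept = fit$analytic_intercept,
        alpha = fit$alpha, rho_w = fit$rho_w, beta_j = beta[[fi]],
        n_points = fit$n_points, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Guild-averaged density-weighted correlation across a leakage sweep
#'
#' For every leakage value and every community replicate: compute `rho_w`
#' of the deltaF-vs-F scan for every focal species, average within the
#' producer guild and within the consumer guild, then aggregate mean and
#' standard deviation across replicates. The community phenotypes are drawn
#' once per replicate and shared across the leakage grid; the background
#' subsets per focal are likewise shared, so the sweep is paired in pp.
#' Degenerate scans (no variance, e.g. every deltaF = 0) are excluded from
#' the guild mean and counted.
#'
#' @param config An [ensemble_config()] with `n_producers >= 1`.
#' @param rel_tol,abs_tol Solver tolerances.
#' @param progress If `TRUE`, print one line per (pp, replicate).
#' @return An object of class `sweep_result`: `long` (one row per
#'   pp/replicate/focal) and `summary` (mean and sd of the per-replicate
#'   guild means, plus degenerate counts, per pp and guild).
#' @export
leakage_sweep <- function(config, rel_tol = 1e-8, abs_tol = 1e-10,
                          progress = FALSE) {
  stopifnot(inherits(config, "ensemble_config"), config$n_producers >= 1)
  long <- list()
  for (rep_i in seq_len(config$n_communities)) {
    base <- sample_community(config, rep_i)
    ids <- species_ids(base)
    guilds <- species_guilds(base)
    bgs_per_focal <- lapply(seq_along(ids), function(fi)
      .ensemble_backgrounds(config, length(ids) - 1L, rep_i, fi))
    for (pp in config$leakage_grid) {
      model <- set_leakage(base, pp)
      if (progress)
        message(sprintf("pp = %.2f, replicate %d", pp, rep_i))
      for (fi in seq_along(ids)) {
        scan <- scan_focal_species(model, ids[fi], bgs_per_focal[[fi]],
                                   rel_tol = rel_tol, abs_tol = abs_tol)
        rho <- tryCatch(
          withCallingHandlers(
            weighted_correlation(scan, n_bins = config$n_bins),
            warning = function(w) invokeRestart("muffleWarning")),
          error = function(e) structure(NA_real_, degenerate = TRUE))
        long[[length(long) + 1L]] <- data.frame(
          replicate = rep_i, pp = pp, guild = guilds[fi], focal = ids[fi],
          rho_w = as.numeric(rho),
          degenerate = isTRUE(attr(rho, "degenerate")) || is.na(rho),
          stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, long)

  # per-replicate guild means, then mean/sd across replicates
  key <- interaction(long$pp, long$guild, long$replicate, drop = TRUE)
  repmean <- stats::aggregate(rho_w ~ pp + guild + replicate,
                              data = long[!long$degenerate, ], FUN = mean)
  summary <- do.call(rbind, lapply(
    split(repmean, interaction(repmean$pp, repmean$guild, drop = TRUE)),
    function(d) data.frame(
      pp = d$pp[1], guild = d$guild[1],
      mean_rho_w = mean(d$rho_w),
      sd_rho_w = stats::sd(d$rho_w),
      n_replicates = nrow(d), stringsAsFactors = FALSE)))
  ndeg <- stats::aggregate(degenerate ~ pp + guild, data = long, FUN = sum)
  names(ndeg)[3] <- "n_degenerate"
  summary <- merge(summary, ndeg, by = c("pp", "guild"))
  summary <- summary[order(summary$guild, summary$pp), ]
  rownames(summary) <- NULL
  if (any(summary$n_degenerate > 0))
    message("excluded ", sum(summary$n_degenerate),
            " degenerate focal scans from guild means")
  structure(list(long = long, summary = summary, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", x$config$n_communities, "replicates,",
      x$config$n_species, "species (", x$config$n_producers, "producers )\n")
  print(x$summary, digits = 3)
  invisible(x)
}

.ensemble_backgrounds <- function(config, pool_size, rep_i, focal_i) {
  mode <- config$background_mode
  if (mode == "auto")
    mode <- if (pool_size < 12) "exhaustive" else "subsample"
  if (mode == "exhaustive") enumerate_backgrounds(pool_size)
  else enumerate_backgrounds(pool_size, "subsample",
                             n_sample = min(config$n_sample, 2^pool_size),
                             seed = .sub_seed(config$seed, rep_i, focal_i))
}

.sub_seed <- function(seed, a, b = 0) {
  (abs(seed) * 10007 + a * 104729 + b * 7919) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
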