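#' Initial state vector of a model
#'
#' Canonical state layout. Community families:
#' `x.<species id>` biomasses, one entry per carbon pool (named by its id),
#' a cross-fed pool `Ccf` (cross-feeding family only), and the accumulated
#' byproduct `B`. Single-species multi-carbon family: `x`, one entry per
#' carbon source, and `N` (omitted when the model has no nitrogen pool).
#'
#' @param model A `community_model`.
#' @return Named numeric vector.
#' @export
model_state0 <- function(model) {
  if (model$family == "single_species_multicarbon") {
    y <- c(x = model$species[[1]]$x0,
           vapply(model$carbons, `[[`, 0, "C0"))
    names(y)[-1] <- vapply(model$carbons, `[[`, "", "id")
    if (!is.null(model$nitrogen)) y <- c(y, N = model$nitrogen$N0)
    return(y)
  }
  x <- vapply(model$species, `[[`, 0, "x0")
  if (length(x)) names(x) <- paste0("x.", species_ids(model))
  r <- vapply(model$carbons, `[[`, 0, "C0")
  names(r) <- vapply(model$carbons, `[[`, "", "id")
  if (model$family == "crossfeeding") r <- c(r, Ccf = 0)
  c(x, r, B = 0)
}

#' Time derivative of a model state
#'
#' Reference implementation of the right-hand sides of all model families,
#' written for readability; the integrator uses an equivalent compiled
#' version (they are tested against each other). Negative state components
#' are a domain error here.
#'
#' Single-species multi-carbon family (substitutable carbons, essential
#' nitrogen, Liebig's minimum):
#' \deqn{\dot x = x \min\left(\sum_i Y_{Ci} r_{Ci} \frac{C_i}{K_{Ci}+C_i},\;
#'       Y_N r_N \frac{N}{K_N+N}\right),\quad
#'       \dot C_i = -x\, r_{Ci} \frac{C_i}{K_{Ci}+C_i},\quad
#'       \dot N = -\dot x / Y_N.}
#' Carbon drain is independent of which term limits growth, so carbon
#' continues to drain under nitrogen arrest.
#'
#' Community families: per-species growth \eqn{\dot x_i = \mu_i
#' R/(K_i+R)\,x_i} on the pool \eqn{R} the species consumes; carbon
#' consumption \eqn{q_i = \dot x_i / ((1-p_i) Y_i)} (so that the biomass
#' yield applies to retained carbon; \eqn{p_i = 0} for everything except
#' cross-feeding producers, which leak \eqn{p_i q_i} into the cross-fed
#' pool); byproduct flux \eqn{\dot B = \sum_i \beta_i^{\mathrm{eff}} q_i},
#' i.e. beta counts per unit carbon consumed.
#'
#' @param model A `community_model`.
#' @param state Named numeric state vector in [model_state0()] layout.
#' @return Named numeric vector of derivatives (same layout).
#' @export
model_rhs <- function(model, state) {
  if (any(state < 0))
    stop("negative state component: ",
         paste(names(state)[state < 0], collapse = ", "), call. = FALSE)

  if (model$family == "single_species_multicarbon") {
    m <- length(model$carbons)
    x <- state[["x"]]
    C <- state[1 + seq_len(m)]
    rC <- vapply(model$carbons, `[[`, 0, "r")
    YC <- vapply(model$carbons, `[[`, 0, "Y")
    KC <- vapply(model$carbons, `[[`, 0, "K")
    M <- rC * C / (KC + C)
    sumC <- sum(YC * M)
    if (is.null(model$nitrogen)) {
      g <- sumC
      dN <- NULL
    } else {
      np <- model$nitrogen
      gN <- np$YN * np$rN * state[["N"]] / (np$KN + state[["N"]])
      g <- min(sumC, gN)
      dN <- -x * g / np$YN
    }
    d <- c(x * g, -x * M, dN)
    names(d) <- names(state)
    return(d)
  }

  n <- length(model$species)
  nres <- length(model$carbons)
  cf <- model$family == "crossfeeding"
  beta <- beta_effective(model)
  d <- numeric(length(state))
  names(d) <- names(state)
  if (n == 0L) return(d)

  res_idx <- .resource_index(model)           # 1-based pool index per species
  pools <- state[n + seq_len(nres + cf)]
  for (i in seq_len(n)) {
    s <- model$species[[i]]
    R <- pools[[res_idx[i]]]
    g <- s$mu * R / (s$K + R) * state[[i]]
    q <- g / ((1 - s$pp) * s$Y)
    d[[i]] <- g
    d[[n + res_idx[i]]] <- d[[n + res_idx[i]]] - q
    if (cf && s$pp > 0)
      d[[n + nres + 1]] <- d[[n + nres + 1]] + s$pp * q
    d[["B"]] <- d[["B"]] +
      if (model$eq6_literal) beta[[i]] * s$Y * g
      else if (isTRUE(model$producer_beta_total)) beta[[i]] * q
      else beta[[i]] * (1 - s$pp) * q   # retained carbon = g / Y
  }
  d
}

# pool index (1-based, into the resource block of the state) per species
.resource_index <- function(model) {
  guilds <- species_guilds(model)
  switch(model$family,
    competitive = ,
    facilitation = rep(1L, length(guilds)),
    crossfeeding = ifelse(guilds == "consumer", 2L, 1L),
    niche_partitioned = ifelse(guilds == "groupB", 2L, 1L),
    stop("no community resource mapping for family ", model$family,
         call. = FALSE))
}

# Pack a model into the fixed-length parameter vector understood by the
# compiled derivatives (src/crm.c). Returns everything lsodar needs.
.pack_model <- function(model, stop_thr = 1e-8) {
  PARMS_LEN <- 1024L
  y0 <- model_state0(model)
  scale <- max(model_C0(model), 1e-6)

  if (model$family == "single_species_multicarbon") {
    m <- length(model$carbons)
    rC <- vapply(model$carbons, `[[`, 0, "r")
    YC <- vapply(model$carbons, `[[`, 0, "Y")
    KC <- vapply(model$carbons, `[[`, 0, "K")
    if (is.null(model$nitrogen)) {
      # sentinel never-limiting pool: uptake cap far above any carbon term
      budget <- model$species[[1]]$x0 + sum(YC * vapply(model$carbons, `[[`, 0, "C0"))
      np <- list(rN = 1e6 * max(1, max(YC * rC)), YN = 1, KN = 1,
                 N0 = 1e6 * max(1, budget))
      y0 <- c(y0, N = np$N0)
    } else np <- model$nitrogen
    p <- numeric(PARMS_LEN)
    p[1] <- m; p[5] <- stop_thr; p[4] <- scale
    p[8 + seq_len(m)] <- rC
    p[8 + m + seq_len(m)] <- YC
    p[8 + 2 * m + seq_len(m)] <- KC
    p[8 + 3 * m + 1:3] <- c(np$rN, np$YN, np$KN)
    return(list(y0 = y0, parms = p, derivs = "ssmc_derivs",
                root = "ssmc_root", scale = scale))
  }

  n <- length(model$species)
  nres <- length(model$carbons)
  cf <- as.integer(model$family == "crossfeeding")
  mu <- vapply(model$species, `[[`, 0, "mu")
  K <- vapply(model$species, `[[`, 0, "K")
  Y <- vapply(model$species, `[[`, 0, "Y")
  pp <- vapply(model$species, `[[`, 0, "pp")
  beta <- beta_effective(model)
  res0 <- .resource_index(model) - 1L

  p <- numeric(PARMS_LEN)
  p[1] <- n; p[2] <- nres; p[3] <- cf
  p[4] <- scale; p[5] <- stop_thr; p[6] <- as.integer(model$eq6_literal)
  p[7] <- as.integer(isTRUE(model$producer_beta_total))
  if (n > 0) {
    at <- function(k) 8 + k * n + seq_len(n)
    p[at(0)] <- mu
    p[at(1)] <- K
    p[at(2)] <- 1 / ((1 - pp) * Y)
    p[at(3)] <- pp
    p[at(4)] <- beta
    p[at(5)] <- res0
    p[at(6)] <- Y
  }
  list(y0 = y0, parms = p, derivs = "crm_derivs", root = "crm_root",
       scale = scale)
}
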