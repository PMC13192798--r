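#' Carbon source specification
#'
#' One substitutable carbon source in the single-species multi-carbon model.
#' Uptake follows Monod kinetics `r * C / (K + C)` and carbon is converted to
#' biomass with yield `Y`.
#'
#' @param id Character label, unique within a model.
#' @param C0 Initial concentration (mass/volume), `>= 0`.
#' @param r Maximal uptake rate (1/time), `> 0`.
#' @param Y Biomass yield per unit carbon, `> 0`.
#' @param K Half-saturation constant (mass/volume), `> 0`.
#' @return An object of class `carbon_source`.
#' @export
carbon_source <- function(id, C0, r = 1, Y = 0.5, K = 0.1) {
  .check_scalar(C0, "C0", min = 0)
  .check_scalar(r, "r", strict = TRUE)
  .check_scalar(Y, "Y", strict = TRUE)
  .check_scalar(K, "K", strict = TRUE)
  structure(list(id = as.character(id), C0 = C0, r = r, Y = Y, K = K),
            class = "carbon_source")
}

#' Nitrogen pool specification
#'
#' The essential, non-substitutable resource of the single-species
#' multi-carbon model. Growth is capped by the nitrogen uptake term
#' `YN * rN * N / (KN + N)` under Liebig's law of the minimum, and the
#' nitrogen budget bounds total biomass: `x(inf) - x0 <= YN * N0`.
#'
#' @param N0 Initial concentration, `>= 0`.
#' @param rN Maximal uptake rate (1/time), `> 0`.
#' @param YN Biomass yield per unit nitrogen, `> 0`.
#' @param KN Half-saturation constant, `> 0`.
#' @return An object of class `nitrogen_pool`.
#' @export
nitrogen_pool <- function(N0, rN = 1, YN = 1, KN = 0.1) {
  .check_scalar(N0, "N0", min = 0)
  .check_scalar(rN, "rN", strict = TRUE)
  .check_scalar(YN, "YN", strict = TRUE)
  .check_scalar(KN, "KN", strict = TRUE)
  structure(list(N0 = N0, rN = rN, YN = YN, KN = KN), class = "nitrogen_pool")
}

#' Species phenotype
#'
#' Growth and excretion parameters of one strain in the community families.
#' Growth is `mu * C/(K + C) * x` on the strain's carbon pool; `beta` is the
#' yield of byproduct per unit carbon consumed (dimensionless); producers in
#' the cross-feeding family additionally leak a fraction `pp` of consumed
#' carbon into the cross-fed pool.
#'
#' @param id Character label, unique within a model.
#' @param mu Maximal growth rate (1/time), `> 0`.
#' @param Y Growth yield (biomass per unit carbon), `> 0`.
#' @param beta Byproduct yield per unit carbon consumed, `>= 0`.
#' @param K Monod half-saturation; `NULL` means "use the community-wide KM".
#' @param x0 Initial biomass, `> 0`.
#' @param guild One of `"competitor"`, `"producer"`, `"consumer"`,
#'   `"groupA"`, `"groupB"`.
#' @param pp Leakage fraction in `[0, 1)`; only producers may have `pp > 0`.
#' @param facilitation_targets Optional list of `list(id=, multiplier=)`
#'   entries: when this strain is present, each named target's `beta` is
#'   multiplied by `multiplier` (`> 0`).
#' @return An object of class `species_phenotype`.
#' @export
species_phenotype <- function(id, mu, Y = 0.5, beta = 0, K = NULL, x0 = 0.01,
                              guild = "competitor", pp = 0,
                              facilitation_targets = NULL) {
  guild <- match.arg(guild, c("competitor", "producer", "consumer",
                              "groupA", "groupB"))
  .check_scalar(mu, "mu", strict = TRUE)
  .check_scalar(Y, "Y", strict = TRUE)
  .check_scalar(beta, "beta", min = 0)
  .check_scalar(x0, "x0", strict = TRUE)
  .check_scalar(pp, "pp", min = 0)
  if (pp >= 1)
    stop("pp: leakage fraction must be < 1 (a producer must retain some ",
         "carbon for growth)", call. = FALSE)
  if (pp > 0 && guild != "producer")
    stop("pp: only producers may leak carbon (guild is '", guild, "')",
         call. = FALSE)
  if (!is.null(K)) .check_scalar(K, "K", strict = TRUE)
  if (!is.null(facilitation_targets)) {
    for (ft in facilitation_targets) {
      if (is.null(ft$id) || is.null(ft$multiplier) || ft$multiplier <= 0)
        stop("facilitation_targets: each entry needs an id and a ",
             "multiplier > 0", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), mu = mu, Y = Y, beta = beta, K = K,
                 x0 = x0, guild = guild, pp = pp,
                 facilitation_targets = facilitation_targets),
            class = "species_phenotype")
}

.crm_families <- c("single_species_multicarbon", "competitive", "crossfeeding",
                   "niche_partitioned", "facilitation")

#' Community model
#'
#' The simulatable unit: a model family, its species, carbon pool(s) and
#' (optionally) a nitrogen pool. See [build_model()] for construction from a
#' plain-list / YAML / JSON specification.
#'
#' @param family One of `"single_species_multicarbon"`, `"competitive"`,
#'   `"crossfeeding"`, `"niche_partitioned"`, `"facilitation"`.
#' @param species List of [species_phenotype()] objects.
#' @param carbons List of [carbon_source()] objects. One pool for the
#'   single-pool community families, exactly two for `niche_partitioned`,
#'   one or more for `single_species_multicarbon`.
#' @param nitrogen Optional [nitrogen_pool()]; `single_species_multicarbon`
#'   only. `NULL` means nitrogen never limits.
#' @param KM Community-wide default half-saturation filled into species whose
#'   `K` is unset.
#' @param eq6_literal Logical; if `TRUE` the byproduct flux uses the literal
#'   transcription `beta * Y * growth` instead of the per-carbon-consumed
#'   convention `beta * consumption`. For comparison only.
#' @param producer_beta_total Logical; cross-feeding family only. By default
#'   a producer's byproduct counts its *retained* carbon (the fraction
#'   `1 - pp` routed through growth, making the byproduct law
#'   `beta * growth / Y` uniform across guilds). Set `TRUE` to count total
#'   consumed carbon, leaked fraction included. See the methods vignette for
#'   why the retained convention is the default.
#' @return An object of class `community_model`.
#' @export
community_model <- function(family, species, carbons,
                            nitrogen = NULL, KM = 0.1, eq6_literal = FALSE,
                            producer_beta_total = FALSE) {
  family <- match.arg(family, .crm_families)
  stopifnot(is.list(species), is.list(carbons))
  .check_scalar(KM, "KM", strict = TRUE)

  species <- lapply(species, function(s) {
    if (!inherits(s, "species_phenotype"))
      stop("species entries must be species_phenotype objects", call. = FALSE)
    if (is.null(s$K)) s$K <- KM
    s
  })
  for (cs in carbons)
    if (!inherits(cs, "carbon_source"))
      stop("carbons entries must be carbon_source objects", call. = FALSE)
  if (!is.null(nitrogen) && !inherits(nitrogen, "nitrogen_pool"))
    stop("nitrogen must be a nitrogen_pool or NULL", call. = FALSE)

  model <- structure(list(family = family, species = species,
                          carbons = carbons, nitrogen = nitrogen, KM = KM,
                          eq6_literal = isTRUE(eq6_literal),
                          producer_beta_total = isTRUE(producer_beta_total)),
                     class = "community_model")
  validate_model(model)
  model
}

#' Validate a community model
#'
#' Checks family-specific composition rules (guild requirements, carbon pool
#' counts, unique ids). Called by [community_model()]; exported so loaders can
#' re-validate deserialized models.
#'
#' @param model A `community_model`.
#' @return The model, invisibly, if valid; otherwise an error.
#' @export
validate_model <- function(model) {
  ids <- species_ids(model)
  if (anyDuplicated(ids))
    stop("species ids must be unique", call. = FALSE)
  cids <- vapply(model$carbons, `[[`, "", "id")
  if (anyDuplicated(cids))
    stop("carbon source ids must be unique", call. = FALSE)
  guilds <- vapply(model$species, `[[`, "", "guild")

  switch(model$family,
    single_species_multicarbon = {
      if (length(model$species) != 1)
        stop("single_species_multicarbon requires exactly one species",
             call. = FALSE)
      if (length(model$carbons) < 1)
        stop("single_species_multicarbon requires at least one carbon source",
             call. = FALSE)
    },
    competitive = ,
    facilitation = {
      if (length(model$carbons) != 1)
        stop(model$family, " requires exactly one carbon pool", call. = FALSE)
      if (!is.null(model$nitrogen))
        stop("nitrogen pool is only part of the single-species family",
             call. = FALSE)
    },
    crossfeeding = {
      if (length(model$carbons) != 1)
        stop("crossfeeding requires exactly one primary carbon pool",
             call. = FALSE)
      if (!is.null(model$nitrogen))
        stop("nitrogen pool is only part of the single-species family",
             call. = FALSE)
      if (!any(guilds == "producer") || !any(guilds == "consumer"))
        stop("crossfeeding requires at least one producer and one consumer",
             call. = FALSE)
      if (any(guilds == "producer" &
              vapply(model$species, `[[`, 0, "pp") >= 1))
        stop("producer leakage pp must be < 1", call. = FALSE)
    },
    niche_partitioned = {
      if (length(model$carbons) != 2)
        stop("niche_partitioned requires exactly two carbon pools",
             call. = FALSE)
      if (!all(guilds %in% c("groupA", "groupB")))
        stop("niche_partitioned species must be in guild groupA or groupB",
             call. = FALSE)
      if (!is.null(model$nitrogen))
        stop("nitrogen pool is only part of the single-species family",
             call. = FALSE)
    })

  for (s in model$species) {
    if (!is.null(s$facilitation_targets)) {
      if (model$family != "facilitation")
        stop("facilitation_targets are only meaningful in the facilitation ",
             "family", call. = FALSE)
      bad <- setdiff(vapply(s$facilitation_targets, `[[`, "", "id"), ids)
      if (length(bad))
        stop("facilitation target '", bad[1], "' is not a species in the ",
             "model", call. = FALSE)
    }
  }
  invisible(model)
}

#' Build a community model from a structured specification
#'
#' Accepts the plain-list form used by the YAML/JSON config files (see
#' [read_model()]): a list with `family`, `species` (list of phenotype field
#' lists), and either `C0` (single central carbon pool) or `carbons` (list of
#' carbon-source field lists), plus optional `nitrogen`, `KM`, `eq6_literal`.
#' Defaults are filled (shared `KM`, `pp = 0` for non-producers) and all
#' invariants are checked.
#'
#' @param spec A named list as described above.
#' @return A validated [community_model()].
#' @examples
#' m <- build_model(list(
#'   family = "competitive", C0 = 10, KM = 1,
#'   species = list(list(id = "a", mu = 1, Y = 0.5, beta = 0.2, x0 = 0.01),
#'                  list(id = "b", mu = 1, Y = 0.5, beta = 0.6, x0 = 0.01))))
#' @export
build_model <- function(spec) {
  if (inherits(spec, "community_model")) return(validate_model(spec))
  if (is.null(spec$family))
    stop("spec$family is missing", call. = FALSE)
  family <- match.arg(spec$family, .crm_families)

  KM <- if (is.null(spec$KM)) 0.1 else spec$KM

  carbons <- if (!is.null(spec$carbons)) {
    lapply(seq_along(spec$carbons), function(i) {
      cs <- spec$carbons[[i]]
      if (inherits(cs, "carbon_source")) return(cs)
      if (is.null(cs$C0)) stop("carbons[[", i, "]]$C0 is missing",
                               call. = FALSE)
      carbon_source(id = if (is.null(cs$id)) paste0("C", i) else cs$id,
                    C0 = cs$C0,
                    r = if (is.null(cs$r)) 1 else cs$r,
                    Y = if (is.null(cs$Y)) 0.5 else cs$Y,
                    K = if (is.null(cs$K)) KM else cs$K)
    })
  } else if (!is.null(spec$C0)) {
    list(carbon_source(id = "C", C0 = spec$C0, r = 1, Y = 1, K = KM))
  } else {
    stop("spec must provide C0 or a carbons list", call. = FALSE)
  }

  nitrogen <- if (!is.null(spec$nitrogen)) {
    np <- spec$nitrogen
    if (inherits(np, "nitrogen_pool")) np
    else {
      if (is.null(np$N0)) stop("nitrogen$N0 is missing", call. = FALSE)
      nitrogen_pool(N0 = np$N0,
                    rN = if (is.null(np$rN)) 1 else np$rN,
                    YN = if (is.null(np$YN)) 1 else np$YN,
                    KN = if (is.null(np$KN)) KM else np$KN)
    }
  }

  if (is.null(spec$species) || !length(spec$species))
    stop("spec$species is missing or empty", call. = FALSE)
  species <- lapply(seq_along(spec$species), function(i) {
    s <- spec$species[[i]]
    if (inherits(s, "species_phenotype")) return(s)
    if (is.null(s$mu)) stop("species[[", i, "]]$mu is missing", call. = FALSE)
    species_phenotype(
      id = if (is.null(s$id)) paste0("sp", i) else s$id,
      mu = s$mu,
      Y = if (is.null(s$Y)) 0.5 else s$Y,
      beta = if (is.null(s$beta)) 0 else s$beta,
      K = s$K,
      x0 = if (is.null(s$x0)) 0.01 else s$x0,
      guild = if (is.null(s$guild)) "competitor" else s$guild,
      pp = if (is.null(s$pp)) 0 else s$pp,
      facilitation_targets = s$facilitation_targets)
  })

  community_model(family = family, species = species, carbons = carbons,
                  nitrogen = nitrogen, KM = KM,
                  eq6_literal = isTRUE(spec$eq6_literal),
                  producer_beta_total = isTRUE(spec$producer_beta_total))
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model>", x$family, "\n")
  cat("  species:", length(x$species),
      paste0("(", paste(utils::head(species_ids(x), 8), collapse = ", "),
             if (length(x$species) > 8) ", ..." else "", ")"), "\n")
  cat("  carbon pools:", length(x$carbons),
      " total C0 =", model_C0(x), "\n")
  if (!is.null(x$nitrogen))
    cat("  nitrogen: N0 =", x$nitrogen$N0, " YN =", x$nitrogen$YN, "\n")
  invisible(x)
}

#' Species identifiers of a model, in template order
#' @param model A `community_model`.
#' @return Character vector of ids.
#' @export
species_ids <- function(model) {
  vapply(model$species, `[[`, "", "id")
}

#' Species guilds of a model, in template order
#' @param model A `community_model`.
#' @return Character vector of guilds.
#' @export
species_guilds <- function(model) {
  vapply(model$species, `[[`, "", "guild")
}

#' Initial carbon budget of a model
#'
#' Sum of the initial concentrations over all carbon pools; for the
#' single-pool community families this is the central budget C0.
#'
#' @param model A `community_model`.
#' @return Numeric scalar.
#' @export
model_C0 <- function(model) {
  sum(vapply(model$carbons, `[[`, 0, "C0"))
}

#' Restrict a model to a subset of its species
#'
#' Species absence means removal from the state vector entirely (not a tiny
#' inoculum), so absent species cannot invade from rare. Resource pools are
#' retained unchanged. Cross-feeding composition rules are not re-imposed on
#' subsets: a background with no producer (or no consumer) is a legal
#' simulation in a landscape scan.
#'
#' @param model A `community_model`.
#' @param ids Character vector of species ids to keep (may be empty).
#' @return A `community_model` with the reduced species list.
#' @export
subset_model <- function(model, ids) {
  all_ids <- species_ids(model)
  bad <- setdiff(ids, all_ids)
  if (length(bad))
    stop("unknown species id: ", paste(bad, collapse = ", "), call. = FALSE)
  model$species <- model$species[all_ids %in% ids]
  model
}

#' Effective byproduct yields in the presence of facilitation
#'
#' For the facilitation family, `beta_eff[i] = beta[i] *` product of the
#' multipliers of all *present* facilitators naming species `i` as a target.
#' For every other family `beta_eff == beta`.
#'
#' @param model A `community_model` (with its present species only).
#' @return Named numeric vector of effective byproduct yields.
#' @export
beta_effective <- function(model) {
  ids <- species_ids(model)
  beta <- vapply(model$species, `[[`, 0, "beta")
  names(beta) <- ids
  if (model$family == "facilitation") {
    for (s in model$species) {
      for (ft in s$facilitation_targets) {
        if (ft$id %in% ids && ft$id != s$id)
          beta[ft$id] <- beta[ft$id] * ft$multiplier
      }
    }
  }
  beta
}

# -- internal ----------------------------------------------------------------

.check_scalar <- function(x, name, min = 0, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(name, ": must be a finite numeric scalar", call. = FALSE)
  if (strict && x <= min)
    stop(name, ": must be > ", min, call. = FALSE)
  if (!strict && x < min)
    stop(name, ": must be >= ", min, call. = FALSE)
  invisible(x)
}
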