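#' Enumerate background subsets
#'
#' Either every subset of a pool of `pool_size` entities (including the empty
#' set, so `2^pool_size` subsets), or `n_sample` distinct subsets drawn
#' uniformly without replacement under a seed. Subsets are returned as a list
#' of integer index vectors into the pool (template order).
#'
#' @param pool_size Number of non-focal entities, `>= 1`.
#' @param mode `"exhaustive"` or `"subsample"`.
#' @param n_sample Number of subsets to draw in subsample mode; must not
#'   exceed `2^pool_size`.
#' @param seed Integer seed for subsample mode (required there). The global
#'   RNG state is left untouched.
#' @return List of integer vectors, with attribute `pool_size`.
#' @examples
#' length(enumerate_backgrounds(9))  # 512
#' @export
enumerate_backgrounds <- function(pool_size,
                                  mode = c("exhaustive", "subsample"),
                                  n_sample = 200, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(pool_size >= 1, pool_size <= 30)
  total <- 2^pool_size
  masks <- if (mode == "exhaustive") {
    0:(total - 1)
  } else {
    if (n_sample > total)
      stop("n_sample (", n_sample, ") exceeds 2^pool_size (", total, ")",
           call. = FALSE)
    if (is.null(seed))
      stop("subsample mode requires a seed", call. = FALSE)
    .with_seed(seed, sample.int(total, n_sample) - 1)
  }
  bits <- 2^(seq_len(pool_size) - 1)
  out <- lapply(masks, function(m) which(bitwAnd(m, bits) > 0))
  attr(out, "pool_size") <- pool_size
  out
}

#' Global-epistasis scan over a focal species
#'
#' For every background subset S of the non-focal species: simulate S to
#' growth arrest and record its function F, then simulate S plus the focal
#' and record F'. Each scan point is (background, F, F', deltaF = F' - F).
#' Absent species are removed from the state vector entirely. Backgrounds
#' whose simulation hits `t_max` are dropped with a warning.
#'
#' @param model Template `community_model` containing the focal and the full
#'   species pool, with all phenotype parameters set.
#' @param focal_id Id of the focal species in the template.
#' @param backgrounds List of index subsets from [enumerate_backgrounds()]
#'   (indices into the non-focal pool in template order); default exhaustive.
#' @param rel_tol,abs_tol,t_max,stop_thr Passed to the integrator.
#' @return An object of class `epistasis_scan`: `focal_id`, `focal_kind`,
#'   `family`, `pool` (non-focal ids in template order), and `points`
#'   (data.frame: `background` bitmask string over the pool, `F`, `Fprime`,
#'   `deltaF`).
#' @export
scan_focal_species <- function(model, focal_id, backgrounds = NULL,
                               rel_tol = 1e-8, abs_tol = 1e-10, t_max = 1e4,
                               stop_thr = 1e-9) {
  ids <- species_ids(model)
  if (!focal_id %in% ids)
    stop("focal_id '", focal_id, "' is not in the model", call. = FALSE)
  pool <- setdiff(ids, focal_id)
  if (is.null(backgrounds)) backgrounds <- enumerate_backgrounds(length(pool))
  if (!is.null(attr(backgrounds, "pool_size")) &&
      attr(backgrounds, "pool_size") != length(pool))
    stop("backgrounds were enumerated for a pool of size ",
         attr(backgrounds, "pool_size"), ", but the non-focal pool has ",
         length(pool), " species", call. = FALSE)

  sim_F <- function(keep_ids) {
    st <- .simulate_terminal(subset_model(model, keep_ids),
                             rel_tol = rel_tol, abs_tol = abs_tol,
                             t_max = t_max, stop_thr = stop_thr)
    if (!st$ok) return(NA_real_)
    .terminal_F(model, st$terminal)
  }

  rows <- lapply(backgrounds, function(idx) {
    bg_ids <- pool[idx]
    F <- sim_F(bg_ids)
    Fp <- sim_F(c(bg_ids, focal_id))
    c(F = F, Fprime = Fp)
  })
  mat <- do.call(rbind, rows)
  pts <- data.frame(
    background = vapply(backgrounds, .mask_string, "",
                        pool_size = length(pool)),
    F = mat[, "F"], Fprime = mat[, "Fprime"],
    deltaF = mat[, "Fprime"] - mat[, "F"],
    stringsAsFactors = FALSE)
  bad <- !is.finite(pts$deltaF)
  if (any(bad)) {
    warning(sum(bad), " background(s) hit t_max and were excluded from the ",
            "scan of '", focal_id, "'")
    pts <- pts[!bad, , drop = FALSE]
  }
  if (anyDuplicated(pts$background))
    stop("duplicate backgrounds in scan", call. = FALSE)
  structure(list(focal_id = focal_id, focal_kind = "species",
                 family = model$family, pool = pool, points = pts),
            class = "epistasis_scan")
}

#' Global-epistasis scan over a focal carbon source
#'
#' Single-species multi-carbon family only. Background subsets choose which
#' of the non-focal carbon sources are supplied (the others have their
#' initial concentration set to zero); F is the terminal biomass. The focal
#' carbon is absent from every background and supplied at its template
#' concentration in every augmented run.
#'
#' @param model Template single-species multi-carbon `community_model`.
#' @param focal_carbon_id Id of the held-out carbon source.
#' @param backgrounds As in [scan_focal_species()], over the non-focal
#'   carbons.
#' @param rel_tol,abs_tol,t_max,stop_thr Passed to the integrator.
#' @return An `epistasis_scan` with `focal_kind = "carbon_source"`.
#' @export
scan_focal_carbon <- function(model, focal_carbon_id, backgrounds = NULL,
                              rel_tol = 1e-8, abs_tol = 1e-10, t_max = 1e4,
                              stop_thr = 1e-9) {
  if (model$family != "single_species_multicarbon")
    stop("scan_focal_carbon requires the single_species_multicarbon family",
         call. = FALSE)
  cids <- vapply(model$carbons, `[[`, "", "id")
  if (!focal_carbon_id %in% cids)
    stop("focal_carbon_id '", focal_carbon_id, "' is not in the model",
         call. = FALSE)
  pool <- setdiff(cids, focal_carbon_id)
  if (is.null(backgrounds)) backgrounds <- enumerate_backgrounds(length(pool))

  with_carbons <- function(keep_ids) {
    m <- model
    m$carbons <- lapply(m$carbons, function(cs) {
      if (!cs$id %in% keep_ids) cs$C0 <- 0
      cs
    })
    m
  }
  sim_F <- function(keep_ids) {
    st <- .simulate_terminal(with_carbons(keep_ids),
                             rel_tol = rel_tol, abs_tol = abs_tol,
                             t_max = t_max, stop_thr = stop_thr)
    if (!st$ok) return(NA_real_)
    .terminal_F(model, st$terminal)
  }

  rows <- lapply(backgrounds, function(idx) {
    bg <- pool[idx]
    c(F = sim_F(bg), Fprime = sim_F(c(bg, focal_carbon_id)))
  })
  mat <- do.call(rbind, rows)
  pts <- data.frame(
    background = vapply(backgrounds, .mask_string, "",
                        pool_size = length(pool)),
    F = mat[, "F"], Fprime = mat[, "Fprime"],
    deltaF = mat[, "Fprime"] - mat[, "F"],
    stringsAsFactors = FALSE)
  bad <- !is.finite(pts$deltaF)
  if (any(bad)) {
    warning(sum(bad), " background(s) hit t_max and were excluded")
    pts <- pts[!bad, , drop = FALSE]
  }
  structure(list(focal_id = focal_carbon_id, focal_kind = "carbon_source",
                 family = model$family, pool = pool, points = pts),
            class = "epistasis_scan")
}

#' @export
print.epistasis_scan <- function(x, ...) {
  cat("<epistasis_scan> focal", x$focal_kind, "'", x$focal_id, "' (",
      x$family, ")\n", sep = "")
  cat("  ", nrow(x$points), " backgrounds over a pool of ", length(x$pool),
      "\n", sep = "")
  cat("  F range [", signif(min(x$points$F), 4), ", ",
      signif(max(x$points$F), 4), "], deltaF range [",
      signif(min(x$points$deltaF), 4), ", ", signif(max(x$points$deltaF), 4),
      "]\n", sep = "")
  invisible(x)
}

.mask_string <- function(idx, pool_size) {
  b <- rep("0", pool_size)
  b[idx] <- "1"
  paste(b, collapse = "")
}

.mask_indices <- function(s) which(strsplit(s, "")[[1]] == "1")

# run thunk with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
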