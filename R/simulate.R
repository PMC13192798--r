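#' Integrate a community model to growth arrest
#'
#' Runs the batch dynamics until growth stops or `t_max` is reached. "Growth
#' stops" is detected by root-finding on the stopping condition: the largest
#' per-capita growth rate over species falls below `stop_thr` (1/time) *and*
#' the total resource-consumption rate falls below `stop_thr * C0`. The
#' second clause matters under nitrogen arrest, where biomass has plateaued
#' but carbon continues to drain. Integration uses a stiff-capable solver
#' (`lsodar` with compiled derivatives); fast consumers near depletion make
#' the final approach stiff.
#'
#' @param model A `community_model`.
#' @param rel_tol,abs_tol Solver tolerances.
#' @param t_max Integration horizon (time units). If the stopping condition
#'   has not triggered by `t_max` the trajectory is flagged `"max_time"` and
#'   the caller decides what to do with it.
#' @param times Optional output grid (must start at 0). Default records only
#'   the start and the stopping time, which is all the terminal analyses
#'   need; pass a dense grid to export full trajectories.
#' @param stop_thr Stopping threshold for the per-capita growth rate and the
#'   scaled consumption rate.
#' @return An object of class `crm_trajectory`: list with `times`, `states`
#'   (matrix, one row per time), `terminal` (named state vector),
#'   `termination_reason` (`"resource_depleted"`, `"growth_arrested"` or
#'   `"max_time"`), and `solver_diagnostics`.
#' @export
integrate_to_depletion <- function(model, rel_tol = 1e-8, abs_tol = 1e-10,
                                   t_max = 1e4, times = NULL,
                                   stop_thr = 1e-9) {
  stopifnot(t_max > 0)
  pk <- .pack_model(model, stop_thr = stop_thr)
  y0 <- pk$y0

  r0 <- .state_rates(model, y0)
  if (r0$maxpercap < stop_thr && r0$cons < stop_thr * pk$scale) {
    states <- matrix(y0, nrow = 1, dimnames = list(NULL, names(y0)))
    return(structure(list(
      times = 0, states = states, terminal = y0,
      termination_reason = .classify_arrest(model, y0, abs_tol, pk$scale),
      solver_diagnostics = list(steps = 0L, rel_tol = rel_tol,
                                abs_tol = abs_tol, stop_thr = stop_thr,
                                root_time = 0),
      family = model$family), class = "crm_trajectory"))
  }

  if (is.null(times)) times <- c(0, t_max)
  if (times[1] != 0) stop("times must start at 0", call. = FALSE)

  out <- deSolve::lsodar(y = y0, times = times, func = pk$derivs,
                         parms = pk$parms, dllname = "crmge",
                         initfunc = "crmge_init", rootfunc = pk$root,
                         nroot = 1L, rtol = rel_tol, atol = abs_tol,
                         maxsteps = 1e5)
  mat <- unclass(out)
  if (any(!is.finite(mat)))
    stop("integration produced non-finite state", call. = FALSE)
  tgrid <- mat[, 1]
  states <- mat[, -1, drop = FALSE]
  colnames(states) <- names(y0)

  # clip roundoff undershoots; anything larger is a real failure
  neg_tol <- max(1e3 * abs_tol, 1e-12)
  if (any(states < -neg_tol))
    stop("state went negative beyond tolerance (min ", min(states), ")",
         call. = FALSE)
  states[states < 0] <- 0

  terminal <- states[nrow(states), ]
  troot <- attr(out, "troot")
  rT <- .state_rates(model, terminal)
  arrested <- rT$maxpercap < stop_thr * 1.01 &&
    rT$cons < stop_thr * pk$scale * 1.01
  reason <- if (arrested) .classify_arrest(model, terminal, abs_tol, pk$scale)
            else "max_time"

  istate <- attr(out, "istate")
  structure(list(
    times = tgrid, states = states, terminal = terminal,
    termination_reason = reason,
    solver_diagnostics = list(
      steps = if (length(istate) >= 3) istate[3] else NA_integer_,
      rel_tol = rel_tol, abs_tol = abs_tol, stop_thr = stop_thr,
      root_time = if (length(troot)) troot[1] else NA_real_),
    family = model$family), class = "crm_trajectory")
}

#' Community function of a finished trajectory
#'
#' Terminal biomass for the single-species multi-carbon family, accumulated
#' byproduct `B(t -> infinity)` for every community family.
#'
#' @param traj A `crm_trajectory` from [integrate_to_depletion()].
#' @param model The model that produced it (only its family is used; may be
#'   omitted).
#' @param allow_max_time If `FALSE` (default), a trajectory flagged
#'   `"max_time"` is an error — the run never reached growth arrest.
#' @return Numeric scalar `F >= 0`.
#' @export
community_function <- function(traj, model = NULL, allow_max_time = FALSE) {
  stopifnot(inherits(traj, "crm_trajectory"))
  if (traj$termination_reason == "max_time" && !allow_max_time)
    stop("trajectory hit t_max before growth arrest; rerun with a larger ",
         "t_max or pass allow_max_time = TRUE", call. = FALSE)
  fam <- if (is.null(model)) traj$family else model$family
  key <- if (fam == "single_species_multicarbon") "x" else "B"
  max(unname(traj$terminal[key]), 0)
}

#' @export
print.crm_trajectory <- function(x, ...) {
  cat("<crm_trajectory>", x$family, "\n")
  cat("  t:", utils::tail(x$times, 1), " termination:",
      x$termination_reason, "\n")
  cat("  terminal:", paste(names(x$terminal), signif(x$terminal, 4),
                           sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `crm_trajectory`.
#' @param row.names,optional,... Ignored (data.frame method signature).
#' @return `data.frame` with columns `time`, `variable`, `value`.
#' @export
as.data.frame.crm_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  vars <- colnames(x$states)
  data.frame(
    time = rep(x$times, times = length(vars)),
    variable = rep(vars, each = length(x$times)),
    value = as.vector(x$states),
    stringsAsFactors = FALSE)
}

#' Write a trajectory as tidy CSV
#' @param traj A `crm_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

# Internal fast path used by the landscape scans: integrate and return the
# terminal state plus the function value, skipping trajectory assembly.
.simulate_terminal <- function(model, rel_tol = 1e-8, abs_tol = 1e-10,
                               t_max = 1e4, stop_thr = 1e-9) {
  pk <- .pack_model(model, stop_thr = stop_thr)
  y0 <- pk$y0
  r0 <- .state_rates(model, y0)
  if (r0$maxpercap < stop_thr && r0$cons < stop_thr * pk$scale)
    return(list(terminal = y0, ok = TRUE))
  out <- deSolve::lsodar(y = y0, times = c(0, t_max), func = pk$derivs,
                         parms = pk$parms, dllname = "crmge",
                         initfunc = "crmge_init", rootfunc = pk$root,
                         nroot = 1L, rtol = rel_tol, atol = abs_tol,
                         maxsteps = 1e5)
  terminal <- out[nrow(out), -1]
  names(terminal) <- names(y0)
  terminal[terminal < 0] <- 0
  rT <- .state_rates(model, terminal)
  ok <- rT$maxpercap < stop_thr * 1.01 && rT$cons < stop_thr * pk$scale * 1.01
  list(terminal = terminal, ok = ok)
}

.terminal_F <- function(model, terminal) {
  key <- if (model$family == "single_species_multicarbon") "x" else "B"
  max(unname(terminal[key]), 0)
}

# max per-capita growth rate and total resource-consumption rate at a state
.state_rates <- function(model, state) {
  if (model$family == "single_species_multicarbon") {
    x <- state[["x"]]
    m <- length(model$carbons)
    C <- pmax(state[1 + seq_len(m)], 0)
    rC <- vapply(model$carbons, `[[`, 0, "r")
    YC <- vapply(model$carbons, `[[`, 0, "Y")
    KC <- vapply(model$carbons, `[[`, 0, "K")
    M <- rC * C / (KC + C)
    g <- sum(YC * M)
    YN <- 1
    if (!is.null(model$nitrogen)) {
      np <- model$nitrogen
      N <- max(state[["N"]], 0)
      g <- min(g, np$YN * np$rN * N / (np$KN + N))
      YN <- np$YN
    }
    return(list(maxpercap = g, cons = x * sum(M) + x * g / YN))
  }
  n <- length(model$species)
  if (n == 0L) return(list(maxpercap = 0, cons = 0))
  nres <- length(model$carbons)
  res_idx <- .resource_index(model)
  pools <- pmax(state[n + seq_len(nres + (model$family == "crossfeeding"))], 0)
  mu <- vapply(model$species, `[[`, 0, "mu")
  K <- vapply(model$species, `[[`, 0, "K")
  Y <- vapply(model$species, `[[`, 0, "Y")
  pp <- vapply(model$species, `[[`, 0, "pp")
  R <- pools[res_idx]
  percap <- mu * R / (K + R)
  q <- percap * pmax(state[seq_len(n)], 0) / ((1 - pp) * Y)
  list(maxpercap = max(percap), cons = sum(q))
}

.classify_arrest <- function(model, state, abs_tol, scale) {
  pool_thr <- max(1e-6 * scale, 100 * abs_tol)
  if (model$family == "single_species_multicarbon") {
    m <- length(model$carbons)
    C0s <- vapply(model$carbons, `[[`, 0, "C0")
    pools <- state[1 + seq_len(m)][C0s > 0]
    if (!is.null(model$nitrogen)) {
      # nitrogen exhausted counts as depletion even if carbon remains
      if (state[["N"]] < pool_thr) return("resource_depleted")
    }
  } else {
    n <- length(model$species)
    if (n == 0L) return("growth_arrested")
    nres <- length(model$carbons)
    pools <- state[n + seq_len(nres + (model$family == "crossfeeding"))]
  }
  if (length(pools) && all(pools < pool_thr)) "resource_depleted"
  else "growth_arrested"
}
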