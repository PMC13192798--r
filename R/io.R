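#' Serialize a community model to a plain list
#'
#' The inverse of [build_model()]: the returned list, fed back through
#' `build_model()`, reproduces the model field-by-field. This is the schema
#' used by the YAML/JSON config files.
#'
#' @param model A `community_model`.
#' @return A named list.
#' @export
model_to_list <- function(model) {
  list(
    family = model$family,
    KM = model$KM,
    eq6_literal = model$eq6_literal,
    producer_beta_total = isTRUE(model$producer_beta_total),
    carbons = lapply(model$carbons, function(cs)
      list(id = cs$id, C0 = cs$C0, r = cs$r, Y = cs$Y, K = cs$K)),
    nitrogen = if (!is.null(model$nitrogen))
      list(N0 = model$nitrogen$N0, rN = model$nitrogen$rN,
           YN = model$nitrogen$YN, KN = model$nitrogen$KN),
    species = lapply(model$species, function(s) {
      out <- list(id = s$id, mu = s$mu, Y = s$Y, beta = s$beta, K = s$K,
                  x0 = s$x0, guild = s$guild, pp = s$pp)
      if (!is.null(s$facilitation_targets))
        out$facilitation_targets <- s$facilitation_targets
      out
    }))
}

#' Write / read a community model (JSON or YAML)
#'
#' Format is chosen by file extension: `.json` via jsonlite (full precision),
#' anything else is treated as YAML. `read_model()` runs the result through
#' [build_model()], so invalid files fail loudly.
#'
#' @param model A `community_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   a validated `community_model`.
#' @export
write_model <- function(model, path) {
  lst <- model_to_list(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lst <- .read_config(path)
  build_model(lst)
}

.read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  else
    yaml::read_yaml(path)
}

#' Hash of a configuration object
#'
#' MD5 over the canonical JSON serialization; embedded in output sidecars so
#' every artifact can be traced to the exact configuration that produced it.
#'
#' @param x Any serializable object.
#' @return Character MD5 digest.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write / read an epistasis scan as CSV
#'
#' The CSV holds one row per scan point (`focal_id`, `background_bitmask`
#' over the non-focal pool in template order, `F`, `Fprime`, `deltaF`);
#' scan metadata (focal kind, family, pool order, config hash) lives in a
#' `<path>.meta.json` sidecar so that `read_scan_csv()` reconstructs the
#' scan object exactly.
#'
#' @param scan An `epistasis_scan`.
#' @param path CSV file path.
#' @return `path` (write) / an `epistasis_scan` (read).
#' @export
write_scan_csv <- function(scan, path) {
  df <- data.frame(focal_id = scan$focal_id,
                   background_bitmask = scan$points$background,
                   F = scan$points$F, Fprime = scan$points$Fprime,
                   deltaF = scan$points$deltaF, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(focal_id = scan$focal_id, focal_kind = scan$focal_kind,
               family = scan$family, pool = as.list(scan$pool),
               hash = config_hash(list(scan$focal_id, scan$pool,
                                       scan$points$background)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path))
    stop("missing scan sidecar ", meta_path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, colClasses = c(background_bitmask = "character"))
  structure(list(focal_id = meta$focal_id, focal_kind = meta$focal_kind,
                 family = meta$family, pool = unlist(meta$pool),
                 points = data.frame(background = df$background_bitmask,
                                     F = df$F, Fprime = df$Fprime,
                                     deltaF = df$deltaF,
                                     stringsAsFactors = FALSE)),
            class = "epistasis_scan")
}

#' Write / read an epistasis fit as JSON
#' @param fit An `epistasis_fit`.
#' @param path JSON file path.
#' @return `path` (write) / an `epistasis_fit` (read).
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lst$rho_w <- as.numeric(lst$rho_w %||% NA)
  structure(lst, class = "epistasis_fit")
}

#' Write / read a leakage-sweep result
#'
#' Long table as tidy CSV (`<prefix>_long.csv`: replicate, pp, guild, focal,
#' rho_w, degenerate) plus a JSON summary (`<prefix>_summary.json`: the
#' aggregated guild means, the generating config and its hash).
#'
#' @param sweep A `sweep_result`.
#' @param prefix Path prefix for the two files.
#' @return `prefix` (write) / a `sweep_result` (read).
#' @export
write_sweep <- function(sweep, prefix) {
  utils::write.csv(sweep$long, paste0(prefix, "_long.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = sweep$summary, config = unclass(sweep$config),
         hash = config_hash(unclass(sweep$config))),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null", dataframe = "columns")
  invisible(prefix)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(prefix) {
  long <- utils::read.csv(paste0(prefix, "_long.csv"))
  js <- jsonlite::fromJSON(paste0(prefix, "_summary.json"),
                           simplifyVector = TRUE)
  config <- js$config
  config$beta_range <- as.numeric(config$beta_range)
  config$leakage_grid <- as.numeric(config$leakage_grid)
  class(config) <- "ensemble_config"
  summary <- as.data.frame(lapply(js$summary, function(col) {
    if (is.list(col)) col <- unlist(lapply(col, function(v) v %||% NA))
    if (is.logical(col) && all(is.na(col))) col <- as.numeric(col)
    col
  }), stringsAsFactors = FALSE)
  structure(list(long = long, summary = summary, config = config),
            class = "sweep_result")
}

#' Write terminal state as JSON
#' @param traj A `crm_trajectory`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_terminal_json <- function(traj, path) {
  jsonlite::write_json(
    list(terminal = as.list(traj$terminal),
         termination_reason = traj$termination_reason,
         diagnostics = traj$solver_diagnostics),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
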