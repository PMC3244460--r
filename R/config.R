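#' Bundled default master configuration
#'
#' The complete configuration of a simulation run, in four sections:
#' `diffusion` ([diffusion_spec()] fields; µm, s, µm²/s), `rates`
#' ([dc_rate_params()] fields), `culture` ([culture_config()] fields) and
#' `run` (seed, output directory, log level).  The bundled values are the
#' package's illustrative parameter set (see the methods vignette); a copy
#' ships as `inst/extdata/default_config.json`.
#'
#' @return nested list of class `master_config`.
#' @export
default_master_config <- function() {
  spec <- default_diffusion_spec()
  structure(list(
    diffusion = list(D = spec$D, delta = spec$delta, dt = spec$dt,
                     p_move = spec$p_move, c = spec$c, dims = spec$dims,
                     N_max = spec$N_max, normal_fallback = spec$normal_fallback),
    rates = unclass(dc_rate_params()),
    culture = unclass(culture_config())[
      c("lattice_shape", "n_cells", "moi", "early_responder_fraction",
        "pr_baseline", "pr_elevated", "pr_distribution", "t_end",
        "record_dt")],
    run = list(seed = 1L, out_dir = "ifnabm_out", log_level = "info")),
    class = "master_config")
}

validate_scalar <- function(violations, section, key, value, min = NULL,
                            max = NULL, integer = FALSE) {
  lab <- paste0(section, "$", key)
  if (!is.numeric(value) || length(value) != 1 || !is.finite(value))
    return(c(violations, sprintf("%s must be a finite numeric scalar", lab)))
  if (!is.null(min) && value < min)
    violations <- c(violations, sprintf("%s must be >= %g (got %g)", lab, min, value))
  if (!is.null(max) && value > max)
    violations <- c(violations, sprintf("%s must be <= %g (got %g)", lab, max, value))
  if (integer && value != floor(value))
    violations <- c(violations, sprintf("%s must be an integer (got %g)", lab, value))
  violations
}

#' Load and validate a master configuration file
#'
#' Reads a JSON configuration, merges it over the bundled defaults, derives
#' missing quantities (`dt` from `delta^2/(c D)` or `c` from `dt`), and
#' validates everything at once: unknown keys, wrong types and out-of-range
#' values are all collected and reported together.
#'
#' @param path path to a JSON file (or a `master_config` list, for
#'   round-tripping).
#' @return validated `master_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) unclass(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  defaults <- unclass(default_master_config())
  v <- character(0)
  unknown_sections <- setdiff(names(cfg), names(defaults))
  if (length(unknown_sections))
    v <- c(v, sprintf("unknown section: %s", unknown_sections))
  for (sec in intersect(names(cfg), names(defaults))) {
    unknown <- setdiff(names(cfg[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      v <- c(v, sprintf("unknown key: %s$%s", sec, unknown))
  }
  merged <- defaults
  for (sec in intersect(names(cfg), names(defaults)))
    merged[[sec]] <- modifyList(defaults[[sec]],
                                cfg[[sec]][names(cfg[[sec]]) %in%
                                             names(defaults[[sec]])])
  # derive dt or c when the file supplies only one of them
  d <- merged$diffusion
  given <- names(cfg$diffusion)
  if (!is.null(cfg$diffusion)) {
    if (!"dt" %in% given) d$dt <- d$delta^2 / (d$c * d$D)
    else if (!"c" %in% given) d$c <- d$delta^2 / (d$dt * d$D)
  }
  merged$diffusion <- d
  v <- validate_scalar(v, "diffusion", "D", d$D, min = 1e-12)
  v <- validate_scalar(v, "diffusion", "delta", d$delta, min = 1e-12)
  v <- validate_scalar(v, "diffusion", "dt", d$dt, min = 1e-12)
  v <- validate_scalar(v, "diffusion", "p_move", d$p_move, min = 1e-9, max = 1 - 1e-9)
  v <- validate_scalar(v, "diffusion", "N_max", d$N_max, min = 1, integer = TRUE)
  if (!d$dims %in% c(2, 3)) v <- c(v, "diffusion$dims must be 2 or 3")
  if (is.numeric(d$dt) && is.numeric(d$c) &&
      abs(d$dt - d$delta^2 / (d$c * d$D)) / d$dt > 1e-9)
    v <- c(v, "diffusion: dt, delta, c and D are mutually inconsistent")
  r <- merged$rates
  for (key in names(r)) v <- validate_scalar(v, "rates", key, r[[key]], min = 0)
  if (is.numeric(r$fold_f) && r$fold_f < 1) v <- c(v, "rates$fold_f must be >= 1")
  if (is.numeric(r$h_P) && r$h_P < 1) v <- c(v, "rates$h_P must be >= 1")
  if (is.numeric(r$h_B) && r$h_B < 1) v <- c(v, "rates$h_B must be >= 1")
  cu <- merged$culture
  if (!is.numeric(cu$lattice_shape) || length(cu$lattice_shape) != 2 ||
      any(cu$lattice_shape < 1))
    v <- c(v, "culture$lattice_shape must be two positive integers")
  v <- validate_scalar(v, "culture", "n_cells", cu$n_cells, min = 1, integer = TRUE)
  if (is.numeric(cu$n_cells) && is.numeric(cu$lattice_shape) &&
      length(cu$lattice_shape) == 2 && cu$n_cells > prod(cu$lattice_shape))
    v <- c(v, "culture$n_cells exceeds the number of lattice squares")
  v <- validate_scalar(v, "culture", "moi", cu$moi, min = 0)
  v <- validate_scalar(v, "culture", "early_responder_fraction",
                       cu$early_responder_fraction, min = 0, max = 1)
  v <- validate_scalar(v, "culture", "t_end", cu$t_end, min = 0)
  v <- validate_scalar(v, "culture", "record_dt", cu$record_dt, min = 1e-12)
  if (!cu$pr_distribution %in% c("two_point", "lognormal"))
    v <- c(v, "culture$pr_distribution must be \"two_point\" or \"lognormal\"")
  v <- validate_scalar(v, "run", "seed", merged$run$seed, integer = TRUE)
  if (length(v))
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  structure(merged, class = "master_config")
}

#' @rdname load_config
#' @param config a `master_config`.
#' @param path output path for the JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Instantiate the typed objects described by a master configuration
#'
#' @param config a `master_config` from [load_config()].
#' @return list with `spec` ([diffusion_spec()]), `params`
#'   ([dc_rate_params()]) and `culture` ([culture_config()]; its seed is the
#'   run seed).
#' @export
realize_config <- function(config) {
  d <- config$diffusion
  spec <- diffusion_spec(D = d$D, delta = d$delta, dt = d$dt,
                         p_move = d$p_move, dims = d$dims,
                         N_max = d$N_max, normal_fallback = d$normal_fallback)
  params <- do.call(dc_rate_params, config$rates)
  cu <- config$culture
  culture <- culture_config(lattice_shape = cu$lattice_shape,
                            n_cells = cu$n_cells, moi = cu$moi,
                            early_responder_fraction = cu$early_responder_fraction,
                            pr_baseline = cu$pr_baseline,
                            pr_elevated = cu$pr_elevated,
                            pr_distribution = cu$pr_distribution,
                            t_end = cu$t_end, record_dt = cu$record_dt,
                            seed = config$run$seed)
  list(spec = spec, params = params, culture = culture)
}

#' Write regenerable validation fixtures
#'
#' Each fixture is a configuration file from which one of the package's
#' validation experiments can be rerun without any external data:
#' `point_source` (deterministic 201x201 point-source calibration run),
#' `two_process_ssa` (two constant-rate reactions for the synchronized-SSA
#' consistency check) and `mini_culture` (a scaled-down 20x20, 50-cell,
#' 2-hour culture for fast tests).
#'
#' @param name one of `"point_source"`, `"two_process_ssa"`,
#'   `"mini_culture"`.
#' @param dir output directory (created if needed).
#' @param ... overrides for individual fixture fields.
#' @return invisibly, the path of the written file.
#' @export
make_fixture <- function(name = c("point_source", "two_process_ssa",
                                  "mini_culture"), dir = ".", ...) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- switch(name,
    point_source = list(kind = "point_source", L = 201, N0 = 1e6,
                        steps = 1000, profile_steps = 2000, p = 0.5, dims = 2),
    two_process_ssa = list(kind = "two_process_ssa", rates = c(1, 3),
                           n_events = 1e5, dt_sync = 0.25),
    mini_culture = {
      cfg <- default_master_config()
      cfg$culture$lattice_shape <- c(20L, 20L)
      cfg$culture$n_cells <- 50L
      cfg$culture$t_end <- 7200
      unclass(cfg)
    })
  fx <- modifyList(fx, list(...))
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(fx, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write simulation outputs as delimited text plus JSON metadata
#'
#' Writes `population.tsv` (one row per record time), `cells.tsv` (one row
#' per cell and record time, when per-cell records exist) and
#' `metadata.json` (configuration, seed, package version and the MD5 hash
#' of the configuration) with deterministic file naming, so identical runs
#' produce byte-identical outputs.
#'
#' @param traj a `culture_trajectory` from [run_culture()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named character vector of file paths.
#' @export
write_outputs <- function(traj, out_dir) {
  stopifnot(inherits(traj, "culture_trajectory"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(population = file.path(out_dir, "population.tsv"),
             metadata = file.path(out_dir, "metadata.json"))
  write.table(traj$pop, paths["population"], sep = "\t", row.names = FALSE,
              quote = FALSE)
  if (!is.null(traj$cells)) {
    n_rec <- dim(traj$cells)[1]; n_cells <- dim(traj$cells)[2]
    long <- data.frame(
      cell = rep(seq_len(n_cells), each = n_rec),
      infected = rep(traj$infected, each = n_rec),
      t = rep(traj$times, times = n_cells),
      M_I = as.vector(traj$cells[, , "M_I"]),
      M_R = as.vector(traj$cells[, , "M_R"]),
      P_R = as.vector(traj$cells[, , "P_R"]),
      B = as.vector(traj$cells[, , "B"]))
    paths["cells"] <- file.path(out_dir, "cells.tsv")
    write.table(long, paths["cells"], sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  cfg_json <- jsonlite::toJSON(list(culture = unclass(traj$config),
                                    rates = unclass(traj$params),
                                    diffusion = unclass(traj$spec)),
                               auto_unbox = TRUE, digits = NA)
  cfg_file <- tempfile(fileext = ".json")
  writeLines(cfg_json, cfg_file)
  meta <- list(package = "ifnabm",
               version = as.character(utils::packageVersion("ifnabm")),
               seed = traj$config$seed,
               config_md5 = unname(tools::md5sum(cfg_file)),
               config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE))
  unlink(cfg_file)
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
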