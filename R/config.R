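#' Read and resolve a run configuration
#'
#' Configuration is a YAML file with (all optional) top-level sections:
#' `model` (`version` "2020" or "2005", `melanopsin_variant` "rea" or
#' "cie", `params` named overrides for the selected model's constants),
#' `cs` (named overrides for the logistic parameters), `exposure`
#' (`t_hours`, `f_factor`), `grid` (`start_nm`, `end_nm`, `step_nm`), and
#' `seed`. Unknown keys are rejected. `overrides` (same structure) wins
#' over the file, so command-line flags can override the config.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides Nested named list merged over the file contents.
#' @return Object of class `run_config`: resolved `grid`, `fns`, `ctx`,
#'   `version`, `cla_params`, `cs_params`, `seed`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  raw <- if (!is.null(path)) yaml::read_yaml(path) else list()
  raw <- modify_nested(raw, overrides)
  known <- c("model", "cs", "exposure", "grid", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop(sprintf("read_run_config: unknown keys: %s",
                 paste(unknown, collapse = ", ")))
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0)
      stop(sprintf("read_run_config: unknown keys in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  check_keys(raw$model, c("version", "melanopsin_variant", "params"), "model")
  check_keys(raw$exposure, c("t_hours", "f_factor"), "exposure")
  check_keys(raw$grid, c("start_nm", "end_nm", "step_nm"), "grid")
  version <- as.character(raw$model$version %||% "2020")
  if (!version %in% c("2005", "2020"))
    stop("read_run_config: model$version must be '2005' or '2020'")
  variant <- raw$model$melanopsin_variant %||% "rea"
  grid <- wl_grid(raw$grid$start_nm %||% 380, raw$grid$end_nm %||% 780,
                  raw$grid$step_nm %||% 1)
  maker <- if (version == "2005") cla_params_2005 else cla_params_2020
  cla_p <- do.call(maker, as.list(raw$model$params %||% list()))
  cs_p <- do.call(cs_params, as.list(raw$cs %||% list()))
  ctx <- exposure_context(raw$exposure$t_hours %||% 1,
                          raw$exposure$f_factor %||% 1)
  structure(list(version = version, melanopsin_variant = variant,
                 grid = grid,
                 fns = build_function_set(grid, variant),
                 ctx = ctx, cla_params = cla_p, cs_params = cs_p,
                 seed = as.integer(raw$seed %||% 1L)),
            class = "run_config")
}

# recursive merge: values in 'over' replace values in 'base'
modify_nested <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_nested(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Compute photometric reports for a set of SPD files
#'
#' Reads each SPD, evaluates the full model under the configuration, and
#' returns one report row per file. The `b_minus_y`, `branch`, `cs` and
#' `cs_tf` columns follow the configured model version; `cla_2005` and
#' `cla_2020` are always both reported.
#'
#' @param config A [read_run_config()] result.
#' @param spd_paths Character vector of SPD file paths (>= 1).
#' @return A data.frame, one row per SPD.
#' @export
run_compute <- function(config, spd_paths) {
  stopifnot(inherits(config, "run_config"))
  if (length(spd_paths) == 0)
    stop("run_compute: usage error, no SPD paths given")
  rows <- lapply(spd_paths, function(pth) {
    x <- read_spd(pth, grid = config$grid)
    fns <- config$fns
    by <- opponent_by(x, fns, version = config$version,
                      k = config$cla_params$k)
    c05 <- if (config$version == "2005")
      cla_2005(x, fns, config$cla_params) else cla_2005(x, fns)
    c20 <- if (config$version == "2020")
      cla_2020(x, fns, config$cla_params) else cla_2020(x, fns)
    active <- if (config$version == "2005") c05 else c20
    data.frame(label = x$label,
               photopic_lux = illuminance(x, "photopic", fns),
               scotopic_lux = illuminance(x, "scotopic", fns),
               b_minus_y = by,
               branch = if (by > 0) "cool" else "warm",
               cla_2005 = c05, cla_2020 = c20,
               cs = cs_from_cla(active, config$cs_params),
               t_hours = config$ctx$t_hours,
               f_factor = config$ctx$f_factor,
               cs_tf = cs_tf(active, config$ctx, config$cs_params),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Calibration self-check
#'
#' Generates CIE Illuminant A, scales it to 1000 photopic lx, and reports
#' CL_A (2005) and CL_A 2.0 with their relative deviations from the
#' nominal calibration value 1000. Parameters are never mutated: any
#' drift, in particular under the revised model whose calibration constant
#' is carried over unchanged, is reported rather than absorbed.
#'
#' @param config A [read_run_config()] result (default configuration if
#'   omitted).
#' @return A data.frame with columns `model`, `cla`,
#'   `relative_deviation`.
#' @export
run_calibrate <- function(config = read_run_config()) {
  stopifnot(inherits(config, "run_config"))
  fns <- config$fns
  a <- generate_spd("illuminant_a", grid = config$grid)
  a <- scale_spd_to(a, "photopic_lux", 1000, fns)
  v05 <- cla_2005(a, fns)
  v20 <- cla_2020(a, fns)
  data.frame(model = c("cla_2005", "cla_2020"),
             cla = c(v05, v20),
             relative_deviation = c(v05, v20) / 1000 - 1,
             stringsAsFactors = FALSE)
}
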