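#' Generate a synthetic melatonin-suppression dataset
#'
#' Emulates the structure of a study-level suppression table: for each
#' protocol row, the stimulus SPD is generated and scaled, the revised
#' model's CS_t,f is computed as the true response, and additive Gaussian
#' assay noise is applied, clipped to \[-0.2, 1\] (observed suppression can
#' be slightly negative from assay noise). Reproducible under a fixed
#' seed.
#'
#' @param protocol A list of rows, each a list with elements `spd` (a
#'   `params` list for [generate_spd()] including `kind`), `level` (> 0),
#'   `level_units` (`"photopic_lux"`, `"scotopic_lux"`, or
#'   `"total_irradiance"`), and optional `t_hours`, `f_factor`.
#' @param noise_sigma SD of the additive Gaussian noise on fractional
#'   suppression, >= 0.
#' @param seed Integer RNG seed.
#' @param fns A [build_function_set()].
#' @return A data.frame with columns `spd_label`, `level`, `level_units`,
#'   `t_hours`, `f_factor`, `suppression`, `model_suppression`,
#'   `noise_sigma`.
#' @export
generate_synthetic_dataset <- function(protocol, noise_sigma = 0.03,
                                       seed = 1L,
                                       fns = build_function_set()) {
  if (!is.list(protocol) || length(protocol) == 0)
    stop("generate_synthetic_dataset: protocol must be a non-empty list")
  if (noise_sigma < 0) stop("generate_synthetic_dataset: noise_sigma must be >= 0")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- lapply(protocol, function(row) {
    if (is.null(row$spd) || is.null(row$spd$kind))
      stop("generate_synthetic_dataset: each protocol row needs spd$kind")
    if (is.null(row$level) || row$level <= 0)
      stop("generate_synthetic_dataset: each protocol row needs level > 0")
    units <- row$level_units %||% "scotopic_lux"
    s <- generate_spd(row$spd$kind, row$spd[setdiff(names(row$spd), "kind")],
                      grid = fns$grid)
    s <- scale_spd_to(s, units, row$level, fns)
    ctx <- exposure_context(row$t_hours %||% 1, row$f_factor %||% 1)
    truth <- cs_tf(cla_2020(s, fns), ctx)
    data.frame(spd_label = s$label, level = row$level, level_units = units,
               t_hours = ctx$t_hours, f_factor = ctx$f_factor,
               model_suppression = truth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$suppression <- pmin(pmax(out$model_suppression +
                                 stats::rnorm(nrow(out), 0, noise_sigma),
                               -0.2), 1)
  out$noise_sigma <- noise_sigma
  out[c("spd_label", "level", "level_units", "t_hours", "f_factor",
        "suppression", "model_suppression", "noise_sigma")]
}

#' Read a suppression dataset from delimited text
#'
#' Expects a header row with at least the columns `spd_label`, `level`,
#' `level_units`, `t_hours`, `f_factor`, `suppression`; validates ranges.
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_suppression_dataset <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("spd_label", "level", "level_units", "t_hours", "f_factor",
            "suppression")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop(sprintf("read_suppression_dataset: missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  if (any(d$level <= 0)) stop("read_suppression_dataset: levels must be > 0")
  if (any(d$suppression < -0.2 | d$suppression > 1))
    stop("read_suppression_dataset: suppression must lie in [-0.2, 1]")
  if (any(d$t_hours <= 0) || any(d$f_factor <= 0))
    stop("read_suppression_dataset: t_hours and f_factor must be > 0")
  d
}

#' Write a suppression dataset to delimited text
#'
#' @param data A suppression data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_suppression_dataset <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
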