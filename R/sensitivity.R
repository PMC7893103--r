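#' Dose-response curve container
#'
#' @param levels Stimulus magnitudes, strictly ascending.
#' @param responses Fractional suppression values in \[0, 1\].
#' @param meta Named list of descriptors (wavelength/SPD label, t, f,
#'   level units).
#' @return Object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(levels, responses, meta = list()) {
  if (length(levels) != length(responses))
    stop("dose_response_curve: levels and responses must have equal length")
  if (is.unsorted(levels, strictly = TRUE))
    stop("dose_response_curve: levels must be strictly ascending")
  if (any(responses < 0 | responses > 1))
    stop("dose_response_curve: responses must lie in [0, 1]")
  structure(list(levels = levels, responses = responses, meta = meta),
            class = "dose_response_curve")
}

#' Model-predicted suppression dose-response for a narrowband stimulus
#'
#' For each stimulus level (scotopic lx), generates a Gaussian narrowband
#' SPD, scales it to that scotopic illuminance, and evaluates CL_A 2.0 and
#' CS_t,f.
#'
#' @param center_nm Center wavelength (nm).
#' @param fwhm_nm Bandwidth (nm), default 10.
#' @param level_grid Ascending positive scotopic illuminances (scotopic lx).
#' @param ctx An [exposure_context()].
#' @param fns A [build_function_set()].
#' @return A [dose_response_curve()].
#' @export
predict_suppression_curve <- function(center_nm, fwhm_nm = 10, level_grid,
                                      ctx = exposure_context(),
                                      fns = build_function_set()) {
  if (any(level_grid <= 0) || is.unsorted(level_grid, strictly = TRUE))
    stop("predict_suppression_curve: level_grid must be ascending and > 0")
  unit <- generate_spd("narrowband",
                       list(center_nm = center_nm, fwhm_nm = fwhm_nm,
                            total_irradiance = 1),
                       grid = fns$grid)
  responses <- vapply(level_grid, function(lv) {
    s <- scale_spd_to(unit, "scotopic_lux", lv, fns)
    cs_tf(cla_2020(s, fns), ctx)
  }, numeric(1))
  dose_response_curve(level_grid, responses,
                      meta = list(center_nm = center_nm, fwhm_nm = fwhm_nm,
                                  t_hours = ctx$t_hours, f_factor = ctx$f_factor,
                                  level_units = "scotopic_lux"))
}

#' Stimulus level reaching a criterion response
#'
#' Inverts a monotone dose-response curve at `criterion` by linear
#' interpolation in (response, log10 level) space.
#'
#' @param curve A [dose_response_curve()] with nondecreasing responses.
#' @param criterion Target response, within the curve's response range.
#' @return Stimulus level (same units as `curve$levels`).
#' @export
criterion_level <- function(curve, criterion = 0.35) {
  stopifnot(inherits(curve, "dose_response_curve"))
  r <- curve$responses
  if (criterion < min(r))
    stop("criterion_level: out of range, criterion below the lowest response (short side)")
  if (criterion > max(r))
    stop("criterion_level: out of range, criterion above the highest response (saturated side)")
  # strictly increasing subsequence for interpolation; curve is monotone by
  # construction but may contain numerically flat runs
  keep <- c(TRUE, diff(r) > 0)
  10^stats::approx(r[keep], log10(curve$levels[keep]), xout = criterion,
                   ties = "ordered")$y
}

#' Constant-criterion spectral sensitivity
#'
#' For each wavelength, finds the total irradiance (W m^-2) of a narrowband
#' stimulus that drives the revised model to the criterion response
#' (default 0.35, half the 0.7 asymptote), searching around a reference
#' overall level (default 300 scotopic lx). Relative sensitivity is the
#' smallest criterion irradiance over all wavelengths divided by the
#' criterion irradiance at each wavelength, so the most sensitive
#' wavelength has sensitivity 1.
#'
#' @param wavelengths Vector of >= 2 center wavelengths (nm).
#' @param criterion Criterion response (CS units).
#' @param reference_scotopic_lux Reference overall level anchoring the
#'   search (scotopic lx).
#' @param ctx An [exposure_context()].
#' @param fns A [build_function_set()].
#' @param fwhm_nm Narrowband FWHM (nm).
#' @return Object of class `sensitivity_curve`: list with `wavelengths`,
#'   `relative_sensitivity`, `criterion_irradiance` (W m^-2), and `meta`
#'   (including wavelengths excluded for failing to reach criterion).
#' @export
derive_relative_sensitivity <- function(wavelengths, criterion = 0.35,
                                        reference_scotopic_lux = 300,
                                        ctx = exposure_context(),
                                        fns = build_function_set(),
                                        fwhm_nm = 10) {
  if (length(wavelengths) < 2)
    stop("derive_relative_sensitivity: need >= 2 wavelengths")
  crit_irr <- vapply(wavelengths, function(wl_c) {
    unit <- generate_spd("narrowband",
                         list(center_nm = wl_c, fwhm_nm = fwhm_nm,
                              total_irradiance = 1), grid = fns$grid)
    ref <- tryCatch(scale_spd_to(unit, "scotopic_lux",
                                 reference_scotopic_lux, fns),
                    error = function(e) NULL)
    if (is.null(ref)) return(NA_real_)
    ref_irr <- total_irradiance(ref)
    g <- function(log_a) {
      s <- spd(fns$grid, ref$values * 10^log_a, label = "probe")
      cs_tf(cla_2020(s, fns), ctx) - criterion
    }
    root <- tryCatch(stats::uniroot(g, c(-9, 9), tol = 1e-10)$root,
                     error = function(e) NA_real_)
    if (is.na(root)) NA_real_ else ref_irr * 10^root
  }, numeric(1))
  ok <- is.finite(crit_irr)
  if (!any(ok))
    stop("derive_relative_sensitivity: no wavelength reached the criterion")
  if (any(!ok))
    warning(sprintf("derive_relative_sensitivity: excluded wavelengths failing criterion: %s",
                    paste(wavelengths[!ok], collapse = ", ")))
  rel <- rep(NA_real_, length(wavelengths))
  rel[ok] <- min(crit_irr[ok]) / crit_irr[ok]
  structure(list(wavelengths = wavelengths[ok],
                 relative_sensitivity = rel[ok],
                 criterion_irradiance = crit_irr[ok],
                 meta = list(criterion = criterion,
                             reference_scotopic_lux = reference_scotopic_lux,
                             t_hours = ctx$t_hours, f_factor = ctx$f_factor,
                             excluded = wavelengths[!ok])),
            class = "sensitivity_curve")
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  pk <- x$wavelengths[which.max(x$relative_sensitivity)]
  cat(sprintf("<sensitivity_curve> %d wavelengths, peak at %g nm\n",
              length(x$wavelengths), pk))
  invisible(x)
}
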