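#' Spectral function
#'
#' A sampled, unitless spectral weighting function on a wavelength grid.
#' Sensitivity functions (photoreceptor templates, luminous efficiency) are
#' peak-normalized to exactly 1; transmittance functions lie in \[0, 1\].
#'
#' @param grid A [wl_grid()].
#' @param values Numeric vector, one value per grid wavelength; all values
#'   must be finite and >= 0.
#' @param name Identifier string.
#' @param type `"sensitivity"` (peak-normalized on construction) or
#'   `"transmittance"` (checked to lie in \[0, 1\]).
#'
#' @return An object of class `spectral_function`.
#' @export
spectral_function <- function(grid, values, name = "unnamed",
                              type = c("sensitivity", "transmittance")) {
  type <- match.arg(type)
  stopifnot(inherits(grid, "wl_grid"))
  wl <- wl_seq(grid)
  if (length(values) != length(wl))
    stop("spectral_function: length(values) must match the grid")
  if (any(!is.finite(values))) stop("spectral_function: values must be finite")
  if (any(values < 0)) stop("spectral_function: values must be >= 0")
  if (type == "sensitivity") {
    m <- max(values)
    if (m > 0) values <- values / m
  } else {
    if (any(values > 1 + 1e-12))
      stop("spectral_function: transmittance values must be <= 1")
    values <- pmin(values, 1)
  }
  structure(list(grid = grid, values = values, name = name, type = type),
            class = "spectral_function")
}

#' @export
print.spectral_function <- function(x, ...) {
  cat(sprintf("<spectral_function> %s (%s), %g-%g nm step %g\n", x$name,
              x$type, x$grid$start_nm, x$grid$end_nm, x$grid$step_nm))
  invisible(x)
}

#' Resample a spectral function onto another grid
#'
#' Linear interpolation onto the target grid. The target grid must lie
#' within the source domain (no extrapolation). Sensitivity functions are
#' re-normalized to peak 1 after interpolation.
#'
#' @param fn A [spectral_function()].
#' @param grid Target [wl_grid()].
#' @return A [spectral_function()] on `grid`.
#' @export
resample_function <- function(fn, grid) {
  stopifnot(inherits(fn, "spectral_function"), inherits(grid, "wl_grid"))
  if (grid$start_nm < fn$grid$start_nm - 1e-9 ||
      grid$end_nm > fn$grid$end_nm + 1e-9)
    stop(sprintf(
      "resample_function: domain error, target %g-%g nm outside source %g-%g nm",
      grid$start_nm, grid$end_nm, fn$grid$start_nm, fn$grid$end_nm))
  out <- stats::approx(wl_seq(fn$grid), fn$values, xout = wl_seq(grid),
                       method = "linear", rule = 2)$y
  spectral_function(grid, out, name = fn$name, type = fn$type)
}

#' Wavelength of maximum sensitivity
#'
#' Ties are broken toward the shorter wavelength (the first maximum on the
#' ascending grid).
#'
#' @param fn A [spectral_function()].
#' @return Wavelength (nm) of the maximum value.
#' @export
peak_wavelength <- function(fn) {
  stopifnot(inherits(fn, "spectral_function"))
  if (all(fn$values == 0))
    stop("peak_wavelength: undefined peak, function is identically zero")
  wl_seq(fn$grid)[which.max(fn$values)]
}

#' Full width at half maximum
#'
#' Distance between the two half-maximum crossings of a unimodal spectral
#' function, each located by linear interpolation between adjacent samples.
#'
#' @param fn A [spectral_function()].
#' @return Width (nm).
#' @export
fwhm <- function(fn) {
  stopifnot(inherits(fn, "spectral_function"))
  wl <- wl_seq(fn$grid)
  v <- fn$values
  half <- max(v) / 2
  if (max(v) == 0) stop("fwhm: undefined for an all-zero function")
  ip <- which.max(v)
  above <- v >= half
  if (above[1])
    stop("fwhm: truncation error, no half-maximum crossing on the short-wavelength side")
  if (above[length(v)])
    stop("fwhm: truncation error, no half-maximum crossing on the long-wavelength side")
  i <- max(which(!above[seq_len(ip)]))           # last below-half sample left of peak
  left <- wl[i] + (half - v[i]) / (v[i + 1] - v[i]) * (wl[i + 1] - wl[i])
  j <- ip - 1 + min(which(!above[ip:length(v)])) # first below-half sample right of peak
  right <- wl[j - 1] + (half - v[j - 1]) / (v[j] - v[j - 1]) * (wl[j] - wl[j - 1])
  right - left
}
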