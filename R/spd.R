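#' Spectral power distribution
#'
#' A sampled corneal spectral irradiance distribution on a wavelength grid,
#' in W m^-2 nm^-1.
#'
#' @param grid A [wl_grid()].
#' @param values Spectral irradiance (W m^-2 nm^-1), one per grid
#'   wavelength; finite and >= 0.
#' @param label Identifier string.
#' @return An object of class `spd`.
#' @export
spd <- function(grid, values, label = "spd") {
  stopifnot(inherits(grid, "wl_grid"))
  wl <- wl_seq(grid)
  if (length(values) != length(wl)) stop("spd: length(values) must match grid")
  if (any(!is.finite(values))) stop("spd: values must be finite")
  if (any(values < 0)) stop("spd: negative spectral irradiance")
  structure(list(grid = grid, values = values, label = label), class = "spd")
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf("<spd> %s, %g-%g nm step %g, total %.4g W/m^2\n", x$label,
              x$grid$start_nm, x$grid$end_nm, x$grid$step_nm,
              total_irradiance(x)))
  invisible(x)
}

#' Read an SPD from two-column delimited text
#'
#' Accepts `#` comment lines, an optional single non-numeric header row,
#' and whitespace/comma/tab delimiters. Wavelengths must be strictly
#' ascending and irradiance non-negative. The SPD is linearly interpolated
#' onto `grid` and is zero outside the supplied wavelength range.
#'
#' @param source File path or connection.
#' @param grid Session [wl_grid()].
#' @param label Identifier; defaults to the file name.
#' @return An [spd()].
#' @export
read_spd <- function(source, grid = wl_grid(),
                     label = if (is.character(source)) basename(source) else "spd") {
  lines <- readLines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop("read_spd: no data rows")
  parse_row <- function(line) {
    parts <- strsplit(trimws(line), "[,;\t ]+")[[1]]
    suppressWarnings(as.numeric(parts[1:2]))
  }
  parsed <- lapply(lines[rows], parse_row)
  bad <- vapply(parsed, function(p) any(is.na(p)), logical(1))
  # tolerate one header row at the top; any other non-numeric row is an error
  if (any(bad)) {
    if (bad[1] && !any(bad[-1])) {
      parsed <- parsed[-1]; rows <- rows[-1]
    } else {
      first_bad <- rows[which(bad & c(FALSE, rep(TRUE, length(bad) - 1)))][1]
      if (is.na(first_bad)) first_bad <- rows[which(bad)][1]
      stop(sprintf("read_spd: parse error, non-numeric data in row %d", first_bad))
    }
  }
  if (length(parsed) < 2) stop("read_spd: need >= 2 data rows")
  m <- do.call(rbind, parsed)
  if (is.unsorted(m[, 1], strictly = TRUE))
    stop("read_spd: format error, wavelengths must be strictly ascending")
  if (any(m[, 2] < 0))
    stop("read_spd: validation error, negative spectral irradiance")
  wl <- wl_seq(grid)
  v <- stats::approx(m[, 1], m[, 2], xout = wl, method = "linear",
                     yleft = 0, yright = 0)$y
  spd(grid, v, label = label)
}

#' Write an SPD to two-column delimited text
#'
#' @param x An [spd()].
#' @param path Output path.
#' @param digits Significant digits (default 6).
#' @return `path`, invisibly.
#' @export
write_spd <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "spd"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# SPD: %s", x$label),
               "# columns: wavelength_nm spectral_irradiance_W_m2_nm"), con)
  writeLines(sprintf("%g %s", wl_seq(x$grid),
                     formatC(x$values, digits = digits, format = "g")), con)
  invisible(path)
}

#' Total irradiance of an SPD
#'
#' Rectangle-rule integral of spectral irradiance over the grid.
#'
#' @param x An [spd()].
#' @return Irradiance (W m^-2).
#' @export
total_irradiance <- function(x) {
  stopifnot(inherits(x, "spd"))
  sum(x$values) * x$grid$step_nm
}

# rectangle-rule integral of weighting function times SPD
weighted_integral <- function(fn, x) {
  stop_if_grid_mismatch(fn$grid, x$grid, "spectral function and SPD")
  sum(fn$values * x$values) * x$grid$step_nm
}

#' Photopic or scotopic illuminance of an SPD
#'
#' Photopic: `683 * integral(V * E)` lm/W; scotopic: `1700 * integral(V' *
#' E)` (1700 lm/W is the scotopic maximum at 507 nm).
#'
#' @param x An [spd()].
#' @param system `"photopic"` or `"scotopic"`.
#' @param fns A [build_function_set()] on the same grid.
#' @return Illuminance (lx or scotopic lx).
#' @export
illuminance <- function(x, system = c("photopic", "scotopic"), fns) {
  system <- match.arg(system)
  stop_if_grid_mismatch(x$grid, fns$grid, "SPD and function set")
  if (system == "photopic") 683 * weighted_integral(fns$V, x)
  else 1700 * weighted_integral(fns$Vprime, x)
}

#' Photometric summary of an SPD
#'
#' @inheritParams illuminance
#' @return List with `photopic_lux`, `scotopic_lux`, `total_irradiance`.
#' @export
photometric_summary <- function(x, fns) {
  list(photopic_lux = illuminance(x, "photopic", fns),
       scotopic_lux = illuminance(x, "scotopic", fns),
       total_irradiance = total_irradiance(x))
}

#' Scale an SPD to a target photometric quantity
#'
#' Multiplies the whole SPD by one scalar so that the chosen quantity
#' equals `target`.
#'
#' @param x An [spd()].
#' @param quantity `"photopic_lux"`, `"scotopic_lux"`, or
#'   `"total_irradiance"`.
#' @param target Target value (> 0 units of the quantity; 0 allowed and
#'   returns a dark SPD).
#' @param fns A [build_function_set()] (needed for the illuminance
#'   quantities).
#' @return The scaled [spd()].
#' @export
scale_spd_to <- function(x, quantity = c("photopic_lux", "scotopic_lux",
                                         "total_irradiance"),
                         target, fns = NULL) {
  quantity <- match.arg(quantity)
  current <- switch(quantity,
                    photopic_lux = illuminance(x, "photopic", fns),
                    scotopic_lux = illuminance(x, "scotopic", fns),
                    total_irradiance = total_irradiance(x))
  if (current <= 0)
    stop(sprintf("scale_spd_to: unscalable, current %s is zero", quantity))
  if (target < 0) stop("scale_spd_to: target must be >= 0")
  spd(x$grid, x$values * (target / current), label = x$label)
}

#' Convert between photon rate density and irradiance
#'
#' Monochromatic conversion between photons cm^-2 s^-1 and W m^-2 using
#' the photon energy `h*c / lambda` (h*c = 1.98645e-25 J m) and the 1e4
#' cm^2/m^2 area factor. The two directions are mutual inverses.
#'
#' @param wavelength_nm Wavelength (nm), > 0.
#' @param value Quantity to convert, >= 0 (photons cm^-2 s^-1 or W m^-2).
#' @param direction `"photons_to_watts"` or `"watts_to_photons"`.
#' @return Converted quantity.
#' @examples
#' photon_irradiance_convert(480, 1, "watts_to_photons") # ~2.417e14
#' @export
photon_irradiance_convert <- function(wavelength_nm, value,
                                      direction = c("photons_to_watts",
                                                    "watts_to_photons")) {
  direction <- match.arg(direction)
  if (any(wavelength_nm <= 0)) stop("photon_irradiance_convert: wavelength must be > 0")
  if (any(value < 0)) stop("photon_irradiance_convert: value must be >= 0")
  hc <- 1.98645e-25                       # J m
  e_photon <- hc / (wavelength_nm * 1e-9) # J per photon
  if (direction == "photons_to_watts") value * 1e4 * e_photon
  else value / (1e4 * e_photon)
}

#' Generate a standard stimulus SPD
#'
#' Available kinds:
#' * `illuminant_a`: Planckian radiator at 2856 K (c2 = 1.4388e-2 m K),
#'   relative value 100 at 560 nm, scaled by `params$total_irradiance`
#'   (W m^-2; default gives the relative spectrum divided by 100).
#' * `blackbody`: Planckian radiator at `params$temperature_K`, scaled to
#'   `params$total_irradiance` (default 1 W m^-2).
#' * `narrowband`: Gaussian line at `params$center_nm` with
#'   `params$fwhm_nm` (default 10) whose integral is
#'   `params$total_irradiance` (default 1 W m^-2).
#' * `led_composite`: sum of Gaussian components
#'   `params$components = list(list(center_nm=, fwhm_nm=, weight=), ...)`,
#'   optionally multiplied by a notch filter (`params$notch_center_nm`,
#'   `params$notch_fwhm_nm`, `params$notch_depth` default 0.98), scaled to
#'   `params$total_irradiance` (default 1 W m^-2).
#' * `equal_energy`: flat spectrum scaled to `params$total_irradiance`
#'   (default 1 W m^-2).
#'
#' @param kind Generator name.
#' @param params Named list of kind-specific parameters.
#' @param grid A [wl_grid()].
#' @return An [spd()].
#' @examples
#' a <- generate_spd("illuminant_a", grid = wl_grid())
#' @export
generate_spd <- function(kind = c("illuminant_a", "blackbody", "narrowband",
                                  "led_composite", "equal_energy"),
                         params = list(), grid = wl_grid()) {
  kind <- match.arg(kind)
  wl <- wl_seq(grid)
  planck_rel <- function(T_K) {
    c2 <- 1.4388e-2                     # m K
    lam <- wl * 1e-9
    v <- lam^-5 / (exp(c2 / (lam * T_K)) - 1)
    v560 <- (560e-9)^-5 / (exp(c2 / (560e-9 * T_K)) - 1)
    100 * v / v560
  }
  gaussian_line <- function(center, fwhm_val) {
    if (fwhm_val <= 0) stop("generate_spd: FWHM must be > 0")
    sigma <- fwhm_val / (2 * sqrt(2 * log(2)))
    exp(-0.5 * ((wl - center) / sigma)^2)
  }
  scale_total <- function(v, total) {
    if (is.null(total)) return(v)
    s <- sum(v) * grid$step_nm
    if (s <= 0) stop("generate_spd: cannot scale an all-zero spectrum")
    v * (total / s)
  }
  values <- switch(kind,
    illuminant_a = {
      v <- planck_rel(2856)
      if (is.null(params$total_irradiance)) v / 100
      else scale_total(v, params$total_irradiance)
    },
    blackbody = {
      T_K <- params$temperature_K
      if (is.null(T_K) || T_K <= 0) stop("generate_spd: temperature_K must be > 0")
      scale_total(planck_rel(T_K), params$total_irradiance %||% 1)
    },
    narrowband = {
      if (is.null(params$center_nm)) stop("generate_spd: center_nm required")
      scale_total(gaussian_line(params$center_nm, params$fwhm_nm %||% 10),
                  params$total_irradiance %||% 1)
    },
    led_composite = {
      comps <- params$components
      if (is.null(comps) || length(comps) == 0)
        stop("generate_spd: led_composite requires a components list")
      v <- Reduce(`+`, lapply(comps, function(cmp) {
        (cmp$weight %||% 1) * gaussian_line(cmp$center_nm, cmp$fwhm_nm %||% 25)
      }))
      if (!is.null(params$notch_center_nm)) {
        depth <- params$notch_depth %||% 0.98
        v <- v * (1 - depth * gaussian_line(params$notch_center_nm,
                                            params$notch_fwhm_nm %||% 20))
      }
      scale_total(v, params$total_irradiance %||% 1)
    },
    equal_energy = scale_total(rep(1, length(wl)), params$total_irradiance %||% 1))
  spd(grid, values, label = params$label %||% kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
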