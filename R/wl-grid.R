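#' Wavelength grid
#'
#' A uniform wavelength sampling grid on which spectral functions and
#' spectral power distributions are evaluated. The default grid, 380-780 nm
#' in 1-nm steps, covers the visible range at the resolution of the bundled
#' luminous-efficiency tabulations.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must exceed `start_nm` and
#'   `end_nm - start_nm` must be an integer multiple of `step_nm`.
#' @param step_nm Grid spacing (nm), > 0.
#'
#' @return An object of class `wl_grid` with fields `start_nm`, `end_nm`,
#'   `step_nm`.
#' @examples
#' g <- wl_grid()
#' head(wl_seq(g))
#' @export
wl_grid <- function(start_nm = 380, end_nm = 780, step_nm = 1) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm),
            length(start_nm) == 1, length(end_nm) == 1, length(step_nm) == 1)
  if (!is.finite(start_nm) || !is.finite(end_nm) || !is.finite(step_nm))
    stop("wl_grid: all fields must be finite")
  if (start_nm >= end_nm) stop("wl_grid: start_nm must be < end_nm")
  if (step_nm <= 0) stop("wl_grid: step_nm must be > 0")
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8)
    stop("wl_grid: (end_nm - start_nm) must be a multiple of step_nm")
  structure(list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm),
            class = "wl_grid")
}

#' Wavelengths of a grid
#'
#' @param grid A [wl_grid()].
#' @return Numeric vector of wavelengths (nm).
#' @export
wl_seq <- function(grid) {
  stopifnot(inherits(grid, "wl_grid"))
  seq(grid$start_nm, grid$end_nm, by = grid$step_nm)
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$end_nm, x$step_nm, length(wl_seq(x))))
  invisible(x)
}

# grids compare equal if start/end/step agree to numerical noise
grids_equal <- function(a, b, tol = 1e-9) {
  inherits(a, "wl_grid") && inherits(b, "wl_grid") &&
    abs(a$start_nm - b$start_nm) < tol &&
    abs(a$end_nm - b$end_nm) < tol &&
    abs(a$step_nm - b$step_nm) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "objects") {
  if (!grids_equal(a, b))
    stop(sprintf("grid mismatch: %s must share one wavelength grid", what))
  invisible(TRUE)
}
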