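#' Read a spectral function from a two-column delimited text file
#'
#' Lines beginning with `#` are comments. Values are linearly interpolated
#' onto `grid`; the grid must lie within the tabulated wavelength range.
#'
#' @param path File path.
#' @param grid Target [wl_grid()].
#' @param name Identifier for the result.
#' @param type Passed to [spectral_function()].
#' @return A [spectral_function()].
#' @export
read_spectral_function <- function(path, grid, name = basename(path),
                                   type = "sensitivity") {
  tab <- utils::read.table(path, comment.char = "#", header = FALSE,
                           col.names = c("wavelength_nm", "value"))
  if (nrow(tab) < 2) stop("read_spectral_function: need >= 2 rows")
  if (is.unsorted(tab$wavelength_nm, strictly = TRUE))
    stop("read_spectral_function: wavelengths must be strictly ascending")
  if (grid$start_nm < min(tab$wavelength_nm) - 1e-9 ||
      grid$end_nm > max(tab$wavelength_nm) + 1e-9)
    stop(sprintf("read_spectral_function: grid %g-%g nm outside tabulated domain %g-%g nm",
                 grid$start_nm, grid$end_nm,
                 min(tab$wavelength_nm), max(tab$wavelength_nm)))
  v <- stats::approx(tab$wavelength_nm, tab$value, xout = wl_seq(grid),
                     method = "linear", rule = 2)$y
  spectral_function(grid, pmax(v, 0), name = name, type = type)
}

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "cslight")
  if (p == "") stop(sprintf("bundled data file '%s' not found", file))
  p
}

#' Build one of the model's spectral weighting functions
#'
#' Constructs, on the requested grid, any of the five weighting functions
#' entering the circadian-light models: the in-vivo (lens-filtered)
#' melanopsin sensitivity `Mc`, the S-cone fundamental `S`, macular pigment
#' transmittance `mp`, and the photopic (`V`) and scotopic (`V'`) luminous
#' efficiency functions. `V` and `V'` come from the bundled CIE
#' tabulations; `Mc`, `S` and `mp` are built from analytic templates (see
#' [pigment_nomogram_a1()], [lens_optical_density()],
#' [macular_optical_density()]); the melanopsin template is tuned at run
#' time to the published peak/FWHM of the selected variant (rea: 485/89 nm,
#' cie: 490/84 nm).
#'
#' @param name One of `"melanopsin_invivo"`, `"scone"`,
#'   `"macular_transmittance"`, `"photopic"`, `"scotopic"`.
#' @param grid A [wl_grid()] within 360-830 nm (the tabulated functions
#'   further require 380-780 nm).
#' @param melanopsin_variant `"rea"` (peak 485 nm, FWHM 89 nm) or `"cie"`
#'   (peak 490 nm, FWHM 84 nm); used only for `melanopsin_invivo`.
#' @param file Optional path to a replacement two-column tabulation; when
#'   given it overrides the built-in construction for `name`.
#' @return A [spectral_function()], peak-normalized for sensitivity
#'   functions.
#' @examples
#' v <- build_weighting_function("photopic", wl_grid())
#' peak_wavelength(v)
#' @export
build_weighting_function <- function(name, grid = wl_grid(),
                                     melanopsin_variant = c("rea", "cie"),
                                     file = NULL) {
  melanopsin_variant <- match.arg(melanopsin_variant)
  stopifnot(inherits(grid, "wl_grid"))
  known <- c("melanopsin_invivo", "scone", "macular_transmittance",
             "photopic", "scotopic")
  if (!is.character(name) || length(name) != 1 || !(name %in% known))
    stop(sprintf("build_weighting_function: unknown function name '%s'",
                 paste(name, collapse = ",")))
  if (grid$start_nm < 360 || grid$end_nm > 830)
    stop("build_weighting_function: grid must lie within 360-830 nm")
  type <- if (name == "macular_transmittance") "transmittance" else "sensitivity"
  if (!is.null(file))
    return(read_spectral_function(file, grid, name = name, type = type))
  wl <- wl_seq(grid)
  switch(name,
    photopic = read_spectral_function(.extdata("cie1924_photopic_vlambda.txt"),
                                      grid, name = "V", type = "sensitivity"),
    scotopic = read_spectral_function(.extdata("cie1951_scotopic_vlambda.txt"),
                                      grid, name = "Vprime", type = "sensitivity"),
    macular_transmittance = spectral_function(
      grid, 10^(-macular_optical_density(wl)), name = "mp",
      type = "transmittance"),
    scone = {
      p <- scone_template_params()
      v <- pigment_nomogram_a1(wl, p$lambda_max) *
        10^(-lens_optical_density(wl, p$lens_scale))
      spectral_function(grid, v, name = "S", type = "sensitivity")
    },
    melanopsin_invivo = {
      p <- melanopsin_template_params(melanopsin_variant)
      v <- pigment_nomogram_a1(wl, p$lambda_max) *
        10^(-lens_optical_density(wl, p$lens_scale))
      spectral_function(grid, v, name = paste0("Mc_", melanopsin_variant),
                        type = "sensitivity")
    })
}

#' Build the full spectral function set for the circadian-light models
#'
#' Assembles all seven weighting curves on one shared grid: `Mc`, `S`,
#' `mp`, `V`, `Vprime`, and the macular-weighted renormalized curves used
#' by the revised model, `Vc = (V*mp)/max(V*mp)` and
#' `Sc = (S*mp)/max(S*mp)`.
#'
#' @inheritParams build_weighting_function
#' @return An object of class `spectral_function_set`.
#' @examples
#' fns <- build_function_set()
#' peak_wavelength(fns$Mc)
#' @export
build_function_set <- function(grid = wl_grid(),
                               melanopsin_variant = c("rea", "cie")) {
  melanopsin_variant <- match.arg(melanopsin_variant)
  Mc <- build_weighting_function("melanopsin_invivo", grid, melanopsin_variant)
  S  <- build_weighting_function("scone", grid)
  mp <- build_weighting_function("macular_transmittance", grid)
  V  <- build_weighting_function("photopic", grid)
  Vp <- build_weighting_function("scotopic", grid)
  Vc <- spectral_function(grid, V$values * mp$values, name = "Vc",
                          type = "sensitivity")
  Sc <- spectral_function(grid, S$values * mp$values, name = "Sc",
                          type = "sensitivity")
  structure(list(Mc = Mc, S = S, mp = mp, V = V, Vprime = Vp,
                 Vc = Vc, Sc = Sc, grid = grid,
                 melanopsin_variant = melanopsin_variant),
            class = "spectral_function_set")
}

#' @export
print.spectral_function_set <- function(x, ...) {
  cat(sprintf(
    "<spectral_function_set> Mc/S/mp/V/V'/Vc/Sc on %g-%g nm step %g (melanopsin: %s)\n",
    x$grid$start_nm, x$grid$end_nm, x$grid$step_nm, x$melanopsin_variant))
  invisible(x)
}
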