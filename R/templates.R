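# Photopigment and ocular-media templates used to construct the weighting
# functions that have no resolvable published tabulation: the in-vivo
# melanopsin curves, the S-cone fundamental, and macular pigment.

#' Vitamin-A1 photopigment absorbance nomogram
#'
#' The Govardovskii et al. (2000) A1 visual-pigment template: alpha band as
#' a sum-of-exponentials sigmoid in normalized frequency `x = lambda_max /
#' lambda`, plus the Gaussian beta band. Values are relative absorbance,
#' peak ~1 at `lambda_max`.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm).
#' @param lambda_max Peak wavelength of the pigment alpha band (nm).
#' @param beta_band Include the short-wavelength beta band (default TRUE).
#' @return Numeric vector of relative absorbances.
#' @export
pigment_nomogram_a1 <- function(wavelength_nm, lambda_max, beta_band = TRUE) {
  stopifnot(lambda_max > 0, all(wavelength_nm > 0))
  x <- lambda_max / wavelength_nm
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; c <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (c - x)) + D)
  if (beta_band) {
    A_beta <- 0.26
    lm_beta <- 189 + 0.315 * lambda_max
    b_beta <- -40.5 + 0.195 * lambda_max
    alpha <- alpha + A_beta * exp(-((wavelength_nm - lm_beta) / b_beta)^2)
  }
  alpha
}

#' Crystalline lens optical density model
#'
#' Smooth single-exponential approximation to young-adult human lens
#' optical density: `D(lambda) = scale * 2.0 * exp(-(lambda - 380) / 60)`,
#' clamped to zero contribution far in the red. `scale = 1` gives density
#' ~1.4 at 400 nm and ~0.12 at 550 nm, in the range of standard small-pupil
#' lens tabulations; the scale is a free parameter used when tuning in-vivo
#' templates.
#'
#' @param wavelength_nm Wavelengths (nm).
#' @param scale Multiplier on the optical density.
#' @return Optical density (log10 attenuation), >= 0.
#' @export
lens_optical_density <- function(wavelength_nm, scale = 1) {
  stopifnot(scale >= 0)
  scale * 2.0 * exp(-(wavelength_nm - 380) / 60)
}

#' Macular pigment optical density model
#'
#' Analytic stand-in for the macular pigment optical density spectrum: an
#' asymmetric Gaussian peaking at 0.35 (2-degree viewing) at 460 nm, with a
#' broader short-wavelength flank (sigma 45 nm) than long-wavelength flank
#' (sigma 27 nm); effectively zero beyond ~540 nm.
#'
#' @param wavelength_nm Wavelengths (nm).
#' @param peak_density Optical density at the 460-nm peak.
#' @return Optical density, >= 0.
#' @export
macular_optical_density <- function(wavelength_nm, peak_density = 0.35) {
  sigma <- ifelse(wavelength_nm < 460, 45, 27)
  peak_density * exp(-0.5 * ((wavelength_nm - 460) / sigma)^2)
}

# Internal reference grid for template tuning: covers the full template
# domain at 1 nm so tuned peak/FWHM values do not depend on the session grid.
template_reference_grid <- function() wl_grid(360, 830, 1)

# Continuous-valued peak wavelength via quadratic interpolation through the
# discrete argmax and its neighbours; used only inside the tuner, where a
# smooth objective is needed.
.peak_continuous <- function(wl, v) {
  i <- which.max(v)
  if (i == 1 || i == length(v)) return(wl[i])
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom == 0) return(wl[i])
  wl[i] + 0.5 * (v[i - 1] - v[i + 1]) / denom * (wl[2] - wl[1])
}

.fwhm_continuous <- function(wl, v) {
  half <- max(v) / 2
  ip <- which.max(v)
  above <- v >= half
  if (above[1] || above[length(v)]) return(NA_real_)
  i <- max(which(!above[seq_len(ip)]))
  left <- wl[i] + (half - v[i]) / (v[i + 1] - v[i]) * (wl[i + 1] - wl[i])
  j <- ip - 1 + min(which(!above[ip:length(v)]))
  right <- wl[j - 1] + (half - v[j - 1]) / (v[j] - v[j - 1]) * (wl[j] - wl[j - 1])
  right - left
}

# Build the in-vivo (lens-filtered) melanopsin curve on the reference grid
# for given nomogram lambda_max and lens-density scale.
.melanopsin_raw <- function(lambda_max, lens_scale) {
  wl <- wl_seq(template_reference_grid())
  v <- pigment_nomogram_a1(wl, lambda_max) *
    10^(-lens_optical_density(wl, lens_scale))
  v / max(v)
}

# Tune (lambda_max, lens_scale) so the in-vivo curve meets the published
# (peak, FWHM) constraints of the requested template variant:
#   rea: peak 485 nm, FWHM 89 nm;  cie: peak 490 nm, FWHM 84 nm.
# Deterministic Nelder-Mead on a smooth objective; cached per variant.
.template_cache <- new.env(parent = emptyenv())

melanopsin_template_params <- function(variant = c("rea", "cie")) {
  variant <- match.arg(variant)
  key <- paste0("mel_", variant)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  target <- switch(variant, rea = c(peak = 485, fwhm = 89),
                   cie = c(peak = 490, fwhm = 84))
  wl <- wl_seq(template_reference_grid())
  obj <- function(par) {
    lmax <- par[1]; s <- exp(par[2])
    if (!is.finite(lmax) || lmax < 400 || lmax > 600 || !is.finite(s))
      return(1e6)
    v <- .melanopsin_raw(lmax, s)
    if (any(!is.finite(v))) return(1e6)
    pk <- .peak_continuous(wl, v)
    fw <- .fwhm_continuous(wl, v)
    if (is.na(fw)) return(1e6)
    (pk - target["peak"])^2 + (fw - target["fwhm"])^2
  }
  fit <- stats::optim(c(target[["peak"]] - 5, log(0.5)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  res <- list(lambda_max = fit$par[1], lens_scale = exp(fit$par[2]),
              objective = fit$value, variant = variant)
  if (fit$value > 1)   # > 1 nm^2 residual: constraints not met
    warning(sprintf("melanopsin template tuning residual %.3g for variant '%s'",
                    fit$value, variant))
  .template_cache[[key]] <- res
  res
}

# S-cone fundamental: nomogram x lens with lambda_max tuned so the corneal
# peak lands at 441 nm (the conventional 2-degree S-cone corneal peak);
# lens at its nominal density (scale 1).
scone_template_params <- function() {
  key <- "scone"
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  wl <- wl_seq(template_reference_grid())
  obj <- function(lmax) {
    v <- pigment_nomogram_a1(wl, lmax) * 10^(-lens_optical_density(wl, 1))
    (.peak_continuous(wl, v / max(v)) - 441)^2
  }
  fit <- stats::optimize(obj, c(400, 460), tol = 1e-6)
  res <- list(lambda_max = fit$minimum, lens_scale = 1)
  .template_cache[[key]] <- res
  res
}
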