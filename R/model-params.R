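#' Parameters of the 2005 two-state circadian-light model
#'
#' Printed constants of the original CL_A formulation: opponent constant
#' `k`, blue-yellow gain `a_by`, rod gain `a_rod`, rod saturation constant
#' `RodSat` (W m^-2, scotopic-weighted irradiance), and the calibration
#' constant `norm` fixing CL_A = 1000 at 1000 photopic lx of Illuminant A.
#'
#' @param k,a_by,a_rod,RodSat,norm Override any constant (> 0).
#' @return Object of class `cla_params_2005`.
#' @export
cla_params_2005 <- function(k = 0.2616, a_by = 0.7, a_rod = 3.3,
                            RodSat = 6.5, norm = 1548) {
  p <- list(k = k, a_by = a_by, a_rod = a_rod, RodSat = RodSat, norm = norm)
  if (any(unlist(p) <= 0)) stop("cla_params_2005: all parameters must be > 0")
  structure(p, class = "cla_params_2005")
}

#' Parameters of the revised circadian-light model (CL_A 2.0)
#'
#' Printed constants of the revised formulation, which adds rod-cone
#' threshold terms to both branches: `a_rod1`/`g1` act on the melanopsin
#' pathway, `a_rod2`/`g2` on the blue-yellow opponent pathway.
#'
#' @param k,a_by,a_rod1,a_rod2,g1,g2,RodSat,norm Override any constant
#'   (> 0).
#' @return Object of class `cla_params_2020`.
#' @export
cla_params_2020 <- function(k = 0.2616, a_by = 0.21, a_rod1 = 2.30,
                            a_rod2 = 1.60, g1 = 1.00, g2 = 0.16,
                            RodSat = 6.50, norm = 1548) {
  p <- list(k = k, a_by = a_by, a_rod1 = a_rod1, a_rod2 = a_rod2,
            g1 = g1, g2 = g2, RodSat = RodSat, norm = norm)
  if (any(unlist(p) <= 0)) stop("cla_params_2020: all parameters must be > 0")
  structure(p, class = "cla_params_2020")
}

#' Parameters of the circadian-stimulus logistic
#'
#' The fixed-shape sigmoid mapping circadian light to predicted fractional
#' nocturnal melatonin suppression after a 1-h exposure: asymptote
#' `max_response` 0.7, half-saturation constant 355.7 CL_A units, exponent
#' 1.1026. `duration_exponent` (-1.0) scales the half-saturation constant
#' with exposure duration in hours.
#'
#' @param max_response Asymptotic fractional suppression, in (0, 1].
#' @param half_sat Half-saturation constant (CL_A units), > 0.
#' @param exponent Logistic slope exponent, > 0.
#' @param duration_exponent Exponent of the duration law.
#' @return Object of class `cs_params`.
#' @export
cs_params <- function(max_response = 0.7, half_sat = 355.7,
                      exponent = 1.1026, duration_exponent = -1.0) {
  if (max_response <= 0 || max_response > 1)
    stop("cs_params: max_response must be in (0, 1]")
  if (half_sat <= 0) stop("cs_params: half_sat must be > 0")
  if (exponent <= 0) stop("cs_params: exponent must be > 0")
  structure(list(max_response = max_response, half_sat = half_sat,
                 exponent = exponent, duration_exponent = duration_exponent),
            class = "cs_params")
}

#' Exposure context: duration and retinal distribution
#'
#' `t` is continuous exposure duration in hours (the model is supported on
#' 0.5-3 h of continuous exposure in the early biological night; values
#' outside that range warn). `f` is the discrete spatial distribution
#' factor: 2.0 full field (Ganzfeld), 1.0 central field, 0.5 superior
#' field; other values are accepted with a warning since the three levels
#' are an acknowledged first approximation.
#'
#' @param t_hours Exposure duration (h), > 0.
#' @param f_factor Distribution factor, > 0.
#' @return Object of class `exposure_context`.
#' @export
exposure_context <- function(t_hours = 1, f_factor = 1) {
  if (!is.numeric(t_hours) || t_hours <= 0)
    stop("exposure_context: t_hours must be > 0")
  if (!is.numeric(f_factor) || f_factor <= 0)
    stop("exposure_context: f_factor must be > 0")
  if (t_hours < 0.5 || t_hours > 3)
    warning("exposure_context: duration outside the supported 0.5-3 h range")
  if (!f_factor %in% c(2.0, 1.0, 0.5))
    warning("exposure_context: f outside the standard levels {2.0, 1.0, 0.5}")
  structure(list(t_hours = t_hours, f_factor = f_factor),
            class = "exposure_context")
}
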