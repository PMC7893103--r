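#' Blue-yellow spectral opponent signal
#'
#' The signed b-y value whose sign selects the model branch ("cool"
#' b-y > 0, "warm" b-y <= 0). The 2005 form uses the macular-weighted,
#' un-renormalized S and V curves; the revised form uses the renormalized
#' `Sc` and `Vc`. Both use the same opponent constant `k`.
#'
#' @param x An [spd()].
#' @param fns A [build_function_set()] on the same grid.
#' @param version `"2005"` or `"2020"`.
#' @param k Opponent constant.
#' @return Signed opponent value (weighted W m^-2).
#' @export
opponent_by <- function(x, fns, version = c("2020", "2005"), k = 0.2616) {
  version <- match.arg(version)
  stop_if_grid_mismatch(x$grid, fns$grid, "SPD and function set")
  if (version == "2005") {
    s_term <- sum(fns$S$values * fns$mp$values * x$values) * x$grid$step_nm
    v_term <- sum(fns$V$values * fns$mp$values * x$values) * x$grid$step_nm
  } else {
    s_term <- weighted_integral(fns$Sc, x)
    v_term <- weighted_integral(fns$Vc, x)
  }
  s_term - k * v_term
}

# scale-invariant rod/cone ratio of the revised model's threshold term:
# integral(V' E) / (integral(Vc E) + g * integral(Sc E)); 0 when the rod
# input is zero (0/0 convention: no rod signal, no threshold elevation)
rod_ratio <- function(x, fns, g) {
  vp <- weighted_integral(fns$Vprime, x)
  if (vp == 0) return(0)
  denom <- weighted_integral(fns$Vc, x) + g * weighted_integral(fns$Sc, x)
  if (denom == 0) return(0)
  vp / denom
}

#' Rod-cone threshold term of the revised model
#'
#' `a_rod * [int(V'E) / (int(VcE) + g int(ScE))] * (1 - exp(-int(V'E) /
#' RodSat))`: a scale-invariant rod/cone ratio times a saturating factor in
#' the scotopic-weighted irradiance. Defined as 0 for a dark stimulus.
#'
#' @param x An [spd()].
#' @param fns A [build_function_set()].
#' @param a_rod Rod gain.
#' @param g S-cone weight in the ratio denominator.
#' @param RodSat Rod saturation constant (W m^-2).
#' @return Threshold term value.
#' @export
rod_term <- function(x, fns, a_rod, g, RodSat = 6.5) {
  vp <- weighted_integral(fns$Vprime, x)
  a_rod * rod_ratio(x, fns, g) * (1 - exp(-vp / RodSat))
}

#' Circadian light, 2005 two-state model
#'
#' For "cool" stimuli (b-y > 0): `norm * [int(Mc E) + a_by * (int(S mp E)
#' - k int(V mp E)) - a_rod * (1 - exp(-int(V'E)/RodSat))]`. For "warm"
#' stimuli (b-y <= 0): `norm * int(Mc E)`. Negative intermediate values are
#' floored at 0 (circadian light is a stimulus magnitude).
#'
#' @param x An [spd()].
#' @param fns A [build_function_set()] on the same grid.
#' @param params A [cla_params_2005()].
#' @return CL_A (unitless; calibrated so 1000 lx of Illuminant A gives
#'   ~1000).
#' @export
cla_2005 <- function(x, fns, params = cla_params_2005()) {
  stop_if_grid_mismatch(x$grid, fns$grid, "SPD and function set")
  mc <- weighted_integral(fns$Mc, x)
  by <- opponent_by(x, fns, version = "2005", k = params$k)
  val <- if (by > 0) {
    vp <- weighted_integral(fns$Vprime, x)
    mc + params$a_by * by - params$a_rod * (1 - exp(-vp / params$RodSat))
  } else mc
  max(params$norm * val, 0)
}

#' Circadian light, revised model (CL_A 2.0)
#'
#' The revised model modulates each retinal pathway by its own rod-cone
#' threshold term. The melanopsin pathway contributes `int(Mc E) -
#' rod_term(a_rod1, g1)`; for "cool" stimuli (b-y > 0, computed with
#' `Sc`/`Vc`) the spectrally opponent pathway adds `a_by * (int(Sc E) - k
#' int(Vc E)) - rod_term(a_rod2, g2)`. Each pathway is floored at zero
#' before summing: the rod-cone interaction elevates a pathway's threshold
#' and can silence it, but cannot drive its signal negative. (Summing the
#' un-floored pathways is an alternative reading of the same display
#' equation; it makes the model's small-signal response negative for
#' narrowband stimuli near 470-490 nm and destroys the published
#' short-wavelength spectral sensitivity peak, so the per-pathway
#' threshold reading is used.)
#'
#' @param x An [spd()].
#' @param fns A [build_function_set()] on the same grid.
#' @param params A [cla_params_2020()].
#' @return CL_A 2.0 (unitless, >= 0).
#' @export
cla_2020 <- function(x, fns, params = cla_params_2020()) {
  stop_if_grid_mismatch(x$grid, fns$grid, "SPD and function set")
  mc <- weighted_integral(fns$Mc, x)
  mel_path <- mc - rod_term(x, fns, params$a_rod1, params$g1, params$RodSat)
  by <- opponent_by(x, fns, version = "2020", k = params$k)
  val <- max(mel_path, 0)
  if (by > 0) {
    opp_path <- params$a_by * by -
      rod_term(x, fns, params$a_rod2, params$g2, params$RodSat)
    val <- val + max(opp_path, 0)
  }
  params$norm * val
}

#' Circadian stimulus from circadian light
#'
#' The fixed-shape logistic `CS = max_response * [1 - 1 / (1 +
#' (CL_A / half_sat)^exponent)]`: predicted fractional nocturnal melatonin
#' suppression for a 1-h exposure. Monotone in `cla`, bounded in
#' \[0, max_response).
#'
#' @param cla CL_A value(s), >= 0 (vectorized).
#' @param p A [cs_params()].
#' @return CS value(s).
#' @examples
#' cs_from_cla(355.7) # 0.35, half of the 0.7 asymptote
#' @export
cs_from_cla <- function(cla, p = cs_params()) {
  if (any(!is.finite(cla)) || any(cla < 0))
    stop("cs_from_cla: cla must be finite and >= 0")
  p$max_response * (1 - 1 / (1 + (cla / p$half_sat)^p$exponent))
}

#' Half-saturation constant for an exposure duration
#'
#' The duration law: `half_sat(t) = 355.7 * t^-1.0` (with the printed
#' defaults), mapping the 1-h half-saturation constant to other continuous
#' exposure durations.
#'
#' @param t_hours Duration (h), > 0; outside 0.5-3 h warns.
#' @param p A [cs_params()].
#' @return Half-saturation constant (CL_A units).
#' @examples
#' halfsat_for_duration(2) # 177.85
#' @export
halfsat_for_duration <- function(t_hours, p = cs_params()) {
  if (any(t_hours <= 0)) stop("halfsat_for_duration: t must be > 0")
  if (any(t_hours < 0.5 | t_hours > 3))
    warning("halfsat_for_duration: duration outside the supported 0.5-3 h range")
  p$half_sat * t_hours^p$duration_exponent
}

#' Duration- and distribution-augmented circadian stimulus
#'
#' `CS_t,f = max_response * [1 - 1 / (1 + (t * f * CL_A /
#' half_sat)^exponent)]`. Depends on the product `t * f * CL_A` only (the
#' product is evaluated in sorted order, so permuting the three factors
#' gives a bit-identical result); with t = 1, f = 1 it reduces to
#' [cs_from_cla()].
#'
#' @param cla CL_A 2.0 value, >= 0.
#' @param ctx An [exposure_context()].
#' @param p A [cs_params()].
#' @return CS_t,f value(s).
#' @export
cs_tf <- function(cla, ctx = exposure_context(), p = cs_params()) {
  if (any(!is.finite(cla)) || any(cla < 0))
    stop("cs_tf: cla must be finite and >= 0")
  stopifnot(inherits(ctx, "exposure_context"))
  eff <- vapply(cla, function(ci)
    prod(sort(c(ctx$t_hours, ctx$f_factor, ci))), numeric(1))
  cs_from_cla(eff, p)
}

#' Circadian light needed for a target circadian stimulus
#'
#' Closed-form inversion of the CS_t,f logistic: the CL_A 2.0 value for
#' which `cs_tf(cla, ctx)` equals `target`.
#'
#' @param target Target CS value, in \[0, max_response).
#' @param ctx An [exposure_context()].
#' @param p A [cs_params()].
#' @return CL_A 2.0 value.
#' @export
cla_for_target_cs <- function(target, ctx = exposure_context(), p = cs_params()) {
  if (any(target < 0) || any(target >= p$max_response))
    stop(sprintf("cla_for_target_cs: unreachable target, CS must be in [0, %g)",
                 p$max_response))
  x <- (target / (p$max_response - target))^(1 / p$exponent)
  p$half_sat * x / (ctx$t_hours * ctx$f_factor)
}

#' Full photometric report for one stimulus
#'
#' Evaluates every model quantity for one SPD: photopic and scotopic
#' illuminance, the revised-model opponent value and branch, CL_A (2005),
#' CL_A 2.0, CS (1-h), and CS_t,f under the supplied exposure context.
#'
#' @param x An [spd()].
#' @param fns A [build_function_set()] on the same grid.
#' @param ctx An [exposure_context()].
#' @return A one-row `data.frame` with columns `label`, `photopic_lux`,
#'   `scotopic_lux`, `b_minus_y`, `branch`, `cla_2005`, `cla_2020`, `cs`,
#'   `t_hours`, `f_factor`, `cs_tf`.
#' @examples
#' fns <- build_function_set()
#' a <- generate_spd("illuminant_a", grid = fns$grid)
#' a <- scale_spd_to(a, "photopic_lux", 1000, fns)
#' photometric_report(a, fns)
#' @export
photometric_report <- function(x, fns, ctx = exposure_context()) {
  by <- opponent_by(x, fns, version = "2020")
  c20 <- cla_2020(x, fns)
  data.frame(label = x$label,
             photopic_lux = illuminance(x, "photopic", fns),
             scotopic_lux = illuminance(x, "scotopic", fns),
             b_minus_y = by,
             branch = if (by > 0) "cool" else "warm",
             cla_2005 = cla_2005(x, fns),
             cla_2020 = c20,
             cs = cs_from_cla(c20),
             t_hours = ctx$t_hours,
             f_factor = ctx$f_factor,
             cs_tf = cs_tf(c20, ctx),
             stringsAsFactors = FALSE)
}
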