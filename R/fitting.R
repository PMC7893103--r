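#' Fit the half-saturation constant of the suppression logistic
#'
#' Least-squares estimate of the half-saturation constant with every other
#' logistic parameter held fixed at its printed value (asymptote 0.7,
#' exponent 1.1026): the response characteristic is assumed fixed and only
#' its position on the log-stimulus axis may vary. Coarse log-spaced search
#' followed by golden-section refinement.
#'
#' @param data A data.frame with columns `level` (stimulus in CL_A units,
#'   > 0) and `suppression` (observed fraction, may be slightly negative
#'   from assay noise), e.g. from [generate_synthetic_dataset()].
#' @param p A [cs_params()] supplying the fixed shape parameters.
#' @param search_range Log10 bounds of the half-saturation search, relative
#'   to the data's level range.
#' @return Object of class `logistic_fit`: list with `half_sat_estimate`,
#'   `residual_sse`, `r_squared`, `n`.
#' @export
fit_half_saturation <- function(data, p = cs_params(),
                                search_range = c(-3, 3)) {
  if (!all(c("level", "suppression") %in% names(data)))
    stop("fit_half_saturation: data needs columns 'level' and 'suppression'")
  lv <- data$level; y <- data$suppression
  if (length(unique(lv)) < 3)
    stop("fit_half_saturation: need >= 3 rows with distinct levels")
  if (any(lv <= 0)) stop("fit_half_saturation: levels must be > 0")
  if (length(unique(y)) == 1)
    stop("fit_half_saturation: degenerate fit, all responses identical")
  sse <- function(log_k) {
    k <- 10^log_k
    pred <- p$max_response * (1 - 1 / (1 + (lv / k)^p$exponent))
    sum((y - pred)^2)
  }
  center <- stats::median(log10(lv))
  grid <- seq(center + search_range[1], center + search_range[2],
              length.out = 121)
  g_sse <- vapply(grid, sse, numeric(1))
  i <- which.min(g_sse)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  k_hat <- 10^opt$minimum
  ss_res <- opt$objective
  ss_tot <- sum((y - mean(y))^2)
  structure(list(half_sat_estimate = k_hat, residual_sse = ss_res,
                 r_squared = 1 - ss_res / ss_tot, n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> half-sat %.4g (n = %d, r^2 = %.4f)\n",
              x$half_sat_estimate, x$n, x$r_squared))
  invisible(x)
}

#' Align two dose-response curves along the log-stimulus axis
#'
#' Finds the log10 shift applied to `curve_b`'s levels that minimizes the
#' squared difference between the curves' responses over their overlapping
#' range, emulating empirical alignment of suppression datasets taken at
#' different exposure durations.
#'
#' @param curve_a,curve_b [dose_response_curve()] objects with overlapping
#'   response ranges.
#' @param search Log10 shift search interval.
#' @return List with `shift_log10` (shift applied to b to match a) and
#'   `sse` at the optimum.
#' @export
align_log_shift <- function(curve_a, curve_b, search = c(-3, 3)) {
  stopifnot(inherits(curve_a, "dose_response_curve"),
            inherits(curve_b, "dose_response_curve"))
  la <- log10(curve_a$levels); lb <- log10(curve_b$levels)
  if (min(curve_b$responses) > max(curve_a$responses) ||
      max(curve_b$responses) < min(curve_a$responses))
    stop("align_log_shift: alignment error, response ranges do not overlap")
  obj <- function(delta) {
    xb <- lb + delta
    inside <- xb >= min(la) & xb <= max(la)
    if (sum(inside) < 2) return(NA_real_)
    pred_a <- stats::approx(la, curve_a$responses, xout = xb[inside],
                            ties = "ordered")$y
    mean((curve_b$responses[inside] - pred_a)^2)
  }
  grid <- seq(search[1], search[2], length.out = 241)
  vals <- vapply(grid, obj, numeric(1))
  if (all(is.na(vals)))
    stop("align_log_shift: alignment error, no overlap within the search window")
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(d) { v <- obj(d); if (is.na(v)) 1e9 else v },
                         c(lo, hi), tol = 1e-9)
  list(shift_log10 = opt$minimum, sse = opt$objective)
}

#' Fit the duration exponent of the half-saturation law
#'
#' Least-squares fit of `half_sat(t) = C * t^b` in log-log space to pairs
#' of (exposure duration, fitted half-saturation constant). With
#' `fix_coefficient = TRUE` the coefficient is pinned to the printed 1-h
#' value (355.7) and only the exponent is estimated.
#'
#' @param pairs A data.frame (or list) with columns `t_hours` (> 0) and
#'   `half_sat` (> 0), >= 3 rows.
#' @param fix_coefficient Pin the coefficient to `p$half_sat`?
#' @param p A [cs_params()] supplying the pinned coefficient.
#' @return List with `exponent`, `coefficient`, `r_squared` (in log-log
#'   space).
#' @export
fit_duration_exponent <- function(pairs, fix_coefficient = TRUE,
                                  p = cs_params()) {
  t <- pairs$t_hours; k <- pairs$half_sat
  if (length(t) < 3) stop("fit_duration_exponent: need >= 3 pairs")
  if (any(t <= 0)) stop("fit_duration_exponent: durations must be > 0")
  if (any(k <= 0)) stop("fit_duration_exponent: half-saturation values must be > 0")
  lt <- log10(t); lk <- log10(k)
  if (fix_coefficient) {
    y <- lk - log10(p$half_sat)
    b <- sum(y * lt) / sum(lt^2)
    fitted <- log10(p$half_sat) + b * lt
    coefficient <- p$half_sat
  } else {
    fit <- stats::lm(lk ~ lt)
    b <- unname(stats::coef(fit)[2])
    coefficient <- 10^unname(stats::coef(fit)[1])
    fitted <- stats::fitted(fit)
  }
  ss_res <- sum((lk - fitted)^2)
  ss_tot <- sum((lk - mean(lk))^2)
  list(exponent = b, coefficient = coefficient,
       r_squared = 1 - ss_res / ss_tot)
}
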