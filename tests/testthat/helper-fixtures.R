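# Shared fixtures. Template tuning is cached inside the package, so building
# the default function set once here keeps the suite fast.
default_grid <- wl_grid()
fns_default <- build_function_set(default_grid)

# single-line ("monochromatic") SPD: all power in one 1-nm bin, so weighted
# integrals reduce to the weighting-function value at that wavelength
delta_spd <- function(center_nm, total_irradiance = 1, grid = default_grid) {
  wl <- wl_seq(grid)
  v <- numeric(length(wl))
  v[match(center_nm, wl)] <- total_irradiance / grid$step_nm
  spd(grid, v, label = sprintf("delta_%g", center_nm))
}

narrowband_spd <- function(center_nm, fwhm_nm = 10, total = 1,
                           grid = default_grid) {
  generate_spd("narrowband", list(center_nm = center_nm, fwhm_nm = fwhm_nm,
                                  total_irradiance = total), grid)
}

# deterministic random polychromatic SPDs for property tests
random_led_spd <- function(grid = default_grid) {
  n <- sample(2:4, 1)
  comps <- lapply(seq_len(n), function(i)
    list(center_nm = runif(1, 420, 680), fwhm_nm = runif(1, 15, 80),
         weight = runif(1, 0.2, 1)))
  generate_spd("led_composite",
               list(components = comps,
                    total_irradiance = 10^runif(1, -2, 0.5)), grid)
}
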