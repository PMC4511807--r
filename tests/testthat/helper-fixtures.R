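# shared fixtures built in code

# V-shaped trajectory: linear decline to a minimum at t = t_min, then rise;
# depth chosen so 5% noise maps onto a realistic imaging-noise level
v_trajectory <- function(t_min = 150, t_total = 600, cadence = 5,
                         noise_sd = 0, slope = 1) {
  tm <- seq(0, t_total, by = cadence)
  fi <- slope * abs(tm - t_min)
  if (noise_sd > 0) fi <- fi + rnorm(length(tm), 0, noise_sd)
  cell_trajectory(cell_id = 1, time_min = tm, fi = fi,
                  depletion_start_min = 0)
}

# non-growing, non-dividing single-channel configuration whose Gal4p count
# is exactly Poisson(E * alpha4 * t): constant energy, no repression in
# reach (c4 huge), Gal2p channel switched off
poisson_params <- function(E = 0.5, alpha4 = 1, delay = 0) {
  constant_energy_params(
    energy_params(alpha4 = alpha4, alpha2 = 0, c4_mean = 1e6,
                  gamma = 0, delay = delay),
    E = E)
}

flat_schedule <- function(total = 900) {
  make_schedule(Td = 0, hold = 0, total = total)
}
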