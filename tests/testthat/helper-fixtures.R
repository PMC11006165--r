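# Shared fixtures: small grids and noiseless simulator bundles.

test_grid <- function(points_per_decade = 40) {
  freq_grid(7, 13000, points_per_decade = points_per_decade)
}

elephant_bundle <- function(distance_mm = 41, noise_sd_db = 0, seed = 1L,
                            grid = test_grid()) {
  simulate_specimen_bundle(species_preset("elephant"),
    specimen_id = "SIM_E",
    probe_distance_mm = distance_mm, grid = grid,
    noise_sd_db = noise_sd_db, seed = seed
  )
}

human_bundle <- function(distance_mm = 5, grid = test_grid()) {
  simulate_specimen_bundle(species_preset("human"),
    specimen_id = "SIM_H",
    probe_distance_mm = distance_mm, grid = grid
  )
}

# delay-only spectrum: flat magnitude, exactly linear phase
delay_line_spectrum <- function(delay_us, f = seq(500, 11000, by = 100)) {
  me_spectrum(f, magnitude = 1, phase_cycles = -f * delay_us * 1e-6)
}

random_angles <- function(order = "zyx") {
  euler_angles(
    stats::runif(1, -180, 180), stats::runif(1, -90, 90),
    stats::runif(1, -180, 180),
    order = order
  )
}
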