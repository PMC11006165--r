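test_that("spectrum container validates its invariants", {
  expect_error(me_spectrum(c(10, 5), 1, 0), "increasing")
  expect_error(me_spectrum(c(-1, 5), 1, 0), "positive")
  expect_error(me_spectrum(c(1, 5), c(-1, 1), 0), "non-negative")
  s <- me_spectrum(c(10, 100), c(1, 2), c(0, -0.1), "umbo", "X")
  expect_s3_class(s, "me_spectrum")
  z <- spectrum_complex(s)
  rt <- spectrum_from_complex(s$frequency_hz, z)
  expect_equal(rt$magnitude, s$magnitude, tolerance = 1e-12)
  expect_equal(magnitude_db(db_to_magnitude(-17.3)), -17.3, tolerance = 1e-12)
  expect_error(magnitude_db(0), "positive")
})

test_that("parameter validation names the offending field", {
  expect_error(
    me_params(K_me = -1, m_me = 1, R_me = 1, A_tm = 1, lever_ratio = 1),
    "K_me"
  )
  expect_error(
    me_params(K_me = 1, m_me = 1, R_me = 1, A_tm = 0, lever_ratio = 1),
    "A_tm"
  )
  expect_error(
    me_params(
      K_me = 1, m_me = 1, R_me = 1, A_tm = 1, lever_ratio = 1,
      tau_tm = -1
    ),
    "tau_tm"
  )
})

test_that("umbo response peaks at the configured resonance with zero-cycle phase", {
  for (species in c("elephant", "human")) {
    p <- species_preset(species)
    f_me <- resonance_frequency(p$K_me, p$m_me)
    expect_equal(f_me, if (species == "elephant") 300 else 1000, tolerance = 1e-9)
    u <- simulate_umbo_response(p, test_grid(100))
    g <- u$frequency_hz
    step <- which.min(abs(g - f_me))
    expect_equal(which.max(u$magnitude), which.min(abs(g - f_me)))
    ph <- u$phase_cycles + g * p$tau_tm # delay factor removed
    expect_lte(abs(which.min(abs(ph)) - step), 1)
  }
})

test_that("umbo magnitude slopes are +6 dB/oct below and -6 dB/oct above resonance", {
  p <- species_preset("elephant")
  u <- simulate_umbo_response(p, test_grid(100))
  g <- u$frequency_hz
  oct_slope <- function(f1, f2) {
    k <- g >= f1 & g <= f2
    unname(stats::coef(stats::lm(magnitude_db(u$magnitude[k]) ~ log2(g[k])))[2])
  }
  expect_lt(abs(oct_slope(300 / 8, 300 / 4) - 6), 0.5)
  expect_lt(abs(oct_slope(4 * 300, 8 * 300) + 6), 0.5)
})

test_that("resistive limit flattens magnitude and phase", {
  p <- me_params(
    K_me = 1000, m_me = 1e-4, R_me = 1e6, A_tm = 100,
    lever_ratio = 2
  )
  u <- simulate_umbo_response(p, test_grid())
  dbm <- magnitude_db(u$magnitude)
  slope <- stats::coef(stats::lm(dbm ~ log2(u$frequency_hz)))[2]
  expect_lt(abs(slope), 1)
  expect_lt(max(abs(u$phase_cycles)), 0.1)
})

test_that("at resonance the response is A_tm/R_me regardless of K and m", {
  f_me <- 500
  grid <- sort(unique(c(test_grid(), f_me)))
  mk <- function(m) {
    me_params(
      K_me = m * (2 * pi * f_me)^2, m_me = m, R_me = 0.3, A_tm = 80,
      lever_ratio = 2, tau_tm = 10e-6
    )
  }
  u1 <- simulate_umbo_response(mk(1e-4), grid)
  u2 <- simulate_umbo_response(mk(5e-3), grid)
  at <- which(abs(grid - f_me) < 1e-9)
  expect_equal(u1$magnitude[at], 80e-6 / 0.3 * 1000, tolerance = 1e-12)
  expect_equal(u1$magnitude[at], u2$magnitude[at], tolerance = 1e-12)
})

test_that("stapes stage applies lever division, delay and ISJ boost", {
  # pure lever division
  p <- me_params(
    K_me = 1000, m_me = 1e-4, R_me = 0.3, A_tm = 80,
    lever_ratio = 2.8, tau_oss = 0
  )
  u <- simulate_umbo_response(p, test_grid())
  s <- simulate_stapes_response(p, u)
  expect_equal(s$magnitude / u$magnitude, rep(1 / 2.8, nrow(u)),
    tolerance = 1e-12
  )
  expect_equal(1 / 2.8, 0.357, tolerance = 5e-4)

  # pure delay line: phase difference is -0.1 f cycles (f in kHz) for 100 us
  p2 <- me_params(
    K_me = 1000, m_me = 1e-4, R_me = 0.3, A_tm = 80,
    lever_ratio = 1, tau_oss = 100e-6
  )
  u2 <- simulate_umbo_response(p2, test_grid())
  s2 <- simulate_stapes_response(p2, u2)
  expect_equal(s2$phase_cycles - u2$phase_cycles,
    -0.1 * u2$frequency_hz / 1000,
    tolerance = 1e-12
  )

  # elephant ISJ resonance boosts TF_IS by ~4x near 9 kHz
  pe <- species_preset("elephant")
  ue <- simulate_umbo_response(pe, test_grid(100))
  inc <- simulate_incus_response(pe, ue)
  st <- simulate_stapes_response(pe, ue)
  tfis <- suppressMessages(transfer_function(st, inc, label = "TF_IS"))
  low <- mean(tfis$magnitude[tfis$frequency_hz < 100])
  peak <- max(tfis$magnitude[tfis$frequency_hz > 7000])
  expect_equal(peak / low, 4, tolerance = 0.05)
})

test_that("ear-canal propagation adds distance/c of pure delay", {
  u <- delay_line_spectrum(0)
  d <- apply_ear_canal_propagation(u, 41)
  gd <- fit_group_delay(d, f_lo = 500, f_hi = 11000)
  expect_equal(gd$gd_us, 119.2, tolerance = 0.05)
  expect_equal(d$magnitude, u$magnitude)
  expect_equal(apply_ear_canal_propagation(u, 0), u)
  d5 <- apply_ear_canal_propagation(u, 5)
  expect_equal(fit_group_delay(d5, f_lo = 500, f_hi = 11000)$gd_us,
    14.5,
    tolerance = 0.05
  )
  expect_error(apply_ear_canal_propagation(u, -1), "non-negative")
})

test_that("seeded noise and virtual-LDV synthesis are deterministic", {
  p <- species_preset("human")
  u <- simulate_umbo_response(p, test_grid())
  n1 <- add_spectrum_noise(u, 3, 0.02, seed = 7)
  n2 <- add_spectrum_noise(u, 3, 0.02, seed = 7)
  expect_identical(n1, n2)
  expect_gt(stats::sd(magnitude_db(n1$magnitude) - magnitude_db(u$magnitude)), 1)

  a <- euler_angles(33, -40, 110, "zyx")
  v1 <- synthesize_ldv_3d(u, a, off_axis_fraction = 0.5, noise_sd_db = 1, seed = 3)
  v2 <- synthesize_ldv_3d(u, a, off_axis_fraction = 0.5, noise_sd_db = 1, seed = 3)
  expect_identical(v1, v2)
  expect_error(synthesize_ldv_3d(u, a, off_axis_fraction = 1), "off_axis")
})

test_that("zero-angle virtual LDV puts the piston on the z axis", {
  u <- delay_line_spectrum(50)
  v <- synthesize_ldv_3d(u, euler_angles(0, 0, 0, "zyx"))
  expect_equal(max(Mod(v$vx)), 0)
  expect_equal(max(Mod(v$vy)), 0)
  expect_equal(Mod(v$vz), u$magnitude, tolerance = 1e-12)
})
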