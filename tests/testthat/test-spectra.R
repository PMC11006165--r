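test_that("phase unwrapping restores continuity and is idempotent", {
  # already-continuous phase is untouched
  f <- seq(100, 10000, by = 100)
  smooth <- -f * 5e-5
  expect_equal(as.numeric(unwrap_phase(smooth)), smooth)

  # wrapped linear phase is recovered exactly
  true <- -0.3 * f / 1000
  wrapped <- ((true + 0.5) %% 1) - 0.5
  wrapped[wrapped == -0.5] <- 0.5
  expect_equal(suppressMessages(as.numeric(unwrap_phase(wrapped))), true,
    tolerance = 1e-12
  )

  # an injected one-cycle jump is removed
  ph <- rep(-0.1, 30)
  ph[12:30] <- ph[12:30] + 1
  fixed <- suppressMessages(unwrap_phase(ph))
  expect_equal(as.numeric(fixed), rep(-0.1, 30))
  expect_equal(sum(diff(attr(fixed, "offsets")) != 0), 1)

  # idempotent: re-unwrapping changes nothing
  expect_equal(
    as.numeric(unwrap_phase(as.numeric(fixed))),
    as.numeric(fixed)
  )

  # adjacent-difference invariant holds for arbitrary input
  set.seed(1)
  raw <- cumsum(stats::rnorm(200, 0, 0.4))
  wrapped <- ((raw + 0.5) %% 1) - 0.5
  out <- suppressMessages(as.numeric(unwrap_phase(wrapped)))
  expect_true(all(diff(out) > -0.5 + 1e-12 & diff(out) <= 0.5 + 1e-12))
})

test_that("monotone-decrease rule applies only above the enforcement frequency", {
  f <- seq(1000, 10000, by = 500)
  ph <- -f * 1e-4
  ph[f >= 6000] <- ph[f >= 6000] + 1 # spurious +1 cycle re-wrap at HF
  out <- suppressMessages(unwrap_phase(ph, f,
    enforce_decrease_above_hz = 5000,
    increase_tol = 0.25
  ))
  expect_equal(as.numeric(out), -f * 1e-4, tolerance = 1e-12)
  # below the enforcement frequency the same rise is left alone
  ph2 <- -f * 1e-4
  ph2[f >= 2000] <- ph2[f >= 2000] + 0.4 # small rise, within (-0.5, 0.5]
  out2 <- unwrap_phase(ph2, f, enforce_decrease_above_hz = 5000)
  expect_equal(as.numeric(out2), ph2)
})

test_that("transfer function of a spectrum with itself is the identity", {
  u <- simulate_umbo_response(species_preset("elephant"), test_grid())
  tf <- transfer_function(u, u)
  expect_equal(tf$magnitude, rep(1, nrow(u)), tolerance = 1e-12)
  expect_equal(tf$phase_cycles, rep(0, nrow(u)), tolerance = 1e-12)
})

test_that("TF_US factors exactly as TF_UI * TF_IS on one grid", {
  for (species in c("elephant", "human")) {
    p <- species_preset(species)
    u <- simulate_umbo_response(p, test_grid())
    i <- simulate_incus_response(p, u)
    s <- simulate_stapes_response(p, u)
    tf_us <- transfer_function(s, u, label = "TF_US")
    tf_ui <- transfer_function(i, u, label = "TF_UI")
    tf_is <- transfer_function(s, i, label = "TF_IS")
    expect_equal(tf_ui$magnitude * tf_is$magnitude, tf_us$magnitude,
      tolerance = 1e-13
    )
    expect_equal(tf_ui$phase_cycles + tf_is$phase_cycles, tf_us$phase_cycles,
      tolerance = 1e-13
    )
  }
})

test_that("low-frequency TF_US magnitude approximates the reciprocal lever ratio", {
  p <- species_preset("elephant")
  u <- simulate_umbo_response(p, test_grid())
  s <- simulate_stapes_response(p, u)
  tf <- transfer_function(s, u, label = "TF_US")
  low <- tf$magnitude[tf$frequency_hz < 50]
  expect_equal(mean(low), 1 / 2.8, tolerance = 1e-3)
})

test_that("grid reconciliation interpolates onto the coarser grid over the overlap", {
  fine <- delay_line_spectrum(100, f = seq(100, 10000, by = 10))
  coarse <- delay_line_spectrum(40, f = seq(500, 8000, by = 250))
  tf <- transfer_function(fine, coarse)
  expect_equal(range(tf$frequency_hz), c(500, 8000))
  expect_equal(nrow(tf), nrow(coarse))
  # both inputs are delay lines: ratio phase is exactly linear
  expect_equal(tf$phase_cycles, -tf$frequency_hz * 60e-6, tolerance = 1e-9)
  expect_equal(tf$magnitude, rep(1, nrow(tf)), tolerance = 1e-9)
})

test_that("near-zero denominator points are masked, not fatal", {
  f <- seq(100, 1000, by = 100)
  num <- me_spectrum(f, 1, 0)
  den_mag <- rep(1, length(f))
  den_mag[4] <- 1e-9
  den <- me_spectrum(f, den_mag, 0)
  expect_message(tf <- transfer_function(num, den), "masked 1")
  expect_true(is.na(tf$magnitude[4]))
  expect_equal(sum(is.na(tf$magnitude)), 1)
})

test_that("group averaging works in dB and cycles with n per point", {
  u <- simulate_umbo_response(species_preset("human"), test_grid())
  a <- u
  a$specimen_id <- "A"
  b <- u
  b$specimen_id <- "B"
  gm <- group_mean_sd(dplyr::bind_rows(a, b))
  expect_equal(gm$mean_magnitude, u$magnitude, tolerance = 1e-9)
  expect_equal(max(gm$sd_db), 0, tolerance = 1e-12)
  expect_true(all(gm$n == 2))

  # dB-domain averaging is a geometric mean: {0.1, 1} -> 0.316
  f <- c(100, 200)
  x <- me_spectrum(f, c(0.1, 0.1), 0, specimen_id = "A")
  y <- me_spectrum(f, c(1, 1), 0, specimen_id = "B")
  gm2 <- group_mean_sd(dplyr::bind_rows(x, y))
  expect_equal(gm2$mean_magnitude, rep(sqrt(0.1), 2), tolerance = 1e-9)
  expect_equal(round(gm2$mean_magnitude[1], 3), 0.316)

  expect_error(group_mean_sd(x), "at least 2")
})

test_that("ensemble mean stays near the noiseless spectrum", {
  u <- simulate_umbo_response(species_preset("elephant"), test_grid(20))
  ens <- dplyr::bind_rows(lapply(1:8, function(k) {
    s <- add_spectrum_noise(u, noise_sd_db = 3, noise_sd_cycles = 0, seed = 100 + k)
    s$specimen_id <- paste0("S", k)
    s
  }))
  gm <- group_mean_sd(ens)
  truth_db <- magnitude_db(u$magnitude)
  within <- abs(gm$mean_db - truth_db) <= 3 * gm$sd_db / sqrt(8) + 1e-9
  expect_gte(mean(within), 0.95)
})

test_that("stats table applies band limits, categories and transforms", {
  f <- c(16.9, 17, 999, 1000, 1000.1, 11000, 11001)
  s <- me_spectrum(f, 2, -0.5, target_label = "umbo", specimen_id = "X")
  s$group <- "elephant"
  tab <- prepare_stats_table(s)
  expect_equal(tab$frequency_hz, c(17, 999, 1000, 1000.1, 11000))
  expect_equal(tab$freq_category, c("low", "low", "low", "high", "high"))
  expect_equal(tab$log_magnitude, rep(log(2), 5))
  expect_equal(tab$log_phase_plus4, rep(log(3.5), 5))

  # the most negative admissible phase: log(phase + 4) at phase -3.49
  s2 <- me_spectrum(c(100, 200), 1, c(-3.49, -4.2), specimen_id = "Y")
  expect_message(tab2 <- prepare_stats_table(s2), "dropped 1")
  expect_equal(tab2$log_phase_plus4, log(0.51), tolerance = 1e-12)
})
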