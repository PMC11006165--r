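#' Read and write the pipeline spectra CSV layout
#'
#' One row per (specimen, target, frequency) with columns `frequency_hz`,
#' `magnitude_mm_s_per_pa`, `phase_cycles`, `target_label`, `specimen_id`.
#' Frequencies are serialised in Hz at full precision, magnitudes in
#' (mm/s)/Pa (dimensionless for transfer functions), phases in cycles.
#'
#' @param spectra A tibble of stacked spectra ([me_spectrum] rows).
#' @param path File path.
#' @return `read_spectra_csv()` returns the tibble; `write_spectra_csv()`
#'   returns `path` invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  out <- tibble::tibble(
    frequency_hz = spectra$frequency_hz,
    magnitude_mm_s_per_pa = spectra$magnitude,
    phase_cycles = spectra$phase_cycles,
    target_label = spectra$target_label,
    specimen_id = spectra$specimen_id
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @param column_map Optional named character vector mapping this layout's
#'   column names to the names used in `path` (for externally produced
#'   files), e.g. `c(frequency_hz = "freq")`.
#' @export
read_spectra_csv <- function(path, column_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  wanted <- c(
    "frequency_hz", "magnitude_mm_s_per_pa", "phase_cycles",
    "target_label", "specimen_id"
  )
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      names(raw)[names(raw) == column_map[[nm]]] <- nm
    }
  }
  missing <- setdiff(wanted, names(raw))
  if (length(missing) > 0) {
    stop("spectra CSV lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    frequency_hz = raw$frequency_hz,
    magnitude = raw$magnitude_mm_s_per_pa,
    phase_cycles = raw$phase_cycles,
    target_label = raw$target_label,
    specimen_id = raw$specimen_id
  )
  class(out) <- c("me_spectrum", class(out))
  out
}

#' Simulate a full specimen measurement bundle
#'
#' Generates umbo, incus and stapes pressure-normalised velocity spectra
#' for one virtual specimen from a lumped-element preset, applies the
#' ear-canal propagation delay to all three (the microphone sits at the
#' probe-tube tip), optionally adds seeded measurement noise, and returns
#' the stacked spectra together with a ground-truth sidecar for downstream
#' parameter-recovery checks. When `out_dir` is given the spectra and the
#' sidecar are also written as CSVs.
#'
#' @param params An [me_params] object (see [species_preset()]).
#' @param specimen_id Identifier for the virtual specimen.
#' @param probe_distance_mm Probe-tube-tip-to-umbo distance in mm.
#' @param grid Frequency grid in Hz.
#' @param noise_sd_db Log-magnitude noise SD in dB (0 = noiseless).
#' @param noise_sd_cycles Phase noise SD in cycles.
#' @param seed RNG seed for the noise.
#' @param out_dir Optional directory for CSV output.
#' @param c Speed of sound in m/s.
#' @return A list with `spectra` (stacked tibble), `truth` (one-row tibble:
#'   injected delays, lever ratio, resonance), and `paths` (written files,
#'   if any).
#' @export
simulate_specimen_bundle <- function(params, specimen_id = "SIM1",
                                     probe_distance_mm = 0,
                                     grid = freq_grid(),
                                     noise_sd_db = 0, noise_sd_cycles = 0,
                                     seed = 1L, out_dir = NULL, c = 344) {
  umbo <- simulate_umbo_response(params, grid, specimen_id = specimen_id)
  incus <- simulate_incus_response(params, umbo)
  stapes <- simulate_stapes_response(params, umbo)
  specs <- list(umbo = umbo, incus = incus, stapes = stapes)
  specs <- lapply(specs, apply_ear_canal_propagation,
    distance_mm = probe_distance_mm, c = c
  )
  if (noise_sd_db > 0 || noise_sd_cycles > 0) {
    specs <- purrr::imap(specs, function(s, nm) {
      add_spectrum_noise(s,
        noise_sd_db = noise_sd_db, noise_sd_cycles = noise_sd_cycles,
        seed = seed + match(nm, c("umbo", "incus", "stapes"))
      )
    })
  }
  spectra <- dplyr::bind_rows(specs)
  truth <- tibble::tibble(
    specimen_id = specimen_id,
    species_label = params$species_label,
    f_me_hz = resonance_frequency(params$K_me, params$m_me),
    lever_ratio = params$lever_ratio,
    tau_tm_us = params$tau_tm * 1e6,
    tau_oss_us = params$tau_oss * 1e6,
    propagation_us = propagation_delay_us(probe_distance_mm, c = c),
    noise_sd_db = noise_sd_db, seed = seed
  )
  paths <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sp <- file.path(out_dir, paste0(specimen_id, "_spectra.csv"))
    tp <- file.path(out_dir, paste0(specimen_id, "_truth.csv"))
    write_spectra_csv(spectra, sp)
    readr::write_csv(truth, tp)
    paths <- c(spectra = sp, truth = tp)
  }
  list(spectra = spectra, truth = truth, paths = paths)
}

#' Run the full analysis pipeline on stacked spectra
#'
#' Ties the stages together in measurement order: unwrap phase (with the
#' high-frequency monotone-decrease rule for elephant ears), form the
#' ossicular transfer functions TF_US, TF_UI and TF_IS per specimen
#' (skipping, with a warning, any whose targets were not measured),
#' estimate banded group delays with propagation corrections, and
#' summarise to group means and transmission delays. All point-level
#' interventions (unwrap offsets, masked ratio points) surface as messages
#' and in the returned `log`.
#'
#' @param spectra Stacked spectra tibble (umbo/incus/stapes rows per
#'   specimen), e.g. from [simulate_specimen_bundle()] or
#'   [read_spectra_csv()].
#' @param config One row per specimen: `specimen_id`, `group`
#'   (`"elephant"`/`"human"`), `probe_distance_mm`.
#' @param unwrap_enforce_hz Enforcement frequency for the monotone-decrease
#'   unwrap rule, applied to elephant specimens only (default 5000 Hz;
#'   `NULL` disables).
#' @param bands Bands to fit (default HF and WB).
#' @param c Speed of sound in m/s.
#' @return A list: `spectra` (unwrapped), `tf` (stacked transfer
#'   functions), `gd` (per-specimen estimates), `gd_summary`,
#'   `transmission`, `stats_table`, `log` (character).
#' @export
run_pipeline <- function(spectra, config, unwrap_enforce_hz = 5000,
                         bands = c("HF", "WB"), c = 344) {
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  combos <- dplyr::distinct(spectra, .data$specimen_id, .data$target_label)
  unwrapped <- purrr::pmap_dfr(combos, function(specimen_id, target_label) {
    s <- spectra[spectra$specimen_id == specimen_id &
      spectra$target_label == target_label, , drop = FALSE]
    grp <- config$group[config$specimen_id == specimen_id]
    enforce <- if (length(grp) == 1 && grp == "elephant") unwrap_enforce_hz else NULL
    out <- suppressMessages(
      unwrap_spectrum(s, enforce_decrease_above_hz = enforce)
    )
    offs <- attr(out, "unwrap_offsets")
    n_adj <- sum(diff(offs) != 0)
    if (n_adj > 0) {
      note(
        "unwrap: ", specimen_id, "/", target_label, ": offsets at ",
        n_adj, " point(s)"
      )
    }
    out
  })

  tf_defs <- tibble::tribble(
    ~label, ~num, ~den,
    "TF_US", "stapes", "umbo",
    "TF_UI", "incus", "umbo",
    "TF_IS", "stapes", "incus"
  )
  tf <- purrr::map_dfr(unique(config$specimen_id), function(id) {
    here <- unwrapped[unwrapped$specimen_id == id, , drop = FALSE]
    purrr::pmap_dfr(tf_defs, function(label, num, den) {
      a <- here[here$target_label == num, , drop = FALSE]
      b <- here[here$target_label == den, , drop = FALSE]
      if (nrow(a) == 0 || nrow(b) == 0) {
        warning("specimen ", id, ": ", label, " skipped (missing ",
          if (nrow(a) == 0) num else den, ")",
          call. = FALSE
        )
        note("tf: ", id, ": ", label, " skipped")
        return(tibble::tibble())
      }
      withCallingHandlers(
        transfer_function(a, b, label = label),
        message = function(m) {
          note("tf: ", id, "/", label, ": ", conditionMessage(m))
          invokeRestart("muffleMessage")
        }
      )
    })
  })

  gd <- estimate_group_delays(unwrapped, config, bands = bands, c = c)
  gd_summary <- summarize_delays(gd)
  trans <- tryCatch(transmission_delay(gd_summary), error = function(e) {
    note("transmission delay skipped: ", conditionMessage(e))
    tibble::tibble()
  })
  stats_table <- suppressMessages(
    prepare_stats_table(dplyr::left_join(
      unwrapped,
      config[, c("specimen_id", "group")],
      by = "specimen_id"
    ))
  )
  list(
    spectra = unwrapped, tf = tf, gd = gd, gd_summary = gd_summary,
    transmission = trans, stats_table = stats_table, log = log
  )
}
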