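#' Analysis-band presets for group-delay fits
#'
#' Bands sit above the middle-ear resonance of each species: a
#' near-resonance (NR) band, a high-frequency (HF) band up to 11 kHz, and
#' their union, the wideband (WB) range. Elephant: NR 600-1200 Hz,
#' HF 1200-11000 Hz, WB 600-11000 Hz. Human: NR 2000-4000 Hz,
#' HF 4000-11000 Hz, WB 2000-11000 Hz. Band membership is inclusive on both
#' edges.
#'
#' @param species `"elephant"` or `"human"`.
#' @return A tibble with columns `band`, `f_lo`, `f_hi`, `species`.
#' @export
band_presets <- function(species = c("elephant", "human")) {
  species <- match.arg(species)
  if (species == "elephant") {
    tibble::tibble(
      band = c("NR", "HF", "WB"),
      f_lo = c(600, 1200, 600),
      f_hi = c(1200, 11000, 11000),
      species = species
    )
  } else {
    tibble::tibble(
      band = c("NR", "HF", "WB"),
      f_lo = c(2000, 4000, 2000),
      f_hi = c(4000, 11000, 11000),
      species = species
    )
  }
}

#' Group delay from unwrapped phase by banded straight-line fit
#'
#' Ordinary least-squares straight line fitted to unwrapped phase (cycles)
#' versus frequency (Hz, linear axis) over the points falling inside the
#' band (edges inclusive). The group delay is the negative of the fitted
#' slope, in microseconds. The fit is unweighted over the points present,
#' so a log-spaced grid places more points (hence more weight) per hertz at
#' the low end of the band.
#'
#' @param spectrum An [me_spectrum] with unwrapped phase.
#' @param f_lo,f_hi Band edges in Hz; alternatively pass a one-row `band`
#'   tibble from [band_presets()].
#' @param band Optional one-row tibble with `f_lo`, `f_hi` (and `band`).
#' @return An object of class `gd_fit`: a list with `gd_us`, `slope`,
#'   `intercept`, `residual_rms` (cycles), `n_points`, `band`, `f_lo`,
#'   `f_hi`, `target_label`, `specimen_id`. [generics::tidy()] and
#'   [generics::glance()] methods return it as tibbles.
#' @examples
#' f <- seq(1000, 11000, by = 100)
#' s <- me_spectrum(f, 1, -1e-4 * f) # pure 100 us delay
#' fit_group_delay(s, f_lo = 1200, f_hi = 11000)$gd_us
#' @export
fit_group_delay <- function(spectrum, f_lo = NULL, f_hi = NULL, band = NULL) {
  if (!is.null(band)) {
    stopifnot(nrow(band) == 1)
    f_lo <- band$f_lo
    f_hi <- band$f_hi
    band_name <- if ("band" %in% names(band)) band$band else NA_character_
  } else {
    band_name <- NA_character_
  }
  stopifnot(is.numeric(f_lo), is.numeric(f_hi), f_lo < f_hi)
  keep <- spectrum$frequency_hz >= f_lo & spectrum$frequency_hz <= f_hi &
    is.finite(spectrum$phase_cycles)
  n <- sum(keep)
  if (n < 3) {
    stop(
      "fewer than 3 usable points in band [", f_lo, ", ", f_hi, "] Hz (got ",
      n, ")",
      call. = FALSE
    )
  }
  fit <- stats::lm(phase ~ f, data = data.frame(
    f = spectrum$frequency_hz[keep],
    phase = spectrum$phase_cycles[keep]
  ))
  slope <- unname(stats::coef(fit)[2]) # cycles per Hz = seconds
  structure(list(
    gd_us = -slope * 1e6,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    n_points = n,
    band = band_name, f_lo = f_lo, f_hi = f_hi,
    target_label = spectrum$target_label[1],
    specimen_id = spectrum$specimen_id[1]
  ), class = "gd_fit")
}

#' @export
print.gd_fit <- function(x, ...) {
  cat(sprintf(
    "<gd_fit> %s / %s, band %s [%g, %g] Hz: GD = %.1f us (n = %d, rms %.2g cycles)\n",
    x$specimen_id, x$target_label,
    ifelse(is.na(x$band), "custom", x$band), x$f_lo, x$f_hi,
    x$gd_us, x$n_points, x$residual_rms
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gd_fit
#' @export
tidy.gd_fit <- function(x, ...) {
  tibble::tibble(
    specimen_id = x$specimen_id, target = x$target_label,
    band = x$band, f_lo = x$f_lo, f_hi = x$f_hi,
    gd_us = x$gd_us, residual_rms = x$residual_rms, n_points = x$n_points
  )
}

#' @method glance gd_fit
#' @export
glance.gd_fit <- function(x, ...) {
  tibble::tibble(
    gd_us = x$gd_us, slope = x$slope, intercept = x$intercept,
    residual_rms = x$residual_rms, n_points = x$n_points
  )
}

#' Acoustic propagation delay of the probe-tube-to-umbo path
#'
#' Travel time of sound over the given distance: `distance / c`, reported
#' in microseconds. Subtracted from measured group delays to remove the
#' ear-canal acoustic path from the middle-ear delay estimate.
#'
#' @param distance_mm Distance in mm (>= 0).
#' @param c Speed of sound in m/s (default 344).
#' @return Delay in microseconds.
#' @examples
#' propagation_delay_us(41) # 119.2 us
#' propagation_delay_us(5) # 14.5 us
#' @export
propagation_delay_us <- function(distance_mm, c = 344) {
  if (any(!is.finite(distance_mm)) || any(distance_mm < 0)) {
    stop("`distance_mm` must be non-negative", call. = FALSE)
  }
  distance_mm / c * 1000
}

#' Per-specimen group-delay estimates across bands
#'
#' Fits the banded group delay of each spectrum and applies its
#' propagation correction: `corrected_gd = raw_gd - propagation_correction`.
#' Corrected delays may legitimately be negative. Subtracting the
#' correction after fitting is identical to delay-correcting the phase
#' before fitting, by linearity of least squares.
#'
#' @param spectra A tibble stacking unwrapped spectra (columns as in
#'   [me_spectrum], one spectrum per `specimen_id` x `target_label`).
#' @param config A tibble with one row per specimen: `specimen_id`,
#'   `group` (`"elephant"` or `"human"`), `probe_distance_mm`.
#' @param bands Which preset bands to fit (default HF and WB).
#' @param c Speed of sound in m/s.
#' @return A tibble: `group`, `specimen_id`, `target`, `band`, `raw_gd_us`,
#'   `correction_us`, `corrected_gd_us`, `residual_rms`, `n_points`.
#' @export
estimate_group_delays <- function(spectra, config, bands = c("HF", "WB"),
                                  c = 344) {
  combos <- dplyr::distinct(
    spectra,
    .data$specimen_id, .data$target_label
  )
  purrr::pmap_dfr(combos, function(specimen_id, target_label) {
    cfg <- config[config$specimen_id == specimen_id, , drop = FALSE]
    if (nrow(cfg) != 1) {
      stop("config must have exactly one row for specimen ", specimen_id,
        call. = FALSE
      )
    }
    preset <- band_presets(cfg$group)
    preset <- preset[preset$band %in% bands, , drop = FALSE]
    s <- spectra[spectra$specimen_id == specimen_id &
      spectra$target_label == target_label, , drop = FALSE]
    corr <- propagation_delay_us(cfg$probe_distance_mm, c = c)
    purrr::pmap_dfr(
      preset[, c("band", "f_lo", "f_hi")],
      function(band, f_lo, f_hi) {
        fit <- fit_group_delay(s, f_lo = f_lo, f_hi = f_hi)
        tibble::tibble(
          group = cfg$group, specimen_id = specimen_id,
          target = target_label, band = band,
          raw_gd_us = fit$gd_us, correction_us = corr,
          corrected_gd_us = fit$gd_us - corr,
          residual_rms = fit$residual_rms, n_points = fit$n_points
        )
      }
    )
  })
}

#' Summarise corrected group delays by group, target and band
#'
#' Arithmetic mean and SD of the corrected delays over specimens within
#' each (group, target, band) cell. The SD is the population form (divisor
#' n, zero for a single specimen): the specimens are summarised as the
#' complete measured set, not as a sample. Cells with no estimates are
#' omitted with a message.
#'
#' @param estimates Output of [estimate_group_delays()], or any tibble with
#'   `group`, `target`, `band`, `corrected_gd_us`.
#' @return A tibble: `group`, `target`, `band`, `mean_gd_us`, `sd_gd_us`, `n`.
#' @export
summarize_delays <- function(estimates) {
  if (nrow(estimates) == 0) stop("no estimates to summarise", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(estimates, .data$group, .data$target, .data$band),
    mean_gd_us = mean(.data$corrected_gd_us),
    sd_gd_us = sqrt(mean((.data$corrected_gd_us - mean(.data$corrected_gd_us))^2)),
    n = dplyr::n(),
    .groups = "drop"
  )
}

#' Ossicular transmission delay
#'
#' Delay accumulated between umbo and stapes: the stapes-re-pressure group
#' delay minus the umbo-re-pressure group delay, per group and band.
#'
#' @param summary Output of [summarize_delays()] containing both `"umbo"`
#'   and `"stapes"` targets.
#' @return A tibble: `group`, `band`, `umbo_gd_us`, `stapes_gd_us`,
#'   `transmission_us`.
#' @export
transmission_delay <- function(summary) {
  wide <- tidyr::pivot_wider(
    summary[, c("group", "target", "band", "mean_gd_us")],
    names_from = "target", values_from = "mean_gd_us"
  )
  if (!all(c("umbo", "stapes") %in% names(wide))) {
    stop("summary must contain both umbo and stapes means for matching cells",
      call. = FALSE
    )
  }
  wide <- wide[!is.na(wide$umbo) & !is.na(wide$stapes), , drop = FALSE]
  tibble::tibble(
    group = wide$group, band = wide$band,
    umbo_gd_us = wide$umbo, stapes_gd_us = wide$stapes,
    transmission_us = wide$stapes - wide$umbo
  )
}

#' Reference per-specimen corrected group delays
#'
#' The corrected group delays (microseconds) measured per specimen in the
#' elephant/human temporal-bone comparison this package models: umbo and
#' stapes targets in the HF and WB bands, after subtraction of each ear's
#' probe-tube propagation delay. Missing cells (targets not measured in a
#' specimen) are absent.
#'
#' @return A tibble: `group`, `specimen_id`, `target`, `band`,
#'   `corrected_gd_us`.
#' @export
gd_reference <- function() {
  tibble::tribble(
    ~group, ~specimen_id, ~target, ~band, ~corrected_gd_us,
    "elephant", "ETB2", "umbo", "HF", 5,
    "elephant", "ETB2", "umbo", "WB", 3,
    "elephant", "ETB3", "umbo", "HF", -2,
    "elephant", "ETB3", "umbo", "WB", 2,
    "elephant", "ETB6", "umbo", "HF", 170,
    "elephant", "ETB6", "umbo", "WB", 161,
    "elephant", "ETB7", "umbo", "HF", 62,
    "elephant", "ETB7", "umbo", "WB", 77,
    "elephant", "ETB2", "stapes", "HF", 121,
    "elephant", "ETB2", "stapes", "WB", 111,
    "elephant", "ETB3", "stapes", "HF", 104,
    "elephant", "ETB3", "stapes", "WB", 111,
    "elephant", "ETB7", "stapes", "HF", 184,
    "elephant", "ETB7", "stapes", "WB", 192,
    "human", "TB19", "umbo", "HF", 10,
    "human", "TB19", "umbo", "WB", 14,
    "human", "TB20", "umbo", "HF", 9,
    "human", "TB20", "umbo", "WB", 14,
    "human", "TB18", "stapes", "HF", 88,
    "human", "TB18", "stapes", "WB", 73,
    "human", "TB19", "stapes", "HF", 50,
    "human", "TB19", "stapes", "WB", 41,
    "human", "TB20", "stapes", "HF", 42,
    "human", "TB20", "stapes", "WB", 54
  )
}

#' Reference probe-tube-to-umbo distances
#'
#' Probe-tube-tip-to-umbo distances (mm) per specimen, from which the
#' propagation corrections are computed at c = 344 m/s.
#'
#' @return A tibble: `group`, `specimen_id`, `probe_distance_mm`.
#' @export
probe_distances_reference <- function() {
  tibble::tribble(
    ~group, ~specimen_id, ~probe_distance_mm,
    "elephant", "ETB2", 41,
    "elephant", "ETB3", 53,
    "elephant", "ETB6", 19,
    "elephant", "ETB7", 45,
    "human", "TB18", 5,
    "human", "TB19", 5,
    "human", "TB20", 5
  )
}
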