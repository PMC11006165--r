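#' Complex velocity spectra as tidy tibbles
#'
#' A spectrum is a tibble with one row per frequency carrying a complex
#' frequency response stored as linear magnitude plus unwrapped phase in
#' cycles. Magnitudes of pressure-normalised velocities are in (mm/s)/Pa;
#' transfer functions between ossicles are dimensionless.
#'
#' @param frequency_hz Numeric, strictly increasing, positive (Hz).
#' @param magnitude Non-negative linear magnitude.
#' @param phase_cycles Unwrapped phase in cycles (1 cycle = 2*pi rad).
#' @param target_label Measurement target, e.g. `"umbo"`, `"incus"`,
#'   `"stapes"`, or a transfer-function label such as `"TF_US"`.
#' @param specimen_id Specimen identifier.
#' @return A tibble of class `me_spectrum` with columns `frequency_hz`,
#'   `magnitude`, `phase_cycles`, `target_label`, `specimen_id`.
#' @examples
#' f <- freq_grid(10, 1000, points_per_decade = 10)
#' me_spectrum(f, magnitude = rep(1, length(f)), phase_cycles = 0)
#' @export
me_spectrum <- function(frequency_hz, magnitude, phase_cycles,
                        target_label = "unlabelled", specimen_id = "synthetic") {
  stopifnot(is.numeric(frequency_hz), is.numeric(magnitude), is.numeric(phase_cycles))
  if (any(!is.finite(frequency_hz)) || any(frequency_hz <= 0)) {
    stop("`frequency_hz` must be finite and positive", call. = FALSE)
  }
  if (is.unsorted(frequency_hz, strictly = TRUE)) {
    stop("`frequency_hz` must be strictly increasing", call. = FALSE)
  }
  if (any(magnitude < 0, na.rm = TRUE)) {
    stop("`magnitude` must be non-negative", call. = FALSE)
  }
  out <- tibble::tibble(
    frequency_hz = as.numeric(frequency_hz),
    magnitude = as.numeric(rep_len(magnitude, length(frequency_hz))),
    phase_cycles = as.numeric(rep_len(phase_cycles, length(frequency_hz))),
    target_label = rep_len(as.character(target_label), length(frequency_hz)),
    specimen_id = rep_len(as.character(specimen_id), length(frequency_hz))
  )
  class(out) <- c("me_spectrum", class(out))
  out
}

#' Logarithmic frequency grid
#'
#' Default analysis grid: log-spaced at a fixed density per decade over the
#' measured band 7 Hz to 13 kHz.
#'
#' @param f_min,f_max Band edges in Hz; `f_min >= 1`, `f_max <= 20000`.
#' @param points_per_decade Grid density (default 100).
#' @return Numeric vector of frequencies in Hz, strictly increasing.
#' @export
freq_grid <- function(f_min = 7, f_max = 13000, points_per_decade = 100) {
  stopifnot(f_min >= 1, f_max <= 20000, f_min < f_max, points_per_decade > 0)
  n <- max(2L, ceiling(log10(f_max / f_min) * points_per_decade) + 1L)
  10^seq(log10(f_min), log10(f_max), length.out = n)
}

#' Complex values of a spectrum
#'
#' @param spectrum An `me_spectrum` (or any data frame with `magnitude` and
#'   `phase_cycles` columns).
#' @return Complex vector `magnitude * exp(2i * pi * phase_cycles)`.
#' @export
spectrum_complex <- function(spectrum) {
  spectrum$magnitude * exp(2i * pi * spectrum$phase_cycles)
}

#' Build a spectrum from complex values
#'
#' Phase is taken as the principal argument and unwrapped along frequency.
#'
#' @param frequency_hz Frequencies in Hz.
#' @param z Complex response values.
#' @inheritParams me_spectrum
#' @return An `me_spectrum` tibble.
#' @export
spectrum_from_complex <- function(frequency_hz, z, target_label = "unlabelled",
                                  specimen_id = "synthetic") {
  me_spectrum(frequency_hz,
    magnitude = Mod(z),
    phase_cycles = unwrap_phase(Arg(z) / (2 * pi)),
    target_label = target_label, specimen_id = specimen_id
  )
}

#' Linear magnitude to decibels and back
#'
#' `magnitude_db()` is `20 * log10(x)`; `db_to_magnitude()` inverts it.
#'
#' @param linear Positive linear magnitude(s).
#' @param db Level(s) in dB.
#' @return Numeric vector.
#' @examples
#' magnitude_db(0.65) # about -3.7 dB
#' @export
magnitude_db <- function(linear) {
  if (any(!is.finite(linear)) || any(linear <= 0)) {
    stop("`linear` must be positive and finite", call. = FALSE)
  }
  20 * log10(linear)
}

#' @rdname magnitude_db
#' @export
db_to_magnitude <- function(db) 10^(db / 20)

assert_shared_grid <- function(a, b, what = "spectra") {
  if (nrow(a) != nrow(b) || any(abs(a$frequency_hz - b$frequency_hz) >
    1e-9 * pmax(a$frequency_hz, 1))) {
    stop("frequency grids of the two ", what, " do not match", call. = FALSE)
  }
  invisible(TRUE)
}
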