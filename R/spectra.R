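#' Unwrap phase expressed in cycles
#'
#' Adds integer cycle offsets so that adjacent differences fall in
#' (-0.5, +0.5]. Above an optional enforcement frequency, additional whole
#' cycles are subtracted wherever the phase would rise by more than
#' `increase_tol` between adjacent points — the rule used to keep
#' high-frequency ossicular phase monotonically decreasing where delay
#' dominates and the raw wrap is ambiguous.
#'
#' @param phase_cycles Raw phase in cycles.
#' @param frequency_hz Frequencies, required only when
#'   `enforce_decrease_above_hz` is set.
#' @param enforce_decrease_above_hz Frequency above which increases larger
#'   than `increase_tol` are forbidden; `NULL` (default) disables the rule.
#' @param increase_tol Largest tolerated increase (cycles) under the rule.
#' @return Unwrapped phase; the integer offsets applied at each point are
#'   attached as attribute `"offsets"`, and a message reports how many
#'   points were adjusted.
#' @export
unwrap_phase <- function(phase_cycles, frequency_hz = NULL,
                         enforce_decrease_above_hz = NULL,
                         increase_tol = 0.25) {
  stopifnot(all(is.finite(phase_cycles)))
  n <- length(phase_cycles)
  if (n == 0) return(phase_cycles)
  d <- diff(phase_cycles)
  # offset per gap: bring each adjacent difference into (-0.5, 0.5]
  k <- -ceiling(d - 0.5)
  offs <- c(0, cumsum(k))
  out <- phase_cycles + offs
  if (!is.null(enforce_decrease_above_hz)) {
    if (is.null(frequency_hz)) {
      stop("`frequency_hz` is required for the monotone-decrease rule", call. = FALSE)
    }
    for (i in seq_len(n - 1)) {
      if (frequency_hz[i + 1] >= enforce_decrease_above_hz) {
        rise <- out[i + 1] - out[i]
        if (rise > increase_tol) {
          drop_k <- ceiling(rise - increase_tol)
          out[(i + 1):n] <- out[(i + 1):n] - drop_k
          offs[(i + 1):n] <- offs[(i + 1):n] - drop_k
        }
      }
    }
  }
  n_adj <- sum(diff(offs) != 0)
  if (n_adj > 0) {
    message("unwrap_phase: applied cycle offsets at ", n_adj, " point(s)")
  }
  attr(out, "offsets") <- offs
  out
}

#' @rdname unwrap_phase
#' @param spectrum An [me_spectrum] whose `phase_cycles` column to unwrap.
#' @export
unwrap_spectrum <- function(spectrum, enforce_decrease_above_hz = NULL,
                            increase_tol = 0.25) {
  p <- unwrap_phase(spectrum$phase_cycles, spectrum$frequency_hz,
    enforce_decrease_above_hz = enforce_decrease_above_hz,
    increase_tol = increase_tol
  )
  out <- spectrum
  out$phase_cycles <- as.numeric(p)
  attr(out, "unwrap_offsets") <- attr(p, "offsets")
  out
}

# Interpolate a spectrum (log-magnitude and unwrapped phase, linearly in
# frequency) onto a target grid restricted to its own range.
interp_spectrum <- function(spectrum, grid) {
  grid <- grid[grid >= min(spectrum$frequency_hz) - 1e-9 &
    grid <= max(spectrum$frequency_hz) + 1e-9]
  logm <- stats::approx(spectrum$frequency_hz, log(pmax(spectrum$magnitude, 1e-300)),
    xout = grid, rule = 1
  )$y
  ph <- stats::approx(spectrum$frequency_hz, spectrum$phase_cycles,
    xout = grid, rule = 1
  )$y
  me_spectrum(grid, exp(logm), ph,
    target_label = spectrum$target_label[1],
    specimen_id = spectrum$specimen_id[1]
  )
}

#' Transfer function between two complex spectra
#'
#' Complex ratio numerator / denominator: magnitudes divide, unwrapped
#' phases subtract. When the two spectra are sampled on different grids they
#' are reconciled by linear interpolation of log-magnitude and unwrapped
#' phase onto the coarser grid, restricted to the overlapping range. Points
#' where the denominator magnitude falls below `floor_frac` of its peak are
#' masked (`NA`) and reported.
#'
#' @param numerator,denominator [me_spectrum] objects (e.g. stapes and umbo
#'   velocity re ear-canal pressure, giving TF_US).
#' @param label Label for the result (default `"<num>/<den>"`).
#' @param floor_frac Denominator magnitude floor, as a fraction of its peak.
#' @return An [me_spectrum] whose `target_label` is `label`, with attributes
#'   `numerator_label` and `denominator_label`.
#' @examples
#' p <- species_preset("human")
#' u <- simulate_umbo_response(p)
#' s <- simulate_stapes_response(p, u)
#' tf <- transfer_function(s, u, label = "TF_US")
#' head(tf$magnitude) # ~ 1/1.4
#' @export
transfer_function <- function(numerator, denominator, label = NULL,
                              floor_frac = 1e-6) {
  f_lo <- max(min(numerator$frequency_hz), min(denominator$frequency_hz))
  f_hi <- min(max(numerator$frequency_hz), max(denominator$frequency_hz))
  if (f_lo >= f_hi) stop("frequency ranges do not overlap", call. = FALSE)
  same_grid <- nrow(numerator) == nrow(denominator) &&
    all(abs(numerator$frequency_hz - denominator$frequency_hz) <
      1e-9 * numerator$frequency_hz)
  if (!same_grid) {
    # coarser grid = fewer points in the overlap
    n_num <- sum(numerator$frequency_hz >= f_lo & numerator$frequency_hz <= f_hi)
    n_den <- sum(denominator$frequency_hz >= f_lo & denominator$frequency_hz <= f_hi)
    base <- if (n_num <= n_den) numerator else denominator
    grid <- base$frequency_hz[base$frequency_hz >= f_lo & base$frequency_hz <= f_hi]
    numerator <- interp_spectrum(numerator, grid)
    denominator <- interp_spectrum(denominator, grid)
  }
  floor_abs <- floor_frac * max(denominator$magnitude)
  masked <- denominator$magnitude < floor_abs
  mag <- numerator$magnitude / denominator$magnitude
  ph <- numerator$phase_cycles - denominator$phase_cycles
  mag[masked] <- NA_real_
  ph[masked] <- NA_real_
  if (any(masked)) {
    message(
      "transfer_function: masked ", sum(masked),
      " point(s) with denominator magnitude below floor"
    )
  }
  if (is.null(label)) {
    label <- paste0(numerator$target_label[1], "/", denominator$target_label[1])
  }
  out <- tibble::tibble(
    frequency_hz = numerator$frequency_hz,
    magnitude = mag, phase_cycles = ph,
    target_label = label, specimen_id = numerator$specimen_id[1]
  )
  class(out) <- c("me_spectrum", class(out))
  attr(out, "numerator_label") <- numerator$target_label[1]
  attr(out, "denominator_label") <- denominator$target_label[1]
  out
}

#' Group mean and SD of a set of spectra
#'
#' Averages in the presentation domains: dB for magnitude (a geometric mean
#' on the linear scale) and cycles for unwrapped phase, per frequency, with
#' the number of contributing spectra at each point. Spectra on different
#' grids are interpolated onto the coarsest grid over the common range.
#'
#' @param spectra A tibble stacking two or more spectra (rows distinguished
#'   by `specimen_id`, or by the grouping column named in `by`).
#' @param by Column distinguishing the individual spectra.
#' @return A tibble with `frequency_hz`, `mean_db`, `sd_db`,
#'   `mean_magnitude`, `mean_phase_cycles`, `sd_phase_cycles`, `n`.
#' @export
group_mean_sd <- function(spectra, by = "specimen_id") {
  ids <- unique(spectra[[by]])
  if (length(ids) < 2) stop("need at least 2 spectra to average", call. = FALSE)
  parts <- lapply(ids, function(id) spectra[spectra[[by]] == id, , drop = FALSE])
  f_lo <- max(vapply(parts, function(s) min(s$frequency_hz), 0))
  f_hi <- min(vapply(parts, function(s) max(s$frequency_hz), 0))
  if (f_lo >= f_hi) stop("spectra have no common frequency range", call. = FALSE)
  counts <- vapply(parts, function(s) {
    sum(s$frequency_hz >= f_lo & s$frequency_hz <= f_hi)
  }, 0L)
  base <- parts[[which.min(counts)]]
  grid <- base$frequency_hz[base$frequency_hz >= f_lo & base$frequency_hz <= f_hi]
  aligned <- lapply(parts, interp_spectrum, grid = grid)
  dbm <- vapply(aligned, function(s) magnitude_db(pmax(s$magnitude, 1e-300)),
    numeric(length(grid))
  )
  ph <- vapply(aligned, function(s) s$phase_cycles, numeric(length(grid)))
  tibble::tibble(
    frequency_hz = grid,
    mean_db = rowMeans(dbm),
    sd_db = apply(dbm, 1, stats::sd),
    mean_magnitude = db_to_magnitude(rowMeans(dbm)),
    mean_phase_cycles = rowMeans(ph),
    sd_phase_cycles = apply(ph, 1, stats::sd),
    n = length(aligned)
  )
}

#' Analysis-ready long table for mixed-model statistics
#'
#' Restricts a stack of spectra to the comparable band, labels each row with
#' a low/high frequency category, and applies the model transforms:
#' `log(magnitude)` and `log(phase + 4)` (the +4 shift accommodates
#' unwrapped phases as negative as about -3.5 cycles). Rows with
#' `phase <= -4` cannot be transformed and are dropped with a message. The
#' mixed models themselves are fitted outside this package; this function
#' only prepares their input.
#'
#' @param spectra A tibble of spectra rows with `specimen_id`,
#'   `target_label`, `frequency_hz`, `magnitude`, `phase_cycles`, and
#'   optionally a `group` column (species group).
#' @param f_min,f_max Retained band in Hz (defaults 17 and 11000).
#' @param split Boundary between categories: `<= split` is `"low"`,
#'   `> split` is `"high"` (default 1000 Hz).
#' @return A tibble with columns `specimen_id`, `group`, `ossicle`,
#'   `frequency_hz`, `freq_category`, `log_magnitude`, `log_phase_plus4`.
#' @export
prepare_stats_table <- function(spectra, f_min = 17, f_max = 11000,
                                split = 1000) {
  grp <- if ("group" %in% names(spectra)) spectra$group else NA_character_
  out <- tibble::tibble(
    specimen_id = spectra$specimen_id,
    group = grp,
    ossicle = spectra$target_label,
    frequency_hz = spectra$frequency_hz,
    magnitude = spectra$magnitude,
    phase_cycles = spectra$phase_cycles
  )
  out <- dplyr::filter(out, .data$frequency_hz >= f_min, .data$frequency_hz <= f_max)
  bad <- out$phase_cycles <= -4
  if (any(bad)) {
    message(
      "prepare_stats_table: dropped ", sum(bad),
      " row(s) with phase <= -4 cycles (log transform undefined)"
    )
    out <- out[!bad, , drop = FALSE]
  }
  dplyr::mutate(out,
    freq_category = ifelse(.data$frequency_hz > split, "high", "low"),
    log_magnitude = log(.data$magnitude),
    log_phase_plus4 = log(.data$phase_cycles + 4),
    magnitude = NULL, phase_cycles = NULL
  )
}
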