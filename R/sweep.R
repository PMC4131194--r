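# Sweep and CellRecord containers. Units are fixed package-wide: voltage mV,
# current pA, sample_rate kHz; time is implicit (sample index / sample_rate).

#' Create a sweep (one stimulus episode)
#'
#' @param sweep_id identifier (character).
#' @param clamp_mode `"current_clamp"` or `"voltage_clamp"`.
#' @param sample_rate sampling rate in kHz.
#' @param voltage numeric series, mV. In current clamp this is the recorded
#'   membrane potential; in voltage clamp the command potential.
#' @param current numeric series, pA. Command current in current clamp,
#'   recorded current in voltage clamp. Must match `voltage` in length.
#' @param protocol a [protocol_descriptor()].
#' @param baseline_window ms interval `c(from, to)` used for baseline
#'   measurements; defaults to the pre-onset segment.
#' @return a `gc_sweep` list.
#' @export
new_sweep <- function(sweep_id, clamp_mode = c("current_clamp", "voltage_clamp"),
                      sample_rate, voltage, current, protocol,
                      baseline_window = NULL) {
  clamp_mode <- match.arg(clamp_mode)
  if (!is_protocol(protocol)) stopf("protocol must be a gc_protocol")
  if (length(voltage) != length(current))
    stopf("sweep %s: voltage and current series have unequal length (%d vs %d)",
          sweep_id, length(voltage), length(current))
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stopf("sweep %s: sample_rate must be > 0 kHz", sweep_id)
  n <- length(voltage)
  dur_ms <- n / sample_rate
  if (is.null(baseline_window)) {
    # pre-onset segment; a zero-onset protocol gets a single-sample window
    baseline_window <- c(0, min(max(protocol$onset_ms, 1 / sample_rate), dur_ms))
  }
  if (baseline_window[1] < 0 || baseline_window[2] > dur_ms + 1e-9 ||
      baseline_window[2] <= baseline_window[1])
    stopf("sweep %s: baseline window [%g, %g] ms outside the sweep (%g ms)",
          sweep_id, baseline_window[1], baseline_window[2], dur_ms)
  structure(list(sweep_id = as.character(sweep_id), clamp_mode = clamp_mode,
                 sample_rate = sample_rate, voltage = as.numeric(voltage),
                 current = as.numeric(current), protocol = protocol,
                 baseline_window = as.numeric(baseline_window)),
            class = "gc_sweep")
}

is_sweep <- function(x) inherits(x, "gc_sweep")

#' @export
print.gc_sweep <- function(x, ...) {
  cat(sprintf("<sweep %s: %s, %g kHz, %d samples, %s>\n", x$sweep_id,
              x$clamp_mode, x$sample_rate, length(x$voltage), x$protocol$kind))
  invisible(x)
}

# sample indices covering a [from, to] ms window (1-based, inclusive)
window_idx <- function(sweep, from_ms, to_ms) {
  n <- length(sweep$voltage)
  i1 <- max(1L, floor(from_ms * sweep$sample_rate) + 1L)
  i2 <- min(n, ceiling(to_ms * sweep$sample_rate))
  if (i2 < i1) stopf("empty window [%g, %g] ms in sweep %s", from_ms, to_ms,
                     sweep$sweep_id)
  i1:i2
}

baseline_mean <- function(sweep, series = c("voltage", "current")) {
  series <- match.arg(series)
  mean(sweep[[series]][window_idx(sweep, sweep$baseline_window[1],
                                  sweep$baseline_window[2])])
}

#' Create a cell record (all sweeps of one cell)
#'
#' @param cell_id,animal_id identifiers.
#' @param age_days postmitotic age in days for birth-dated (labeled) cells;
#'   must lie in 21-72 when `labeled = TRUE`. Use `NA` for non-labeled cells.
#' @param labeled logical; whether the cell is retrovirally birth-dated.
#' @param sweeps list of [new_sweep()] objects.
#' @param notes free text.
#' @return a `gc_cell_record` list.
#' @export
cell_record <- function(cell_id, animal_id = NA_character_, age_days = NA,
                        labeled = FALSE, sweeps = list(), notes = "") {
  if (labeled) {
    if (is.na(age_days) || age_days < LABELED_AGE_RANGE_DAYS[1] ||
        age_days > LABELED_AGE_RANGE_DAYS[2])
      stopf("cell %s: labeled cells must have age_days in [%d, %d], got %s",
            cell_id, LABELED_AGE_RANGE_DAYS[1], LABELED_AGE_RANGE_DAYS[2],
            format(age_days))
  }
  if (!all(vapply(sweeps, is_sweep, logical(1))))
    stopf("cell %s: sweeps must all be gc_sweep objects", cell_id)
  ids <- vapply(sweeps, `[[`, character(1), "sweep_id")
  if (anyDuplicated(ids)) stopf("cell %s: duplicated sweep ids", cell_id)
  names(sweeps) <- ids
  structure(list(cell_id = as.character(cell_id),
                 animal_id = as.character(animal_id),
                 age_days = if (is.na(age_days)) NA_integer_ else as.integer(age_days),
                 labeled = isTRUE(labeled), sweeps = sweeps,
                 notes = as.character(notes)),
            class = "gc_cell_record")
}

is_cell_record <- function(x) inherits(x, "gc_cell_record")

#' @export
print.gc_cell_record <- function(x, ...) {
  kinds <- table(vapply(x$sweeps, function(s) s$protocol$kind, character(1)))
  cat(sprintf("<cell %s: %s, %d sweeps (%s)>\n", x$cell_id,
              if (x$labeled) sprintf("%d days postmitotic", x$age_days)
              else "non-labeled",
              length(x$sweeps),
              paste(sprintf("%s x%d", names(kinds), kinds), collapse = ", ")))
  invisible(x)
}

#' Subset the sweeps of a record by protocol kind
#' @param record a [cell_record()].
#' @param kind protocol kind to keep.
#' @param frequency optional sinusoid frequency filter (Hz).
#' @return list of sweeps.
#' @export
sweeps_of_kind <- function(record, kind, frequency = NULL) {
  keep <- vapply(record$sweeps, function(s) {
    s$protocol$kind == kind &&
      (is.null(frequency) ||
         (!is.null(s$protocol$frequency) && s$protocol$frequency == frequency))
  }, logical(1))
  unname(record$sweeps[keep])
}
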