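# Sinusoidal input-output curves and the three gain statistics.
#
# For one cell and one sinusoid frequency f, the input-output curve is the
# spike count per 1 s sweep against the peak amplitude of the injected
# sinusoid (50 pA grid). With d the successive differences of the included
# counts (spikes per 50 pA increment):
#   asl_f    = mean(d) / sqrt(f)            (average slope, frequency-weighted)
#   var_f    = sampleVariance(d) / f        (variance of the increments)
#   offset_f = A* / f^(1/4),  A* the smallest amplitude whose count strictly
#              exceeds f/2 (i.e. output rate > half the input frequency)
# Pooled per-cell values are arithmetic means of the defined per-frequency
# values. The frequency weighting is applied by *division* so that the
# frequency-driven growth of spike counts is compressed into a single
# frequency-independent number per cell.

#' Construct an input-output curve
#'
#' @param frequency sinusoid frequency, Hz (one of 5/10/20/40/60/80).
#' @param amplitudes strictly increasing peak amplitudes on the 50 pA grid.
#' @param counts non-negative integer spike counts per 1 s sweep.
#' @param included logical inclusion mask (single contiguous run); defaults to
#'   all included. Usually set by [mask_io_curve()].
#' @return a `gc_io_curve`.
#' @export
io_curve <- function(frequency, amplitudes, counts, included = NULL) {
  if (!(frequency %in% SINE_FREQUENCIES_HZ))
    stopf("frequency not in protocol grid (%s Hz): got %s",
          paste(SINE_FREQUENCIES_HZ, collapse = "/"), format(frequency))
  n <- length(amplitudes)
  if (length(counts) != n) stopf("amplitudes and counts differ in length")
  if (n && (any(diff(amplitudes) != SINE_AMP_STEP_PA) ||
            amplitudes[1] %% SINE_AMP_STEP_PA != 0 || amplitudes[1] <= 0))
    stopf("non-contiguous grid: amplitudes must advance by %d pA from a positive multiple of %d",
          SINE_AMP_STEP_PA, SINE_AMP_STEP_PA)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be non-negative integers")
  if (is.null(included)) included <- rep(TRUE, n)
  if (length(included) != n) stopf("included mask length mismatch")
  w <- which(included)
  if (length(w) && any(diff(w) != 1L))
    stopf("included mask must be a single contiguous run")
  structure(list(frequency = frequency, amplitudes = as.numeric(amplitudes),
                 counts = as.integer(round(counts)), included = included),
            class = "gc_io_curve")
}

#' @export
print.gc_io_curve <- function(x, ...) {
  cat(sprintf("<io_curve %g Hz: %d points, %d included>\n", x$frequency,
              length(x$counts), sum(x$included)))
  invisible(x)
}

#' Build an input-output curve from the sine sweeps at one frequency
#'
#' Spike counts come from [detect_spikes()] per sweep; the inclusion mask is
#' then refined by [mask_io_curve()].
#'
#' @param sine_sweeps list of `sine_family` current-clamp sweeps sharing one
#'   frequency and covering a contiguous 50 pA amplitude grid.
#' @param on_duplicate `"error"` (fixtures) or `"average"` (real data;
#'   conflicting counts at one amplitude are averaged with a warning).
#' @return a masked `gc_io_curve`.
#' @export
build_io_curve <- function(sine_sweeps, on_duplicate = c("error", "average")) {
  on_duplicate <- match.arg(on_duplicate)
  if (!length(sine_sweeps)) stopf("no sine sweeps supplied")
  freqs <- vapply(sine_sweeps, function(s) s$protocol$frequency, numeric(1))
  if (length(unique(freqs)) != 1L)
    stopf("sweeps mix frequencies: %s", paste(unique(freqs), collapse = ", "))
  amps <- vapply(sine_sweeps, function(s) s$protocol$amplitude, numeric(1))
  counts <- vapply(sine_sweeps, function(s) nrow(detect_spikes(s)), integer(1))
  if (anyDuplicated(amps)) {
    agg <- tapply(counts, amps, function(x) x)
    bad <- vapply(agg, function(x) length(unique(x)) > 1L, logical(1))
    if (any(bad) && on_duplicate == "error")
      stopf("duplicate amplitude with conflicting counts at %s pA",
            paste(names(agg)[bad], collapse = ", "))
    if (any(bad)) warnf("conflicting counts at duplicated amplitudes averaged")
    counts <- vapply(agg, function(x) round(mean(x)), numeric(1))
    amps <- as.numeric(names(agg))
  }
  ord <- order(amps)
  mask_io_curve(io_curve(freqs[1], amps[ord], counts[ord]))
}

#' Apply the lack/saturation inclusion mask
#'
#' Leading zero counts are excluded (lack of spiking); the tail is excluded
#' from the first amplitude whose count fails to exceed the previous included
#' count (saturation onset). If the resulting run has fewer than 3 points, the
#' longest maximal strictly increasing run of positive counts is used instead
#' when one of length >= 3 exists; otherwise the curve is undefined (empty
#' mask) and yields no slope statistics at this frequency.
#'
#' Idempotent: masking a masked curve changes nothing.
#'
#' @param curve a `gc_io_curve`.
#' @return the curve with its `included` mask set.
#' @export
mask_io_curve <- function(curve) {
  stopifnot(inherits(curve, "gc_io_curve"))
  counts <- curve$counts
  n <- length(counts)
  inc <- rep(FALSE, n)
  start <- which(counts > 0)[1]
  if (!is.na(start)) {
    end <- start
    while (end < n && counts[end + 1L] > counts[end]) end <- end + 1L
    if (end - start + 1L >= 3L) {
      inc[start:end] <- TRUE
    } else {
      # fall back to the longest strictly increasing run of positive counts
      runs <- list()
      i <- 1L
      while (i <= n) {
        if (counts[i] > 0) {
          j <- i
          while (j < n && counts[j + 1L] > counts[j]) j <- j + 1L
          runs[[length(runs) + 1L]] <- c(i, j)
          i <- j + 1L
        } else i <- i + 1L
      }
      if (length(runs)) {
        lens <- vapply(runs, function(r) r[2] - r[1] + 1L, integer(1))
        if (max(lens) >= 3L) {
          r <- runs[[which.max(lens)]]
          inc[r[1]:r[2]] <- TRUE
        }
      }
    }
  }
  curve$included <- inc
  curve
}

#' Slope statistics of one input-output curve
#'
#' @param curve a masked `gc_io_curve` with >= 3 included points.
#' @return list with `asl_f` (mean increment / sqrt(f)) and `var_f` (sample
#'   variance of the increments / f); both `NA` for undefined curves.
#' @export
compute_io_statistics <- function(curve) {
  stopifnot(inherits(curve, "gc_io_curve"))
  if (sum(curve$included) < 3L) return(list(asl_f = NA_real_, var_f = NA_real_))
  d <- diff(curve$counts[curve$included])
  f <- curve$frequency
  list(asl_f = mean(d) / sqrt(f), var_f = stats::var(d) / f)
}

#' Normalized offset of one input-output curve
#'
#' Smallest amplitude whose count strictly exceeds half the input frequency
#' (counts over a 1 s sweep are rates in Hz), divided by the fourth root of
#' the frequency.
#'
#' @param curve a `gc_io_curve`.
#' @return offset in pA * Hz^(-1/4), or `NA` when the criterion is never met.
#' @export
compute_offset <- function(curve) {
  stopifnot(inherits(curve, "gc_io_curve"))
  i <- which(curve$counts > curve$frequency / 2)[1]
  if (is.na(i)) return(NA_real_)
  curve$amplitudes[i] / curve$frequency^0.25
}

#' Pool per-frequency statistics into one feature set per cell
#'
#' Pooled ASL, VAR and offset are the arithmetic means of the defined
#' per-frequency weighted values. A statistic with fewer than `min_defined`
#' defined frequencies is `NA` and the cell is flagged incomplete.
#'
#' @param curves list of `gc_io_curve` objects (one per frequency), or a
#'   data.frame with columns `frequency`, `asl_f`, `var_f`, `offset_f`.
#' @param min_defined minimum number of defined frequencies per statistic.
#' @return list with `asl`, `var`, `offset_norm`, `incomplete` flag and the
#'   `per_frequency` table.
#' @export
pool_features <- function(curves, min_defined = 3L) {
  if (is.data.frame(curves)) {
    per <- curves
  } else {
    per <- do.call(rbind, lapply(curves, function(cv) {
      st <- compute_io_statistics(cv)
      data.frame(frequency = cv$frequency, asl_f = st$asl_f, var_f = st$var_f,
                 offset_f = compute_offset(cv))
    }))
    per <- per[order(per$frequency), , drop = FALSE]
    rownames(per) <- NULL
  }
  pool1 <- function(x) if (sum(!is.na(x)) >= min_defined) mean(x, na.rm = TRUE)
                       else NA_real_
  out <- list(asl = pool1(per$asl_f), var = pool1(per$var_f),
              offset_norm = pool1(per$offset_f))
  out$incomplete <- anyNA(unlist(out[c("asl", "var", "offset_norm")]))
  out$n_defined <- c(asl = sum(!is.na(per$asl_f)),
                     var = sum(!is.na(per$var_f)),
                     offset = sum(!is.na(per$offset_f)))
  out$per_frequency <- per
  out
}

#' Per-cell input-output features from a cell record
#'
#' Builds one curve per recorded sinusoid frequency and pools.
#' @param record a [cell_record()] with `sine_family` sweeps.
#' @return as [pool_features()].
#' @export
cell_io_features <- function(record) {
  sine <- sweeps_of_kind(record, "sine_family")
  if (!length(sine)) stopf("cell %s: no sine_family sweeps", record$cell_id)
  freqs <- sort(unique(vapply(sine, function(s) s$protocol$frequency,
                              numeric(1))))
  curves <- lapply(freqs, function(f)
    build_io_curve(sweeps_of_kind(record, "sine_family", f)))
  pool_features(curves)
}
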