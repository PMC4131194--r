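# Stimulation protocol descriptors and the named constants of the recording
# and analysis conventions. All thresholds that gate analysis decisions are
# surfaced here as documented constants.

#' Analysis constants
#'
#' Named constants used throughout the pipeline, with units:
#' \describe{
#'   \item{SINE_FREQUENCIES_HZ}{admissible sinusoid frequencies: 5, 10, 20, 40,
#'     60, 80 Hz.}
#'   \item{SINE_AMP_STEP_PA}{sinusoid peak-amplitude grid step, 50 pA,
#'     starting from a holding level of 0 pA.}
#'   \item{SINE_DURATION_MS}{sinusoid stimulus duration, 1000 ms.}
#'   \item{SQUARE_AMP_STEP_PA}{square-family amplitude step, 20 pA.}
#'   \item{SPIKE_DVDT_CRITERION}{spike criterion on the low-pass filtered
#'     derivative, 20 mV/ms.}
#'   \item{SPIKE_FILTER_KHZ}{post hoc low-pass cutoff for spike detection,
#'     4 kHz.}
#'   \item{RMP_DRIFT_MAX_MV}{maximum tolerated resting-potential drift, 4 mV.}
#'   \item{SEMILUNAR_RIN_MOHM}{input-resistance floor below which a cell is
#'     excluded as a semilunar granule cell, 90 MOhm.}
#'   \item{LABELED_AGE_RANGE_DAYS}{admissible postmitotic age for birth-dated
#'     cells, 21-72 days.}
#' }
#' @name gcio-constants
#' @export SINE_FREQUENCIES_HZ SINE_AMP_STEP_PA SINE_DURATION_MS
#'   SQUARE_AMP_STEP_PA SPIKE_DVDT_CRITERION SPIKE_FILTER_KHZ RMP_DRIFT_MAX_MV
#'   SEMILUNAR_RIN_MOHM LABELED_AGE_RANGE_DAYS
NULL

SINE_FREQUENCIES_HZ <- c(5, 10, 20, 40, 60, 80)
SINE_AMP_STEP_PA <- 50
SINE_DURATION_MS <- 1000
SQUARE_AMP_STEP_PA <- 20
SPIKE_DVDT_CRITERION <- 20
SPIKE_FILTER_KHZ <- 4
RMP_DRIFT_MAX_MV <- 4
SEMILUNAR_RIN_MOHM <- 90
LABELED_AGE_RANGE_DAYS <- c(21L, 72L)

PROTOCOL_KINDS <- c("hyperpol_step", "square_family", "sine_family",
                    "vc_step", "monitor_step")

#' Create a stimulation protocol descriptor
#'
#' @param kind one of `"hyperpol_step"` (small negative current step),
#'   `"square_family"` (1 s square steps on a 20 pA grid), `"sine_family"`
#'   (1 s sinusoid, 50 pA peak-amplitude grid, frequencies 5/10/20/40/60/80
#'   Hz), `"vc_step"` (voltage-clamp step, amplitude in mV), `"monitor_step"`
#'   (brief monitoring step).
#' @param amplitude step or peak amplitude; pA for current-clamp kinds, mV for
#'   `vc_step`.
#' @param frequency sinusoid frequency in Hz; required for `sine_family`,
#'   must lie on the admissible grid.
#' @param duration_ms stimulus duration in ms (sinusoids are fixed at 1000 ms).
#' @param onset_ms stimulus onset relative to sweep start, ms. The pre-onset
#'   segment is the baseline.
#' @param holding holding level (pA, or mV for `vc_step`).
#' @return a `gc_protocol` list.
#' @export
protocol_descriptor <- function(kind, amplitude, frequency = NULL,
                                duration_ms = NULL, onset_ms = 100,
                                holding = 0) {
  kind <- match.arg(kind, PROTOCOL_KINDS)
  if (is.null(duration_ms)) {
    duration_ms <- switch(kind,
      hyperpol_step = 400, square_family = 1000, sine_family = SINE_DURATION_MS,
      vc_step = 100, monitor_step = 50)
  }
  if (kind == "sine_family") {
    if (is.null(frequency) || !(frequency %in% SINE_FREQUENCIES_HZ))
      stopf("frequency not in protocol grid (%s Hz): got %s",
            paste(SINE_FREQUENCIES_HZ, collapse = "/"),
            deparse(frequency))
    if (duration_ms != SINE_DURATION_MS)
      stopf("sine_family duration must be %d ms", SINE_DURATION_MS)
    if (amplitude <= 0 || amplitude %% SINE_AMP_STEP_PA != 0)
      stopf("sine amplitude must be a positive multiple of %d pA, got %s",
            SINE_AMP_STEP_PA, format(amplitude))
  } else {
    frequency <- NULL
  }
  if (kind == "square_family" && amplitude %% SQUARE_AMP_STEP_PA != 0)
    stopf("square_family amplitude must lie on the %d pA grid, got %s",
          SQUARE_AMP_STEP_PA, format(amplitude))
  if (!is.numeric(amplitude) || length(amplitude) != 1L)
    stopf("amplitude must be a single number")
  if (onset_ms < 0 || duration_ms <= 0) stopf("invalid protocol timing")
  structure(list(kind = kind, amplitude = as.numeric(amplitude),
                 frequency = if (is.null(frequency)) NULL else as.numeric(frequency),
                 duration_ms = as.numeric(duration_ms),
                 onset_ms = as.numeric(onset_ms),
                 holding = as.numeric(holding)),
            class = "gc_protocol")
}

is_protocol <- function(x) inherits(x, "gc_protocol")

#' @export
print.gc_protocol <- function(x, ...) {
  cat(sprintf("<protocol %s: %g %s%s, %g ms from %g ms, holding %g>\n",
              x$kind, x$amplitude, if (x$kind == "vc_step") "mV" else "pA",
              if (!is.null(x$frequency)) sprintf(" @ %g Hz", x$frequency) else "",
              x$duration_ms, x$onset_ms, x$holding))
  invisible(x)
}
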