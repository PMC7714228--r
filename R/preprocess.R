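# Envelope preprocessing: rectify + zero-lag lowpass -> decimate -> remove
# rest -> pool across trials -> per-channel unit-variance normalization.
# Stage order is fixed; pool_movements() expects an already nonnegative
# envelope signal.

#' Rectify and lowpass-filter an EMG recording into its envelope
#'
#' Applies a zero-lag (forward-backward, [signal::filtfilt()]) Butterworth
#' lowpass to the rectified signal of every channel. The forward-backward pass
#' doubles the effective magnitude-response order and cancels phase lag.
#' Undershoot from filter ringing is clipped to zero so the envelope stays
#' nonnegative.
#'
#' @param recording An [emg_recording()].
#' @param cutoff Lowpass cutoff in Hz (default 3).
#' @param order Butterworth design order (default 4; effective order 8 after
#'   the forward-backward pass).
#' @return An `emg_recording` holding the envelope; labels unchanged.
#' @export
envelope <- function(recording, cutoff = 3, order = 4) {
  stopifnot(inherits(recording, "emg_recording"))
  stopifnot_scalar_number(cutoff, "cutoff")
  if (recording$sampling_rate <= 2 * cutoff) {
    stop("sampling rate must exceed twice the filter cutoff", call. = FALSE)
  }
  if (any(!is.finite(recording$signal))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  if (nrow(recording$signal) < 3 * order) {
    stop("signal too short for the requested filter order", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (recording$sampling_rate / 2), type = "low")
  env <- apply(abs(recording$signal), 2L, function(x) {
    pmax(signal::filtfilt(bf, x), 0)
  })
  out <- recording
  out$signal <- matrix(env, nrow = nrow(recording$signal))
  out
}

#' Decimate a recording to a lower sampling rate
#'
#' Plain decimation: keeps every (rate ratio)-th sample of the signal and of
#' both label tracks, starting at the first sample. Intended for envelope
#' signals whose bandwidth (3 Hz by default upstream) is far below the target
#' Nyquist rate, so no anti-alias stage is applied.
#'
#' @param recording An [emg_recording()].
#' @param target_rate Target rate in Hz; must divide the sampling rate.
#' @return The decimated `emg_recording`.
#' @export
downsample <- function(recording, target_rate = 100) {
  stopifnot(inherits(recording, "emg_recording"))
  stopifnot_scalar_number(target_rate, "target_rate")
  ratio <- recording$sampling_rate / target_rate
  if (!isTRUE(all.equal(ratio, round(ratio))) || ratio < 1) {
    stop("sampling rate must be an integer multiple of `target_rate`", call. = FALSE)
  }
  keep <- seq(1L, nrow(recording$signal), by = as.integer(round(ratio)))
  out <- recording
  out$signal <- recording$signal[keep, , drop = FALSE]
  out$movement_label <- recording$movement_label[keep]
  out$repetition_label <- recording$repetition_label[keep]
  out$sampling_rate <- target_rate
  out
}

#' Pool non-rest envelope samples and normalize each channel to unit variance
#'
#' Drops every rest-labeled sample, restricts channels to `keep_roles` (BB/TB
#' are never eligible: they record arm muscles uninvolved in hand/wrist
#' movements), concatenates the remaining samples across trials in temporal
#' order, and divides each channel by its own standard deviation computed over
#' the pooled samples. No centering is applied: the matrix must stay
#' nonnegative for NMF.
#'
#' @param recording An envelope `emg_recording` (nonnegative signal).
#' @param keep_roles Channel roles to keep (default: all forearm roles present).
#' @return A `pooled_envelope`: list with `E` (channels x samples, unit
#'   variance per channel), `movement_of_sample`, `channel_roles`,
#'   `channel_scale` (the divisors), `envelope_rate`.
#' @export
pool_movements <- function(recording, keep_roles = NULL) {
  stopifnot(inherits(recording, "emg_recording"))
  if (any(recording$signal < 0)) {
    stop("`recording` must hold a nonnegative envelope; run envelope() first",
         call. = FALSE)
  }
  keep_roles <- keep_roles %||%
    intersect(recording$channel_roles, electrode_roles("forearm10"))
  if (any(keep_roles %in% c("BB", "TB"))) {
    stop("BB and TB channels are excluded from synergy analysis", call. = FALSE)
  }
  sel <- which(recording$channel_roles %in% keep_roles)
  if (length(sel) == 0L) {
    stop("none of `keep_roles` are present in the recording", call. = FALSE)
  }
  cols <- which(recording$movement_label > 0L)
  if (length(cols) < 2L) {
    stop("no (or too few) non-rest samples to pool", call. = FALSE)
  }
  E <- t(recording$signal[cols, sel, drop = FALSE])
  roles <- recording$channel_roles[sel]
  scale <- apply(E, 1L, sd)
  if (any(scale == 0)) {
    stop(sprintf("channel %s has zero variance over pooled samples",
                 paste(roles[scale == 0], collapse = ", ")), call. = FALSE)
  }
  E <- E / scale
  rownames(E) <- roles
  structure(
    list(E = E,
         movement_of_sample = recording$movement_label[cols],
         channel_roles = roles,
         channel_scale = setNames(scale, roles),
         envelope_rate = recording$sampling_rate),
    class = "pooled_envelope"
  )
}

#' @export
print.pooled_envelope <- function(x, ...) {
  cat(sprintf("<pooled_envelope> %d channels x %d samples @ %g Hz\n",
              nrow(x$E), ncol(x$E), x$envelope_rate))
  cat(sprintf("  channels: %s\n", paste(x$channel_roles, collapse = ", ")))
  cat(sprintf("  movements: %d distinct\n", length(unique(x$movement_of_sample))))
  invisible(x)
}

#' @export
as.data.frame.pooled_envelope <- function(x, ...) {
  df <- as.data.frame(t(x$E))
  names(df) <- x$channel_roles
  cbind(data.frame(sample = seq_len(ncol(x$E)), movement = x$movement_of_sample), df)
}

#' @method as_tibble pooled_envelope
#' @export
as_tibble.pooled_envelope <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}
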