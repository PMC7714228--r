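# NinaPro-style recording container: a samples x channels signal matrix with
# per-sample movement and repetition labels and a role for every channel.

#' Channel roles for the standard electrode montages
#'
#' The acquisition montage places eight electrodes evenly spaced around the
#' forearm (`RING1`..`RING8`), one each over the flexor and extensor digitorum
#' superficialis (`FDS`, `EDS`), and one each over biceps and triceps (`BB`,
#' `TB`). `BB`/`TB` record arm muscles not involved in hand/wrist movements
#' and are excluded from synergy analysis.
#'
#' @param set One of `"ring8"` (eight forearm ring electrodes),
#'   `"forearm10"` (ring plus FDS/EDS), or `"all_available"` (all twelve).
#' @return Character vector of role names.
#' @export
#' @examples
#' electrode_roles("ring8")
electrode_roles <- function(set = c("forearm10", "ring8", "all_available")) {
  set <- match.arg(set)
  ring <- paste0("RING", 1:8)
  switch(set,
    ring8 = ring,
    forearm10 = c(ring, "FDS", "EDS"),
    all_available = c(ring, "FDS", "EDS", "BB", "TB")
  )
}

default_channel_roles <- function(n_channels) {
  all_roles <- electrode_roles("all_available")
  if (n_channels > length(all_roles)) {
    stop(sprintf("no default channel map for %d channels", n_channels), call. = FALSE)
  }
  all_roles[seq_len(n_channels)]
}

#' Construct a multichannel EMG recording
#'
#' @param signal Numeric matrix, samples x channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param movement_label Integer per sample; 0 marks rest.
#' @param repetition_label Integer per sample; 0 marks rest.
#' @param channel_roles Character vector of roles, one per channel (see
#'   [electrode_roles()]). Defaults to the standard column order: ring
#'   electrodes first, then FDS/EDS, then BB/TB.
#' @param subject_id,exercise_id Identifier strings.
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(signal, sampling_rate, movement_label,
                          repetition_label = NULL,
                          channel_roles = NULL,
                          subject_id = "S1", exercise_id = "B") {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (samples x channels)", call. = FALSE)
  }
  if (nrow(signal) == 0L) stop("recording has 0 samples", call. = FALSE)
  stopifnot_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive", call. = FALSE)
  movement_label <- as.integer(round(as.numeric(movement_label)))
  if (is.null(repetition_label)) repetition_label <- rep(0L, nrow(signal))
  repetition_label <- as.integer(round(as.numeric(repetition_label)))
  if (length(movement_label) != nrow(signal) ||
      length(repetition_label) != nrow(signal)) {
    stop("label length does not match the number of signal samples", call. = FALSE)
  }
  if (any(movement_label < 0L)) {
    stop("movement labels must be nonnegative integers", call. = FALSE)
  }
  channel_roles <- channel_roles %||% default_channel_roles(ncol(signal))
  if (length(channel_roles) != ncol(signal)) {
    stop("`channel_roles` length must equal the number of channels", call. = FALSE)
  }
  structure(
    list(signal = unname(signal), sampling_rate = as.numeric(sampling_rate),
         movement_label = movement_label, repetition_label = repetition_label,
         channel_roles = as.character(channel_roles),
         subject_id = as.character(subject_id),
         exercise_id = as.character(exercise_id)),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s, exercise %s\n", x$subject_id, x$exercise_id))
  cat(sprintf("  %d samples x %d channels @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate))
  cat(sprintf("  channels: %s\n", paste(x$channel_roles, collapse = ", ")))
  mv <- sort(unique(x$movement_label[x$movement_label > 0L]))
  cat(sprintf("  movements: %d distinct (%s)\n", length(mv),
              paste(head(mv, 10), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.emg_recording <- function(x, ...) {
  sig <- as.data.frame(x$signal)
  names(sig) <- x$channel_roles
  cbind(
    data.frame(sample = seq_len(nrow(x$signal)),
               time_s = (seq_len(nrow(x$signal)) - 1L) / x$sampling_rate,
               movement = x$movement_label,
               repetition = x$repetition_label),
    sig
  )
}

#' Tidy a recording into a long tibble (for CSV export or plotting)
#'
#' @param x An `emg_recording`.
#' @param ... Unused.
#' @return A tibble with one row per sample and one column per channel role.
#' @method as_tibble emg_recording
#' @export
as_tibble.emg_recording <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Read a NinaPro-style .mat recording
#'
#' Expects the public NinaPro container layout: an `emg` array (samples x
#' channels) plus label vectors `stimulus`/`repetition` and, when present,
#' their refined movie-aligned counterparts `restimulus`/`rerepetition`,
#' which take precedence. A `frequency` scalar overrides `sampling_rate`.
#'
#' @param path Path to a MAT v5 file.
#' @param subject_id Subject identifier to attach.
#' @param sampling_rate Fallback sampling rate (Hz) when the file carries none.
#' @param channel_roles Optional role vector; defaults to the standard column
#'   order (see [electrode_roles()]).
#' @param prefer_refined Use refined (`re`-prefixed) label vectors when both
#'   raw and refined are present (the dataset documentation designates the
#'   refined labels as corrections; default `TRUE`).
#' @param exercise_id Exercise identifier; read from the file when present.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, subject_id = "S1", sampling_rate = 2000,
                           channel_roles = NULL, prefer_refined = TRUE,
                           exercise_id = "B") {
  vars <- read_mat5(path)
  if (is.null(vars$emg)) {
    stop("format error: required array 'emg' is missing", call. = FALSE)
  }
  pick <- function(refined, raw) {
    if (prefer_refined && !is.null(vars[[refined]])) return(vars[[refined]])
    vars[[raw]] %||% vars[[refined]]
  }
  mv <- pick("restimulus", "stimulus")
  if (is.null(mv)) {
    stop("format error: required array 'stimulus' (or 'restimulus') is missing",
         call. = FALSE)
  }
  rp <- pick("rerepetition", "repetition")
  mv <- as.vector(mv)
  rp <- if (is.null(rp)) rep(0, nrow(vars$emg)) else as.vector(rp)
  if (length(mv) != nrow(vars$emg) || length(rp) != nrow(vars$emg)) {
    stop("integrity error: label vector length does not match the EMG signal",
         call. = FALSE)
  }
  fs <- if (!is.null(vars$frequency)) as.vector(vars$frequency)[1] else sampling_rate
  ex <- if (!is.null(vars$exercise)) as.character(as.vector(vars$exercise)[1]) else exercise_id
  emg_recording(vars$emg, fs, mv, rp, channel_roles,
                subject_id = subject_id, exercise_id = ex)
}

#' Write a recording as a NinaPro-style .mat fixture
#'
#' Inverse of [read_recording()]: `read_recording(write_fixture(x, p))`
#' reproduces the signal to full floating precision and the labels exactly.
#' Both raw and refined label vectors are written (identical).
#'
#' @param recording An [emg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(recording, path) {
  if (!inherits(recording, "emg_recording")) {
    stop("`recording` must be an emg_recording", call. = FALSE)
  }
  lab <- function(v) matrix(as.double(v), ncol = 1L)
  write_mat5(list(
    emg = recording$signal,
    stimulus = lab(recording$movement_label),
    restimulus = lab(recording$movement_label),
    repetition = lab(recording$repetition_label),
    rerepetition = lab(recording$repetition_label),
    frequency = matrix(recording$sampling_rate)
  ), path)
}

#' Read a channel-map configuration file
#'
#' Plain-text `column=ROLE` lines, e.g. `1=RING1`. Blank lines and `#`
#' comments are ignored.
#'
#' @param path Path to the config file.
#' @return Character vector of roles ordered by column index.
#' @export
read_channel_map <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop(sprintf("malformed channel-map line: '%s'", lines[bad][1]), call. = FALSE)
  }
  idx <- as.integer(trimws(vapply(parts, `[[`, "", 1L)))
  role <- trimws(vapply(parts, `[[`, "", 2L))
  if (anyNA(idx) || anyDuplicated(idx)) {
    stop("channel-map column indices must be unique integers", call. = FALSE)
  }
  role[order(idx)]
}
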