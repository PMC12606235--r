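#' Downsample a recording to 250 kHz
#'
#' Recordings digitized above 250 kHz are brought to exactly 250 kHz so the
#' digitization rate cannot leak into acoustic measures. Decimation uses a
#' zero-phase FIR low-pass (order-128 Hamming `fir1` at the target Nyquist,
#' applied forward-backward), attenuating energy above 125 kHz by far more
#' than 60 dB before sample dropping.
#'
#' @param w a `waveform` with `rate >= 250000` and `rate` an integer multiple
#'   of 250000 (the supported hardware rates are 250 and 500 kHz).
#' @return A `waveform` at exactly 250000 Hz.
#' @export
resample_to_250k <- function(w) {
  w <- as_waveform(w)
  target <- 250000
  if (w$rate < target)
    stop("input rate is below 250 kHz; upsampling is out of contract")
  if (w$rate == target) return(w)
  q <- w$rate / target
  if (abs(q - round(q)) > 1e-9)
    stop("rate must be an integer multiple of 250 kHz")
  q <- as.integer(round(q))
  h <- signal::fir1(128, 1 / q)
  y <- signal::filtfilt(h, w$samples)
  waveform(y[seq(1L, length(y), by = q)], target)
}

#' Detection parameters
#'
#' @param envelope_ms RMS-envelope window length (ms).
#' @param threshold_k segments require envelope above
#'   `median(env) + threshold_k * mad(env)` (robust noise floor).
#' @param merge_gap_ms segments separated by less than this are merged.
#' @param spectral_min_khz band edge for the spectral-density criterion.
#' @param spectral_frac minimum fraction of segment spectral energy that must
#'   lie above `spectral_min_khz`.
#' @return List of class `detect_params`.
#' @export
detect_params <- function(envelope_ms = 0.5, threshold_k = 5,
                          merge_gap_ms = 2, spectral_min_khz = 10,
                          spectral_frac = 0.7) {
  structure(list(envelope_ms = envelope_ms, threshold_k = threshold_k,
                 merge_gap_ms = merge_gap_ms,
                 spectral_min_khz = spectral_min_khz,
                 spectral_frac = spectral_frac), class = "detect_params")
}

# Sliding RMS envelope (centred window of `n` samples).
rms_envelope <- function(x, n) {
  n <- max(as.integer(n), 1L)
  e2 <- stats::filter(x^2, rep(1 / n, n), sides = 2)
  e2[is.na(e2)] <- 0
  sqrt(pmax(as.numeric(e2), 0))
}

#' Detect calls in a recording
#'
#' Two-criterion segmentation: (a) the sliding RMS amplitude envelope must
#' exceed a robust noise floor (`median + k * MAD` of the envelope), and (b)
#' the candidate segment's spectral energy must be concentrated above the
#' ultrasonic band edge (fraction above `spectral_min_khz` at least
#' `spectral_frac`), which rejects low-frequency transients. Candidate runs
#' separated by gaps shorter than `merge_gap_ms` are merged. Segments are
#' returned sorted and non-overlapping.
#'
#' @param w a `waveform` at 250 kHz.
#' @param params a [detect_params()].
#' @param source recording identifier stored with each segment.
#' @return Data frame of class `call_segments`: `source`, `onset_s`,
#'   `offset_s`, `duration_ms`.
#' @export
detect_calls <- function(w, params = detect_params(), source = "recording") {
  w <- as_waveform(w)
  if (w$rate != 250000) stop("detect_calls expects a 250 kHz waveform")
  empty <- data.frame(source = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_ms = numeric(0))
  class(empty) <- c("call_segments", "data.frame")
  if (length(w$samples) == 0L) return(empty)
  nwin <- round(params$envelope_ms / 1000 * w$rate)
  env <- rms_envelope(w$samples, nwin)
  floor_ <- median(env) + params$threshold_k * mad(env)
  above <- env > floor_
  runs <- logical_runs(above)
  if (nrow(runs) == 0L) return(empty)
  # merge close runs
  gap <- round(params$merge_gap_ms / 1000 * w$rate)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) for (k in 2:nrow(runs)) {
    if (runs[k, 1] - merged[nrow(merged), 2] <= gap)
      merged[nrow(merged), 2] <- runs[k, 2]
    else merged <- rbind(merged, runs[k, , drop = FALSE])
  }
  # spectral-density criterion per candidate segment
  keep <- apply(merged, 1, function(r) {
    seg <- w$samples[r[1]:r[2]]
    if (length(seg) < 16L) return(FALSE)
    spec <- Mod(fft(seg))[seq_len(floor(length(seg) / 2))]^2
    f_khz <- (seq_along(spec) - 1) / length(seg) * w$rate / 1000
    sum(spec[f_khz >= params$spectral_min_khz]) / sum(spec) >=
      params$spectral_frac
  })
  merged <- merged[keep, , drop = FALSE]
  out <- data.frame(source = rep(source, nrow(merged)),
                    onset_s = (merged[, 1] - 1) / w$rate,
                    offset_s = merged[, 2] / w$rate)
  out$duration_ms <- (out$offset_s - out$onset_s) * 1000
  class(out) <- c("call_segments", "data.frame")
  out
}

# Start/end indices of TRUE runs in a logical vector.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Measure per-segment peak frequency
#'
#' Peak frequency (kHz) of each detected segment's power spectrum, used by
#' the low-frequency inclusion filter.
#'
#' @param w source `waveform`.
#' @param segments a `call_segments` table from [detect_calls()].
#' @return `segments` with a `peak_khz` column added.
#' @export
measure_peaks <- function(w, segments) {
  w <- as_waveform(w)
  segments$peak_khz <- vapply(seq_len(nrow(segments)), function(k) {
    i0 <- round(segments$onset_s[k] * w$rate) + 1L
    i1 <- round(segments$offset_s[k] * w$rate)
    seg <- w$samples[i0:i1]
    spec <- Mod(fft(seg))[seq_len(max(floor(length(seg) / 2), 1L))]^2
    (which.max(spec) - 1) / length(seg) * w$rate / 1000
  }, numeric(1))
  segments
}

#' Apply the duration and peak-frequency call filters
#'
#' Keeps exactly the segments with duration in `[3, 50]` ms (boundaries
#' inclusive) and peak frequency at or above 10 kHz (calls with peak
#' frequency strictly below 10 kHz are removed). Order-preserving and
#' idempotent.
#'
#' @param segments a `call_segments` table with a `peak_khz` column (see
#'   [measure_peaks()]).
#' @param min_ms,max_ms duration bounds (ms).
#' @param min_peak_khz peak-frequency bound (kHz).
#' @return The filtered table.
#' @export
filter_calls <- function(segments, min_ms = 3, max_ms = 50, min_peak_khz = 10) {
  if (is.null(segments$peak_khz))
    stop("segments need a `peak_khz` column; run measure_peaks() first")
  keep <- segments$duration_ms >= min_ms & segments$duration_ms <= max_ms &
    segments$peak_khz >= min_peak_khz
  segments[keep, , drop = FALSE]
}

#' Remove clipped calls
#'
#' After full-scale normalization of the source recording (dividing by its
#' maximum absolute amplitude), removes segments whose maximum relative
#' amplitude is strictly greater than 0.99. A segment at exactly 0.99 is
#' kept.
#'
#' @param segments a `call_segments` table.
#' @param w the source `waveform`.
#' @param limit relative-amplitude limit (default 0.99).
#' @return The filtered table, with a `rel_amp` column added.
#' @export
remove_clipped <- function(segments, w, limit = 0.99) {
  w <- as_waveform(w)
  peak <- max(abs(w$samples))
  if (peak == 0) return(segments)
  rel <- vapply(seq_len(nrow(segments)), function(k) {
    i0 <- round(segments$onset_s[k] * w$rate) + 1L
    i1 <- round(segments$offset_s[k] * w$rate)
    max(abs(w$samples[i0:i1])) / peak
  }, numeric(1))
  segments$rel_amp <- rel
  segments[rel <= limit, , drop = FALSE]
}

#' Extract segment waveforms
#'
#' Slices a recording into per-call `call_segment` objects carrying samples,
#' rate, times and provenance, ready for feature extraction.
#'
#' @param w source `waveform`.
#' @param segments a `call_segments` table.
#' @return List of `call_segment` objects.
#' @export
segment_waveform <- function(w, segments) {
  w <- as_waveform(w)
  lapply(seq_len(nrow(segments)), function(k) {
    i0 <- round(segments$onset_s[k] * w$rate) + 1L
    i1 <- round(segments$offset_s[k] * w$rate)
    call_segment(w$samples[i0:i1], w$rate,
                 onset_s = segments$onset_s[k],
                 offset_s = segments$offset_s[k],
                 source = as.character(segments$source[k]))
  })
}

#' Construct a call segment
#'
#' @param samples amplitude slice.
#' @param rate sampling rate (Hz).
#' @param onset_s,offset_s position in the source recording (seconds).
#' @param source recording identifier.
#' @return Object of class `call_segment`.
#' @export
call_segment <- function(samples, rate, onset_s = 0,
                         offset_s = onset_s + length(samples) / rate,
                         source = "segment") {
  if (offset_s <= onset_s) stop("offset_s must exceed onset_s")
  structure(list(samples = as.numeric(samples), rate = rate,
                 onset_s = onset_s, offset_s = offset_s, source = source),
            class = "call_segment")
}
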