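#' Compute a short-time magnitude spectrogram of a call
#'
#' Hann-windowed STFT via [signal::specgram()]. The default 256-sample window
#' (about 1 ms at 250 kHz) with 75% overlap guarantees at least three frames
#' for the shortest admissible (3 ms) call.
#'
#' @param seg a `call_segment` at 250 kHz.
#' @param window window length in samples.
#' @param overlap overlap fraction in `[0, 1)`.
#' @return List of class `call_spectrogram`: `mag` (frequency bins x time
#'   frames), `freq_khz`, `time_ms` (frame centres from segment onset),
#'   `window`, `overlap`.
#' @export
compute_spectrogram <- function(seg, window = 256, overlap = 0.75) {
  x <- seg$samples
  if (length(x) < window)
    stop("segment shorter than one analysis window")
  step <- max(round(window * (1 - overlap)), 1L)
  sp <- signal::specgram(x, n = window, Fs = seg$rate,
                         window = signal::hanning(window),
                         overlap = window - step)
  mag <- abs(sp$S)
  nt <- ncol(mag)
  centres <- (seq_len(nt) - 1L) * step + window / 2
  structure(list(mag = mag, freq_khz = as.numeric(sp$f) / 1000,
                 time_ms = centres / seg$rate * 1000,
                 window = window, overlap = overlap),
            class = "call_spectrogram")
}

#' Names of the 35 per-call acoustic features
#'
#' The first 27 are spectro-temporal measures (durations and envelope-energy
#' time quantiles; aggregated-spectrum statistics; entropies and flatness;
#' peak and dominant-frequency contour statistics). The last 8 are slope
#' measures of the tracked fundamental contour. Times are ms, frequencies
#' kHz, slopes kHz/ms.
#'
#' @return Character vector of length 35 with a `group` attribute
#'   (`"spectrotemporal"`/`"slope"`).
#' @export
feature_names <- function() {
  st <- c("duration", "time.Q25", "time.median", "time.Q75", "time.IQR",
          "meanfreq", "freq.sd", "freq.median", "freq.Q25", "freq.Q75",
          "freq.IQR", "skewness", "kurtosis", "sp.ent", "time.ent",
          "entropy", "sfm", "peakf", "meanpeakf", "meandom", "mindom",
          "maxdom", "startdom", "enddom", "dfrange", "dfslope", "modindx")
  sl <- c("maxslope", "minslope", "absminslope", "meanslope",
          "npos", "nneg", "nturns", "nsegments")
  structure(c(st, sl),
            group = c(rep("spectrotemporal", length(st)), rep("slope", length(sl))))
}

#' Spectro-temporal features of one call (27 measures)
#'
#' Frequency statistics come from the band-limited aggregated power spectrum
#' (mean over frames); time quantiles from cumulative envelope energy;
#' dominant-frequency statistics from the per-frame spectral argmax over
#' frames holding at least 5% of the maximum frame energy. The modulation
#' index is the cumulative absolute dominant-frequency change divided by the
#' dominant range (0 for a flat contour); the dominant slope is
#' (end - start dominant) / duration.
#'
#' @param seg a `call_segment`.
#' @param spec its `call_spectrogram` (computed if omitted).
#' @param band analysis band in kHz for frequency statistics.
#' @return Named numeric vector of 27 measures.
#' @export
spectro_temporal_features <- function(seg, spec = NULL, band = c(10, 125)) {
  if (is.null(spec)) spec <- compute_spectrogram(seg)
  if (ncol(spec$mag) < 2L)
    stop("degenerate spectrogram: need at least two frames")
  dur_ms <- length(seg$samples) / seg$rate * 1000

  # time quantiles from cumulative envelope energy (ms from onset)
  e <- seg$samples^2
  cum <- cumsum(e) / sum(e)
  tq <- function(q) (which(cum >= q)[1]) / seg$rate * 1000

  inband <- spec$freq_khz >= band[1] & spec$freq_khz <= band[2]
  f <- spec$freq_khz[inband]
  pwr <- spec$mag[inband, , drop = FALSE]^2
  agg <- rowMeans(pwr)
  p <- agg / sum(agg)
  mu <- sum(p * f)
  sdev <- sqrt(sum(p * (f - mu)^2))
  cumf <- cumsum(p)
  fq <- function(q) f[which(cumf >= q)[1]]
  skew <- sum(p * (f - mu)^3) / sdev^3
  kurt <- sum(p * (f - mu)^4) / sdev^4
  sp_ent <- -sum(ifelse(p > 0, p * log(p), 0)) / log(length(p))
  en_t <- colSums(pwr)
  q_t <- en_t / sum(en_t)
  time_ent <- -sum(ifelse(q_t > 0, q_t * log(q_t), 0)) / log(length(q_t))
  aggc <- pmax(agg, max(agg) * 1e-12)
  sfm <- exp(mean(log(aggc))) / mean(aggc)

  # peak frequencies: aggregated peak, and mean of full-band per-frame peaks
  peakf <- f[which.max(agg)]
  full_f <- spec$freq_khz
  pk_t <- full_f[apply(spec$mag, 2, which.max)]
  meanpeakf <- mean(pk_t)

  # dominant-frequency contour over energetic frames
  keep <- en_t >= 0.05 * max(en_t)
  dom <- f[apply(pwr[, keep, drop = FALSE], 2, which.max)]
  dfrange <- max(dom) - min(dom)
  dfslope <- (dom[length(dom)] - dom[1]) / dur_ms
  modindx <- if (dfrange > 0) sum(abs(diff(dom))) / dfrange else 0

  q25 <- tq(0.25); q50 <- tq(0.5); q75 <- tq(0.75)
  c(duration = dur_ms, time.Q25 = q25, time.median = q50, time.Q75 = q75,
    time.IQR = q75 - q25, meanfreq = mu, freq.sd = sdev,
    freq.median = fq(0.5), freq.Q25 = fq(0.25), freq.Q75 = fq(0.75),
    freq.IQR = fq(0.75) - fq(0.25), skewness = skew, kurtosis = kurt,
    sp.ent = sp_ent, time.ent = time_ent, entropy = sp_ent * time_ent,
    sfm = sfm, peakf = peakf, meanpeakf = meanpeakf, meandom = mean(dom),
    mindom = min(dom), maxdom = max(dom), startdom = dom[1],
    enddom = dom[length(dom)], dfrange = dfrange, dfslope = dfslope,
    modindx = modindx)
}

#' Track the fundamental frequency contour of a call
#'
#' Dominant-bin tracking with a continuity constraint, suited to the
#' near-tonal FM sweeps of contact calls. A frame is voiced when its spectral
#' peak stands out against the frame's mean in-band magnitude (tonality
#' ratio); tracking starts at the most tonal frame and constrains each
#' neighbouring frame's search to within `max_jump_khz` of the last defined
#' value. Unvoiced frames are `NA`.
#'
#' @param seg a `call_segment`.
#' @param spec optional precomputed `call_spectrogram`.
#' @param band analysis band (kHz).
#' @param tonality_min minimum peak-to-mean magnitude ratio for voicing.
#' @param max_jump_khz continuity limit between adjacent voiced frames.
#' @param min_energy_frac frames below this fraction of the maximum frame
#'   RMS are unvoiced regardless of tonality.
#' @return Data frame of class `frequency_contour`: `time_ms`, `f_khz`
#'   (NA where unvoiced).
#' @export
fundamental_contour <- function(seg, spec = NULL, band = c(10, 125),
                                tonality_min = 4, max_jump_khz = 8,
                                min_energy_frac = 0.1) {
  if (is.null(spec)) spec <- compute_spectrogram(seg)
  inband <- spec$freq_khz >= band[1] & spec$freq_khz <= band[2]
  f <- spec$freq_khz[inband]
  bin_khz <- mean(diff(spec$freq_khz))
  m <- spec$mag[inband, , drop = FALSE]
  nt <- ncol(m)
  tone <- apply(m, 2, function(col) max(col) / mean(col))
  energy <- sqrt(colSums(m^2))
  voiced <- tone >= tonality_min & energy >= min_energy_frac * max(energy)
  # sub-bin refinement: parabolic interpolation of log magnitude at the peak
  refine <- function(col, k) {
    if (k <= 1L || k >= length(col)) return(f[k])
    lm <- log(pmax(col[(k - 1L):(k + 1L)], .Machine$double.xmin))
    den <- lm[1] - 2 * lm[2] + lm[3]
    delta <- if (den < 0) 0.5 * (lm[1] - lm[3]) / den else 0
    f[k] + max(min(delta, 0.5), -0.5) * bin_khz
  }
  out <- rep(NA_real_, nt)
  if (any(voiced)) {
    anchor <- which.max(tone * voiced)
    out[anchor] <- refine(m[, anchor], which.max(m[, anchor]))
    track <- function(idx_seq) {
      prev <- out[anchor]
      for (k in idx_seq) {
        if (!voiced[k]) { prev <- NA; next }
        if (is.na(prev)) {
          out[k] <<- refine(m[, k], which.max(m[, k]))
        } else {
          win <- abs(f - prev) <= max_jump_khz
          if (!any(win)) { prev <- NA; next }
          cand <- which(win)[which.max(m[win, k])]
          out[k] <<- refine(m[, k], cand)
        }
        prev <- out[k]
      }
    }
    if (anchor < nt) track((anchor + 1L):nt)
    if (anchor > 1L) track((anchor - 1L):1L)
  }
  structure(data.frame(time_ms = spec$time_ms, f_khz = out),
            class = c("frequency_contour", "data.frame"))
}

#' Slope measures of a fundamental contour (8 measures)
#'
#' Inter-frame slopes (kHz/ms) are computed within each maximal run of
#' contiguous defined frames and pooled. Reports the maximum, minimum, mean
#' and minimum-absolute slope; the counts of positive and negative slopes
#' exceeding the `negligible` magnitude; the number of turns (sign changes
#' between consecutive non-negligible slopes); and the number of segments
#' (defined runs). With no defined slopes the four slope statistics are 0.
#'
#' @param contour a `frequency_contour`.
#' @param negligible slope magnitude (kHz/ms) below which a slope is ignored
#'   for the count measures.
#' @param absmin `"min_abs"` (default) reports `min(|slope|)`;
#'   `"abs_min"` reports `|min(slope)|`.
#' @return Named numeric vector of 8 measures.
#' @export
slope_measures <- function(contour, negligible = 0.1,
                           absmin = c("min_abs", "abs_min")) {
  absmin <- match.arg(absmin)
  def <- !is.na(contour$f_khz)
  runs <- logical_runs(def)
  nseg <- nrow(runs)
  slopes <- numeric(0)
  turns <- 0L
  if (nseg > 0) for (k in seq_len(nseg)) {
    idx <- runs[k, 1]:runs[k, 2]
    if (length(idx) < 2L) next
    sl <- diff(contour$f_khz[idx]) / diff(contour$time_ms[idx])
    slopes <- c(slopes, sl)
    nn <- sl[abs(sl) > negligible]
    if (length(nn) > 1L) turns <- turns + sum(diff(sign(nn)) != 0)
  }
  if (length(slopes) == 0L) slopes <- 0
  c(maxslope = max(slopes), minslope = min(slopes),
    absminslope = if (absmin == "min_abs") min(abs(slopes)) else abs(min(slopes)),
    meanslope = mean(slopes),
    npos = sum(slopes > negligible), nneg = sum(slopes < -negligible),
    nturns = turns, nsegments = nseg)
}

#' Extract all 35 acoustic features of a call
#'
#' Combines the 27 spectro-temporal measures and the 8 fundamental-contour
#' slope measures into one named vector with stable field order (see
#' [feature_names()]).
#'
#' @param seg a `call_segment` that has passed the call filters.
#' @param band analysis band (kHz).
#' @param window,overlap spectrogram parameters.
#' @return Named numeric vector of exactly 35 finite values.
#' @export
extract_all <- function(seg, band = c(10, 125), window = 256, overlap = 0.75) {
  spec <- compute_spectrogram(seg, window = window, overlap = overlap)
  st <- spectro_temporal_features(seg, spec, band = band)
  contour <- fundamental_contour(seg, spec, band = band)
  sl <- slope_measures(contour)
  out <- c(st, sl)
  stopifnot(identical(names(out), as.character(feature_names())))
  out
}

#' Extract a feature table for a batch of calls
#'
#' @param calls list of `call_segment` objects.
#' @param bat_id caller identifier(s), recycled across calls.
#' @param ... passed to [extract_all()].
#' @return Data frame: `bat_id`, `source`, `call`, then the 35 feature
#'   columns in fixed order.
#' @export
extract_features <- function(calls, bat_id = "unknown", ...) {
  feats <- t(vapply(calls, extract_all, numeric(35), ...))
  data.frame(bat_id = rep_len(bat_id, length(calls)),
             source = vapply(calls, function(s) s$source, character(1)),
             call = seq_along(calls), feats,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulate a per-bat feature table directly from contour signatures
#'
#' Synthesizes `calls_per_bat` calls for every bat in a profile table and
#' extracts the 35 features of each, bypassing session assembly and
#' detection. This is the fast path used for similarity and convergence
#' analyses on synthetic populations.
#'
#' @param bats bat profile data frame (see [make_population()]).
#' @param calls_per_bat calls to synthesize per bat.
#' @param seed RNG seed.
#' @param noise_db per-call SNR (dB); `Inf` for clean calls.
#' @param ... passed to [extract_all()].
#' @return Feature table as in [extract_features()].
#' @export
simulate_feature_table <- function(bats, calls_per_bat = 120, seed = 1L,
                                   noise_db = 30, ...) {
  tabs <- lapply(seq_len(nrow(bats)), function(i) {
    calls <- lapply(seq_len(calls_per_bat), function(k) {
      w <- synthesize_call(bats[i, ], rate = 250000, noise_db = noise_db,
                           seed = derive_seed(seed, paste(bats$bat_id[i], k)))
      call_segment(w$samples, w$rate, source = bats$bat_id[i])
    })
    extract_features(calls, bat_id = bats$bat_id[i], ...)
  })
  do.call(rbind, tabs)
}
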