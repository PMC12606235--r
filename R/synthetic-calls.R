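#' Synthesize one frequency-modulated contact call
#'
#' Renders a downward FM sweep whose instantaneous frequency follows the
#' exponential-decay contour
#' `f(t) = f_end + (f_start - f_end) * exp(-curvature * t / T)`,
#' with per-call jitter drawn around the bat's contour-parameter means. The
#' sweep is shaped by a raised-cosine onset/offset ramp (10% of duration each
#' side) and optionally embedded in white Gaussian noise at a given SNR.
#'
#' @param profile a one-row bat profile (data frame or list) with fields
#'   `f_start`, `f_end` (kHz), `duration_ms`, `curvature`, optional
#'   `sd_f_start`, `sd_f_end`, `sd_duration_ms`, `sd_curvature` (default 0,
#'   i.e. no jitter) and optional `amplitude` (peak, default 0.3).
#' @param rate sampling rate in Hz; 250000 or 500000.
#' @param noise_db signal-to-noise ratio in dB (RMS signal over RMS noise);
#'   `Inf` for a noise-free call.
#' @param wobble_khz SD of a slow random frequency wobble (a few sinusoidal
#'   components at 100-400 Hz) superimposed on the sweep. Contact calls are
#'   not perfectly monotone; the wobble gives the within-call contour
#'   micro-structure (turns, sign changes) natural within-bat variation.
#'   Set 0 for an exact parametric sweep.
#' @param seed optional RNG seed; the same seed gives a bit-identical call.
#' @return A `waveform`. Attribute `params` holds the jittered contour
#'   parameters actually used.
#' @export
synthesize_call <- function(profile, rate = 250000, noise_db = Inf,
                            wobble_khz = 0.8, seed = NULL) {
  if (!rate %in% c(250000, 500000))
    stop("`rate` must be 250000 or 500000 Hz")
  p <- as.list(profile)
  sdv <- function(nm) if (!is.null(p[[nm]])) p[[nm]] else 0
  amp <- if (!is.null(p$amplitude)) p$amplitude else 0.3
  with_seed(seed, {
    f_end <- max(rnorm(1, p$f_end, sdv("sd_f_end")), 10.5)
    f_start <- max(rnorm(1, p$f_start, sdv("sd_f_start")), f_end + 5)
    dur_ms <- min(max(rnorm(1, p$duration_ms, sdv("sd_duration_ms")), 3), 50)
    curv <- max(rnorm(1, p$curvature, sdv("sd_curvature")), 0.05)
    n <- max(round(dur_ms / 1000 * rate), 2L)
    tt <- seq_len(n) / rate                      # seconds
    f_khz <- f_end + (f_start - f_end) * exp(-curv * tt / (dur_ms / 1000))
    if (wobble_khz > 0) {
      wf <- runif(3, 100, 400)         # wobble component frequencies (Hz)
      wa <- rnorm(3, 0, wobble_khz / sqrt(3))
      wp <- runif(3, 0, 2 * pi)
      f_khz <- f_khz + colSums(wa * sin(outer(2 * pi * wf, tt) + wp))
      f_khz <- pmax(f_khz, 10.5)
    }
    phase <- 2 * pi * cumsum(f_khz * 1000) / rate
    env <- ramp_envelope(n, frac = runif(1, 0.08, 0.25))
    # occasional mid-call amplitude dip (contact calls are amplitude-modulated;
    # deep dips break the tracked contour into multiple segments)
    if (runif(1) < 0.35) {
      centre <- runif(1, 0.25, 0.75) * n
      width <- runif(1, 0.001, 0.003) * rate
      depth <- runif(1, 0.7, 1)
      env <- env * (1 - depth * exp(-((seq_len(n) - centre) / width)^2))
    }
    x <- amp * env * sin(phase)
    if (is.finite(noise_db)) {
      sig_rms <- sqrt(mean(x^2))
      x <- x + rnorm(n, 0, sig_rms / 10^(noise_db / 20))
    }
    w <- waveform(x, rate)
    attr(w, "params") <- list(f_start = f_start, f_end = f_end,
                              duration_ms = dur_ms, curvature = curv)
    w
  })
}

# Raised-cosine on/off ramps covering `frac` of the length at each end.
ramp_envelope <- function(n, frac = 0.1) {
  nr <- max(round(n * frac), 1L)
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env[seq_len(nr)] <- up
  env[n + 1L - seq_len(nr)] <- up
  env
}

#' Generate an isolation recording session with ground truth
#'
#' Places `n_calls` synthesized calls of one bat at randomized,
#' non-overlapping onsets in a white Gaussian noise background, returning both
#' the waveform and the exact onset/offset of every call.
#'
#' Each call is rescaled so its RMS sits `noise_db` dB above the background
#' RMS, which is the SNR the detector sees.
#'
#' @param profile one-row bat profile (see [synthesize_call()]).
#' @param n_calls number of calls to place (>= 0).
#' @param rate sampling rate in Hz; 250000 or 500000.
#' @param seed RNG seed.
#' @param noise_db per-call SNR in dB over the background.
#' @param background_rms RMS amplitude of the noise background.
#' @param gap_range_ms uniform range for inter-call gaps (ms).
#' @return List of class `recording_session`: `wave` (a `waveform`) and
#'   `truth` (data frame: `call`, `onset_s`, `offset_s`).
#' @export
generate_recording_session <- function(profile, n_calls, rate = 250000,
                                       seed = NULL, noise_db = 30,
                                       background_rms = 0.002,
                                       gap_range_ms = c(30, 120)) {
  stopifnot_scalar_count(n_calls, "n_calls", min = 0L)
  if (!rate %in% c(250000, 500000)) stop("`rate` must be 250000 or 500000 Hz")
  with_seed(seed, {
    calls <- list()
    if (n_calls > 0) {
      seeds <- sample.int(2^31 - 2, n_calls)
      calls <- lapply(seeds, function(s)
        synthesize_call(profile, rate = rate, noise_db = Inf, seed = s))
    }
    gaps <- round(runif(n_calls + 1L, gap_range_ms[1], gap_range_ms[2]) / 1000 * rate)
    lens <- vapply(calls, function(w) length(w$samples), integer(1))
    onsets <- cumsum(c(gaps[1], head(lens, -1) + gaps[-1][seq_len(max(n_calls - 1L, 0L))]))
    total <- if (n_calls > 0) onsets[n_calls] + lens[n_calls] + gaps[n_calls + 1L]
    else round(0.5 * rate)
    x <- rnorm(total, 0, background_rms)
    target_rms <- background_rms * 10^(noise_db / 20)
    for (k in seq_len(n_calls)) {
      ck <- calls[[k]]$samples
      ck <- ck * target_rms / sqrt(mean(ck^2))
      idx <- onsets[k] + seq_along(ck)
      x[idx] <- x[idx] + ck
    }
    truth <- data.frame(call = seq_len(n_calls),
                        onset_s = if (n_calls > 0) onsets / rate else numeric(0),
                        offset_s = if (n_calls > 0) (onsets + lens) / rate else numeric(0))
    structure(list(wave = waveform(x, rate), truth = truth),
              class = "recording_session")
  })
}

#' Write a recording session to disk
#'
#' Writes the waveform as 16-bit PCM WAV and the ground-truth call table as
#' CSV (`session`, `call`, `onset_s`, `offset_s`).
#'
#' @param session a `recording_session`.
#' @param dir output directory (created if needed).
#' @param name session name used for file stems.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_session <- function(session, dir, name = "session") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wav_path <- file.path(dir, paste0(name, ".wav"))
  csv_path <- file.path(dir, paste0(name, "_truth.csv"))
  write_wav(session$wave, wav_path)
  truth <- cbind(session = name, session$truth)
  write.csv(truth, csv_path, row.names = FALSE)
  invisible(c(wav = wav_path, truth = csv_path))
}
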