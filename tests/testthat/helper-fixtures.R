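# Shared fixtures: analytic test signals and simulated feature tables.

# Pure tone segment (no ramps, so envelope and contour are exactly flat).
tone_segment <- function(f_khz = 40, dur_ms = 10, rate = 250000, amp = 0.3) {
  n <- round(dur_ms / 1000 * rate)
  call_segment(amp * sin(2 * pi * f_khz * 1000 * seq_len(n) / rate), rate)
}

# Linear chirp f0 -> f1 kHz over dur_ms (analytic contour oracle).
chirp_segment <- function(f0_khz = 80, f1_khz = 20, dur_ms = 10,
                          rate = 250000, amp = 0.3) {
  n <- round(dur_ms / 1000 * rate)
  tt <- seq_len(n) / rate
  f_khz <- f0_khz + (f1_khz - f0_khz) * tt / (dur_ms / 1000)
  call_segment(amp * sin(2 * pi * cumsum(f_khz * 1000) / rate), rate)
}

# Gaussian feature table: K bats, n calls each, d features, class means
# `sep` SDs apart along successive axes (sep = 0 gives a zero-signal table).
gauss_feature_table <- function(K, n, d = 5, sep = 0, sd_within = 1) {
  X <- do.call(rbind, lapply(seq_len(K), function(k) {
    mu <- rep(0, d)
    mu[(k - 1L) %% d + 1L] <- sep * (1 + (k - 1L) %/% d)
    matrix(rnorm(n * d, 0, sd_within), n, d) +
      matrix(mu, n, d, byrow = TRUE)
  }))
  colnames(X) <- paste0("V", seq_len(d))
  data.frame(bat_id = rep(sprintf("bat%02d", seq_len(K)), each = n), X,
             stringsAsFactors = FALSE)
}

# Small all-adult-female population, everyone captured into the colony, for
# convergence-direction checks.
af_population <- function(n_bats, n_sites = 2, spec = convergence_spec(0.5, 0),
                          seed = 1, p_captive = 0.8) {
  pop <- make_population(n_bats, n_sites, config = spec, seed = seed,
                         p_captive = p_captive)
  pop$bats$sex <- "F"
  pop$bats$age_class <- "adult"
  pop
}

fast_mcmc <- function(seed = 1L, chains = 2L, iter = 1500L, warmup = 500L) {
  mcmc_control(chains = chains, iter = iter, warmup = warmup, seed = seed)
}

# mm fits at reduced test settings trip the R-hat guard occasionally; the
# calibration loops only need the CIs.
quiet_fit <- function(expr) suppressWarnings(expr)
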