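test_that("spectrogram localizes tones and resolves chirp direction", {
  sp <- compute_spectrogram(tone_segment(40))
  peak_bins <- apply(sp$mag, 2, which.max)
  expect_true(all(abs(sp$freq_khz[peak_bins] - 40) <= mean(diff(sp$freq_khz))))
  expect_error(compute_spectrogram(tone_segment(40, dur_ms = 0.5)), "window")
  ch <- compute_spectrogram(chirp_segment(80, 20, 10))
  track <- sp_track <- ch$freq_khz[apply(ch$mag, 2, which.max)]
  expect_lt(cor(seq_along(track), track), -0.95)   # monotone decreasing
})

test_that("tone and chirp features match their analytic values", {
  tone <- extract_all(tone_segment(40, 10))
  expect_equal(unname(tone[c("meandom", "mindom", "maxdom", "startdom",
                             "enddom")]),
               rep(40, 5), tolerance = 0.02)
  expect_equal(unname(tone["dfrange"]), 0, tolerance = 0.5)
  expect_equal(unname(tone["dfslope"]), 0, tolerance = 0.05)
  expect_equal(unname(tone["duration"]), 10)
  # symmetric (constant) envelope: median of cumulative energy at duration/2
  expect_equal(unname(tone["time.median"]), 5, tolerance = 0.3)
  # linear chirp 80 -> 20 over 10 ms: dominant slope -6 kHz/ms
  chirp <- extract_all(chirp_segment(80, 20, 10))
  expect_equal(unname(chirp["dfslope"]), -6, tolerance = 0.4)
  expect_lt(unname(chirp["meanslope"]), -5)
})

test_that("slope measures handle flat, V-shaped and broken contours", {
  flat <- structure(data.frame(time_ms = 0:10, f_khz = rep(40, 11)),
                    class = c("frequency_contour", "data.frame"))
  sf <- slope_measures(flat)
  expect_equal(unname(sf[c("maxslope", "minslope", "meanslope", "npos",
                           "nneg", "nturns")]), rep(0, 6))
  expect_equal(unname(sf["nsegments"]), 1)
  # V shape at +-2 kHz/ms: one turn
  v <- structure(data.frame(time_ms = 0:10,
                            f_khz = 40 + 2 * abs(5 - (0:10))),
                 class = c("frequency_contour", "data.frame"))
  sv <- slope_measures(v)
  expect_equal(unname(sv[c("minslope", "maxslope", "nturns")]), c(-2, 2, 1))
  # a gap splits the contour into two segments
  broken <- structure(data.frame(time_ms = 0:10,
                                 f_khz = c(rep(40, 4), NA, NA, NA, rep(35, 4))),
                      class = c("frequency_contour", "data.frame"))
  expect_equal(unname(slope_measures(broken)["nsegments"]), 2)
  # empty contour: zero counts
  empty <- structure(data.frame(time_ms = 0:5, f_khz = rep(NA_real_, 6)),
                     class = c("frequency_contour", "data.frame"))
  expect_equal(unname(slope_measures(empty)["nsegments"]), 0)
})

test_that("white noise is mostly unvoiced", {
  set.seed(3)
  seg <- call_segment(rnorm(2500, 0, 0.1), 250000)
  ct <- fundamental_contour(seg)
  expect_gt(mean(is.na(ct$f_khz)), 0.7)
})

test_that("every valid call yields 35 finite, consistently ordered features", {
  fn <- feature_names()
  expect_length(fn, 35)
  expect_equal(sum(attr(fn, "group") == "spectrotemporal"), 27)
  expect_equal(sum(attr(fn, "group") == "slope"), 8)
  prof <- list(f_start = 65, f_end = 22, duration_ms = 15, curvature = 2,
               sd_f_start = 2, sd_f_end = 1, sd_duration_ms = 1.5,
               sd_curvature = 0.2)
  w <- synthesize_call(prof, noise_db = 30, seed = 77)
  seg <- call_segment(w$samples, w$rate)
  v1 <- extract_all(seg)
  expect_identical(names(v1), as.character(fn))
  expect_true(all(is.finite(v1)))
  # identical segments give identical vectors
  expect_identical(v1, extract_all(call_segment(w$samples, w$rate)))
  # halving the amplitude changes no feature (scale invariance)
  vhalf <- extract_all(call_segment(w$samples * 0.5, w$rate))
  expect_equal(v1, vhalf, tolerance = 1e-10)
})

test_that("feature invariants hold over a large synthetic batch", {
  pop <- make_population(25, 2, seed = 19)
  pop$bats$duration_ms <- pmin(pop$bats$duration_ms, 12)  # keep the batch fast
  tab <- simulate_feature_table(pop$bats, calls_per_bat = 400, seed = 6)
  expect_equal(nrow(tab), 10000)
  X <- tab[, as.character(feature_names())]
  expect_true(all(vapply(X, function(c) all(is.finite(c)), logical(1))))
  expect_true(all(X$freq.Q25 <= X$freq.median & X$freq.median <= X$freq.Q75))
  expect_true(all(X$time.Q25 <= X$time.median & X$time.median <= X$time.Q75))
  expect_true(all(X$mindom <= X$meandom & X$meandom <= X$maxdom))
  expect_true(all(X$duration >= 3 & X$duration <= 50))
})

test_that("features separate individual bats far above chance", {
  pop <- make_population(10, 2, seed = 23)
  tab <- simulate_feature_table(pop$bats, calls_per_bat = 40, seed = 8)
  acc <- classify_loocv(tab[, c("bat_id", as.character(feature_names()))])
  expect_gt(acc$overall, 5 * 0.1)
})
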