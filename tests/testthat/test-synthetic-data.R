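test_that("populations are deterministic and socially coherent", {
  pop <- make_population(12, 2, seed = 7)
  pop2 <- make_population(12, 2, seed = 7)
  expect_identical(pop, pop2)
  s <- pop$social
  expect_true(isSymmetric(unname(s$kinship)))
  expect_true(all(is.na(diag(s$kinship))))
  # never-met pairs have zero interaction seconds
  nm <- s$familiarity_class == "never-met" & !is.na(s$familiarity_class)
  expect_true(all(s$sampling_seconds[nm] == 0))
  expect_true(all(s$groom_seconds[nm] == 0))
  # observed behaviour cannot exceed sampling effort
  ok <- !is.na(s$share_seconds) & !is.na(s$sampling_seconds)
  expect_true(all((s$groom_seconds[ok] + s$share_seconds[ok]) <=
                    pmax(s$sampling_seconds[ok] - 1, 0) |
                    s$sampling_seconds[ok] == 0))
  expect_error(make_population(1, 1), "n_bats")
})

test_that("familiarity classes follow the site and co-housing assignment", {
  # everyone captured: all cross-site pairs are introduced-cohoused
  pop <- make_population(12, 2, seed = 3, p_captive = 1)
  cross <- outer(pop$bats$site, pop$bats$site, "!=")
  expect_true(all(pop$social$familiarity_class[cross] == "introduced-cohoused"))
  # nobody captured: a cross-site pair is never-met with zero seconds
  pop2 <- make_population(2, 2, seed = 3, p_captive = 0)
  expect_identical(pop2$social$familiarity_class[1, 2], "never-met")
  expect_identical(pop2$social$sampling_seconds[1, 2], 0)
})

test_that("call counts are heavy-tailed with the configured median", {
  counts <- unlist(lapply(11:14, function(s)
    make_population(95, 2, seed = s)$bats$n_calls))   # 380 draws
  expect_gt(median(counts), 1800)
  expect_lt(median(counts), 3500)
  expect_gt(mean(counts), median(counts))       # right skew
  expect_true(all(counts >= 100 & counts <= 1e5))
})

test_that("convergence shrinks contour means as specified", {
  pop <- make_population(8, 2, seed = 5, p_captive = 1)
  # identity case
  same <- apply_convergence(pop$bats, pop$social, convergence_spec(0, 0))
  expect_equal(same, pop$bats)
  # full shrinkage: all co-housed bats share identical means
  full <- apply_convergence(pop$bats, pop$social, convergence_spec(1, 0))
  mu <- as.matrix(full[, c("f_start", "f_end", "duration_ms", "curvature")])
  expect_lt(max(apply(mu, 2, sd)), 1e-10)
  # two-bat hand computation: means 40, 60 with delta 0.5 -> 45, 55
  two <- make_population(2, 1, seed = 1, p_captive = 1)
  two$bats$f_start <- c(40, 60)
  out <- apply_convergence(two$bats, two$social, convergence_spec(0.5, 0))
  expect_equal(out$f_start, c(45, 55))
  # dimension mismatch
  expect_error(apply_convergence(pop$bats[1:3, ], pop$social,
                                 convergence_spec()), "conform")
})

test_that("co-housed contour spread is non-increasing in delta_cohouse", {
  deltas <- c(0, 0.25, 0.5, 0.75, 1)
  for (rep in 1:20) {
    pop <- make_population(8, 2, seed = 100 + rep, p_captive = 1)
    spread <- vapply(deltas, function(d) {
      contour_distance(apply_convergence(pop$bats, pop$social,
                                         convergence_spec(d, 0)))
    }, numeric(1))
    expect_true(all(diff(spread) <= 1e-12))
  }
})

test_that("synthesized calls follow their FM contour and are reproducible", {
  prof <- list(f_start = 80, f_end = 20, duration_ms = 10, curvature = 2)
  w1 <- synthesize_call(prof, 250000, Inf, wobble_khz = 0, seed = 42)
  w2 <- synthesize_call(prof, 250000, Inf, wobble_khz = 0, seed = 42)
  expect_identical(w1$samples, w2$samples)
  expect_error(synthesize_call(prof, rate = 44100), "rate")
  # tracked contour matches the analytic sweep
  seg <- call_segment(w1$samples, 250000)
  ct <- fundamental_contour(seg)
  tt <- ct$time_ms / 10   # fraction of duration
  truth <- 20 + 60 * exp(-2 * tt)
  ok <- !is.na(ct$f_khz)
  expect_gt(mean(ok), 0.8)
  expect_lt(sqrt(mean((ct$f_khz[ok] - truth[ok])^2)), 2)
  # durations stay in the admissible band under jitter
  prof$sd_duration_ms <- 30
  durs <- vapply(1:25, function(k) {
    length(synthesize_call(prof, seed = k)$samples) / 250
  }, numeric(1))
  expect_true(all(durs >= 3 & durs <= 50))
  # zero-amplitude profile yields silence
  prof0 <- c(prof, list(amplitude = 0))
  expect_equal(max(abs(synthesize_call(prof0, 250000, Inf, seed = 1)$samples)), 0)
})

test_that("recording sessions carry exact non-overlapping ground truth", {
  prof <- list(f_start = 70, f_end = 25, duration_ms = 12, curvature = 2)
  s <- generate_recording_session(prof, 5, seed = 9)
  expect_equal(nrow(s$truth), 5)
  expect_true(all(diff(as.vector(t(s$truth[, c("onset_s", "offset_s")]))) > 0))
  s0 <- generate_recording_session(prof, 0, seed = 9)
  expect_equal(nrow(s0$truth), 0)
  expect_gt(length(s0$wave$samples), 0)
  # write/read round trip
  dir <- withr::local_tempdir()
  paths <- write_session(s, dir, "bat01_post")
  expect_true(all(file.exists(paths)))
  w <- read_wav(paths["wav"])
  expect_equal(length(w$samples), length(s$wave$samples))
})

test_that("dyadic generator matches beta moments and recovers edge cases", {
  # logit^-1(0) = 0.5 mean outcome with alpha = 0 and no effects
  sim <- generate_dyadic_dataset(40, beta = c(cohoused = 0), phi = 20,
                                 sigma_bat = 0, alpha = 0, seed = 2)
  expect_lt(abs(mean(sim$dyads$similarity) - 0.5), 0.02)
  # empirical mean/variance agree with Beta(mu*phi, (1-mu)*phi) moments
  mu <- plogis(-1); phi <- 30
  sims <- lapply(1:7, function(k)
    generate_dyadic_dataset(55, beta = c(cohoused = 0), phi = phi,
                            sigma_bat = 0, alpha = -1, seed = k)$dyads$similarity)
  y <- unlist(sims)   # > 10000 draws
  expect_gt(length(y), 10000)
  se_mean <- sqrt(mu * (1 - mu) / (1 + phi) / length(y))
  expect_lt(abs(mean(y) - mu), 4 * se_mean)
  expect_lt(abs(var(y) / (mu * (1 - mu) / (1 + phi)) - 1), 0.1)
  # high-precision outcomes concentrate at logit^-1(alpha + X beta)
  conc <- generate_dyadic_dataset(30, beta = c(cohoused = 0.5), phi = 5000,
                                  sigma_bat = 0, alpha = 0, seed = 3)
  mu_d <- plogis(0.5 * conc$dyads$cohoused)
  expect_lt(max(abs(conc$dyads$similarity - mu_d)), 0.05)
  expect_error(generate_dyadic_dataset(10, phi = -1), "phi")
})
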