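test_that("split R-hat and ESS behave on known chains", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(good), 1.01)
  expect_gt(ess_bulk(good), 2000)
  expect_gt(ess_tail(good), 1000)
  # diverged chain means inflate R-hat
  bad <- good
  bad[, 1] <- bad[, 1] + 5
  expect_gt(rhat(bad), 1.5)
  # strong autocorrelation cuts the effective sample size
  ar <- apply(matrix(rnorm(4000), 1000, 4), 2,
              function(z) as.numeric(stats::filter(z, 0.9, "recursive")))
  expect_lt(ess_bulk(ar), 1000)
})

test_that("the beta multi-membership model recovers simulated parameters", {
  sim <- generate_dyadic_dataset(25, beta = c(cohoused = 0.5), phi = 30,
                                 sigma_bat = 0.3, alpha = -1, seed = 44)
  fit <- quiet_fit(fit_beta_mm(sim$dyads, "cohoused", mcmc = fast_mcmc(10)))
  sm <- fit$summary
  co <- sm[sm$parameter == "cohoused", ]
  expect_gt(co$ci_97.5, 0.5 - 1e-9)
  expect_lt(co$ci_2.5, 0.5 + 1e-9)
  expect_lt(abs(co$mean - 0.5), 0.15)
  expect_true(all(c("rhat", "ess_bulk", "ess_tail") %in% names(sm)))
  # errors on invalid outcomes
  bad <- sim$dyads
  bad$similarity[1] <- 1
  expect_error(fit_beta_mm(bad, "cohoused"), "strictly")
  expect_error(fit_beta_mm(sim$dyads[1:5, ], "cohoused"), "10 dyads")
})

test_that("fits are seed-reproducible and exchangeable in bat labels", {
  sim <- generate_dyadic_dataset(15, beta = c(cohoused = 0.4), phi = 40,
                                 sigma_bat = 0.2, seed = 45)
  mc <- fast_mcmc(21, iter = 800L, warmup = 300L)
  f1 <- quiet_fit(fit_beta_mm(sim$dyads, "cohoused", mcmc = mc))
  f2 <- quiet_fit(fit_beta_mm(sim$dyads, "cohoused", mcmc = mc))
  expect_identical(f1$summary, f2$summary)
  # swapping bat_i/bat_j on every record leaves the posterior unchanged
  swapped <- sim$dyads
  swapped[, c("bat_i", "bat_j")] <- swapped[, c("bat_j", "bat_i")]
  f3 <- quiet_fit(fit_beta_mm(swapped, "cohoused", mcmc = mc))
  expect_identical(f1$summary, f3$summary)
})

test_that("posterior predictive checks separate self-fit from gross misfit", {
  sim <- generate_dyadic_dataset(20, beta = c(cohoused = 0.5), phi = 25,
                                 sigma_bat = 0.2, seed = 46)
  fit <- quiet_fit(fit_beta_mm(sim$dyads, "cohoused",
                               mcmc = fast_mcmc(11, iter = 1200L,
                                                warmup = 400L)))
  ppc <- posterior_predictive_check(fit, n_rep = 200, seed = 5)
  expect_gt(ppc$p_mean, 0.02); expect_lt(ppc$p_mean, 0.98)
  expect_gt(ppc$p_sd, 0.02); expect_lt(ppc$p_sd, 0.98)
  ppc2 <- posterior_predictive_check(fit, n_rep = 200, seed = 5)
  expect_identical(ppc$replicated, ppc2$replicated)
  # gross misspecification: uniform outcomes against the concentrated fit
  mis <- fit
  mis$data$y <- runif(length(mis$data$y))
  ppc3 <- posterior_predictive_check(mis, n_rep = 200, seed = 5)
  expect_true(ppc3$p_sd <= 0.01 || ppc3$p_sd >= 0.99)
})

test_that("the model battery reproduces the kinship-confound logic", {
  # construct dyads where kinship has no direct effect but kin pairs share
  # more food, and co-housing and sharing raise similarity
  set.seed(52)
  n <- 24
  pr <- t(combn(n, 2))
  nd <- nrow(pr)
  kin <- ifelse(rbinom(nd, 1, 0.3) == 1, sample(c(0.5, 0.25), nd, TRUE), 0)
  cohoused <- rbinom(nd, 1, 0.6)
  share_raw <- pmax(rnorm(nd, 2 * kin + 0.5, 0.5), 0) * cohoused
  aff <- share_raw / max(share_raw)
  u <- rnorm(n, 0, 0.15)
  eta <- -1 + 0.8 * cohoused + 1.2 * aff + 0 * kin +
    0.5 * u[pr[, 1]] + 0.5 * u[pr[, 2]]
  y <- rbeta(nd, plogis(eta) * 40, (1 - plogis(eta)) * 40)
  dy <- data.frame(bat_i = sprintf("b%02d", pr[, 1]),
                   bat_j = sprintf("b%02d", pr[, 2]),
                   similarity = pmin(pmax(y, 1e-9), 1 - 1e-9),
                   kinship = kin, cohoused = cohoused == 1,
                   familiarity_class = ifelse(cohoused == 1,
                                              "introduced-cohoused",
                                              "never-met"),
                   same_site = FALSE, both_adult_female = TRUE,
                   sampling_seconds = 10000, groom_seconds = 0,
                   share_seconds = share_raw * 100,
                   share_sampling_seconds = 10000,
                   affiliation_lograte = aff, sharing_lograte = aff)
  bat <- quiet_fit(run_model_battery(dy, mcmc = fast_mcmc(31, iter = 1200L,
                                                          warmup = 400L),
                                     models = c(1, 2)))
  cf <- bat$coefficients
  k1 <- cf[cf$model == 1 & cf$term == "kinship", ]
  k2 <- cf[cf$model == 2 & cf$term == "kinship", ]
  # model 1: kinship proxies the affiliation path, so its CI excludes 0;
  # model 2 conditions on affiliation and co-housing, absorbing the effect
  expect_gt(k1$ci_2.5, 0)
  expect_lt(k2$ci_2.5, 0)
  expect_gt(k2$ci_97.5, 0)
  expect_equal(nrow(cf), 4)   # kinship + (kinship, cohoused, affiliation)
})
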