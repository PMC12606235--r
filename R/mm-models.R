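#' MCMC sampler settings
#'
#' Defaults follow the convention of 4 chains of total length 6000 with 2000
#' warmup iterations each (4000 posterior draws per chain).
#'
#' @param chains number of chains.
#' @param iter total iterations per chain (including warmup).
#' @param warmup warmup iterations per chain (also used for JAGS adaptation).
#' @param seed RNG seed; chain RNGs are derived from it.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iter = 6000, warmup = 2000, seed = 1L) {
  stopifnot(iter > warmup, chains >= 1, warmup >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_control")
}

mm_model_string <- function(family) {
  likelihood <- switch(family,
    beta = "
    logit(mu[d]) <- alpha + inprod(X[d, ], beta) + wi * u[i[d]] + wj * u[j[d]]
    y[d] ~ dbeta(mu[d] * phi, (1 - mu[d]) * phi)",
    gaussian = "
    mu[d] <- alpha + inprod(X[d, ], beta) + wi * u[i[d]] + wj * u[j[d]]
    y[d] ~ dnorm(mu[d], tau_res)")
  scale_prior <- switch(family,
    beta = "phi ~ dgamma(0.01, 0.01)",
    gaussian = "sigma_res ~ dt(0, 1 / (2.5^2), 3) T(0,)
  tau_res <- pow(sigma_res, -2)")
  sprintf("model {
  for (d in 1:N) {%s
  }
  for (k in 1:K) { u[k] ~ dnorm(0, tau_u) }
  alpha ~ dnorm(0, 1e-6)
  for (p in 1:P) { beta[p] ~ dnorm(0, 1e-6) }
  sigma_bat ~ dt(0, 1 / (2.5^2), 3) T(0,)
  tau_u <- pow(sigma_bat, -2)
  %s
}", likelihood, scale_prior)
}

# Shared multi-membership fitter behind the beta and Gaussian models.
fit_mm <- function(y, X, i, j, ids, family, weights = c(0.5, 0.5),
                   mcmc = mcmc_control(), quiet = TRUE) {
  N <- length(y); K <- length(ids); P <- ncol(X)
  scale_par <- if (family == "beta") "phi" else "sigma_res"
  data <- list(y = y, X = X, i = i, j = j, N = N, K = K, P = P,
               wi = weights[1], wj = weights[2])
  inits <- lapply(seq_len(mcmc$chains), function(c_) list(
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = derive_seed(mcmc$seed, paste0("chain", c_))))
  model <- rjags::jags.model(textConnection(mm_model_string(family)),
                             data = data, inits = inits,
                             n.chains = mcmc$chains,
                             n.adapt = min(mcmc$warmup, 1000L), quiet = TRUE)
  burn <- max(mcmc$warmup - min(mcmc$warmup, 1000L), 0L)
  if (burn > 0) update(model, burn, progress.bar = "none")
  monitors <- c("alpha", "beta", "sigma_bat", scale_par, "u")
  samp <- rjags::coda.samples(model, monitors, n.iter = mcmc$iter - mcmc$warmup,
                              progress.bar = "none")
  # iterations x chains matrices per parameter
  varnames <- coda::varnames(samp)
  pull <- function(v) sapply(samp, function(ch) as.numeric(ch[, v]))
  beta_names <- if ("beta" %in% varnames) "beta" else sprintf("beta[%d]", 1:P)
  par_names <- c("alpha", beta_names, "sigma_bat", scale_par)
  label <- c("intercept", colnames(X), "sigma_bat", scale_par)
  draws <- setNames(lapply(par_names, pull), label)
  u_names <- if (K == 1L && "u" %in% varnames) "u" else sprintf("u[%d]", seq_len(K))
  u_mat <- do.call(cbind, lapply(u_names, function(v) as.numeric(pull(v))))
  colnames(u_mat) <- ids
  # sum-to-zero recentring: only alpha + mean(u) is likelihood-identified, so
  # report that sum as the intercept and centre the random effects per draw
  # (leaves every mu_d draw unchanged, but mixes far better)
  cent <- rowMeans(u_mat)
  draws$intercept <- draws$intercept +
    matrix(sum(weights) * cent, nrow(draws$intercept), mcmc$chains)
  u_mat <- u_mat - cent
  summary <- summarize_draws(draws)
  converged <- all(summary$rhat <= 1.01, na.rm = TRUE)
  if (!converged)
    warning(sprintf("possible non-convergence: max R-hat = %.4f",
                    max(summary$rhat, na.rm = TRUE)))
  structure(list(summary = summary, draws = draws, u = u_mat,
                 data = list(y = y, X = X, i = i, j = j, ids = ids),
                 family = family, weights = weights, mcmc = mcmc,
                 converged = converged),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit: %s outcome, %d dyads, %d bats, %d chains%s>\n",
              x$family, length(x$data$y), length(x$data$ids),
              x$mcmc$chains,
              if (x$converged) "" else " [NON-CONVERGED]"))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Fit a Bayesian beta multi-membership model of dyadic similarity
#'
#' Models a dyadic similarity outcome in `(0, 1)` as
#' `y_d ~ Beta(mu_d phi, (1 - mu_d) phi)` with
#' `logit(mu_d) = alpha + X_d beta + u_i/2 + u_j/2` and per-bat random
#' intercepts `u ~ Normal(0, sigma_bat^2)` capturing the dependence of each
#' pair on both member identities. Continuous predictors are z-scaled before
#' fitting. Priors: vague Normal on intercept and coefficients,
#' half-Student-t(3, 0, 2.5) on `sigma_bat`, Gamma(0.01, 0.01) on `phi`.
#' Sampling runs in JAGS; chains whose split R-hat exceeds 1.01 raise a
#' non-convergence warning and flag.
#'
#' @param records a `dyad_table` (or any data frame with `bat_i`, `bat_j`,
#'   an outcome column and the predictor columns).
#' @param spec a [model_spec()] or a character vector of predictor columns.
#' @param mcmc an [mcmc_control()].
#' @param outcome outcome column name (default `"similarity"`).
#' @param weights multi-membership weights for the two member bats.
#' @return An `mm_fit`: `summary` (mean, SD, 95% CI, R-hat, bulk/tail ESS per
#'   parameter), `draws`, per-bat random-effect draws `u`, `converged` flag.
#' @export
fit_beta_mm <- function(records, spec, mcmc = mcmc_control(),
                        outcome = "similarity", weights = c(0.5, 0.5)) {
  predictors <- if (inherits(spec, "model_spec")) spec$predictors else spec
  scale_cont <- if (inherits(spec, "model_spec")) spec$scale_continuous
    else setdiff(predictors, "cohoused")
  if (nrow(records) < 10L) stop("need at least 10 dyads")
  y <- records[[outcome]]
  if (any(y <= 0 | y >= 1)) stop("outcome must lie strictly in (0, 1)")
  X <- build_design(records, predictors, scale_cont)
  idx <- dyad_indices(records)
  fit_mm(y, X, idx$i, idx$j, idx$ids, "beta", weights, mcmc)
}

#' Fit a Gaussian multi-membership model
#'
#' Same multi-membership structure as [fit_beta_mm()] with a Gaussian
#' outcome, used for modelling changes in similarity (which can be negative).
#'
#' @inheritParams fit_beta_mm
#' @param outcome outcome column name (default `"delta_similarity"`).
#' @param scale_continuous predictor columns to z-scale (default none:
#'   indicator predictors are left as is).
#' @export
fit_gaussian_mm <- function(records, spec, mcmc = mcmc_control(),
                            outcome = "delta_similarity",
                            scale_continuous = character(0),
                            weights = c(0.5, 0.5)) {
  predictors <- if (inherits(spec, "model_spec")) spec$predictors else spec
  if (nrow(records) < 10L) stop("need at least 10 dyads")
  X <- build_design(records, predictors, scale_continuous)
  idx <- dyad_indices(records)
  fit_mm(records[[outcome]], X, idx$i, idx$j, idx$ids, "gaussian",
         weights, mcmc)
}

build_design <- function(records, predictors, scale_continuous) {
  cols <- lapply(predictors, function(p) {
    v <- records[[p]]
    if (is.null(v)) stop("predictor column not found: ", p)
    v <- as.numeric(v)
    if (p %in% scale_continuous) v <- z_scale(v)
    v
  })
  X <- do.call(cbind, cols)
  colnames(X) <- predictors
  if (any(!is.finite(X))) stop("predictors contain missing values")
  X
}

dyad_indices <- function(records) {
  ids <- sort(unique(c(records$bat_i, records$bat_j)))
  list(ids = ids, i = match(records$bat_i, ids), j = match(records$bat_j, ids))
}

#' Posterior predictive check
#'
#' Simulates replicate outcome vectors from the fitted model's posterior
#' draws and compares the observed mean and SD with their replicated
#' distributions. Tail probabilities near 0 or 1 indicate misfit.
#'
#' @param fit an `mm_fit`.
#' @param n_rep number of posterior draws to replicate from.
#' @param seed RNG seed.
#' @return List of class `ppc_report`: `p_mean`, `p_sd` (probability the
#'   replicated statistic is at least the observed), `observed`, `replicated`
#'   (data frame of replicate statistics), `y_rep` (first 20 replicate
#'   vectors, for density overlays).
#' @export
posterior_predictive_check <- function(fit, n_rep = 200, seed = 1L) {
  d <- fit$data
  ndraw <- length(fit$draws$intercept)
  with_seed(seed, {
    take <- sample.int(ndraw, min(n_rep, ndraw))
    P <- ncol(d$X)
    beta_draws <- do.call(cbind, lapply(colnames(d$X), function(p)
      as.numeric(fit$draws[[p]])))
    y_rep <- vapply(take, function(t_) {
      eta <- as.numeric(fit$draws$intercept)[t_] +
        drop(d$X %*% beta_draws[t_, ]) +
        fit$weights[1] * fit$u[t_, d$i] + fit$weights[2] * fit$u[t_, d$j]
      if (fit$family == "beta") {
        mu <- plogis(eta)
        phi <- as.numeric(fit$draws$phi)[t_]
        rbeta(length(eta), mu * phi, (1 - mu) * phi)
      } else {
        rnorm(length(eta), eta, as.numeric(fit$draws$sigma_res)[t_])
      }
    }, numeric(length(d$y)))
    rep_stats <- data.frame(mean = colMeans(y_rep), sd = apply(y_rep, 2, sd))
    structure(list(
      p_mean = mean(rep_stats$mean >= mean(d$y)),
      p_sd = mean(rep_stats$sd >= sd(d$y)),
      observed = c(mean = mean(d$y), sd = sd(d$y)),
      replicated = rep_stats,
      y_rep = y_rep[, seq_len(min(20, ncol(y_rep))), drop = FALSE]),
      class = "ppc_report")
  })
}

#' Run the five-model dyadic regression battery
#'
#' Applies each model's inclusion predicate, fits the beta multi-membership
#' model, and collects the seven headline coefficients: kinship (model 1);
#' kinship, co-housing and affiliation (model 2); co-housing (model 3);
#' affiliation (model 4); food sharing (model 5).
#'
#' @param records a `dyad_table`.
#' @param mcmc an [mcmc_control()]; each model gets a sub-seed derived from
#'   `mcmc$seed`.
#' @param models which of models 1-5 to run.
#' @return List of class `model_battery`: `fits` (per-model `mm_fit`),
#'   `coefficients` (data frame: model, term, mean, ci_2.5, ci_97.5, rhat).
#' @export
run_model_battery <- function(records, mcmc = mcmc_control(), models = 1:5) {
  fits <- list()
  coef_rows <- list()
  for (m in models) {
    spec <- model_spec(m)
    sel <- select_dyads(records, spec)
    sub_mcmc <- mcmc
    sub_mcmc$seed <- derive_seed(mcmc$seed, paste0("model", m))
    fit <- fit_beta_mm(sel, spec, mcmc = sub_mcmc)
    fits[[as.character(m)]] <- fit
    sm <- fit$summary
    keep <- sm$parameter %in% spec$predictors
    coef_rows[[as.character(m)]] <- data.frame(
      model = m, term = sm$parameter[keep], n_dyads = nrow(sel),
      sm[keep, c("mean", "ci_2.5", "ci_97.5", "rhat")],
      stringsAsFactors = FALSE)
  }
  structure(list(fits = fits,
                 coefficients = do.call(rbind, c(coef_rows,
                                                 make.row.names = FALSE))),
            class = "model_battery")
}

#' @export
print.model_battery <- function(x, ...) {
  cat("<model_battery>\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}
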