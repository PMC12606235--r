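#' MCMC diagnostics: split R-hat and bulk/tail effective sample sizes
#'
#' `rhat()` is the potential scale reduction factor computed on chains split
#' in half (so within-chain drift also inflates it). `ess_bulk()` is the
#' effective sample size of rank-normalized split draws, estimated with
#' Geyer's initial monotone positive sequence on chain-averaged
#' autocorrelations; `ess_tail()` is the minimum ESS of the 5% and 95%
#' tail-exceedance indicators.
#'
#' @param draws iterations x chains numeric matrix for one parameter.
#' @return A single number.
#' @name mcmc-diagnostics
NULL

split_chains <- function(draws) {
  n <- nrow(draws)
  h <- floor(n / 2)
  cbind(draws[seq_len(h), , drop = FALSE],
        draws[(n - h + 1L):n, , drop = FALSE])
}

rank_normalize <- function(draws) {
  r <- rank(draws, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}

#' @rdname mcmc-diagnostics
#' @export
rhat <- function(draws) {
  x <- split_chains(rank_normalize(draws))
  n <- nrow(x); m <- ncol(x)
  if (n < 2L) return(NA_real_)
  means <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# ESS of the mean of `draws` via chain-averaged autocorrelations and Geyer's
# initial monotone positive sequence (pairs of consecutive rho sums).
ess_mean <- function(draws) {
  x <- split_chains(draws)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  B <- n * var(colMeans(x))
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus == 0) return(m * n)
  max_lag <- min(n - 1L, 1000L)
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(c_) {
    a <- acf(x[, c_], lag.max = max_lag, plot = FALSE, type = "covariance",
             demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov[-1]) / var_plus
  # Geyer pairs
  even <- seq(1L, length(rho) - 1L, by = 2L)
  psum <- rho[even] + rho[even + 1L]
  tau <- 1
  run_min <- Inf
  for (k in seq_along(psum)) {
    if (psum[k] < 0) break
    run_min <- min(run_min, psum[k])
    tau <- tau + 2 * run_min
  }
  max(m * n / tau, 1)
}

#' @rdname mcmc-diagnostics
#' @export
ess_bulk <- function(draws) ess_mean(rank_normalize(draws))

#' @rdname mcmc-diagnostics
#' @export
ess_tail <- function(draws) {
  q <- quantile(draws, c(0.05, 0.95))
  min(ess_mean((draws <= q[1]) * 1), ess_mean((draws >= q[2]) * 1))
}

# Summarize a named list of iterations x chains matrices into the standard
# posterior summary table.
summarize_draws <- function(draws_list) {
  rows <- lapply(names(draws_list), function(nm) {
    d <- draws_list[[nm]]
    v <- as.numeric(d)
    data.frame(parameter = nm, mean = mean(v), sd = sd(v),
               ci_2.5 = unname(quantile(v, 0.025)),
               ci_97.5 = unname(quantile(v, 0.975)),
               rhat = rhat(d), ess_bulk = ess_bulk(d), ess_tail = ess_tail(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
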