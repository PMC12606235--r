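#' Simulate a dyadic similarity dataset from the beta multi-membership model
#'
#' Draws dyadic similarity outcomes directly from the generative model the
#' fitting module assumes, for parameter-recovery and calibration tests:
#' `logit(mu_d) = alpha + X_d beta + u_i/2 + u_j/2`, `u ~ Normal(0, sigma_bat^2)`,
#' `y_d ~ Beta(mu_d * phi, (1 - mu_d) * phi)` over all unordered pairs of
#' `n_bats` bats.
#'
#' Covariates are built per named coefficient: `cohoused` is Bernoulli(0.5);
#' `sharing` is a standardized lograte, nonzero only for co-housed pairs;
#' `kinship` is a standardized zero-inflated kinship coefficient. Any other
#' name gets an independent standard normal column.
#'
#' @param n_bats number of bats; the table has `choose(n_bats, 2)` dyads.
#' @param beta named numeric vector of true coefficients (logit scale).
#' @param phi beta precision (> 0).
#' @param sigma_bat SD of per-bat random intercepts (>= 0).
#' @param alpha true intercept (logit scale).
#' @param seed RNG seed.
#' @return List with `dyads` (data frame: `bat_i`, `bat_j`, one column per
#'   covariate, `similarity`) and `truth` (list: `alpha`, `beta`, `phi`,
#'   `sigma_bat`, `u`).
#' @export
generate_dyadic_dataset <- function(n_bats, beta = c(cohoused = 0.5),
                                    phi = 30, sigma_bat = 0.3,
                                    alpha = -1, seed = NULL) {
  stopifnot_scalar_count(n_bats, "n_bats", min = 2L)
  if (!is.numeric(phi) || phi <= 0) stop("`phi` must be > 0")
  if (sigma_bat < 0) stop("`sigma_bat` must be >= 0")
  with_seed(seed, {
    pr <- t(combn(n_bats, 2))
    nd <- nrow(pr)
    X <- matrix(0, nd, length(beta), dimnames = list(NULL, names(beta)))
    cohoused <- rbinom(nd, 1, 0.5)
    for (nm in names(beta)) {
      X[, nm] <- switch(nm,
        cohoused = cohoused,
        sharing = {
          s <- ifelse(cohoused == 1 & rbinom(nd, 1, 0.4) == 1,
                      log(rlnorm(nd, 5, 1) + 1) / log(20000), 0)
          if (sd(s) > 0) (s - mean(s)) / sd(s) else s
        },
        kinship = {
          k <- ifelse(rbinom(nd, 1, 0.2) == 1,
                      sample(c(0.5, 0.25, 0.125), nd, TRUE), 0)
          (k - mean(k)) / sd(k)
        },
        rnorm(nd))
    }
    u <- rnorm(n_bats, 0, sigma_bat)
    eta <- alpha + drop(X %*% beta) + 0.5 * u[pr[, 1]] + 0.5 * u[pr[, 2]]
    mu <- plogis(eta)
    y <- rbeta(nd, mu * phi, (1 - mu) * phi)
    # beta draws can hit 0/1 at machine precision for extreme mu; keep in (0,1)
    eps <- .Machine$double.eps
    y <- pmin(pmax(y, eps), 1 - eps)
    dyads <- data.frame(bat_i = sprintf("bat%02d", pr[, 1]),
                        bat_j = sprintf("bat%02d", pr[, 2]),
                        X, similarity = y, stringsAsFactors = FALSE)
    list(dyads = dyads,
         truth = list(alpha = alpha, beta = beta, phi = phi,
                      sigma_bat = sigma_bat, u = u))
  })
}
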