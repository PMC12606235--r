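#' Drop bats with too few calls
#'
#' Caller-level classification rates stabilize once a caller contributes on
#' the order of a hundred calls; bats below the threshold are excluded from
#' the discriminant analysis.
#'
#' @param table feature table with a `bat_id` column.
#' @param min_calls minimum rows per bat (default 100).
#' @return The filtered table. Warns if no bats survive.
#' @export
filter_bats_min_calls <- function(table, min_calls = 100) {
  counts <- table(table$bat_id)
  keep_ids <- names(counts)[counts >= min_calls]
  out <- table[table$bat_id %in% keep_ids, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no bats reach the minimum call count; empty table returned")
  out
}

# Feature columns of a feature table (everything in feature_names()).
feature_matrix <- function(table) {
  fn <- as.character(feature_names())
  missing <- setdiff(fn, names(table))
  cols <- if (length(missing) == 0L) fn else
    setdiff(names(table), c("bat_id", "source", "call", "site", "epoch"))
  as.matrix(table[, cols, drop = FALSE])
}

# MASS::lda warns about exactly collinear columns (e.g. IQR = Q75 - Q25 by
# construction); that collinearity is expected and handled downstream by
# ridge regularization of the pooled covariance, so silence just that warning.
quiet_lda <- function(...) {
  withCallingHandlers(MASS::lda(...), warning = function(w) {
    if (grepl("collinear", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit the caller discriminant model
#'
#' Linear discriminant analysis classifying calls to bats on all 35 features,
#' with class priors proportional to training counts. Alongside the
#' discriminant fit, stores the per-bat feature centroids and the pooled
#' within-class covariance used for Mahalanobis centroid distances.
#'
#' @param table feature table (`bat_id` + 35 feature columns).
#' @param ridge relative ridge added to the pooled covariance diagonal when
#'   it is numerically singular.
#' @return Object of class `dfa_model`: `lda` (the [MASS::lda()] fit),
#'   `centroids`, `pooled_cov`, `counts`, `priors`, `features`.
#' @export
fit_dfa <- function(table) {
  ids <- factor(table$bat_id)
  if (nlevels(ids) < 2L) stop("need at least 2 bats")
  X <- feature_matrix(table)
  if (nrow(X) <= ncol(X)) stop("need more calls than features")
  fit <- quiet_lda(X, grouping = ids)
  centroids <- fit$means
  counts <- as.integer(table(ids))
  names(counts) <- levels(ids)
  # pooled within-class covariance
  K <- nlevels(ids)
  S <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  for (lev in levels(ids)) {
    Xi <- X[ids == lev, , drop = FALSE]
    if (nrow(Xi) > 1L) S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  S <- S / (nrow(X) - K)
  structure(list(lda = fit, centroids = centroids, pooled_cov = S,
                 counts = counts, priors = fit$prior,
                 features = colnames(X)),
            class = "dfa_model")
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf("<dfa_model: %d bats, %d features, %d training calls>\n",
              nrow(x$centroids), length(x$features), sum(x$counts)))
  invisible(x)
}

#' Leave-one-out cross-validated caller classification
#'
#' @param table feature table.
#' @return List of class `loocv_result`: `overall` accuracy, `per_bat`
#'   accuracy vector, `confusion` table.
#' @export
classify_loocv <- function(table) {
  ids <- factor(table$bat_id)
  if (any(table(ids) < 2L))
    stop("every bat needs at least 2 calls for leave-one-out classification")
  X <- feature_matrix(table)
  fit <- quiet_lda(X, grouping = ids, CV = TRUE)
  pred <- fit$class
  per_bat <- vapply(levels(ids), function(l)
    mean(pred[ids == l] == l), numeric(1))
  structure(list(overall = mean(pred == ids), per_bat = per_bat,
                 confusion = table(truth = ids, predicted = pred)),
            class = "loocv_result")
}

# Non-cross-validated (training set) classification accuracy.
noncv_accuracy <- function(table) {
  ids <- factor(table$bat_id)
  X <- feature_matrix(table)
  fit <- quiet_lda(X, grouping = ids)
  pred <- predict(fit, X)$class
  list(overall = mean(pred == ids),
       per_bat = vapply(levels(ids), function(l)
         mean(pred[ids == l] == l), numeric(1)))
}

#' Randomized-label permutation null for caller classification
#'
#' Refits the (non-cross-validated) discriminant analysis with bat labels
#' randomly permuted to build the null distribution of classification
#' accuracy expected when calls carry no caller information.
#'
#' @param table feature table.
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return List of class `permutation_null`: `observed` accuracy, `null`
#'   vector, `p` = (1 + #\{null >= observed\}) / (1 + n_perm), `null_q95`
#'   (2.5% and 97.5% quantiles of the null).
#' @export
permutation_null_accuracy <- function(table, n_perm = 1000, seed = 1L) {
  stopifnot_scalar_count(n_perm, "n_perm", min = 1L)
  observed <- noncv_accuracy(table)$overall
  ids <- factor(table$bat_id)
  X <- feature_matrix(table)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    perm <- sample(ids)
    fit <- quiet_lda(X, grouping = perm)
    mean(predict(fit, X)$class == perm)
  }, numeric(1)))
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (1 + n_perm),
                 null_q95 = quantile(null, c(0.025, 0.975)),
                 n_perm = n_perm, seed = seed),
            class = "permutation_null")
}

#' Compare cross-validated and non-cross-validated accuracies
#'
#' Robustness check for the discriminant analysis: per-bat accuracy from
#' leave-one-out cross-validation against per-bat accuracy of the single
#' training-set fit, with their Pearson correlation.
#'
#' @param table feature table.
#' @return List: `per_bat` data frame (`bat_id`, `loocv`, `noncv`),
#'   `correlation`, `degenerate` flag (TRUE with fewer than 3 bats, where
#'   the correlation is forced to +-1).
#' @export
compare_cv_noncv <- function(table) {
  cv <- classify_loocv(table)
  ncv <- noncv_accuracy(table)
  df <- data.frame(bat_id = names(cv$per_bat), loocv = unname(cv$per_bat),
                   noncv = unname(ncv$per_bat))
  list(per_bat = df, correlation = cor(df$loocv, df$noncv),
       degenerate = nrow(df) < 3L)
}

#' Mahalanobis distances between caller centroids
#'
#' `D_ij = sqrt((mu_i - mu_j)' Sigma^{-1} (mu_i - mu_j))` with `Sigma` the
#' pooled within-class covariance. The exactly collinear feature pairs (the
#' IQR-type measures) make `Sigma` rank-deficient; a relative ridge of
#' `ridge * mean(diag(Sigma))` is added in that case. Centroid differences
#' have no component along those null directions, so distances are unaffected.
#'
#' @param model a `dfa_model`.
#' @param ridge relative ridge (default 1e-8).
#' @return Symmetric distance matrix with zero diagonal, bats as dimnames.
#' @export
centroid_mahalanobis_matrix <- function(model, ridge = 1e-8) {
  mu <- model$centroids
  S <- model$pooled_cov
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(Sinv)) {
    S <- S + diag(ridge * mean(diag(S)), ncol(S))
    Sinv <- tryCatch(chol2inv(chol(S)), error = function(e)
      stop("pooled covariance is singular even after regularization"))
  }
  n <- nrow(mu)
  D <- matrix(0, n, n, dimnames = list(rownames(mu), rownames(mu)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- mu[i, ] - mu[j, ]
    D[i, j] <- D[j, i] <- sqrt(max(drop(t(d) %*% Sinv %*% d), 0))
  }
  D
}

#' Similarity matrix from centroid distances
#'
#' Caller similarity `S = 1 - D / max(D)`, normalized within the analysis
#' that produced `D`. The pair(s) attaining the maximum distance would score
#' exactly 0, which a beta-distributed outcome cannot take, so exact zeros
#' are replaced by `floor` (default 0.001).
#'
#' @param D symmetric nonnegative distance matrix with `max(D) > 0`.
#' @param floor replacement for exact-zero similarities.
#' @return Object of class `similarity_matrix`: the similarity matrix (unit
#'   diagonal) with attributes `D` and `max_D`.
#' @export
similarity_from_distances <- function(D, floor = 0.001) {
  if (!isSymmetric(unname(D), tol = 1e-10)) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be nonnegative")
  mx <- max(D)
  if (mx == 0) stop("max(D) is zero: no variation among bats")
  S <- 1 - D / mx
  off <- row(S) != col(S)
  S[off & S == 0] <- floor
  diag(S) <- 1
  structure(S, D = D, max_D = mx, floor = floor, class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d bats, max D = %.4g>\n",
              nrow(x), attr(x, "max_D")))
  print(round(unclass(x)[, ], 3))
  invisible(x)
}

#' Caller similarity from a feature table in one step
#'
#' Convenience wrapper: minimum-call filter, DFA fit, centroid Mahalanobis
#' distances, similarity transform.
#'
#' @param table feature table.
#' @param min_calls minimum calls per bat.
#' @param floor zero-similarity replacement.
#' @return A `similarity_matrix`.
#' @export
caller_similarity <- function(table, min_calls = 100, floor = 0.001) {
  table <- filter_bats_min_calls(table, min_calls)
  model <- fit_dfa(table)
  similarity_from_distances(centroid_mahalanobis_matrix(model), floor = floor)
}
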