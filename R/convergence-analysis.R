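#' Change in caller similarity between recording epochs
#'
#' Runs two independent discriminant analyses — residents plus the focal
#' bats' pre-introduction calls, and the same residents plus the focal bats'
#' post-introduction calls — extracts each epoch's similarity matrix
#' (normalized by that analysis's own maximum centroid distance), and
#' differences them: `delta = S_post - S_pre` over the common pairs. Note the
#' two epochs are normalized independently, so `delta` mixes two scales; the
#' downstream tests are rank- or sign-based in the predicted direction.
#'
#' @param features_pre feature table for the pre-introduction epoch
#'   (residents + focal bats recorded before introduction).
#' @param features_post feature table for the post-introduction epoch
#'   (residents, typically the same recordings, + focal bats recorded after).
#' @param design list with `residents` and `focals` (bat-id vectors); every
#'   design bat must appear in both tables.
#' @param min_calls per-bat minimum call count passed to the similarity step.
#' @param floor zero-similarity replacement.
#' @return List of class `pre_post_result`: `delta` (matrix), `S_pre`,
#'   `S_post`.
#' @export
pre_post_similarity <- function(features_pre, features_post, design,
                                min_calls = 100, floor = 0.001) {
  bats <- c(design$residents, design$focals)
  for (tb in list(features_pre, features_post)) {
    miss <- setdiff(bats, unique(tb$bat_id))
    if (length(miss))
      stop("bats missing from an epoch: ", paste(miss, collapse = ", "))
  }
  S_pre <- caller_similarity(features_pre[features_pre$bat_id %in% bats, ],
                             min_calls = min_calls, floor = floor)
  S_post <- caller_similarity(features_post[features_post$bat_id %in% bats, ],
                              min_calls = min_calls, floor = floor)
  common <- intersect(rownames(S_pre), rownames(S_post))
  delta <- unclass(S_post)[common, common] - unclass(S_pre)[common, common]
  structure(list(delta = delta, S_pre = S_pre, S_post = S_post),
            class = "pre_post_result")
}

#' Mantel test with Spearman correlation
#'
#' Tests the association between two symmetric dyadic matrices by the
#' Spearman correlation of their off-diagonal pairs, with a null built by
#' jointly permuting the rows and columns of the second matrix (permuting
#' individuals, which preserves each matrix's dyadic dependence structure).
#' One-tailed in the positive direction by default, matching a directional
#' convergence prediction.
#'
#' @param m1,m2 conforming symmetric matrices (>= 4 rows).
#' @param n_perm number of permutations, or `"exact"` to enumerate all `n!`
#'   row permutations (n <= 8).
#' @param seed RNG seed (ignored for exact enumeration).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List of class `mantel_result`: `statistic` (observed Spearman
#'   rho), `p`, `n_perm`, `null`, `seed`.
#' @export
mantel_spearman <- function(m1, m2, n_perm = 1000, seed = 1L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- nrow(m1)
  if (n < 4L) stop("need at least 4 individuals")
  if (!all(dim(m1) == dim(m2))) stop("matrices do not conform")
  lower <- lower.tri(m1)
  if (sd(m1[lower], na.rm = TRUE) == 0 || sd(m2[lower], na.rm = TRUE) == 0)
    stop("constant matrix: correlation undefined")
  stat <- function(perm) {
    mp <- m2[perm, perm]
    cor(m1[lower], mp[lower], method = "spearman", use = "complete.obs")
  }
  observed <- stat(seq_len(n))
  tail_count <- function(null) switch(alternative,
    greater = sum(null >= observed),
    less = sum(null <= observed),
    two.sided = sum(abs(null) >= abs(observed)))
  if (identical(n_perm, "exact")) {
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    perms <- all_permutations(n)
    null <- vapply(perms, stat, numeric(1))
    p <- tail_count(null) / length(null)   # identity permutation included
    n_used <- length(null)
  } else {
    stopifnot_scalar_count(n_perm, "n_perm", min = 1L)
    null <- with_seed(seed, vapply(seq_len(n_perm), function(k)
      stat(sample(n)), numeric(1)))
    p <- (1 + tail_count(null)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(statistic = observed, p = p, n_perm = n_used, null = null,
                 seed = seed, alternative = alternative),
            class = "mantel_result")
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (Spearman, %s): rho = %.3f, p = %.4g (%d permutations)\n",
              x$alternative, x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' Permuted DFA for group (site) signatures
#'
#' Tests whether calls classify to social group above chance while
#' respecting the nesting of calls within callers. The observed accuracy
#' holds out whole bats in rotation: each bat's calls are classified by a
#' discriminant function trained on all other bats. The null permutes
#' bat-to-site assignments (preserving site sizes, never splitting a bat's
#' calls) and recomputes the same rotation accuracy.
#'
#' @param features feature table with `bat_id` and `site` columns.
#' @param n_perm number of bat-label permutations.
#' @param seed RNG seed.
#' @return List of class `pdfa_result`: `observed` accuracy, `null` vector,
#'   `p`, `per_bat` accuracy of the observed rotation.
#' @export
pdfa_site <- function(features, n_perm = 100, seed = 1L) {
  stopifnot_scalar_count(n_perm, "n_perm", min = 1L)
  bat_ids <- unique(features$bat_id)
  site_of <- vapply(bat_ids, function(b)
    as.character(features$site[features$bat_id == b][1]), character(1))
  if (length(unique(site_of)) < 2L) stop("need at least 2 sites")
  if (any(table(site_of) < 2L)) stop("every site needs at least 2 bats")
  X <- feature_matrix(features)
  bat_f <- features$bat_id

  rotation_accuracy <- function(site_assign) {
    site_call <- factor(site_assign[match(bat_f, bat_ids)])
    correct <- vapply(bat_ids, function(b) {
      hold <- bat_f == b
      fit <- quiet_lda(X[!hold, , drop = FALSE],
                       grouping = droplevels(site_call[!hold]))
      pred <- predict(fit, X[hold, , drop = FALSE])$class
      c(sum(as.character(pred) == as.character(site_call[hold])), sum(hold))
    }, numeric(2))
    list(acc = sum(correct[1, ]) / sum(correct[2, ]),
         per_bat = correct[1, ] / correct[2, ])
  }

  obs <- rotation_accuracy(setNames(site_of, bat_ids))
  null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    perm <- setNames(sample(site_of), bat_ids)
    rotation_accuracy(perm)$acc
  }, numeric(1)))
  structure(list(observed = obs$acc, per_bat = setNames(obs$per_bat, bat_ids),
                 null = null, p = (1 + sum(null >= obs$acc)) / (1 + n_perm),
                 n_perm = n_perm, seed = seed),
            class = "pdfa_result")
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("Permuted DFA: site accuracy = %.3f, p = %.4g (%d permutations)\n",
              x$observed, x$p, x$n_perm))
  invisible(x)
}

#' Dyad records of a similarity-change matrix
#'
#' Flattens a `pre_post_similarity()` change matrix into one row per
#' unordered pair with an `introduced` indicator (cross-site pair), ready for
#' [fit_gaussian_mm()].
#'
#' @param delta symmetric change matrix with bat-id dimnames.
#' @param site named vector mapping bat id to site.
#' @return Data frame: `bat_i`, `bat_j`, `delta_similarity`, `introduced`.
#' @export
delta_records <- function(delta, site) {
  ids <- rownames(delta)
  pr <- t(combn(length(ids), 2))
  data.frame(bat_i = ids[pr[, 1]], bat_j = ids[pr[, 2]],
             delta_similarity = delta[pr],
             introduced = as.integer(site[ids[pr[, 1]]] != site[ids[pr[, 2]]]),
             stringsAsFactors = FALSE)
}
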