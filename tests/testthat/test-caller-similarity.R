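test_that("minimum-call filter keeps exactly the bats at or above threshold", {
  tab <- data.frame(bat_id = rep(c("a", "b", "c"), c(99, 100, 150)), x = 0)
  out <- filter_bats_min_calls(tab)
  expect_setequal(unique(out$bat_id), c("b", "c"))
  full <- data.frame(bat_id = rep(c("a", "b"), c(120, 200)), x = 0)
  expect_identical(filter_bats_min_calls(full), full)
  expect_warning(filter_bats_min_calls(tab, min_calls = 1000), "no bats")
})

test_that("the discriminant fit is invariant to row order", {
  set.seed(5)
  tab <- gauss_feature_table(4, 60, d = 6, sep = 2)
  fit <- fit_dfa(tab)
  perm <- tab[sample(nrow(tab)), ]
  fit2 <- fit_dfa(perm)
  expect_equal(fit$centroids, fit2$centroids)
  expect_equal(fit$pooled_cov, fit2$pooled_cov)
  expect_error(fit_dfa(tab[tab$bat_id == "bat01", ]), "2 bats")
})

test_that("classification accuracy tracks the class separation", {
  set.seed(6)
  # identical feature distributions: chance level for 4 balanced bats
  null_tab <- gauss_feature_table(4, 80, d = 6, sep = 0)
  acc0 <- classify_loocv(null_tab)$overall
  expect_lt(abs(acc0 - 0.25), 3 * sqrt(0.25 * 0.75 / 320))
  # 10-SD separation: near-perfect
  far_tab <- gauss_feature_table(3, 50, d = 6, sep = 10)
  expect_gt(classify_loocv(far_tab)$overall, 0.99)
  # single-call bat cannot be held out
  bad <- rbind(null_tab, data.frame(bat_id = "lone",
                                    null_tab[1, -1, drop = FALSE]))
  expect_error(classify_loocv(bad), "at least 2 calls")
})

test_that("randomized-label null behaves and is seed-stable", {
  set.seed(7)
  tab <- gauss_feature_table(3, 60, d = 5, sep = 6)
  p1 <- permutation_null_accuracy(tab, n_perm = 99, seed = 4)
  p2 <- permutation_null_accuracy(tab, n_perm = 99, seed = 4)
  expect_identical(p1$null, p2$null)
  expect_equal(p1$p, 1 / 100)           # strong signal beats every null
  expect_length(p1$null_q95, 2)
  expect_error(permutation_null_accuracy(tab, n_perm = 0), "n_perm")
})

test_that("cross-validated and training accuracies correlate per bat", {
  set.seed(9)
  # bats of graded difficulty so per-bat accuracy spans a range
  tabs <- lapply(1:5, function(k) {
    X <- matrix(rnorm(400 * 5), 400, 5)
    X[, 1] <- X[, 1] + 1.1 * k
    colnames(X) <- paste0("V", 1:5)
    data.frame(bat_id = sprintf("bat%02d", k), X)
  })
  cmp <- compare_cv_noncv(do.call(rbind, tabs))
  expect_false(cmp$degenerate)
  expect_gt(cmp$correlation, 0.99)
  expect_true(all(abs(cmp$per_bat$loocv - cmp$per_bat$noncv) < 0.05))
})

test_that("centroid Mahalanobis distances match hand and whitening oracles", {
  # identity covariance, centroids (0,0) and (3,4): D = 5
  m <- structure(list(centroids = rbind(a = c(0, 0), b = c(3, 4)),
                      pooled_cov = diag(2)), class = "dfa_model")
  expect_equal(centroid_mahalanobis_matrix(m)["a", "b"], 5)
  # 1-D: pooled variance 4, means 0 and 4: D = 2
  m1 <- structure(list(centroids = rbind(a = 0, b = 4),
                       pooled_cov = matrix(4, 1, 1)), class = "dfa_model")
  expect_equal(centroid_mahalanobis_matrix(m1)["a", "b"], 2)
  # identical centroids: D = 0
  m0 <- structure(list(centroids = rbind(a = c(1, 2), b = c(1, 2)),
                       pooled_cov = diag(2)), class = "dfa_model")
  expect_equal(centroid_mahalanobis_matrix(m0)["a", "b"], 0)
  # whitening-then-Euclidean brute force on random 5-bat, 5-feature fits
  for (k in 1:10) {
    set.seed(300 + k)
    tab <- gauss_feature_table(5, 40, d = 5, sep = 1.5)
    fit <- fit_dfa(tab)
    D <- centroid_mahalanobis_matrix(fit)
    W <- solve(chol(fit$pooled_cov))          # whitening transform
    white <- fit$centroids %*% W
    D_brute <- as.matrix(dist(white))
    expect_lt(max(abs(D - D_brute)), 1e-8)
  }
})

test_that("the similarity transform follows S = 1 - D/max(D) with the floor", {
  D <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D["A", "B"] <- D["B", "A"] <- 4
  D["A", "C"] <- D["C", "A"] <- 2
  S <- similarity_from_distances(D)
  expect_equal(S["A", "B"], 0.001)    # the maximal pair gets the floor
  expect_equal(S["A", "C"], 0.5)
  expect_equal(S["B", "C"], 1)
  # scale invariance
  S10 <- similarity_from_distances(D * 10)
  expect_equal(unclass(S10)[, ], unclass(S)[, ])
  expect_error(similarity_from_distances(D * 0), "no variation")
  expect_error(similarity_from_distances(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("similarity among co-housed bats rises with convergence strength", {
  # non-co-housed pairs anchor the max-distance normalization, so shrinking
  # co-housed centroids raises their similarity specifically
  deltas <- c(0, 0.25, 0.5, 0.75)
  mean_S <- vapply(deltas, function(d) {
    vals <- vapply(1:3, function(rep) {
      pop <- make_population(8, 2, seed = 400 + rep, p_captive = 0.6)
      conv <- apply_convergence(pop$bats, pop$social, convergence_spec(d, 0))
      tab <- simulate_feature_table(conv, calls_per_bat = 40,
                                    seed = 500 + rep)
      S <- caller_similarity(tab, min_calls = 30)
      co <- pop$social$cohoused[rownames(S), colnames(S)] %in% TRUE &
        upper.tri(S)
      mean(S[co])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_S) > 0))
})
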