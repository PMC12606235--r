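make_sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("b%d", 1:n), sprintf("b%d", 1:n))
  m
}

test_that("identical epochs give a near-zero change matrix", {
  pop <- af_population(8, seed = 61, p_captive = 1)
  tab <- simulate_feature_table(pop$bats, calls_per_bat = 50, seed = 62)
  residents <- pop$bats$bat_id[pop$bats$site == "site1"]
  focals <- pop$bats$bat_id[pop$bats$site == "site2"]
  pp <- pre_post_similarity(tab, tab, list(residents = residents,
                                           focals = focals), min_calls = 40)
  expect_lt(max(abs(pp$delta)), 1e-10)
  # swapping the epochs negates the change matrix exactly
  tab2 <- simulate_feature_table(pop$bats, calls_per_bat = 50, seed = 63)
  a <- pre_post_similarity(tab, tab2, list(residents = residents,
                                           focals = focals), min_calls = 40)
  b <- pre_post_similarity(tab2, tab, list(residents = residents,
                                           focals = focals), min_calls = 40)
  expect_equal(a$delta, -b$delta)
  expect_error(pre_post_similarity(tab[tab$bat_id != focals[1], ], tab,
                                   list(residents = residents,
                                        focals = focals)), "missing")
})

test_that("Mantel permutations preserve values and detect association", {
  m1 <- make_sym(8, 71)
  # indicator derived from m1 itself: perfect association
  ind <- (m1 > median(m1[lower.tri(m1)])) * 1
  diag(ind) <- 0
  mt <- mantel_spearman(m1, ind, n_perm = 199, seed = 3)
  expect_equal(mt$p, 1 / 200)
  expect_gt(mt$statistic, 0.5)
  # permutation null preserves the multiset of values by construction:
  # every null draw is a statistic of the same matrix under relabelling
  expect_true(all(is.finite(mt$null)))
  mt2 <- mantel_spearman(m1, ind, n_perm = 199, seed = 3)
  expect_identical(mt2$null, mt$null)
  expect_error(mantel_spearman(m1, ind * 0, n_perm = 10), "constant")
  expect_error(mantel_spearman(m1[1:3, 1:3], ind[1:3, 1:3], 10), "4 individuals")
})

test_that("exact Mantel p matches brute-force enumeration at n = 5", {
  m1 <- make_sym(5, 81)
  m2 <- make_sym(5, 82)
  res <- mantel_spearman(m1, m2, n_perm = "exact")
  # independent enumeration with plain loops
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  lower <- lower.tri(m1)
  obs <- cor(m1[lower], m2[lower], method = "spearman")
  null <- apply(perms, 1, function(p) {
    mp <- m2[p, p]
    cor(m1[lower], mp[lower], method = "spearman")
  })
  expect_equal(nrow(perms), 120)
  expect_equal(res$n_perm, 120)
  expect_equal(res$p, sum(null >= obs) / 120)
  # the observed statistic agrees with the independent implementation
  expect_equal(res$statistic, obs)
  # and with vegan's Mantel statistic on the same matrices
  skip_if_not_installed("vegan")
  veg <- vegan::mantel(as.dist(m1), as.dist(m2), method = "spearman",
                       permutations = 9)
  expect_equal(res$statistic, unname(veg$statistic))
})

test_that("the permuted site DFA respects nesting and ranks separability", {
  pop <- af_population(10, seed = 91, p_captive = 1,
                       spec = convergence_spec(0, 0))
  tab <- simulate_feature_table(pop$bats, calls_per_bat = 40, seed = 92)
  tab$site <- pop$bats$site[match(tab$bat_id, pop$bats$bat_id)]
  res <- pdfa_site(tab, n_perm = 30, seed = 5)
  expect_true(res$observed >= 0 && res$observed <= 1)
  expect_length(res$null, 30)
  expect_true(res$p > 0 && res$p <= 1)
  # a site with a single bat cannot be permuted or held out
  tab1 <- tab[tab$bat_id %in% c(pop$bats$bat_id[pop$bats$site == "site1"],
                                pop$bats$bat_id[pop$bats$site == "site2"][1]), ]
  expect_error(pdfa_site(tab1, n_perm = 10), "at least 2 bats")
  # strongly separated site signatures: accuracy near 1, minimal p
  pop2 <- af_population(10, seed = 93, p_captive = 1)
  pop2$bats$f_start <- pop2$bats$f_start +
    ifelse(pop2$bats$site == "site1", -20, 20)
  tab2 <- simulate_feature_table(pop2$bats, calls_per_bat = 40, seed = 94)
  tab2$site <- pop2$bats$site[match(tab2$bat_id, pop2$bats$bat_id)]
  res2 <- pdfa_site(tab2, n_perm = 30, seed = 6)
  expect_gt(res2$observed, 0.9)
  expect_equal(res2$p, 1 / 31)
})
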