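#' Convergence specification for the synthetic population
#'
#' Controls how co-housing and food-sharing bonds pull individual
#' frequency-modulation (FM) contour signatures together in the generator.
#' `delta_cohouse` is the fraction by which each co-housed bat's contour
#' parameter means move toward its captive group's mean; `delta_bond` is the
#' additional fraction moved toward specific partners, weighted by each pair's
#' food-sharing lograte. Together they implement the two causal paths of
#' interest: group-level acoustic exposure and bond-specific convergence.
#'
#' @param delta_cohouse fraction in `[0, 1]`; default 0.25.
#' @param delta_bond fraction in `[0, 1]`; default 0.15.
#'   `delta_cohouse + delta_bond` must not exceed 1.
#' @param seed optional RNG seed recorded with the spec.
#' @return An object of class `convergence_spec`.
#' @export
convergence_spec <- function(delta_cohouse = 0.25, delta_bond = 0.15, seed = NULL) {
  if (delta_cohouse < 0 || delta_cohouse > 1) stop("`delta_cohouse` must be in [0, 1]")
  if (delta_bond < 0 || delta_bond > 1) stop("`delta_bond` must be in [0, 1]")
  if (delta_cohouse + delta_bond > 1)
    stop("`delta_cohouse` + `delta_bond` must be <= 1")
  structure(list(delta_cohouse = delta_cohouse, delta_bond = delta_bond,
                 seed = seed), class = "convergence_spec")
}

# FM-contour parameter columns a bat's vocal signature lives in.
contour_cols <- function() c("f_start", "f_end", "duration_ms", "curvature")

#' Generate a synthetic bat population with social structure
#'
#' Creates per-bat FM-contour signatures (exponential-decay downward sweeps:
#' start/end frequency, duration, curvature), origin sites, sex and age
#' classes, heavy-tailed planned call counts, and a full dyadic social
#' structure: kinship, co-housing, familiarity classes, and observed seconds
#' of allogrooming and food sharing with sampling effort.
#'
#' A fraction `p_captive` of each site's bats is "captured" into one shared
#' captive colony; pairs within it are co-housed (`introduced-cohoused` across
#' sites, `same-site-cohoused` within a site). Pairs not both in the colony
#' are `never-met` (different sites, zero interaction) or `unknown` (same
#' site, kinship unrecorded). Call counts are lognormal, parameterized by
#' median and truncated to `[100, 100000]`, matching the strong right skew of
#' per-individual call-sample sizes in isolation-recording studies.
#'
#' @param n_bats number of bats (>= 2).
#' @param n_sites number of origin sites (>= 1).
#' @param config a [convergence_spec()] (carried through to
#'   [apply_convergence()]).
#' @param seed RNG seed; identical seeds give bit-identical populations.
#' @param p_captive fraction of each site's bats placed in the captive colony.
#' @param median_calls median of the per-bat call-count distribution.
#' @param sdlog_calls lognormal log-scale SD of call counts (default 1.464
#'   reproduces a mean near 7300 when the median is 2500).
#' @param p_kin probability a same-site pair is kin (coefficient drawn from
#'   {0.5, 0.25, 0.125}).
#' @param p_share probability a co-housed pair has a food-sharing relationship.
#' @param p_share_unknown probability a co-housed pair's food-sharing rate was
#'   never sampled (share seconds recorded as missing).
#' @param site_sd named SDs of per-site mean offsets on the four contour
#'   parameters. Sites separated by large distances carry group-level call
#'   signatures (founder effects plus prior within-site convergence); these
#'   offsets are what site-classification analyses detect and what merging
#'   groups erodes.
#' @return A list of class `bat_population` with elements `bats` (data frame,
#'   one row per bat: identifiers, site, sex, age class, contour-parameter
#'   means, within-bat SDs, planned call count) and `social` (a
#'   `social_structure`: named symmetric matrices `kinship`, `cohoused`,
#'   `groom_seconds`, `share_seconds`, `sampling_seconds`,
#'   `share_sampling_seconds`, `familiarity_class`).
#' @export
make_population <- function(n_bats, n_sites, config = convergence_spec(),
                            seed = 1L, p_captive = 0.75,
                            median_calls = 2500, sdlog_calls = 1.464,
                            p_kin = 0.25, p_share = 0.35,
                            p_share_unknown = 0.3,
                            site_sd = c(f_start = 4, f_end = 2,
                                        duration_ms = 2.5, curvature = 0.3)) {
  stopifnot_scalar_count(n_bats, "n_bats", min = 2L)
  stopifnot_scalar_count(n_sites, "n_sites", min = 1L)
  with_seed(seed, {
    ids <- sprintf("bat%02d", seq_len(n_bats))
    site <- sprintf("site%d", rep_len(seq_len(n_sites), n_bats))
    sex <- sample(c("F", "M"), n_bats, replace = TRUE, prob = c(0.75, 0.25))
    age_class <- ifelse(sex == "M",
                        sample(c("adult", "subadult"), n_bats, TRUE, c(0.4, 0.6)),
                        sample(c("adult", "subadult"), n_bats, TRUE, c(0.85, 0.15)))
    bats <- data.frame(
      bat_id = ids, site = site, sex = sex, age_class = age_class,
      f_start = pmin(pmax(rnorm(n_bats, 65, 8), 40), 95),
      f_end = pmin(pmax(rnorm(n_bats, 22, 3), 12), 35),
      duration_ms = pmin(pmax(rnorm(n_bats, 20, 5), 5), 45),
      curvature = pmin(pmax(rnorm(n_bats, 2, 0.6), 0.3), 5),
      sd_f_start = 2, sd_f_end = 1, sd_duration_ms = 1.5, sd_curvature = 0.2,
      stringsAsFactors = FALSE)
    for (col in contour_cols()) {
      offs <- rnorm(n_sites, 0, site_sd[[col]])
      bats[[col]] <- bats[[col]] + offs[match(site, sprintf("site%d", seq_len(n_sites)))]
    }
    bats$f_end <- pmin(pmax(bats$f_end, 12), 35)
    bats$duration_ms <- pmin(pmax(bats$duration_ms, 5), 45)
    bats$curvature <- pmin(pmax(bats$curvature, 0.3), 5)
    bats$f_start <- pmax(bats$f_start, bats$f_end + 15)
    bats$n_calls <- rtrunc_lnorm(n_bats, meanlog = log(median_calls),
                                 sdlog = sdlog_calls, lo = 100, hi = 1e5)
    captive <- runif(n_bats) < p_captive

    m0 <- function(fill = 0) {
      m <- matrix(fill, n_bats, n_bats, dimnames = list(ids, ids))
      diag(m) <- NA
      m
    }
    kinship <- m0(); cohoused <- m0(FALSE)
    groom <- m0(); share <- m0(); sampl <- m0(); share_sampl <- m0()
    fam <- m0(NA_character_)

    for (i in seq_len(n_bats - 1L)) for (j in seq((i + 1L), n_bats)) {
      same_site <- site[i] == site[j]
      both_cap <- captive[i] && captive[j]
      k <- if (same_site) {
        if (runif(1) < p_kin) sample(c(0.5, 0.25, 0.125), 1) else 0
      } else 0
      f <- if (both_cap && same_site) "same-site-cohoused"
      else if (both_cap) "introduced-cohoused"
      else if (same_site) "unknown"
      else "never-met"
      if (f == "unknown") k <- NA_real_
      s_eff <- 0; g_s <- 0; sh_s <- 0; sh_eff <- 0
      if (both_cap) {
        s_eff <- round(rlnorm(1, log(20000), 0.4))
        g_s <- round(s_eff * rbeta(1, 1.5, 30))
        if (runif(1) < p_share_unknown) {
          sh_eff <- NA_real_; sh_s <- NA_real_
        } else {
          sh_eff <- s_eff
          sh_s <- if (runif(1) < p_share) round(s_eff * rbeta(1, 1.2, 50)) else 0
        }
        tot <- g_s + ifelse(is.na(sh_s), 0, sh_s)
        if (tot > s_eff - 1) g_s <- max(0, s_eff - 1 - ifelse(is.na(sh_s), 0, sh_s))
      }
      kinship[i, j] <- kinship[j, i] <- k
      cohoused[i, j] <- cohoused[j, i] <- both_cap
      groom[i, j] <- groom[j, i] <- g_s
      share[i, j] <- share[j, i] <- sh_s
      sampl[i, j] <- sampl[j, i] <- s_eff
      share_sampl[i, j] <- share_sampl[j, i] <- sh_eff
      fam[i, j] <- fam[j, i] <- f
    }
    social <- structure(list(kinship = kinship, cohoused = cohoused,
                             groom_seconds = groom, share_seconds = share,
                             sampling_seconds = sampl,
                             share_sampling_seconds = share_sampl,
                             familiarity_class = fam),
                        class = "social_structure")
    structure(list(bats = bats, social = social, config = config, seed = seed),
              class = "bat_population")
  })
}

# Lognormal truncated to [lo, hi] by inverse-CDF sampling.
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  round(stats::qlnorm(runif(n, plo, phi), meanlog, sdlog))
}

#' @export
print.bat_population <- function(x, ...) {
  cat(sprintf("<bat_population: %d bats, %d sites, %d co-housed pairs>\n",
              nrow(x$bats), length(unique(x$bats$site)),
              sum(x$social$cohoused[upper.tri(x$social$cohoused)])))
  invisible(x)
}

#' Apply vocal convergence to a population's contour signatures
#'
#' Moves co-housed bats' FM-contour parameter means toward their captive
#' group's mean by fraction `delta_cohouse`, then applies an additional
#' partner-specific shift of up to fraction `delta_bond` toward food-sharing
#' partners, weighted by each pair's food-sharing lograte. Never-met bats are
#' untouched. Only the parameter means change; within-bat SDs are preserved,
#' so convergence moves caller centroids without altering within-caller
#' variance.
#'
#' With `scope = "within-site"` the co-housing (and food-sharing) graph is
#' restricted to same-site pairs: this models the state of an introduction
#' experiment *before* groups are merged, when each site's bats had already
#' converged among themselves. Applying the same spec at scope `"all"` to the
#' same starting profiles gives the post-introduction state; within-site
#' pairwise distances are then identical between the two states, so any
#' pre/post similarity change is confined to the newly introduced
#' (cross-site) pairs.
#'
#' @param bats the `bats` data frame of a [make_population()] result (or a
#'   whole `bat_population`, in which case it is returned with `bats` updated).
#' @param social the matching `social_structure`.
#' @param spec a [convergence_spec()].
#' @param scope `"all"` (default) converges every co-housed pair;
#'   `"within-site"` only pairs from the same origin site.
#' @return The profiles with shifted contour means, same shape as the input.
#' @export
apply_convergence <- function(bats, social, spec = NULL,
                              scope = c("all", "within-site")) {
  scope <- match.arg(scope)
  if (inherits(bats, "bat_population")) {
    pop <- bats
    if (is.null(spec)) spec <- pop$config     # the spec the population carries
    pop$bats <- apply_convergence(pop$bats, pop$social, spec, scope)
    return(pop)
  }
  if (is.null(spec)) spec <- convergence_spec()
  stopifnot(inherits(spec, "convergence_spec"))
  n <- nrow(bats)
  if (!all(dim(social$cohoused) == c(n, n)))
    stop("social matrices do not conform to the profile list")
  cols <- contour_cols()
  mu <- as.matrix(bats[, cols])

  # group shrink: connected components of the co-housing graph
  co <- social$cohoused; co[is.na(co)] <- FALSE
  if (scope == "within-site")
    co <- co & outer(bats$site, bats$site, "==")
  comp <- graph_components(co)
  mu1 <- mu
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (length(members) < 2L) next
    center <- colMeans(mu[members, , drop = FALSE])
    mu1[members, ] <- mu[members, , drop = FALSE] +
      spec$delta_cohouse *
      (matrix(center, length(members), length(cols), byrow = TRUE) -
         mu[members, , drop = FALSE])
  }

  # bond shift: weighted pull toward food-sharing partners (same restricted
  # graph as the group shrink)
  if (spec$delta_bond > 0) {
    w <- sharing_lograte_matrix(social)
    w[!co | is.na(w)] <- 0
    wsum <- rowSums(w)
    wmax <- max(wsum)
    if (wmax > 0) {
      mu2 <- mu1
      for (i in seq_len(n)) {
        if (wsum[i] == 0) next
        pull <- colSums(w[i, ] * sweep(mu1, 2, mu1[i, ])) / wmax
        mu2[i, ] <- mu1[i, ] + spec$delta_bond * pull
      }
      mu1 <- mu2
    }
  }
  bats[, cols] <- mu1
  bats
}

# Pairwise food-sharing lograte matrix, log(share+1)/log(sampling); 0 where
# sharing was observed to be absent, NA where unobserved.
sharing_lograte_matrix <- function(social) {
  s <- social$share_seconds
  eff <- social$share_sampling_seconds
  out <- s * NA_real_
  ok <- !is.na(s) & !is.na(eff) & eff > 1
  out[ok] <- log(s[ok] + 1) / log(eff[ok])
  out
}

# Connected-component labels of a symmetric logical adjacency matrix.
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(adj[v, ] %in% TRUE)
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

#' Mean pairwise contour-parameter distance within a set of bats
#'
#' Euclidean distance over the four FM-contour parameter means, averaged over
#' the given pairs. Used to verify that convergence shrinks signature spread.
#'
#' @param bats bat profile data frame.
#' @param pairs two-column matrix of row indices (default: all pairs).
#' @return Mean pairwise distance (single number).
#' @export
contour_distance <- function(bats, pairs = NULL) {
  mu <- as.matrix(bats[, contour_cols()])
  if (is.null(pairs)) pairs <- t(combn(nrow(bats), 2))
  mean(sqrt(rowSums((mu[pairs[, 1], , drop = FALSE] -
                       mu[pairs[, 2], , drop = FALSE])^2)))
}
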