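#' Affiliation lograte
#'
#' `log(observed + 1) / log(sampling)`: seconds of observed affiliative
#' behaviour scaled by sampling effort on a log scale, mapping 0 observed
#' seconds to 0 and `sampling - 1` observed seconds to 1. Vectorized; NA
#' inputs propagate.
#'
#' @param observed seconds of observed behaviour (>= 0).
#' @param sampling seconds of sampling effort (> 1).
#' @return lograte in `[0, 1]` (for `observed <= sampling - 1`).
#' @export
affiliation_lograte <- function(observed, sampling) {
  bad <- !is.na(sampling) & sampling <= 1
  if (any(bad)) stop("`sampling` must be > 1 seconds")
  if (any(!is.na(observed) & observed < 0)) stop("`observed` must be >= 0")
  log(observed + 1) / log(sampling)
}

#' z-transform a numeric column
#'
#' Centres to mean 0 and scales to sample SD 1 (denominator `n - 1`).
#' Missing entries are ignored in the moments and propagate to the output.
#'
#' @param values numeric vector with at least 2 distinct non-missing values.
#' @return Scaled vector.
#' @export
z_scale <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) stop("cannot z-scale a constant column")
  (values - mean(v)) / sd(v)
}

#' Build the dyad table
#'
#' One record per unordered pair of bats with a similarity score: kinship,
#' co-housing flag, familiarity class, site/sex/age composition, affiliation
#' lograte (allogrooming + food-sharing seconds pooled before the lograte
#' transform) and food-sharing lograte. Never-met pairs get affiliation and
#' sharing rates of exactly 0 (they could not have interacted); co-housed
#' pairs whose food sharing was never sampled get a missing sharing lograte.
#'
#' @param similarity a `similarity_matrix` (or plain symmetric matrix with
#'   bat-id dimnames).
#' @param social a `social_structure` (see [make_population()]).
#' @param bats bat metadata data frame (`bat_id`, `site`, `sex`, `age_class`).
#' @return Data frame of class `dyad_table`, `choose(n, 2)` rows.
#' @export
build_dyad_table <- function(similarity, social, bats) {
  ids <- rownames(similarity)
  if (is.null(ids)) stop("similarity matrix needs bat-id dimnames")
  if (!all(ids %in% bats$bat_id) || !all(ids %in% rownames(social$kinship)))
    stop("bat identifiers do not match between similarity, social and metadata")
  meta <- bats[match(ids, bats$bat_id), ]
  n <- length(ids)
  pr <- t(combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  gi <- ids[i]; gj <- ids[j]
  sampl <- social$sampling_seconds[cbind(gi, gj)]
  groom <- social$groom_seconds[cbind(gi, gj)]
  share <- social$share_seconds[cbind(gi, gj)]
  share_eff <- social$share_sampling_seconds[cbind(gi, gj)]
  fam <- social$familiarity_class[cbind(gi, gj)]
  never <- fam == "never-met"

  aff <- ifelse(never, 0,
                ifelse(!is.na(sampl) & sampl > 1,
                       affiliation_lograte(groom + ifelse(is.na(share), 0, share),
                                           ifelse(sampl > 1, sampl, 2)),
                       NA_real_))
  shr <- ifelse(never, 0,
                ifelse(!is.na(share_eff) & share_eff > 1,
                       log(share + 1) / log(share_eff), NA_real_))
  out <- data.frame(
    bat_i = gi, bat_j = gj,
    similarity = similarity[cbind(gi, gj)],
    kinship = social$kinship[cbind(gi, gj)],
    cohoused = social$cohoused[cbind(gi, gj)] %in% TRUE,
    familiarity_class = fam,
    same_site = meta$site[i] == meta$site[j],
    both_adult_female = meta$sex[i] == "F" & meta$sex[j] == "F" &
      meta$age_class[i] == "adult" & meta$age_class[j] == "adult",
    sampling_seconds = sampl, groom_seconds = groom, share_seconds = share,
    share_sampling_seconds = share_eff,
    affiliation_lograte = aff, sharing_lograte = shr,
    stringsAsFactors = FALSE)
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Specification of one dyadic regression model
#'
#' The five-model battery disentangles kinship, co-housing and affiliation
#' effects on dyadic call similarity:
#' \describe{
#'   \item{1}{kinship only; pairs with estimated kinship.}
#'   \item{2}{kinship + co-housing + affiliation lograte (zeros for pairs
#'     that never met); pairs with estimated kinship.}
#'   \item{3}{co-housing only; non-kin (kinship 0) adult-female pairs from
#'     different sites.}
#'   \item{4}{affiliation lograte; adult-female pairs caged together with
#'     kinship at most 0.05 and observed affiliation sampling.}
#'   \item{5}{food-sharing lograte; as model 4 restricted to pairs with
#'     known food-sharing rates.}
#' }
#'
#' @param model_id integer 1-5.
#' @return List of class `model_spec`: `model_id`, `predictors`,
#'   `scale_continuous`, `select` (predicate function on a dyad table).
#' @export
model_spec <- function(model_id) {
  stopifnot(model_id %in% 1:5)
  specs <- list(
    list(predictors = "kinship",
         select = function(d) !is.na(d$kinship)),
    list(predictors = c("kinship", "cohoused", "affiliation_lograte"),
         select = function(d) !is.na(d$kinship) & !is.na(d$affiliation_lograte)),
    list(predictors = "cohoused",
         select = function(d) !is.na(d$kinship) & d$kinship == 0 &
           d$both_adult_female & !d$same_site),
    list(predictors = "affiliation_lograte",
         select = function(d) !is.na(d$kinship) & d$kinship <= 0.05 &
           d$both_adult_female & d$cohoused & !is.na(d$affiliation_lograte)),
    list(predictors = "sharing_lograte",
         select = function(d) !is.na(d$kinship) & d$kinship <= 0.05 &
           d$both_adult_female & d$cohoused & !is.na(d$sharing_lograte)))
  s <- specs[[model_id]]
  structure(list(model_id = model_id, predictors = s$predictors,
                 scale_continuous = setdiff(s$predictors, "cohoused"),
                 select = s$select),
            class = "model_spec")
}

#' Select the dyads a model applies to
#'
#' @param records a `dyad_table`.
#' @param spec a [model_spec()] (or a model id 1-5).
#' @return The subset of `records` satisfying the model's inclusion
#'   predicate. Warns when the selection is empty.
#' @export
select_dyads <- function(records, spec) {
  if (is.numeric(spec)) spec <- model_spec(spec)
  out <- records[spec$select(records), , drop = FALSE]
  if (nrow(out) == 0L)
    warning(sprintf("model %d selects no dyads", spec$model_id))
  out
}
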