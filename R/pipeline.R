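#' Default pipeline configuration
#'
#' A complete nested run configuration: synthetic-population settings,
#' recording and detection parameters, feature extraction, the call filters,
#' similarity settings, the model battery and the pre/post convergence test.
#' Every stochastic stage draws a sub-seed derived from the global seed and
#' the stage name, recorded in the run manifest.
#'
#' @param out_dir output directory of the run.
#' @param seed global RNG seed.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(out_dir = "vc-run", seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, detect = TRUE, features = TRUE,
                  similarity = TRUE, models = TRUE, convergence = TRUE),
    population = list(n_bats = 12L, n_sites = 2L, p_captive = 0.75,
                      median_calls = 2500, calls_per_session = 200L),
    convergence = list(delta_cohouse = 0.25, delta_bond = 0.15),
    recording = list(rate = 250000, noise_db = 30, background_rms = 0.002),
    detection = list(envelope_ms = 0.5, threshold_k = 5, merge_gap_ms = 2,
                     spectral_min_khz = 10, spectral_frac = 0.7),
    features = list(window = 256L, overlap = 0.75, band = c(10, 125)),
    filters = list(min_ms = 3, max_ms = 50, min_peak_khz = 10,
                   clip_limit = 0.99, min_calls = 100L,
                   similarity_floor = 0.001),
    models = list(run = c(1L, 2L, 3L), chains = 4L, iter = 6000L,
                  warmup = 2000L),
    convergence_test = list(n_perm = 1000L)),
    class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Values in the file override the defaults; unspecified settings keep their
#' default values.
#'
#' @param path YAML file.
#' @param ... passed to [default_config()] (e.g. `out_dir`).
#' @return A `run_config`.
#' @export
load_config <- function(path, ...) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(...)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "run_config")
}

#' Validate a run configuration
#'
#' Schema and range checks: the call filters must match the analysis
#' contract (duration bounds within 3-50 ms, positive similarity floor,
#' minimum call count), rates must be supported, permutation and MCMC counts
#' positive, and — when the simulate stage is off — the expected input files
#' must already exist under `out_dir`.
#'
#' @param config a `run_config`.
#' @return Data frame of class `validation_report` (`check`, `ok`,
#'   `message`) with attribute `valid`.
#' @export
validate_config <- function(config) {
  checks <- list()
  add <- function(name, ok, msg = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = name, ok = ok,
                                                 message = if (ok) "" else msg)
  }
  f <- config$filters
  add("duration_bounds", isTRUE(f$min_ms >= 3 && f$max_ms <= 50 &&
                                  f$min_ms < f$max_ms),
      "duration filter must lie within [3, 50] ms")
  add("peak_cut", isTRUE(f$min_peak_khz > 0), "peak-frequency cut must be > 0")
  add("similarity_floor", isTRUE(f$similarity_floor > 0 &&
                                   f$similarity_floor < 0.05),
      "similarity floor must be a small positive value")
  add("min_calls", isTRUE(f$min_calls >= 1), "min_calls must be >= 1")
  add("clip_limit", isTRUE(f$clip_limit > 0 && f$clip_limit <= 1),
      "clip limit must be in (0, 1]")
  add("rate", isTRUE(config$recording$rate %in% c(250000, 500000)),
      "rate must be 250000 or 500000")
  add("n_bats", isTRUE(config$population$n_bats >= 2), "need >= 2 bats")
  add("n_perm", isTRUE(config$convergence_test$n_perm >= 1),
      "n_perm must be >= 1")
  add("mcmc", isTRUE(config$models$iter > config$models$warmup &&
                       config$models$chains >= 1),
      "iter must exceed warmup; chains >= 1")
  dc <- config$convergence
  add("convergence_deltas",
      isTRUE(dc$delta_cohouse >= 0 && dc$delta_bond >= 0 &&
               dc$delta_cohouse + dc$delta_bond <= 1),
      "delta_cohouse + delta_bond must be <= 1 with both nonnegative")
  if (!isTRUE(config$stages$simulate)) {
    add("input_audio", dir.exists(file.path(config$out_dir, "audio")),
        sprintf("missing input path: %s (simulate stage is off)",
                file.path(config$out_dir, "audio")))
  }
  out <- do.call(rbind, checks)
  attr(out, "valid") <- all(out$ok)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Run the analysis pipeline
#'
#' Executes the toggled stages in order — simulate, detect, features,
#' similarity, models, convergence — reading each stage's inputs from and
#' writing its outputs to `config$out_dir`, so a run can resume from any
#' stage whose inputs already exist. Writes a JSON manifest recording the
#' configuration, per-stage seeds, per-filter call accounting and MD5 hashes
#' of every output file.
#'
#' @param config a `run_config`; validated before anything runs.
#' @return The manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  report <- validate_config(config)
  if (!attr(report, "valid")) {
    bad <- report[!report$ok, ]
    stop("invalid configuration:\n",
         paste(sprintf("- %s: %s", bad$check, bad$message), collapse = "\n"))
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  outputs <- character(0)

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      manifest$stages[[name]] <<- list(skipped = TRUE)
      message(sprintf("[%s] skipped", name))
      return(invisible(NULL))
    }
    seed <- derive_seed(config$seed, name)
    info <- tryCatch(fun(seed),
                     error = function(e) stop(sprintf("stage `%s` failed: %s",
                                                      name, conditionMessage(e)),
                                              call. = FALSE))
    manifest$stages[[name]] <<- c(list(skipped = FALSE, seed = seed), info)
    outputs <<- union(outputs, info$files)
    invisible(NULL)
  }

  run_stage("simulate", function(seed) pipeline_simulate(config, seed))
  run_stage("detect", function(seed) pipeline_detect(config))
  run_stage("features", function(seed) pipeline_features(config))
  run_stage("similarity", function(seed) pipeline_similarity(config))
  run_stage("models", function(seed) pipeline_models(config, seed))
  run_stage("convergence", function(seed) pipeline_convergence(config, seed))

  manifest$hashes <- as.list(tools::md5sum(
    outputs[order(basename(outputs))]))
  names(manifest$hashes) <- basename(names(manifest$hashes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("run complete: %d output files in %s", length(outputs), out_dir))
  invisible(manifest)
}

pipeline_simulate <- function(config, seed) {
  pc <- config$population
  spec <- convergence_spec(config$convergence$delta_cohouse,
                           config$convergence$delta_bond)
  pop0 <- make_population(pc$n_bats, pc$n_sites, config = spec,
                          seed = derive_seed(seed, "population"),
                          p_captive = pc$p_captive,
                          median_calls = pc$median_calls)
  pop <- apply_convergence(pop0)
  audio_dir <- file.path(config$out_dir, "audio")
  files <- character(0)
  epochs <- list(post = pop$bats)
  if (isTRUE(config$stages$convergence)) {
    # pre-introduction state: convergence restricted to same-site pairs
    pre_pop <- apply_convergence(pop0, scope = "within-site")
    captive <- captive_bats(pop$social)
    sites <- pop$bats$site[match(captive, pop$bats$bat_id)]
    focal_site <- sort(unique(sites))[length(unique(sites))]
    focals <- captive[sites == focal_site]
    epochs$pre <- pre_pop$bats[pre_pop$bats$bat_id %in% focals, ]
  }
  rc <- config$recording
  for (ep in names(epochs)) {
    for (k in seq_len(nrow(epochs[[ep]]))) {
      bat <- epochs[[ep]][k, ]
      sess <- generate_recording_session(
        bat, pc$calls_per_session, rate = rc$rate,
        seed = derive_seed(seed, paste(ep, bat$bat_id)),
        noise_db = rc$noise_db, background_rms = rc$background_rms)
      files <- c(files, write_session(sess, audio_dir,
                                      paste(bat$bat_id, ep, sep = "_")))
    }
  }
  pop_csv <- file.path(config$out_dir, "population.csv")
  write.csv(pop$bats, pop_csv, row.names = FALSE)
  social_files <- write_social(pop$social, config$out_dir)
  truth_json <- file.path(config$out_dir, "ground_truth.json")
  jsonlite::write_json(list(seed = seed, delta_cohouse = spec$delta_cohouse,
                            delta_bond = spec$delta_bond,
                            pre_profiles = pop0$bats),
                       truth_json, auto_unbox = TRUE, digits = NA)
  message(sprintf("[simulate] %d bats, %d sessions", nrow(pop$bats),
                  length(files) / 2))
  list(files = unname(c(files, pop_csv, social_files, truth_json)),
       n_bats = nrow(pop$bats))
}

pipeline_detect <- function(config) {
  audio_dir <- file.path(config$out_dir, "audio")
  wavs <- list.files(audio_dir, pattern = "\\.wav$", full.names = TRUE)
  if (length(wavs) == 0L) stop("no WAV files under ", audio_dir)
  params <- do.call(detect_params, config$detection)
  segs <- lapply(sort(wavs), function(p) {
    w <- read_wav(p)
    if (w$rate > 250000) w <- resample_to_250k(w)
    name <- sub("\\.wav$", "", basename(p))
    s <- detect_calls(w, params, source = name)
    s <- measure_peaks(w, s)
    s
  })
  seg_tab <- do.call(rbind, segs)
  n_detected <- nrow(seg_tab)
  f <- config$filters
  seg_tab <- filter_calls(seg_tab, f$min_ms, f$max_ms, f$min_peak_khz)
  n_dur <- nrow(seg_tab)
  path <- file.path(config$out_dir, "segments.csv")
  write.csv(seg_tab, path, row.names = FALSE)
  message(sprintf("[detect] %d segments detected, %d after duration/frequency filters",
                  n_detected, n_dur))
  list(files = path, detected = n_detected, kept = n_dur)
}

pipeline_features <- function(config) {
  seg_tab <- read.csv(file.path(config$out_dir, "segments.csv"),
                      stringsAsFactors = FALSE)
  audio_dir <- file.path(config$out_dir, "audio")
  fc <- config$features
  tabs <- lapply(split(seg_tab, seg_tab$source), function(ss) {
    w <- read_wav(file.path(audio_dir, paste0(ss$source[1], ".wav")))
    if (w$rate > 250000) w <- resample_to_250k(w)
    ss <- remove_clipped(ss, w, config$filters$clip_limit)
    if (nrow(ss) == 0L) return(NULL)
    calls <- segment_waveform(w, ss)
    bat <- sub("_(pre|post)$", "", ss$source[1])
    tb <- extract_features(calls, bat_id = bat, band = fc$band,
                           window = fc$window, overlap = fc$overlap)
    tb$epoch <- sub("^.*_", "", ss$source[1])
    tb
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  path <- file.path(config$out_dir, "features.csv")
  write.csv(tab, path, row.names = FALSE)
  message(sprintf("[features] %d calls x %d features", nrow(tab), 35L))
  list(files = path, n_calls = nrow(tab))
}

pipeline_similarity <- function(config) {
  tab <- read.csv(file.path(config$out_dir, "features.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[tab$epoch == "post", ]
  n_before <- length(unique(tab$bat_id))
  tab <- filter_bats_min_calls(tab, config$filters$min_calls)
  n_after <- length(unique(tab$bat_id))
  model <- fit_dfa(tab[, c("bat_id", as.character(feature_names()))])
  D <- centroid_mahalanobis_matrix(model)
  S <- similarity_from_distances(D, floor = config$filters$similarity_floor)
  cv <- classify_loocv(tab[, c("bat_id", as.character(feature_names()))])
  d_path <- file.path(config$out_dir, "distances.csv")
  s_path <- file.path(config$out_dir, "similarity.csv")
  j_path <- file.path(config$out_dir, "dfa_summary.json")
  write.csv(as.data.frame(D), d_path)
  write.csv(as.data.frame(unclass(S)), s_path)
  jsonlite::write_json(list(n_bats = n_after, bats_removed = n_before - n_after,
                            loocv_overall = cv$overall,
                            loocv_per_bat = as.list(cv$per_bat),
                            max_D = attr(S, "max_D")),
                       j_path, auto_unbox = TRUE, digits = NA)
  message(sprintf("[similarity] %d bats (removed %d below min calls), LOOCV accuracy %.3f",
                  n_after, n_before - n_after, cv$overall))
  list(files = c(d_path, s_path, j_path), loocv = cv$overall)
}

pipeline_models <- function(config, seed) {
  S <- as.matrix(read.csv(file.path(config$out_dir, "similarity.csv"),
                          row.names = 1, check.names = FALSE))
  social <- read_social(config$out_dir)
  bats <- read.csv(file.path(config$out_dir, "population.csv"),
                   stringsAsFactors = FALSE)
  dyads <- build_dyad_table(S, social, bats)
  d_path <- file.path(config$out_dir, "dyads.csv")
  write.csv(dyads, d_path, row.names = FALSE)
  mc <- mcmc_control(config$models$chains, config$models$iter,
                     config$models$warmup, seed = seed)
  battery <- run_model_battery(dyads, mcmc = mc, models = config$models$run)
  c_path <- file.path(config$out_dir, "battery_coefficients.csv")
  write.csv(battery$coefficients, c_path, row.names = FALSE)
  j_path <- file.path(config$out_dir, "battery_summaries.json")
  jsonlite::write_json(lapply(battery$fits, function(f) f$summary),
                       j_path, auto_unbox = TRUE, digits = NA)
  message(sprintf("[models] fitted models %s on %d dyads",
                  paste(config$models$run, collapse = ","), nrow(dyads)))
  list(files = c(d_path, c_path, j_path), n_dyads = nrow(dyads))
}

pipeline_convergence <- function(config, seed) {
  tab <- read.csv(file.path(config$out_dir, "features.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
  bats <- read.csv(file.path(config$out_dir, "population.csv"),
                   stringsAsFactors = FALSE)
  focals <- unique(tab$bat_id[tab$epoch == "pre"])
  if (length(focals) == 0L) stop("no pre-introduction recordings found")
  social <- read_social(config$out_dir)
  residents <- setdiff(captive_bats(social), focals)
  design <- list(residents = residents, focals = focals)
  feats_post <- tab[tab$epoch == "post", ]
  feats_pre <- rbind(feats_post[feats_post$bat_id %in% residents, ],
                     tab[tab$epoch == "pre", ])
  pp <- pre_post_similarity(feats_pre, feats_post, design,
                            min_calls = config$filters$min_calls,
                            floor = config$filters$similarity_floor)
  site <- setNames(bats$site, bats$bat_id)
  recs <- delta_records(pp$delta, site)
  mt <- mantel_spearman(pp$delta,
                        outer(site[rownames(pp$delta)],
                              site[colnames(pp$delta)], "!=") * 1,
                        n_perm = config$convergence_test$n_perm,
                        seed = derive_seed(seed, "mantel"))
  gm <- fit_gaussian_mm(recs, "introduced",
                        mcmc = mcmc_control(config$models$chains,
                                            config$models$iter,
                                            config$models$warmup,
                                            seed = derive_seed(seed, "gaussian")))
  pd_pre <- pdfa_site(merge_site(feats_pre, bats),
                      n_perm = min(config$convergence_test$n_perm, 100),
                      seed = derive_seed(seed, "pdfa_pre"))
  pd_post <- pdfa_site(merge_site(feats_post[feats_post$bat_id %in%
                                               c(residents, focals), ], bats),
                       n_perm = min(config$convergence_test$n_perm, 100),
                       seed = derive_seed(seed, "pdfa_post"))
  delta_path <- file.path(config$out_dir, "delta_similarity.csv")
  write.csv(as.data.frame(pp$delta), delta_path)
  j_path <- file.path(config$out_dir, "convergence_tests.json")
  jsonlite::write_json(list(
    mantel = list(statistic = mt$statistic, p = mt$p, n_perm = mt$n_perm),
    gaussian_mm = gm$summary,
    pdfa = list(pre_accuracy = pd_pre$observed, pre_p = pd_pre$p,
                post_accuracy = pd_post$observed, post_p = pd_post$p)),
    j_path, auto_unbox = TRUE, digits = NA)
  message(sprintf("[convergence] Mantel rho %.3f (p %.3g); site accuracy %.3f -> %.3f",
                  mt$statistic, mt$p, pd_pre$observed, pd_post$observed))
  list(files = c(delta_path, j_path), mantel_p = mt$p)
}

merge_site <- function(features, bats) {
  features$site <- bats$site[match(features$bat_id, bats$bat_id)]
  features
}

captive_bats <- function(social) {
  co <- social$cohoused
  co[is.na(co)] <- FALSE
  rownames(co)[rowSums(co) > 0]
}

write_social <- function(social, dir) {
  paths <- vapply(names(social), function(nm) {
    p <- file.path(dir, paste0("social_", nm, ".csv"))
    write.csv(as.data.frame(social[[nm]]), p)
    p
  }, character(1))
  unname(paths)
}

read_social <- function(dir) {
  nms <- c("kinship", "cohoused", "groom_seconds", "share_seconds",
           "sampling_seconds", "share_sampling_seconds", "familiarity_class")
  out <- lapply(nms, function(nm) {
    as.matrix(read.csv(file.path(dir, paste0("social_", nm, ".csv")),
                       row.names = 1, check.names = FALSE))
  })
  names(out) <- nms
  out$cohoused <- out$cohoused == "TRUE" | out$cohoused == TRUE
  for (nm in setdiff(nms, c("cohoused", "familiarity_class")))
    storage.mode(out[[nm]]) <- "double"
  structure(out, class = "social_structure")
}
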