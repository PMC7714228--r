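# Orchestration: per-subject runs (preprocess -> k selection -> refit ->
# features) and cohort runs (control clustering, patient typing, group
# statistics).

#' Assemble a run configuration
#'
#' A run is reproducible from `(config, inputs)` alone: every tunable of the
#' pipeline lives here and the list serializes to JSON/YAML as-is.
#'
#' @param electrode_set `"forearm10"`, `"ring8"`, or a character vector of
#'   roles.
#' @param cutoff,order Envelope filter (Hz, Butterworth design order).
#' @param envelope_rate Decimation target in Hz.
#' @param n_repeats,fraction,global_threshold,local_threshold Synergy-number
#'   selection (see [estimate_k()]).
#' @param max_iter,tol NMF stopping rule (see [factorize()]).
#' @param refit_restarts Random restarts when refitting the reported model on
#'   all pooled samples at the chosen k (default 50).
#' @param k_range,cluster_restarts Clustering grid and restarts (see
#'   [cluster_features()]).
#' @param movement_list Movement ids used for feature profiles (default 1:17).
#' @param skip_envelope Set `TRUE` when the input recordings already hold
#'   envelopes at the target rate (e.g. synthetic `carrier = FALSE` data at
#'   100 Hz would still need decimation; skip only applies to the
#'   rectify/filter stage).
#' @param seed Master seed.
#' @param k_max,early_stop Passed to [estimate_k()] (candidate-k cap and
#'   early stopping once the dual criterion is met).
#' @return A `run_config` list.
#' @export
run_config <- function(electrode_set = "forearm10", cutoff = 3, order = 4,
                       envelope_rate = 100, n_repeats = 50L, fraction = 0.75,
                       global_threshold = 95, local_threshold = 85,
                       max_iter = 500L, tol = 1e-6, refit_restarts = 50L,
                       k_range = 2:15, cluster_restarts = 50L,
                       movement_list = 1:17, skip_envelope = FALSE, seed = 1L,
                       k_max = NULL, early_stop = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

config_roles <- function(config) {
  s <- config$electrode_set
  if (length(s) == 1L && s %in% c("ring8", "forearm10", "all_available")) {
    electrode_roles(s)
  } else as.character(s)
}

#' Run the per-subject analysis
#'
#' Executes envelope extraction, decimation, rest removal and pooling,
#' synergy-number selection, a refit of the reported model on 100% of the
#' pooled samples at the chosen k (best global VAF over
#' `config$refit_restarts` restarts), and feature construction.
#'
#' @param recording An [emg_recording()].
#' @param config A [run_config()].
#' @return A `subject_run`: `subject_id`, `dimensionality`
#'   (a `dimensionality_result`), `model` (the refit `synergy_model`), and
#'   `features` (tibble).
#' @export
run_subject <- function(recording, config = run_config()) {
  roles <- config_roles(config)
  missing <- setdiff(roles, recording$channel_roles)
  if (length(missing) > 0L) {
    stop(sprintf("subject %s: recording lacks channels required by electrode set: %s",
                 recording$subject_id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  env <- if (config$skip_envelope) recording else {
    envelope(recording, config$cutoff, config$order)
  }
  if (env$sampling_rate != config$envelope_rate) {
    env <- downsample(env, config$envelope_rate)
  }
  pool <- pool_movements(env, keep_roles = roles)
  dim_res <- estimate_k(pool, n_repeats = config$n_repeats,
                        fraction = config$fraction,
                        global_threshold = config$global_threshold,
                        local_threshold = config$local_threshold,
                        seed = child_seed(config$seed, 1L, 0L),
                        max_iter = config$max_iter, tol = config$tol,
                        k_max = config$k_max, early_stop = config$early_stop)
  best <- NULL
  for (r in seq_len(config$refit_restarts)) {
    mod <- factorize(pool$E, dim_res$chosen_k,
                     seed = child_seed(config$seed, 2L, r),
                     max_iter = config$max_iter, tol = config$tol)
    if (is.null(best) || mod$global_vaf > best$global_vaf) best <- mod
  }
  features <- build_features(best, pool$movement_of_sample,
                             movement_list = config$movement_list,
                             E = pool$E, subject_id = recording$subject_id)
  structure(
    list(subject_id = recording$subject_id, dimensionality = dim_res,
         model = best, features = features, config = config),
    class = "subject_run"
  )
}

#' @export
print.subject_run <- function(x, ...) {
  cat(sprintf("<subject_run> %s: k = %d (global VAF %.2f%%)\n",
              x$subject_id, x$dimensionality$chosen_k, x$model$global_vaf))
  invisible(x)
}

#' Run the cohort-level analysis
#'
#' Runs every subject through [run_subject()], pools the control features and
#' clusters them into synergy types, names representative movements, assigns
#' each patient synergy to its nearest control type (0 = untyped), and runs
#' the group statistics: Spearman associations of patient synergy counts with
#' clinical covariates, and a Mann-Whitney comparison of counts between
#' groups.
#'
#' @param subjects List of subject entries, each a list with `recording`, a
#'   `group` string (`"control"` or `"patient"`), and optionally a one-row
#'   `clinical` tibble (as produced by [make_cohort()]).
#' @param config A [run_config()].
#' @return A `cohort_report`: tibbles `counts`, `typing`, `cluster_summary`,
#'   `stats`, plus the fitted `clusters` and the per-subject `runs`.
#' @export
run_cohort <- function(subjects, config = run_config()) {
  groups <- vapply(subjects, function(s) s$group %||% "control", character(1))
  if (sum(groups == "control") < 2L) {
    stop("need at least 2 control subjects for clustering", call. = FALSE)
  }
  runs <- lapply(subjects, function(s) run_subject(s$recording, config))
  counts <- dplyr::bind_rows(lapply(seq_along(runs), function(i) {
    tibble::tibble(subject_id = runs[[i]]$subject_id, group = groups[i],
                   chosen_k = runs[[i]]$dimensionality$chosen_k,
                   saturated = runs[[i]]$dimensionality$saturated,
                   global_vaf = runs[[i]]$model$global_vaf)
  }))
  control_features <- dplyr::bind_rows(
    lapply(runs[groups == "control"], function(r) r$features)
  )
  clusters <- cluster_features(control_features, k_range = config$k_range,
                               restarts = config$cluster_restarts,
                               seed = child_seed(config$seed, 3L, 0L))
  cluster_summary <- dplyr::bind_rows(lapply(seq_len(clusters$n_clusters), function(kk) {
    members <- which(clusters$assignment == kk)
    tibble::tibble(
      cluster = kk, n_synergies = length(members),
      mean_variance_share = mean(control_features$explained_variance_share[members]),
      primary = clusters$representatives$primary[kk],
      secondary = clusters$representatives$secondary[kk]
    )
  }))
  typing <- NULL
  if (any(groups == "patient")) {
    typing <- dplyr::bind_rows(lapply(runs[groups == "patient"], function(r) {
      assign_patient_synergies(r$features, clusters)
    })) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::arrange(dplyr::desc(.data$explained_variance_share), .by_group = TRUE) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::select("subject_id", "rank", "cluster", "explained_variance_share")
  }
  stats_tbl <- NULL
  clinical <- dplyr::bind_rows(lapply(subjects, function(s) s$clinical))
  if (nrow(clinical) > 0L && any(groups == "patient")) {
    pk <- dplyr::left_join(counts[counts$group == "patient", ],
                           clinical, by = "subject_id")
    covs <- intersect(c("residual_forearm_pct", "age", "years_since_amputation",
                        "phantom_sensation"), names(pk))
    if (nrow(pk) >= 4L) {
      stats_tbl <- dplyr::bind_rows(lapply(covs, function(cv) {
        res <- tryCatch(spearman_assoc(pk[[cv]], pk$chosen_k),
                        error = function(e) stat_result("spearman_rho", NA_real_,
                                                        NA_real_, nrow(pk), 0,
                                                        degenerate = TRUE))
        dplyr::mutate(res, covariate = cv, .before = 1L)
      }))
    }
  }
  comparison <- NULL
  if (any(groups == "patient") && sum(groups == "control") >= 3L &&
      sum(groups == "patient") >= 3L) {
    comparison <- unpaired_compare(counts$chosen_k[counts$group == "control"],
                                   counts$chosen_k[counts$group == "patient"])
  }
  structure(
    list(counts = counts, typing = typing, cluster_summary = cluster_summary,
         stats = stats_tbl, comparison = comparison, clusters = clusters,
         runs = runs, config = config),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, %d synergy types\n",
              nrow(x$counts), x$clusters$n_clusters))
  print(x$counts)
  invisible(x)
}
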