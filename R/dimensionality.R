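# Synergy-number selection: repeated random extraction/validation splits,
# best-of-repeats validation VAF per candidate k, and the dual criterion
# (global VAF > 95 AND every local VAF > 85, both strict, both on the
# validation reconstruction).

#' Randomly split pooled samples into extraction and validation subsets
#'
#' Columns (samples) are partitioned uniformly at random without replacement;
#' the extraction part receives `round(fraction * T)` samples. The two parts
#' are disjoint and jointly exhaustive; within each part the original
#' temporal order is preserved.
#'
#' @param E A `pooled_envelope` or channels x samples matrix with at least 8
#'   samples.
#' @param fraction Extraction fraction in (0, 1); default 0.75.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with matrices `extraction` and `validation` plus the index
#'   vectors `extraction_idx` and `validation_idx`.
#' @export
split_pool <- function(E, fraction = 0.75, seed = 1L) {
  mv <- NULL
  if (inherits(E, "pooled_envelope")) { mv <- E$movement_of_sample; E <- E$E }
  T_ <- ncol(E)
  if (T_ < 8L) stop("need at least 8 pooled samples to split", call. = FALSE)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  n_ext <- round(fraction * T_)
  idx <- with_seed(seed, sample.int(T_, n_ext))
  ext <- sort(idx)
  val <- setdiff(seq_len(T_), ext)
  out <- list(extraction = E[, ext, drop = FALSE],
              validation = E[, val, drop = FALSE],
              extraction_idx = ext, validation_idx = val)
  if (!is.null(mv)) {
    out$extraction_movement <- mv[ext]
    out$validation_movement <- mv[val]
  }
  out
}

#' Estimate the number of muscle synergies
#'
#' For each candidate `k` from 1 to the channel count, runs `n_repeats`
#' independent trials: split the pooled samples (75/25 by default), factorize
#' the extraction subset at `k`, refit coefficients on the validation subset
#' against the extracted basis, and compute global and per-channel VAF of the
#' validation reconstruction. The trial with the maximum validation global VAF
#' is recorded per `k`. The chosen synergy number is the minimum `k` whose
#' recorded trial exceeds both thresholds strictly (global VAF >
#' `global_threshold` and every local VAF > `local_threshold`). When no `k`
#' qualifies the result saturates at `k = n` and is flagged.
#'
#' @param E A `pooled_envelope` (or nonnegative channels x samples matrix)
#'   with at least 2 channels.
#' @param n_repeats Independent split/refit trials per candidate `k`
#'   (default 50).
#' @param fraction Extraction fraction (default 0.75).
#' @param global_threshold,local_threshold VAF criteria in percent (defaults
#'   95 and 85, strict inequalities).
#' @param seed Master seed; per-(k, repeat) child seeds are spawned
#'   deterministically.
#' @param max_iter,tol NMF stopping parameters, see [factorize()].
#' @param k_max Optional cap on the largest candidate `k` (defaults to the
#'   channel count).
#' @param early_stop Stop scanning once the dual criterion is first met
#'   (default `FALSE`). The chosen k is unchanged by construction (it is the
#'   minimum qualifying k); only the per-k curves beyond it are left `NA`.
#' @return A `dimensionality_result` with fields `chosen_k`,
#'   `per_k_global_vaf`, `per_k_min_local_vaf`, `per_k_local_vaf` (matrix),
#'   `criteria_met`, `thresholds`, `n_repeats`, `saturated`.
#' @export
estimate_k <- function(E, n_repeats = 50L, fraction = 0.75,
                       global_threshold = 95, local_threshold = 85,
                       seed = 1L, max_iter = 500L, tol = 1e-6, k_max = NULL,
                       early_stop = FALSE) {
  if (inherits(E, "pooled_envelope")) E <- E$E
  check_nonneg_matrix(E)
  n <- nrow(E)
  if (n < 2L) stop("need at least 2 channels", call. = FALSE)
  if (!is.finite(global_threshold) || !is.finite(local_threshold) ||
      global_threshold > 100 || local_threshold > 100) {
    stop("invalid VAF thresholds", call. = FALSE)
  }
  k_max <- as.integer(k_max %||% n)
  if (k_max < 1L || k_max > n) stop("`k_max` must lie in [1, n]", call. = FALSE)
  ks <- seq_len(k_max)
  per_global <- rep(NA_real_, n)
  per_min_local <- rep(NA_real_, n)
  per_local <- matrix(NA_real_, nrow = n, ncol = n,
                      dimnames = list(rownames(E), paste0("k", seq_len(n))))
  met <- rep(FALSE, n)
  for (k in ks) {
    best_g <- -Inf
    best_local <- NULL
    for (r in seq_len(n_repeats)) {
      sp <- split_pool(E, fraction, seed = child_seed(seed, k, r, 1L))
      mod <- factorize(sp$extraction, k, seed = child_seed(seed, k, r, 2L),
                       max_iter = max_iter, tol = tol)
      Hv <- fit_coefficients(sp$validation, mod$W,
                             seed = child_seed(seed, k, r, 3L),
                             max_iter = max_iter, tol = tol)
      Rv <- mod$W %*% Hv
      g <- vaf_global(sp$validation, Rv)
      if (g > best_g) {
        best_g <- g
        best_local <- vaf_local(sp$validation, Rv)
      }
    }
    per_global[k] <- best_g
    per_min_local[k] <- min(best_local)
    per_local[, k] <- best_local
    met[k] <- (best_g > global_threshold) && all(best_local > local_threshold)
    if (early_stop && met[k]) break
  }
  saturated <- !any(met, na.rm = TRUE)
  chosen <- if (saturated) n else min(which(met))
  structure(
    list(chosen_k = as.integer(chosen),
         per_k_global_vaf = per_global,
         per_k_min_local_vaf = per_min_local,
         per_k_local_vaf = per_local,
         criteria_met = met,
         thresholds = c(global = global_threshold, local = local_threshold),
         n_repeats = as.integer(n_repeats),
         n_channels = n, k_max = k_max,
         saturated = saturated, seed = as.integer(seed)),
    class = "dimensionality_result"
  )
}

#' @export
print.dimensionality_result <- function(x, ...) {
  cat(sprintf("<dimensionality_result> chosen k = %d%s (of %d channels, %d repeats/k)\n",
              x$chosen_k, if (x$saturated) " [saturated]" else "",
              x$n_channels, x$n_repeats))
  cat(sprintf("  criteria: global VAF > %g%%, local VAF > %g%%\n",
              x$thresholds["global"], x$thresholds["local"]))
  invisible(x)
}

#' @rdname estimate_k
#' @param x A `dimensionality_result`.
#' @param ... Unused.
#' @method tidy dimensionality_result
#' @export
tidy.dimensionality_result <- function(x, ...) {
  ks <- seq_len(x$k_max)
  tibble::tibble(k = ks,
                 global_vaf = x$per_k_global_vaf[ks],
                 min_local_vaf = x$per_k_min_local_vaf[ks],
                 criteria_met = x$criteria_met[ks])
}

#' @rdname estimate_k
#' @method glance dimensionality_result
#' @export
glance.dimensionality_result <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, saturated = x$saturated,
                 n_channels = x$n_channels, n_repeats = x$n_repeats,
                 global_threshold = unname(x$thresholds["global"]),
                 local_threshold = unname(x$thresholds["local"]))
}

#' @rdname estimate_k
#' @param object A `dimensionality_result`.
#' @method autoplot dimensionality_result
#' @export
autoplot.dimensionality_result <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("global_vaf", "min_local_vaf"),
                        names_to = "measure", values_to = "vaf")
  thr <- tibble::tibble(
    measure = c("global_vaf", "min_local_vaf"),
    threshold = unname(object$thresholds[c("global", "local")])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$vaf,
                                  color = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$threshold,
                                     color = .data$measure),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dotted") +
    ggplot2::labs(x = "number of synergies k", y = "VAF (%)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Estimate synergy counts under several electrode configurations
#'
#' Reruns the full preprocessing + k-selection pipeline once per electrode
#' set, starting from the raw recording (envelope, decimation, pooling and
#' normalization are all recomputed per set, so each configuration is
#' normalized on its own channels). Results are paired for downstream paired
#' tests.
#'
#' @param recording A raw [emg_recording()].
#' @param sets Named list of electrode sets: each element either a character
#'   vector of roles or a montage name understood by [electrode_roles()].
#' @param cutoff,order Envelope filter parameters (see [envelope()]).
#' @param envelope_rate Decimation target in Hz (see [downsample()]).
#' @inheritParams estimate_k
#' @return Named list of `dimensionality_result`, one per set.
#' @export
compare_configurations <- function(recording, sets = list(ring8 = "ring8",
                                                          forearm10 = "forearm10"),
                                   cutoff = 3, order = 4, envelope_rate = 100,
                                   n_repeats = 50L, fraction = 0.75,
                                   global_threshold = 95, local_threshold = 85,
                                   seed = 1L, max_iter = 500L, tol = 1e-6) {
  if (length(sets) == 0L) stop("`sets` must name at least one electrode set", call. = FALSE)
  env <- downsample(envelope(recording, cutoff, order), envelope_rate)
  out <- lapply(sets, function(s) {
    roles <- if (length(s) == 1L && s %in% c("ring8", "forearm10", "all_available")) {
      electrode_roles(s)
    } else as.character(s)
    if (length(roles) == 0L) stop("empty electrode set", call. = FALSE)
    missing <- setdiff(roles, recording$channel_roles)
    if (length(missing) > 0L) {
      stop(sprintf("recording lacks channels required by this set: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    pool <- pool_movements(env, keep_roles = roles)
    estimate_k(pool, n_repeats = n_repeats, fraction = fraction,
               global_threshold = global_threshold,
               local_threshold = local_threshold,
               seed = seed, max_iter = max_iter, tol = tol)
  })
  out
}
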