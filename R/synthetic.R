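# Synthetic EMG generator with known ground truth. A session emulates the
# NinaPro acquisition protocol: movement blocks (17 simple hand/wrist
# movements by default, 6 repetitions each) interleaved with rest, sampled at
# 2 kHz. The envelope-level signal is W_true %*% activation; by default it is
# emitted as a broadband carrier (zero-mean noise amplitude-modulated by the
# envelope) so the rectify/filter/decimate stages are genuinely exercised.

tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Build a library of synergy activation prototypes
#'
#' Partitions the movement list into contiguous blocks, one per type; a type's
#' prototype is strongly activated (about 1) within its block and near
#' baseline (below 0.1) elsewhere, so each type dominates a disjoint movement
#' subset and the resulting z-normalized feature vectors are well separated.
#'
#' @param n_types Number of synergy types.
#' @param n_movements Length of the movement list (default 17).
#' @param seed Integer seed.
#' @return `n_types x n_movements` nonnegative prototype matrix.
#' @export
make_type_library <- function(n_types, n_movements = 17L, seed = 1L) {
  if (n_types > n_movements) stop("more types than movements", call. = FALSE)
  sizes <- rep(n_movements %/% n_types, n_types)
  extra <- n_movements %% n_types
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, head(stops, -1L) + 1L)
  with_seed(seed, {
    lib <- matrix(runif(n_types * n_movements, 0, 0.05), n_types, n_movements)
    for (t in seq_len(n_types)) {
      blk <- starts[t]:stops[t]
      lib[t, blk] <- runif(length(blk), 0.9, 1.1)
    }
    lib
  })
}

#' Sample a ground-truth synergy structure
#'
#' Each synergy is anchored on its own electrode subset (the electrodes are
#' partitioned among synergies and anchor weights drawn near 1), reflecting
#' that distinct synergies recruit distinct muscle groups under the ring
#' montage; off-anchor weights are a sparse gamma profile with a small uniform
#' floor on every electrode (every surface channel picks up some
#' volume-conducted activity). Columns are resampled until all pairwise
#' cosine similarities are at or below `separation`. The per-movement
#' activation matrix gives each synergy a disjoint dominant movement block
#' (see [make_type_library()]), or rows of a shared `type_library` when
#' building cohorts with common synergy types.
#'
#' @param n_electrodes Number of channels n.
#' @param k_true True synergy count, `1 <= k_true <= n_electrodes`.
#' @param seed Integer seed; output is deterministic per seed.
#' @param separation Pairwise cosine bound for weight columns (default 0.7).
#' @param noise_sd Sensor noise level relative to the mean movement envelope
#'   amplitude (default 0.1).
#' @param n_movements,repetitions,movement_duration,rest_duration,sampling_rate
#'   Protocol: movement count (17), repetitions per movement (6), block and
#'   rest durations in seconds (5 and 3), and sampling rate in Hz (2000).
#' @param type_library Optional prototype matrix from [make_type_library()].
#' @param types Row indices of `type_library` to use (length `k_true`).
#' @return A `ground_truth` object with `W_true`, `movement_activation`,
#'   `k_true`, `types`, `noise_sd`, and `protocol`.
#' @export
make_ground_truth <- function(n_electrodes, k_true, seed = 1L, separation = 0.7,
                              noise_sd = 0.1, n_movements = 17L,
                              repetitions = 6L, movement_duration = 5,
                              rest_duration = 3, sampling_rate = 2000,
                              type_library = NULL, types = NULL) {
  if (k_true < 1L || k_true > n_electrodes) {
    stop("`k_true` must lie in [1, n_electrodes]", call. = FALSE)
  }
  out <- with_seed(seed, {
    anchors <- split(sample.int(n_electrodes),
                     rep(seq_len(k_true), length.out = n_electrodes))
    W <- matrix(NA_real_, n_electrodes, k_true)
    for (j in seq_len(k_true)) {
      ok <- FALSE
      for (try in seq_len(500L)) {
        cand <- rgamma(n_electrodes, shape = 0.4) * 0.15 +
          runif(n_electrodes, 0.02, 0.08)
        cand[anchors[[j]]] <- runif(length(anchors[[j]]), 0.8, 1.2)
        if (j == 1L ||
            all(apply(W[, seq_len(j - 1L), drop = FALSE], 2L,
                      cosine_sim, v = cand) <= separation)) {
          W[, j] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf("could not sample %d weight columns at separation %.2f; try a looser bound",
                     k_true, separation), call. = FALSE)
      }
    }
    if (is.null(type_library)) {
      type_library <- make_type_library(k_true, n_movements,
                                        seed = child_seed(seed, 1L, 1L))
      types <- seq_len(k_true)
    } else if (is.null(types)) {
      types <- seq_len(k_true)
    }
    if (length(types) != k_true || any(types > nrow(type_library))) {
      stop("`types` must index `type_library` rows, one per synergy", call. = FALSE)
    }
    act <- type_library[types, , drop = FALSE] +
      matrix(runif(k_true * n_movements, 0, 0.02), k_true, n_movements)
    list(W = W, act = act, types = as.integer(types))
  })
  structure(
    list(W_true = out$W, movement_activation = out$act,
         k_true = as.integer(k_true), types = out$types,
         noise_sd = noise_sd, separation = separation,
         protocol = list(n_movements = as.integer(n_movements),
                         repetitions = as.integer(repetitions),
                         movement_duration = movement_duration,
                         rest_duration = rest_duration,
                         sampling_rate = sampling_rate),
         seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' Synthesize a labeled EMG recording from a ground truth
#'
#' Builds the label track (every movement repeated the configured number of
#' times, rest between repetitions), shapes each repetition's activation as
#' the per-movement activation level times a Tukey-window pulse with a
#' lognormal-like per-repetition gain jitter, and maps through `W_true` to the
#' envelope. With `carrier = TRUE` (default) the emitted signal is zero-mean
#' white noise amplitude-modulated by the envelope plus additive broadband
#' sensor noise, so the preprocessing stages are exercised; with
#' `carrier = FALSE` the nonnegative envelope itself is emitted (sensor noise
#' then half-normal to preserve nonnegativity).
#'
#' @param truth A `ground_truth` from [make_ground_truth()].
#' @param seed Integer seed.
#' @param carrier Emit a broadband carrier (default) or the envelope directly.
#' @param subject_id Identifier attached to the recording.
#' @return An [emg_recording()]; the planted envelope (channels x samples) is
#'   attached as attribute `"truth_envelope"`.
#' @export
synthesize <- function(truth, seed = 1L, carrier = TRUE, subject_id = "SYN1") {
  stopifnot(inherits(truth, "ground_truth"))
  pr <- truth$protocol
  fs <- pr$sampling_rate
  L_mov <- max(8L, as.integer(round(pr$movement_duration * fs)))
  L_rest <- max(4L, as.integer(round(pr$rest_duration * fs)))
  n <- nrow(truth$W_true)
  k <- truth$k_true
  n_blocks <- pr$n_movements * pr$repetitions
  T_total <- L_rest + n_blocks * (L_mov + L_rest)
  pulse <- tukey_window(L_mov, alpha = 0.5)
  env <- matrix(0, n, T_total)
  movement <- integer(T_total)
  repetition <- integer(T_total)
  rec <- with_seed(seed, {
    pos <- L_rest
    for (m in seq_len(pr$n_movements)) {
      for (rep_i in seq_len(pr$repetitions)) {
        gains <- pmax(1 + rnorm(k, 0, 0.1), 0.5)
        amp <- truth$movement_activation[, m] * gains
        idx <- (pos + 1L):(pos + L_mov)
        env[, idx] <- truth$W_true %*% (amp %o% pulse)
        movement[idx] <- m
        repetition[idx] <- rep_i
        pos <- pos + L_mov + L_rest
      }
    }
    mean_env <- mean(env[, movement > 0L])
    if (carrier) {
      sig <- env * matrix(rnorm(n * T_total), n, T_total)
      if (truth$noise_sd > 0) {
        sig <- sig + truth$noise_sd * mean_env * matrix(rnorm(n * T_total), n, T_total)
      }
    } else {
      sig <- env
      if (truth$noise_sd > 0) {
        sig <- sig + truth$noise_sd * mean_env *
          abs(matrix(rnorm(n * T_total), n, T_total))
      }
    }
    list(sig = sig, env = env)
  })
  out <- emg_recording(t(rec$sig), fs, movement, repetition,
                       channel_roles = default_channel_roles(n),
                       subject_id = subject_id, exercise_id = "B")
  attr(out, "truth_envelope") <- rec$env
  out
}

# Clinical covariate marginals on a uniform quantile, spanning the ranges
# typical of transradial amputee cohorts.
clinical_marginals <- list(
  residual_forearm_pct = function(u) round(pmin(pmax(qnorm(u, 55, 25), 0), 100)),
  age = function(u) round(pmin(pmax(qnorm(u, 42, 12), 20), 75)),
  years_since_amputation = function(u) round(pmin(pmax(stats::qgamma(u, shape = 2, scale = 3.5), 0.5), 25), 1),
  phantom_sensation = function(u) pmin(floor(u * 6), 5)
)

#' Generate a synthetic cohort with known synergy structure
#'
#' Per-subject ground truths draw their synergy count from `k_distribution`
#' and their synergy types (without replacement) from a shared library of
#' `n_types` prototypes, so features pooled across subjects carry a planted
#' type structure. Clinical covariates are generated through a Gaussian
#' copula whose latent variable also drives the synergy count, embedding a
#' configurable Spearman association between each covariate and `k_true`.
#'
#' @param n_subjects Number of subjects (at least 4).
#' @param k_distribution Candidate synergy counts, sampled uniformly (an
#'   unnamed vector) or with probabilities (a named numeric vector with
#'   values as names).
#' @param clinical_model Named numeric vector of target Spearman correlations
#'   between each covariate and `k_true`; covariates are
#'   `residual_forearm_pct`, `age`, `years_since_amputation`,
#'   `phantom_sensation`.
#' @param seed Master seed; the whole cohort is deterministic per seed.
#' @param n_types Size of the shared synergy-type library (default 6).
#' @param n_electrodes,noise_sd,separation,carrier,... Passed through to
#'   [make_ground_truth()] and [synthesize()] (protocol overrides such as
#'   `movement_duration` go through `...`).
#' @param group Label attached to every subject (e.g. "control", "patient").
#' @return List with `subjects` (each `list(recording, truth, clinical)`),
#'   the pooled `clinical` tibble, and the shared `type_library`.
#' @export
make_cohort <- function(n_subjects, k_distribution = c(4L, 5L, 6L),
                        clinical_model = c(residual_forearm_pct = 0.8,
                                           age = 0.5,
                                           years_since_amputation = 0,
                                           phantom_sensation = 0),
                        seed = 1L, n_types = 6L, n_electrodes = 10L,
                        noise_sd = 0.1, separation = 0.7, carrier = TRUE,
                        group = "control", ...) {
  if (n_subjects < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (is.null(names(k_distribution))) {
    k_vals <- as.integer(k_distribution)
    k_probs <- rep(1 / length(k_vals), length(k_vals))
  } else {
    k_vals <- as.integer(names(k_distribution))
    k_probs <- as.numeric(k_distribution) / sum(k_distribution)
  }
  if (any(is.na(k_vals)) || any(k_vals < 1L) || any(k_vals > n_types)) {
    stop("invalid `k_distribution`: counts must lie in [1, n_types]", call. = FALSE)
  }
  lib <- make_type_library(n_types, seed = child_seed(seed, 1L, 0L))
  breaks <- cumsum(k_probs)
  cov_names <- names(clinical_model)
  unknown <- setdiff(cov_names, names(clinical_marginals))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown clinical covariate(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  sampled <- with_seed(child_seed(seed, 2L, 0L), {
    z0 <- rnorm(n_subjects)                       # latent driver of k_true
    k_true <- k_vals[findInterval(pnorm(z0), c(0, head(breaks, -1L))) ]
    covs <- lapply(cov_names, function(nm) {
      rho_s <- clinical_model[[nm]]
      rho_g <- 2 * sin(pi * rho_s / 6)            # Spearman -> Gaussian copula
      zc <- rho_g * z0 + sqrt(1 - rho_g^2) * rnorm(n_subjects)
      clinical_marginals[[nm]](pnorm(zc))
    })
    names(covs) <- cov_names
    types <- lapply(k_true, function(kk) sample.int(n_types, kk))
    list(k_true = k_true, covs = covs, types = types)
  })
  clinical <- tibble::as_tibble(c(
    list(subject_id = sprintf("%s%02d", toupper(substr(group, 1, 1)), seq_len(n_subjects)),
         group = rep(group, n_subjects),
         k_true = sampled$k_true),
    sampled$covs
  ))
  clinical$prosthesis_experience <- with_seed(child_seed(seed, 3L, 0L), {
    sample(c("Myo", "Cos", "Kin", "No"), n_subjects, replace = TRUE,
           prob = c(6, 1, 2, 2) / 11)
  })
  clinical$amputated_hand <- with_seed(child_seed(seed, 4L, 0L), {
    sample(c("R", "L"), n_subjects, replace = TRUE, prob = c(10, 1) / 11)
  })
  subjects <- lapply(seq_len(n_subjects), function(i) {
    truth <- make_ground_truth(
      n_electrodes, sampled$k_true[i],
      seed = child_seed(seed, 5L, i), separation = separation,
      noise_sd = noise_sd, type_library = lib, types = sampled$types[[i]], ...
    )
    rec <- synthesize(truth, seed = child_seed(seed, 6L, i), carrier = carrier,
                      subject_id = clinical$subject_id[i])
    list(recording = rec, truth = truth, clinical = clinical[i, ])
  })
  list(subjects = subjects, clinical = clinical, type_library = lib)
}
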