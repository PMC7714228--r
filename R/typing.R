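# Synergy typing: movement-activation feature vectors, k-means clustering
# under the correlation distance 1 - r with silhouette model selection,
# representative movements per cluster, and classification of patient
# synergies against the control clusters.

#' Correlation distance between two profiles
#'
#' `1 - r` with `r` the Pearson correlation; ranges over \[0, 2\].
#'
#' @param u,v Non-constant numeric vectors of equal length.
#' @return The distance `1 - cor(u, v)`.
#' @export
corr_distance <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length", call. = FALSE)
  if (sd_pop(u) == 0 || sd_pop(v) == 0) {
    stop("correlation distance is undefined for a constant vector", call. = FALSE)
  }
  1 - cor(u, v)
}

#' Variance explained by a single synergy
#'
#' Global VAF of the rank-1 reconstruction `W[, i] %*% H[i, ]` against `E`.
#' Because synergies are not orthogonal, per-synergy shares need not sum
#' to the full model's VAF.
#'
#' @param E Pooled envelope matrix (channels x samples) or `pooled_envelope`.
#' @param W,H Factor pair of a fitted model.
#' @param i Synergy index.
#' @return Percent variance explained.
#' @export
per_synergy_variance <- function(E, W, H, i) {
  if (inherits(E, "pooled_envelope")) E <- E$E
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > ncol(W) || i != round(i)) {
    stop("synergy index out of range", call. = FALSE)
  }
  vaf_global(E, W[, i, drop = FALSE] %*% H[i, , drop = FALSE])
}

#' Build movement-activation feature vectors from a fitted synergy model
#'
#' For each synergy (row of `H`), element `m` of the raw profile is the mean
#' activation coefficient over all samples labeled with movement `m`, pooled
#' across repetitions. The profile is then z-normalized (zero mean, unit
#' population standard deviation across the movement list) to remove the NMF
#' scale ambiguity.
#'
#' @param model A `synergy_model` from [factorize()].
#' @param movement_of_sample Integer movement id per column of `H`.
#' @param movement_list Movement ids forming the profile (default `1:17`,
#'   the simple-movement exercise).
#' @param E Optional pooled envelope matrix used to compute each synergy's
#'   explained-variance share via [per_synergy_variance()]; `NA` otherwise.
#' @param subject_id Identifier attached to each feature row.
#' @return A tibble with columns `subject_id`, `synergy_index`,
#'   `explained_variance_share`, and `m1..m<p>` profile columns.
#' @export
build_features <- function(model, movement_of_sample, movement_list = 1:17,
                           E = NULL, subject_id = "S1") {
  stopifnot(inherits(model, "synergy_model"))
  H <- model$H
  if (length(movement_of_sample) != ncol(H)) {
    stop("`movement_of_sample` must align with the columns of H", call. = FALSE)
  }
  if (inherits(E, "pooled_envelope")) E <- E$E
  p <- length(movement_list)
  raw <- matrix(NA_real_, nrow = model$k, ncol = p)
  for (j in seq_len(p)) {
    cols <- which(movement_of_sample == movement_list[j])
    if (length(cols) == 0L) {
      stop(sprintf("movement %s has no samples", movement_list[j]), call. = FALSE)
    }
    raw[, j] <- rowMeans(H[, cols, drop = FALSE])
  }
  prof <- matrix(NA_real_, nrow = model$k, ncol = p)
  share <- rep(NA_real_, model$k)
  for (i in seq_len(model$k)) {
    if (sd_pop(raw[i, ]) == 0) {
      stop(sprintf("synergy %d is untypable: constant activation across movements", i),
           call. = FALSE)
    }
    prof[i, ] <- zscore_pop(raw[i, ])
    if (!is.null(E)) share[i] <- per_synergy_variance(E, model$W, H, i)
  }
  colnames(prof) <- paste0("m", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id,
                   synergy_index = seq_len(model$k),
                   explained_variance_share = share),
    tibble::as_tibble(prof)
  )
}

# Extract the profile matrix (features x movements) from a feature tibble.
feature_matrix <- function(features) {
  cols <- grep("^m[0-9]+$", names(features), value = TRUE)
  if (length(cols) == 0L) stop("no m1..mP profile columns found", call. = FALSE)
  cols <- cols[order(as.integer(sub("^m", "", cols)))]
  X <- as.matrix(features[, cols])
  storage.mode(X) <- "double"
  X
}

# Pairwise 1 - r distances between rows of X.
corr_distance_matrix <- function(X) {
  1 - cor(t(X))
}

# Distances from z-normalized rows of X to z-normalized centroids C:
# with population z-scores, r(u, c) = sum(u * c) / p.
zrow_distance <- function(X, C) {
  1 - X %*% t(C) / ncol(X)
}

zscore_rows <- function(M) t(apply(M, 1L, zscore_pop))

# Mean silhouette under an arbitrary precomputed distance matrix. Clusters of
# size one contribute 0 (the usual convention).
silhouette_mean <- function(D, assignment) {
  n <- nrow(D)
  ks <- sort(unique(assignment))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assignment[i]
    same <- which(assignment == own)
    if (length(same) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(same, i)])
    b <- min(vapply(setdiff(ks, own), function(kk) {
      mean(D[i, assignment == kk])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# One Lloyd run of k-means under 1 - r on z-normalized rows. Centroids are
# member means re-z-normalized; empty clusters are reseeded from the sample
# farthest from its current centroid.
kmeans_corr_once <- function(X, k, seed, max_iter = 100L) {
  n <- nrow(X)
  C <- X[with_seed(seed, sample.int(n, k)), , drop = FALSE]
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D <- zrow_distance(X, C)
    assignment <- max.col(-D, ties.method = "first")
    d_own <- D[cbind(seq_len(n), assignment)]
    for (kk in seq_len(k)) {
      if (!any(assignment == kk)) {
        # reseed from the farthest sample whose donor cluster keeps >= 1 member
        sizes <- tabulate(assignment, k)
        eligible <- which(sizes[assignment] >= 2L)
        far <- eligible[which.max(d_own[eligible])]
        assignment[far] <- kk
        d_own[far] <- 0
      }
    }
    if (identical(assignment, assign_old)) break
    assign_old <- assignment
    for (kk in seq_len(k)) {
      C[kk, ] <- zscore_pop(colMeans(X[assignment == kk, , drop = FALSE]))
    }
  }
  D <- zrow_distance(X, C)
  assignment <- max.col(-D, ties.method = "first")
  tw <- sum(D[cbind(seq_len(n), assignment)])
  list(assignment = assignment, centroids = C, tot_within = tw)
}

#' Cluster synergy feature vectors across subjects
#'
#' k-means under the correlation distance `1 - r`: assignment to the nearest
#' centroid, centroid update as the member mean re-z-normalized (on
#' z-normalized profiles `1 - r` is a monotone function of squared Euclidean
#' distance, so the Lloyd iteration converges). For each candidate cluster
#' count the best of `restarts` random restarts (minimum total within-cluster
#' distance) is kept; the cluster count maximizing the mean silhouette (also
#' under `1 - r`) wins, ties going to the smaller count.
#'
#' @param features Feature tibble from [build_features()] (rows may be pooled
#'   across subjects), or a numeric matrix of z-normalized profiles.
#' @param k_range Candidate cluster counts (default `2:15`).
#' @param restarts Random restarts per candidate count (default 50).
#' @param seed Master seed.
#' @return A `synergy_clusters` object: `n_clusters`, `assignment`,
#'   `centroids`, `silhouette_by_k`, `max_within_distance`,
#'   `representatives`, plus the input `features`.
#' @export
cluster_features <- function(features, k_range = 2:15, restarts = 50L, seed = 1L) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  n <- nrow(X)
  if (n < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 features to cluster", call. = FALSE)
  }
  ok <- apply(X, 1L, function(r) abs(mean(r)) < 1e-6 && abs(sd_pop(r) - 1) < 1e-6)
  if (!all(ok)) {
    stop("feature profiles must be z-normalized (zero mean, unit population SD)",
         call. = FALSE)
  }
  D_full <- corr_distance_matrix(X)
  sil <- setNames(rep(NA_real_, length(k_range)), paste0("k", k_range))
  best_by_k <- vector("list", length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- kmeans_corr_once(X, k, seed = child_seed(seed, k, r))
      if (is.null(best) || run$tot_within < best$tot_within) best <- run
    }
    sil[j] <- silhouette_mean(D_full, best$assignment)
    best_by_k[[j]] <- best
  }
  j_opt <- which.max(sil)
  best <- best_by_k[[j_opt]]
  k_opt <- k_range[j_opt]
  D <- zrow_distance(X, best$centroids)
  d_own <- D[cbind(seq_len(n), best$assignment)]
  max_within <- vapply(seq_len(k_opt), function(kk) {
    max(d_own[best$assignment == kk])
  }, numeric(1))
  reps <- dplyr::bind_rows(lapply(seq_len(k_opt), function(kk) {
    rm <- representative_movements(best$centroids[kk, ])
    tibble::tibble(cluster = kk, primary = rm$primary, secondary = rm$secondary)
  }))
  structure(
    list(n_clusters = k_opt,
         assignment = best$assignment,
         centroids = best$centroids,
         silhouette_by_k = sil,
         max_within_distance = max_within,
         representatives = reps,
         features = if (is.matrix(features)) NULL else features,
         k_range = k_range, restarts = as.integer(restarts),
         seed = as.integer(seed)),
    class = "synergy_clusters"
  )
}

#' @export
print.synergy_clusters <- function(x, ...) {
  cat(sprintf("<synergy_clusters> %d clusters over %d features (silhouette %.3f)\n",
              x$n_clusters, length(x$assignment),
              max(x$silhouette_by_k)))
  cat(sprintf("  cluster sizes: %s\n",
              paste(tabulate(x$assignment, x$n_clusters), collapse = ", ")))
  invisible(x)
}

#' @rdname cluster_features
#' @param x A `synergy_clusters` object.
#' @param ... Unused.
#' @method tidy synergy_clusters
#' @export
tidy.synergy_clusters <- function(x, ...) {
  base <- tibble::tibble(feature = seq_along(x$assignment),
                         cluster = x$assignment)
  if (!is.null(x$features)) {
    base <- dplyr::bind_cols(
      x$features[, intersect(c("subject_id", "synergy_index",
                               "explained_variance_share"), names(x$features))],
      base["cluster"]
    )
  }
  base
}

#' @rdname cluster_features
#' @method glance synergy_clusters
#' @export
glance.synergy_clusters <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters,
                 n_features = length(x$assignment),
                 mean_silhouette = max(x$silhouette_by_k),
                 restarts = x$restarts)
}

#' @rdname cluster_features
#' @param object A `synergy_clusters` object.
#' @method autoplot synergy_clusters
#' @export
autoplot.synergy_clusters <- function(object, ...) {
  C <- object$centroids
  d <- tibble::tibble(
    cluster = rep(seq_len(nrow(C)), times = ncol(C)),
    movement = rep(seq_len(ncol(C)), each = nrow(C)),
    activation = as.vector(C)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$movement, y = factor(.data$cluster),
                                  fill = .data$activation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(C))) +
    ggplot2::labs(x = "movement", y = "synergy type (cluster)",
                  fill = "relative\nactivation") +
    ggplot2::theme_minimal()
}

#' Representative movements of a cluster centroid
#'
#' Over the centroid's movement entries, with mean `m` and population standard
#' deviation `s`: the strongest movement is primary when its activation is at
#' least `m + 2s`; the second strongest is secondary when at least `m + s`.
#' Ties break toward the lower movement index; a constant centroid has no
#' representatives.
#'
#' @param centroid Numeric centroid profile (one entry per movement).
#' @param movement_list Movement ids corresponding to the entries.
#' @return List with `primary` and `secondary` movement ids (`NA` when the
#'   rule is not met).
#' @export
representative_movements <- function(centroid, movement_list = seq_along(centroid)) {
  if (length(centroid) != length(movement_list)) {
    stop("`movement_list` must match the centroid length", call. = FALSE)
  }
  m <- mean(centroid)
  s <- sd_pop(centroid)
  if (s == 0) return(list(primary = NA_integer_, secondary = NA_integer_))
  ord <- order(-centroid, seq_along(centroid))
  primary <- if (centroid[ord[1]] >= m + 2 * s) movement_list[ord[1]] else NA_integer_
  secondary <- if (centroid[ord[2]] >= m + s) movement_list[ord[2]] else NA_integer_
  list(primary = primary, secondary = secondary)
}

#' Classify a patient synergy against control synergy types
#'
#' Computes the correlation distance from the z-normalized feature profile to
#' every control cluster centroid and returns the nearest cluster when that
#' distance does not exceed the cluster's maximum within-cluster
#' sample-to-centroid distance, else 0 (untyped). The inclusive comparison
#' guarantees that every feature used in training re-assigns to its own
#' cluster.
#'
#' @param feature A z-normalized profile vector, or a one-row feature tibble.
#' @param clusters A `synergy_clusters` model.
#' @return Integer cluster id, 0 when no cluster is close enough.
#' @export
assign_patient_synergy <- function(feature, clusters) {
  stopifnot(inherits(clusters, "synergy_clusters"))
  v <- if (is.numeric(feature)) feature else as.vector(feature_matrix(feature)[1L, ])
  d <- vapply(seq_len(clusters$n_clusters), function(kk) {
    corr_distance(v, clusters$centroids[kk, ])
  }, numeric(1))
  j <- which.min(d)
  if (d[j] <= clusters$max_within_distance[j]) as.integer(j) else 0L
}

#' Classify every synergy in a feature table
#'
#' Vectorized wrapper around [assign_patient_synergy()].
#'
#' @param features Feature tibble (see [build_features()]).
#' @param clusters A `synergy_clusters` model fitted on control features.
#' @return The input tibble with an added `cluster` column (0 = untyped).
#' @export
assign_patient_synergies <- function(features, clusters) {
  X <- feature_matrix(features)
  cl <- vapply(seq_len(nrow(X)), function(i) {
    assign_patient_synergy(X[i, ], clusters)
  }, integer(1))
  dplyr::mutate(features, cluster = cl)
}
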