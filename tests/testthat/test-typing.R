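# Feature construction, correlation-distance k-means, silhouette selection,
# representative movements, and patient-synergy classification.

test_that("corr_distance matches direct Pearson arithmetic", {
  expect_equal(corr_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(corr_distance(c(1, 2, 3), -c(1, 2, 3)), 2)
  expect_equal(corr_distance(c(1, 2, 3), c(1, 2, 4)),
               1 - cor(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  expect_lt(abs(corr_distance(c(1, 2, 3), c(1, 2, 4)) - 0.0180), 1e-3)
  expect_error(corr_distance(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(corr_distance(1:3, 1:4), "length")
})

test_that("build_features averages per movement and z-normalizes", {
  # toy 2-movement list: H row (1,1,2,2) with labels (1,1,2,2)
  mod <- structure(list(W = matrix(c(1, 1), 2, 1),
                        H = matrix(c(1, 1, 2, 2), 1, 4),
                        k = 1L, global_vaf = 100,
                        local_vaf = c(100, 100), seed = 1L,
                        iterations_run = 0L, sse_trace = 0),
                   class = "synergy_model")
  ft <- build_features(mod, c(1L, 1L, 2L, 2L), movement_list = 1:2,
                       subject_id = "T1")
  expect_equal(unlist(ft[1, c("m1", "m2")], use.names = FALSE), c(-1, 1))
  # z-normalization contract on a real fit
  pool <- tiny_pool(k_true = 2, n = 6, seed = 12, carrier = FALSE)
  mod2 <- factorize(pool, 2, seed = 3)
  ft2 <- build_features(mod2, pool$movement_of_sample, E = pool$E)
  X <- as.matrix(ft2[, paste0("m", 1:17)])
  expect_true(all(abs(rowMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 1, function(r) sqrt(mean((r - mean(r))^2))) - 1) < 1e-9))
  expect_true(all(ft2$explained_variance_share > 0))
})

test_that("degenerate feature inputs raise the stated errors", {
  mod <- structure(list(W = matrix(1, 2, 1), H = matrix(3, 1, 4), k = 1L,
                        global_vaf = 100, local_vaf = c(100, 100), seed = 1L,
                        iterations_run = 0L, sse_trace = 0),
                   class = "synergy_model")
  expect_error(build_features(mod, c(1L, 1L, 2L, 2L), movement_list = 1:2),
               "untypable")
  expect_error(build_features(mod, c(1L, 1L, 1L, 1L), movement_list = 1:2),
               "no samples")
})

test_that("per-synergy variance shares reproduce known structure", {
  pool <- tiny_pool(k_true = 1, n = 6, seed = 14, carrier = FALSE)
  mod <- factorize(pool, 1, seed = 5)
  expect_equal(per_synergy_variance(pool$E, mod$W, mod$H, 1), mod$global_vaf,
               tolerance = 1e-9)
  # two orthogonally supported synergies of equal energy split evenly
  W <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  H <- rbind(c(rep(1, 50), rep(0, 50)), c(rep(0, 50), rep(1, 50)))
  E <- W %*% H
  s1 <- per_synergy_variance(E, W, H, 1)
  s2 <- per_synergy_variance(E, W, H, 2)
  expect_lt(abs(s1 - s2), 1)
  expect_error(per_synergy_variance(E, W, H, 3), "range")
})

test_that("planted correlation groups are recovered exactly", {
  pf <- planted_profiles(groups = 3, per = 8, seed = 7)
  cl <- cluster_features(pf$X, k_range = 2:6, restarts = 20, seed = 2)
  expect_equal(cl$n_clusters, 3)
  expect_equal(partition_agreement(cl$assignment, pf$label), 1)
  # duplication invariance: every profile twice, same optimal k
  cl2 <- cluster_features(rbind(pf$X, pf$X), k_range = 2:6, restarts = 20,
                          seed = 2)
  expect_equal(cl2$n_clusters, 3)
  dup <- cl2$assignment[1:nrow(pf$X)] == cl2$assignment[(nrow(pf$X) + 1):(2 * nrow(pf$X))]
  expect_true(all(dup))
})

test_that("clustering is invariant to feature order up to relabeling", {
  pf <- planted_profiles(groups = 3, per = 7, seed = 9)
  cl <- cluster_features(pf$X, k_range = 2:5, restarts = 15, seed = 4)
  set.seed(1)
  perm <- sample(nrow(pf$X))
  cl_p <- cluster_features(pf$X[perm, ], k_range = 2:5, restarts = 15, seed = 4)
  expect_equal(cl_p$n_clusters, cl$n_clusters)
  expect_equal(partition_agreement(cl_p$assignment, cl$assignment[perm]), 1)
})

test_that("null structure yields a flat, low silhouette curve", {
  set.seed(33)
  X <- t(replicate(30, zrow(rnorm(17))))
  cl <- cluster_features(X, k_range = 2:8, restarts = 15, seed = 6)
  expect_lt(diff(range(cl$silhouette_by_k)), 0.3)
  expect_lt(max(cl$silhouette_by_k), 0.35)
})

test_that("mean silhouette agrees with the cluster-package oracle", {
  pf <- planted_profiles(groups = 3, per = 6, seed = 15, noise = 0.4)
  cl <- cluster_features(pf$X, k_range = 2:5, restarts = 10, seed = 8)
  D <- 1 - cor(t(pf$X))
  oracle <- mean(cluster::silhouette(cl$assignment, dmatrix = D)[, "sil_width"])
  expect_equal(unname(cl$silhouette_by_k[paste0("k", cl$n_clusters)]), oracle,
               tolerance = 1e-10)
})

test_that("representative movements follow the 2 SD / 1 SD rule", {
  # single spike: 16 zeros and one 5.0 at movement 5
  centroid <- rep(0, 17); centroid[5] <- 5
  rm <- representative_movements(centroid)
  expect_equal(rm$primary, 5)
  expect_true(is.na(rm$secondary))
  # flat centroid: no representatives
  rm0 <- representative_movements(rep(1, 17))
  expect_true(is.na(rm0$primary) && is.na(rm0$secondary))
  # two equal maxima, both past 2 SD: tie goes to the lower movement index
  c2 <- rep(0, 17); c2[c(4, 9)] <- 5
  expect_equal(representative_movements(c2)$primary, 4)
  # secondary rule: second strongest must clear mean + 1 SD
  c3 <- rep(0, 17); c3[3] <- 5; c3[11] <- 2.2
  rm3 <- representative_movements(c3)
  expect_equal(rm3$primary, 3)
  expect_equal(rm3$secondary, 11)
})

test_that("representative movements are shift and positive-scale invariant", {
  set.seed(44)
  centroid <- rnorm(17)
  base <- representative_movements(centroid)
  shifted <- representative_movements(centroid + 3.7)
  scaled <- representative_movements(centroid * 4.2)
  expect_identical(base, shifted)
  expect_identical(base, scaled)
})

test_that("patient synergies classify by nearest-centroid with within-cluster gate", {
  pf <- planted_profiles(groups = 3, per = 8, seed = 18)
  cl <- cluster_features(pf$X, k_range = 2:5, restarts = 15, seed = 10)
  # a centroid itself: assigned to its own cluster at distance ~0
  expect_equal(assign_patient_synergy(cl$centroids[2, ], cl), 2L)
  # anti-correlated with everything: untyped
  expect_equal(assign_patient_synergy(-cl$centroids[1, ], cl), 0L)
  # every training feature re-assigns to its own cluster, never 0
  re <- vapply(seq_len(nrow(pf$X)), function(i) {
    assign_patient_synergy(pf$X[i, ], cl)
  }, integer(1))
  expect_identical(re, cl$assignment)
  expect_true(all(re != 0L))
})

test_that("tidy, glance and autoplot expose the cluster model", {
  pf <- planted_profiles(groups = 2, per = 6, seed = 25)
  feats <- tibble::tibble(subject_id = "X", synergy_index = 1:12,
                          explained_variance_share = runif(12))
  feats <- dplyr::bind_cols(feats, tibble::as_tibble(`colnames<-`(pf$X, paste0("m", 1:17))))
  cl <- cluster_features(feats, k_range = 2:4, restarts = 10, seed = 3)
  expect_equal(cl$n_clusters, 2)
  td <- tidy(cl)
  expect_true(all(c("subject_id", "cluster") %in% names(td)))
  expect_equal(glance(cl)$n_features, 12)
  expect_s3_class(autoplot(cl), "ggplot")
  assigned <- assign_patient_synergies(feats, cl)
  expect_true(all(assigned$cluster %in% 0:2))
})
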