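# Extraction/validation splitting and synergy-number selection.

test_that("split_pool produces the stated sizes and a true partition", {
  E <- matrix(runif(3 * 100), 3, 100)
  sp <- split_pool(E, 0.75, seed = 5)
  expect_equal(ncol(sp$extraction), 75)
  expect_equal(ncol(sp$validation), 25)
  expect_length(intersect(sp$extraction_idx, sp$validation_idx), 0)
  expect_equal(sort(c(sp$extraction_idx, sp$validation_idx)), 1:100)
  # determinism
  sp2 <- split_pool(E, 0.75, seed = 5)
  expect_identical(sp$extraction_idx, sp2$extraction_idx)
  expect_error(split_pool(E[, 1:5], 0.75, seed = 1), "at least 8")
  expect_error(split_pool(E, 1.2), "between 0 and 1")
})

test_that("estimate_k recovers the planted synergy count on clean data", {
  pool <- tiny_pool(k_true = 3, n = 10, seed = 2, carrier = FALSE,
                    noise_sd = 0)
  res <- estimate_k(pool, n_repeats = 5, seed = 9)
  expect_s3_class(res, "dimensionality_result")
  expect_equal(res$chosen_k, 3)
  expect_false(res$saturated)
  expect_true(res$criteria_met[3])
  expect_false(any(res$criteria_met[1:2]))
  # VAF saturates once k reaches the true dimensionality
  expect_true(all(res$per_k_global_vaf[3:10] > 99.9))
  # best-of-repeats validation VAF is non-decreasing up to sampling noise
  expect_true(all(diff(res$per_k_global_vaf) > -1))
})

test_that("a single-synergy recording yields k = 1", {
  pool <- tiny_pool(k_true = 1, n = 6, seed = 3, carrier = FALSE,
                    noise_sd = 0.05)
  res <- estimate_k(pool, n_repeats = 5, seed = 4, early_stop = TRUE)
  expect_equal(res$chosen_k, 1)
})

test_that("early stopping never changes the chosen k", {
  pool <- tiny_pool(k_true = 2, n = 6, seed = 6)
  full <- estimate_k(pool, n_repeats = 4, seed = 11)
  fast <- estimate_k(pool, n_repeats = 4, seed = 11, early_stop = TRUE)
  expect_equal(fast$chosen_k, full$chosen_k)
  expect_equal(fast$per_k_global_vaf[seq_len(fast$chosen_k)],
               full$per_k_global_vaf[seq_len(full$chosen_k)])
})

test_that("chosen k is invariant to channel order and global rescaling", {
  pool <- tiny_pool(k_true = 3, n = 8, seed = 8, carrier = FALSE,
                    noise_sd = 0.05)
  base <- estimate_k(pool, n_repeats = 5, seed = 13, early_stop = TRUE)
  perm <- sample(nrow(pool$E))
  res_perm <- estimate_k(pool$E[perm, ], n_repeats = 5, seed = 13,
                         early_stop = TRUE)
  res_scale <- estimate_k(3.7 * pool$E, n_repeats = 5, seed = 13,
                          early_stop = TRUE)
  expect_equal(res_perm$chosen_k, base$chosen_k)
  expect_equal(res_scale$chosen_k, base$chosen_k)
})

test_that("saturation is reported when no k meets the criteria", {
  set.seed(99)
  E <- matrix(runif(4 * 200), 4, 200)     # unstructured noise
  res <- estimate_k(E, n_repeats = 3, seed = 7, global_threshold = 99.999,
                    local_threshold = 99.999)
  expect_true(res$saturated)
  expect_equal(res$chosen_k, 4)
  expect_error(estimate_k(E, global_threshold = 150), "thresholds")
})

test_that("tidy and glance summarize the per-k table", {
  pool <- tiny_pool(k_true = 2, n = 6, seed = 20, carrier = FALSE)
  res <- estimate_k(pool, n_repeats = 3, seed = 2)
  td <- tidy(res)
  expect_named(td, c("k", "global_vaf", "min_local_vaf", "criteria_met"))
  expect_equal(nrow(td), 6)
  gl <- glance(res)
  expect_equal(gl$chosen_k, res$chosen_k)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("redundant extra channels do not raise the synergy count", {
  gt <- tiny_truth(k_true = 3, n = 8, seed = 30, noise_sd = 0.05)
  rec8 <- synthesize(gt, seed = 31, carrier = FALSE)
  # duplicate two ring channels as FDS/EDS lookalikes
  sig10 <- cbind(rec8$signal, rec8$signal[, 1:2])
  rec10 <- emg_recording(sig10, rec8$sampling_rate, rec8$movement_label,
                         rec8$repetition_label,
                         channel_roles = electrode_roles("forearm10"))
  res <- compare_configurations(rec10,
                                sets = list(ring8 = "ring8",
                                            forearm10 = "forearm10"),
                                n_repeats = 3, seed = 17,
                                cutoff = 3, order = 4)
  expect_equal(res$ring8$chosen_k, res$forearm10$chosen_k)
})

test_that("an extra independent source on FDS/EDS can only raise the count", {
  gt <- tiny_truth(k_true = 3, n = 10, seed = 40, noise_sd = 0.05)
  # plant a 4th synergy carried almost entirely by the FDS/EDS channels
  W4 <- c(rep(0.03, 8), 1.1, 0.95)
  act4 <- c(rep(0.02, 14), 1, 1, 1)     # dominates the last movements
  gt$W_true <- cbind(gt$W_true, W4)
  gt$movement_activation <- rbind(gt$movement_activation, act4)
  gt$k_true <- 4L
  rec <- synthesize(gt, seed = 41, carrier = FALSE)
  res <- compare_configurations(rec,
                                sets = list(ring8 = "ring8",
                                            forearm10 = "forearm10"),
                                n_repeats = 3, seed = 19)
  expect_gte(res$forearm10$chosen_k, res$ring8$chosen_k)
  # identical sets under identical seeds give identical results
  res2 <- compare_configurations(rec, sets = list(a = "ring8", b = "ring8"),
                                 n_repeats = 2, seed = 23)
  expect_identical(res2$a$per_k_global_vaf, res2$b$per_k_global_vaf)
  expect_error(compare_configurations(rec, sets = list(character(0))), "empty")
})
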