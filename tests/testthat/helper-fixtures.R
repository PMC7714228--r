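# Fixture builders shared across test files. Recordings are generated at
# reduced block durations (0.3 s movement / 0.2 s rest) so the suite stays
# fast; protocol structure (17 movements x 6 repetitions, 2 kHz) is the
# generator default.

zrow <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

tiny_truth <- function(k_true = 3, n = 10, seed = 1, noise_sd = 0.1, ...) {
  make_ground_truth(n, k_true, seed = seed, noise_sd = noise_sd,
                    movement_duration = 0.3, rest_duration = 0.2, ...)
}

# Pooled envelope from a synthetic recording; carrier = TRUE exercises the
# rectify/filter stage, carrier = FALSE emits the envelope directly.
tiny_pool <- function(k_true = 3, n = 10, seed = 1, carrier = TRUE,
                      noise_sd = 0.1, ...) {
  gt <- tiny_truth(k_true, n, seed, noise_sd, ...)
  rec <- synthesize(gt, seed = seed + 1000, carrier = carrier)
  env <- if (carrier) envelope(rec) else rec
  pool_movements(downsample(env, 100))
}

# z-normalized feature profiles in `groups` planted correlation groups.
planted_profiles <- function(groups = 3, per = 10, p = 17, seed = 1,
                             noise = 0.05) {
  lib <- make_type_library(groups, p, seed = seed)
  set.seed(seed + 1)
  X <- do.call(rbind, lapply(seq_len(groups), function(g) {
    t(vapply(seq_len(per), function(i) {
      zrow(lib[g, ] + runif(p, 0, noise))
    }, numeric(p)))
  }))
  list(X = X, label = rep(seq_len(groups), each = per))
}

# Best one-to-one agreement between a clustering and planted labels:
# greedily matches clusters to labels on the contingency table.
partition_agreement <- function(assignment, label) {
  tab <- table(assignment, label)
  total <- 0L
  while (nrow(tab) > 0L && ncol(tab) > 0L) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1L, ]
    total <- total + tab[ij[1L], ij[2L]]
    tab <- tab[-ij[1L], -ij[2L], drop = FALSE]
  }
  as.numeric(total) / length(assignment)
}
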