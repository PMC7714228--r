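# Non-negative matrix factorization by Frobenius multiplicative updates.
# The envelope matrix E (channels x samples) is approximated as W %*% H with
# W (channels x k) the synergy weights and H (k x samples) the activation
# coefficients. Reconstruction quality is summarized by the variance
# accounted for, VAF = 100 * (1 - SSE/SST), where SST is the sum of squares
# of the original data (no mean subtraction).

#' Variance accounted for by a reconstruction (global)
#'
#' `100 * (1 - SSE/SST)` with `SSE = sum((E - R)^2)` and `SST = sum(E^2)`.
#' Can be negative for reconstructions worse than the zero matrix; equals 100
#' only when `R` reproduces `E` exactly.
#'
#' @param E Original matrix (not all zero).
#' @param R Reconstruction, same shape.
#' @return VAF in percent.
#' @export
vaf_global <- function(E, R) {
  if (!all(dim(as.matrix(E)) == dim(as.matrix(R)))) {
    stop("`E` and `R` must have the same shape", call. = FALSE)
  }
  sst <- sum(E^2)
  if (sst == 0) stop("`E` is all zero: SST = 0", call. = FALSE)
  100 * (1 - sum((E - R)^2) / sst)
}

#' Variance accounted for, per channel (local)
#'
#' Applies the VAF formula to each row (channel) separately.
#'
#' @inheritParams vaf_global
#' @return Numeric vector of per-channel VAF percents, named by channel when
#'   `E` has row names.
#' @export
vaf_local <- function(E, R) {
  E <- as.matrix(E); R <- as.matrix(R)
  if (!all(dim(E) == dim(R))) {
    stop("`E` and `R` must have the same shape", call. = FALSE)
  }
  sst <- rowSums(E^2)
  if (any(sst == 0)) {
    ch <- rownames(E) %||% as.character(seq_len(nrow(E)))
    stop(sprintf("channel %s is all zero: SST = 0",
                 paste(ch[sst == 0], collapse = ", ")), call. = FALSE)
  }
  setNames(100 * (1 - rowSums((E - R)^2) / sst), rownames(E))
}

#' Extract muscle synergies by multiplicative-update NMF
#'
#' Lee-Seung multiplicative updates for the squared (Frobenius) error, with
#' uniform random initialization of both factors from `seed`. The squared
#' error is non-increasing across iterations; iteration stops at `max_iter`
#' or when the relative error change between evaluations (every `eval_every`
#' iterations) drops below `tol`.
#'
#' @param E Nonnegative matrix, channels x samples (or a `pooled_envelope`).
#' @param k Number of synergies, `1 <= k <= min(dim(E))`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative error-change tolerance (default 1e-6).
#' @param eval_every Error evaluation stride in iterations (default 10; use 1
#'   to record the full per-iteration error trajectory).
#' @return A `synergy_model`: `W`, `H`, `k`, `global_vaf`, `local_vaf`,
#'   `seed`, `iterations_run`, and the evaluated error trajectory `sse_trace`.
#' @export
factorize <- function(E, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                      eval_every = 10L) {
  if (inherits(E, "pooled_envelope")) E <- E$E
  check_nonneg_matrix(E)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > min(dim(E)) ||
      k != round(k)) {
    stop("`k` must be an integer in [1, min(dim(E))]", call. = FALSE)
  }
  k <- as.integer(k)
  n <- nrow(E); T_ <- ncol(E)
  init <- with_seed(seed, list(W = matrix(runif(n * k), n, k),
                               H = matrix(runif(k * T_), k, T_)))
  fit <- .nmf_mu_cpp(E, init$W, init$H, as.integer(max_iter), tol, TRUE,
                     as.integer(eval_every))
  R <- fit$W %*% fit$H
  rownames(fit$W) <- rownames(E)
  structure(
    list(W = fit$W, H = fit$H, k = k,
         global_vaf = vaf_global(E, R),
         local_vaf = vaf_local(E, R),
         seed = as.integer(seed), iterations_run = fit$iterations,
         sse_trace = fit$sse),
    class = "synergy_model"
  )
}

#' Fit activation coefficients against a fixed synergy basis
#'
#' Multiplicative updates on `H` only, with `W` held fixed; used to evaluate
#' a basis extracted on one subset against the held-out validation subset.
#' Stopping rule as in [factorize()].
#'
#' @param E Nonnegative matrix, channels x samples.
#' @param W Fixed nonnegative basis, channels x k.
#' @inheritParams factorize
#' @return Nonnegative `k x ncol(E)` coefficient matrix with attributes
#'   `iterations` and `sse_trace`.
#' @export
fit_coefficients <- function(E, W, seed = 1L, max_iter = 500L, tol = 1e-6,
                             eval_every = 10L) {
  if (inherits(E, "pooled_envelope")) E <- E$E
  check_nonneg_matrix(E)
  check_nonneg_matrix(W, "W")
  if (nrow(W) != nrow(E)) {
    stop("`W` must have as many rows as `E` has channels", call. = FALSE)
  }
  k <- ncol(W)
  H0 <- with_seed(seed, matrix(runif(k * ncol(E)), k, ncol(E)))
  fit <- .nmf_mu_cpp(E, W, H0, as.integer(max_iter), tol, FALSE,
                     as.integer(eval_every))
  H <- fit$H
  attr(H, "iterations") <- fit$iterations
  attr(H, "sse_trace") <- fit$sse
  H
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> k = %d over %d channels, %d samples\n",
              x$k, nrow(x$W), ncol(x$H)))
  cat(sprintf("  global VAF %.2f%%, min local VAF %.2f%% (%d iterations)\n",
              x$global_vaf, min(x$local_vaf), x$iterations_run))
  invisible(x)
}

#' @rdname factorize
#' @param x A `synergy_model`.
#' @param ... Unused.
#' @method tidy synergy_model
#' @export
tidy.synergy_model <- function(x, ...) {
  ch <- rownames(x$W) %||% as.character(seq_len(nrow(x$W)))
  tibble::tibble(
    channel = rep(ch, times = x$k),
    synergy = rep(seq_len(x$k), each = nrow(x$W)),
    weight = as.vector(x$W)
  )
}

#' @rdname factorize
#' @method glance synergy_model
#' @export
glance.synergy_model <- function(x, ...) {
  tibble::tibble(k = x$k, global_vaf = x$global_vaf,
                 min_local_vaf = min(x$local_vaf),
                 iterations = x$iterations_run, seed = x$seed)
}

#' @rdname factorize
#' @param object A `synergy_model`.
#' @method autoplot synergy_model
#' @export
autoplot.synergy_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$channel, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~synergy, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "electrode", y = "synergy weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
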