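# Group-level statistics on synergy counts and clinical covariates. Each
# function returns a one-row tibble (statistic, two-sided p, sample sizes,
# effect direction) so results bind into report tables.

stat_result <- function(statistic_name, statistic, p_value, n,
                        effect_direction, degenerate = FALSE) {
  tibble::tibble(statistic_name = statistic_name,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 n = paste(n, collapse = ","),
                 effect_direction = effect_direction,
                 degenerate = degenerate)
}

#' Spearman rank association
#'
#' Spearman's rho with mid-rank ties and a two-sided p-value; used to relate
#' per-subject synergy counts to clinical covariates (residual forearm
#' percentage, age, years since amputation, phantom-sensation score).
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @return One-row tibble (see [spearman_assoc()] siblings).
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("`x` and `y` must have equal length >= 4", call. = FALSE)
  }
  if (sd_pop(x) == 0 || sd_pop(y) == 0) {
    stop("Spearman association is undefined for a constant input", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  stat_result("spearman_rho", ct$estimate, ct$p.value, length(x),
              sign(unname(ct$estimate)))
}

#' Paired comparison (Wilcoxon signed-rank)
#'
#' Zero differences are excluded; the p-value is exact for up to 25 nonzero
#' differences without ties, otherwise the normal approximation with tie
#' correction is used. All-zero differences yield a degenerate-flagged result
#' rather than an error.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return One-row tibble with the signed-rank statistic `V`, two-sided p,
#'   and the sign of the median nonzero difference.
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  d <- a - b
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    return(stat_result("wilcoxon_signed_rank", NA_real_, NA_real_,
                       length(a), 0, degenerate = TRUE))
  }
  use_exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = use_exact,
                                     correct = !use_exact))
  stat_result("wilcoxon_signed_rank", wt$statistic, wt$p.value,
              length(a), sign(median(nz)))
}

#' Unpaired comparison (Mann-Whitney U)
#'
#' Two-sided rank-sum test with tie correction; exact p for small untied
#' samples. Used to compare synergy counts between groups.
#'
#' @param a,b Numeric vectors (each at least 3 values).
#' @return One-row tibble with the `U` statistic, two-sided p, and the sign
#'   of `median(a) - median(b)`.
#' @export
unpaired_compare <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("both groups need at least 3 values", call. = FALSE)
  }
  use_exact <- (length(a) + length(b)) <= 50L && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = use_exact,
                                     correct = !use_exact))
  stat_result("mann_whitney_u", wt$statistic, wt$p.value,
              c(length(a), length(b)), sign(median(a) - median(b)))
}

#' Welch two-sample t-test
#'
#' Plain Welch t (no equal-variance assumption); used for body-size and age
#' comparisons between groups.
#'
#' @param a,b Numeric vectors (each at least 2 values).
#' @return One-row tibble with the t statistic, two-sided p, and the sign of
#'   `mean(a) - mean(b)`.
#' @export
welch_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  tt <- t.test(a, b)
  stat_result("welch_t", tt$statistic, tt$p.value,
              c(length(a), length(b)), sign(mean(a) - mean(b)))
}

#' Optional Holm adjustment across a table of test results
#'
#' The primary analysis reports unadjusted p-values (one test per covariate);
#' this helper adds a Holm-adjusted column for reuse in larger screens.
#'
#' @param results Tibble of stacked test results with a `p_value` column.
#' @return The tibble with an added `p_holm` column.
#' @export
adjust_holm <- function(results) {
  dplyr::mutate(results, p_holm = stats::p.adjust(.data$p_value, method = "holm"))
}
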