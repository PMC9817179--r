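#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided test of symmetry about zero for paired live/fixed parameter
#' changes. Zero differences are dropped (the standard convention); the
#' p-value is exact for n <= 25 without tied absolute values, otherwise a
#' normal approximation with continuity correction is used.
#'
#' @param differences Numeric vector of paired differences (e.g. percent
#'   changes); fewer than 5 non-zero values triggers a warning.
#' @return List with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_used` (non-zero differences) and `exact`.
#' @examples
#' wilcoxon_signed_rank(c(3, 8, 1, 4, 6, 2))$p_value  # 0.03125
#' @export
wilcoxon_signed_rank <- function(differences) {
  stopifnot(is.numeric(differences))
  d <- differences[differences != 0]
  if (length(d) == 0L)
    stop("all differences are zero; signed-rank test undefined",
         call. = FALSE)
  if (length(d) < 5L)
    warning("fewer than 5 non-zero differences; exact p-values are ",
            "coarse", call. = FALSE)
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  ht <- stats::wilcox.test(d, exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = length(d), exact = exact)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided comparison of two independent samples (e.g. corrected
#' residence times of two proteins). Exact for small tie-free samples,
#' normal approximation with continuity correction otherwise.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List with `statistic` (W), `p_value` and `exact`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  exact <- length(group_a) <= 25L && length(group_b) <= 25L &&
    !any(duplicated(c(group_a, group_b)))
  ht <- stats::wilcox.test(group_a, group_b, exact = exact,
                           correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       exact = exact)
}
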