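#' Compare two clone-size distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, the default two-sample
#' test for clone-size data (no distributional assumption, robust to the
#' heavy tails of clone-size distributions). The U statistic counts pairs
#' `(a_i, b_j)` with `a_i > b_j`, ties contributing 1/2.
#'
#' The p-value route depends on the data: without ties and with both sample
#' sizes at most 20, the exact null distribution of U is used; with ties,
#' the exact permutation distribution is enumerated when the number of group
#' assignments is small enough (<= `enumeration_cap`); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Two-sided p-values are defined symmetrically as
#' `P(|U* - n1 n2 / 2| >= |u - n1 n2 / 2|)`.
#'
#' @param a,b Numeric vectors of clone sizes (both non-empty).
#' @param enumeration_cap Maximum number of group assignments for exact
#'   enumeration in the presence of ties.
#' @return List with `U` (for `a` vs `b`), `p_value`, `median_a`,
#'   `median_b`, `n_a`, `n_b`, and `method` (`"exact"`,
#'   `"exact_enumeration"` or `"normal_approximation"`).
#' @export
#' @examples
#' compare_clone_distributions(c(1, 2, 3), c(10, 20, 30))$U   # 0
compare_clone_distributions <- function(a, b, enumeration_cap = 2e5) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  mu <- n1 * n2 / 2

  if (!ties && max(n1, n2) <= 20L) {
    u_low <- min(u, n1 * n2 - u)
    p <- min(1, 2 * stats::pwilcox(u_low, n1, n2))
    method <- "exact"
  } else if (choose(n1 + n2, n1) <= enumeration_cap) {
    # exact permutation distribution of U over all group assignments,
    # computed from rank sums (ties handled via midranks)
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    method <- "exact_enumeration"
  } else {
    n <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_approximation"
  }
  list(
    U = u,
    p_value = p,
    median_a = stats::median(a),
    median_b = stats::median(b),
    n_a = n1,
    n_b = n2,
    method = method
  )
}
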