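#' Two-sample Wilcoxon rank-sum test with exact enumeration for small groups
#'
#' Computes the two-sided Wilcoxon rank-sum (Mann-Whitney) p-value. For small
#' groups (both sizes at most `exact_limit`) the null distribution of the
#' rank-sum statistic is enumerated over all assignments of the pooled
#' observations to groups, which is exact even in the presence of ties
#' (mid-ranks). Larger samples use the normal approximation with tie
#' correction and continuity correction, matching `wilcox.test()`.
#'
#' @param x,y Numeric vectors of observations in the two groups.
#' @param exact_limit Largest group size for which full enumeration is used.
#' @return A list with elements `statistic` (rank sum W of `x`, Mann-Whitney
#'   U convention as in `wilcox.test`), `p.value`, and `method`.
#' @examples
#' rank_sum_test(c(1, 5, 7), c(2, 3, 4, 6))
#' @export
rank_sum_test <- function(x, y, exact_limit = 8) {
  assert_that(length(x) >= 1 && length(y) >= 1, "both groups must be nonempty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    sets <- combn(n, n1)
    ws <- colSums(matrix(r[sets], nrow = n1))
    p <- 2 * min(mean(ws <= w), mean(ws >= w))
    p <- min(1, p)
    return(list(statistic = u, p.value = p, method = "exact enumeration"))
  }
  list(statistic = u,
       p.value = rank_sum_p_approx(w, r, n1, n2),
       method = "normal approximation")
}

# normal approximation for the rank-sum W with tie and continuity correction
rank_sum_p_approx <- function(w, r, n1, n2) {
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sig2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sig2)
  z <- max(z, 0)
  min(1, 2 * pnorm(z, lower.tail = FALSE))
}

#' Precompute genewise ranks for repeated rank-sum testing
#'
#' Ranks every row of an expression matrix across cells and records the tie
#' correction term per gene. The result can be reused across many group
#' comparisons on the same matrix (one-vs-rest tests for several programs,
#' label permutations), where re-ranking would dominate the cost.
#'
#' @param mat Numeric matrix, genes x cells.
#' @return An object of class `rank_prep` holding the rank matrix and per-gene
#'   tie terms.
#' @export
precompute_ranks <- function(mat) {
  genes <- rownames(mat) %||% paste0("g", seq_len(nrow(mat)))
  ranks <- matrix(0, nrow(mat), ncol(mat))
  tie_term <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    ranks[i, ] <- rank(v)
    tl <- rle(sort(v))$lengths
    tie_term[i] <- sum(tl^3 - tl)
  }
  rownames(ranks) <- genes
  structure(list(ranks = ranks, tie_term = tie_term, genes = genes,
                 n = ncol(mat)),
            class = "rank_prep")
}

#' Genewise Wilcoxon rank-sum tests on an expression matrix
#'
#' Vectorised one-vs-rest Wilcoxon rank-sum test for every row (gene) of an
#' expression matrix, comparing cells in `in_group` against the rest. Uses
#' the normal approximation with tie correction (the group sizes at which
#' this path is taken are far beyond exact-test territory); when both sides
#' have at most `exact_limit` cells it falls back to exact enumeration per
#' gene.
#'
#' @param mat Numeric matrix, genes x cells. May be `NULL` if `prep` is given.
#' @param in_group Logical vector over columns: the focal group.
#' @param exact_limit Group-size bound below which exact enumeration is used.
#' @param prep Optional [precompute_ranks()] result for `mat`, reused across
#'   repeated calls with different groupings.
#' @return Tibble with columns `gene`, `p`, `auc` (Mann-Whitney U / (n1*n2)).
#' @export
rank_sum_matrix <- function(mat, in_group, exact_limit = 8, prep = NULL) {
  if (is.null(prep)) prep <- precompute_ranks(mat)
  assert_that(is.logical(in_group) && length(in_group) == prep$n,
              "in_group must be logical over columns of mat")
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  assert_that(n1 >= 1 && n2 >= 1, "both groups must be nonempty")
  if (n1 <= exact_limit && n2 <= exact_limit && !is.null(mat)) {
    res <- apply(mat, 1, function(v) {
      t <- rank_sum_test(v[in_group], v[!in_group], exact_limit = exact_limit)
      c(t$statistic, t$p.value)
    })
    return(tibble(gene = prep$genes, p = res[2, ], auc = res[1, ] / (n1 * n2)))
  }
  w <- rowSums(prep$ranks[, in_group, drop = FALSE])
  mu <- n1 * (n + 1) / 2
  sig2 <- n1 * n2 / 12 * ((n + 1) - prep$tie_term / (n * (n - 1)))
  z <- pmax((abs(w - mu) - 0.5) / sqrt(pmax(sig2, .Machine$double.eps)), 0)
  p <- ifelse(sig2 <= 0, 1, pmin(1, 2 * pnorm(z, lower.tail = FALSE)))
  tibble(gene = prep$genes, p = unname(p),
         auc = unname(w - n1 * (n1 + 1) / 2) / (n1 * n2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; thin wrapper over
#' `stats::p.adjust(method = "BH")` so the multiple-testing rule used across
#' the package is a single named choice. `NA` inputs propagate as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  assert_that(all(p[ok] >= 0 & p[ok] <= 1), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# log2 fold change of mean de-logged expression, with a small pseudo-value
log2fc_expm1 <- function(mat, in_group, eps = 1e-9) {
  m_in <- rowMeans(expm1(mat[, in_group, drop = FALSE]))
  m_out <- rowMeans(expm1(mat[, !in_group, drop = FALSE]))
  log2(m_in + eps) - log2(m_out + eps)
}
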