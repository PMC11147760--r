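#' Differential expression between co-culture timepoints
#'
#' Per-gene two-sided Wilcoxon rank-sum tests of normalised expression at 24h
#' versus 0h (within one stratum, e.g. T cells co-cultured with sensitive
#' targets), BH correction across genes, and log2 fold change on de-logged
#' means. A gene is differentially expressed when `q < q_cut` and
#' `|log2fc| > lfc_cut`.
#'
#' @param nm A `normalized_matrix`, typically restricted to one population
#'   and stratum.
#' @param condition Per-cell condition labels aligned with `nm` cells; the
#'   contrast is `level_test` vs `level_ref`.
#' @param level_test,level_ref Condition levels contrasted (defaults
#'   `"24h"` vs `"0h"`).
#' @param lfc_cut,q_cut DE thresholds (defaults 0.25 and 0.05).
#' @return A `de_table` tibble: `gene`, `log2fc`, `p`, `q`, `mean_test`,
#'   `mean_ref`, `frac_test`, `frac_ref`, `de`; attribute `n_de`.
#' @export
de_between_conditions <- function(nm, condition, level_test = "24h",
                                  level_ref = "0h", lfc_cut = 0.25,
                                  q_cut = 0.05) {
  ing <- condition == level_test
  ref <- condition == level_ref
  if (sum(ing) == 0 || sum(ref) == 0)
    abort("empty condition stratum", class = "amlprog_empty_stratum")
  assert_that(sum(ing) >= 3 && sum(ref) >= 3,
              "both conditions need at least 3 cells")
  vals <- nm$values[, ing | ref, drop = FALSE]
  grp <- ing[ing | ref]
  rs <- rank_sum_matrix(vals, grp)
  e <- expm1(vals)
  lfc <- log2(rowMeans(e[, grp, drop = FALSE]) + 1e-9) -
    log2(rowMeans(e[, !grp, drop = FALSE]) + 1e-9)
  pos <- vals > 0
  out <- tibble(gene = nm$genes, log2fc = unname(lfc), p = rs$p,
                q = bh_adjust(rs$p),
                mean_test = unname(rowMeans(vals[, grp, drop = FALSE])),
                mean_ref = unname(rowMeans(vals[, !grp, drop = FALSE])),
                frac_test = unname(rowMeans(pos[, grp, drop = FALSE])),
                frac_ref = unname(rowMeans(pos[, !grp, drop = FALSE]))) |>
    mutate(de = .data$q < q_cut & abs(.data$log2fc) > lfc_cut)
  attr(out, "n_de") <- sum(out$de)
  class(out) <- c("de_table", class(out))
  out
}

#' Genes uniquely overexpressed in one condition
#'
#' Genes overexpressed (`q < q_cut`, `log2fc > lfc_cut`) in table A but not
#' overexpressed in table B, ranked by A's fold change; the top `n` are
#' returned. Used to contrast the response to sensitive versus resistant
#' co-culture partners.
#'
#' @param de_a,de_b Two [de_between_conditions()] tables over the same gene
#'   universe.
#' @param n List size (default 50).
#' @param lfc_cut,q_cut Overexpression thresholds.
#' @return Character vector of up to `n` genes.
#' @export
unique_top_genes <- function(de_a, de_b, n = 50, lfc_cut = 0.25,
                             q_cut = 0.05) {
  assert_that(setequal(de_a$gene, de_b$gene),
              "tables must share a gene universe")
  up_a <- de_a$q < q_cut & de_a$log2fc > lfc_cut
  up_b <- de_b$gene[de_b$q < q_cut & de_b$log2fc > lfc_cut]
  cand <- de_a[up_a & !(de_a$gene %in% up_b), ]
  cand <- cand[order(-cand$log2fc, cand$gene), ]
  head(cand$gene, n)
}

#' Hypergeometric over-representation of a gene list in signatures
#'
#' One-sided hypergeometric tail test `P(X >= overlap)` of the gene list
#' against each named signature within a gene universe of `universe_size`,
#' BH-corrected across signatures. Zero overlap gives p = 1 by the one-sided
#' convention.
#'
#' @param gene_list Character query list (must lie within the universe).
#' @param signatures Named list of gene sets.
#' @param universe Character vector of universe genes (or a single integer
#'   universe size, in which case signature sizes are taken as given).
#' @return Tibble `signature`, `overlap`, `signature_size`, `p`, `q`.
#' @export
overrepresentation_test <- function(gene_list, signatures, universe) {
  assert_that(length(signatures) > 0, "signatures must be nonempty")
  if (is.numeric(universe) && length(universe) == 1) {
    n_univ <- as.integer(universe)
    sig_in_univ <- signatures
  } else {
    n_univ <- length(unique(universe))
    assert_that(all(gene_list %in% universe),
                "gene_list must be a subset of the universe")
    sig_in_univ <- lapply(signatures, intersect, y = universe)
  }
  k <- length(gene_list)
  res <- purrr::imap_dfr(sig_in_univ, function(sig, name) {
    m <- length(sig)
    if (m == 0)
      return(tibble(signature = name, overlap = NA_integer_,
                    signature_size = 0L, p = NA_real_))
    ov <- length(intersect(gene_list, sig))
    p <- phyper(ov - 1, m, n_univ - m, k, lower.tail = FALSE)
    tibble(signature = name, overlap = as.integer(ov),
           signature_size = as.integer(m), p = p)
  })
  res$q <- bh_adjust(res$p)
  res
}

#' Read signature gene sets from a GMT-like file
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character gene sets.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                       character(1))
  out
}

#' Write signature gene sets to a GMT-like file
#' @param signatures Named list of gene sets.
#' @param path Output path.
#' @param description Description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, description = "synthetic") {
  lines <- vapply(names(signatures), function(n)
    paste(c(n, description, signatures[[n]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
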