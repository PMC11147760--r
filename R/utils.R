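#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   left_join bind_rows desc n across all_of rename relocate pull slice_head
#' @importFrom stats p.adjust phyper wilcox.test cor cor.test prcomp hclust
#'   cutree dist as.dist median quantile rnbinom rlnorm rnorm rexp runif var
#'   sd setNames pnorm aggregate IQR rmultinom complete.cases
#' @importFrom utils head read.csv write.csv combn
#' @importFrom methods as
NULL

# single source of truth for the mitochondrial-gene naming convention
MITO_PREFIX <- "MT-"

is_mito_gene <- function(genes) startsWith(genes, MITO_PREFIX)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# deterministic per-stage seeds derived from one global seed: stage i gets
# seed + 1000 * i, kept under 2^31
stage_seed <- function(seed, stage) {
  s <- (as.numeric(seed) + 1000 * stage) %% 2147483647
  as.integer(s)
}

# match discovered labels to planted labels by greedy maximum overlap;
# returns named vector mapping discovered -> planted
match_labels <- function(found, truth) {
  tab <- table(found, truth)
  map <- character(0)
  while (length(tab) && nrow(tab) > 0 && ncol(tab) > 0) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    map[rownames(tab)[idx[1]]] <- colnames(tab)[idx[2]]
    tab <- tab[-idx[1], -idx[2], drop = FALSE]
  }
  map
}
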