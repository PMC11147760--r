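#' Cluster cells within each patient x timepoint sample
#'
#' Tier 1 of the two-tier program-discovery procedure: each sample (patient x
#' timepoint) is clustered independently so that patient- and culture-induced
#' global differences cannot drive the grouping. Cells are embedded by PCA of
#' the highly variable genes and grouped by Ward agglomerative clustering;
#' the number of clusters is chosen per sample by maximum mean silhouette
#' width over `k_range`. The procedure is fully deterministic.
#'
#' @param nm A `normalized_matrix` (typically restricted to AML cells).
#' @param hvgs Genes to cluster on; defaults to [select_hvgs()] output.
#' @param n_pcs Number of principal components (default 30).
#' @param k_range Candidate cluster numbers per sample.
#' @param min_cluster_size Samples with fewer than `2 * min_cluster_size`
#'   cells are assigned a single cluster with a warning.
#' @return Tibble with `barcode`, `sample`, `cluster` (labels namespaced by
#'   sample, e.g. `"PT01_0h#2"`).
#' @export
cluster_within_sample <- function(nm, hvgs = NULL, n_pcs = 30,
                                  k_range = 2:8, min_cluster_size = 20) {
  if (is.null(hvgs)) hvgs <- select_hvgs(nm, min(2000, length(nm$genes)))
  sample_key <- paste(nm$cells$patient, nm$cells$timepoint, sep = "_")
  out <- vector("list", length(unique(sample_key)))
  names(out) <- unique(sample_key)
  for (s in unique(sample_key)) {
    idx <- which(sample_key == s)
    if (length(idx) < 2 * min_cluster_size) {
      warn(paste0("sample ", s, " too small; assigned a single cluster"))
      out[[s]] <- tibble(barcode = nm$cells$barcode[idx], sample = s,
                         cluster = paste0(s, "#1"))
      next
    }
    x <- t(nm$values[hvgs, idx, drop = FALSE])
    labels <- ward_silhouette(x, n_pcs, k_range)
    out[[s]] <- tibble(barcode = nm$cells$barcode[idx], sample = s,
                       cluster = paste0(s, "#", labels))
  }
  dplyr::bind_rows(out)
}

# PCA + Ward + silhouette model selection; single cluster when degenerate
ward_silhouette <- function(x, n_pcs, k_range) {
  keep <- apply(x, 2, var) > 0
  if (!any(keep)) return(rep(1L, nrow(x)))
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
               rank. = min(n_pcs, sum(keep), nrow(x) - 1))
  emb <- pc$x
  d <- dist(emb)
  if (max(d) == 0) return(rep(1L, nrow(x)))
  hc <- hclust(d, method = "ward.D2")
  k_range <- k_range[k_range < nrow(x)]
  sil <- vapply(k_range, function(k) {
    cl <- cutree(hc, k = k)
    if (length(unique(cl)) < 2) return(-Inf)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1))
  if (all(!is.finite(sil))) return(rep(1L, nrow(x)))
  cutree(hc, k = k_range[which.max(sil)])
}

#' Average transcriptome per within-sample cluster
#'
#' Tier-1 output: the arithmetic mean of normalised expression over the HVG
#' space for every within-sample cluster, with cell counts and the
#' cell-weighted mean mitochondrial fraction attached.
#'
#' @param nm A `normalized_matrix` covering the clustered cells.
#' @param clusters Output of [cluster_within_sample()] (or any tibble with
#'   `barcode`, `cluster`).
#' @param hvgs Genes over which centroids are computed; default all genes of
#'   `nm`.
#' @return A `cluster_profiles` object: `centroids` (hvgs x clusters matrix)
#'   and `meta` tibble (`cluster`, `patient`, `timepoint`, `n_cells`,
#'   `mean_mito`).
#' @export
compute_cluster_centroids <- function(nm, clusters, hvgs = NULL) {
  assert_that(all(nm$cells$barcode %in% clusters$barcode),
              "labels must cover all cells")
  if (is.null(hvgs)) hvgs <- nm$genes
  cl <- clusters$cluster[match(nm$cells$barcode, clusters$barcode)]
  ids <- sort(unique(cl))
  cent <- vapply(ids, function(id)
    rowMeans(nm$values[hvgs, cl == id, drop = FALSE]), numeric(length(hvgs)))
  rownames(cent) <- hvgs
  meta <- tibble(
    cluster = ids,
    patient = vapply(ids, function(id)
      nm$cells$patient[cl == id][1], character(1)),
    timepoint = vapply(ids, function(id)
      nm$cells$timepoint[cl == id][1], character(1)),
    n_cells = vapply(ids, function(id) sum(cl == id), integer(1)),
    mean_mito = vapply(ids, function(id)
      mean(nm$cells$mito_fraction[cl == id]), numeric(1))
  )
  structure(list(centroids = cent, meta = meta), class = "cluster_profiles")
}

#' Meta-cluster cluster centroids into shared programs
#'
#' Tier 2: hierarchical clustering of the within-sample cluster centroids
#' with correlation distance (1 - Pearson over the HVG space) and average
#' linkage, cut at `k_programs`. Because every patient and timepoint
#' contributes centroids, the resulting groups are transcriptional programs
#' shared across patients and timepoints. Program labels are ordered by
#' decreasing total member cell count (`TP1` largest).
#'
#' @param profiles A [compute_cluster_centroids()] result.
#' @param k_programs Number of programs to cut (default 5; program-level QC
#'   typically removes a low-quality one afterwards).
#' @return Tibble mapping `cluster` to `program`.
#' @export
metacluster_centroids <- function(profiles, k_programs = 5) {
  n_cl <- ncol(profiles$centroids)
  if (k_programs > n_cl)
    abort("k_programs exceeds the number of clusters",
          class = "amlprog_too_few_clusters")
  d <- as.dist(1 - cor(profiles$centroids))
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = k_programs)
  sizes <- tapply(profiles$meta$n_cells, raw[profiles$meta$cluster], sum)
  ord <- order(-sizes, as.integer(names(sizes)))
  relabel <- setNames(paste0("P", seq_len(k_programs)), names(sizes)[ord])
  tibble(cluster = profiles$meta$cluster,
         program = unname(relabel[as.character(raw[profiles$meta$cluster])]))
}

#' Per-program marker genes by one-vs-rest Wilcoxon tests
#'
#' For each program, every gene is tested with a two-sided Wilcoxon rank-sum
#' test of the program's cells against all other assigned cells; fold change
#' is computed on de-logged means
#' (`log2(mean(expm1(in)) + eps) - log2(mean(expm1(out)) + eps)`), and BH
#' correction is applied across genes within each program. A gene is an
#' overexpressed marker when `log2fc > log2fc_cut` and `q < q_cut`.
#'
#' @param nm A `normalized_matrix`.
#' @param program_labels Per-cell program labels aligned with `nm` cells;
#'   `NA` cells are excluded.
#' @param log2fc_cut,q_cut Marker thresholds (defaults 0.25 and 0.05).
#' @param eps Pseudo-value in the fold-change computation.
#' @param prep Optional [precompute_ranks()] of the assigned-cell submatrix,
#'   reused across repeated calls (e.g. label permutations).
#' @return Tibble with `program`, `gene`, `log2fc`, `p`, `q`, `frac_in`,
#'   `frac_out`, `overexpressed`. Programs with fewer than 3 cells are
#'   flagged in the `skipped_programs` attribute.
#' @export
derive_program_markers <- function(nm, program_labels, log2fc_cut = 0.25,
                                   q_cut = 0.05, eps = 1e-9, prep = NULL) {
  keep <- !is.na(program_labels)
  vals <- nm$values[, keep, drop = FALSE]
  labs <- program_labels[keep]
  progs <- sort(unique(labs))
  assert_that(length(progs) >= 2, "need at least 2 assigned programs")
  if (is.null(prep)) prep <- precompute_ranks(vals)
  e <- expm1(vals)
  pos <- vals > 0
  skipped <- character(0)
  res <- vector("list", length(progs))
  for (i in seq_along(progs)) {
    p <- progs[i]
    ing <- labs == p
    if (sum(ing) < 3) {
      skipped <- c(skipped, p)
      next
    }
    rs <- rank_sum_matrix(vals, ing, prep = prep)
    lfc <- log2(rowMeans(e[, ing, drop = FALSE]) + eps) -
      log2(rowMeans(e[, !ing, drop = FALSE]) + eps)
    res[[i]] <- tibble(program = p, gene = prep$genes,
                       log2fc = unname(lfc), p = rs$p,
                       q = bh_adjust(rs$p),
                       frac_in = unname(rowMeans(pos[, ing, drop = FALSE])),
                       frac_out = unname(rowMeans(pos[, !ing, drop = FALSE])))
  }
  out <- dplyr::bind_rows(res) |>
    mutate(overexpressed = .data$log2fc > log2fc_cut & .data$q < q_cut)
  attr(out, "skipped_programs") <- skipped
  out
}

#' Assemble a program set from discovery outputs
#'
#' Combines the cluster-to-program map, per-cell labels, marker tables and
#' per-program QC fields into one object; extracts per-program signature
#' gene lists (top `signature_n` overexpressed markers by fold change).
#'
#' @param clusters [cluster_within_sample()] output.
#' @param assignment [metacluster_centroids()] output.
#' @param markers [derive_program_markers()] output.
#' @param profiles [compute_cluster_centroids()] output.
#' @param signature_n Signature size (default 50).
#' @return A `program_set`: list with `assignment`, `cell_programs`,
#'   `markers`, `qc` (per-program `n_cells`, `n_markers`, `mean_mito`,
#'   `kept`), `signatures`.
#' @export
program_set <- function(clusters, assignment, markers, profiles,
                        signature_n = 50) {
  cell_programs <- clusters |>
    left_join(assignment, by = "cluster")
  qc <- profiles$meta |>
    left_join(assignment, by = "cluster") |>
    group_by(.data$program) |>
    summarise(mean_mito = sum(.data$mean_mito * .data$n_cells) /
                sum(.data$n_cells),
              n_cells = sum(.data$n_cells),
              .groups = "drop") |>
    relocate("program", "n_cells", "mean_mito") |>
    left_join(markers |>
                group_by(.data$program) |>
                summarise(n_markers = sum(.data$overexpressed),
                          .groups = "drop"),
              by = "program") |>
    mutate(n_markers = ifelse(is.na(.data$n_markers), 0L, .data$n_markers),
           kept = TRUE)
  structure(list(assignment = assignment, cell_programs = cell_programs,
                 markers = markers, qc = qc,
                 signatures = extract_signatures(markers, signature_n)),
            class = "program_set")
}

extract_signatures <- function(markers, n = 50) {
  sp <- split(markers[markers$overexpressed, ], markers$program[markers$overexpressed])
  lapply(sp, function(df) {
    df <- df[order(-df$log2fc, df$gene), ]
    head(df$gene, n)
  })
}

#' @export
print.program_set <- function(x, ...) {
  cat("<program_set> ", nrow(x$qc), " programs\n", sep = "")
  print(x$qc)
  invisible(x)
}

#' Drop low-quality programs
#'
#' A program is removed if and only if it has fewer than `min_markers`
#' overexpressed markers AND a cell-weighted mean mitochondrial fraction
#' above `max_mito` (a conjunction: many-marker programs survive regardless
#' of mitochondrial load, and clean programs survive regardless of marker
#' count). Cells of dropped programs are flagged unassigned (`NA`); the
#' dropped programs' audit rows are retained with `kept = FALSE`.
#'
#' @param ps A [program_set()].
#' @param min_markers,max_mito QC thresholds (defaults 200 and 0.20).
#' @return The filtered `program_set`.
#' @export
qc_filter_programs <- function(ps, min_markers = 200, max_mito = 0.20) {
  drop <- ps$qc$n_markers < min_markers & ps$qc$mean_mito > max_mito
  if (all(drop)) abort("all programs dropped by QC",
                       class = "amlprog_all_programs_dropped")
  dropped <- ps$qc$program[drop]
  ps$qc$kept <- !drop
  # audit trail: the pre-QC assignment stays available alongside the NAs
  if (!"program_pre_qc" %in% names(ps$cell_programs))
    ps$cell_programs$program_pre_qc <- ps$cell_programs$program
  if (!"program_pre_qc" %in% names(ps$assignment))
    ps$assignment$program_pre_qc <- ps$assignment$program
  ps$cell_programs$program[ps$cell_programs$program %in% dropped] <-
    NA_character_
  ps$assignment$program[ps$assignment$program %in% dropped] <- NA_character_
  ps$signatures <- ps$signatures[setdiff(names(ps$signatures), dropped)]
  ps
}

#' Top surface-molecule markers per program
#'
#' Intersects each program's overexpressed markers with a surface-protein
#' gene list and returns the top `n` by log2 fold change (ties broken by
#' gene identifier).
#'
#' @param ps A [program_set()] (or its `markers` tibble).
#' @param surface_genes Character vector of surface-annotated genes.
#' @param n Markers per program (default 5).
#' @return Tibble `program`, `gene`, `log2fc`, `rank`.
#' @export
top_surface_markers <- function(ps, surface_genes, n = 5) {
  assert_that(length(surface_genes) > 0, "surface gene list is empty")
  markers <- if (inherits(ps, "program_set")) ps$markers else ps
  out <- markers |>
    filter(.data$overexpressed, .data$gene %in% surface_genes) |>
    arrange(.data$program, desc(.data$log2fc), .data$gene) |>
    group_by(.data$program) |>
    slice_head(n = n) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select("program", "gene", "log2fc", "rank")
  empty <- setdiff(unique(markers$program), out$program)
  if (length(empty))
    warn(paste("no surface markers for program(s):",
               paste(empty, collapse = ", ")))
  out
}

#' Transcriptional-diversity differentiation score
#'
#' A simplified differentiation-potential score in the spirit of
#' transcriptional-diversity methods (higher diversity, less differentiated):
#' per-cell gene counts are correlated with every gene's normalised
#' expression, the per-cell mean expression of the `n_top` most correlated
#' genes is taken as the raw score, and scores are min-max rescaled to
#' \[0, 1\]. Higher score = higher inferred potential. This is a
#' reimplementation of the idea, not of any published tool.
#'
#' @param nm A `normalized_matrix` with at least 30 cells.
#' @param n_top Genes in the score signature (default 200).
#' @return Tibble `barcode`, `score`; attribute `signature_genes`.
#' @export
differentiation_score <- function(nm, n_top = 200) {
  assert_that(ncol(nm$values) >= 30, "need at least 30 cells")
  gc <- nm$cells$n_genes_detected
  if (sd(gc) == 0) abort("degenerate: constant gene counts",
                         class = "amlprog_degenerate_gene_counts")
  r <- as.numeric(cor(t(nm$values), gc))
  r[is.na(r)] <- -Inf
  ord <- order(-r, nm$genes)
  top <- nm$genes[ord][seq_len(min(n_top, length(nm$genes)))]
  raw <- colMeans(nm$values[top, , drop = FALSE])
  score <- (raw - min(raw)) / (max(raw) - min(raw))
  out <- tibble(barcode = nm$cells$barcode, score = unname(score))
  attr(out, "signature_genes") <- top
  attr(out, "convention") <- "higher = less differentiated (more potential)"
  out
}

#' Program composition per sample and timepoint
#'
#' Percentage of cells assigned to each program within every
#' patient x timepoint; unassigned cells (dropped programs) appear as their
#' own category so percentages always total 100.
#'
#' @param cell_programs Tibble with `barcode` and `program` (NA =
#'   unassigned), e.g. `program_set$cell_programs`.
#' @param cell_meta Tibble with `barcode`, `patient`, `timepoint`.
#' @return Tibble `patient`, `timepoint`, `program`, `n`, `pct`.
#' @export
program_composition <- function(cell_programs, cell_meta) {
  df <- cell_programs |>
    left_join(cell_meta |> select("barcode", "patient", "timepoint"),
              by = "barcode") |>
    mutate(program = ifelse(is.na(.data$program), "unassigned",
                            .data$program)) |>
    dplyr::count(.data$patient, .data$timepoint, .data$program, name = "n") |>
    group_by(.data$patient, .data$timepoint) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  df
}

#' Run the full two-tier program discovery
#'
#' Convenience wrapper: HVG selection, within-sample clustering, centroid
#' averaging, meta-clustering, marker derivation and program-level QC in one
#' call.
#'
#' @param nm A `normalized_matrix` of the cells to analyse (typically AML
#'   only).
#' @param k_programs Programs to cut at tier 2 (default 5).
#' @param n_hvgs Highly variable genes for tiers 1-2 (default 2000, capped
#'   at the gene count).
#' @param min_markers,max_mito Program-QC thresholds.
#' @param signature_n Signature size per program.
#' @param ... Passed to [cluster_within_sample()].
#' @return A QC-filtered [program_set()].
#' @export
discover_programs <- function(nm, k_programs = 5, n_hvgs = 2000,
                              min_markers = 200, max_mito = 0.20,
                              signature_n = 50, ...) {
  hvgs <- select_hvgs(nm, min(n_hvgs, length(nm$genes)))
  clusters <- cluster_within_sample(nm, hvgs = hvgs, ...)
  profiles <- compute_cluster_centroids(nm, clusters, hvgs = hvgs)
  assignment <- metacluster_centroids(profiles, k_programs = k_programs)
  labels <- assignment$program[
    match(clusters$cluster[match(nm$cells$barcode, clusters$barcode)],
          assignment$cluster)]
  markers <- derive_program_markers(nm, labels)
  ps <- program_set(clusters, assignment, markers, profiles,
                    signature_n = signature_n)
  qc_filter_programs(ps, min_markers = min_markers, max_mito = max_mito)
}
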