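# build a normalized_matrix directly from a dense value matrix
nm_from_values <- function(vals, meta) {
  structure(list(values = vals, genes = rownames(vals), cells = meta,
                 scale = 10000),
            class = "normalized_matrix")
}

blob_meta <- function(n, patient = "P1", timepoint = "0h") {
  tibble::tibble(barcode = sprintf("%s_%s_b%03d", patient, timepoint, 1:n),
                 patient = patient, timepoint = timepoint,
                 replicate = "R1", population = "AML",
                 total_counts = 1000, n_genes_detected = 50,
                 mito_fraction = 0.05)
}

test_that("two well-separated blobs per sample are recovered with k = 2", {
  set.seed(1)
  n <- 60
  vals <- cbind(matrix(rnorm(50 * n, 0, 0.3), 50),
                matrix(rnorm(50 * n, 3, 0.3), 50))
  rownames(vals) <- paste0("G", 1:50)
  meta <- blob_meta(2 * n)
  cl <- cluster_within_sample(nm_from_values(vals, meta),
                              hvgs = rownames(vals), n_pcs = 10)
  truth <- rep(1:2, each = n)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(ari(cl$cluster, truth), 1)
})

test_that("identical cells fall back to a single cluster", {
  vals <- matrix(1, 20, 50, dimnames = list(paste0("G", 1:20), NULL))
  meta <- blob_meta(50)
  cl <- cluster_within_sample(nm_from_values(vals, meta),
                              hvgs = rownames(vals), min_cluster_size = 10)
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("small samples get one cluster with a warning", {
  set.seed(2)
  vals <- matrix(rnorm(20 * 15), 20, dimnames = list(paste0("G", 1:20), NULL))
  meta <- blob_meta(15)
  expect_warning(
    cl <- cluster_within_sample(nm_from_values(vals, meta),
                                hvgs = rownames(vals),
                                min_cluster_size = 10),
    "too small")
  expect_equal(length(unique(cl$cluster)), 1)
})

test_that("centroids are means: single cells, linearity, order invariance", {
  set.seed(3)
  vals <- matrix(rnorm(10 * 5), 10,
                 dimnames = list(paste0("G", 1:10), paste0("c", 1:5)))
  meta <- blob_meta(5)
  meta$barcode <- paste0("c", 1:5)
  nm <- nm_from_values(vals, meta)
  cl <- tibble::tibble(barcode = meta$barcode, sample = "s",
                       cluster = c("a", "a", "b", "b", "c"))
  prof <- compute_cluster_centroids(nm, cl)
  # singleton cluster equals its cell
  expect_equal(unname(prof$centroids[, "c"]), unname(vals[, 5]))
  # merging two equal-size clusters averages their centroids
  cl2 <- cl; cl2$cluster <- c("ab", "ab", "ab", "ab", "c")
  prof2 <- compute_cluster_centroids(nm, cl2)
  expect_equal(prof2$centroids[, "ab"],
               (prof$centroids[, "a"] + prof$centroids[, "b"]) / 2)
  # permuting cells changes nothing
  idx <- c(4, 2, 5, 1, 3)
  nm_p <- nm_from_values(vals[, idx], meta[idx, ])
  expect_equal(compute_cluster_centroids(nm_p, cl)$centroids,
               prof$centroids)
})

test_that("meta-clustering separates distinct centroids and ignores scale", {
  set.seed(4)
  base <- matrix(rnorm(30 * 3), 30)
  cent <- base[, c(1, 1, 2, 2, 3, 3)] +
    matrix(rnorm(30 * 6, 0, 0.01), 30)
  colnames(cent) <- paste0("cl", 1:6)
  rownames(cent) <- paste0("G", 1:30)
  meta <- tibble::tibble(cluster = colnames(cent), patient = "P1",
                         timepoint = "0h", n_cells = c(30, 20, 10, 5, 4, 3),
                         mean_mito = 0.05)
  prof <- structure(list(centroids = cent, meta = meta),
                    class = "cluster_profiles")
  asn <- metacluster_centroids(prof, k_programs = 3)
  expect_equal(asn$program[1], asn$program[2])
  expect_equal(asn$program[3], asn$program[4])
  expect_false(asn$program[1] == asn$program[3])
  # programs ordered by decreasing member cell count
  expect_equal(asn$program[1], "P1")
  # correlation distance is invariant to per-centroid affine rescaling
  cent2 <- sweep(sweep(cent, 2, runif(6, 0.5, 2), `*`), 2, rnorm(6), `+`)
  prof2 <- structure(list(centroids = cent2, meta = meta),
                     class = "cluster_profiles")
  expect_equal(metacluster_centroids(prof2, 3), asn)
  expect_error(metacluster_centroids(prof, 7),
               class = "amlprog_too_few_clusters")
})

test_that("meta-clustering is invariant to sample processing order", {
  run <- tiny_run()
  nm <- run$nm_aml
  hv <- select_hvgs(nm, 300)
  cl <- cluster_within_sample(nm, hvgs = hv)
  prof <- compute_cluster_centroids(nm, cl, hvgs = hv)
  asn <- metacluster_centroids(prof, 4)
  # reverse the centroid order (samples contribute in reverse)
  idx <- rev(seq_len(ncol(prof$centroids)))
  prof_r <- structure(list(centroids = prof$centroids[, idx],
                           meta = prof$meta[idx, ]),
                      class = "cluster_profiles")
  asn_r <- metacluster_centroids(prof_r, 4)
  merged <- dplyr::left_join(asn, asn_r, by = "cluster")
  expect_equal(ari(merged$program.x, merged$program.y), 1)
})

test_that("a gene expressed only in one program is its marker", {
  set.seed(6)
  n <- 40
  vals <- matrix(rpois(30 * 2 * n, 2) / 2, 30)
  rownames(vals) <- paste0("G", 1:30)
  vals["G1", ] <- 0
  vals["G1", 1:n] <- 2  # exclusive to program A
  meta <- blob_meta(2 * n)
  nm <- nm_from_values(vals, meta)
  labels <- rep(c("A", "B"), each = n)
  mk <- derive_program_markers(nm, labels)
  g1 <- mk[mk$program == "A" & mk$gene == "G1", ]
  expect_true(g1$overexpressed)
  expect_false(mk$overexpressed[mk$program == "B" & mk$gene == "G1"])
})

test_that("markers flag tiny programs and respect the NA exclusion", {
  set.seed(7)
  vals <- matrix(rnorm(20 * 30), 20, dimnames = list(paste0("G", 1:20), NULL))
  meta <- blob_meta(30)
  labels <- c(rep("A", 14), rep("B", 14), "C", NA)
  mk <- derive_program_markers(nm_from_values(vals, meta), labels)
  expect_equal(attr(mk, "skipped_programs"), "C")
  expect_setequal(unique(mk$program), c("A", "B"))
})

test_that("program QC implements the printed conjunction rule", {
  qc <- tibble::tibble(program = c("P1", "P2", "P3"),
                       n_cells = c(100L, 50L, 40L),
                       mean_mito = c(0.30, 0.30, 0.05),
                       n_markers = c(500L, 10L, 10L),
                       kept = TRUE)
  ps <- structure(list(
    assignment = tibble::tibble(cluster = c("a", "b", "c"),
                                program = c("P1", "P2", "P3")),
    cell_programs = tibble::tibble(barcode = c("x", "y", "z"),
                                   cluster = c("a", "b", "c"),
                                   program = c("P1", "P2", "P3")),
    markers = tibble::tibble(), qc = qc,
    signatures = list(P1 = "G1", P2 = "G2", P3 = "G3")),
    class = "program_set")
  # 500 markers + 30% mito -> kept (conjunction fails); few markers + low
  # mito -> kept; few markers + high mito -> dropped
  out <- qc_filter_programs(ps, min_markers = 200, max_mito = 0.20)
  expect_equal(out$qc$kept, c(TRUE, FALSE, TRUE))
  expect_true(is.na(out$cell_programs$program[2]))
  expect_false("P2" %in% names(out$signatures))
  # identity thresholds keep everything
  ident <- qc_filter_programs(ps, min_markers = 0, max_mito = 1)
  expect_true(all(ident$qc$kept))
  # all dropped is an error
  qc_all <- qc; qc_all$n_markers <- 0L; qc_all$mean_mito <- 0.9
  ps_all <- ps; ps_all$qc <- qc_all
  expect_error(qc_filter_programs(ps_all),
               class = "amlprog_all_programs_dropped")
})

test_that("surface marker ranking intersects, ranks and truncates", {
  mk <- tibble::tibble(
    program = rep("P1", 5),
    gene = c("S1", "S2", "N1", "S3", "N2"),
    log2fc = c(1.0, 2.0, 3.0, 0.5, 0.3),
    p = 1e-4, q = 1e-3,
    frac_in = 0.5, frac_out = 0.1,
    overexpressed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  surface <- c("S1", "S2", "S3")
  top <- top_surface_markers(mk, surface, n = 2)
  expect_equal(top$gene, c("S2", "S1"))
  # surface list covering all genes returns overall top markers
  all_top <- top_surface_markers(mk, mk$gene, n = 5)
  expect_equal(all_top$gene[1], "N1")
  # n beyond the intersection returns the whole intersection
  expect_equal(nrow(top_surface_markers(mk, surface, n = 10)), 3)
  expect_warning(top_surface_markers(mk, "ABSENT"), "no surface markers")
})

test_that("differentiation score is bounded, stable under duplication", {
  run <- tiny_run()
  nm <- run$nm_aml
  sc <- differentiation_score(nm)
  expect_equal(min(sc$score), 0)
  expect_equal(max(sc$score), 1)
  # duplicating every cell leaves each original score unchanged
  nm_dup <- nm
  nm_dup$values <- cbind(nm$values, nm$values)
  cells2 <- dplyr::bind_rows(nm$cells,
                             dplyr::mutate(nm$cells,
                                           barcode = paste0(barcode, "_d")))
  nm_dup$cells <- cells2
  sc2 <- differentiation_score(nm_dup)
  expect_equal(sc2$score[seq_len(nrow(sc))], sc$score, tolerance = 1e-12)
  # degenerate input errors
  nm_const <- nm
  nm_const$cells$n_genes_detected <- 100L
  expect_error(differentiation_score(nm_const),
               class = "amlprog_degenerate_gene_counts")
})

test_that("differentiation score tracks planted transcriptional diversity", {
  run <- tiny_run()
  sc <- differentiation_score(run$nm_aml)
  planted <- run$sim$truth$maturation_rank[
    match(run$nm_aml$cells$barcode, run$sim$cells$cells$barcode)]
  expect_gte(cor(sc$score, planted, method = "spearman"), 0.8)
})

test_that("program composition sums to 100 and reflects planted depletion", {
  run <- tiny_run()
  sim <- run$sim
  cp <- tibble::tibble(barcode = sim$cells$cells$barcode,
                       program = sim$truth$program)
  comp <- program_composition(cp[sim$cells$cells$population == "AML", ],
                              sim$cells$cells)
  sums <- comp |>
    dplyr::group_by(patient, timepoint) |>
    dplyr::summarise(s = sum(pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
  # the depleted program loses share at 24h in every patient
  depl <- paste0("TP", tiny_config()$depleted_program)
  wide <- comp |>
    dplyr::filter(program == depl) |>
    tidyr::pivot_wider(names_from = timepoint, values_from = pct,
                       id_cols = patient)
  expect_true(all(wide$`24h` < wide$`0h`))
  # single-program composition is 100%
  one <- program_composition(
    tibble::tibble(barcode = c("a", "b"), program = "P1"),
    tibble::tibble(barcode = c("a", "b"), patient = "X", timepoint = "0h"))
  expect_equal(one$pct, 100)
})

test_that("a surface gene list file drives surface-marker ranking", {
  path <- system.file("extdata", "synthetic_surface_genes.txt",
                      package = "amlprog")
  surface <- readLines(path)
  run <- tiny_run()
  ps <- memo("tiny_ps", discover_programs(run$nm_aml, k_programs = 4,
                                          n_hvgs = 300, min_markers = 40))
  top <- top_surface_markers(ps, surface, n = 5)
  expect_true(all(top$gene %in% surface))
  expect_true(all(top$rank <= 5))
  # within each program, ranked by decreasing fold change
  ok <- top |>
    dplyr::group_by(program) |>
    dplyr::summarise(sorted = !is.unsorted(rev(log2fc)), .groups = "drop")
  expect_true(all(ok$sorted))
})
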