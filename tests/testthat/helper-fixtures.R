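library(Matrix)

# small simulated dataset for module-level tests: fast but structured
tiny_config <- function(seed = 1, ...) {
  sim_config(n_patients = 2, cells_per_sample = 150, tcells_per_sample = 60,
             n_genes = 600, n_programs = 4, signature_size = 60,
             lowq_signature_size = 10, activation_size = 25,
             tcell_response_size = 40, seed = seed, ...)
}

# memoised fixtures shared across test files (computed once per test run)
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_run <- function() {
  memo("tiny_run", {
    sim <- simulate_cells(tiny_config())
    cells <- qc_filter_cells(sim$cells, min_genes = 50, max_mito = 0.75)
    nm <- normalize_log_cpm(cells)
    list(sim = sim, cells = cells, nm = nm,
         nm_aml = subset_cells(nm, nm$cells$population == "AML"))
  })
}

# the full study-scale dataset and discovery used by the acceptance suite
default_run <- function(seed = 1) {
  memo(paste0("default_run_", seed), {
    t0 <- Sys.time()
    sim <- simulate_cells(sim_config(seed = seed))
    cells <- qc_filter_cells(sim$cells, min_genes = 200, max_mito = 0.75)
    nm <- normalize_log_cpm(cells)
    nm_aml <- subset_cells(nm, nm$cells$population == "AML")
    ps <- discover_programs(nm_aml)
    el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    list(sim = sim, nm = nm, nm_aml = nm_aml, ps = ps, elapsed = el)
  })
}

# program QC outcome at study scale for one seed, without caching the
# (large) intermediates: returns per-program QC with the matched planted label
lean_qc_outcome <- function(seed) {
  sim <- simulate_cells(sim_config(seed = seed))
  cells <- qc_filter_cells(sim$cells, min_genes = 200, max_mito = 0.75)
  nm <- normalize_log_cpm(cells)
  nm_aml <- subset_cells(nm, nm$cells$population == "AML")
  ps <- discover_programs(nm_aml)
  pm <- program_match(list(sim = sim, nm_aml = nm_aml, ps = ps))
  qc <- ps$qc
  qc$planted <- unname(pm$map[qc$program])
  qc$lowq <- qc$planted == sim$truth$lowq_program
  qc
}

# map discovered programs to the planted ones by majority overlap (using the
# pre-QC assignment so dropped programs stay mappable); returns the mapping
# plus per-cell truth/found label vectors
program_match <- function(run) {
  cp <- run$ps$cell_programs
  idx <- match(run$nm_aml$cells$barcode, cp$barcode)
  truth <- run$sim$truth$program[match(run$nm_aml$cells$barcode,
                                       run$sim$cells$cells$barcode)]
  found <- cp$program[idx]
  found_all <- (cp$program_pre_qc %||% cp$program)[idx]
  tab <- table(found_all, truth)
  map <- setNames(colnames(tab)[apply(tab, 1, which.max)], rownames(tab))
  list(map = map, truth = truth, found = found, found_all = found_all)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two label vectors (pairs with NA dropped)
ari <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  mclust::adjustedRandIndex(a[ok], b[ok])
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
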