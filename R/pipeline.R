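#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Unknown keys are rejected outright so silent typos cannot change an
#' analysis. The global `seed` fans out to per-stage seeds as
#' `seed + 1000 * stage_index`, so any stage can be reproduced in isolation.
#'
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param sim Named list of [sim_config()] overrides.
#' @param qc List: `min_genes`, `max_mito` for cell-level QC. The default
#'   mito ceiling is permissive (0.75) so that high-mitochondrial programs
#'   survive to program-level QC, where the conjunction rule removes them.
#' @param discovery List: `k_programs`, `n_hvgs`, `min_markers`, `max_mito`,
#'   `signature_n`.
#' @param bulk List: `n_samples`, `noise_sd`.
#' @param lr List: `n_pairs`, `complex_fraction`.
#' @param verbose Emit progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("amlprog_run_"),
                            seed = 1,
                            sim = list(),
                            qc = list(min_genes = 200, max_mito = 0.75),
                            discovery = list(k_programs = 5, n_hvgs = 2000,
                                             min_markers = 200,
                                             max_mito = 0.20,
                                             signature_n = 50),
                            bulk = list(n_samples = 50, noise_sd = 0.3),
                            lr = list(n_pairs = 25, complex_fraction = 0.3),
                            verbose = TRUE, ...) {
  extra <- list(...)
  if (length(extra))
    abort(paste("unknown config key(s):",
                paste(names(extra), collapse = ", ")),
          class = "amlprog_unknown_config_key")
  cfg <- list(out_dir = out_dir, seed = seed, sim = sim, qc = qc,
              discovery = discovery, bulk = bulk, lr = lr, verbose = verbose)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- c("out_dir", "seed", "sim", "qc", "discovery", "bulk", "lr",
             "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")),
          class = "amlprog_unknown_config_key")
  defaults <- list(
    qc = list(min_genes = 200, max_mito = 0.75),
    discovery = list(k_programs = 5, n_hvgs = 2000, min_markers = 200,
                     max_mito = 0.20, signature_n = 50),
    bulk = list(n_samples = 50, noise_sd = 0.3),
    lr = list(n_pairs = 25, complex_fraction = 0.3))
  for (blk in names(defaults)) {
    bad <- setdiff(names(cfg[[blk]]), names(defaults[[blk]]))
    if (blk != "sim" && length(bad))
      abort(paste0("unknown config key(s) in ", blk, ": ",
                   paste(bad, collapse = ", ")),
            class = "amlprog_unknown_config_key")
    cfg[[blk]] <- utils::modifyList(defaults[[blk]], cfg[[blk]] %||% list())
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the keys of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate -> cell QC -> normalisation -> two-tier program
#' discovery -> T-cell response DE and over-representation -> interaction
#' scoring -> bulk-cohort outcome association -> killing-assay summary, and
#' writes every result as CSV/JSON under `config$out_dir` along with the
#' resolved configuration and a manifest of MD5 hashes covering every file
#' written. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; attribute `results` holds the
#'   in-memory objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message("[amlprog] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
            class = "amlprog_stage_error"))
  }
  res <- list()

  say("stage 1/7: simulate")
  sim_args <- utils::modifyList(list(seed = stage_seed(config$seed, 1)),
                                config$sim)
  sim <- stage("simulate", {
    simulate_cells(do.call(sim_config, sim_args))
  })
  res$sim <- sim

  say("stage 2/7: qc + normalise")
  nm <- stage("io_qc", {
    cells <- qc_filter_cells(sim$cells, config$qc$min_genes,
                             config$qc$max_mito)
    normalize_log_cpm(cells)
  })

  say("stage 3/7: program discovery")
  aml_idx <- nm$cells$population == "AML"
  nm_aml <- subset_cells(nm, aml_idx)
  ps <- stage("program_discovery", {
    do.call(discover_programs, c(list(nm_aml), config$discovery))
  })
  res$programs <- ps
  readr::write_csv(ps$cell_programs, file.path(config$out_dir, "programs.csv"))
  readr::write_csv(ps$markers, file.path(config$out_dir, "markers.csv"))
  readr::write_csv(ps$qc, file.path(config$out_dir, "program_qc.csv"))
  comp <- program_composition(ps$cell_programs, nm_aml$cells)
  readr::write_csv(comp, file.path(config$out_dir, "composition.csv"))
  diff_sc <- differentiation_score(nm_aml)
  readr::write_csv(diff_sc, file.path(config$out_dir, "differentiation.csv"))

  say("stage 4/7: T-cell response")
  tc <- stage("tcell_response", {
    sens <- nm$cells$patient %in% sim$truth$sensitive_patients
    tcell <- nm$cells$population == "TCELL"
    nm_s <- subset_cells(nm, tcell & sens)
    nm_r <- subset_cells(nm, tcell & !sens)
    de_s <- de_between_conditions(nm_s, nm_s$cells$timepoint)
    de_r <- de_between_conditions(nm_r, nm_r$cells$timepoint)
    top <- unique_top_genes(de_s, de_r)
    ora <- overrepresentation_test(
      top,
      signatures = list(
        planted_response = sim$truth$tcell_response_genes,
        activation_module = sim$truth$activation_genes),
      universe = nm$genes)
    list(de_sensitive = de_s, de_resistant = de_r, top_unique = top,
         enrichment = ora)
  })
  res$tcell <- tc
  readr::write_csv(tc$de_sensitive,
                   file.path(config$out_dir, "de_sensitive.csv"))
  readr::write_csv(tc$de_resistant,
                   file.path(config$out_dir, "de_resistant.csv"))
  readr::write_csv(tc$enrichment,
                   file.path(config$out_dir, "enrichment_top50.csv"))

  say("stage 5/7: interaction scoring")
  inter <- stage("interaction_scoring", {
    kept <- ps$qc$program[ps$qc$kept]
    focal <- kept[1]
    labels <- ps$cell_programs$program[
      match(nm$cells$barcode, ps$cell_programs$barcode)]
    prog_cells <- which(!is.na(labels) & labels == focal)
    sens <- nm$cells$patient %in% sim$truth$sensitive_patients
    t_cells <- which(nm$cells$population == "TCELL" & sens &
                       nm$cells$timepoint == "24h")
    planted <- list(partner_a = sim$truth$signatures[[1]][1],
                    partner_b = sim$truth$tcell_response_genes[1])
    db <- simulate_lr_database(config$lr$n_pairs, config$lr$complex_fraction,
                               gene_universe = nm$genes,
                               seed = stage_seed(config$seed, 5),
                               planted = planted)
    fm <- ps$markers[ps$markers$program == focal, ]
    scored <- score_interactions(qc_filter_cells(sim$cells,
                                                 config$qc$min_genes,
                                                 config$qc$max_mito),
                                 prog_cells, t_cells, db, fm,
                                 tc$de_sensitive)
    list(db = db, scored = scored, focal = focal)
  })
  res$interactions <- inter
  readr::write_csv(inter$scored, file.path(config$out_dir, "interactions.csv"))

  say("stage 6/7: outcome association")
  outc <- stage("outcome_association", {
    bk <- simulate_bulk_cohort(sim$truth$signatures[
      setdiff(names(sim$truth$signatures),
              sim$truth$lowq_program)],
      n_samples = config$bulk$n_samples,
      noise_sd = config$bulk$noise_sd,
      seed = stage_seed(config$seed, 6))
    ab <- score_program_abundance(bk$cohort, ps$signatures)
    ee_cor <- correlate_abundance_with_killing(ab, bk$cohort$samples$ee)
    enr <- subtype_enrichment(ab, bk$cohort$samples$subtype)
    dom <- assign_dominant_program(ab)
    km <- km_logrank(bk$cohort$samples$survival_time,
                     bk$cohort$samples$event,
                     dom$program)
    cox <- lapply(rownames(ab), function(p)
      cox_model(bk$cohort$samples$survival_time, bk$cohort$samples$event,
                ab[p, ], high_risk = bk$cohort$samples$high_risk))
    names(cox) <- rownames(ab)
    list(bulk = bk, abundance = ab, ee_cor = ee_cor, enrichment = enr,
         dominant = dom, km = km, cox = cox)
  })
  res$outcome <- outc
  readr::write_csv(as_tibble(t(outc$abundance), rownames = "sample"),
                   file.path(config$out_dir, "abundance.csv"))
  readr::write_csv(outc$ee_cor, file.path(config$out_dir, "ee_correlation.csv"))
  readr::write_csv(outc$enrichment, file.path(config$out_dir, "enrichment.csv"))
  surv_json <- list(
    logrank = list(chisq = outc$km$logrank_chisq, df = outc$km$logrank_df,
                   p = outc$km$logrank_p),
    cox = lapply(outc$cox, function(f)
      list(beta = f$beta, se = f$se, hr = f$hr, ci = f$hr_ci,
           wald_p = f$wald_p)))
  jsonlite::write_json(surv_json, file.path(config$out_dir,
                                            "survival_fits.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  say("stage 7/7: killing assay")
  kill <- stage("killing_assay", {
    ee <- outc$bulk$cohort$samples$ee
    recs <- tibble(target_id = rep(outc$bulk$cohort$samples$sample, each = 2),
                   donor_id = rep(c("D1", "D2"),
                                  length(ee)),
                   count_alone = 1000) |>
      mutate(count_with_t = pmax(0, round(
        1000 * (1 - rep(ee, each = 2) / 100))),
        ee_percent = elimination_efficiency(.data$count_with_t,
                                            .data$count_alone))
    summarize_replicates(recs)
  })
  res$killing <- kill
  readr::write_csv(kill, file.path(config$out_dir, "killing_summary.csv"))

  # resolved config (minus the run-specific output path) + manifest
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")],
                   file.path(config$out_dir, "config.yaml"))
  files <- setdiff(list.files(config$out_dir), "manifest.csv")
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(
                       file.path(config$out_dir, files))))
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"))
  say("done: ", config$out_dir)
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}
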