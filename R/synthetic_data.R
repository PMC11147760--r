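#' Simulation configuration for the single-cell generator
#'
#' Encodes the study design the generator emulates: several patients sampled
#' at 0h and 24h of co-culture, two replicate effector donors, a few thousand
#' AML cells per sample plus effector T cells, and a handful of planted
#' transcriptional programs with overlapping gene signatures. One planted
#' program is deliberately low quality: few, weak markers and a high
#' mitochondrial load, so program-level QC has something to remove.
#'
#' @param n_patients Number of patients; the first half are "sensitive", the
#'   rest "resistant" (drives the planted T-cell response asymmetry).
#' @param n_replicates Replicate effector donors per patient x timepoint.
#' @param cells_per_sample AML cells per patient x timepoint x replicate.
#' @param tcells_per_sample Effector T cells per sample.
#' @param n_genes Total genes, including `mito_gene_count` MT- genes.
#' @param n_programs Planted programs; the last is the low-quality one when
#'   `lowq_program` is TRUE.
#' @param signature_size Genes per good program signature.
#' @param signature_overlap Fraction of each signature shared with the
#'   previous program's signature.
#' @param signature_uplift Multiplicative mean uplift on signature genes in
#'   cells of the matching program.
#' @param program_mix Base per-sample program proportions (simplex over
#'   `n_programs`).
#' @param depleted_program Program index depleted at 24h, `depletion_factor`
#'   the multiplier applied to its mixing weight before renormalisation.
#' @param depletion_factor See `depleted_program`.
#' @param nb_dispersion Negative-binomial dispersion (size = 1/dispersion),
#'   shared across genes.
#' @param libsize_meanlog,libsize_sdlog Log-normal library-size parameters.
#' @param mito_gene_count Number of MT- prefixed genes.
#' @param lowq_program Plant a low-quality program? Its cells receive a
#'   mitochondrial uplift targeting `lowq_mito_target` mean mito fraction and
#'   a small weak signature (`lowq_signature_size`, `lowq_uplift`).
#' @param lowq_mito_target Target mean mitochondrial fraction for the planted
#'   low-quality program's cells.
#' @param lowq_signature_size,lowq_uplift Size and uplift of the low-quality
#'   program's (weak) signature.
#' @param patient_shift_sd SD (log scale) of the patient-specific per-gene
#'   multiplicative baseline shift.
#' @param activation_size Genes in the shared 24h activation module,
#'   `activation_uplift` its multiplier (applied to all 24h cells).
#' @param activation_uplift See `activation_size`.
#' @param tcell_response_size Genes uplifted in T cells at 24h when
#'   co-cultured with a sensitive patient sample; `tcell_response_uplift`
#'   the multiplier.
#' @param tcell_response_uplift See `tcell_response_size`.
#' @param seed Integer seed; fully determines the output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 4,
                       n_replicates = 2,
                       cells_per_sample = 800,
                       tcells_per_sample = 250,
                       n_genes = 2000,
                       n_programs = 5,
                       signature_size = 150,
                       signature_overlap = 0.10,
                       signature_uplift = 3,
                       program_mix = NULL,
                       depleted_program = 2,
                       depletion_factor = 0.4,
                       nb_dispersion = 0.5,
                       libsize_meanlog = log(2500),
                       libsize_sdlog = 0.3,
                       mito_gene_count = 15,
                       lowq_program = TRUE,
                       lowq_mito_target = 0.30,
                       lowq_signature_size = 20,
                       lowq_uplift = 1.5,
                       patient_shift_sd = 0.15,
                       activation_size = 50,
                       activation_uplift = 2,
                       tcell_response_size = 100,
                       tcell_response_uplift = 3,
                       seed = 1) {
  if (is.null(program_mix)) {
    program_mix <- if (lowq_program && n_programs >= 2) {
      w <- c(rev(seq_len(n_programs - 1)) + 1, 1)
      w / sum(w)
    } else {
      rep(1 / n_programs, n_programs)
    }
  }
  cfg <- list(n_patients = n_patients, n_timepoints = 2L,
              n_replicates = n_replicates,
              cells_per_sample = cells_per_sample,
              tcells_per_sample = tcells_per_sample,
              n_genes = n_genes, n_programs = n_programs,
              signature_size = signature_size,
              signature_overlap = signature_overlap,
              signature_uplift = signature_uplift,
              program_mix = program_mix,
              depleted_program = depleted_program,
              depletion_factor = depletion_factor,
              nb_dispersion = nb_dispersion,
              libsize_meanlog = libsize_meanlog,
              libsize_sdlog = libsize_sdlog,
              mito_gene_count = mito_gene_count,
              lowq_program = lowq_program,
              lowq_mito_target = lowq_mito_target,
              lowq_signature_size = lowq_signature_size,
              lowq_uplift = lowq_uplift,
              patient_shift_sd = patient_shift_sd,
              activation_size = activation_size,
              activation_uplift = activation_uplift,
              tcell_response_size = tcell_response_size,
              tcell_response_uplift = tcell_response_uplift,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$n_programs >= 2, "need at least 2 programs")
  if (abs(sum(cfg$program_mix) - 1) > 1e-8 || any(cfg$program_mix < 0))
    abort("program_mix must be a simplex (nonnegative, summing to 1)",
          class = "amlprog_invalid_simplex")
  assert_that(length(cfg$program_mix) == cfg$n_programs,
              "program_mix length must equal n_programs")
  n_good <- cfg$n_programs - as.integer(cfg$lowq_program)
  need <- n_good * cfg$signature_size +
    as.integer(cfg$lowq_program) * cfg$lowq_signature_size +
    cfg$activation_size + cfg$tcell_response_size + cfg$mito_gene_count
  if (need > cfg$n_genes)
    abort("signature_size x n_programs (plus modules) exceeds n_genes",
          class = "amlprog_signature_overflow")
  invisible(cfg)
}

#' Simulate a longitudinal co-culture single-cell dataset with planted truth
#'
#' Draws negative-binomial counts for AML and T cells across patients,
#' timepoints and replicates. AML cells belong to planted transcriptional
#' programs whose signature genes carry a multiplicative mean uplift;
#' patient-specific per-gene baseline shifts, a shared 24h activation
#' module, log-normal library sizes, and a high-mitochondrial low-quality
#' program emulate the main nuisance structure of real droplet data.
#' T cells of sensitive-patient samples receive a planted 24h response
#' module; resistant-partner T cells do not.
#'
#' @param config A [sim_config()].
#' @return List with `cells` (a [cell_matrix()]) and `truth` (list:
#'   `program` per-cell planted labels (NA for T cells), `signatures` named
#'   list of gene sets, `lowq_program` name or NA, `activation_genes`,
#'   `tcell_response_genes`, `sensitive_patients`, `maturation_rank`
#'   per-cell rank of transcriptional diversity, `program_mix` matrix of
#'   per-sample mixing proportions).
#' @export
simulate_cells <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  g <- config$n_genes
  mito_genes <- sprintf("%s%02d", MITO_PREFIX, seq_len(config$mito_gene_count))
  other_genes <- sprintf("G%04d", seq_len(g - config$mito_gene_count))
  genes <- c(mito_genes, other_genes)

  n_good <- config$n_programs - as.integer(config$lowq_program)
  prog_names <- paste0("TP", seq_len(config$n_programs))

  # disjoint signature blocks over non-mito genes, then overlap with the
  # previous program's block
  pool <- other_genes
  sigs <- vector("list", config$n_programs)
  names(sigs) <- prog_names
  idx <- 0
  for (p in seq_len(n_good)) {
    sigs[[p]] <- pool[idx + seq_len(config$signature_size)]
    idx <- idx + config$signature_size
  }
  if (config$lowq_program) {
    sigs[[config$n_programs]] <- pool[idx + seq_len(config$lowq_signature_size)]
    idx <- idx + config$lowq_signature_size
  }
  n_ov <- round(config$signature_overlap * config$signature_size)
  if (n_ov > 0 && n_good >= 2) {
    for (p in 2:n_good) {
      sigs[[p]][seq_len(n_ov)] <- sigs[[p - 1]][
        config$signature_size - n_ov + seq_len(n_ov)]
    }
  }
  activation_genes <- pool[idx + seq_len(config$activation_size)]
  idx <- idx + config$activation_size
  tcell_genes <- pool[idx + seq_len(config$tcell_response_size)]

  # baselines: lognormal relative expression; mito genes get ~6% of mass
  base <- rlnorm(g, meanlog = 0, sdlog = 1)
  names(base) <- genes
  mito_share <- 0.06
  base[mito_genes] <- sum(base[other_genes]) * mito_share /
    ((1 - mito_share) * length(mito_genes))
  # mito uplift for low-quality cells, solved so their mito share hits target
  s0 <- mito_share; st <- config$lowq_mito_target
  mito_uplift <- st * (1 - s0) / (s0 * (1 - st))

  shifts <- matrix(rlnorm(g * config$n_patients, 0, config$patient_shift_sd),
                   nrow = g,
                   dimnames = list(genes, NULL))

  patients <- sprintf("PT%02d", seq_len(config$n_patients))
  sensitive <- patients[seq_len(ceiling(config$n_patients / 2))]
  timepoints <- c("0h", "24h")
  size <- 1 / config$nb_dispersion

  blocks <- list(); meta <- list(); truth_prog <- list(); mix_rows <- list()
  cell_id <- 0
  for (q in seq_len(config$n_patients)) {
    for (t in timepoints) {
      for (r in seq_len(config$n_replicates)) {
        sample_id <- paste(patients[q], t, paste0("R", r), sep = "_")
        mix <- config$program_mix
        if (t == "24h") {
          mix[config$depleted_program] <-
            mix[config$depleted_program] * config$depletion_factor
          mix <- mix / sum(mix)
        }
        mix_rows[[sample_id]] <- mix
        n_per <- as.vector(rmultinom(1, config$cells_per_sample, mix))
        for (p in seq_len(config$n_programs)) {
          if (n_per[p] == 0) next
          rel <- base * shifts[, q]
          rel[sigs[[p]]] <- rel[sigs[[p]]] *
            if (config$lowq_program && p == config$n_programs)
              config$lowq_uplift else config$signature_uplift
          if (config$lowq_program && p == config$n_programs)
            rel[mito_genes] <- rel[mito_genes] * mito_uplift
          if (t == "24h")
            rel[activation_genes] <- rel[activation_genes] *
              config$activation_uplift
          blocks[[length(blocks) + 1]] <-
            nb_block(rel, n_per[p], config, size)
          bc <- sprintf("C%06d", cell_id + seq_len(n_per[p]))
          cell_id <- cell_id + n_per[p]
          meta[[length(meta) + 1]] <- tibble(
            barcode = bc, patient = patients[q], timepoint = t,
            replicate = paste0("R", r), population = "AML")
          truth_prog[[length(truth_prog) + 1]] <-
            rep(prog_names[p], n_per[p])
        }
        if (config$tcells_per_sample > 0) {
          rel <- base * shifts[, q]
          if (t == "24h") {
            rel[activation_genes] <- rel[activation_genes] *
              config$activation_uplift
            if (patients[q] %in% sensitive)
              rel[tcell_genes] <- rel[tcell_genes] *
                config$tcell_response_uplift
          }
          blocks[[length(blocks) + 1]] <-
            nb_block(rel, config$tcells_per_sample, config, size)
          bc <- sprintf("C%06d", cell_id + seq_len(config$tcells_per_sample))
          cell_id <- cell_id + config$tcells_per_sample
          meta[[length(meta) + 1]] <- tibble(
            barcode = bc, patient = patients[q], timepoint = t,
            replicate = paste0("R", r), population = "TCELL")
          truth_prog[[length(truth_prog) + 1]] <-
            rep(NA_character_, config$tcells_per_sample)
        }
      }
    }
  }
  counts <- do.call(cbind, blocks)
  rownames(counts) <- genes
  meta <- dplyr::bind_rows(meta)
  colnames(counts) <- meta$barcode
  cm <- cell_matrix(counts, meta)
  # planted maturation rank: monotone in the number of distinct genes
  # expressed, ties broken by cell index
  ngd <- cm$cells$n_genes_detected
  mat_rank <- order(order(ngd, seq_along(ngd)))
  truth <- list(program = unlist(truth_prog),
                signatures = sigs,
                lowq_program = if (config$lowq_program)
                  prog_names[config$n_programs] else NA_character_,
                activation_genes = activation_genes,
                tcell_response_genes = tcell_genes,
                sensitive_patients = sensitive,
                maturation_rank = mat_rank,
                program_mix = do.call(rbind, mix_rows))
  list(cells = cm, truth = truth)
}

# draw an NB count block for n cells sharing one relative-expression profile
nb_block <- function(rel, n, config, size) {
  reln <- rel / sum(rel)
  lib <- rlnorm(n, config$libsize_meanlog, config$libsize_sdlog)
  mu <- outer(reln, lib)
  m <- matrix(rnbinom(length(mu), size = size, mu = mu), nrow = length(rel))
  Matrix::Matrix(m, sparse = TRUE)
}

#' Simulate a bulk RNA-seq cohort as noisy mixtures of program profiles
#'
#' Each sample's expression is `log2` of a convex mixture of per-program
#' pseudo-bulk profiles plus Gaussian noise on the log scale. Elimination
#' efficiency is a linear function of the mixing proportions (clipped to
#' \[-20, 100\]), subtypes are drawn with program-dependent odds, a high-risk
#' flag tracks one program, and survival times are exponential with hazard
#' proportional to `exp(sum(beta_p * proportion_p))`.
#'
#' @param signatures Named list of program signature gene sets.
#' @param n_samples Number of bulk samples (>= 3).
#' @param ee_coeffs Named numeric: `intercept` plus one coefficient per
#'   program, mapping mixing proportions to elimination efficiency.
#' @param hazard_coeffs Named numeric log-hazard coefficients per program.
#' @param noise_sd SD of Gaussian expression noise (log2 scale).
#' @param ee_noise_sd SD of noise added to EE before clipping.
#' @param n_background Extra non-signature genes in the bulk gene space.
#' @param profile_uplift Linear-scale uplift of a program's signature genes in
#'   its pseudo-bulk profile.
#' @param censor_frac Target censoring fraction for survival times.
#' @param mix_alpha Dirichlet concentration for the mixing proportions.
#' @param seed Integer seed.
#' @return List with `cohort` (a `bulk_cohort`: `expr` genes x samples log2
#'   matrix, `samples` annotation tibble) and `truth` (mixing proportions,
#'   the EE and hazard coefficients, the program profiles).
#' @export
simulate_bulk_cohort <- function(signatures,
                                 n_samples = 50,
                                 ee_coeffs = NULL,
                                 hazard_coeffs = NULL,
                                 noise_sd = 0.3,
                                 ee_noise_sd = 5,
                                 n_background = 500,
                                 profile_uplift = 8,
                                 censor_frac = 0.2,
                                 mix_alpha = 1.5,
                                 seed = 1) {
  if (n_samples < 3)
    abort("n_samples must be at least 3", class = "amlprog_cohort_too_small")
  set.seed(seed)
  progs <- names(signatures)
  k <- length(progs)
  if (is.null(ee_coeffs)) {
    ee_coeffs <- setNames(rep(0, k + 1), c("intercept", progs))
    ee_coeffs["intercept"] <- 30
    ee_coeffs[progs[1]] <- 60
    if (k >= 3) ee_coeffs[progs[3]] <- -50
  }
  if (is.null(hazard_coeffs)) {
    hazard_coeffs <- setNames(rep(0, k), progs)
    hazard_coeffs[progs[1]] <- -0.8
    if (k >= 3) hazard_coeffs[progs[3]] <- 1.0
    if (k >= 4) hazard_coeffs[progs[4]] <- 1.0
  }
  genes <- unique(c(unlist(signatures),
                    sprintf("BG%04d", seq_len(n_background))))
  base <- rlnorm(length(genes), meanlog = 2, sdlog = 0.8)
  names(base) <- genes
  profiles <- sapply(progs, function(p) {
    pr <- base
    pr[signatures[[p]]] <- pr[signatures[[p]]] * profile_uplift
    pr
  })
  # Dirichlet mixing proportions via gamma draws
  w <- matrix(stats::rgamma(n_samples * k, shape = mix_alpha), ncol = k)
  w <- w / rowSums(w)
  colnames(w) <- progs
  lin <- profiles %*% t(w)
  expr <- log2(lin) + matrix(rnorm(length(lin), 0, noise_sd), nrow(lin))
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))

  ee <- as.numeric(ee_coeffs["intercept"] + w %*% ee_coeffs[progs]) +
    rnorm(n_samples, 0, ee_noise_sd)
  ee <- pmin(100, pmax(-20, ee))

  # subtype odds increase in the matching program's proportion
  subtypes <- paste0("M", seq_len(k))
  odds <- exp(4 * w)
  subtype <- apply(odds, 1, function(o) sample(subtypes, 1, prob = o))

  hr_p <- if (k >= 3) stats::plogis(-1.5 + 3 * w[, 3]) else rep(0.3, n_samples)
  high_risk <- stats::rbinom(n_samples, 1, hr_p)

  lp <- as.numeric(w %*% hazard_coeffs)
  lambda <- 0.1 * exp(lp)
  t_event <- rexp(n_samples, rate = lambda)
  lam_c <- mean(lambda) * censor_frac / max(1 - censor_frac, 1e-6)
  t_cens <- if (censor_frac > 0) rexp(n_samples, rate = lam_c) else
    rep(Inf, n_samples)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  samples <- tibble(sample = colnames(expr), ee = ee, subtype = subtype,
                    risk = ifelse(high_risk == 1, "high", "standard"),
                    high_risk = high_risk,
                    survival_time = time, event = event)
  cohort <- structure(list(expr = expr, samples = samples),
                      class = "bulk_cohort")
  list(cohort = cohort,
       truth = list(mixing = w, ee_coeffs = ee_coeffs,
                    hazard_coeffs = hazard_coeffs, profiles = profiles))
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat("<bulk_cohort> ", nrow(x$expr), " genes x ", ncol(x$expr),
      " samples\n", sep = "")
  invisible(x)
}

#' Simulate survival data with a known log-hazard coefficient
#'
#' Standard-normal covariate, exponential event times with hazard
#' `0.1 * exp(beta * x)`, independent exponential censoring tuned to the
#' requested censoring fraction. Used to check Cox coefficient recovery.
#'
#' @param n Subjects.
#' @param beta Planted per-unit log hazard ratio.
#' @param censor_frac Target censoring fraction.
#' @param seed Integer seed.
#' @return Tibble with `x`, `time`, `event`.
#' @export
simulate_survival_data <- function(n, beta = 0.7, censor_frac = 0.2,
                                   seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  lambda <- 0.1 * exp(beta * x)
  t_event <- rexp(n, rate = lambda)
  lam_c <- mean(lambda) * censor_frac / max(1 - censor_frac, 1e-6)
  t_cens <- if (censor_frac > 0) rexp(n, rate = lam_c) else rep(Inf, n)
  tibble(x = x, time = pmin(t_event, t_cens),
         event = as.integer(t_event <= t_cens))
}

#' Simulate a receptor-ligand pair database
#'
#' Generates ordered ligand -> receptor pairs over a gene universe; a
#' configurable fraction of receptor sides are two-subunit complexes whose
#' subunits are joined by `"+"`, the display convention for multi-subunit
#' receptor complexes.
#'
#' @param n_pairs Number of pairs.
#' @param complex_fraction Fraction of receptor sides with 2 subunits.
#' @param gene_universe Character vector of candidate genes (nonempty).
#' @param seed Integer seed.
#' @param planted Optional list(partner_a=, partner_b=) prepended as the
#'   first pair (e.g. a known co-upregulated pair).
#' @return Tibble with `pair_id`, `partner_a`, `partner_b`, `source`.
#' @export
simulate_lr_database <- function(n_pairs, complex_fraction = 0.3,
                                 gene_universe, seed = 1, planted = NULL) {
  if (length(gene_universe) == 0)
    abort("gene universe is empty", class = "amlprog_empty_universe")
  assert_that(complex_fraction >= 0 && complex_fraction <= 1,
              "complex_fraction must lie in [0, 1]")
  set.seed(seed)
  n_complex <- round(complex_fraction * n_pairs)
  is_complex <- c(rep(TRUE, n_complex), rep(FALSE, n_pairs - n_complex))
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- sample(gene_universe, 1)
    b <- sample(setdiff(gene_universe, a), if (is_complex[i]) 2 else 1)
    tibble(partner_a = a, partner_b = paste(b, collapse = "+"))
  })
  db <- dplyr::bind_rows(rows)
  if (!is.null(planted)) {
    db <- dplyr::bind_rows(
      tibble(partner_a = paste(planted$partner_a, collapse = "+"),
             partner_b = paste(planted$partner_b, collapse = "+")),
      db)
  }
  db |>
    mutate(pair_id = sprintf("LR%03d", dplyr::row_number()),
           source = "synthetic") |>
    select("pair_id", "partner_a", "partner_b", "source")
}
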