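#' Construct a bulk cohort container
#'
#' @param expr Numeric matrix, genes x samples, log-scale expression with no
#'   missing values; row names gene ids, column names sample ids.
#' @param samples Tibble with a `sample` column matching `colnames(expr)`;
#'   optional annotation columns `ee`, `subtype`, `risk`, `high_risk`,
#'   `survival_time`, `event`.
#' @return A `bulk_cohort`.
#' @export
bulk_cohort <- function(expr, samples) {
  assert_that(!anyNA(expr), "expression matrix contains missing values")
  assert_that(!is.null(rownames(expr)) && !is.null(colnames(expr)),
              "expr needs gene row names and sample column names")
  samples <- as_tibble(samples)
  assert_that(all(colnames(expr) %in% samples$sample),
              "sample annotations must cover all expression columns")
  samples <- samples[match(colnames(expr), samples$sample), ]
  structure(list(expr = expr, samples = samples), class = "bulk_cohort")
}

#' Read a bulk cohort from CSV/TSV files
#'
#' @param expr_path Genes x samples table; first column gene ids, header of
#'   sample ids. Tab- or comma-separated by extension.
#' @param annot_path CSV of per-sample annotations with a `sample` column.
#' @return A [bulk_cohort()].
#' @export
read_bulk_cohort <- function(expr_path, annot_path) {
  sep <- if (grepl("\\.tsv$", expr_path)) "\t" else ","
  df <- read.csv(expr_path, row.names = 1, check.names = FALSE, sep = sep)
  annot <- readr::read_csv(annot_path, show_col_types = FALSE)
  bulk_cohort(as.matrix(df), annot)
}

#' Score program abundance in bulk samples
#'
#' The `zsig` method: every gene is z-scored across samples, and a program's
#' abundance in a sample is the mean z-score over its signature genes.
#' Scores are therefore z-standardised per program across samples, making
#' programs with different signature sizes comparable. Genes constant across
#' samples contribute 0 (logged).
#'
#' @param bulk A [bulk_cohort()].
#' @param signatures Named list of signature gene sets (e.g.
#'   `program_set$signatures`).
#' @param method Scoring method; only `"zsig"` is built in, but externally
#'   computed abundance matrices can be passed downstream directly.
#' @return An `abundance_matrix`: programs x samples numeric matrix with
#'   attribute `method`; rows z-standardised across samples.
#' @export
score_program_abundance <- function(bulk, signatures, method = "zsig") {
  method <- match.arg(method, "zsig")
  expr <- bulk$expr
  sds <- apply(expr, 1, sd)
  if (any(sds == 0))
    warn(paste(sum(sds == 0), "genes constant across samples score 0"))
  z <- (expr - rowMeans(expr)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  ab <- t(vapply(names(signatures), function(p) {
    sig <- signatures[[p]]
    hit <- intersect(sig, rownames(z))
    if (length(hit) == 0)
      abort(paste0("no signature genes of ", p, " present in the bulk data"),
            class = "amlprog_no_signature_genes")
    if (length(hit) < 0.25 * length(sig))
      warn(paste0("fewer than 25% of ", p, "'s signature genes in bulk data"))
    colMeans(z[hit, , drop = FALSE])
  }, numeric(ncol(z))))
  # standardise per program so dominant-program grouping is scale-free
  m <- rowMeans(ab); s <- apply(ab, 1, sd)
  ab <- (ab - m) / ifelse(s == 0, 1, s)
  structure(ab, method = method, class = c("abundance_matrix", "matrix"))
}

#' Correlate program abundance with killing sensitivity
#'
#' Spearman rank correlation between each program's abundance and per-sample
#' elimination efficiency, with a two-sided p-value (exact for n <= 9,
#' t-approximation otherwise).
#'
#' @param ab An [score_program_abundance()] result (programs x samples).
#' @param ee Numeric elimination efficiencies aligned with the columns of
#'   `ab`; NA samples are dropped.
#' @return Tibble `program`, `rho`, `p`, `n`.
#' @export
correlate_abundance_with_killing <- function(ab, ee) {
  ok <- !is.na(ee)
  assert_that(sum(ok) >= 5, "need at least 5 samples with EE")
  if (sd(ee[ok]) == 0)
    abort("EE constant: correlation undefined", class = "amlprog_constant_ee")
  n <- sum(ok)
  purrr::map_dfr(rownames(ab), function(p) {
    ct <- suppressWarnings(
      cor.test(ab[p, ok], ee[ok], method = "spearman", exact = n <= 9))
    tibble(program = p, rho = unname(ct$estimate), p = ct$p.value, n = n)
  })
}

#' Subtype enrichment of program abundance
#'
#' For every program x category cell, a two-sided Wilcoxon rank-sum test of
#' the abundance in samples of that category against all other samples;
#' direction is the sign of the median difference. BH correction is applied
#' across the whole programs x categories grid. Significance tiers `q < 0.05`
#' and `q < 0.1` are flagged.
#'
#' @param ab Abundance matrix (programs x samples).
#' @param labels Per-sample categorical labels aligned with columns; NA
#'   samples are dropped.
#' @param min_n Minimum samples per tested category (default 3); smaller
#'   categories are reported as NA.
#' @return Tibble `program`, `category`, `direction`, `p`, `q`, `sig`.
#' @export
subtype_enrichment <- function(ab, labels, min_n = 3) {
  ok <- !is.na(labels)
  ab <- ab[, ok, drop = FALSE]
  labels <- labels[ok]
  cats <- sort(unique(labels))
  grid <- tidyr::expand_grid(program = rownames(ab), category = cats)
  res <- purrr::pmap_dfr(grid, function(program, category) {
    ing <- labels == category
    if (sum(ing) < min_n || sum(!ing) < min_n)
      return(tibble(program = program, category = category,
                    direction = NA_real_, p = NA_real_))
    x <- ab[program, ing]; y <- ab[program, !ing]
    pv <- suppressWarnings(wilcox.test(x, y)$p.value)
    tibble(program = program, category = category,
           direction = sign(median(x) - median(y)), p = pv)
  })
  res |>
    mutate(q = bh_adjust(.data$p),
           sig = dplyr::case_when(is.na(.data$q) ~ "",
                                  .data$q < 0.05 ~ "*",
                                  .data$q < 0.1 ~ ".",
                                  TRUE ~ ""))
}

#' Dominant program per bulk sample
#'
#' Argmax of the z-standardised abundance per sample; exact ties resolve to
#' the lowest-indexed program and the winning margin is recorded.
#'
#' @param ab Abundance matrix (programs x samples), z-standardised rows.
#' @return Tibble `sample`, `program`, `margin`.
#' @export
assign_dominant_program <- function(ab) {
  progs <- rownames(ab)
  purrr::map_dfr(seq_len(ncol(ab)), function(j) {
    v <- ab[, j]
    i <- which.max(v)  # first maximum = lowest-indexed program on ties
    margin <- if (length(v) > 1) v[i] - max(v[-i]) else Inf
    tibble(sample = colnames(ab)[j], program = progs[i],
           margin = unname(margin))
  })
}

#' Kaplan-Meier curves and log-rank test by group
#'
#' Product-limit estimates per group with a k-group log-rank test (k - 1
#' degrees of freedom); for two groups the univariate Cox hazard ratio and
#' its 95% confidence interval are attached, matching the usual
#' Kaplan-Meier panel annotation.
#'
#' @param time,event Survival time and event indicator (1 = event).
#' @param groups Per-sample group labels; empty groups are dropped with a
#'   warning.
#' @return A `survival_fit` object: `km` (a `survfit`), `logrank_chisq`,
#'   `logrank_df`, `logrank_p`, and for two groups `hr`, `hr_ci`, `cox`.
#' @export
km_logrank <- function(time, event, groups) {
  ok <- !is.na(groups) & !is.na(time)
  time <- time[ok]; event <- event[ok]; groups <- droplevels(factor(groups[ok]))
  assert_that(nlevels(groups) >= 2, "need at least 2 nonempty groups")
  assert_that(sum(event) >= 1, "need at least one event")
  df <- data.frame(time = time, event = event, group = groups)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(groups)
  out <- list(km = km,
              logrank_chisq = unname(lr$chisq),
              logrank_df = k - 1,
              logrank_p = stats::pchisq(lr$chisq, df = k - 1,
                                        lower.tail = FALSE),
              groups = levels(groups), data = df)
  if (k == 2) {
    cox <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                           ties = "efron")
    s <- summary(cox)
    out$hr <- unname(s$conf.int[1, "exp(coef)"])
    out$hr_ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
    out$cox <- cox
  }
  structure(out, class = "survival_fit")
}

#' Cox proportional-hazards model on program abundance
#'
#' Univariate (abundance only) or risk-adjusted (abundance + high-risk
#' indicator) Cox model, maximising the partial likelihood with Efron tie
#' handling by Newton-Raphson; standard errors from the observed
#' information. Fits with fewer than 10 events warn; monotone-likelihood
#' fits (perfect separation) are flagged with no estimate.
#'
#' @param time,event Survival time and event indicator.
#' @param abundance Continuous covariate (e.g. one program's abundance).
#' @param high_risk Optional 0/1 adjustment covariate.
#' @return A `survival_fit` with `beta`, `se`, `hr`, `hr_ci`, `wald_p` for
#'   the abundance term, the fitted `cox` object, and `covariates`.
#' @export
cox_model <- function(time, event, abundance, high_risk = NULL) {
  if (sum(event) < 10) warn("fewer than 10 events: Cox fit may be unstable")
  if (sd(abundance) == 0) {
    return(structure(list(beta = 0, se = NA_real_, hr = 1,
                          hr_ci = c(NA_real_, NA_real_), wald_p = NA_real_,
                          cox = NULL, covariates = "abundance",
                          flag = "constant covariate"),
                     class = "survival_fit"))
  }
  df <- data.frame(time = time, event = event, abundance = abundance)
  fm <- survival::Surv(time, event) ~ abundance
  covs <- "abundance"
  if (!is.null(high_risk)) {
    df$high_risk <- high_risk
    fm <- survival::Surv(time, event) ~ abundance + high_risk
    covs <- c("abundance", "high_risk")
  }
  fit <- tryCatch(
    survival::coxph(fm, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        structure(list(), class = "amlprog_separation")
      } else {
        suppressWarnings(survival::coxph(fm, data = df, ties = "efron"))
      }
    })
  if (inherits(fit, "amlprog_separation")) {
    return(structure(list(beta = NA_real_, se = NA_real_, hr = NA_real_,
                          hr_ci = c(NA_real_, NA_real_), wald_p = NA_real_,
                          cox = NULL, covariates = covs,
                          flag = "monotone likelihood / non-convergence"),
                     class = "survival_fit"))
  }
  s <- summary(fit)
  structure(list(beta = unname(s$coefficients["abundance", "coef"]),
                 se = unname(s$coefficients["abundance", "se(coef)"]),
                 hr = unname(s$conf.int["abundance", "exp(coef)"]),
                 hr_ci = unname(s$conf.int["abundance",
                                           c("lower .95", "upper .95")]),
                 wald_p = unname(s$coefficients["abundance", "Pr(>|z|)"]),
                 cox = fit, covariates = covs),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("<survival_fit>\n")
  if (!is.null(x$logrank_chisq))
    cat(sprintf("log-rank chisq = %.3f (df %d), p = %.4g\n",
                x$logrank_chisq, x$logrank_df, x$logrank_p))
  if (!is.null(x$beta) && !is.null(x$se))
    cat(sprintf("Cox beta = %.4f (SE %.4f), HR = %.3f, Wald p = %.4g\n",
                x$beta, x$se, x$hr, x$wald_p))
  if (!is.null(x$hr) && !is.null(x$hr_ci))
    cat(sprintf("HR 95%% CI [%.3f, %.3f]\n", x$hr_ci[1], x$hr_ci[2]))
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a survival fit
#'
#' One row per estimated quantity: the Cox abundance term (if fitted) and
#' the log-rank test (if computed).
#'
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy survival_fit
#' @export
tidy.survival_fit <- function(x, ...) {
  rows <- list()
  if (!is.null(x$beta) && !is.null(x$se)) {
    rows$cox <- tibble(term = "abundance", estimate = x$beta,
                       std.error = x$se, hr = x$hr,
                       conf.low = x$hr_ci[1], conf.high = x$hr_ci[2],
                       p.value = x$wald_p)
  } else if (!is.null(x$hr)) {
    rows$hr <- tibble(term = "group", estimate = log(x$hr),
                      std.error = NA_real_, hr = x$hr,
                      conf.low = x$hr_ci[1], conf.high = x$hr_ci[2],
                      p.value = NA_real_)
  }
  if (!is.null(x$logrank_chisq)) {
    rows$lr <- tibble(term = "logrank", estimate = x$logrank_chisq,
                      std.error = NA_real_, hr = NA_real_,
                      conf.low = NA_real_, conf.high = NA_real_,
                      p.value = x$logrank_p)
  }
  dplyr::bind_rows(rows)
}

#' Glance at a survival fit
#' @param x A `survival_fit`.
#' @param ... Unused.
#' @return One-row tibble of headline statistics.
#' @method glance survival_fit
#' @export
glance.survival_fit <- function(x, ...) {
  tibble(logrank_p = x$logrank_p %||% NA_real_,
         hr = x$hr %||% NA_real_,
         cox_beta = x$beta %||% NA_real_,
         wald_p = x$wald_p %||% NA_real_)
}

#' Kaplan-Meier survival table from a fit
#'
#' Step-function values per group, right-continuous, starting from 1.
#'
#' @param x A `survival_fit` from [km_logrank()].
#' @return Tibble `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_table <- function(x) {
  km <- x$km
  strata <- rep(names(km$strata) %||% "all", km$strata %||% length(km$time))
  tibble(group = sub("^group=", "", strata), time = km$time,
         n_risk = km$n.risk, n_event = km$n.event, surv = km$surv)
}
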