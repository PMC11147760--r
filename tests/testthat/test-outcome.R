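mini_cohort <- function() {
  sigs <- list(A = paste0("G", 1:15), B = paste0("G", 16:30))
  bk <- simulate_bulk_cohort(sigs, n_samples = 30, noise_sd = 0,
                             ee_noise_sd = 0, seed = 8)
  list(sigs = sigs, bk = bk)
}

test_that("zsig abundance ranks a pure sample highest on its program", {
  mc <- mini_cohort()
  ab <- score_program_abundance(mc$bk$cohort, mc$sigs)
  w <- mc$bk$truth$mixing
  # the sample most enriched for A scores highest on A
  expect_equal(unname(which.max(ab["A", ])), unname(which.max(w[, "A"])))
  expect_equal(unname(which.max(ab["B", ])), unname(which.max(w[, "B"])))
  # abundance tracks the planted proportions tightly even at modest n
  expect_gte(cor(ab["A", ], w[, "A"], method = "spearman"), 0.9)
  # constant genes score zero
  expr <- mc$bk$cohort$expr
  expr["G1", ] <- 5
  bc <- bulk_cohort(expr, mc$bk$cohort$samples)
  expect_warning(score_program_abundance(bc, list(const = "G1")), "constant")
})

test_that("abundance errors when no signature gene is present", {
  mc <- mini_cohort()
  expect_error(score_program_abundance(mc$bk$cohort, list(X = "NOPE")),
               class = "amlprog_no_signature_genes")
})

test_that("EE correlation: monotone pairs, antisymmetry, planted signs", {
  ab <- matrix(seq(0.1, 1, length.out = 10), nrow = 1,
               dimnames = list("P1", paste0("s", 1:10)))
  ee <- 1:10
  res <- correlate_abundance_with_killing(ab, ee)
  expect_equal(res$rho, 1)
  rev_res <- correlate_abundance_with_killing(ab, rev(ee))
  expect_equal(rev_res$rho, -1)
  expect_error(correlate_abundance_with_killing(ab, rep(1, 10)),
               class = "amlprog_constant_ee")
  expect_error(correlate_abundance_with_killing(ab[, 1:4, drop = FALSE],
                                                ee[1:4]),
               "at least 5")
})

test_that("subtype enrichment p equals exact enumeration for sizes (3, 4)", {
  set.seed(9)
  ab <- matrix(rnorm(7), nrow = 1, dimnames = list("P1", paste0("s", 1:7)))
  labels <- c("a", "a", "a", "b", "b", "b", "b")
  res <- subtype_enrichment(ab, labels)
  # independent oracle: enumerate all rank assignments
  r <- rank(ab[1, ])
  w_obs <- sum(r[labels == "a"])
  ws <- apply(combn(7, 3), 2, function(ix) sum(r[ix]))
  p_exact <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  expect_equal(res$p[res$category == "a"], p_exact, tolerance = 1e-12)
})

test_that("subtype enrichment flags planted associations, respects min_n", {
  sigs <- list(A = paste0("G", 1:15), B = paste0("G", 16:30),
               C = paste0("G", 31:45))
  bk <- simulate_bulk_cohort(sigs, n_samples = 200, seed = 10)
  ab <- score_program_abundance(bk$cohort, sigs)
  enr <- subtype_enrichment(ab, bk$cohort$samples$subtype)
  # the subtype drawn with odds increasing in program A is enriched for A
  expect_lt(enr$q[enr$program == "A" & enr$category == "M1"], 0.05)
  expect_equal(enr$direction[enr$program == "A" & enr$category == "M1"], 1)
  # categories below the minimum are NA
  enr2 <- subtype_enrichment(ab, c("rare", rep("big", 199)))
  expect_true(all(is.na(enr2$p[enr2$category == "rare"])))
})

test_that("label shuffles rarely reach q < 0.05", {
  sigs <- list(A = paste0("G", 1:15), B = paste0("G", 16:30))
  bk <- simulate_bulk_cohort(sigs, n_samples = 100, seed = 11)
  ab <- score_program_abundance(bk$cohort, sigs)
  set.seed(12)
  hits <- replicate(20, {
    enr <- subtype_enrichment(ab, sample(bk$cohort$samples$subtype))
    mean(enr$q < 0.05, na.rm = TRUE)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("dominant program: one-hot, tie rule and margin", {
  ab <- matrix(c(1, 0, 0,
                 0.5, 0.5, 0,
                 0, 0.2, 0.9), nrow = 3,
               dimnames = list(c("P1", "P2", "P3"), c("s1", "s2", "s3")))
  dom <- assign_dominant_program(ab)
  expect_equal(dom$program, c("P1", "P1", "P3"))
  expect_equal(dom$margin[2], 0)  # exact tie -> lowest-indexed program
  expect_equal(dom$margin[1], 1)
})

test_that("dominant label matches the planted majority program", {
  # sparse mixtures (most samples clearly dominated by one program) are the
  # regime in which dominant-program grouping is meaningful
  sigs <- list(A = paste0("G", 1:15), B = paste0("G", 16:30),
               C = paste0("G", 31:45))
  bk <- simulate_bulk_cohort(sigs, n_samples = 40, noise_sd = 0,
                             mix_alpha = 0.5, seed = 18)
  ab <- score_program_abundance(bk$cohort, sigs)
  dom <- assign_dominant_program(ab)
  planted <- colnames(bk$truth$mixing)[apply(bk$truth$mixing, 1, which.max)]
  expect_gte(mean(dom$program == planted), 0.9)
})

test_that("log-rank O-E matches the hand-computed contingency oracle", {
  # group A: events at t=1, 2; group B: censored at t=5
  time <- c(1, 2, 5); event <- c(1, 1, 0); grp <- c("A", "A", "B")
  fit <- km_logrank(time, event, grp)
  # at t=1: 2 of 3 at risk in A, 1 event -> E_A = 2/3; at t=2: 1 of 2 in A,
  # 1 event -> E_A = 1/2. O_A = 2, E_A = 7/6.
  # variances: t=1: 1*(2/3)*(1/3) = 2/9; t=2: 1*(1/2)*(1/2) = 1/4.
  oe <- 2 - 7 / 6
  v <- 2 / 9 + 1 / 4
  expect_equal(fit$logrank_chisq, oe^2 / v, tolerance = 1e-10)
  sd_ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(fit$logrank_chisq, unname(sd_ref$chisq))
})

test_that("identical groups give a null log-rank test", {
  time <- rep(c(1, 2, 3, 4), 2); event <- rep(c(1, 1, 0, 1), 2)
  grp <- rep(c("A", "B"), each = 4)
  fit <- km_logrank(time, event, grp)
  expect_lt(fit$logrank_chisq, 1e-10)
  expect_gt(fit$logrank_p, 0.99)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(13)
  time <- rexp(40); event <- rep(1, 40)
  grp <- rep(c("A", "B"), 20)
  fit <- km_logrank(time, event, grp)
  tb <- km_table(fit)
  for (g in c("A", "B")) {
    tg <- time[grp == g]
    sub <- tb[tb$group == g, ]
    emp <- vapply(sub$time, function(t) mean(tg > t), numeric(1))
    expect_equal(sub$surv, emp, tolerance = 1e-12)
  }
  # right-continuity: value beyond the last event equals the last value
  last <- tb[tb$group == "A", ]
  expect_equal(min(last$surv), 0)
})

test_that("Cox beta matches a grid-search partial-likelihood oracle", {
  # 6 subjects, binary covariate, no ties
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- cox_model(time, event, x)
  # independent oracle: maximise the (tie-free) partial likelihood on a grid
  logpl <- function(beta) {
    ord <- order(time)
    lp <- beta * x
    s <- 0
    for (i in ord) {
      if (event[i] == 1) {
        risk <- time >= time[i]
        s <- s + lp[i] - log(sum(exp(lp[risk])))
      }
    }
    s
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_star <- grid[which.max(vapply(grid, logpl, numeric(1)))]
  expect_lt(abs(fit$beta - beta_star), 1e-4 + 1e-4)
})

test_that("Cox handles degenerate covariates and separation", {
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 0)
  flat <- suppressWarnings(cox_model(time, event, rep(1, 4)))
  expect_equal(flat$beta, 0)
  expect_equal(flat$hr, 1)
  # perfect separation is flagged, not reported as an estimate
  sep <- suppressWarnings(
    cox_model(c(1, 2, 10, 11), c(1, 1, 1, 1), c(1, 1, 0, 0)))
  expect_true(is.na(sep$beta) || abs(sep$beta) > 5)
})

test_that("Cox sign is consistent with the log-rank direction", {
  set.seed(14)
  time <- c(rexp(30, 2), rexp(30, 0.5))
  event <- rep(1, 60)
  grp <- rep(c(1, 0), each = 30)
  fit <- suppressWarnings(cox_model(time, event, grp))
  expect_gt(fit$beta, 0)  # group 1 has higher hazard
  km <- km_logrank(time, event, grp)
  expect_gt(km$hr, 1)
})

test_that("risk-adjusted Cox keeps the abundance effect identifiable", {
  set.seed(15)
  df <- simulate_survival_data(200, beta = 0.7, censor_frac = 0.2, seed = 15)
  hr_flag <- rbinom(200, 1, 0.3)
  fit <- cox_model(df$time, df$event, df$x, high_risk = hr_flag)
  expect_equal(fit$covariates, c("abundance", "high_risk"))
  expect_lt(abs(fit$beta - 0.7), 0.3)
})

test_that("tidy and glance expose the fit in broom style", {
  df <- simulate_survival_data(100, beta = 0.5, seed = 16)
  fit <- cox_model(df$time, df$event, df$x)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate", "hr", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  km <- km_logrank(df$time, df$event, df$x > 0)
  expect_true("logrank" %in% tidy(km)$term)
  expect_false(is.na(glance(km)$logrank_p))
})
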