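make_phen <- function(n, seed = 1, families = TRUE) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    family_id = if (families) sprintf("F%04d", sample(ceiling(n * 0.75), n, TRUE))
      else sprintf("F%04d", seq_len(n)),
    wave = "baseline",
    mdd_status = sample(c("control", "remitted", "current"), n, TRUE),
    ids_total = rpois(n, 15),
    sex = sample(c("female", "male"), n, TRUE),
    age = round(runif(n, 18, 65)),
    education = round(runif(n, 6, 20)),
    physical_activity = round(rlnorm(n, 8, 0.5)),
    smoking = sample(c("never", "ex", "current"), n, TRUE),
    alcohol = round(rgamma(n, 2, 0.5), 1),
    n_chronic_diseases = rpois(n, 0.5),
    bmi = round(rnorm(n, 26, 4), 1),
    shipment = sample(1:2, n, TRUE),
    ad_ssri = runif(n) < 0.1, ad_tca = runif(n) < 0.05,
    ad_snri = runif(n) < 0.05,
    stringsAsFactors = FALSE)
}

test_that("GEE with singleton clusters reproduces OLS coefficients", {
  phen <- make_phen(200, seed = 5, families = FALSE)
  set.seed(6)
  y <- rnorm(200) + 0.4 * (phen$mdd_status == "current")
  fit <- fit_clustered_model(y, model_spec("mdd_status"), phen)

  df <- phen
  df$mdd_status <- factor(df$mdd_status, c("control", "remitted", "current"))
  df$smoking <- factor(df$smoking, c("never", "ex", "current"))
  ols <- lm(scale(y) ~ mdd_status + education + sex + age + physical_activity +
              smoking + alcohol + n_chronic_diseases + factor(shipment), df)
  expect_equal(fit$beta[fit$contrast == "current-vs-control"],
               unname(coef(ols)["mdd_statuscurrent"]), tolerance = 1e-10)
  expect_equal(fit$beta[fit$contrast == "remitted-vs-control"],
               unname(coef(ols)["mdd_statusremitted"]), tolerance = 1e-10)
})

test_that("exchangeable GEE recovers a known cluster-correlated effect", {
  set.seed(7)
  n_fam <- 150
  fam_sizes <- sample(1:4, n_fam, TRUE)
  cl <- rep.int(seq_len(n_fam), fam_sizes)
  n <- length(cl)
  x <- cbind(1, rnorm(n))
  y <- drop(x %*% c(0.5, 0.3)) + rep(rnorm(n_fam, 0, 0.7), fam_sizes) + rnorm(n)
  fit <- fit_gee_gaussian(y, x, cl)
  expect_gt(fit$rho, 0.1)           # family correlation detected
  expect_lt(abs(fit$coef[2] - 0.3), 3 * fit$se[2])
  expect_true(fit$converged)
})

test_that("rank-deficient designs fail with the collinear term named", {
  set.seed(8)
  x <- cbind(intercept = 1, a = rnorm(50), b = 0)
  x <- cbind(x, dup = x[, "a"])
  expect_error(fit_gee_gaussian(rnorm(50), x, rep(1:25, 2)), "b|dup")
})

test_that("BH q-values match the hand-computed step-up and stay valid", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(9)
  p <- runif(50)^1.5
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("mwas returns one row per metabolite per contrast with within-family q-values", {
  sim <- simulate_cohort(cohort_sim_config(n_subjects = 150, n_families = 110,
                                           n_metabolites = 12, n_assoc_true = 3,
                                           n_ad_true = 1, n_waves = 1,
                                           missing_rate = 0, seed = 41))
  qc <- suppressWarnings(run_qc_pipeline(sim$abundance))
  tab <- mwas(qc$matrix, sim$phenotypes, model_spec("mdd_status"))
  expect_equal(nrow(tab), 2 * ncol(qc$matrix$values))
  expect_equal(anyDuplicated(tab[, c("metabolite_id", "contrast")]), 0L)
  for (ct in unique(tab$contrast)) {
    sel <- tab$contrast == ct
    expect_equal(tab$qvalue[sel], bh_fdr(tab$pvalue[sel]))
  }
  sev <- mwas(qc$matrix, sim$phenotypes, model_spec("ids_total"))
  expect_equal(unique(sev$contrast), "severity")
})

test_that("beta comparison handles identity, antisymmetry and tiny overlap", {
  a <- data.frame(metabolite_id = sprintf("M%d", 1:10),
                  beta = c(-(5:1) / 10, (1:5) / 10))
  cmp <- compare_betas(a, a)
  expect_equal(cmp$r, 1)
  expect_equal(cmp$pct_same_direction, 100)
  expect_equal(cmp$by_sign$down$n, 5)

  b <- a
  b$beta <- -a$beta
  cmp2 <- compare_betas(a, b)
  expect_equal(cmp2$r, -1)
  expect_equal(cmp2$pct_same_direction, 0)

  expect_error(compare_betas(a[1:2, ], a[1:2, ]), "fewer than 3")
})

test_that("replication rule follows sign and nominal significance exactly", {
  base <- data.frame(metabolite_id = c("M1", "M2", "M3"),
                     contrast = "current-vs-control", beta = c(-0.2, -0.2, 0.3))
  fu_st <- data.frame(metabolite_id = c("M1", "M2"),
                      contrast = "current-vs-control",
                      beta = c(-0.1, 0.1), pvalue = c(0.01, 0.001))
  fu_sev <- data.frame(metabolite_id = c("M1", "M2"),
                       contrast = "severity",
                       beta = c(-0.05, 0.05), pvalue = c(0.5, 0.2))
  out <- replicate_hits(base, fu_st, fu_sev, c("M1", "M2", "M3"))
  expect_true(out$replicated[out$metabolite_id == "M1"])      # status branch
  expect_false(out$replicated[out$metabolite_id == "M2"])     # sign mismatch / ns
  expect_true(is.na(out$replicated[out$metabolite_id == "M3"]))
  expect_match(out$reason[out$metabolite_id == "M3"], "not assessable")

  ## severity-only branch
  fu_sev2 <- fu_sev
  fu_sev2$pvalue[1] <- 0.01
  fu_st2 <- fu_st
  fu_st2$pvalue[1] <- 0.5
  out2 <- replicate_hits(base, fu_st2, fu_sev2, "M1")
  expect_true(out2$replicated)
  expect_match(out2$reason, "severity")
})

test_that("AD-domination flag uses a strict 2x threshold", {
  base <- data.frame(metabolite_id = c("M1", "M2"),
                     contrast = "current-vs-control", beta = c(0.2, 0.2))
  cls <- data.frame(metabolite_id = c("M1", "M2"),
                    contrast = "TCA", beta = c(0.42, 0.38))
  fl <- flag_ad_dominated(base, cls, c("M1", "M2"))
  expect_identical(fl$metabolite_id, "M1")   # 2.1x flagged, 1.9x not
  ## exactly 2.0x is not flagged (strictly greater)
  cls2 <- data.frame(metabolite_id = "M1", contrast = "TCA", beta = 0.4)
  expect_equal(nrow(flag_ad_dominated(base, cls2, "M1")), 0L)
  ## sign-independent
  cls3 <- data.frame(metabolite_id = "M1", contrast = "SSRI", beta = -0.5)
  expect_equal(nrow(flag_ad_dominated(base, cls3, "M1")), 1L)
})

test_that("a fully BMI-mediated effect vanishes when BMI enters the model", {
  set.seed(10)
  n <- 500
  phen <- make_phen(n, seed = 10, families = FALSE)
  ## status shifts BMI; the mediated metabolite tracks BMI only
  phen$bmi <- phen$bmi + 3 * (phen$mdd_status == "current")
  z_bmi <- as.numeric(scale(phen$bmi))
  y_mediated <- 0.8 * z_bmi + rnorm(n, 0, 0.5)
  y_direct <- 0.5 * (phen$mdd_status == "current") + rnorm(n, 0, 0.9)

  f_med <- fit_clustered_model(y_mediated, model_spec("mdd_status"), phen)
  f_med_bmi <- fit_clustered_model(y_mediated, model_spec("mdd_status", add_bmi = TRUE), phen)
  cur <- function(f) f[f$contrast == "current-vs-control", ]
  expect_lt(cur(f_med_bmi)$pvalue, 1)
  expect_gt(cur(f_med_bmi)$pvalue, 0.01)       # significance lost
  expect_lt(cur(f_med)$pvalue, 1e-4)           # present without BMI

  f_dir <- fit_clustered_model(y_direct, model_spec("mdd_status", add_bmi = TRUE), phen)
  expect_lt(cur(f_dir)$pvalue, 1e-4)           # unaffected by BMI
})

test_that("antidepressant sensitivity refits exclude users and per-class models run", {
  sim <- simulate_cohort(cohort_sim_config(n_subjects = 250, n_families = 190,
                                           n_metabolites = 10, n_assoc_true = 3,
                                           n_ad_true = 1, n_waves = 1,
                                           missing_rate = 0, seed = 43))
  qc <- suppressWarnings(run_qc_pipeline(sim$abundance))
  status <- mwas(qc$matrix, sim$phenotypes, model_spec("mdd_status"))
  res <- suppressWarnings(
    ad_sensitivity(qc$matrix, sim$phenotypes, status,
                   hits = unique(status$metabolite_id)))
  expect_identical(unique(res$no_ad$model), "no-AD-users")
  n_users <- sum(sim$phenotypes$ad_ssri | sim$phenotypes$ad_tca |
                   sim$phenotypes$ad_snri)
  expect_equal(unique(res$no_ad$n_used),
               nrow(sim$phenotypes) - n_users)
  expect_true(all(res$ad_class$contrast %in% c("SSRI", "TCA", "SNRI")))
})
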