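test_that("sample exclusion removes only extreme-missingness samples within strata", {
  set.seed(1)
  v <- matrix(rlnorm(101 * 50, 3, 0.3), 101, 50,
              dimnames = list(sprintf("S%03d", 1:101), sprintf("M%02d", 1:50)))
  ## ~1% missing everywhere, one sample at 90%
  v[cbind(sample(1:100, 50, replace = TRUE), sample(1:50, 50, replace = TRUE))] <- NA
  v[101, 1:45] <- NA
  m <- make_abundance(v)
  res <- exclude_high_missingness_samples(m)
  expect_identical(res$report$excluded, "S101")
  expect_equal(nrow(res$matrix$values), 100L)

  ## all samples identical missingness: SD = 0, threshold = mean, none removed
  v2 <- matrix(1, 10, 10, dimnames = list(sprintf("S%d", 1:10), sprintf("M%d", 1:10)))
  v2[, 1] <- NA
  res2 <- exclude_high_missingness_samples(make_abundance(v2))
  expect_length(res2$report$excluded, 0)

  ## an extreme reference sample is removed within its own stratum and
  ## does not trigger experimental removals
  set.seed(3)
  v3 <- matrix(rlnorm(140 * 40), 140, 40,
               dimnames = list(sprintf("S%03d", 1:140), sprintf("M%02d", 1:40)))
  is_ref3 <- c(rep(FALSE, 100), rep(TRUE, 40))
  v3[cbind(sample(1:139, 60, replace = TRUE),
           sample(1:40, 60, replace = TRUE))] <- NA   # ~1.5% baseline missingness
  v3[140, 1:36] <- NA                                  # one 90%-missing reference
  m3 <- abundance_matrix(v3, make_meta(rownames(v3), is_reference = is_ref3))
  res3 <- exclude_high_missingness_samples(m3)
  expect_identical(res3$report$excluded, "S140")
  expect_equal(sum(!res3$matrix$sample_meta$is_reference), 100L)
})

test_that("metabolite exclusion uses a strict 30% boundary", {
  v <- matrix(1, 100, 3, dimnames = list(sprintf("S%03d", 1:100), c("A", "B", "C")))
  v[1:31, 1] <- NA   # 31% -> excluded
  v[1:30, 2] <- NA   # 30% -> kept
  res <- exclude_high_missingness_metabolites(make_abundance(v))
  expect_identical(res$report$excluded, "A")
  expect_identical(colnames(res$matrix$values), c("B", "C"))

  res2 <- exclude_high_missingness_metabolites(make_abundance(
    matrix(1, 5, 2, dimnames = list(letters[1:5], c("X", "Y")))))
  expect_length(res2$report$excluded, 0)

  v3 <- matrix(1, 10, 2, dimnames = list(sprintf("S%d", 1:10), c("gone", "kept")))
  v3[, 1] <- NA
  res3 <- exclude_high_missingness_metabolites(make_abundance(v3), threshold = 0.999)
  expect_identical(res3$report$excluded, "gone")
})

test_that("plate masking flags aberrant plates, is idempotent, leaves homogeneous data alone", {
  set.seed(2)
  ids <- sprintf("S%02d", 1:30)
  plate <- rep(c("P1", "P2", "P3"), each = 10)
  v <- matrix(rlnorm(30 * 4, 2, 0.1), 30, 4,
              dimnames = list(ids, sprintf("M%d", 1:4)))
  v[plate == "P2", 1] <- v[plate == "P2", 1] * 100
  m <- abundance_matrix(v, make_meta(ids, plate = plate))
  res <- mask_plates(m)
  expect_true(all(is.na(res$matrix$values[plate == "P2", 1])))
  expect_true(all(!is.na(res$matrix$values[, 2:4])))
  expect_identical(res$report$detail$masked$plate, "P2")

  res2 <- mask_plates(res$matrix)
  expect_identical(res2$matrix$values, res$matrix$values)
  expect_equal(nrow(res2$report$detail$masked), 0L)

  hom <- mask_plates(abundance_matrix(
    matrix(rlnorm(30 * 4, 2, 0.1), 30, 4, dimnames = list(ids, sprintf("M%d", 1:4))),
    make_meta(ids, plate = plate)))
  expect_equal(nrow(hom$report$detail$masked), 0L)
})

test_that("run-day normalisation scales to unit medians and is idempotent", {
  ids <- sprintf("S%d", 1:3)
  m <- abundance_matrix(matrix(c(2, 4, 6), 3, 1, dimnames = list(ids, "M1")),
                        make_meta(ids))
  norm <- runday_normalize(m)
  expect_equal(unname(norm$values[, 1]), c(0.5, 1.0, 1.5))
  expect_identical(norm$scale, "normalized")

  single <- abundance_matrix(matrix(7, 1, 1, dimnames = list("S1", "M1")),
                             make_meta("S1"))
  expect_equal(unname(runday_normalize(single)$values[1, 1]), 1)

  ## two run-days on different scales both end at median 1
  ids2 <- sprintf("S%d", 1:6)
  rd <- rep(c("D1", "D2"), each = 3)
  m2 <- abundance_matrix(matrix(c(2, 4, 6, 20, 40, 60), 6, 1,
                                dimnames = list(ids2, "M1")),
                         make_meta(ids2, run_day = rd))
  n2 <- runday_normalize(m2)
  for (g in c("D1", "D2"))
    expect_equal(median(n2$values[rd == g, 1]), 1)
  ## idempotence
  n3 <- runday_normalize(n2)
  expect_equal(n3$values, n2$values)
})

test_that("batch normalisation yields unit batch medians and composes with run-day scaling", {
  ids <- sprintf("S%d", 1:8)
  batch <- rep(c("B1", "B2"), each = 4)
  v <- matrix(c(8, 9, 10, 12, 18, 19, 20, 24), 8, 1, dimnames = list(ids, "M1"))
  m <- abundance_matrix(v, make_meta(ids, batch = batch,
                                     run_day = rep(c("D1", "D2"), 4)))
  n <- batch_median_normalize(m)
  for (b in c("B1", "B2"))
    expect_equal(median(n$values[batch == b, 1]), 1)

  const <- abundance_matrix(matrix(5, 4, 1, dimnames = list(ids[1:4], "M1")),
                            make_meta(ids[1:4]))
  expect_true(all(batch_median_normalize(const)$values == 1))

  both <- batch_median_normalize(runday_normalize(m))
  for (b in c("B1", "B2"))
    expect_equal(median(both$values[batch == b, 1]), 1)
})

test_that("technical CV filter matches the hand-computed sample CV", {
  ids <- c("E1", "E2", "R1", "R2", "R3")
  is_ref <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  v <- matrix(c(1, 1, 1, 1, 1,
                1, 1, 1, 2, 2), 5, 2, dimnames = list(ids, c("flat", "noisy")))
  m <- abundance_matrix(v, make_meta(ids, is_reference = is_ref))
  res <- technical_cv_filter(m, threshold = 0.30)
  expect_equal(unname(res$cv["flat"]), 0)
  ## reference values {1, 2, 2}: sd = 0.5774, mean = 1.667 -> cv = 0.346
  expect_equal(unname(res$cv["noisy"]), sd(c(1, 2, 2)) / mean(c(1, 2, 2)))
  expect_identical(res$report$excluded, "noisy")

  ## two-value hand case {1, 2}: cv = 0.7071/1.5 > 0.3 -> removed
  v2 <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("E1", "R1", "R2"), "M1"))
  m2 <- abundance_matrix(v2, make_meta(rownames(v2),
                                       is_reference = c(FALSE, TRUE, TRUE)))
  res2 <- technical_cv_filter(m2)
  expect_equal(unname(res2$cv["M1"]), 0.7071068 / 1.5, tolerance = 1e-6)
  expect_identical(res2$report$excluded, "M1")

  expect_length(technical_cv_filter(m2, threshold = Inf)$report$excluded, 0)
  expect_error(technical_cv_filter(make_abundance(matrix(1, 2, 1)), 0.3),
               "no reference samples")
})

test_that("wave-missingness test agrees with the hypergeometric oracle", {
  n_per_wave <- 100
  ids <- sprintf("S%03d", 1:200)
  wave <- rep(c("baseline", "followup6"), each = n_per_wave)
  v <- matrix(1, 200, 2, dimnames = list(ids, c("skewed", "balanced")))
  v[1:10, 1] <- NA               # 10 missing in baseline, 0 in follow-up
  v[c(1:5, 101:105), 2] <- NA    # identical pattern per wave
  m <- abundance_matrix(v, make_meta(ids, wave = wave))
  tab <- test_wave_missingness(m, alpha = 0.05)
  p_oracle <- oracle_fisher2x2(10, 90, 0, 100)
  expect_equal(tab$pvalue[tab$metabolite_id == "skewed"], p_oracle,
               tolerance = 1e-10)
  expect_equal(tab$pvalue[tab$metabolite_id == "balanced"], 1)

  ## all-observed metabolite: p = 1; single wave: empty with warning
  v2 <- matrix(1, 4, 1, dimnames = list(ids[1:4], "M1"))
  m2 <- abundance_matrix(v2, make_meta(ids[1:4],
                                       wave = c("baseline", "baseline",
                                                "followup6", "followup6")))
  expect_equal(test_wave_missingness(m2, alpha = 0.05)$pvalue, 1)
  m3 <- abundance_matrix(v2, make_meta(ids[1:4]))
  expect_warning(empty <- test_wave_missingness(m3), "fewer than two waves")
  expect_equal(nrow(empty), 0L)
})

test_that("kNN imputation fills every cell, never alters observed values", {
  ## constant-neighbour case: all metabolites share an identical profile
  ## and the held-out cell sits at the profile mean, so the standardized
  ## neighbour mean maps back to exactly that value
  base <- c(5, 7, 9, 11, 13)
  v <- matrix(rep(base, 6), 5, 6,
              dimnames = list(sprintf("S%d", 1:5), sprintf("M%d", 1:6)))
  v[3, 1] <- NA
  m <- make_abundance(v, scale = "normalized")
  imp <- knn_impute(m, k = 3)
  expect_equal(unname(imp$values[3, 1]), 9)

  ## identity when nothing is missing
  m_full <- make_abundance(matrix(rlnorm(30), 5, 6), scale = "normalized")
  expect_identical(knn_impute(m_full, k = 2)$values, m_full$values)

  ## observed cells bitwise unchanged on simulator output
  sim <- simulate_cohort(cohort_sim_config(n_subjects = 80, n_families = 60,
                                           n_metabolites = 30, n_assoc_true = 5,
                                           n_ad_true = 1, n_waves = 1,
                                           seed = 21))
  norm <- batch_median_normalize(runday_normalize(sim$abundance))
  obs <- !is.na(norm$values)
  imp2 <- knn_impute(norm, k = 10)
  expect_identical(imp2$values[obs], norm$values[obs])
  expect_false(anyNA(imp2$values))
})

test_that("masked true values are recovered within one within-metabolite SD", {
  ## correlated metabolites (shared latent factor) so neighbours carry
  ## real information about the held-out cells
  set.seed(99)
  n <- 120
  p <- 30
  f <- rnorm(n)
  lv <- 0.85 * matrix(f, n, p) + 0.55 * matrix(rnorm(n * p), n, p) +
    matrix(rep(runif(p, 4, 8), each = n), n, p)
  v <- 2^lv
  dimnames(v) <- list(sprintf("S%03d", 1:n), sprintf("M%02d", 1:p))
  m <- make_abundance(v, scale = "normalized")
  holdout <- cbind(sample(n, 40), sample(p, 40, replace = TRUE))
  truth_vals <- v[holdout]
  v2 <- v
  v2[holdout] <- NA
  masked <- abundance_matrix(v2, m$sample_meta, scale = "normalized")
  imp <- knn_impute(masked, k = 10)
  err <- log2(imp$values[holdout]) - log2(truth_vals)
  sds <- apply(lv, 2, sd)[holdout[, 2]]
  expect_gt(mean(abs(err) <= sds), 0.75)
})

test_that("log2 transform and winsorisation clip exactly at mean +/- 5 SD", {
  expect_equal(log2_and_winsorize(make_abundance(
    matrix(8, 5, 1, dimnames = list(sprintf("S%d", 1:5), "M1")),
    scale = "normalized"))$values[1, 1], 3, ignore_attr = TRUE)

  set.seed(4)
  x <- rnorm(200, 10, 1)
  ## construct a log2 vector whose largest element sits exactly at
  ## mean + 6 SD of the full vector (fixed-point iteration)
  out <- mean(x) + 6 * sd(x)
  for (i in 1:50) out <- mean(c(x, out)) + 6 * sd(c(x, out))
  lv <- c(x, out)
  raw <- matrix(2^lv, length(lv), 1,
                dimnames = list(sprintf("S%03d", seq_along(lv)), "M1"))
  w <- log2_and_winsorize(make_abundance(raw, scale = "normalized"))
  bound <- mean(lv) + 5 * sd(lv)
  expect_equal(max(w$values), bound)
  ## every value within the pre-clipping mean +/- 5 SD band
  expect_true(all(w$values >= mean(lv) - 5 * sd(lv) - 1e-12))
  expect_true(all(w$values <= bound + 1e-12))
  ## monotone: value order preserved
  expect_identical(order(w$values[, 1]), order(lv))

  neg <- make_abundance(matrix(c(1, 0), 2, 1,
                               dimnames = list(c("S1", "S2"), "M1")),
                        scale = "normalized")
  expect_error(log2_and_winsorize(neg), "non-positive.*S2.*M1")
})

test_that("full QC chain runs in order, records reasons and leaves a complete log2 matrix", {
  sim <- simulate_cohort(cohort_sim_config(seed = 17))
  res <- suppressWarnings(run_qc_pipeline(sim$abundance))
  expect_identical(res$matrix$scale, "log2")
  expect_false(anyNA(res$matrix$values))
  expect_false(any(res$matrix$sample_meta$is_reference))
  tab <- qc_report_table(res$report)
  expect_true(all(tab$n_samples_after <= tab$n_samples_before))
  expect_true(all(tab$n_metabolites_after <= tab$n_metabolites_before))

  ## constructed offenders: one metabolite too missing, one too noisy
  v <- sim$abundance$values
  v[seq_len(ceiling(0.4 * nrow(v))), "M100"] <- NA
  is_ref <- sim$abundance$sample_meta$is_reference
  v[is_ref, "M101"] <- v[is_ref, "M101"] * exp(rnorm(sum(is_ref), 0, 0.6))
  m2 <- abundance_matrix(v, sim$abundance$sample_meta)
  res2 <- suppressWarnings(run_qc_pipeline(m2))
  expect_false("M100" %in% colnames(res2$matrix$values))
  expect_false("M101" %in% colnames(res2$matrix$values))
  reasons <- unlist(lapply(res2$report$steps, function(s)
    paste(s$step, s$excluded, s$reasons)))
  expect_true(any(grepl("exclude_high_missingness_metabolites M100", reasons)))
  expect_true(any(grepl("technical_cv_filter M101", reasons)))
})

test_that("estimated reference CV tracks the generating technical CV", {
  sim <- simulate_cohort(cohort_sim_config(seed = 23))
  norm <- batch_median_normalize(runday_normalize(sim$abundance))
  est <- technical_cv_filter(norm, threshold = Inf)$cv
  truth <- sim$truth$cv[names(est)]
  expect_gt(cor(est, truth, method = "spearman"), 0.9)
})

test_that("wave-missingness p-values are calibrated under wave-homogeneous missingness", {
  sim <- simulate_cohort(cohort_sim_config(seed = 29))
  norm <- runday_normalize(sim$abundance)
  tab <- test_wave_missingness(norm, alpha = 0.05 / 200)
  ## valid exact tests are (super-)uniform: the rejection rate at any level
  ## must not exceed the level by more than Monte-Carlo error
  for (a in c(0.05, 0.1, 0.2))
    expect_lte(mean(tab$pvalue < a), a + 2 * sqrt(a * (1 - a) / nrow(tab)))
  expect_gt(mean(tab$pvalue < 0.2), 0.02)  # not degenerate either
})
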