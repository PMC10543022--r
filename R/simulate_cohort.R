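#' Configuration for the cohort simulator
#'
#' Defines the generating model for a synthetic clinical metabolomics cohort:
#' family-clustered subjects with a 3-level depression status (control /
#' remitted / current) drawn from a probit liability model, an IDS-like
#' continuous severity score, the covariates used by the association models,
#' antidepressant-class flags concentrated among currently depressed
#' subjects, and a multi-wave abundance matrix with run-day/batch/plate
#' structure, reference samples, metabolite-specific technical CVs and
#' MNAR-weighted missingness.
#'
#' @param n_subjects Number of subjects at baseline.
#' @param n_families Number of families the subjects are partitioned into.
#' @param n_metabolites Number of metabolites.
#' @param n_waves 1 (baseline only) or 2 (baseline + 6-year follow-up).
#' @param followup_fraction Fraction of subjects re-measured at follow-up.
#' @param n_batches,run_days_per_batch,plates_per_batch Technical layout.
#' @param n_reference_samples Pooled-plasma reference samples spread over the
#'   technical layout; they share one fixed profile and differ only by
#'   technical factors.
#' @param cv_meanlog,cv_sdlog Log-normal distribution of per-metabolite
#'   technical coefficients of variation (defaults centre the CV near 10%).
#' @param runday_sdlog,batch_sdlog Spread (log scale) of multiplicative
#'   run-day and batch factors, drawn per (metabolite, run-day/batch).
#' @param missing_rate Overall expected fraction of missing cells.
#' @param mnar_weight In `[0,1]`: 0 gives purely random missingness, 1 makes
#'   missingness probability proportional to the rank of lowness of the true
#'   abundance within a metabolite (low-abundance cells go missing more).
#' @param status_props Probabilities of control/remitted/current status.
#' @param family_liability_cor Intra-family correlation of the depression
#'   liability (probit random-effect model).
#' @param n_assoc_true Number of metabolites truly shifted by depression.
#' @param delta Current-MDD effect size in within-metabolite SD units on the
#'   log2 scale; remitted subjects receive half this shift.
#' @param n_ad_true Number of metabolites shifted by antidepressant use
#'   (disjoint from the depression-associated set).
#' @param ad_delta Antidepressant effect size (SD units).
#' @param ad_driver_class Which class flag drives the antidepressant-true
#'   metabolites (a single-class effect, like a drug-metabolism product;
#'   default the most prevalent class, SSRI).
#' @param covariate_effect_sd SD of per-metabolite loadings on standardized
#'   age, sex and BMI (SD units per covariate SD).
#' @param wave_cor Correlation of a subject's metabolite deviation across
#'   waves (persistence of the biological signal).
#' @param classified_fraction Fraction of metabolites assigned to a pathway.
#' @param seed Integer RNG seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_subjects = 600,
                              n_families = 450,
                              n_metabolites = 200,
                              n_waves = 2,
                              followup_fraction = 0.8,
                              n_batches = 4,
                              run_days_per_batch = 2,
                              plates_per_batch = 4,
                              n_reference_samples = 60,
                              cv_meanlog = log(0.10),
                              cv_sdlog = 0.6,
                              runday_sdlog = 0.2,
                              batch_sdlog = 0.15,
                              missing_rate = 0.05,
                              mnar_weight = 0.5,
                              status_props = c(control = 0.29, remitted = 0.31, current = 0.40),
                              family_liability_cor = 0.3,
                              n_assoc_true = 20,
                              delta = 0.5,
                              n_ad_true = 3,
                              ad_delta = 2.5,
                              ad_driver_class = "ad_ssri",
                              covariate_effect_sd = 0.1,
                              wave_cor = 0.7,
                              classified_fraction = 0.83,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_subjects, n_families, n_metabolites, n_batches,
              run_days_per_batch, plates_per_batch, n_reference_samples)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_families > n_subjects)
    stop("infeasible family partition: n_families > n_subjects")
  if (mnar_weight < 0 || mnar_weight > 1) stop("mnar_weight must lie in [0,1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0,1)")
  if (n_assoc_true + n_ad_true > n_metabolites)
    stop("n_assoc_true + n_ad_true must not exceed n_metabolites")
  if (abs(sum(status_props) - 1) > 1e-8) stop("status_props must sum to 1")
  if (!n_waves %in% 1:2) stop("n_waves must be 1 or 2")
  structure(cfg, class = "cohort_sim_config")
}

## partition n_subjects into n_families groups of size >= 1
draw_family_sizes <- function(n_subjects, n_families) {
  sizes <- rep(1L, n_families)
  extra <- n_subjects - n_families
  if (extra > 0) {
    add <- table(sample.int(n_families, extra, replace = TRUE))
    sizes[as.integer(names(add))] <- sizes[as.integer(names(add))] + as.integer(add)
  }
  sizes
}

lognorm_mean1 <- function(n, cv) {
  ## multiplicative noise with E[X] = 1 and SD/mean = cv
  if (length(cv) == 1) cv <- rep(cv, n)
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a multi-wave metabolomics cohort with known ground truth
#'
#' Generates all observational inputs of the pipeline. Abundances follow
#' `raw = 2^(mu_m + sd_m * (status/AD/covariate effects + subject deviation))
#' * runday_factor * batch_factor * technical_noise`, reference samples share
#' the fixed profile `2^mu_m` scaled by the same technical factors, and
#' missingness follows the MNAR-weighted rule of [cohort_sim_config()].
#'
#' @param config A [cohort_sim_config()].
#' @return List with elements `abundance` ([abundance_matrix()], raw scale),
#'   `phenotypes` (data frame, one row per subject per wave), `annotation`
#'   (pathway table) and `truth` (list: `assoc` and `ad` effect tables,
#'   per-metabolite `cv`, `runday_factors`, `batch_factors`, per-subject
#'   `liability`, the per-metabolite `mu` and `sigma` and the config).
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  ns <- config$n_subjects
  nm <- config$n_metabolites

  ## --- subjects, families, liability-based status -------------------------
  fam_sizes <- draw_family_sizes(ns, config$n_families)
  family_id <- sprintf("F%04d", rep.int(seq_along(fam_sizes), fam_sizes))
  subject_id <- sprintf("S%04d", seq_len(ns))
  rho <- config$family_liability_cor
  fam_eff <- stats::rnorm(config$n_families)
  liability <- sqrt(rho) * rep.int(fam_eff, fam_sizes) +
    sqrt(1 - rho) * stats::rnorm(ns)
  p <- config$status_props
  cuts <- stats::qnorm(cumsum(p)[1:2])
  mdd_status <- cut(liability, c(-Inf, cuts, Inf),
                    labels = c("control", "remitted", "current"))
  mdd_status <- as.character(mdd_status)

  ## IDS severity: status-dependent mean plus liability leakage
  ids_mean <- c(control = 8, remitted = 15, current = 30)[mdd_status]
  ids_sd <- c(control = 5, remitted = 8, current = 10)[mdd_status]
  ids_total <- round(pmin(84, pmax(0, ids_mean + 3 * liability +
                                     stats::rnorm(ns, 0, ids_sd))))

  ## covariates
  sex <- sample(c("female", "male"), ns, replace = TRUE, prob = c(0.65, 0.35))
  age <- round(pmin(65, pmax(18, stats::rnorm(ns, 43, 13))))
  education <- round(pmin(22, pmax(5, stats::rnorm(ns, 12, 3))))
  physical_activity <- round(stats::rlnorm(ns, log(3000), 0.6))
  smoking <- sample(c("never", "ex", "current"), ns, replace = TRUE,
                    prob = c(0.45, 0.3, 0.25))
  alcohol <- round(stats::rgamma(ns, shape = 1.2, scale = 5), 1)
  n_chronic_diseases <- stats::rpois(ns, 0.7)
  bmi <- round(pmax(16, stats::rnorm(ns, 26, 5)), 1)
  shipment <- sample(1:2, ns, replace = TRUE)

  ## antidepressant flags, concentrated in current MDD
  p_ssri <- c(control = 0.005, remitted = 0.10, current = 0.27)[mdd_status]
  p_tca <- c(control = 0.001, remitted = 0.015, current = 0.04)[mdd_status]
  p_snri <- c(control = 0.002, remitted = 0.04, current = 0.11)[mdd_status]
  ad_ssri <- stats::runif(ns) < p_ssri
  ad_tca <- stats::runif(ns) < p_tca
  ad_snri <- stats::runif(ns) < p_snri
  ad_any <- ad_ssri | ad_tca | ad_snri

  ## --- metabolite generating model ---------------------------------------
  metabolite_id <- sprintf("M%03d", seq_len(nm))
  mu <- stats::runif(nm, 10, 20)          # log2 location
  sigma <- stats::runif(nm, 0.5, 1.5)     # biological SD (log2 units)
  cv <- stats::rlnorm(nm, config$cv_meanlog, config$cv_sdlog)

  assoc_ids <- ad_ids <- character(0)
  assoc_sign <- integer(0)
  if (config$n_assoc_true > 0) {
    assoc_idx <- seq_len(config$n_assoc_true)
    assoc_ids <- metabolite_id[assoc_idx]
    assoc_sign <- sample(c(-1L, 1L), config$n_assoc_true, replace = TRUE)
  }
  if (config$n_ad_true > 0) {
    ad_idx <- config$n_assoc_true + seq_len(config$n_ad_true)
    ad_ids <- metabolite_id[ad_idx]
  }
  eff_assoc <- numeric(nm)
  eff_assoc[match(assoc_ids, metabolite_id)] <- config$delta * assoc_sign
  eff_ad <- numeric(nm)
  eff_ad[match(ad_ids, metabolite_id)] <- config$ad_delta
  load_age <- stats::rnorm(nm, 0, config$covariate_effect_sd)
  load_sex <- stats::rnorm(nm, 0, config$covariate_effect_sd)
  load_bmi <- stats::rnorm(nm, 0, config$covariate_effect_sd)

  z_age <- as.numeric(scale(age))
  z_bmi <- as.numeric(scale(bmi))
  z_sex <- as.numeric(sex == "female")
  status_mult <- c(control = 0, remitted = 0.5, current = 1)[mdd_status]

  ## per-subject stable deviation + per-wave innovation
  u_stable <- matrix(stats::rnorm(ns * nm), ns, nm)

  ## fixed-effect part shared across waves (SD units)
  fixed_part <- outer(status_mult, eff_assoc) +
    outer(as.numeric(get(config$ad_driver_class)), eff_ad) +
    outer(z_age, load_age) + outer(z_sex, load_sex) + outer(z_bmi, load_bmi)

  waves <- c("baseline", if (config$n_waves == 2) "followup6")
  if (config$n_waves == 2) {
    n_fu <- round(config$followup_fraction * ns)
    fu_subjects <- sort(sample.int(ns, n_fu))
  } else fu_subjects <- integer(0)

  make_wave_log2 <- function(subj_idx) {
    k <- length(subj_idx)
    innov <- matrix(stats::rnorm(k * nm), k, nm)
    z <- sqrt(config$wave_cor) * u_stable[subj_idx, , drop = FALSE] +
      sqrt(1 - config$wave_cor) * innov
    sweep((fixed_part[subj_idx, , drop = FALSE] + z) %*% diag(sigma, nm), 2, mu, "+")
  }

  log2_base <- make_wave_log2(seq_len(ns))
  rownames(log2_base) <- paste0(subject_id, "_b")
  log2_all <- log2_base
  if (length(fu_subjects)) {
    log2_fu <- make_wave_log2(fu_subjects)
    rownames(log2_fu) <- paste0(subject_id[fu_subjects], "_f6")
    log2_all <- rbind(log2_all, log2_fu)
  }
  exp_wave <- rep(c("baseline", "followup6"),
                  c(ns, length(fu_subjects)))

  ## reference samples: one fixed plasma profile
  nref <- config$n_reference_samples
  ref_ids <- sprintf("REF%03d", seq_len(nref))
  log2_ref <- matrix(mu, nref, nm, byrow = TRUE, dimnames = list(ref_ids, NULL))
  log2_all <- rbind(log2_all, log2_ref)
  colnames(log2_all) <- metabolite_id
  all_ids <- rownames(log2_all)
  n_all <- nrow(log2_all)
  is_reference <- c(rep(FALSE, n_all - nref), rep(TRUE, nref))
  wave_all <- c(exp_wave, sample(waves, nref, replace = TRUE))

  ## --- technical layout and multiplicative factors ------------------------
  batch <- sample(sprintf("B%02d", seq_len(config$n_batches)), n_all, replace = TRUE)
  run_day <- paste0(batch, "_D",
                    sample.int(config$run_days_per_batch, n_all, replace = TRUE))
  plate <- paste0(batch, "_P",
                  sample.int(config$plates_per_batch, n_all, replace = TRUE))

  runday_levels <- sort(unique(run_day))
  batch_levels <- sort(unique(batch))
  runday_fac <- matrix(stats::rlnorm(length(runday_levels) * nm, 0, config$runday_sdlog),
                       length(runday_levels), nm,
                       dimnames = list(runday_levels, metabolite_id))
  batch_fac <- matrix(stats::rlnorm(length(batch_levels) * nm, 0, config$batch_sdlog),
                      length(batch_levels), nm,
                      dimnames = list(batch_levels, metabolite_id))

  tech_noise <- matrix(lognorm_mean1(n_all * nm, rep(cv, each = n_all)), n_all, nm)
  raw <- 2^log2_all * runday_fac[run_day, , drop = FALSE] *
    batch_fac[batch, , drop = FALSE] * tech_noise

  ## --- MNAR-weighted missingness ------------------------------------------
  if (config$missing_rate > 0) {
    w <- config$mnar_weight
    u <- apply(raw, 2, function(col) (rank(col) - 0.5) / length(col))
    p_miss <- pmin(1, config$missing_rate * ((1 - w) + 2 * w * (1 - u)))
    raw[stats::runif(n_all * nm) < p_miss] <- NA
  }

  subject_of <- c(subject_id, subject_id[fu_subjects], rep(NA_character_, nref))
  sample_meta <- data.frame(sample_id = all_ids, subject_id = subject_of,
                            batch = batch, plate = plate,
                            run_day = run_day, wave = wave_all,
                            is_reference = is_reference,
                            stringsAsFactors = FALSE)
  abundance <- abundance_matrix(raw, sample_meta, scale = "raw")

  ## --- phenotype table ----------------------------------------------------
  base_phen <- data.frame(
    subject_id = subject_id, family_id = family_id, wave = "baseline",
    mdd_status = mdd_status, ids_total = ids_total, sex = sex, age = age,
    education = education, physical_activity = physical_activity,
    smoking = smoking, alcohol = alcohol,
    n_chronic_diseases = n_chronic_diseases, bmi = bmi, shipment = shipment,
    ad_ssri = ad_ssri, ad_tca = ad_tca, ad_snri = ad_snri,
    stringsAsFactors = FALSE)
  phen <- base_phen
  if (length(fu_subjects)) {
    fu_phen <- base_phen[fu_subjects, ]
    fu_phen$wave <- "followup6"
    ## severity re-assessed at follow-up around the same status-level mean
    fu_phen$ids_total <- round(pmin(84, pmax(0,
      ids_mean[fu_subjects] + 3 * liability[fu_subjects] +
        stats::rnorm(length(fu_subjects), 0, ids_sd[fu_subjects]))))
    phen <- rbind(phen, fu_phen)
  }
  rownames(phen) <- NULL

  annotation <- simulate_annotation(metabolite_id, assoc_ids, assoc_sign,
                                    config$classified_fraction)

  truth <- list(
    assoc = data.frame(metabolite_id = assoc_ids,
                       effect = config$delta * assoc_sign,
                       stringsAsFactors = FALSE),
    ad = data.frame(metabolite_id = ad_ids,
                    effect = rep(config$ad_delta, length(ad_ids)),
                    driver_class = rep(config$ad_driver_class, length(ad_ids)),
                    stringsAsFactors = FALSE),
    cv = stats::setNames(cv, metabolite_id),
    mu = stats::setNames(mu, metabolite_id),
    sigma = stats::setNames(sigma, metabolite_id),
    runday_factors = runday_fac,
    batch_factors = batch_fac,
    liability = stats::setNames(liability, subject_id),
    config = config)

  list(abundance = abundance, phenotypes = validate_phenotypes(phen),
       annotation = annotation, truth = truth)
}

## pathway labels mimic an untargeted-platform annotation: ~10 super
## pathways, sub pathways nested under them; truly shifted metabolites are
## concentrated in two lipid sub pathways so enrichment has signal to find.
simulate_annotation <- function(metabolite_id, assoc_ids, assoc_sign,
                                classified_fraction) {
  subs <- c(Lipid = "Lysophospholipid",
            Lipid = "Long Chain Saturated Fatty Acid",
            Lipid = "Long Chain Monounsaturated Fatty Acid",
            Lipid = "Sphingomyelins",
            `Amino Acid` = "Leucine, Isoleucine and Valine Metabolism",
            `Amino Acid` = "Tryptophan Metabolism",
            `Amino Acid` = "Urea cycle",
            Carbohydrate = "Glycolysis and Gluconeogenesis",
            Nucleotide = "Purine Metabolism",
            `Cofactors and Vitamins` = "Nicotinate and Nicotinamide Metabolism",
            Energy = "TCA Cycle",
            Peptide = "Dipeptide",
            Xenobiotics = "Food Component/Plant",
            `Partially Characterized Molecules` = "Partially Characterized Molecules")
  nm <- length(metabolite_id)
  super_pathway <- rep(NA_character_, nm)
  sub_pathway <- rep(NA_character_, nm)
  classified <- stats::runif(nm) < classified_fraction
  idx <- sample.int(length(subs), nm, replace = TRUE)
  super_pathway[classified] <- names(subs)[idx[classified]]
  sub_pathway[classified] <- unname(subs)[idx[classified]]
  ## concentrate true positives: up-shifted in lysophospholipids,
  ## down-shifted in long-chain saturated fatty acids
  if (length(assoc_ids)) {
    pos <- match(assoc_ids, metabolite_id)
    up <- assoc_sign > 0
    super_pathway[pos] <- "Lipid"
    sub_pathway[pos[up]] <- "Lysophospholipid"
    sub_pathway[pos[!up]] <- "Long Chain Saturated Fatty Acid"
  }
  data.frame(metabolite_id = metabolite_id, super_pathway = super_pathway,
             sub_pathway = sub_pathway, stringsAsFactors = FALSE)
}
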