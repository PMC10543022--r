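#' Configuration for the summary-statistics simulator
#'
#' Defines paired exposure (metabolite) and outcome (depression) GWAS summary
#' statistics in a two-sample design with a known causal effect and tunable
#' horizontal pleiotropy.
#'
#' @param n_metabolites Number of exposures to simulate.
#' @param snps_per_metabolite Independent instrument SNPs per exposure.
#' @param h2_per_snp Per-SNP variance in the (SD-scaled) exposure explained
#'   by each instrument.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome (binary trait) GWAS sample sizes.
#' @param theta True causal effect, log-odds of outcome per SD of exposure.
#' @param pleiotropy_frac Fraction of SNPs with a direct (horizontal) effect
#'   on the outcome.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects)
#'   or `"directional"` (positive-mean direct effects).
#' @param pleiotropy_mean Mean direct effect under `"directional"`.
#' @param pleiotropy_sd SD of direct effects under either non-null mode.
#' @param maf_range Range of minor-allele frequencies, within (0, 0.5].
#' @param palindromic_frac Fraction of SNPs given strand-ambiguous (A/T or
#'   C/G) allele pairs.
#' @param outcome_flip_frac Fraction of outcome records stored with the
#'   effect/other alleles swapped (exercises harmonization).
#' @param seed Integer RNG seed.
#' @return An `mr_sim_config` list.
#' @export
mr_sim_config <- function(n_metabolites = 5,
                          snps_per_metabolite = 20,
                          h2_per_snp = 0.005,
                          n_exposure = 14000,
                          n_cases = 246363,
                          n_controls = 561190,
                          theta = 0.09,
                          pleiotropy_frac = 0,
                          pleiotropy_mode = c("none", "balanced", "directional"),
                          pleiotropy_mean = 0.02,
                          pleiotropy_sd = 0.01,
                          maf_range = c(0.05, 0.5),
                          palindromic_frac = 0.1,
                          outcome_flip_frac = 0.3,
                          seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  cfg <- c(as.list(environment()))
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1)
    stop("pleiotropy_frac must lie in [0,1]")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (h2_per_snp <= 0 || h2_per_snp >= 1)
    stop("h2_per_snp must lie in (0,1)")
  structure(cfg, class = "mr_sim_config")
}

## binary-outcome per-allele SE approximation:
## se = 1 / sqrt(2 maf (1-maf) n_eff v), n_eff = 4/(1/n_cases + 1/n_controls)
## and v = 0.25 the balanced case-fraction variance factor.
outcome_se <- function(maf, n_cases, n_controls) {
  n_eff <- 4 / (1 / n_cases + 1 / n_controls)
  1 / sqrt(2 * maf * (1 - maf) * n_eff * 0.25)
}

#' Simulate paired two-sample MR summary statistics
#'
#' For each instrument SNP j of a metabolite, the true per-allele exposure
#' effect is `b_xj = sqrt(h2 / (2 maf_j (1 - maf_j)))` with random sign, the
#' observed `beta_x ~ N(b_xj, se_xj)` with `se_xj = 1/sqrt(2 maf (1-maf)
#' n_x)`, and the true outcome effect is `b_yj = theta * b_xj + alpha_j`
#' where `alpha_j` is the SNP's horizontal-pleiotropy effect (zero,
#' zero-mean, or positive-mean depending on the mode). Observed outcome
#' effects are drawn with the binary-trait SE approximation. SNPs are placed
#' far apart on the genome so that they are independent instruments.
#'
#' @param config An [mr_sim_config()].
#' @return List with `exposure` (named list of per-metabolite sumstats
#'   data frames), `outcome` (one sumstats data frame covering all SNPs),
#'   `ld_map` (data frame `variant_a`, `variant_b`, `r2`; empty because
#'   generated instruments are mutually independent) and `truth` (per-SNP
#'   table with true effects and pleiotropy, plus `theta` and the config).
#' @export
simulate_sumstats <- function(config = mr_sim_config()) {
  stopifnot(inherits(config, "mr_sim_config"))
  set.seed(config$seed)
  nm <- config$n_metabolites
  k <- config$snps_per_metabolite
  met_ids <- sprintf("M%03d", seq_len(nm))

  exposure <- vector("list", nm)
  names(exposure) <- met_ids
  truth_rows <- vector("list", nm)
  outcome_rows <- vector("list", nm)

  non_pal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

  for (m in seq_len(nm)) {
    variant_id <- sprintf("rs%d%03d", m, seq_len(k))
    chr <- ((seq_len(k) - 1) %% 22) + 1
    pos <- (m * 31 + seq_len(k) * 17) %% 40 * 3e6 + 2e7 +
      ((seq_len(k) - 1) %/% 22) * 1.3e8
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    eaf <- ifelse(stats::runif(k) < 0.5, maf, 1 - maf)
    is_pal <- stats::runif(k) < config$palindromic_frac
    alle <- lapply(seq_len(k), function(j)
      if (is_pal[j]) pal[[sample.int(4, 1)]] else non_pal[[sample.int(8, 1)]])
    effect_allele <- vapply(alle, `[`, "", 1)
    other_allele <- vapply(alle, `[`, "", 2)

    ## per-SNP variance explained varies around its mean: instrument
    ## strengths in metabolite GWAS are heterogeneous, and a spread in |bx|
    ## is what identifies the intercept of an Egger regression
    h2 <- config$h2_per_snp * stats::runif(k, 0.3, 1.7)
    bx_true <- sqrt(h2 / (2 * maf * (1 - maf))) *
      sample(c(-1, 1), k, replace = TRUE)
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    beta_x <- stats::rnorm(k, bx_true, se_x)
    p_x <- 2 * stats::pnorm(-abs(beta_x / se_x))

    ## pleiotropy is defined in the exposure-raising orientation (the
    ## convention under which a directional mean is identifiable by the
    ## Egger intercept), hence the sign(bx) factor on the per-allele scale
    alpha <- numeric(k)
    if (config$pleiotropy_mode != "none" && config$pleiotropy_frac > 0) {
      which_pl <- stats::runif(k) < config$pleiotropy_frac
      mu_a <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
      alpha[which_pl] <- stats::rnorm(sum(which_pl), mu_a, config$pleiotropy_sd)
    }
    by_true <- config$theta * bx_true + sign(bx_true) * alpha
    se_y <- outcome_se(maf, config$n_cases, config$n_controls)
    beta_y <- stats::rnorm(k, by_true, se_y)
    p_y <- 2 * stats::pnorm(-abs(beta_y / se_y))

    exposure[[m]] <- data.frame(
      variant_id = variant_id, chr = chr, pos = pos,
      effect_allele = effect_allele, other_allele = other_allele,
      eaf = eaf, beta = beta_x, se = se_x, pvalue = p_x,
      n = config$n_exposure, stringsAsFactors = FALSE)

    ## outcome records, a fraction stored with swapped allele order
    flip <- stats::runif(k) < config$outcome_flip_frac
    outcome_rows[[m]] <- data.frame(
      variant_id = variant_id, chr = chr, pos = pos,
      effect_allele = ifelse(flip, other_allele, effect_allele),
      other_allele = ifelse(flip, effect_allele, other_allele),
      eaf = ifelse(flip, 1 - eaf, eaf),
      beta = ifelse(flip, -beta_y, beta_y),
      se = se_y, pvalue = p_y,
      n = config$n_cases + config$n_controls, stringsAsFactors = FALSE)

    truth_rows[[m]] <- data.frame(
      metabolite_id = met_ids[m], variant_id = variant_id,
      bx_true = bx_true, alpha = alpha, by_true = by_true,
      palindromic = is_pal, stringsAsFactors = FALSE)
  }

  list(exposure = exposure,
       outcome = do.call(rbind, outcome_rows),
       ld_map = data.frame(variant_a = character(0), variant_b = character(0),
                           r2 = numeric(0), stringsAsFactors = FALSE),
       truth = list(snps = do.call(rbind, truth_rows),
                    theta = config$theta, config = config))
}
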