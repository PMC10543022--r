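## Two-sample Mendelian randomization from GWAS summary statistics,
## implemented from first principles: instrument selection with greedy
## clumping, allele harmonization, IVW / weighted-median / MR-Egger
## estimators, Cochran's Q, a global outlier (residual-sum-of-squares
## simulation) test, and single-SNP / leave-one-out diagnostics.

VALID_ALLELES <- c("A", "C", "G", "T")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Select MR instruments from exposure summary statistics
#'
#' Keeps biallelic single-nucleotide variants, drops strand-ambiguous
#' (A/T, C/G) variants and those with minor-allele frequency below
#' `maf_min`, keeps genome-wide significant variants (`pvalue < p_max`),
#' and greedily clumps: variants are visited by ascending p-value and kept
#' only if no previously kept variant on the same chromosome lies within
#' `clump_kb` and has LD `r2 >= clump_r2` in the supplied LD map. Without an
#' LD map, any variant within the window is treated as correlated
#' (distance-only clumping).
#'
#' @param exp Exposure sumstats data frame (see [read_sumstats()]).
#' @param maf_min Minimum minor-allele frequency (default 0.01).
#' @param p_max Significance threshold (default 5.0e-8).
#' @param clump_kb Clumping window in kb (default 10000).
#' @param clump_r2 LD threshold (default 0.001).
#' @param ld Optional LD map data frame (`variant_a`, `variant_b`, `r2`).
#' @return Filtered sumstats of approximately independent instruments.
#' @export
select_instruments <- function(exp, maf_min = 0.01, p_max = 5.0e-8,
                               clump_kb = 10000, clump_r2 = 0.001,
                               ld = NULL) {
  ss <- exp
  snv <- ss$effect_allele %in% VALID_ALLELES & ss$other_allele %in% VALID_ALLELES &
    ss$effect_allele != ss$other_allele
  ss <- ss[snv, , drop = FALSE]
  ss <- ss[!is_palindromic(ss$effect_allele, ss$other_allele), , drop = FALSE]
  maf <- pmin(ss$eaf, 1 - ss$eaf)
  ss <- ss[!is.na(maf) & maf >= maf_min, , drop = FALSE]
  ss <- ss[!is.na(ss$pvalue) & ss$pvalue < p_max, , drop = FALSE]
  if (!nrow(ss)) return(ss)
  if (anyNA(ss$pos) || anyNA(ss$chr))
    stop("positions required for clumping")

  ld_r2 <- function(v1, v2) {
    if (is.null(ld) || !nrow(ld)) return(1)  # distance-only fallback
    hit <- (ld$variant_a == v1 & ld$variant_b == v2) |
      (ld$variant_a == v2 & ld$variant_b == v1)
    if (any(hit)) max(ld$r2[hit]) else 0
  }
  ss <- ss[order(ss$pvalue), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(ss))) {
    ok <- TRUE
    for (j in kept) {
      if (ss$chr[i] == ss$chr[j] &&
          abs(ss$pos[i] - ss$pos[j]) <= clump_kb * 1000 &&
          ld_r2(ss$variant_id[i], ss$variant_id[j]) >= clump_r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- ss[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns both studies to the exposure's effect allele: where the outcome
#' stores the allele pair in swapped order, the outcome beta changes sign
#' and its frequency becomes `1 - eaf`; variants whose alleles cannot be
#' matched even after the swap are dropped with a logged reason.
#' Palindromic variants are expected to have been removed upstream. The
#' per-SNP instrument F-statistic `(bx/sx)^2` is attached.
#'
#' @param exp Exposure instruments ([select_instruments()] output).
#' @param out Outcome sumstats covering (some of) the same variants.
#' @return A `harmonized_set`: data frame `variant_id`, `bx`, `sx`, `by`,
#'   `sy`, `eaf`, `f_statistic` plus a `dropped` attribute.
#' @export
harmonize <- function(exp, out) {
  shared <- intersect(exp$variant_id, out$variant_id)
  if (!length(shared)) stop("no shared variants between exposure and outcome")
  e <- exp[match(shared, exp$variant_id), ]
  o <- out[match(shared, out$variant_id), ]
  same <- e$effect_allele == o$effect_allele & e$other_allele == o$other_allele
  swapped <- e$effect_allele == o$other_allele & e$other_allele == o$effect_allele
  mism <- !same & !swapped
  by <- ifelse(swapped, -o$beta, o$beta)
  dropped <- data.frame(variant_id = shared[mism],
                        reason = rep("allele mismatch", sum(mism)),
                        stringsAsFactors = FALSE)
  if (nrow(dropped))
    message(nrow(dropped), " variant(s) dropped at harmonization: allele mismatch")
  keep <- !mism
  h <- data.frame(variant_id = shared[keep],
                  bx = e$beta[keep], sx = e$se[keep],
                  by = by[keep], sy = o$se[keep],
                  eaf = e$eaf[keep],
                  f_statistic = (e$beta[keep] / e$se[keep])^2,
                  stringsAsFactors = FALSE)
  attr(h, "dropped") <- dropped
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' Inverse-variance weighted estimator
#'
#' `estimate = sum(bx by / sy^2) / sum(bx^2 / sy^2)`, equivalent to weighted
#' least squares of `by` on `bx` through the origin with weights `1/sy^2`.
#' The fixed-effect SE `sqrt(1 / sum(bx^2/sy^2))` is multiplied by
#' `max(1, sqrt(Q/(k-1)))` (multiplicative random-effects inflation) unless
#' `random_effect = FALSE`.
#'
#' @param h A [harmonize()]d set with at least 2 SNPs.
#' @param random_effect Apply the multiplicative variance inflation.
#' @param allow_single Permit a single-SNP set (internal use; the estimate
#'   then reduces to the Wald ratio `by/bx`).
#' @return List `estimate`, `se`, `p`, `or`, `ci_lower`, `ci_upper`,
#'   `se_fixed`, `n_snps`.
#' @export
ivw <- function(h, random_effect = TRUE, allow_single = FALSE) {
  k <- nrow(h)
  if (k < 2 && !allow_single)
    stop("insufficient instruments (need >= 2 SNPs, have ", k, ")")
  if (k < 1) stop("empty instrument set")
  w <- 1 / h$sy^2
  est <- sum(h$bx * h$by * w) / sum(h$bx^2 * w)
  se_fixed <- sqrt(1 / sum(h$bx^2 * w))
  se <- se_fixed
  if (random_effect && k >= 2) {
    q <- cochran_q(h, est)$Q
    se <- se_fixed * max(1, sqrt(q / (k - 1)))
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  list(estimate = est, se = se, p = p, or = exp(est),
       ci_lower = exp(est - 1.96 * se), ci_upper = exp(est + 1.96 * se),
       se_fixed = se_fixed, n_snps = k)
}

## weighted quantile with linear interpolation across cumulative weight
weighted_quantile <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w) - w / 2
  if (q <= cw[1]) return(x[1])
  if (q >= cw[length(cw)]) return(x[length(x)])
  stats::approx(cw, x, xout = q)$y
}

#' Weighted-median estimator
#'
#' The 50% weighted quantile of the per-SNP Wald ratios `by/bx` with
#' normalized inverse-variance weights `bx^2/sy^2`; consistent when at
#' least half the weight comes from valid instruments. The SE is a seeded
#' parametric bootstrap perturbing `bx` and `by` by their SEs.
#'
#' @param h A [harmonize()]d set with at least 3 SNPs.
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return List `estimate`, `se`, `p`, `or`, `ci_lower`, `ci_upper`,
#'   `n_snps`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  k <- nrow(h)
  if (k < 3) stop("weighted median needs >= 3 SNPs, have ", k)
  w <- h$bx^2 / h$sy^2
  est <- weighted_quantile(h$by / h$bx, w)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(k, h$bx, h$sx)
    by <- stats::rnorm(k, h$by, h$sy)
    weighted_quantile(by / bx, bx^2 / h$sy^2)
  }, 0)
  se <- stats::sd(boot)
  p <- 2 * stats::pnorm(-abs(est / se))
  list(estimate = est, se = se, p = p, or = exp(est),
       ci_lower = exp(est - 1.96 * se), ci_upper = exp(est + 1.96 * se),
       n_snps = k)
}

#' MR-Egger regression
#'
#' Weighted regression of `by` on `bx` with intercept and weights `1/sy^2`,
#' after flipping each SNP so that `bx >= 0` (orientation convention for an
#' interpretable intercept). The slope is the causal estimate; a nonzero
#' intercept indicates directional horizontal pleiotropy.
#'
#' @param h A [harmonize()]d set with at least 3 SNPs.
#' @return List with `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `or`, `ci_lower`, `ci_upper`, `n_snps`.
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs >= 3 SNPs, have ", k)
  flip <- sign(h$bx)
  flip[flip == 0] <- 1
  bx <- h$bx * flip
  by <- h$by * flip
  w <- 1 / h$sy^2
  x <- cbind(1, bx)
  xtwx <- crossprod(x, x * w)
  coefs <- drop(solve(xtwx, crossprod(x, by * w)))
  resid <- by - drop(x %*% coefs)
  ## t-distributed inference with multiplicative overdispersion >= 1
  phi <- max(1, sum(w * resid^2) / (k - 2))
  vc <- solve(xtwx) * phi
  se <- sqrt(diag(vc))
  tval <- coefs / se
  pv <- 2 * stats::pt(-abs(tval), df = k - 2)
  list(slope = coefs[2], slope_se = se[2], slope_p = pv[2],
       intercept = coefs[1], intercept_se = se[1], intercept_p = pv[1],
       or = exp(coefs[2]),
       ci_lower = exp(coefs[2] - 1.96 * se[2]),
       ci_upper = exp(coefs[2] + 1.96 * se[2]),
       n_snps = k)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - estimate)^2` over per-SNP Wald ratios
#' `theta_j = by_j/bx_j` with first-order weights `w_j = bx_j^2/sy_j^2`,
#' referred to a chi-square with `k - 1` degrees of freedom.
#'
#' @param h A [harmonize()]d set with at least 2 SNPs.
#' @param estimate Pooled estimate to measure heterogeneity around
#'   (defaults to the fixed-effect IVW estimate).
#' @return List `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, estimate = NULL) {
  k <- nrow(h)
  if (k < 2) stop("Cochran's Q needs >= 2 SNPs")
  if (is.null(estimate)) {
    w0 <- 1 / h$sy^2
    estimate <- sum(h$bx * h$by * w0) / sum(h$bx^2 * w0)
  }
  theta <- h$by / h$bx
  w <- h$bx^2 / h$sy^2
  q <- sum(w * (theta - estimate)^2)
  list(Q = q, df = k - 1, p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

## leave-one-out IVW estimates, vectorised
loo_ivw_estimates <- function(bx, by, sy) {
  w <- 1 / sy^2
  num <- sum(bx * by * w)
  den <- sum(bx^2 * w)
  (num - bx * by * w) / (den - bx^2 * w)
}

#' Global outlier test by residual-sum-of-squares simulation
#'
#' The observed statistic is the weighted residual sum of squares of the
#' outcome effects around their leave-one-out IVW predictions. Its null
#' distribution is simulated by redrawing both studies' effects —
#' `bx_j ~ N(bx_j, sx_j^2)` and `by_j ~ N(bx_j * theta_loo(-j), sy_j^2)` —
#' and recomputing the statistic on each draw (redrawing the exposure as
#' well keeps the test calibrated when exposure effects carry measurement
#' error); the p-value is the add-one-smoothed fraction of simulated
#' statistics at least as large.
#'
#' @param h A [harmonize()]d set with at least 4 SNPs.
#' @param n_sim Simulated null draws (default 1000).
#' @param seed RNG seed.
#' @return List `rss_obs`, `p`, `n_sim`; `NULL` (with a warning) below 4
#'   SNPs.
#' @export
presso_global <- function(h, n_sim = 1000, seed = 1L) {
  k <- nrow(h)
  if (k < 4) {
    warning("global outlier test needs >= 4 SNPs, have ", k, "; skipped")
    return(NULL)
  }
  w <- 1 / h$sy^2
  loo <- loo_ivw_estimates(h$bx, h$by, h$sy)
  rss_obs <- sum(w * (h$by - h$bx * loo)^2)
  set.seed(seed)
  sims <- matrix(stats::rnorm(n_sim * k, mean = rep(h$bx * loo, each = n_sim),
                              sd = rep(h$sy, each = n_sim)), n_sim, k)
  bxm <- matrix(stats::rnorm(n_sim * k, mean = rep(h$bx, each = n_sim),
                             sd = rep(h$sx, each = n_sim)), n_sim, k)
  ## recompute LOO predictions within each simulated dataset
  wm <- matrix(w, n_sim, k, byrow = TRUE)
  num <- rowSums(bxm * sims * wm)
  den <- rowSums(bxm^2 * wm)
  loo_sim <- (num - bxm * sims * wm) / (den - bxm^2 * wm)
  rss_sim <- rowSums(wm * (sims - bxm * loo_sim)^2)
  p <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)
  list(rss_obs = rss_obs, p = p, n_sim = n_sim)
}

#' Single-SNP and leave-one-out analyses
#'
#' Per-SNP Wald ratios `by/bx` with first-order SEs `sy/|bx|`, and the IVW
#' estimate recomputed with each SNP left out in turn.
#'
#' @param h A [harmonize()]d set (>= 3 SNPs for leave-one-out).
#' @return List `single_snp` (data frame: `variant_id`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`) and `leave_one_out` (data frame: `left_out`,
#'   `estimate`).
#' @export
loo_and_single_snp <- function(h) {
  nonzero <- h$bx != 0
  if (any(!nonzero))
    warning(sum(!nonzero), " SNP(s) with bx = 0 excluded from Wald ratios")
  hh <- h[nonzero, , drop = FALSE]
  est <- hh$by / hh$bx
  se <- hh$sy / abs(hh$bx)
  single <- data.frame(variant_id = hh$variant_id, estimate = est, se = se,
                       ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
                       stringsAsFactors = FALSE)
  loo <- NULL
  if (nrow(hh) >= 3)
    loo <- data.frame(left_out = hh$variant_id,
                      estimate = loo_ivw_estimates(hh$bx, hh$by, hh$sy),
                      stringsAsFactors = FALSE)
  list(single_snp = single, leave_one_out = loo)
}

#' Run the full MR pipeline over a set of metabolites
#'
#' For each metabolite with exposure summary statistics: selects
#' instruments, harmonizes against the outcome, and (for metabolites
#' passing the >= 2 independent-instruments gate) computes all estimators
#' and diagnostics. BH q-values are computed across metabolites on the IVW
#' p-values. Metabolites failing the gate are listed with reasons.
#'
#' @param exposures Named list of exposure sumstats data frames (one per
#'   metabolite).
#' @param outcome Outcome sumstats data frame.
#' @param ld Optional LD map for clumping.
#' @param maf_min,p_max,clump_kb,clump_r2 Instrument-selection parameters.
#' @param n_boot,n_sim,seed Bootstrap/simulation control for the weighted
#'   median and global outlier test.
#' @return List `results` (data frame, one row per analysed metabolite with
#'   all estimates, diagnostics and `qvalue`), `skipped` (data frame
#'   `metabolite_id`, `reason`), `detail` (per-metabolite list with the
#'   harmonized set and single-SNP/leave-one-out tables).
#' @export
mr_pipeline <- function(exposures, outcome, ld = NULL,
                        maf_min = 0.01, p_max = 5.0e-8,
                        clump_kb = 10000, clump_r2 = 0.001,
                        n_boot = 1000, n_sim = 1000, seed = 1L) {
  results <- list()
  skipped <- list()
  detail <- list()
  for (id in names(exposures)) {
    inst <- select_instruments(exposures[[id]], maf_min, p_max,
                               clump_kb, clump_r2, ld)
    if (nrow(inst) < 2) {
      skipped[[id]] <- sprintf("only %d independent instrument(s)", nrow(inst))
      next
    }
    h <- tryCatch(harmonize(inst, outcome), error = function(e) NULL)
    if (is.null(h) || nrow(h) < 2) {
      skipped[[id]] <- "fewer than 2 instruments after harmonization"
      next
    }
    fit_ivw <- ivw(h)
    fit_q <- cochran_q(h)
    fit_wm <- if (nrow(h) >= 3) weighted_median(h, n_boot, seed) else NULL
    fit_eg <- if (nrow(h) >= 3) mr_egger(h) else NULL
    fit_pr <- withCallingHandlers(presso_global(h, n_sim, seed),
                                  warning = function(w) invokeRestart("muffleWarning"))
    results[[id]] <- data.frame(
      metabolite_id = id, n_snps = nrow(h),
      ivw_estimate = fit_ivw$estimate, ivw_se = fit_ivw$se,
      ivw_p = fit_ivw$p, ivw_or = fit_ivw$or,
      ivw_ci_lower = fit_ivw$ci_lower, ivw_ci_upper = fit_ivw$ci_upper,
      wm_estimate = if (is.null(fit_wm)) NA_real_ else fit_wm$estimate,
      wm_se = if (is.null(fit_wm)) NA_real_ else fit_wm$se,
      wm_p = if (is.null(fit_wm)) NA_real_ else fit_wm$p,
      wm_or = if (is.null(fit_wm)) NA_real_ else fit_wm$or,
      egger_estimate = if (is.null(fit_eg)) NA_real_ else fit_eg$slope,
      egger_se = if (is.null(fit_eg)) NA_real_ else fit_eg$slope_se,
      egger_p = if (is.null(fit_eg)) NA_real_ else fit_eg$slope_p,
      egger_or = if (is.null(fit_eg)) NA_real_ else fit_eg$or,
      egger_intercept = if (is.null(fit_eg)) NA_real_ else fit_eg$intercept,
      egger_intercept_p = if (is.null(fit_eg)) NA_real_ else fit_eg$intercept_p,
      cochran_q = fit_q$Q, q_pvalue = fit_q$p,
      presso_global_p = if (is.null(fit_pr)) NA_real_ else fit_pr$p,
      min_f_statistic = min(h$f_statistic),
      stringsAsFactors = FALSE)
    detail[[id]] <- c(list(harmonized = h), loo_and_single_snp(h))
  }
  res <- if (length(results)) do.call(rbind, results) else
    data.frame(metabolite_id = character(0), n_snps = integer(0),
               ivw_estimate = numeric(0), ivw_p = numeric(0),
               qvalue = numeric(0))
  if (nrow(res)) res$qvalue <- bh_fdr(res$ivw_p)
  rownames(res) <- NULL
  skip <- if (length(skipped))
    data.frame(metabolite_id = names(skipped),
               reason = unlist(skipped, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(metabolite_id = character(0), reason = character(0),
                  stringsAsFactors = FALSE)
  if (!nrow(res) && length(exposures))
    warning("no metabolite passed the >= 2 independent-instruments gate")
  list(results = res, skipped = skip, detail = detail)
}
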