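## Metabolite QC chain: sample/metabolite exclusions, plate masking,
## run-day and batch median normalisation, reference-sample CV filtering,
## wave-missingness testing, kNN imputation, log2 transform, winsorisation.

qc_step <- function(step, before, after, excluded = character(0),
                    reasons = character(0), detail = NULL) {
  list(step = step,
       n_samples_before = before[1], n_samples_after = after[1],
       n_metabolites_before = before[2], n_metabolites_after = after[2],
       excluded = excluded, reasons = reasons, detail = detail)
}

#' Exclude samples with outlying missingness
#'
#' A sample is removed when its missing fraction exceeds the mean plus
#' `sd_mult` standard deviations of the per-sample missing fractions,
#' computed separately within experimental and within reference samples.
#'
#' @param m An [abundance_matrix()].
#' @param sd_mult Multiplier of the SD above the mean (default 5).
#' @return List `matrix` (filtered [abundance_matrix()]) and `report` (step
#'   record).
#' @export
exclude_high_missingness_samples <- function(m, sd_mult = 5) {
  if (all(is.na(m$values))) stop("all values missing")
  frac <- rowMeans(is.na(m$values))
  drop <- logical(length(frac))
  for (ref in c(FALSE, TRUE)) {
    in_stratum <- m$sample_meta$is_reference == ref
    if (!any(in_stratum)) next
    f <- frac[in_stratum]
    thr <- mean(f) + sd_mult * stats::sd(f)
    if (is.na(thr)) thr <- mean(f)  # single sample in stratum
    drop[in_stratum] <- f > thr
  }
  excluded <- sample_ids(m)[drop]
  out <- if (any(drop)) subset_abundance(m, samples = !drop) else m
  list(matrix = out,
       report = qc_step("exclude_high_missingness_samples",
                        dim(m$values), dim(out$values), excluded,
                        sprintf("sample missingness %.3f > mean+%gSD",
                                frac[drop], sd_mult)))
}

#' Exclude metabolites with high missingness
#'
#' A metabolite is kept iff its missing fraction over all samples is at most
#' `threshold` (strictly "over" the threshold means exclusion).
#'
#' @param m An [abundance_matrix()].
#' @param threshold Maximum tolerated missing fraction (default 0.30).
#' @return List `matrix` and `report`.
#' @export
exclude_high_missingness_metabolites <- function(m, threshold = 0.30) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- colMeans(is.na(m$values))
  drop <- frac > threshold
  out <- if (any(drop)) subset_abundance(m, metabolites = !drop) else m
  list(matrix = out,
       report = qc_step("exclude_high_missingness_metabolites",
                        dim(m$values), dim(out$values),
                        metabolite_ids(m)[drop],
                        sprintf("metabolite missingness %.3f > %.2f",
                                frac[drop], threshold)))
}

#' Mask plates with aberrant medians
#'
#' Formalises visual plate review: for each (metabolite, plate) pair, the
#' plate median is compared with the median over the plate's batch; when the
#' ratio exceeds `factor` (or falls below `1/factor`) all values of that
#' metabolite on that plate are set missing so they cannot distort the
#' subsequent batch correction.
#'
#' @param m An [abundance_matrix()] on the raw/normalized scale.
#' @param factor Maximum tolerated plate/batch median ratio (default 4).
#' @return List `matrix` and `report`; `report$detail$masked` lists masked
#'   (metabolite, plate) pairs.
#' @export
mask_plates <- function(m, factor = 4) {
  v <- m$values
  plate <- m$sample_meta$plate
  batch <- m$sample_meta$batch
  masked <- list()
  for (b in unique(batch)) {
    rows_b <- which(batch == b)
    batch_med <- apply(v[rows_b, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    for (p in unique(plate[rows_b])) {
      rows_p <- rows_b[plate[rows_b] == p]
      plate_med <- apply(v[rows_p, , drop = FALSE], 2, stats::median, na.rm = TRUE)
      ratio <- plate_med / batch_med
      flag <- which(!is.na(ratio) & (ratio > factor | ratio < 1 / factor))
      if (length(flag)) {
        v[rows_p, flag] <- NA
        masked[[length(masked) + 1]] <-
          data.frame(metabolite_id = colnames(v)[flag], plate = p,
                     ratio = ratio[flag], stringsAsFactors = FALSE)
      }
    }
  }
  masked <- if (length(masked)) do.call(rbind, masked) else
    data.frame(metabolite_id = character(0), plate = character(0),
               ratio = numeric(0), stringsAsFactors = FALSE)
  out <- abundance_matrix(v, m$sample_meta, scale = m$scale)
  list(matrix = out,
       report = qc_step("mask_plates", dim(m$values), dim(out$values),
                        detail = list(masked = masked)))
}

group_median_normalize <- function(m, labels, what) {
  if (anyNA(labels)) stop(what, " label absent for some sample(s)")
  v <- m$values
  for (g in unique(labels)) {
    rows <- which(labels == g)
    med <- apply(v[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    none <- is.na(med) | med == 0
    if (any(none)) {
      warning(sum(none), " (metabolite, ", what,
              ") group(s) without a usable median left unscaled")
      med[none] <- 1
    }
    v[rows, ] <- sweep(v[rows, , drop = FALSE], 2, med, "/")
  }
  abundance_matrix(v, m$sample_meta, scale = "normalized")
}

#' Run-day median normalisation
#'
#' Divides each value by the median of the observed values of that
#' metabolite on that run-day, so every (metabolite, run-day) observed
#' median becomes 1. Emulates the platform's run-day correction.
#'
#' @param m An [abundance_matrix()] on the raw scale.
#' @return A normalized-scale [abundance_matrix()].
#' @export
runday_normalize <- function(m) group_median_normalize(m, m$sample_meta$run_day, "run-day")

#' Batch median normalisation
#'
#' Divides each value by the batch-wise observed median of its metabolite;
#' all (metabolite, batch) observed medians become 1.
#'
#' @param m An [abundance_matrix()].
#' @return A normalized-scale [abundance_matrix()].
#' @export
batch_median_normalize <- function(m) group_median_normalize(m, m$sample_meta$batch, "batch")

#' Filter metabolites by reference-sample technical variability
#'
#' The technical CV of a metabolite is SD/mean (sample SD, n-1 denominator)
#' over its observed reference-sample values, pooled over all reference
#' samples (or averaged over per-batch CVs with `per_batch = TRUE`).
#' Metabolites with CV above `threshold` are removed. Applied after batch
#' correction.
#'
#' @param m An [abundance_matrix()] containing reference samples.
#' @param threshold Maximum tolerated CV (default 0.30).
#' @param per_batch Average per-batch CVs instead of pooling.
#' @return List `matrix`, `cv` (named per-metabolite vector) and `report`.
#' @export
technical_cv_filter <- function(m, threshold = 0.30, per_batch = FALSE) {
  is_ref <- m$sample_meta$is_reference
  if (!any(is_ref)) stop("no reference samples in matrix")
  ref <- m$values[is_ref, , drop = FALSE]
  cv_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / mean(x)
  }
  if (per_batch) {
    bt <- m$sample_meta$batch[is_ref]
    cv <- apply(ref, 2, function(col)
      mean(vapply(split(col, bt), cv_of, 0), na.rm = TRUE))
  } else {
    cv <- apply(ref, 2, cv_of)
  }
  names(cv) <- metabolite_ids(m)
  drop <- !is.na(cv) & cv > threshold
  out <- if (any(drop)) subset_abundance(m, metabolites = !drop) else m
  list(matrix = out, cv = cv,
       report = qc_step("technical_cv_filter", dim(m$values), dim(out$values),
                        metabolite_ids(m)[drop],
                        sprintf("reference CV %.3f > %.2f", cv[drop], threshold),
                        detail = list(cv = cv)))
}

#' Test accumulation of missingness in measurement waves
#'
#' For each metabolite, builds the wave x (missing, observed) contingency
#' table over experimental samples and applies Fisher's exact test (exact
#' network algorithm; Monte-Carlo with 1e5 draws for tables too large for
#' exact evaluation). Metabolites with p below `alpha` are flagged for
#' wave-stratified imputation.
#'
#' @param m An [abundance_matrix()] with at least two waves.
#' @param alpha Flagging threshold; default Bonferroni `0.05 / n_metabolites`.
#' @return Data frame `metabolite_id`, `pvalue`, `flagged`.
#' @export
test_wave_missingness <- function(m, alpha = 0.05 / ncol(m$values)) {
  exp_rows <- !m$sample_meta$is_reference
  waves <- m$sample_meta$wave[exp_rows]
  if (length(unique(waves)) < 2) {
    warning("fewer than two waves present; wave-missingness test skipped")
    return(data.frame(metabolite_id = character(0), pvalue = numeric(0),
                      flagged = logical(0)))
  }
  miss <- is.na(m$values[exp_rows, , drop = FALSE])
  pvals <- apply(miss, 2, function(col) {
    tab <- table(factor(waves), factor(col, levels = c(FALSE, TRUE)))
    if (any(colSums(tab) == 0)) return(1)
    out <- tryCatch(stats::fisher.test(tab)$p.value,
                    error = function(e)
                      stats::fisher.test(tab, simulate.p.value = TRUE,
                                         B = 1e5)$p.value)
    min(out, 1)
  })
  data.frame(metabolite_id = metabolite_ids(m), pvalue = unname(pvals),
             flagged = unname(pvals < alpha), stringsAsFactors = FALSE)
}

## squared Euclidean distance between metabolite profiles on
## pairwise-complete standardized entries, returned as mean squared
## difference (NA when no complete pair exists)
metabolite_distances <- function(z) {
  obs <- !is.na(z)
  z0 <- z
  z0[!obs] <- 0
  o <- obs * 1
  a <- z0^2
  cross <- crossprod(z0)
  d2 <- crossprod(a, o) + crossprod(o, a) - 2 * cross
  npair <- crossprod(o)
  d2 <- d2 / npair
  d2[npair == 0] <- NA
  d2
}

#' k-nearest-neighbour imputation in metabolite space
#'
#' Imputes each missing cell as the mean of the values, in the same sample,
#' of the `k` metabolites whose standardized profiles are closest to the
#' target metabolite (Euclidean distance on pairwise-complete entries),
#' back-transformed to the target metabolite's scale. Observed values are
#' never altered. All waves are pooled unless `stratify_waves` lists
#' metabolites to impute within wave.
#'
#' @param m An [abundance_matrix()].
#' @param k Number of neighbours (default 10).
#' @param stratify_waves Character vector of metabolite ids to impute within
#'   each wave separately (those flagged by [test_wave_missingness()]).
#' @return An [abundance_matrix()] with no missing cells.
#' @export
knn_impute <- function(m, k = 10, stratify_waves = character(0)) {
  v <- m$values
  if (!anyNA(v)) return(m)
  zero_obs <- colSums(!is.na(v)) == 0
  if (any(zero_obs))
    stop("metabolite(s) with no observed values reached imputation: ",
         paste(colnames(v)[zero_obs], collapse = ", "))

  impute_block <- function(vb) {
    mu <- colMeans(vb, na.rm = TRUE)
    sd_ <- apply(vb, 2, stats::sd, na.rm = TRUE)
    sd_[is.na(sd_) | sd_ == 0] <- 1
    ## floor for back-transformed imputations: on the positive abundance
    ## scale a neighbour mean in z-space can fall below zero for skewed
    ## metabolites; missing cells are predominantly low-abundance, so the
    ## smallest observed value is the natural lower bound
    min_obs <- suppressWarnings(apply(vb, 2, min, na.rm = TRUE))
    z <- sweep(sweep(vb, 2, mu, "-"), 2, sd_, "/")
    d2 <- metabolite_distances(z)
    diag(d2) <- Inf
    d2[is.na(d2)] <- Inf
    nb_order <- apply(d2, 2, order)
    for (j in which(colSums(is.na(vb)) > 0)) {
      ord <- nb_order[, j]
      for (i in which(is.na(vb[, j]))) {
        zrow <- z[i, ord]
        zrow <- zrow[!is.na(zrow)]
        if (!length(zrow))
          stop("no observed neighbour for sample ", rownames(vb)[i],
               ", metabolite ", colnames(vb)[j])
        use <- zrow[seq_len(min(k, length(zrow)))]
        vb[i, j] <- max(mu[j] + sd_[j] * mean(use), min_obs[j])
      }
    }
    vb
  }

  strat <- intersect(stratify_waves, colnames(v))
  if (length(strat)) {
    joint_cols <- setdiff(colnames(v), strat)
    if (length(joint_cols))
      v[, joint_cols] <- impute_block(v[, joint_cols, drop = FALSE])
    for (w in unique(m$sample_meta$wave)) {
      rows <- which(m$sample_meta$wave == w)
      if (anyNA(v[rows, strat])) {
        vb <- impute_block(v[rows, , drop = FALSE])
        v[rows, strat] <- vb[, strat]
      }
    }
  } else {
    v <- impute_block(v)
  }
  abundance_matrix(v, m$sample_meta, scale = m$scale)
}

#' Log2 transform and winsorize
#'
#' Log2-transforms the matrix, then clips each metabolite's values to
#' `mean +/- sd_mult * SD`, with mean and SD computed once on the log2
#' values before clipping.
#'
#' @param m An [abundance_matrix()] with strictly positive values.
#' @param sd_mult Winsorization bound in SD units (default 5).
#' @return A log2-scale [abundance_matrix()].
#' @export
log2_and_winsorize <- function(m, sd_mult = 5) {
  v <- m$values
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at sample '%s', metabolite '%s'",
                 rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]))
  lv <- log2(v)
  mu <- colMeans(lv, na.rm = TRUE)
  sd_ <- apply(lv, 2, stats::sd, na.rm = TRUE)
  hi <- mu + sd_mult * sd_
  lo <- mu - sd_mult * sd_
  lv <- pmin(sweep(lv * 0, 2, hi, "+"), lv)
  lv <- pmax(sweep(lv * 0, 2, lo, "+"), lv)
  abundance_matrix(lv, m$sample_meta, scale = "log2")
}

#' Run the full QC chain
#'
#' Stages, in order: run-day median normalisation, exclusion of
#' high-missingness samples, exclusion of high-missingness metabolites,
#' plate masking, batch median normalisation, reference-sample technical CV
#' filtering, wave-missingness testing, removal of reference samples, kNN
#' imputation, log2 transform and winsorisation.
#'
#' @param m Raw-scale [abundance_matrix()] with metadata.
#' @param sample_sd_mult,met_miss_threshold,plate_factor,cv_threshold,
#'   wave_alpha,k,winsor_sd Stage parameters (see the stage functions).
#' @param do_runday_normalize Set `FALSE` if the input is already run-day
#'   normalized.
#' @param wave_alpha Flagging threshold for the wave-missingness test;
#'   default Bonferroni across metabolites.
#' @return List `matrix` (final log2 [abundance_matrix()], experimental
#'   samples only, no missing values) and `report` (class `qc_report`).
#' @export
run_qc_pipeline <- function(m,
                            sample_sd_mult = 5,
                            met_miss_threshold = 0.30,
                            plate_factor = 4,
                            cv_threshold = 0.30,
                            wave_alpha = NULL,
                            k = 10,
                            winsor_sd = 5,
                            do_runday_normalize = TRUE) {
  steps <- list()
  if (do_runday_normalize) {
    m <- runday_normalize(m)
    steps[[length(steps) + 1]] <- qc_step("runday_normalize", dim(m$values), dim(m$values))
  }
  st <- exclude_high_missingness_samples(m, sample_sd_mult)
  m <- st$matrix; steps[[length(steps) + 1]] <- st$report
  st <- exclude_high_missingness_metabolites(m, met_miss_threshold)
  m <- st$matrix; steps[[length(steps) + 1]] <- st$report
  st <- mask_plates(m, plate_factor)
  m <- st$matrix; steps[[length(steps) + 1]] <- st$report
  m <- batch_median_normalize(m)
  steps[[length(steps) + 1]] <- qc_step("batch_median_normalize", dim(m$values), dim(m$values))
  st <- technical_cv_filter(m, cv_threshold)
  m <- st$matrix; cv <- st$cv; steps[[length(steps) + 1]] <- st$report
  if (is.null(wave_alpha)) wave_alpha <- 0.05 / ncol(m$values)
  wave_tab <- test_wave_missingness(m, alpha = wave_alpha)
  steps[[length(steps) + 1]] <- qc_step("test_wave_missingness", dim(m$values),
                                        dim(m$values),
                                        detail = list(flagged = wave_tab$metabolite_id[wave_tab$flagged]))
  keep_exp <- !m$sample_meta$is_reference
  m <- subset_abundance(m, samples = keep_exp)
  steps[[length(steps) + 1]] <- qc_step("drop_reference_samples",
                                        c(sum(keep_exp) + sum(!keep_exp), ncol(m$values)),
                                        dim(m$values))
  m <- knn_impute(m, k = k,
                  stratify_waves = wave_tab$metabolite_id[wave_tab$flagged])
  steps[[length(steps) + 1]] <- qc_step("knn_impute", dim(m$values), dim(m$values))
  m <- log2_and_winsorize(m, winsor_sd)
  steps[[length(steps) + 1]] <- qc_step("log2_and_winsorize", dim(m$values), dim(m$values))
  report <- structure(list(steps = steps, cv = cv, wave_missingness = wave_tab),
                      class = "qc_report")
  list(matrix = m, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  for (s in x$steps)
    cat(sprintf("  %-36s samples %4d -> %4d   metabolites %4d -> %4d\n",
                s$step, s$n_samples_before, s$n_samples_after,
                s$n_metabolites_before, s$n_metabolites_after))
  invisible(x)
}

#' Flatten a QC report into a step table
#'
#' @param report A `qc_report`.
#' @return Data frame with one row per QC step.
#' @export
qc_report_table <- function(report) {
  do.call(rbind, lapply(report$steps, function(s)
    data.frame(step = s$step,
               n_samples_before = s$n_samples_before,
               n_samples_after = s$n_samples_after,
               n_metabolites_before = s$n_metabolites_before,
               n_metabolites_after = s$n_metabolites_after,
               n_excluded = length(s$excluded),
               excluded = paste(s$excluded, collapse = ";"),
               stringsAsFactors = FALSE)))
}
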