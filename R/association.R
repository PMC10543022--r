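#' Specify a per-metabolite association model
#'
#' Encodes the modelling choices of the MWAS: the exposure (3-level MDD
#' status with control as reference, giving the current-vs-control and
#' remitted-vs-control contrasts, or the continuous IDS severity score),
#' the baseline covariate set (education, sex, age, physical activity,
#' smoking as two dummies vs never, alcohol, number of chronic diseases,
#' shipment batch), optional BMI adjustment, the clustering variable and the
#' estimator. Metabolite values are z-scored before modelling so betas are
#' in within-metabolite SD units; `ids_total` is likewise z-scored so the
#' severity beta is per SD of severity.
#'
#' @param exposure `"mdd_status"`, `"ids_total"`, or one of the
#'   antidepressant flags `"ad_ssri"`, `"ad_tca"`, `"ad_snri"`.
#' @param covariates Character vector of covariate columns.
#' @param add_bmi Add BMI to the covariates (sensitivity model).
#' @param cluster Cluster column (default `"family_id"`) or `NULL` for a
#'   plain linear model.
#' @param exclude_ad_users Drop users of any antidepressant class.
#' @param estimator `"gee"` (clustered) or `"ols"`.
#' @param corstr Working correlation for the GEE.
#' @return A `model_spec` list.
#' @export
model_spec <- function(exposure = c("mdd_status", "ids_total",
                                    "ad_ssri", "ad_tca", "ad_snri"),
                       covariates = c("education", "sex", "age",
                                      "physical_activity", "smoking",
                                      "alcohol", "n_chronic_diseases",
                                      "shipment"),
                       add_bmi = FALSE,
                       cluster = "family_id",
                       exclude_ad_users = FALSE,
                       estimator = c("gee", "ols"),
                       corstr = c("exchangeable", "independence")) {
  exposure <- match.arg(exposure)
  estimator <- match.arg(estimator)
  corstr <- match.arg(corstr)
  if (add_bmi) covariates <- union(covariates, "bmi")
  structure(list(exposure = exposure, covariates = covariates,
                 add_bmi = add_bmi, cluster = cluster,
                 exclude_ad_users = exclude_ad_users,
                 estimator = estimator, corstr = corstr),
            class = "model_spec")
}

model_label <- function(spec) {
  if (spec$exclude_ad_users) "no-AD-users"
  else if (spec$add_bmi) "+BMI"
  else "main"
}

## design matrix + exposure column names for one wave's phenotype rows
build_design <- function(phen, spec) {
  df <- phen
  df$mdd_status <- factor(df$mdd_status,
                          levels = c("control", "remitted", "current"))
  df$smoking <- factor(df$smoking, levels = c("never", "ex", "current"))
  df$sex <- factor(df$sex)
  df$shipment <- factor(df$shipment)
  if (spec$exposure == "ids_total") df$ids_total <- as.numeric(scale(df$ids_total))
  rhs <- paste(c(spec$exposure, spec$covariates), collapse = " + ")
  mf <- stats::model.frame(stats::as.formula(paste("~", rhs)), df,
                           na.action = stats::na.pass)
  complete <- stats::complete.cases(mf)
  x <- stats::model.matrix(stats::as.formula(paste("~", rhs)), mf[complete, , drop = FALSE])
  exposure_cols <- switch(spec$exposure,
    mdd_status = c("current-vs-control" = "mdd_statuscurrent",
                   "remitted-vs-control" = "mdd_statusremitted"),
    ids_total = c(severity = "ids_total"),
    stats::setNames(paste0(spec$exposure, "TRUE"),
                    toupper(sub("ad_", "", spec$exposure))))
  missing_cols <- setdiff(exposure_cols, colnames(x))
  if (length(missing_cols))
    stop("exposure term(s) absent from design (constant column?): ",
         paste(missing_cols, collapse = ", "))
  list(x = x, complete = complete, exposure_cols = exposure_cols)
}

#' Fit one family-clustered metabolite model
#'
#' Regresses a (z-scored) metabolite on the exposure and covariates of a
#' [model_spec()], by GEE with family clusters or by OLS, and returns the
#' per-term estimates with robust standard errors and Wald p-values.
#'
#' @param y Metabolite values aligned with `data` rows (log2 scale).
#' @param spec A [model_spec()].
#' @param data Phenotype rows aligned with `y`.
#' @return Data frame with one row per exposure contrast: `contrast`,
#'   `beta`, `se`, `pvalue`, `n_used`.
#' @export
fit_clustered_model <- function(y, spec, data) {
  if (spec$exclude_ad_users) {
    keep <- !(data$ad_ssri | data$ad_tca | data$ad_snri)
    keep[is.na(keep)] <- FALSE
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  des <- build_design(data, spec)
  y_used <- y[des$complete]
  obs <- !is.na(y_used)
  x <- des$x[obs, , drop = FALSE]
  y_used <- y_used[obs]
  y_std <- as.numeric(scale(y_used))
  use_gee <- spec$estimator == "gee" && !is.null(spec$cluster)
  if (use_gee) {
    cl <- data[[spec$cluster]][des$complete][obs]
    fit <- fit_gee_gaussian(y_std, x, cl, corstr = spec$corstr)
    est <- fit$coef; se <- fit$se; pv <- fit$p
  } else {
    fit <- stats::lm.fit(x, y_std)
    est <- fit$coefficients
    r <- fit$residuals
    df_res <- length(y_std) - fit$rank
    xtx_inv <- chol2inv(chol(crossprod(x)))
    se <- sqrt(diag(xtx_inv) * sum(r^2) / df_res)
    pv <- 2 * stats::pt(-abs(est / se), df_res)
  }
  data.frame(contrast = names(des$exposure_cols),
             beta = unname(est[des$exposure_cols]),
             se = unname(se[des$exposure_cols]),
             pvalue = unname(pv[des$exposure_cols]),
             n_used = length(y_std),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH with monotonicity enforcement:
#' `q_i = min over {j : p_j >= p_i} of m * p_j / rank_j`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

## match abundance rows of one wave to phenotype rows via sample_meta
align_wave <- function(matrix, phen, wave) {
  meta <- matrix$sample_meta
  if (!"subject_id" %in% names(meta))
    stop("sample_meta needs a subject_id column to join with phenotypes")
  rows <- which(!meta$is_reference & meta$wave == wave)
  ph <- phen[phen$wave == wave, , drop = FALSE]
  idx <- match(meta$subject_id[rows], ph$subject_id)
  keep <- !is.na(idx)
  list(values = matrix$values[rows[keep], , drop = FALSE],
       phen = ph[idx[keep], , drop = FALSE])
}

#' Metabolome-wide association study
#'
#' Fits one model per metabolite and assembles the association table with
#' BH q-values computed within each contrast family (current-vs-control,
#' remitted-vs-control and severity are separate families).
#'
#' @param matrix QC'd log2 [abundance_matrix()] whose `sample_meta` carries
#'   `subject_id`.
#' @param phen Phenotype table.
#' @param spec A [model_spec()].
#' @param wave Which wave to analyse (default `"baseline"`).
#' @return Association table: `metabolite_id`, `contrast`, `model`, `beta`,
#'   `se`, `pvalue`, `qvalue`, `n_used`.
#' @export
mwas <- function(matrix, phen, spec = model_spec(), wave = "baseline") {
  al <- align_wave(matrix, phen, wave)
  mets <- colnames(al$values)
  rows <- lapply(mets, function(id) {
    res <- fit_clustered_model(al$values[, id], spec, al$phen)
    res$metabolite_id <- id
    res
  })
  tab <- do.call(rbind, rows)
  tab$model <- model_label(spec)
  tab$qvalue <- NA_real_
  for (ct in unique(tab$contrast)) {
    sel <- tab$contrast == ct
    tab$qvalue[sel] <- bh_fdr(tab$pvalue[sel])
  }
  tab[, c("metabolite_id", "contrast", "model", "beta", "se",
          "pvalue", "qvalue", "n_used")]
}

#' Antidepressant sensitivity analyses
#'
#' (a) Refits the MDD-status model excluding all antidepressant users;
#' (b) fits per-class models (SSRI, TCA, SNRI use vs non-use, same
#' covariates); (c) flags any hit metabolite whose absolute class beta
#' exceeds `flag_factor` times its absolute current-MDD beta. Flagged
#' metabolites should be dropped from the replication candidate set.
#'
#' @param matrix QC'd log2 [abundance_matrix()].
#' @param phen Phenotype table.
#' @param baseline Association table of the main MDD-status model (for the
#'   current-vs-control betas the class effects are compared against).
#' @param hits Character vector of hit metabolite ids to screen.
#' @param spec Base [model_spec()] (exposure is overridden per analysis).
#' @param flag_factor Flagging multiple (default 2).
#' @param min_class_users Classes with fewer users are skipped (default 10).
#' @param wave Wave to analyse.
#' @return List `no_ad` (association table without AD users), `ad_class`
#'   (per-class association table), `flagged` (data frame of flagged hits).
#' @export
ad_sensitivity <- function(matrix, phen, baseline, hits,
                           spec = model_spec(), flag_factor = 2,
                           min_class_users = 10, wave = "baseline") {
  spec_noad <- spec
  spec_noad$exposure <- "mdd_status"
  spec_noad$exclude_ad_users <- TRUE
  no_ad <- mwas(matrix, phen, spec_noad, wave = wave)

  class_tabs <- list()
  ph_wave <- phen[phen$wave == wave, ]
  for (fl in c("ad_ssri", "ad_tca", "ad_snri")) {
    n_users <- sum(ph_wave[[fl]], na.rm = TRUE)
    if (n_users < min_class_users) {
      warning(sprintf("%s has %d user(s) (< %d); class skipped",
                      fl, n_users, min_class_users))
      next
    }
    spec_cl <- spec
    spec_cl$exposure <- fl
    spec_cl$exclude_ad_users <- FALSE
    class_tabs[[fl]] <- mwas(matrix, phen, spec_cl, wave = wave)
  }
  ad_class <- if (length(class_tabs)) do.call(rbind, class_tabs) else
    data.frame(metabolite_id = character(0), contrast = character(0),
               model = character(0), beta = numeric(0), se = numeric(0),
               pvalue = numeric(0), qvalue = numeric(0), n_used = integer(0))
  rownames(ad_class) <- NULL

  flagged <- flag_ad_dominated(baseline, ad_class, hits, flag_factor)
  list(no_ad = no_ad, ad_class = ad_class, flagged = flagged)
}

#' Flag hits whose antidepressant-class effect dominates the MDD effect
#'
#' A hit metabolite is flagged when the absolute beta of any
#' antidepressant-class association strictly exceeds `flag_factor` times
#' the absolute current-vs-control beta.
#'
#' @param baseline Association table containing current-vs-control rows.
#' @param ad_class Per-class association table (contrast = class label).
#' @param hits Metabolite ids to screen.
#' @param flag_factor Flagging multiple (default 2).
#' @return Data frame `metabolite_id`, `class`, `beta_ad`, `beta_mdd`.
#' @export
flag_ad_dominated <- function(baseline, ad_class, hits, flag_factor = 2) {
  base_cur <- baseline[baseline$contrast == "current-vs-control", ]
  flagged <- data.frame(metabolite_id = character(0), class = character(0),
                        beta_ad = numeric(0), beta_mdd = numeric(0),
                        stringsAsFactors = FALSE)
  for (id in intersect(hits, base_cur$metabolite_id)) {
    b_mdd <- base_cur$beta[base_cur$metabolite_id == id]
    cls <- ad_class[ad_class$metabolite_id == id, , drop = FALSE]
    over <- which(abs(cls$beta) > flag_factor * abs(b_mdd))
    if (length(over))
      flagged <- rbind(flagged, data.frame(
        metabolite_id = id, class = cls$contrast[over],
        beta_ad = cls$beta[over], beta_mdd = b_mdd,
        stringsAsFactors = FALSE))
  }
  flagged
}

#' Compare two sets of association betas
#'
#' Pearson correlation and fraction of equal-signed effects for the
#' metabolites shared by two association tables, optionally stratified by
#' the sign of the effect in the first table.
#'
#' @param a,b Association tables (one contrast each, or pre-filtered).
#' @param subset Optional metabolite ids to restrict to.
#' @return List `r`, `pct_same_direction`, `n`, and `by_sign` (the same
#'   summaries within `a`-downregulated and `a`-upregulated strata).
#' @export
compare_betas <- function(a, b, subset = NULL) {
  shared <- intersect(a$metabolite_id, b$metabolite_id)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3)
    stop("fewer than 3 shared metabolites (", length(shared), ")")
  ba <- a$beta[match(shared, a$metabolite_id)]
  bb <- b$beta[match(shared, b$metabolite_id)]
  summarise <- function(x, y) {
    if (length(x) < 3) return(list(r = NA_real_,
                                   pct_same_direction = if (length(x)) 100 * mean(sign(x) == sign(y)) else NA_real_,
                                   n = length(x)))
    list(r = stats::cor(x, y), pct_same_direction = 100 * mean(sign(x) == sign(y)),
         n = length(x))
  }
  out <- summarise(ba, bb)
  out$by_sign <- list(down = summarise(ba[ba < 0], bb[ba < 0]),
                      up = summarise(ba[ba > 0], bb[ba > 0]))
  out
}

#' Apply the cross-wave replication rule
#'
#' A candidate metabolite replicates when its follow-up association with
#' current MDD status or with severity has nominal p < 0.05 and the same
#' direction of effect as its baseline current-vs-control beta. Candidates
#' absent from the follow-up tables are recorded as not assessable.
#'
#' @param baseline Baseline association table (current-vs-control rows used).
#' @param followup_status Follow-up MDD-status association table.
#' @param followup_severity Follow-up severity association table.
#' @param candidates Metabolite ids to assess (baseline FDR hits minus
#'   AD-flagged).
#' @param alpha Nominal replication threshold (default 0.05).
#' @return Data frame: `metabolite_id`, `beta_baseline`, `beta_fu_status`,
#'   `p_fu_status`, `beta_fu_severity`, `p_fu_severity`, `replicated`
#'   (logical, `NA` if not assessable), `reason`.
#' @export
replicate_hits <- function(baseline, followup_status, followup_severity,
                           candidates, alpha = 0.05) {
  base_cur <- baseline[baseline$contrast == "current-vs-control", ]
  fu_cur <- followup_status[followup_status$contrast == "current-vs-control", ]
  fu_sev <- followup_severity[followup_severity$contrast == "severity", ]
  out <- lapply(candidates, function(id) {
    b0 <- base_cur$beta[base_cur$metabolite_id == id]
    i1 <- match(id, fu_cur$metabolite_id)
    i2 <- match(id, fu_sev$metabolite_id)
    if (!length(b0) || (is.na(i1) && is.na(i2)))
      return(data.frame(metabolite_id = id, beta_baseline = if (length(b0)) b0 else NA,
                        beta_fu_status = NA_real_, p_fu_status = NA_real_,
                        beta_fu_severity = NA_real_, p_fu_severity = NA_real_,
                        replicated = NA, reason = "not assessable at follow-up",
                        stringsAsFactors = FALSE))
    b1 <- if (is.na(i1)) NA_real_ else fu_cur$beta[i1]
    p1 <- if (is.na(i1)) NA_real_ else fu_cur$pvalue[i1]
    b2 <- if (is.na(i2)) NA_real_ else fu_sev$beta[i2]
    p2 <- if (is.na(i2)) NA_real_ else fu_sev$pvalue[i2]
    ok1 <- isTRUE(p1 < alpha && sign(b1) == sign(b0))
    ok2 <- isTRUE(p2 < alpha && sign(b2) == sign(b0))
    reason <- if (ok1 && ok2) "status and severity replicate"
      else if (ok1) "status replicates"
      else if (ok2) "severity replicates"
      else "no consistent nominal association at follow-up"
    data.frame(metabolite_id = id, beta_baseline = b0,
               beta_fu_status = b1, p_fu_status = p1,
               beta_fu_severity = b2, p_fu_severity = p2,
               replicated = ok1 || ok2, reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
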