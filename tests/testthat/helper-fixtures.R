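## Fixture builders and independent oracles shared across test files.

make_meta <- function(ids, batch = "B01", plate = "B01_P1", run_day = "B01_D1",
                      wave = "baseline", is_reference = FALSE,
                      subject_id = NULL) {
  df <- data.frame(sample_id = ids, batch = batch, plate = plate,
                   run_day = run_day, wave = wave,
                   is_reference = is_reference, stringsAsFactors = FALSE)
  if (!is.null(subject_id)) df$subject_id <- subject_id
  df
}

make_abundance <- function(values, ..., scale = "raw") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%02d", seq_len(ncol(values)))
  abundance_matrix(values, make_meta(rownames(values), ...), scale = scale)
}

make_sumstats <- function(n = 5, variant_id = sprintf("rs%d", seq_len(n)),
                          chr = 1, pos = seq_len(n) * 2e7,
                          effect_allele = "A", other_allele = "G",
                          eaf = 0.3, beta = 0.1, se = 0.01,
                          pvalue = 1e-10, n_samples = 10000) {
  data.frame(variant_id = variant_id, chr = chr, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue,
             n = n_samples, stringsAsFactors = FALSE)
}

make_harmonized <- function(bx, by, sx = 0.01, sy = 0.005,
                            ids = sprintf("rs%d", seq_along(bx))) {
  h <- data.frame(variant_id = ids, bx = bx, sx = sx, by = by, sy = sy,
                  eaf = 0.3, f_statistic = (bx / sx)^2,
                  stringsAsFactors = FALSE)
  class(h) <- c("harmonized_set", "data.frame")
  h
}

## minimum-likelihood two-sided Fisher p by full enumeration of the
## hypergeometric support of the 2x2 table [[a, b], [c, d]]
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + c          # first-column margin
  n <- b + d
  k <- a + b          # first-row margin
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

## brute-force BH: evaluate every p-value as a candidate threshold
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i)
    min(1, min(m * p[p >= p[i]] / r[p >= p[i]])), 0)
}

## origin-constrained weighted least squares via lm (independent route)
oracle_ivw_wls <- function(bx, by, sy) {
  unname(coef(lm(by ~ 0 + bx, weights = 1 / sy^2)))
}

oracle_egger_wls <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  unname(coef(lm(I(by * flip) ~ I(bx * flip), weights = 1 / sy^2)))
}

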