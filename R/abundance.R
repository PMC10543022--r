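#' Construct an abundance matrix
#'
#' The central container of the pipeline: a samples x metabolites matrix of
#' abundances together with per-sample technical metadata. Missing cells are
#' stored as `NA` in `values`; `is.na(values)` is the missingness mask.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns.
#'   Row names are sample ids, column names metabolite ids. `NA` marks a
#'   missing measurement. Raw-scale values must be non-negative where
#'   observed.
#' @param sample_meta Data frame with one row per sample, columns
#'   `sample_id`, `batch`, `plate`, `run_day`, `wave`, `is_reference`.
#'   `wave` must be one of `"baseline"`, `"followup6"`, `"followup9"`.
#' @param scale One of `"raw"`, `"normalized"`, `"log2"`. Raw and normalized
#'   matrices live on the positive abundance scale; `"log2"` marks the
#'   transformed matrix used for modelling.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, sample_meta,
                             scale = c("raw", "normalized", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("`values` must have sample ids as rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("`values` must have metabolite ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated metabolite ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  required <- c("sample_id", "batch", "plate", "run_day", "wave", "is_reference")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample_meta lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(rownames(values) %in% sample_meta$sample_id))
    stop("sample_meta row missing for sample(s): ",
         paste(setdiff(rownames(values), sample_meta$sample_id), collapse = ", "))
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  bad_wave <- setdiff(unique(as.character(sample_meta$wave)),
                      c("baseline", "followup6", "followup9"))
  if (length(bad_wave))
    stop("unknown wave label(s): ", paste(bad_wave, collapse = ", "))
  for (col in c("batch", "plate", "run_day", "wave")) {
    if (anyNA(sample_meta[[col]]))
      stop("sample_meta column '", col, "' has missing entries")
  }
  if (scale != "log2") {
    neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative %s-scale abundance at sample '%s', metabolite '%s'",
                   scale, rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  structure(list(values = values,
                 sample_meta = sample_meta,
                 scale = scale),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d metabolites [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  reference samples: %d; waves: %s\n",
              sum(x$sample_meta$is_reference),
              paste(unique(x$sample_meta$wave), collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.2f%%)\n",
              sum(is.na(x$values)), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

sample_ids <- function(m) rownames(m$values)
metabolite_ids <- function(m) colnames(m$values)

#' Missingness mask of an abundance matrix
#'
#' @param m An `abundance_matrix`.
#' @return Logical matrix, `TRUE` where a cell is missing.
#' @export
missing_mask <- function(m) is.na(m$values)

#' Subset an abundance matrix by samples and/or metabolites
#'
#' @param m An `abundance_matrix`.
#' @param samples,metabolites Character vectors of ids, or logical/integer
#'   indices; `NULL` keeps everything.
#' @return The subsetted `abundance_matrix`.
#' @export
subset_abundance <- function(m, samples = NULL, metabolites = NULL) {
  v <- m$values
  meta <- m$sample_meta
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
    meta <- meta[match(rownames(v), meta$sample_id), , drop = FALSE]
  }
  if (!is.null(metabolites)) v <- v[, metabolites, drop = FALSE]
  abundance_matrix(v, meta, scale = m$scale)
}
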