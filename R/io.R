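## Readers/writers for the pipeline's tab-delimited formats.
## Dialect: TSV, UTF-8, "NA" as the missing token on write; "" and "NA"
## accepted as missing on read.

read_tsv_base <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), check.names = FALSE, ...)
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Read an abundance matrix and its sample metadata
#'
#' @param path TSV with sample ids in the first column (`sample_id`) and one
#'   column per metabolite. Empty cells or `NA` are missing values.
#' @param meta_path TSV keyed by `sample_id` with columns `batch`, `plate`,
#'   `run_day`, `wave`, `is_reference`.
#' @param scale Scale tag of the stored values (default `"raw"`).
#' @return An [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, meta_path, scale = "raw") {
  raw <- read_tsv_base(path)
  if (names(raw)[1] != "sample_id")
    stop("first column of an abundance file must be 'sample_id'")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicated sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  met_ids <- names(raw)[-1]
  if (anyDuplicated(met_ids))
    stop("duplicated metabolite column(s) in ", path, ": ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  values <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  meta <- read_tsv_base(meta_path)
  meta$sample_id <- as.character(meta$sample_id)
  meta$is_reference <- as.logical(meta$is_reference)
  abundance_matrix(values, meta, scale = scale)
}

#' Write an abundance matrix and its sample metadata
#'
#' @param m An [abundance_matrix()].
#' @param path,meta_path Output TSV paths for values and sample metadata.
#' @return Invisibly, `m`.
#' @export
write_abundance_matrix <- function(m, path, meta_path) {
  df <- data.frame(sample_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_base(df, path)
  write_tsv_base(m$sample_meta, meta_path)
  invisible(m)
}

PHENO_COLS <- c("subject_id", "family_id", "wave", "mdd_status", "ids_total",
                "sex", "age", "education", "physical_activity", "smoking",
                "alcohol", "n_chronic_diseases", "bmi", "shipment",
                "ad_ssri", "ad_tca", "ad_snri")

validate_phenotypes <- function(phen) {
  missing_cols <- setdiff(PHENO_COLS, names(phen))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(as.character(phen$mdd_status)),
                 c("control", "remitted", "current"))
  if (length(bad))
    stop("mdd_status outside {control, remitted, current}: ",
         paste(bad, collapse = ", "))
  key <- paste(phen$subject_id, phen$wave)
  if (anyDuplicated(key))
    stop("more than one phenotype record per subject per wave")
  if (any(is.na(phen$family_id[phen$wave == "baseline"])))
    stop("family_id missing for baseline-wave record(s)")
  phen
}

#' Read a phenotype/covariate table
#'
#' One row per subject per wave with 3-level MDD status, IDS severity score,
#' covariates, family id and antidepressant-class flags.
#'
#' @param path TSV path.
#' @return A validated data frame.
#' @export
read_phenotypes <- function(path) {
  phen <- read_tsv_base(path)
  phen$subject_id <- as.character(phen$subject_id)
  for (col in c("ad_ssri", "ad_tca", "ad_snri"))
    if (col %in% names(phen)) phen[[col]] <- as.logical(phen[[col]])
  validate_phenotypes(phen)
}

#' Write a phenotype/covariate table
#' @param phen Phenotype data frame.
#' @param path TSV path.
#' @return Invisibly, `phen`.
#' @export
write_phenotypes <- function(phen, path) {
  write_tsv_base(validate_phenotypes(phen), path)
  invisible(phen)
}

#' Read a metabolite pathway annotation table
#'
#' @param path TSV with columns `metabolite_id`, `super_pathway`,
#'   `sub_pathway`. Unclassified metabolites carry `NA` in both pathway
#'   columns; a metabolite with a sub pathway must also have a super pathway.
#' @return Data frame.
#' @export
read_pathway_annotation <- function(path) {
  ann <- read_tsv_base(path)
  missing_cols <- setdiff(c("metabolite_id", "super_pathway", "sub_pathway"), names(ann))
  if (length(missing_cols))
    stop("annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  orphans <- !is.na(ann$sub_pathway) & is.na(ann$super_pathway)
  if (any(orphans))
    stop("metabolite(s) with a sub_pathway but no super_pathway: ",
         paste(ann$metabolite_id[orphans], collapse = ", "))
  ann
}

#' Write a pathway annotation table
#' @param ann Annotation data frame.
#' @param path TSV path.
#' @return Invisibly, `ann`.
#' @export
write_pathway_annotation <- function(ann, path) {
  write_tsv_base(ann, path)
  invisible(ann)
}

SUMSTATS_COLS <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

#' Read GWAS summary statistics
#'
#' Tab-delimited per-variant records with case-insensitive header matching.
#' Rows with `se <= 0` are dropped with a warning.
#'
#' @param path TSV with columns `variant_id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` (any case).
#' @return Data frame of typed records with canonical lower-case names.
#' @export
read_sumstats <- function(path) {
  ss <- read_tsv_base(path)
  names(ss) <- tolower(names(ss))
  missing_cols <- setdiff(SUMSTATS_COLS, names(ss))
  if (length(missing_cols))
    stop("sumstats file lacks column(s): ", paste(missing_cols, collapse = ", "))
  ss <- ss[, SUMSTATS_COLS]
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    ss[[col]] <- as.numeric(ss[[col]])
  for (col in c("effect_allele", "other_allele"))
    ss[[col]] <- toupper(as.character(ss[[col]]))
  bad_se <- !is.na(ss$se) & ss$se <= 0
  if (any(bad_se)) {
    warning(sum(bad_se), " sumstats row(s) with se <= 0 dropped")
    ss <- ss[!bad_se, , drop = FALSE]
  }
  rownames(ss) <- NULL
  ss
}

#' Write GWAS summary statistics
#' @param ss Sumstats data frame.
#' @param path TSV path.
#' @return Invisibly, `ss`.
#' @export
write_sumstats <- function(ss, path) {
  write_tsv_base(ss, path)
  invisible(ss)
}

#' Read/write an association results table
#'
#' Columns: `metabolite_id`, `contrast`, `model`, `beta`, `se`, `pvalue`,
#' `qvalue`, `n_used`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_association_table <- function(path) read_tsv_base(path)

#' @rdname read_association_table
#' @param tab Association table.
#' @export
write_association_table <- function(tab, path) {
  write_tsv_base(tab, path)
  invisible(tab)
}
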