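#' Pathway over-representation by Fisher's exact test
#'
#' Tests each super and sub pathway for over-representation of a hit set
#' against the universe of pathway-classified metabolites. The hit set is
#' intersected with the classified universe before testing; super and sub
#' pathways are tested (and BH-corrected) as separate families. Two-sided
#' p-values follow the minimum-likelihood convention (sum over tables with
#' probability at most that of the observed table).
#'
#' @param hits Character vector of hit metabolite ids. When `betas` is
#'   supplied, `direction` can restrict the hit set by effect sign.
#' @param ann Pathway annotation table (`metabolite_id`, `super_pathway`,
#'   `sub_pathway`).
#' @param direction `"all"`, `"up"` (positive beta) or `"down"`.
#' @param betas Optional named vector of betas used to split by direction.
#' @return Data frame: `pathway`, `level`, the 2x2 counts `a` (hit, in
#'   pathway), `b` (hit, not in pathway), `c` (non-hit, in pathway), `d`
#'   (non-hit, not in pathway), `odds_ratio`, `pvalue`, `qvalue`.
#' @export
fisher_enrichment <- function(hits, ann, direction = c("all", "up", "down"),
                              betas = NULL) {
  direction <- match.arg(direction)
  if (direction != "all") {
    if (is.null(betas)) stop("`betas` needed to split hits by direction")
    keep <- if (direction == "up") betas[hits] > 0 else betas[hits] < 0
    hits <- hits[which(keep)]
  }
  universe <- ann$metabolite_id[!is.na(ann$super_pathway)]
  hits <- intersect(hits, universe)
  if (!length(hits)) {
    warning("no classified hit metabolites; empty enrichment table")
    return(data.frame(pathway = character(0), level = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      pvalue = numeric(0), qvalue = numeric(0)))
  }
  test_level <- function(level_col, level_name) {
    labels <- ann[[level_col]][match(universe, ann$metabolite_id)]
    paths <- sort(unique(labels[!is.na(labels)]))
    rows <- lapply(paths, function(pw) {
      in_pw <- universe[!is.na(labels) & labels == pw]
      a <- length(intersect(hits, in_pw))
      b <- length(hits) - a
      c_ <- length(in_pw) - a
      d <- length(universe) - a - b - c_
      ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      data.frame(pathway = pw, level = level_name, a = a, b = b, c = c_,
                 d = d, odds_ratio = unname(ft$estimate), pvalue = ft$p.value,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$qvalue <- bh_fdr(tab$pvalue)
    tab
  }
  out <- rbind(test_level("super_pathway", "super"),
               test_level("sub_pathway", "sub"))
  rownames(out) <- NULL
  out[order(out$level, out$pvalue), ]
}
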