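# Spatial stage: anchor-gene correlated modules, per-spot module scores,
# and spot-wise correlations against immune enrichment and marker
# expression. Scores are coordinate-free; coordinates matter only to
# region-based comparisons.

#' Top positively correlated genes of an anchor gene
#'
#' Pearson correlation of every other gene with the anchor across spots;
#' returns the `k` genes with the largest strictly positive correlations
#' (fewer, with a warning, if fewer genes correlate positively). The
#' anchor itself is excluded so the module does not restate it.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "lognorm"`.
#' @param anchor_gene Gene id of the anchor (e.g. "SLC2A1").
#' @param k Number of genes to return (default 50).
#' @return Character vector of gene ids ordered by decreasing correlation,
#'   with the correlations as a `"correlation"` attribute.
#' @export
topk_correlated_genes <- function(matrix, anchor_gene, k = 50) {
  check_layer(matrix, c("lognorm", "cpm"))
  if (length(matrix$obs_ids) < 3) stop("need at least 3 spots")
  anchor <- gene_row(matrix, anchor_gene)
  if (stats::sd(anchor) == 0) {
    stop(sprintf("anchor gene '%s' is constant across spots", anchor_gene))
  }
  others <- setdiff(matrix$gene_ids, anchor_gene)
  r <- suppressWarnings(
    as.vector(stats::cor(anchor, t(matrix$values[others, , drop = FALSE]))))
  names(r) <- others
  r <- r[!is.na(r) & r > 0]
  r <- sort(r, decreasing = TRUE)
  if (length(r) < k) {
    warning(sprintf("only %d genes positively correlated with '%s' (k = %d)",
                    length(r), anchor_gene, k))
  }
  out <- utils::head(names(r), k)
  attr(out, "correlation") <- unname(utils::head(r, k))
  out
}

#' Per-spot module scores for anchor genes
#'
#' For each anchor, a binned-control module score over its top-`k`
#' positively correlated genes; the composite immune score and the raw
#' log-normalized EPCAM expression are appended as additional columns.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "counts"` over spots.
#' @param anchors Anchor genes (default `c("SLC2A1", "SLC2A3")`).
#' @param signatures Signature collection for the immune score (default
#'   [builtin_signature_collection()]).
#' @param k Genes per anchor module (default 50).
#' @param nbin,nctrl,seed Passed to [module_score()].
#' @param epithelial_gene Raw-expression column to append (default EPCAM;
#'   skipped if absent).
#' @return Data frame: `obs_id`, one `<anchor>_module` column per anchor,
#'   `ImmuneScore`, and the epithelial gene, plus a `"module_genes"`
#'   attribute with each anchor's gene list.
#' @export
spatial_module_scores <- function(matrix, anchors = c("SLC2A1", "SLC2A3"),
                                  signatures = builtin_signature_collection(),
                                  k = 50, nbin = 24, nctrl = 100, seed = 1L,
                                  epithelial_gene = "EPCAM") {
  check_layer(matrix, "counts")
  ln <- log_normalize_cells(matrix)
  missing <- setdiff(anchors, ln$gene_ids)
  if (length(missing) > 0) {
    stop("anchor gene(s) missing: ", paste(missing, collapse = ", "))
  }
  module_genes <- lapply(anchors, function(a) topk_correlated_genes(ln, a, k))
  names(module_genes) <- anchors
  out <- data.frame(obs_id = ln$obs_ids, row.names = NULL)
  for (a in anchors) {
    out[[paste0(a, "_module")]] <-
      unname(module_score(ln, module_genes[[a]], nbin = nbin, nctrl = nctrl,
                          seed = seed))
  }
  enr <- immune_composite_score(
    cell_type_enrichment(cpm_normalize(matrix), signatures))
  out$ImmuneScore <- enr$ImmuneScore[match(out$obs_id, enr$obs_id)]
  if (epithelial_gene %in% ln$gene_ids) {
    out[[epithelial_gene]] <- unname(gene_row(ln, epithelial_gene))
  }
  attr(out, "module_genes") <- module_genes
  out
}

#' Spot-wise correlation of two score columns
#'
#' @param table A score table (e.g. from [spatial_module_scores()]).
#' @param x,y Names of the two score columns.
#' @return List with `r`, `p` (two-sided) and `n`.
#' @export
spot_correlation <- function(table, x, y) {
  for (nm in c(x, y)) {
    if (!nm %in% names(table)) stop("score not present: ", nm)
  }
  res <- pearson_corr_test(table[[x]], table[[y]])
  list(r = res$statistic, p = res$p_value, n = res$n)
}
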