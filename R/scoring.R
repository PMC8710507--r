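#' Counts-per-million normalization
#'
#' Scales every observation (column) so its entries sum to one million.
#'
#' @param matrix An [expression_matrix()] with `layer = "counts"`.
#' @return An `ExpressionMatrix` with `layer = "cpm"`.
#' @export
cpm_normalize <- function(matrix) {
  check_layer(matrix, "counts")
  totals <- colSums(matrix$values)
  if (any(totals == 0)) {
    stop("observation(s) with zero total count: ",
         paste(utils::head(matrix$obs_ids[totals == 0], 5), collapse = ", "))
  }
  vals <- sweep(matrix$values, 2, totals, "/") * 1e6
  expression_matrix(vals, matrix$gene_ids, matrix$obs_ids, layer = "cpm")
}

#' Per-cell log-normalization
#'
#' Divides each cell's counts by its total, multiplies by `scale_factor`
#' and applies `log1p`: entry = ln(1 + scale_factor * count / total).
#'
#' @param matrix An [expression_matrix()] with `layer = "counts"`.
#' @param scale_factor Library-size target (default 1e4).
#' @return An `ExpressionMatrix` with `layer = "lognorm"`.
#' @export
log_normalize_cells <- function(matrix, scale_factor = 1e4) {
  check_layer(matrix, "counts")
  totals <- colSums(matrix$values)
  if (any(totals == 0)) {
    stop("cell(s) with zero total count: ",
         paste(utils::head(matrix$obs_ids[totals == 0], 5), collapse = ", "))
  }
  vals <- log1p(sweep(matrix$values, 2, totals, "/") * scale_factor)
  expression_matrix(vals, matrix$gene_ids, matrix$obs_ids, layer = "lognorm")
}

#' Single-sample gene-set enrichment score
#'
#' Rank-based running-sum enrichment of one gene set in one expression
#' profile. Genes are ranked by decreasing expression (ties receive average
#' ranks); walking down the ranked list, the in-set empirical CDF weighted
#' by rank^alpha is accumulated against the uniform out-of-set CDF, and the
#' score is the sum of their differences over all positions (the
#' single-sample running-sum integral). No cross-sample rescaling is
#' applied.
#'
#' @param expr Named numeric vector of expression values over genes, or an
#'   unnamed vector with `genes` supplied.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank-weight exponent (default 0.25).
#' @param genes Optional gene ids when `expr` is unnamed.
#' @return A single numeric score.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25, genes = names(expr)) {
  expr <- as.numeric(expr)
  if (is.null(genes) || length(genes) != length(expr)) {
    stop("gene ids must accompany the expression vector")
  }
  in_set <- genes %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0) stop("gene set does not intersect the gene universe")
  if (n_in == length(expr)) {
    stop("gene set covers the whole universe; out-of-set CDF undefined")
  }
  ord <- order(expr, decreasing = TRUE)
  w <- rank(expr)^alpha          # average ranks for ties, high expr = high rank
  w_sorted <- w[ord]
  in_sorted <- in_set[ord]
  p_in <- cumsum(w_sorted * in_sorted) / sum(w_sorted[in_sorted])
  p_out <- cumsum(!in_sorted) / (length(expr) - n_in)
  sum(p_in - p_out)
}

# ssGSEA over every observation and every set of a collection; shares the
# per-observation ranking across sets.
ssgsea_table <- function(matrix, collection, alpha = 0.25) {
  genes <- matrix$gene_ids
  out <- sapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    if (length(intersect(set, genes)) == 0) {
      stop(sprintf("signature '%s' does not intersect the gene universe", nm))
    }
    apply(matrix$values, 2, ssgsea_score, gene_set = set, alpha = alpha,
          genes = genes)
  })
  data.frame(obs_id = matrix$obs_ids, out, check.names = FALSE,
             row.names = NULL)
}

#' Binned-control module score
#'
#' The expression-program score of Tirosh and colleagues: genes are binned
#' by their average expression across observations; for each set gene,
#' control genes are drawn from its bin; the score of an observation is the
#' mean expression of the set genes minus the mean expression of the pooled
#' control genes. Centering against abundance-matched controls removes the
#' library-depth and overall-abundance component that a raw mean would keep.
#'
#' When the universe has fewer than `3 * nbin` genes the bin count falls
#' back to `max(2, floor(n_genes / 3))` so every bin keeps a few genes.
#'
#' @param matrix An `ExpressionMatrix` (`lognorm` or `cpm`).
#' @param gene_set Character vector of gene ids.
#' @param nbin Number of average-expression bins (default 24).
#' @param nctrl Control genes sampled per set gene (default 100); sampling
#'   is without replacement within a bin, capped at the bin size.
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector, one score per observation.
#' @export
module_score <- function(matrix, gene_set, nbin = 24, nctrl = 100, seed = 1L) {
  check_layer(matrix, c("lognorm", "cpm"))
  genes <- matrix$gene_ids
  set_genes <- intersect(gene_set, genes)
  if (length(set_genes) == 0) {
    stop("gene set does not intersect the gene universe")
  }
  n_genes <- length(genes)
  if (n_genes < 3 * nbin) nbin <- max(2, floor(n_genes / 3))
  avg <- rowMeans(matrix$values)
  # rank-based ntile binning: equal-occupancy bins even with skewed means
  bin <- ceiling(rank(avg, ties.method = "first") / n_genes * nbin)
  ctrl <- withr::with_seed(as.integer(seed), {
    unique(unlist(lapply(set_genes, function(g) {
      pool <- genes[bin == bin[match(g, genes)]]
      sample(pool, size = min(nctrl, length(pool)), replace = FALSE)
    })))
  })
  set_mean <- colMeans(matrix$values[set_genes, , drop = FALSE])
  ctrl_mean <- colMeans(matrix$values[ctrl, , drop = FALSE])
  stats::setNames(set_mean - ctrl_mean, matrix$obs_ids)
}

#' Per-signature single-sample enrichment table
#'
#' One ssGSEA score per observation per signature; the building block of
#' the composite immune score.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "cpm"`.
#' @param signatures A `GeneSetCollection` (e.g.
#'   [builtin_signature_collection()]).
#' @param alpha Rank-weight exponent passed to [ssgsea_score()].
#' @return Data frame: `obs_id` plus one numeric column per signature.
#' @export
cell_type_enrichment <- function(matrix, signatures, alpha = 0.25) {
  check_layer(matrix, "cpm")
  ssgsea_table(matrix, signatures, alpha = alpha)
}

# The ten immune cell types whose enrichment scores are summed into the
# composite ImmuneScore.
immune_score_components <- function() {
  c("B_cells", "CD4_T_cells", "CD8_T_cells", "Dendritic_cells",
    "Eosinophils", "Macrophages", "Monocytes", "Mast_cells",
    "Neutrophils", "NK_cells")
}

#' Composite immune enrichment score
#'
#' Sums the enrichment scores of the ten immune cell types (B cells, CD4 T,
#' CD8 T, dendritic cells, eosinophils, macrophages, monocytes, mast cells,
#' neutrophils, NK cells) into a per-observation `ImmuneScore` column.
#'
#' @param table Score table from [cell_type_enrichment()] containing all
#'   ten component columns.
#' @return `table` with an `ImmuneScore` column appended.
#' @export
immune_composite_score <- function(table) {
  comp <- immune_score_components()
  missing <- setdiff(comp, names(table))
  if (length(missing) > 0) {
    stop("missing immune component score(s): ", paste(missing, collapse = ", "))
  }
  table$ImmuneScore <- rowSums(as.matrix(table[, comp, drop = FALSE]))
  table
}

#' Hypoxia enrichment score
#'
#' ssGSEA of a hypoxia signature, per observation.
#'
#' @param matrix An `ExpressionMatrix` (`cpm`).
#' @param hypoxia_set Character vector of hypoxia genes.
#' @param alpha Rank-weight exponent.
#' @return Named numeric vector of scores.
#' @export
hypoxia_score <- function(matrix, hypoxia_set, alpha = 0.25) {
  check_layer(matrix, "cpm")
  stats::setNames(
    apply(matrix$values, 2, ssgsea_score, gene_set = hypoxia_set,
          alpha = alpha, genes = matrix$gene_ids),
    matrix$obs_ids)
}

#' Cytolytic activity score
#'
#' Effector T-cell activity proxy: geometric mean of the
#' pseudocount-shifted CPM of a granzyme and a perforin transcript. The
#' default pair is (GZMB, PRF1); (GZMA, PRF1) is the historical alternative
#' and may be supplied instead.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "cpm"`.
#' @param gene_a,gene_b The two effector transcripts.
#' @param pseudocount Added to each CPM before the geometric mean.
#' @return Named numeric vector of scores.
#' @export
cytolytic_score <- function(matrix, gene_a = "GZMB", gene_b = "PRF1",
                            pseudocount = 1) {
  check_layer(matrix, "cpm")
  a <- gene_row(matrix, gene_a)
  b <- gene_row(matrix, gene_b)
  stats::setNames(sqrt((a + pseudocount) * (b + pseudocount)), matrix$obs_ids)
}

#' GLUT3-to-GLUT1 expression ratio
#'
#' The GLUTratio: per-observation (CPM(SLC2A3) + pseudocount) /
#' (CPM(SLC2A1) + pseudocount). GLUT3 is enriched in immune cells and GLUT1
#' in cancer cells, so the ratio rises with the immune share of a sample.
#' Correlation analyses downstream use `log2` of this ratio, which makes
#' reciprocal effects symmetric around zero.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "cpm"`.
#' @param pseudocount Added to both CPM values (default 1).
#' @param gene_glut3,gene_glut1 Gene ids of the two transporters.
#' @return Named numeric vector of ratios.
#' @export
glut_ratio <- function(matrix, pseudocount = 1,
                       gene_glut3 = "SLC2A3", gene_glut1 = "SLC2A1") {
  check_layer(matrix, "cpm")
  num <- gene_row(matrix, gene_glut3)
  den <- gene_row(matrix, gene_glut1)
  stats::setNames((num + pseudocount) / (den + pseudocount), matrix$obs_ids)
}
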