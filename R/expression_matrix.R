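#' Gene-by-observation expression matrix
#'
#' The container passed between every stage of the pipeline: a dense numeric
#' matrix with genes as rows and observations (bulk samples, cells, or spatial
#' spots) as columns, plus a `layer` tag recording what the values are.
#'
#' @param values Numeric matrix, genes as rows, observations as columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param obs_ids Character vector of unique observation identifiers (columns).
#' @param layer One of `"counts"`, `"cpm"`, `"lognorm"`, `"scaled"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `obs_ids`, `layer`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:3, 2, 2), c("A", "B"), c("s1", "s2"))
expression_matrix <- function(values, gene_ids, obs_ids,
                              layer = c("counts", "cpm", "lognorm", "scaled")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  if (nrow(values) != length(gene_ids)) {
    stop(sprintf("matrix has %d rows but %d gene ids", nrow(values),
                 length(gene_ids)))
  }
  if (ncol(values) != length(obs_ids)) {
    stop(sprintf("matrix has %d columns but %d observation ids", ncol(values),
                 length(obs_ids)))
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(obs_ids)) stop("duplicate observation ids")
  if (layer == "counts" && any(values < 0)) {
    stop("layer 'counts' requires all entries >= 0")
  }
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
                 layer = layer),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d observations\n",
              x$layer, length(x$gene_ids), length(x$obs_ids)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# internal: stop unless the matrix carries one of the accepted layers
check_layer <- function(matrix, accepted) {
  if (!inherits(matrix, "ExpressionMatrix")) {
    stop("expected an ExpressionMatrix")
  }
  if (!matrix$layer %in% accepted) {
    stop(sprintf("expected layer %s, got '%s'",
                 paste(sQuote(accepted), collapse = " or "), matrix$layer))
  }
  invisible(matrix)
}

# internal: fetch one gene's row as a plain vector, with a named error
gene_row <- function(matrix, gene) {
  if (!gene %in% matrix$gene_ids) {
    stop(sprintf("gene '%s' not present in the matrix", gene))
  }
  matrix$values[gene, ]
}
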