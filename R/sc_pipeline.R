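# Single-cell stage: HVG selection -> scaling -> PCA -> SNN graph ->
# Louvain clustering -> marker detection -> annotation -> CNA scoring ->
# coarse cancer/immune classification.

#' Highly variable genes by variance-stabilizing transformation
#'
#' Fits a loess curve of log10 variance against log10 mean across genes,
#' standardizes every gene by its predicted standard deviation with values
#' clipped at `sqrt(n_obs)`, and ranks genes by the variance of the clipped
#' standardized values.
#'
#' @param matrix An `ExpressionMatrix` (counts or lognorm).
#' @param n_hvg Number of genes to return (default 2000; all genes if the
#'   matrix has fewer).
#' @param loess_span Span of the mean-variance trend fit (default 0.3).
#' @return Character vector of gene ids, most variable first.
#' @export
select_hvg_vst <- function(matrix, n_hvg = 2000, loess_span = 0.3) {
  check_layer(matrix, c("counts", "lognorm"))
  if (length(matrix$obs_ids) < 2) stop("need at least 2 observations")
  x <- matrix$values
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  std_var <- rep(0, nrow(x))
  usable <- v > 0 & mu > 0
  if (any(usable)) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = loess_span, degree = 2)
    sd_pred <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(ncol(x))
    z <- sweep(x[usable, , drop = FALSE], 1, mu[usable], "-")
    z <- sweep(z, 1, sd_pred, "/")
    z <- pmin(z, clip)
    std_var[usable] <- rowSums((z - rowMeans(z))^2) / (ncol(x) - 1)
  }
  ord <- order(std_var, decreasing = TRUE)
  matrix$gene_ids[utils::head(ord, min(n_hvg, nrow(x)))]
}

#' Per-gene z-scaling
#'
#' Centers and scales each gene of the chosen subset to mean 0 and unit
#' variance; zero-variance genes map to all zeros; values are clipped at
#' +/- 10.
#'
#' @param matrix An `ExpressionMatrix` (typically lognorm).
#' @param genes Genes to keep (default: all).
#' @param clip Absolute clip value (default 10).
#' @return An `ExpressionMatrix` with `layer = "scaled"` over `genes`.
#' @export
scale_zscore <- function(matrix, genes = matrix$gene_ids, clip = 10) {
  missing <- setdiff(genes, matrix$gene_ids)
  if (length(missing) > 0) {
    stop("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- matrix$values[genes, , drop = FALSE]
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- sweep(x, 1, mu, "-")
  z <- sweep(z, 1, ifelse(sd == 0, 1, sd), "/")
  z[sd == 0, ] <- 0
  z <- pmin(pmax(z, -clip), clip)
  expression_matrix(z, genes, matrix$obs_ids, layer = "scaled")
}

#' Principal component reduction
#'
#' PCA of observations in the scaled gene space. The sign of each
#' component is fixed by making its largest-magnitude gene loading
#' positive, so results are deterministic.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "scaled"`.
#' @param n_pcs Number of components (default 10).
#' @return List with `obs_ids`, `coordinates` (obs x n_pcs matrix),
#'   `loadings` and `explained_variance` (non-increasing).
#' @export
pca_reduce <- function(matrix, n_pcs = 10) {
  check_layer(matrix, "scaled")
  n_obs <- length(matrix$obs_ids)
  if (n_pcs > min(nrow(matrix$values), n_obs)) {
    stop(sprintf("n_pcs = %d exceeds min(n_genes, n_obs) = %d", n_pcs,
                 min(nrow(matrix$values), n_obs)))
  }
  pc <- stats::prcomp(t(matrix$values), center = FALSE, scale. = FALSE,
                      rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  rownames(scores) <- matrix$obs_ids
  list(obs_ids = matrix$obs_ids, coordinates = scores, loadings = loadings,
       explained_variance = pc$sdev[seq_len(n_pcs)]^2)
}

#' Shared-nearest-neighbor graph
#'
#' k-nearest-neighbor graph in PC space (Euclidean, each cell's neighbor
#' set includes itself), re-weighted by the Jaccard overlap of neighbor
#' sets; edges with weight below `prune` are removed.
#'
#' @param embedding Result of [pca_reduce()], or a cells-by-dims matrix.
#' @param k Neighborhood size (default 20), must be < n_cells.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return An undirected weighted [igraph::graph] over cells.
#' @export
build_snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  coords <- if (is.list(embedding)) embedding$coordinates else embedding
  n <- nrow(coords)
  if (k >= n) stop(sprintf("k = %d must be smaller than n_cells = %d", k, n))
  d <- as.matrix(stats::dist(coords))
  # neighbor sets of size k, self included (self has distance 0)
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.vector(nn), x = 1, dims = c(n, n))
  inter <- as.matrix(Matrix::tcrossprod(adj))
  jac <- inter / (2 * k - inter)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::set_vertex_attr(g, "name", value = rownames(coords))
}

#' Louvain clustering of the SNN graph
#'
#' Modularity optimization at the given resolution; cluster ids are
#' relabeled by decreasing size (0 = largest) and the run is deterministic
#' given the seed.
#'
#' @param graph Weighted undirected graph from [build_snn_graph()].
#' @param resolution Louvain resolution (default 1).
#' @param seed Integer seed.
#' @return Integer vector of cluster labels (0-based), named by cell.
#' @export
louvain_cluster <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  cl <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(graph, resolution = resolution))
  labels <- igraph::membership(cl)
  sizes <- sort(table(labels), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  stats::setNames(unname(relabel[as.character(labels)]),
                  igraph::V(graph)$name)
}

# align a label vector to the matrix observations, tolerating unnamed
# vectors already in matrix order
align_labels <- function(labels, obs_ids) {
  if (is.null(names(labels))) {
    if (length(labels) != length(obs_ids)) {
      stop("labels must be named by cell or aligned to the matrix")
    }
    names(labels) <- obs_ids
  }
  labels[obs_ids]
}

# log fold change between two cell groups on log-normalized data:
# natural-log ratio of (mean expm1 + 1), the convention of the standard
# single-cell toolchain.
lognorm_logfc <- function(x1, x2) {
  log((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))
}

# Mann-Whitney + logFC for every gene, one group vs another; returns an
# unfiltered table sorted by decreasing log_fc.
markers_between <- function(matrix, cells_a, cells_b) {
  res <- lapply(matrix$gene_ids, function(g) {
    xa <- matrix$values[g, cells_a]
    xb <- matrix$values[g, cells_b]
    mw <- mann_whitney_u(xa, xb, alternative = "two.sided")
    lfc <- lognorm_logfc(xa, xb)
    data.frame(gene_id = g, log_fc = lfc, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$fdr <- bh_fdr(tab$p_value)
  tab$direction <- ifelse(tab$log_fc >= 0, "up", "down")
  tab[order(-tab$log_fc), ]
}

#' Per-cluster marker genes (one vs rest)
#'
#' For every cluster, tests each gene with a one-vs-rest Mann-Whitney U
#' test on log-normalized expression, with BH adjustment within the
#' cluster's gene family; rows are ranked by log fold change and the top
#' `top_n` per cluster retained. Clusters with fewer than 3 cells are
#' skipped with a warning.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "lognorm"`.
#' @param labels Cluster labels named by cell (from [louvain_cluster()]).
#' @param top_n Markers kept per cluster (default 5); `Inf` keeps all.
#' @return Data frame with `cluster`, `gene_id`, `log_fc`, `p_value`,
#'   `fdr`, `direction`.
#' @export
find_all_markers <- function(matrix, labels, top_n = 5) {
  check_layer(matrix, "lognorm")
  labels <- align_labels(labels, matrix$obs_ids)
  if (length(unique(labels)) < 2) stop("need >= 2 clusters")
  out <- lapply(sort(unique(labels)), function(cl) {
    cells_a <- matrix$obs_ids[labels == cl]
    if (length(cells_a) < 3) {
      warning(sprintf("cluster %s has fewer than 3 cells; skipped", cl))
      return(NULL)
    }
    tab <- markers_between(matrix, cells_a, matrix$obs_ids[labels != cl])
    tab <- utils::head(tab, top_n)
    cbind(cluster = cl, tab)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Differential expression between two clusters
#'
#' Mann-Whitney U per gene between the two clusters; genes passing BOTH
#' `|log_fc| > logfc_min` and BH-FDR `< fdr_max` are returned with their
#' direction (up = higher in `cluster_a`).
#'
#' @param matrix An `ExpressionMatrix` with `layer = "lognorm"`.
#' @param labels Cluster labels named by cell.
#' @param cluster_a,cluster_b The two cluster ids to contrast.
#' @param logfc_min Absolute log-fold-change gate (default 0.25).
#' @param fdr_max BH-FDR gate (default 0.05).
#' @return Data frame as in [find_all_markers()] (without `cluster`).
#' @export
find_markers_pairwise <- function(matrix, labels, cluster_a, cluster_b,
                                  logfc_min = 0.25, fdr_max = 0.05) {
  check_layer(matrix, "lognorm")
  labels <- align_labels(labels, matrix$obs_ids)
  for (cl in c(cluster_a, cluster_b)) {
    if (!cl %in% labels) stop("unknown cluster id: ", cl)
  }
  tab <- markers_between(matrix, matrix$obs_ids[labels == cluster_a],
                         matrix$obs_ids[labels == cluster_b])
  tab <- tab[abs(tab$log_fc) > logfc_min & tab$fdr < fdr_max, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Annotate clusters by marker-set expression
#'
#' Assigns each cluster the cell type whose marker-set mean (log-normalized)
#' is highest in that cluster AND exceeds the across-cluster mean of the
#' same marker set; clusters clearing neither gate stay `"unknown"`. Ties
#' are broken by the fixed type order of `marker_map`.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "lognorm"`.
#' @param labels Cluster labels named by cell.
#' @param marker_map Named list mapping cell types to marker genes; the
#'   default is the published roster: cancer = EPCAM, Tcell =
#'   CD3D/CD8A/CD4, Bcell = CD79A/IGHM, myeloid = CD68/LYZ.
#' @return List of class `ClusterAssignment` with `obs_ids`,
#'   `cluster_labels`, `cell_type` (per cluster) and `coarse_class`.
#' @export
annotate_clusters <- function(matrix, labels, marker_map = type_markers()) {
  check_layer(matrix, "lognorm")
  labels <- align_labels(labels, matrix$obs_ids)
  present <- lapply(marker_map, intersect, matrix$gene_ids)
  if (all(lengths(present) == 0)) {
    stop("none of the marker genes are present in the matrix")
  }
  clusters <- sort(unique(labels))
  # cluster x type matrix of marker-set means
  means <- do.call(cbind, lapply(names(marker_map), function(tp) {
    gs <- present[[tp]]
    if (length(gs) == 0) return(rep(NA_real_, length(clusters)))
    vapply(clusters, function(cl) {
      mean(matrix$values[gs, labels == cl, drop = FALSE])
    }, 0)
  }))
  colnames(means) <- names(marker_map)
  overall <- colMeans(means, na.rm = TRUE)
  cell_type <- vapply(seq_along(clusters), function(i) {
    row <- means[i, ]
    ok <- which(!is.na(row) & row > overall[names(row)])
    if (length(ok) == 0) return("unknown")
    names(row)[ok][which.max(row[ok])]
  }, "")
  names(cell_type) <- as.character(clusters)
  new_assignment(matrix$obs_ids, labels, cell_type)
}

# build a ClusterAssignment and derive the coarse class from the cell type
new_assignment <- function(obs_ids, cluster_labels, cell_type) {
  coarse <- ifelse(cell_type == "cancer", "cancer",
                   ifelse(cell_type %in% c("Tcell", "Bcell", "myeloid"),
                          "immune", "other"))
  names(coarse) <- names(cell_type)
  structure(list(obs_ids = obs_ids, cluster_labels = cluster_labels,
                 cell_type = cell_type, coarse_class = coarse),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells, %d clusters\n",
              length(x$obs_ids), length(x$cell_type)))
  print(data.frame(cluster = names(x$cell_type), cell_type = x$cell_type,
                   coarse = x$coarse_class, row.names = NULL))
  invisible(x)
}

#' Chromosome-level copy-number module score
#'
#' Module score over all genes annotated to one chromosome — a coarse
#' copy-number-alteration proxy: cells carrying a dosage gain of that
#' chromosome score high relative to abundance-matched controls.
#'
#' @param matrix An `ExpressionMatrix` with `layer = "lognorm"`.
#' @param annotation Data frame with `gene_id` and `chromosome` columns.
#' @param chromosome Chromosome label (default "7").
#' @param nbin,nctrl,seed Passed to [module_score()].
#' @return Named numeric vector, one score per cell.
#' @export
cna_module_score <- function(matrix, annotation, chromosome = "7",
                             nbin = 24, nctrl = 100, seed = 1L) {
  chr_genes <- annotation$gene_id[annotation$chromosome == chromosome]
  chr_genes <- intersect(chr_genes, matrix$gene_ids)
  if (length(chr_genes) < 5) {
    stop(sprintf("only %d genes annotated to chromosome '%s'; need >= 5",
                 length(chr_genes), chromosome))
  }
  module_score(matrix, chr_genes, nbin = nbin, nctrl = nctrl, seed = seed)
}

#' Coarse cancer/immune classification of clusters
#'
#' CNA mode (when `cna_scores` is supplied): cluster-median CNA scores are
#' split into two groups by one-dimensional two-means; the high group is
#' called cancer, and immune/other calls are kept from the marker
#' annotation where available. Marker mode (no CNA scores): cancer =
#' EPCAM-annotated clusters, immune = T/B/myeloid clusters, remainder
#' other.
#'
#' @param assignment A `ClusterAssignment` (cluster labels present).
#' @param cna_scores Optional per-cell CNA module scores from
#'   [cna_module_score()].
#' @return The `ClusterAssignment` with `coarse_class` (and, in CNA mode,
#'   cancer `cell_type` calls) filled.
#' @export
classify_cancer_immune <- function(assignment, cna_scores = NULL) {
  stopifnot(inherits(assignment, "ClusterAssignment"))
  cell_type <- assignment$cell_type
  if (is.null(cna_scores)) {
    if (all(cell_type == "unknown")) {
      stop("no evidence: all cell types unknown and no CNA scores supplied")
    }
    return(new_assignment(assignment$obs_ids, assignment$cluster_labels,
                          cell_type))
  }
  labels <- assignment$cluster_labels
  clusters <- names(cell_type)
  med <- vapply(clusters, function(cl) {
    stats::median(cna_scores[assignment$obs_ids[labels == cl]])
  }, 0)
  if (length(med) < 2) stop("cannot split a single cluster into two groups")
  high <- clusters[two_means_high(med)]
  cell_type[high] <- "cancer"
  cell_type[cell_type == "cancer" & !(clusters %in% high)] <- "unknown"
  new_assignment(assignment$obs_ids, labels, cell_type)
}

# deterministic 1-D two-means: choose the split of the sorted values that
# minimizes within-group sum of squares; returns logical "in high group"
two_means_high <- function(x) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1), function(k) {
    sum((xs[1:k] - mean(xs[1:k]))^2) + sum((xs[(k + 1):n] - mean(xs[(k + 1):n]))^2)
  }, 0)
  k <- which.min(wss)
  high <- rep(FALSE, n)
  high[ord[(k + 1):n]] <- TRUE
  high
}

#' Two-dimensional embedding for visualization
#'
#' Force-directed layout of the SNN graph, seeded with the first two
#' principal components — a quick 2-D map of the cell neighborhoods for
#' plotting. No analysis step depends on the layout.
#'
#' @param embedding Result of [pca_reduce()].
#' @param seed Integer seed.
#' @return A cells-by-2 coordinate matrix.
#' @export
embed_2d <- function(embedding, seed = 1L) {
  coords <- embedding$coordinates
  n <- nrow(coords)
  withr::with_seed(as.integer(seed), {
    g <- build_snn_graph(embedding, k = min(15, n - 1))
    xy <- igraph::layout_with_fr(g, coords = coords[, 1:2, drop = FALSE] /
                                   max(abs(coords[, 1:2])))
    rownames(xy) <- rownames(coords)
    xy
  })
}
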