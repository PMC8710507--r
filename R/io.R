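#' Read a count matrix from MatrixMarket or dense TSV
#'
#' Reads a gene-by-observation count matrix. For MatrixMarket input,
#' `path_matrix` is the `.mtx` file and `path_genes` / `path_obs` are sidecar
#' text files with one identifier per line (genes correspond to matrix rows,
#' observations to columns, 10x-style). A dense TSV with gene ids in the
#' first column and observation ids in the header may be given instead, in
#' which case the sidecar paths are omitted.
#'
#' @param path_matrix Path to the `.mtx` matrix (or dense TSV).
#' @param path_genes Path to the gene-id sidecar (one id per line).
#' @param path_obs Path to the observation-id sidecar (one id per line).
#' @return An [expression_matrix()] with `layer = "counts"`.
#' @export
read_counts <- function(path_matrix, path_genes = NULL, path_obs = NULL) {
  if (!file.exists(path_matrix)) stop("matrix file not found: ", path_matrix)
  if (is.null(path_genes) != is.null(path_obs)) {
    stop("supply both sidecar paths or neither")
  }
  if (is.null(path_genes)) {
    tab <- utils::read.table(path_matrix, header = TRUE, sep = "\t",
                             row.names = 1, check.names = FALSE)
    return(expression_matrix(as.matrix(tab), rownames(tab), colnames(tab),
                             layer = "counts"))
  }
  m <- Matrix::readMM(path_matrix)
  m <- as.matrix(m)
  storage.mode(m) <- "double"   # pattern/integer MTX variants come back logical
  genes <- readLines(path_genes)
  obs <- readLines(path_obs)
  if (nrow(m) != length(genes)) {
    stop(sprintf("matrix declares %d rows but gene file has %d ids",
                 nrow(m), length(genes)))
  }
  if (ncol(m) != length(obs)) {
    stop(sprintf("matrix declares %d columns but observation file has %d ids",
                 ncol(m), length(obs)))
  }
  expression_matrix(as.matrix(m), genes, obs, layer = "counts")
}

#' Write a count matrix as MatrixMarket plus id sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.txt` and `<prefix>.obs.txt`,
#' readable back with [read_counts()].
#'
#' @param matrix An [expression_matrix()] with `layer = "counts"` and
#'   integer-valued entries.
#' @param path_prefix Output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_counts <- function(matrix, path_prefix) {
  check_layer(matrix, "counts")
  if (any(matrix$values != round(matrix$values))) {
    stop("count matrix has non-integer entries; refusing to write as counts")
  }
  paths <- paste0(path_prefix, c(".mtx", ".genes.txt", ".obs.txt"))
  Matrix::writeMM(methods::as(Matrix::Matrix(matrix$values, sparse = TRUE),
                              "generalMatrix"), paths[1])
  writeLines(matrix$gene_ids, paths[2])
  writeLines(matrix$obs_ids, paths[3])
  invisible(paths)
}

#' Read a GMT gene-set file
#'
#' Each line holds a set name, a description, and one or more member genes,
#' tab-separated (the MSigDB convention).
#'
#' @param path Path to the GMT file.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d fields; need at least 3 (name, description, genes)",
                   i, length(fields)))
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop(sprintf("duplicate set name '%s' at GMT line %d", name, i))
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      stop(sprintf("duplicated gene within set '%s'", name))
    }
    sets[[name]] <- genes
    desc[[name]] <- fields[2]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (one per set, no duplicates
#'   within a set, all sets non-empty).
#' @param description Optional named character vector of free-text
#'   descriptions; defaults to empty strings.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("set names must be present and unique")
  }
  if (any(lengths(sets) == 0)) stop("every set must be non-empty")
  if (any(vapply(sets, anyDuplicated, 0L) > 0)) {
    stop("sets must not contain duplicated genes")
  }
  if (is.null(description)) {
    description <- stats::setNames(rep("", length(sets)), names(sets))
  }
  structure(list(sets = lapply(sets, as.character),
                 description = description[names(sets)]),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (%s)\n", length(x$sets),
              paste(utils::head(names(x$sets), 5), collapse = ", ")))
  invisible(x)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$description[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Run-configuration defaults shared by the CLI and the pipeline functions.
config_defaults <- function() {
  list(
    n_hvg = 2000L,       # highly variable genes kept for PCA
    n_pcs = 10L,         # principal components used for the SNN graph
    cluster_resolution = 1.0,  # Louvain resolution (dataset-dependent)
    knn_k = 20L,         # neighbors for the SNN graph
    topk_corr = 50L,     # genes per spatial anchor module
    de_logfc = 0.25,     # |log fold change| gate for pairwise markers
    de_fdr = 0.05,       # BH-FDR gate for pairwise markers
    go_p = 0.05,         # raw-p gate for over-representation rows
    go_fdr = 0.2,        # BH-FDR gate for over-representation rows
    module_nbin = 24L,   # expression bins for module-score controls
    module_nctrl = 100L, # control genes sampled per set gene
    ssgsea_alpha = 0.25, # rank-weight exponent of the running sum
    pseudocount = 1,
    seed = 1L
  )
}

#' Load a run configuration
#'
#' Reads a flat `key = value` (or `key: value`) plain-text file, then applies
#' any overrides given as a named list. Unspecified keys keep their defaults
#' (`n_hvg = 2000`, `n_pcs = 10`, `topk_corr = 50`, ...). Unknown keys and
#' out-of-range values are rejected.
#'
#' @param path Optional path to a config file; `#` starts a comment.
#' @param overrides Named list of values overriding both defaults and file.
#' @return A named list of class `RunConfig`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- sub("#.*$", "", readLines(path))
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "[=:]")[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      from_file[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  for (src in list(from_file, overrides)) {
    for (key in names(src)) {
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      val <- suppressWarnings(as.numeric(src[[key]]))
      if (is.na(val)) stop(sprintf("non-numeric value for '%s'", key))
      if (is.integer(cfg[[key]])) val <- as.integer(val)
      cfg[[key]] <- val
    }
  }
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  pos <- c("n_hvg", "n_pcs", "cluster_resolution", "knn_k", "topk_corr",
           "de_logfc", "module_nbin", "module_nctrl", "ssgsea_alpha")
  for (key in pos) {
    if (cfg[[key]] <= 0) stop(sprintf("config '%s' must be strictly positive", key))
  }
  for (key in c("de_fdr", "go_p", "go_fdr")) {
    if (cfg[[key]] <= 0 || cfg[[key]] >= 1) {
      stop(sprintf("config '%s' must lie in (0,1)", key))
    }
  }
  if (cfg$pseudocount < 0) stop("config 'pseudocount' must be nonnegative")
  invisible(cfg)
}

#' Write a score table as TSV
#'
#' Observations as rows (first column `obs_id`), one column per score.
#'
#' @param table Data frame with an `obs_id` column and numeric score columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
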