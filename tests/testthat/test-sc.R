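test_that("HVG selection prefers genuinely over-dispersed genes", {
  set.seed(0)
  n_genes <- 2000; n_cells <- 150
  disp <- rep(0.05, n_genes)
  planted <- sample(n_genes, 100)
  disp[planted] <- 2
  counts <- t(sapply(seq_len(n_genes), function(g) {
    rnbinom(n_cells, mu = 10, size = 1 / disp[g])
  }))
  em <- tiny_matrix(counts, genes = sprintf("g%04d", seq_len(n_genes)))
  hvg <- select_hvg_vst(em, n_hvg = 800)
  recovered <- sum(sprintf("g%04d", planted) %in% hvg)
  expect_gte(recovered, 90)
})

test_that("HVG selection honors its boundary contracts", {
  set.seed(1)
  counts <- matrix(rpois(30 * 10, 5), 30, 10)
  counts[1, ] <- 4  # zero-variance gene
  em <- tiny_matrix(counts)
  expect_false("g01" %in% select_hvg_vst(em, n_hvg = 29))
  expect_length(select_hvg_vst(em, n_hvg = 100), 30)
  expect_error(select_hvg_vst(tiny_matrix(matrix(1, 5, 1))), "2 observations")
})

test_that("z-scaling is exact, degenerate-safe and clipped", {
  set.seed(2)
  em <- tiny_matrix(matrix(rpois(20 * 30, 6) + 0.0, 20, 30), layer = "lognorm")
  z <- scale_zscore(em)
  expect_lt(max(abs(rowMeans(z$values))), 1e-9)
  vars <- apply(z$values, 1, var)
  expect_true(all(abs(vars - 1) < 1e-6 | vars == 0))
  cst <- tiny_matrix(matrix(5, 3, 10), layer = "lognorm")
  expect_equal(unname(scale_zscore(cst)$values), matrix(0, 3, 10))
  # an extreme outlier lands exactly on the clip (the achievable z grows
  # with sqrt(n), so use enough cells for the clip to bind)
  x <- matrix(rnorm(1 * 200), 1, 200)
  x[1, 1] <- mean(x[1, -1]) + 500 * sd(x[1, -1])
  zc <- scale_zscore(tiny_matrix(x, layer = "lognorm"))
  expect_equal(max(zc$values), 10)
})

test_that("PCA is variance-ordered, sign-fixed, and separates planted blobs", {
  set.seed(3)
  em <- tiny_matrix(matrix(rnorm(40 * 60), 40, 60), layer = "scaled")
  pc <- pca_reduce(em, 5)
  expect_true(all(diff(pc$explained_variance) <= 1e-9))
  # rank-1 input: a single dominant direction
  u <- rnorm(30); v <- rnorm(50)
  r1 <- tiny_matrix(outer(u, v) + 1e-6 * matrix(rnorm(1500), 30, 50),
                    layer = "scaled")
  p1 <- pca_reduce(r1, 3)
  expect_gt(p1$explained_variance[1] / sum(p1$explained_variance), 0.999)
  expect_error(pca_reduce(em, 50), "exceeds")

  # two planted cell types: PC1 tracks the true label
  sim <- generate_sc_counts(200, type_proportions = c(cancer = 0.5, Tcell = 0.5,
                                                      Bcell = 0, myeloid = 0),
                            glut_effect = 6, marker_effect = 6,
                            n_genes = 200, seed = 0)
  ln <- log_normalize_cells(sim$matrix)
  emb <- pca_reduce(scale_zscore(ln, select_hvg_vst(ln, 100)), 5)
  lab <- as.numeric(sim$truth$cell_type_labels[emb$obs_ids] == "cancer")
  expect_gt(abs(cor(emb$coordinates[, 1], lab)), 0.9)
})

test_that("SNN graph weights are Jaccard-bounded and respect blob structure", {
  set.seed(4)
  blob <- rbind(matrix(rnorm(50 * 2), 50, 2),
                matrix(rnorm(50 * 2, mean = 30), 50, 2))
  rownames(blob) <- sprintf("c%03d", 1:100)
  g <- build_snn_graph(blob, k = 10)
  w <- igraph::E(g)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(igraph::degree(g) >= 1))
  # cross-blob edge mass is negligible
  ends <- igraph::ends(g, igraph::E(g))
  side <- function(v) as.integer(substring(v, 2)) > 50
  cross <- side(ends[, 1]) != side(ends[, 2])
  expect_lt(sum(w[cross]) / sum(w), 0.01)
  expect_error(build_snn_graph(blob, k = 100), "smaller")
})

test_that("Louvain clustering recovers planted partitions deterministically", {
  set.seed(5)
  blob <- rbind(matrix(rnorm(60 * 3), 60, 3),
                matrix(rnorm(60 * 3, mean = 12), 60, 3))
  rownames(blob) <- sprintf("c%03d", 1:120)
  g <- build_snn_graph(blob, k = 20)
  lab <- louvain_cluster(g, resolution = 0.5, seed = 1)
  expect_identical(lab, louvain_cluster(g, resolution = 0.5, seed = 1))
  truth <- rep(c("a", "b"), each = 60)
  expect_equal(length(unique(lab)), 2)
  expect_gt(adjusted_rand(lab, truth), 0.95)
  # labels are size-ranked from zero
  expect_identical(sort(unique(unname(lab))), c(0L, 1L))
})

test_that("pairwise markers apply both gates with correct directions", {
  # craft two groups of cells: g1 strongly up in A with a big fold change,
  # g2 significant but with a tiny fold change, g3 pure noise
  set.seed(6)
  nA <- 40; nB <- 40
  g1 <- c(rnorm(nA, 3, 0.3), rnorm(nB, 1, 0.3))
  g2 <- c(rnorm(nA, 2.00, 0.05), rnorm(nB, 1.90, 0.05))
  g3 <- rnorm(nA + nB, 1.5, 0.3)
  em <- tiny_matrix(pmax(rbind(g1, g2, g3, deparse.level = 0), 0),
                    layer = "lognorm",
                    genes = c("big", "small", "noise"))
  labels <- setNames(rep(c("A", "B"), c(nA, nB)), em$obs_ids)
  out <- find_markers_pairwise(em, labels, "A", "B")
  expect_true("big" %in% out$gene_id)
  expect_false("small" %in% out$gene_id)  # fails the logFC gate despite FDR
  expect_false("noise" %in% out$gene_id)
  expect_identical(out$direction[out$gene_id == "big"], "up")
  expect_true(all(out$fdr >= out$p_value - 1e-12))
  # a significant fold change below the gate is excluded
  small_row <- glutme:::markers_between(em, em$obs_ids[labels == "A"],
                                        em$obs_ids[labels == "B"])
  expect_lt(small_row$fdr[small_row$gene_id == "small"], 0.001)
  expect_lt(abs(small_row$log_fc[small_row$gene_id == "small"]), 0.25)
  expect_error(find_markers_pairwise(em, labels, "A", "Z"), "unknown cluster")
})

test_that("per-cluster markers recover the planted roster and ignore order", {
  sim <- generate_sc_counts(400, glut_effect = 6, marker_effect = 6,
                            n_genes = 200, seed = 11)
  ln <- log_normalize_cells(sim$matrix)
  labels <- sim$truth$cell_type_labels
  mk <- find_all_markers(ln, labels, top_n = 5)
  roster <- list(cancer = "EPCAM", Tcell = c("CD3D", "CD8A", "CD4"),
                 Bcell = c("CD79A", "IGHM"), myeloid = c("CD68", "LYZ"))
  for (tp in names(roster)) {
    expect_true(all(roster[[tp]] %in% mk$gene_id[mk$cluster == tp]),
                info = tp)
  }
  # permuting cell order leaves the table unchanged
  perm <- withr::with_seed(1, sample(ncol(ln$values)))
  ln_perm <- expression_matrix(ln$values[, perm], ln$gene_ids,
                               ln$obs_ids[perm], layer = "lognorm")
  mk_perm <- find_all_markers(ln_perm, labels, top_n = 5)
  expect_equal(mk_perm, mk)
  # undersized clusters are skipped with a warning
  expect_warning(find_all_markers(ln, replace(labels, 1:2, "tiny"), top_n = 2),
                 "fewer than 3")
})

test_that("annotation assigns planted types and gates weak clusters", {
  sim <- generate_sc_counts(400, glut_effect = 6, marker_effect = 6,
                            n_genes = 200, seed = 12)
  ln <- log_normalize_cells(sim$matrix)
  ann <- annotate_clusters(ln, sim$truth$cell_type_labels)
  expect_identical(ann$cell_type[c("cancer", "Tcell", "Bcell", "myeloid")],
                   c(cancer = "cancer", Tcell = "Tcell", Bcell = "Bcell",
                     myeloid = "myeloid"))
  expect_false(any(ann$cell_type == "unknown"))
  expect_identical(unname(ann$coarse_class[ann$cell_type == "cancer"]),
                   "cancer")
  expect_true(all(ann$coarse_class[ann$cell_type %in%
                                     c("Tcell", "Bcell", "myeloid")] == "immune"))
  # a matrix without any marker gene is rejected
  bare <- tiny_matrix(matrix(rpois(40 * 20, 4) + 0.0, 40, 20),
                      layer = "lognorm")
  expect_error(annotate_clusters(bare, setNames(rep(0:1, 10), bare$obs_ids)),
               "marker genes")
  # a flat cluster with no elevated marker set stays unknown
  nt <- sim$truth$cell_type_labels
  flat <- replace(nt, nt == "Bcell", "flat")
  ln_flat <- ln
  bgenes <- c("CD79A", "IGHM")
  ln_flat$values[bgenes, flat == "flat"] <- 0
  ann2 <- annotate_clusters(ln_flat, flat)
  expect_identical(unname(ann2$cell_type["flat"]), "unknown")
  expect_identical(unname(ann2$coarse_class["flat"]), "other")
})

test_that("CNA module score flags planted chromosome-7 gains", {
  sim <- generate_sc_counts(600, chr7_gain = 1.5, n_genes = 300, seed = 13)
  ln <- log_normalize_cells(sim$matrix)
  cna <- cna_module_score(ln, sim$annotation, "7", seed = 1)
  truthc <- sim$truth$cell_type_labels == "cancer"
  expect_gt(auc_score(cna, truthc), 0.9)
  # delegation: identical to module_score over the chromosome's genes
  chr7 <- sim$annotation$gene_id[sim$annotation$chromosome == "7"]
  expect_identical(cna, module_score(ln, chr7, seed = 1))
  expect_error(cna_module_score(ln, sim$annotation, "X"), ">= 5")
})

test_that("cancer/immune classification agrees across evidence modes", {
  sim <- generate_sc_counts(600, glut_effect = 6, marker_effect = 6,
                            chr7_gain = 1.5, n_genes = 300, seed = 14)
  ln <- log_normalize_cells(sim$matrix)
  labels <- sim$truth$cell_type_labels
  ann <- annotate_clusters(ln, labels)
  by_marker <- classify_cancer_immune(ann)
  cna <- cna_module_score(ln, sim$annotation, "7", seed = 1)
  by_cna <- classify_cancer_immune(ann, cna)
  expect_identical(by_cna$coarse_class, by_marker$coarse_class)
  expect_identical(unname(by_cna$coarse_class["cancer"]), "cancer")
  # GBM-like data: no EPCAM signal, CNA alone must call the cancer cluster
  blind <- ann
  blind$cell_type[] <- "unknown"
  by_cna_only <- classify_cancer_immune(blind, cna)
  expect_identical(unname(by_cna_only$coarse_class["cancer"]), "cancer")
  expect_error(classify_cancer_immune(blind), "no evidence")
  # a single cluster cannot be split
  one <- glutme:::new_assignment(ln$obs_ids,
                                 setNames(rep(0L, ncol(ln$values)),
                                          ln$obs_ids),
                                 c(`0` = "unknown"))
  expect_error(classify_cancer_immune(one, cna), "single cluster")
})
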