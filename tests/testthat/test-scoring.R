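test_that("CPM normalization conserves column mass", {
  em <- tiny_matrix(matrix(c(1, 3, 2, 2), 2, 2))
  cpm <- cpm_normalize(em)
  expect_equal(unname(cpm$values[, 1]), c(250000, 750000))
  expect_equal(unname(colSums(cpm$values)), rep(1e6, 2))
  zero <- tiny_matrix(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(cpm_normalize(zero), "s02")
})

test_that("log-normalization matches its closed form", {
  em <- tiny_matrix(matrix(c(5, 0, 3, 1), 2, 2))
  ln <- log_normalize_cells(em)
  # a cell where one gene carries the full library: ln(1 + 1e4)
  expect_equal(unname(ln$values[1, 1]), log(10001))
  expect_equal(unname(ln$values[2, 1]), 0)
  # scale invariance: doubling a cell's counts changes nothing
  dbl <- tiny_matrix(matrix(c(10, 0, 3, 1), 2, 2))
  expect_equal(log_normalize_cells(dbl)$values[, 1], ln$values[, 1])
  expect_error(log_normalize_cells(tiny_matrix(matrix(c(0, 0, 1, 1), 2, 2))),
               "zero total")
})

test_that("ssGSEA equals the hand-computed running sum and is rank-based", {
  genes <- paste0("g", 1:5)
  expr <- c(5, 4, 3, 2, 1)
  # set = the single top gene: in-set CDF jumps to 1 at step 1, so the
  # integral is 1 + 3/4 + 1/2 + 1/4 + 0 = 2.5
  expect_equal(ssgsea_score(expr, "g1", genes = genes), 2.5)
  expect_equal(ssgsea_score(expr, "g1", genes = genes),
               ssgsea_oracle(expr, genes, "g1"))
  # invariant under strictly increasing transforms
  expect_equal(ssgsea_score(exp(expr), c("g2", "g4"), genes = genes),
               ssgsea_score(expr * 10 + 3, c("g2", "g4"), genes = genes))
  # a top-ranked set scores higher than a bottom-ranked one
  top <- ssgsea_score(10:1, paste0("h", 1:5), genes = paste0("h", 1:10))
  bottom <- ssgsea_score(10:1, paste0("h", 6:10), genes = paste0("h", 1:10))
  expect_gt(top, bottom)
  expect_error(ssgsea_score(expr, "absent", genes = genes), "intersect")
  expect_error(ssgsea_score(expr, genes, genes = genes), "whole universe")
})

test_that("module score centers to zero on degenerate designs", {
  const <- tiny_matrix(matrix(3, 40, 6), layer = "lognorm")
  expect_equal(unname(module_score(const, c("g01", "g05"), seed = 1)),
               rep(0, 6))
  # set == whole universe: controls are the universe, score identically 0
  set.seed(2)
  em <- tiny_matrix(matrix(rpois(40 * 6, 8), 40, 6) + 0.0, layer = "lognorm")
  expect_equal(unname(module_score(em, em$gene_ids, seed = 3)), rep(0, 6))
  expect_error(module_score(em, "absent"), "intersect")
})

test_that("module score is centered under the null and seeded", {
  means <- numeric(10)
  for (s in 1:10) {
    sim <- generate_bulk_cohort(30, n_genes = 200, immune_effect = 1, seed = s)
    ln <- log_normalize_cells(sim$matrix)
    rset <- withr::with_seed(s, sample(ln$gene_ids, 10))
    means[s] <- mean(module_score(ln, rset, seed = s))
  }
  expect_lt(abs(mean(means)), 0.05)
  # same seed, same control draw
  sim <- generate_bulk_cohort(20, n_genes = 200, seed = 1)
  ln <- log_normalize_cells(sim$matrix)
  expect_identical(module_score(ln, c("SLC2A1", "EPCAM"), seed = 4),
                   module_score(ln, c("SLC2A1", "EPCAM"), seed = 4))
})

test_that("module score separates a planted subpopulation", {
  sim <- generate_sc_counts(300, glut_effect = 6, n_genes = 200, seed = 7)
  ln <- log_normalize_cells(sim$matrix)
  sc <- module_score(ln, c("SLC2A3"), seed = 1)
  immune <- sim$truth$cell_type_labels != "cancer"
  res <- mann_whitney_u(sc[immune], sc[!immune], "greater")
  expect_lt(res$p_value, 1e-6)
})

test_that("cell-type enrichment table has the expected shape and ordering", {
  sim <- generate_bulk_cohort(40, n_genes = 200, seed = 4)
  cpm <- cpm_normalize(sim$matrix)
  sigs <- builtin_signature_collection()
  tab <- cell_type_enrichment(cpm, sigs)
  expect_identical(tab$obs_id, cpm$obs_ids)
  expect_true(all(names(sigs$sets) %in% names(tab)))
  # the most immune-rich sample outscores the most cancer-rich on every
  # immune signature
  f <- sim$truth$immune_fraction
  hi <- which.max(f); lo <- which.min(f)
  for (nm in glutme:::immune_score_components()) {
    expect_gte(tab[[nm]][hi], tab[[nm]][lo])
  }
  # permutation equivariance over observations
  perm <- rev(seq_along(cpm$obs_ids))
  cpm_perm <- expression_matrix(cpm$values[, perm], cpm$gene_ids,
                                cpm$obs_ids[perm], layer = "cpm")
  tab_perm <- cell_type_enrichment(cpm_perm, sigs)
  expect_equal(tab_perm$B_cells, tab$B_cells[perm])
})

test_that("the composite immune score is the stated ten-way sum", {
  obs <- paste0("s", 1:4)
  comp <- glutme:::immune_score_components()
  tab <- data.frame(obs_id = obs)
  for (nm in comp) tab[[nm]] <- rep(0.1, 4)
  out <- immune_composite_score(tab)
  expect_equal(out$ImmuneScore, rep(1.0, 4))
  # linearity: adding c to one component adds c to the composite
  tab2 <- tab; tab2$NK_cells <- tab2$NK_cells + 0.5
  expect_equal(immune_composite_score(tab2)$ImmuneScore,
               out$ImmuneScore + 0.5)
  expect_error(immune_composite_score(tab[, -2]), comp[1])
})

test_that("cytolytic score and GLUTratio follow their closed forms", {
  vals <- matrix(c(3, 1, 0, 3, 7, 7, 2, 2), 4, 2)
  em <- expression_matrix(vals, c("SLC2A3", "SLC2A1", "GZMB", "PRF1"),
                          c("a", "b"), layer = "cpm")
  cyto <- cytolytic_score(em)
  expect_equal(unname(cyto["a"]), sqrt(1 * 4))  # CPM (0, 3), pseudocount 1
  expect_equal(unname(cyto["b"]), 3)            # both at CPM 2 -> 2 + 1
  expect_equal(cytolytic_score(em, "PRF1", "GZMB"), cyto)  # symmetric
  gr <- glut_ratio(em)
  expect_equal(unname(gr["a"]), 4 / 2)
  expect_equal(unname(gr["b"]), 1)              # equal CPM -> ratio 1
  swapped <- glut_ratio(em, gene_glut3 = "SLC2A1", gene_glut1 = "SLC2A3")
  expect_equal(gr * swapped, stats::setNames(rep(1, 2), c("a", "b")))
  expect_error(glut_ratio(expression_matrix(vals[1:2, ] , c("SLC2A3", "x"),
                                            c("a", "b"), layer = "cpm")),
               "SLC2A1")
  expect_error(cytolytic_score(em, gene_a = "GZMA"), "GZMA")
})

test_that("hypoxia score delegates to ssGSEA", {
  sim <- generate_bulk_cohort(15, n_genes = 200, seed = 6)
  cpm <- cpm_normalize(sim$matrix)
  hset <- builtin_signature_collection()$sets$hypoxia
  hx <- hypoxia_score(cpm, hset)
  direct <- apply(cpm$values, 2, function(col) {
    ssgsea_score(col, hset, genes = cpm$gene_ids)
  })
  expect_equal(unname(hx), unname(direct))
})
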