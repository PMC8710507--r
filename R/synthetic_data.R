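# Synthetic cohorts with planted ground truth.
#
# All three generators share one reserved gene roster: the two glucose
# transporters, the epithelial marker, cytolytic effector genes, the
# single-cell type markers, and thirteen 5-gene signature sets (ten immune
# cell types plus hypoxia, glycolysis, OXPHOS). Remaining genes are i.i.d.
# background; fifty of them are annotated to chromosome "7" so dosage gains
# are recoverable by a chromosome-level module score.

sig_genes <- function() {
  list(
    B_cells         = c("CD19", "MS4A1", "CD79B", "BLNK", "BANK1"),
    CD4_T_cells     = c("IL7R", "CD40LG", "CCR7", "TCF7", "LEF1"),
    CD8_T_cells     = c("CD8B", "GZMK", "KLRG1", "CCL5", "EOMES"),
    Dendritic_cells = c("FCER1A", "CD1C", "CLEC9A", "BATF3", "IRF8"),
    Eosinophils     = c("CLC", "PRG2", "EPX", "IL5RA", "CCR3"),
    Macrophages     = c("CD163", "MRC1", "MSR1", "MARCO", "C1QA"),
    Monocytes       = c("CD14", "FCN1", "S100A8", "S100A9", "VCAN"),
    Mast_cells      = c("TPSAB1", "TPSB2", "CPA3", "MS4A2", "KIT"),
    Neutrophils     = c("FCGR3B", "CSF3R", "CXCR2", "S100A12", "MPO"),
    NK_cells        = c("NCR1", "KLRD1", "NKG7", "GNLY", "KIR2DL1"),
    hypoxia         = c("HIF1A", "VEGFA", "CA9", "LDHA", "PGK1"),
    glycolysis      = c("HK2", "PFKM", "ALDOA", "ENO1", "PKM"),
    OXPHOS          = c("NDUFA1", "SDHB", "UQCRC1", "COX5A", "ATP5F1A")
  )
}

type_markers <- function() {
  list(cancer = "EPCAM",
       Tcell = c("CD3D", "CD8A", "CD4"),
       Bcell = c("CD79A", "IGHM"),
       myeloid = c("CD68", "LYZ"))
}

# Cell-type programs beyond the defining markers: each immune cell-type
# signature (and the cytolytic effector genes) belongs to one of the three
# coarse immune types of the single-cell model. NK cells and the cytotoxic
# program ride with the lymphoid T compartment; granulocyte and
# mononuclear-phagocyte signatures with the myeloid compartment.
type_programs <- function() {
  sigs <- sig_genes()
  list(
    Tcell = c(unlist(sigs[c("CD4_T_cells", "CD8_T_cells", "NK_cells")],
                     use.names = FALSE), "GZMB", "PRF1", "GZMA"),
    Bcell = sigs$B_cells,
    myeloid = unlist(sigs[c("Dendritic_cells", "Macrophages", "Monocytes",
                            "Eosinophils", "Mast_cells", "Neutrophils")],
                     use.names = FALSE))
}

N_CHR7_BACKGROUND <- 50L

# Reserved roster + background genes, with chromosome and program labels.
# Roles: cancer-program genes rise with the cancer compartment, immune ones
# with the immune compartment, neutral ones with neither.
gene_roster <- function(n_genes) {
  sigs <- sig_genes()
  mk <- type_markers()
  reserved <- data.frame(
    gene_id = c("SLC2A1", "SLC2A3", "EPCAM", "GZMB", "PRF1", "GZMA",
                unlist(mk[c("Tcell", "Bcell", "myeloid")], use.names = FALSE),
                unlist(sigs, use.names = FALSE)),
    stringsAsFactors = FALSE)
  reserved$program <- "immune"
  reserved$program[reserved$gene_id %in%
    c("SLC2A1", "EPCAM", unlist(sigs[c("hypoxia", "glycolysis")]))] <- "cancer"
  reserved$program[reserved$gene_id %in% sigs$OXPHOS] <- "neutral"
  min_genes <- nrow(reserved) + N_CHR7_BACKGROUND + 10L
  if (n_genes < min_genes) {
    stop(sprintf(
      "n_genes = %d cannot host the reserved gene roster; need at least %d",
      n_genes, min_genes))
  }
  n_bg <- n_genes - nrow(reserved)
  bg <- data.frame(gene_id = sprintf("BG%04d", seq_len(n_bg)),
                   program = "neutral", stringsAsFactors = FALSE)
  roster <- rbind(reserved, bg)
  roster$chromosome <- "1"
  roster$chromosome[nrow(reserved) + seq_len(N_CHR7_BACKGROUND)] <- "7"
  roster$is_marker_of <- NA_character_
  for (tp in names(mk)) roster$is_marker_of[roster$gene_id %in% mk[[tp]]] <- tp
  rownames(roster) <- NULL
  roster
}

# Baseline mean expression per gene: fixed for roster genes, gamma-drawn
# for background (consumes RNG, so call inside with_seed).
baseline_means <- function(roster) {
  mu <- ifelse(roster$program == "neutral" & grepl("^BG", roster$gene_id),
               stats::rgamma(nrow(roster), shape = 2, scale = 10), 30)
  pmax(mu, 0.5)
}

nb_draw <- function(mu, dispersion) {
  matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
         nrow = nrow(mu))
}

# Bulk cancer/immune compartment profiles. The immune compartment is a
# fixed 0.4 T / 0.2 B / 0.4 myeloid mixture, so the single-cell type
# markers carry their mixture weight while compartment-wide immune genes
# (SLC2A3, cytolytic genes, the ten cell-type signatures) carry the full
# effect.
bulk_profiles <- function(roster, base, effect) {
  mu_cancer <- ifelse(roster$program == "cancer", base * effect, base)
  mu_immune <- ifelse(roster$program == "immune", base * effect, base)
  wts <- c(Tcell = 0.4, Bcell = 0.2, myeloid = 0.4)
  for (tp in names(wts)) {
    i <- which(!is.na(roster$is_marker_of) & roster$is_marker_of == tp)
    mu_immune[i] <- base[i] * (wts[[tp]] * (effect - 1) + 1)
  }
  list(cancer = mu_cancer, immune = mu_immune)
}

roster_annotation <- function(roster) {
  roster[, c("gene_id", "chromosome", "is_marker_of")]
}

#' Built-in toy signature collection
#'
#' Five-gene signatures for the ten immune cell types that make up the
#' composite immune score (B cells, CD4 T, CD8 T, dendritic cells,
#' eosinophils, macrophages, monocytes, mast cells, neutrophils, NK cells)
#' plus hypoxia, glycolysis and OXPHOS sets — thirteen sets in all,
#' consistent with the genes the synthetic generators plant.
#'
#' @return A `GeneSetCollection` of 13 sets.
#' @export
builtin_signature_collection <- function() {
  sigs <- sig_genes()
  desc <- stats::setNames(
    c(rep("immune cell-type signature", 10),
      "hypoxia program", "glycolysis pathway", "oxidative phosphorylation"),
    names(sigs))
  gene_set_collection(sigs, desc)
}

#' Simulate a bulk cancer/immune mixture cohort
#'
#' Each sample is a two-compartment mixture with immune fraction
#' `f ~ Uniform(0, 1)`: gene means are `(1 - f) * mu_cancer + f * mu_immune`
#' scaled by a per-sample library factor, and counts are drawn
#' negative-binomially with a common dispersion. The cancer compartment
#' over-expresses SLC2A1, EPCAM and the hypoxia/glycolysis sets by
#' `immune_effect`; the immune compartment over-expresses SLC2A3, the
#' cytolytic genes and the ten immune cell-type signatures by the same
#' factor. With `immune_effect = 1` no structure is planted.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_genes Number of genes (>= the reserved roster plus background).
#' @param immune_effect Fold change tied to the immune fraction (default 8).
#' @param noise_dispersion Negative-binomial dispersion (default 0.3).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return List with `matrix` (counts `ExpressionMatrix`), `truth`
#'   (`SyntheticTruth`: seed, `immune_fraction`, `effect_sizes`,
#'   `library_sizes`) and `annotation` (gene, chromosome, marker role).
#' @export
generate_bulk_cohort <- function(n_samples, n_genes = 500,
                                 immune_effect = 8, noise_dispersion = 0.3,
                                 seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (immune_effect <= 0 || noise_dispersion <= 0) {
    stop("effect and dispersion must be positive")
  }
  roster <- gene_roster(n_genes)
  withr::with_seed(as.integer(seed), {
    base <- baseline_means(roster)
    prof <- bulk_profiles(roster, base, immune_effect)
    f <- stats::runif(n_samples)
    lib <- exp(stats::rnorm(n_samples, 0, 0.2))
    mu <- outer(prof$cancer, (1 - f) * lib) + outer(prof$immune, f * lib)
    counts <- nb_draw(mu, noise_dispersion)
    obs <- sprintf("sample%03d", seq_len(n_samples))
    em <- expression_matrix(counts, roster$gene_id, obs, layer = "counts")
    truth <- list(seed = as.integer(seed),
                  immune_fraction = stats::setNames(f, obs),
                  effect_sizes = c(immune_effect = immune_effect),
                  library_sizes = stats::setNames(round(colSums(mu)), obs),
                  immune_genes = roster$gene_id[roster$program == "immune"],
                  cancer_genes = roster$gene_id[roster$program == "cancer"])
    list(matrix = em, truth = truth, annotation = roster_annotation(roster))
  })
}

#' Simulate single-cell counts with discrete cell types
#'
#' Cells belong to one of four types (cancer, Tcell, Bcell, myeloid) drawn
#' at the requested proportions. Cancer cells over-express SLC2A1 by
#' `glut_effect` and EPCAM by `marker_effect`; the immune types
#' over-express SLC2A3 by `glut_effect` and their published markers
#' (CD3D/CD8A/CD4; CD79A/IGHM; CD68/LYZ) by `marker_effect`. If
#' `chr7_gain` is given, every gene annotated to chromosome "7" is
#' multiplied by that factor in cancer cells only, emulating a clonal
#' dosage gain.
#'
#' @param n_cells Number of cells (>= 40).
#' @param type_proportions Named vector over the four types, summing to 1.
#' @param glut_effect Fold change for the transporter genes (default 6).
#' @param marker_effect Fold change for the type markers (default 6).
#' @param chr7_gain Optional multiplicative dosage of chromosome-7 genes in
#'   cancer cells (e.g. 1.5); `NULL` plants no gain.
#' @param n_genes Number of genes (default 400).
#' @param noise_dispersion Negative-binomial dispersion (default 0.3).
#' @param seed Integer seed.
#' @return List with `matrix`, `truth` (`cell_type_labels`,
#'   `amplified_flags`, `effect_sizes`, `library_sizes`, seed) and
#'   `annotation`.
#' @export
generate_sc_counts <- function(n_cells,
                               type_proportions = c(cancer = 0.4, Tcell = 0.3,
                                                    Bcell = 0.15, myeloid = 0.15),
                               glut_effect = 6, marker_effect = 6,
                               chr7_gain = NULL, n_genes = 400,
                               noise_dispersion = 0.3, seed = 1L) {
  if (n_cells < 40) stop("n_cells must be >= 40")
  types <- c("cancer", "Tcell", "Bcell", "myeloid")
  if (!setequal(names(type_proportions), types)) {
    stop("type_proportions must be named over: ", paste(types, collapse = ", "))
  }
  type_proportions <- type_proportions[types]
  if (any(type_proportions < 0)) stop("proportions must be nonnegative")
  if (abs(sum(type_proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (!is.null(chr7_gain) && chr7_gain <= 0) stop("chr7_gain must be positive")
  roster <- gene_roster(n_genes)
  mk <- type_markers()
  withr::with_seed(as.integer(seed), {
    base <- baseline_means(roster)
    # per-type mean profiles
    programs <- type_programs()
    # secondary program genes carry a weaker fold than the defining
    # markers, so marker genes stay the top-ranked discriminants
    program_effect <- sqrt(marker_effect)
    mu_type <- sapply(types, function(tp) {
      mu <- base
      if (tp == "cancer") {
        mu[roster$gene_id == "SLC2A1"] <- base[roster$gene_id == "SLC2A1"] * glut_effect
      } else {
        mu[roster$gene_id == "SLC2A3"] <- base[roster$gene_id == "SLC2A3"] * glut_effect
        j <- which(roster$gene_id %in% programs[[tp]])
        mu[j] <- base[j] * program_effect
      }
      i <- which(roster$gene_id %in% mk[[tp]])
      mu[i] <- base[i] * marker_effect
      mu
    })
    labels <- sample(rep(types, times = round_proportions(type_proportions, n_cells)))
    lib <- exp(stats::rnorm(n_cells, 0, 0.2))
    mu <- sweep(mu_type[, labels, drop = FALSE], 2, lib, "*")
    amplified <- labels == "cancer" & !is.null(chr7_gain)
    if (!is.null(chr7_gain)) {
      chr7 <- roster$chromosome == "7"
      mu[chr7, amplified] <- mu[chr7, amplified] * chr7_gain
    }
    counts <- nb_draw(mu, noise_dispersion)
    obs <- sprintf("cell%04d", seq_len(n_cells))
    em <- expression_matrix(counts, roster$gene_id, obs, layer = "counts")
    truth <- list(seed = as.integer(seed),
                  cell_type_labels = stats::setNames(labels, obs),
                  amplified_flags = stats::setNames(amplified, obs),
                  effect_sizes = c(glut_effect = glut_effect,
                                   marker_effect = marker_effect,
                                   chr7_gain = if (is.null(chr7_gain)) 1 else chr7_gain),
                  library_sizes = stats::setNames(round(colSums(mu)), obs))
    list(matrix = em, truth = truth, annotation = roster_annotation(roster))
  })
}

# largest-remainder rounding of proportions to integer counts summing to n
round_proportions <- function(p, n) {
  raw <- p * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    i <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[i] <- k[i] + 1
  }
  as.integer(k)
}

#' Simulate a spatial grid with a tumor region
#'
#' Spots lie on an integer `width x height` grid. Spots inside
#' `tumor_region` are cancer-dominated (immune fraction around 0.1, so
#' EPCAM/SLC2A1-high); spots outside are immune-rich (immune fraction
#' around 0.7, SLC2A3/immune-signature-high). Gene profiles and the
#' mixture model are those of [generate_bulk_cohort()], with `glut_effect`
#' playing the fold-change role.
#'
#' @param width,height Grid dimensions (width * height >= 16).
#' @param tumor_region Integer vector `c(row_min, row_max, col_min,
#'   col_max)`, inclusive, strictly inside the grid with nonzero area.
#' @param glut_effect Planted fold change (default 6); 1 plants nothing.
#' @param n_genes Number of genes (default 400).
#' @param noise_dispersion Negative-binomial dispersion (default 0.3).
#' @param seed Integer seed.
#' @return List with `matrix` (spots as observations), `coords` (data frame
#'   `spot_id`, `row`, `col`), `truth` and `annotation`.
#' @export
generate_spatial_grid <- function(width, height,
                                  tumor_region = round(c(width * 0.25, width * 0.6,
                                                         height * 0.25, height * 0.6)),
                                  glut_effect = 6, n_genes = 400,
                                  noise_dispersion = 0.3, seed = 1L) {
  if (width * height < 16) stop("grid must hold at least 16 spots")
  tr <- as.integer(round(tumor_region))
  if (length(tr) != 4) stop("tumor_region must be c(row_min, row_max, col_min, col_max)")
  if (tr[1] > tr[2] || tr[3] > tr[4]) stop("tumor_region has zero area")
  if (tr[1] < 1 || tr[2] > width || tr[3] < 1 || tr[4] > height) {
    stop("tumor_region must lie strictly inside the grid")
  }
  if (tr[1] == 1 && tr[2] == width && tr[3] == 1 && tr[4] == height) {
    stop("tumor_region covers the whole grid; no immune region left")
  }
  roster <- gene_roster(n_genes)
  coords <- expand.grid(row = seq_len(width), col = seq_len(height))
  inside <- coords$row >= tr[1] & coords$row <= tr[2] &
    coords$col >= tr[3] & coords$col <= tr[4]
  n_spots <- nrow(coords)
  withr::with_seed(as.integer(seed), {
    base <- baseline_means(roster)
    prof <- bulk_profiles(roster, base, glut_effect)
    f <- ifelse(inside, stats::runif(n_spots, 0.05, 0.15),
                stats::runif(n_spots, 0.6, 0.8))
    lib <- exp(stats::rnorm(n_spots, 0, 0.2))
    mu <- outer(prof$cancer, (1 - f) * lib) + outer(prof$immune, f * lib)
    counts <- nb_draw(mu, noise_dispersion)
    obs <- sprintf("spot_%03dx%03d", coords$row, coords$col)
    em <- expression_matrix(counts, roster$gene_id, obs, layer = "counts")
    coords_tab <- data.frame(spot_id = obs, row = coords$row, col = coords$col,
                             stringsAsFactors = FALSE)
    truth <- list(seed = as.integer(seed),
                  immune_fraction = stats::setNames(f, obs),
                  in_tumor_region = stats::setNames(inside, obs),
                  effect_sizes = c(glut_effect = glut_effect),
                  library_sizes = stats::setNames(round(colSums(mu)), obs),
                  immune_genes = roster$gene_id[roster$program == "immune"],
                  cancer_genes = roster$gene_id[roster$program == "cancer"])
    list(matrix = em, coords = coords_tab, truth = truth,
         annotation = roster_annotation(roster))
  })
}

#' Write a synthetic truth record as JSON
#'
#' @param truth A truth list from one of the generators.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
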