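#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. When both groups have at most
#' eight observations the null distribution of U is obtained by exact
#' enumeration of all group assignments of the pooled values (so ties are
#' handled exactly); otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' U counts the pairs (x_i, y_j) with x_i > y_j, ties counting one half, so
#' `alternative = "greater"` asks whether x tends to exceed y.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @return List with `statistic` (U of x), `p_value`, `n` (c(n_x, n_y)) and
#'   `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= 8 && n2 <= 8) {
    u_null <- u_exact_distribution(r, n1)
    p <- switch(alternative,
      greater = mean(u_null >= u - 1e-9),
      less = mean(u_null <= u + 1e-9),
      two.sided = min(1, 2 * min(mean(u_null >= u - 1e-9),
                                 mean(u_null <= u + 1e-9))))
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      p <- switch(alternative,
        greater = stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = stats::pnorm((u - mu + 0.5) / sigma),
        two.sided = min(1, 2 * min(
          stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
          stats::pnorm((u - mu + 0.5) / sigma))))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  list(statistic = u, p_value = p, n = c(n1, n2), method = method)
}

# Null distribution of U over all choose(n, n1) assignments of the pooled
# ranks to group 1. Works on the joint rank vector so ties are respected.
u_exact_distribution <- function(r, n1) {
  idx <- utils::combn(length(r), n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' Kruskal-Wallis rank test across several groups
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `statistic` (H, tie-corrected), `p_value` (chi-squared
#'   on g-1 df), `n` (group sizes) and `method`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    # all observations identical: no rank variation, H = 0 by convention
    return(list(statistic = 0, p_value = 1, n = lengths(groups),
                method = "Kruskal-Wallis"))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = lengths(groups), method = "Kruskal-Wallis")
}

#' Pearson correlation with significance
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return List with `statistic` (r), `p_value` (two-sided, t transform on
#'   n-2 df), `n` and `method`.
#' @export
pearson_corr_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$estimate), p_value = ct$p.value,
       n = length(x), method = "Pearson correlation (t test)")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone, capped at 1, original order restored.
#'
#' @param p_values Numeric vector with all values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation of gene sets
#'
#' For each set, tests whether the overlap between `query` and the set
#' (both intersected with `universe`) exceeds chance, using the upper-tail
#' hypergeometric probability P(X >= overlap). BH adjustment is applied
#' across all tested sets; rows passing both the raw-p and FDR gates are
#' returned sorted by p.
#'
#' @param query Character vector of genes (no duplicates, all in universe).
#' @param collection A `GeneSetCollection`.
#' @param universe Character vector: the gene background.
#' @param p_max Raw p-value cutoff (default 0.05).
#' @param fdr_max BH-FDR cutoff (default 0.2).
#' @return Data frame with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `fdr`.
#' @export
hypergeom_enrichment <- function(query, collection, universe,
                                 p_max = 0.05, fdr_max = 0.2) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  query <- as.character(query)
  universe <- unique(as.character(universe))
  if (anyDuplicated(query)) stop("duplicate genes in query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  n_univ <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- intersect(collection$sets[[nm]], universe)
    k <- length(set)
    if (k == 0) return(NULL)
    ov <- length(intersect(set, query))
    p <- stats::phyper(ov - 1, k, n_univ - k, n_query, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = k,
               query_size = n_query, universe_size = n_univ,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      fdr = numeric()))
  }
  rows$fdr <- bh_fdr(rows$p_value)
  rows <- rows[rows$p_value < p_max & rows$fdr < fdr_max, , drop = FALSE]
  rows <- rows[order(rows$p_value), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Significance stars for a p-value
#'
#' `ns`, `*`, `**`, `***`, `****` at 0.05 / 0.01 / 0.001 / 0.0001
#' (uncorrected), the convention of the package's figure-style reporting.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}
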