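# Independent oracles and small fixtures used across the suite. Each
# oracle recomputes a quantity by the most literal route available
# (term-by-term accumulation, full enumeration, closed form), sharing no
# code with the implementation it checks.

# ssGSEA running sum, accumulated step by step down the ranked list.
ssgsea_oracle <- function(expr, genes, gene_set, alpha = 0.25) {
  ord <- order(expr, decreasing = TRUE)
  rk <- rank(expr)
  in_set <- genes %in% gene_set
  denom_in <- sum(rk[in_set]^alpha)
  denom_out <- sum(!in_set)
  cum_in <- 0
  cum_out <- 0
  score <- 0
  for (i in ord) {
    if (in_set[i]) cum_in <- cum_in + rk[i]^alpha else cum_out <- cum_out + 1
    score <- score + cum_in / denom_in - cum_out / denom_out
  }
  score
}

# Mann-Whitney by brute force: U from pair counting, null distribution by
# enumerating every assignment of the pooled values to group 1.
mw_u_pairs <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

mw_enum_oracle <- function(x, y, alternative) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- mw_u_pairs(x, y)
  combos <- utils::combn(length(pooled), n1)
  u_null <- apply(combos, 2, function(idx) {
    mw_u_pairs(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  switch(alternative,
         greater = mean(u_null >= u_obs - eps),
         less = mean(u_null <= u_obs + eps),
         two.sided = min(1, 2 * min(mean(u_null >= u_obs - eps),
                                    mean(u_null <= u_obs + eps))))
}

# Benjamini-Hochberg by the min-over-tail definition:
# adj_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Rank-based AUC of score for positives vs negatives.
auc_score <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * (length(score) - n1))
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ni <- sum(choose(rowSums(tab), 2))
  nj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ni * nj / nn
  (nij - expected) / ((ni + nj) / 2 - expected)
}

# Tiny ExpressionMatrix from a dense matrix with auto ids.
tiny_matrix <- function(values, layer = "counts", genes = NULL, obs = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(obs)) obs <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, genes, obs, layer = layer)
}

# Majority-cluster purity of each true cell type under a clustering.
type_purities <- function(labels, truth_types) {
  tab <- table(labels, truth_types[names(labels)])
  vapply(colnames(tab), function(tp) {
    cl <- which.max(tab[, tp])
    tab[cl, tp] / sum(tab[cl, ])
  }, 0)
}
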