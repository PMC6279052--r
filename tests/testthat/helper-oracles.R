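# Independent oracles coded from first principles; they never call the
# package functions they are used to check.

# Rand index by explicit pair enumeration.
rand_oracle <- function(a, b) {
  co_a <- outer(a, a, "==")
  co_b <- outer(b, b, "==")
  ut <- upper.tri(co_a)
  mean(co_a[ut] == co_b[ut])
}

# Two-sided Fisher exact p by full enumeration of the hypergeometric
# support (minimum-likelihood rule).
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Evasion rules transcribed independently as plain boolean expressions.
mechanisms_oracle <- function(calls) {
  up <- function(g) calls[g] == "up"
  nu <- function(g) !up(g)  # "not up-regulated": down or not_up
  out <- character()
  if (up("IL10") || up("TGFB1") || up("TGFB2")) out <- c(out, "M1")
  if (up("CTLA4") || (up("PDCD1") && (up("CD274") || up("PDCD1LG2"))) || up("IFNG"))
    out <- c(out, "M2")
  if (sum(up("BIRC3"), up("TNFAIP3"), up("TRAF1"), up("TNFRSF10D")) >= 2)
    out <- c(out, "M3")
  if (up("TNFRSF6B")) out <- c(out, "M4")
  if ((nu("B2M") || nu("HLA-A") || nu("HLA-B")) &&
      (nu("CD4") || nu("CD8A")) &&
      ((up("GZMA") || up("GZMB") || up("PRF1")) || up("TGFB1")))
    out <- c(out, "M5")
  if (nu("B2M") && nu("HLA-A") && nu("HLA-B") && nu("CD4") && nu("CD8A") &&
      nu("GZMA") && nu("GZMB") && nu("PRF1") && nu("TGFB1"))
    out <- c(out, "M6")
  out
}

# Exhaustive best split by nested loops over genes and midpoints.
best_split_oracle <- function(X, y, min_leaf = 1L) {
  y <- as.character(y)
  gini <- function(lab) {
    p <- table(lab) / length(lab)
    1 - sum(p^2)
  }
  n <- length(y)
  parent <- gini(y)
  best <- NULL
  for (g in sort(colnames(X))) {
    vals <- sort(unique(X[, g]))
    if (length(vals) < 2L) next
    for (i in seq_len(length(vals) - 1L)) {
      thr <- (vals[i] + vals[i + 1L]) / 2
      left <- X[, g] < thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      dec <- parent - (sum(left) * gini(y[left]) + sum(!left) * gini(y[!left])) / n
      if (is.null(best) || dec > best$decrease + 1e-12)
        best <- list(gene = g, threshold = thr, decrease = dec)
    }
  }
  best
}

# Direction-call map with every vocabulary gene not_up except the named ones.
calls_with_up <- function(up_genes = character()) {
  calls <- setNames(rep("not_up", length(mechanism_vocabulary())),
                    mechanism_vocabulary())
  calls[up_genes] <- "up"
  calls
}

# A small cohort with three planted 40-patient clusters; conditions shared
# by several recovery tests.
standard_cohort <- function(seed, n_genes = 500, n_tumor = 200, n_normal = 50,
                            mu = 2, noise_sd = 1, ...) {
  generate_cohort(
    n_genes = n_genes, n_tumor = n_tumor, n_normal = n_normal,
    layers = list(list(n_genes = 60, n_cols = 40, mu = mu),
                  list(n_genes = 60, n_cols = 40, mu = mu),
                  list(n_genes = 60, n_cols = 40, mu = mu)),
    noise_sd = noise_sd, seed = seed, ...)
}

# Best column-set Jaccard of each truth cluster against the found clusters.
cluster_recovery <- function(assignment, truth) {
  vapply(truth$clusters, function(tc) {
    found <- lapply(setdiff(unique(assignment$labels), "other"), function(k)
      names(assignment$labels)[assignment$labels == k])
    if (!length(found)) return(0)
    max(vapply(found, function(fc) recovery_jaccard(fc, tc), numeric(1)))
  }, numeric(1))
}
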