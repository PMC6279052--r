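# Vectorized Welch statistics over matrix rows. Returns one row per gene.
# Degenerate rows (both variances zero) follow the documented convention:
# equal means -> t = 0, p = 1; different means -> t = +/-Inf, p = 0.
row_welch <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (m1 != m2)
    t[ne] <- sign(m1 - m2)[ne] * Inf; p[ne] <- 0
    df[zero] <- NA
  }
  data.frame(mean_x = m1, mean_y = m2, t_stat = t, df = df, p_value = p)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. When both samples have zero variance the test is degenerate and
#' the convention is: equal means give p = 1, different means give p = 0.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  r <- row_welch(matrix(x, 1L), matrix(y, 1L))
  list(t = r$t_stat, df = r$df, p = r$p_value)
}

call_direction <- function(p, lfc, p_thresh, fc_thresh) {
  ifelse(p <= p_thresh & lfc >= fc_thresh, "up",
         ifelse(p <= p_thresh & lfc <= -fc_thresh, "down", "not_up"))
}

#' Per-cluster differential expression against two references
#'
#' For every gene, compares the cluster's tumors against (a) all other
#' tumor samples, including unclustered ones (`tumor_vs_tumor`) and (b) the
#' normal samples (`tumor_vs_normal`). A gene is called `up` when p <=
#' `p_thresh` and log2 fold change >= `fc_thresh`, `down` symmetrically,
#' otherwise `not_up`. Tumor-vs-tumor alone can mislead (a gene can exceed
#' other tumors yet sit below normal), so mechanism calling downstream uses
#' the tumor-vs-normal calls.
#'
#' @param tumor Tumor [expr_matrix()] (log2).
#' @param assignment A `cluster_assignment` over its samples.
#' @param cluster Cluster id to test.
#' @param normal Normal [expr_matrix()] or `NULL` (then the
#'   tumor_vs_normal comparison is skipped with a warning).
#' @param p_thresh,fc_thresh Call thresholds (defaults 0.05 and 1 log2
#'   unit); echoed in the result's attributes.
#' @param adjust `"none"` (default, every gene tested on its own) or
#'   `"BH"` for Benjamini-Hochberg adjustment of the p-values before
#'   calling.
#' @return A `de_table` data.frame: gene, comparison, mean_in, mean_ref,
#'   log2fc, t_stat, p_value, call.
#' @export
de_table <- function(tumor, assignment, cluster, normal = NULL,
                     p_thresh = 0.05, fc_thresh = 1, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  members <- cluster_members(assignment, cluster)
  if (!length(members)) stop("cluster has no members: ", cluster)
  others <- setdiff(colnames(tumor), members)
  X <- unclass(tumor)[, members, drop = FALSE]
  one <- function(R, label) {
    w <- row_welch(X, R)
    p <- if (adjust == "BH") stats::p.adjust(w$p_value, "BH") else w$p_value
    lfc <- w$mean_x - w$mean_y
    data.frame(gene = rownames(tumor), comparison = label,
               mean_in = w$mean_x, mean_ref = w$mean_y, log2fc = lfc,
               t_stat = w$t_stat, p_value = p,
               call = call_direction(p, lfc, p_thresh, fc_thresh),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- list()
  if (length(others) >= 2L)
    out$tt <- one(unclass(tumor)[, others, drop = FALSE], "tumor_vs_tumor")
  else warning("fewer than 2 reference tumors; tumor_vs_tumor skipped")
  if (!is.null(normal)) out$tn <- one(unclass(normal), "tumor_vs_normal")
  else warning("no normal reference; tumor_vs_normal skipped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cluster") <- cluster
  attr(res, "p_thresh") <- p_thresh
  attr(res, "fc_thresh") <- fc_thresh
  class(res) <- c("de_table", "data.frame")
  res
}

#' Mean expression of a unified gene set per cluster
#'
#' The defining gene sets of individual clusters can be too small to read a
#' mechanism from, so the union of all clusters' gene sets is summarized:
#' mean log2 expression of every union gene within each cluster's patients.
#'
#' @param tumor Tumor [expr_matrix()].
#' @param assignment A `cluster_assignment`.
#' @param gene_union Character vector of gene ids (subset of the matrix
#'   genes); default: the union of the assignment's per-cluster gene sets.
#' @return Numeric matrix, clusters x genes.
#' @export
unified_cluster_means <- function(tumor, assignment,
                                  gene_union = unique(unlist(assignment$cluster_genes))) {
  if (!length(gene_union)) stop("empty gene union")
  missing <- setdiff(gene_union, rownames(tumor))
  if (length(missing)) stop("genes not in matrix: ", paste(missing, collapse = ", "))
  ids <- sort(as.integer(cluster_ids(assignment)))
  out <- t(vapply(ids, function(k)
    rowMeans(unclass(tumor)[gene_union, cluster_members(assignment, k), drop = FALSE]),
    numeric(length(gene_union))))
  dimnames(out) <- list(as.character(ids), gene_union)
  out
}

#' Default cancer-immunity cycle step map
#'
#' Groups the rule vocabulary by role in the cancer-immunity cycle, from
#' antigen presentation through T-cell engagement to tumor killing, plus
#' the evasion-side groups (immunosuppression, apoptosis resistance).
#'
#' @return Named character vector gene -> step label.
#' @export
default_cycle_steps <- function() {
  steps <- list(
    antigen_presentation = c("B2M", "HLA-A", "HLA-B"),
    t_cell_engagement = c("CD4", "CD8A", "CTLA4", "PDCD1", "CD274", "PDCD1LG2", "IFNG"),
    cytotoxicity = c("GZMA", "GZMB", "PRF1"),
    immunosuppression = c("IL10", "TGFB1", "TGFB2"),
    apoptosis_resistance = c("BIRC3", "TNFAIP3", "TRAF1", "TNFRSF10D", "TNFRSF6B")
  )
  stats::setNames(rep(names(steps), lengths(steps)), unlist(steps))
}

#' Map genes to cancer-immunity cycle steps
#'
#' @param genes Character vector of gene symbols.
#' @param step_map Named vector gene -> step; default
#'   [default_cycle_steps()], replaceable from a YAML config
#'   (`yaml::read_yaml` of a step -> genes mapping).
#' @return Character vector of step labels, `"unmapped"` for genes absent
#'   from the map.
#' @export
assign_cycle_step <- function(genes, step_map = default_cycle_steps()) {
  out <- unname(step_map[genes])
  out[is.na(out)] <- "unmapped"
  out
}
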