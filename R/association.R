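# Join a cluster assignment with one clinical label; samples with a
# missing value are dropped from all denominators.
labeled_clusters <- function(assignment, clinical, label_name) {
  cl <- clinical[clinical$label_name == label_name & !is.na(clinical$label_value), ]
  if (!nrow(cl)) stop("label not present in clinical table: ", label_name)
  cl <- cl[cl$sample_id %in% names(assignment$labels), ]
  cl$cluster <- assignment$labels[cl$sample_id]
  cl
}

#' Cluster composition by clinical label
#'
#' Counts and percentages of each label value among the labeled members of
#' every cluster (including `"other"`). Samples missing the label are
#' excluded from the denominators.
#'
#' @param assignment A `cluster_assignment`.
#' @param clinical Long clinical data.frame (see [load_clinical()]).
#' @param label_name Which label to tabulate.
#' @return Data.frame: cluster, n_labeled, label_value, count, percent
#'   (percent is `NA` for a cluster with no labeled members).
#' @export
composition <- function(assignment, clinical, label_name) {
  cl <- labeled_clusters(assignment, clinical, label_name)
  clusters <- c(sort(as.integer(cluster_ids(assignment))), "other")
  values <- sort(unique(cl$label_value))
  rows <- list()
  for (k in as.character(clusters)) {
    members <- cl[cl$cluster == k, ]
    for (v in values) {
      cnt <- sum(members$label_value == v)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, n_labeled = nrow(members), label_value = v, count = cnt,
        percent = if (nrow(members)) 100 * cnt / nrow(members) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test with the two-sided p-value summing all tables
#' (at fixed margins) no more probable than the observed one. The odds
#' ratio is the sample cross-product ad/bc (infinite when bc = 0). A table
#' with a zero margin carries no information: p = 1, odds ratio `NA`.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @return List with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))  # p = 2/252
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0), all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = NA_real_, p_value = 1))
  or <- if (table[2, 1] * table[1, 2] == 0) Inf
        else (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(odds_ratio = or,
       p_value = min(1, stats::fisher.test(table)$p.value))
}

#' Enrichment of clinical label values across clusters
#'
#' One 2x2 Fisher exact test per (cluster, label value): the cluster's
#' with/without counts against reference counts. `reference = "cohort"`
#' (default) compares against the whole labeled cohort's totals — the
#' construction that asks whether the cluster's split differs from the
#' overall pattern; `"rest"` compares against all labeled samples outside
#' the cluster.
#'
#' @param assignment A `cluster_assignment`.
#' @param clinical Long clinical data.frame.
#' @param label_name Which label to test.
#' @param reference `"cohort"` or `"rest"`.
#' @param alpha Significance threshold for the `significant` flag (0.05).
#' @return Data.frame: cluster, label_value, the four table counts
#'   (in_with, in_without, ref_with, ref_without), odds_ratio, p_value,
#'   significant.
#' @export
enrichment_scan <- function(assignment, clinical, label_name,
                            reference = c("cohort", "rest"), alpha = 0.05) {
  reference <- match.arg(reference)
  cl <- labeled_clusters(assignment, clinical, label_name)
  values <- sort(unique(cl$label_value))
  if (length(values) < 2L) stop("need at least 2 label values")
  clusters <- c(sort(as.integer(cluster_ids(assignment))), "other")
  rows <- list()
  for (k in as.character(clusters)) {
    inside <- cl$cluster == k
    for (v in values) {
      with_v <- cl$label_value == v
      a <- sum(inside & with_v); b <- sum(inside & !with_v)
      cw <- sum(with_v); cwo <- sum(!with_v)
      if (reference == "rest") { cw <- cw - a; cwo <- cwo - b }
      ft <- fisher_exact_2x2(matrix(c(a, cw, b, cwo), 2L))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = k, label_value = v, in_with = a, in_without = b,
        ref_with = cw, ref_without = cwo,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        significant = ft$p_value <= alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Omnibus association of each cluster with a multi-valued label
#'
#' One exact test per cluster: its counts over all label values against the
#' labeled cohort's totals (2 x k table). Useful when the label has more
#' than two values and a single per-cluster p-value is wanted.
#'
#' @inheritParams enrichment_scan
#' @return Data.frame: cluster, n_labeled, p_value, significant.
#' @export
omnibus_enrichment <- function(assignment, clinical, label_name, alpha = 0.05) {
  cl <- labeled_clusters(assignment, clinical, label_name)
  values <- sort(unique(cl$label_value))
  totals <- vapply(values, function(v) sum(cl$label_value == v), integer(1))
  clusters <- c(sort(as.integer(cluster_ids(assignment))), "other")
  rows <- lapply(as.character(clusters), function(k) {
    cnt <- vapply(values, function(v) sum(cl$cluster == k & cl$label_value == v), integer(1))
    p <- if (sum(cnt) == 0) 1 else
      stats::fisher.test(rbind(cnt, totals), workspace = 2e7)$p.value
    data.frame(cluster = k, n_labeled = sum(cnt), p_value = p,
               significant = p <= alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
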