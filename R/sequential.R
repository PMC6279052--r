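#' Sequential plaid biclustering into disjoint patient clusters
#'
#' Plaid layers may overlap in patients; this wrapper enforces the one
#' patient, one cluster structure. Each round fits a plaid model to the
#' remaining tumor samples, scans the accepted layers in discovery order,
#' and promotes the earliest layer covering at least `min_fraction` of the
#' *original* cohort to the next cluster; its patients are removed and the
#' procedure repeats. The fixed absolute threshold (default 5%) guarantees
#' every cluster is a representative slice of the cohort. Patients never
#' captured are labelled `"other"`.
#'
#' @param tumor Tumor [expr_matrix()] (genes x patients) on the log2 scale.
#' @param min_fraction Minimum cluster size as a fraction of the original
#'   cohort, in (0, 1); default 0.05.
#' @param max_rounds Safety cap on extraction rounds.
#' @param params [plaid_params()] passed to each round's [fit_plaid()].
#' @param seed Integer seed; one stream drives every round's shuffle tests.
#' @return Object of class `cluster_assignment`: list with
#'   `labels` (named character vector sample -> "1".."K"/"other"),
#'   `cluster_genes` (list of gene-id vectors from the defining layers),
#'   `round_log` (data.frame: round, layer index taken, size, fraction),
#'   `n0`, `min_fraction`, `seed`.
#' @examples
#' coh <- generate_cohort(n_genes = 80, n_tumor = 60, n_normal = 10,
#'                        layers = list(list(n_genes = 20, n_cols = 20, mu = 3)),
#'                        noise_sd = 0.5, seed = 1)
#' sequential_bicluster(split_by_role(coh$expr)$tumor, seed = 1)
#' @export
sequential_bicluster <- function(tumor, min_fraction = 0.05, max_rounds = 25L,
                                 params = plaid_params(), seed = NULL) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  n0 <- ncol(tumor)
  if (n0 < 2L) stop("tumor matrix must have at least 2 samples")
  samples <- colnames(tumor)
  labels <- stats::setNames(rep("other", n0), samples)
  cluster_genes <- list()
  log_rows <- list()
  with_seed(seed, {
    remaining <- samples
    k <- 0L
    for (round in seq_len(max_rounds)) {
      if (length(remaining) < 2L) break
      fit <- fit_plaid(unclass(tumor)[, remaining, drop = FALSE], params, seed = NULL)
      sizes <- vapply(fit$layers, function(l) length(l$cols), integer(1))
      take <- which(sizes >= min_fraction * n0)[1L]
      if (!length(fit$layers) || is.na(take)) {
        log_rows[[round]] <- data.frame(round = round, layer = NA_integer_,
                                        size = NA_integer_, fraction = NA_real_,
                                        note = if (length(fit$layers)) "no qualifying layer" else "no layers")
        break
      }
      k <- k + 1L
      members <- remaining[fit$layers[[take]]$cols]
      labels[members] <- as.character(k)
      cluster_genes[[as.character(k)]] <- rownames(tumor)[fit$layers[[take]]$rows]
      log_rows[[round]] <- data.frame(round = round, layer = take,
                                      size = length(members),
                                      fraction = length(members) / n0,
                                      note = "")
      remaining <- setdiff(remaining, members)
    }
  })
  structure(list(labels = labels, cluster_genes = cluster_genes,
                 round_log = do.call(rbind, log_rows) %||%
                   data.frame(round = integer(), layer = integer(),
                              size = integer(), fraction = numeric(), note = character()),
                 n0 = n0, min_fraction = min_fraction, seed = seed),
            class = "cluster_assignment")
}

cluster_ids <- function(assignment) {
  setdiff(unique(assignment$labels), "other")
}

cluster_members <- function(assignment, cluster) {
  names(assignment$labels)[assignment$labels == as.character(cluster)]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(factor(x$labels, levels = c(sort(as.integer(cluster_ids(x))), "other")))
  clustered <- sum(x$labels != "other")
  cat(sprintf("cluster_assignment: %d patients, %d cluster(s), %.1f%% clustered\n",
              x$n0, length(cluster_ids(x)), 100 * clustered / x$n0))
  print(sizes)
  invisible(x)
}

#' @export
summary.cluster_assignment <- function(object, ...) {
  print(object)
  cat("\nRound log:\n")
  print(object$round_log, row.names = FALSE)
  invisible(object)
}

#' @export
plot.cluster_assignment <- function(x, ...) {
  sizes <- table(factor(x$labels, levels = c(sort(as.integer(cluster_ids(x))), "other")))
  graphics::barplot(sizes, xlab = "cluster", ylab = "patients", ...)
  invisible(x)
}

#' Write a cluster assignment to disk
#'
#' Emits a sample/cluster TSV, a JSON round log, and a cluster-gene TSV.
#'
#' @param assignment A `cluster_assignment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assignment <- function(assignment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(sample_id = names(assignment$labels), cluster = assignment$labels),
    file.path(dir, "assignment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(assignment$round_log, file.path(dir, "round_log.json"),
                       auto_unbox = TRUE, digits = NA)
  genes <- do.call(rbind, lapply(names(assignment$cluster_genes), function(k)
    data.frame(cluster = k, gene_id = assignment$cluster_genes[[k]])))
  if (!is.null(genes))
    utils::write.table(genes, file.path(dir, "cluster_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Pairwise concordance (Rand index) of two clusterings
#'
#' The fraction of patient pairs treated consistently by two labelings:
#' co-clustered in both or separated in both. Unclustered patients keep
#' their shared `"other"` label, so they count as one group. Equivalent to
#' the Rand index; 1 means identical partitions.
#'
#' @param c0,ck Labelings: named vectors over the same sample set, or
#'   `cluster_assignment` objects.
#' @return Concordance gamma in `[0, 1]`.
#' @export
pairwise_concordance <- function(c0, ck) {
  if (inherits(c0, "cluster_assignment")) c0 <- c0$labels
  if (inherits(ck, "cluster_assignment")) ck <- ck$labels
  if (!is.null(names(c0)) && !is.null(names(ck))) {
    if (!setequal(names(c0), names(ck))) stop("labelings cover different sample sets")
    ck <- ck[names(c0)]
  } else if (length(c0) != length(ck)) {
    stop("labelings cover different sample sets")
  }
  n <- length(c0)
  if (n < 2L) stop("need at least 2 samples")
  # Rand index from the contingency table: pairs together in both vs apart in both
  tab <- table(c0, ck)
  s_tot <- choose(n, 2)
  s_both <- sum(choose(tab, 2))
  s_c0 <- sum(choose(rowSums(tab), 2))
  s_ck <- sum(choose(colSums(tab), 2))
  (s_tot + 2 * s_both - s_c0 - s_ck) / s_tot
}

#' Reproducibility of the sequential biclustering across seeds
#'
#' Reruns [sequential_bicluster()] once per seed and computes the pairwise
#' concordance of every run against the first (reference) run.
#'
#' @param tumor Tumor [expr_matrix()].
#' @param seeds Integer vector of length >= 2; `seeds[1]` is the reference.
#' @param min_fraction,max_rounds,params Passed to [sequential_bicluster()].
#' @return List with `gamma` (one value per non-reference seed, named),
#'   `assignments` (all runs).
#' @export
robustness_assessment <- function(tumor, seeds, min_fraction = 0.05,
                                  max_rounds = 25L, params = plaid_params()) {
  if (length(seeds) < 2L) stop("need at least 2 seeds")
  runs <- lapply(seeds, function(s)
    sequential_bicluster(tumor, min_fraction, max_rounds, params, seed = s))
  gamma <- vapply(runs[-1L], function(r) pairwise_concordance(runs[[1L]], r), numeric(1))
  names(gamma) <- paste0("seed_", seeds[-1L])
  list(gamma = gamma, assignments = runs)
}
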