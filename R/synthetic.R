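#' Canonical up-regulated gene sets for planting evasion mechanisms
#'
#' The genes a simulated cluster up-shifts to express each mechanism:
#' M1 IL10 + TGFB1; M2 CTLA4, PDCD1, CD274, IFNG; M3 BIRC3, TNFAIP3, TRAF1;
#' M4 TNFRSF6B; M5 GZMA + GZMB (cytotoxicity present, presentation silent);
#' M6 nothing (no danger signals).
#'
#' @return Named list of character vectors keyed M1..M6.
#' @export
mechanism_signature_genes <- function() {
  list(M1 = c("IL10", "TGFB1"),
       M2 = c("CTLA4", "PDCD1", "CD274", "IFNG"),
       M3 = c("BIRC3", "TNFAIP3", "TRAF1"),
       M4 = "TNFRSF6B",
       M5 = c("GZMA", "GZMB"),
       M6 = character())
}

#' Generate a synthetic tumor cohort with planted structure
#'
#' Builds a log2-scale expression matrix with the statistical structure the
#' analysis assumes: a two-way additive background (grand mean + gene
#' effect + sample effect), disjoint planted plaid layers defining patient
#' clusters, per-cluster mechanism gene signatures up-shifted relative to
#' the normal baseline, per-cluster marker genes for classification, i.i.d.
#' Gaussian noise on the log2 scale, and cluster-biased categorical
#' clinical labels. Normal samples carry the baseline only.
#'
#' @param n_genes Total genes. When a mechanism plan or marker plan is
#'   given, the 21-gene rule vocabulary (and the marker genes) occupy the
#'   first rows under their own symbols.
#' @param n_tumor,n_normal Sample counts.
#' @param layers List of layer specs, each a list with `mu` (layer effect)
#'   and either explicit `rows`/`cols` index vectors or sizes `n_genes` /
#'   `n_cols` (columns are then assigned as consecutive disjoint blocks,
#'   rows sampled outside the vocabulary). Optional `alpha`, `beta` give
#'   zero-sum member offsets (default 0). Explicit column sets must be
#'   pairwise disjoint: the planted clusters are the disjoint structure the
#'   sequential procedure recovers.
#' @param mechanism_plan Named list, cluster index (`"1"`, `"2"`, ...) ->
#'   character vector of mechanism ids (drawing up-gene sets from
#'   [mechanism_signature_genes()]) and/or gene symbols to up-shift
#'   directly.
#' @param label_plan Optional list describing one clinical label:
#'   `name`, `values`, optional `base_probs` (default uniform), `odds`
#'   (named list cluster -> named odds multipliers on the value
#'   probabilities), optional `missing_rate`.
#' @param marker_plan Optional list: `n_per_cluster` marker genes per
#'   cluster, shifted by `delta` log2 units in that cluster only.
#' @param noise_sd Gaussian noise SD on the log2 scale (default 1).
#' @param mech_delta Up-shift of mechanism signature genes in log2 units
#'   (default 2); must be positive.
#' @param grand_mean,gene_sd,sample_sd Background parameters: grand mean
#'   log2 expression and the SDs of the gene and sample effects.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return Object of class `synthetic_cohort`: list with `expr`
#'   ([expr_matrix()] of tumors then normals), `clinical` (long
#'   data.frame), and `truth` (planted layers with index sets and effects,
#'   cluster sample ids, mechanism sets implied by the planted calls,
#'   marker genes, the noise-free signal matrix, and the seed).
#' @examples
#' coh <- generate_cohort(n_genes = 60, n_tumor = 50, n_normal = 10,
#'                        layers = list(list(n_genes = 15, n_cols = 20, mu = 2)),
#'                        mechanism_plan = list(`1` = "M1"), seed = 1)
#' coh$truth$mechanisms
#' @export
generate_cohort <- function(n_genes = 500L, n_tumor = 200L, n_normal = 50L,
                            layers = list(), mechanism_plan = NULL,
                            label_plan = NULL, marker_plan = NULL,
                            noise_sd = 1, mech_delta = 2,
                            grand_mean = 8, gene_sd = 1.5, sample_sd = 0.25,
                            seed = NULL) {
  if (!is.null(mechanism_plan) && mech_delta <= 0)
    stop("mech_delta must be positive: mechanism signatures are up-regulated")
  vocab <- mechanism_vocabulary()
  use_panel <- !is.null(mechanism_plan) || !is.null(marker_plan)
  n_markers <- if (is.null(marker_plan)) 0L else marker_plan$n_per_cluster * length(layers)
  if (use_panel && n_genes < length(vocab) + n_markers)
    stop("n_genes too small for the gene panel plus marker genes")

  marker_names <- if (n_markers)
    sprintf("MK%d_%d", rep(seq_along(layers), each = marker_plan$n_per_cluster),
            seq_len(marker_plan$n_per_cluster)) else character()
  gene_names <- if (use_panel)
    c(vocab, marker_names, sprintf("gene_%04d", seq_len(n_genes - length(vocab) - n_markers)))
  else sprintf("gene_%04d", seq_len(n_genes))
  tumor_ids <- sprintf("T%04d", seq_len(n_tumor))
  normal_ids <- sprintf("N%04d", seq_len(n_normal))
  reserved <- if (use_panel) seq_len(length(vocab) + n_markers) else integer()

  with_seed(seed, {
    # materialize layer row/column index sets
    next_col <- 1L
    used_cols <- integer()
    layers <- lapply(layers, function(sp) {
      if (is.null(sp$cols)) {
        nc <- sp$n_cols %||% stop("layer spec needs cols or n_cols")
        sp$cols <- seq.int(next_col, length.out = nc)
        next_col <<- next_col + nc
      }
      if (max(sp$cols) > n_tumor) stop("layer columns exceed n_tumor")
      if (length(intersect(sp$cols, used_cols)))
        stop("planted layer column sets overlap; clusters must be disjoint")
      used_cols <<- c(used_cols, sp$cols)
      if (is.null(sp$rows)) {
        ng <- sp$n_genes %||% stop("layer spec needs rows or n_genes")
        sp$rows <- sort(sample(setdiff(seq_len(n_genes), reserved), ng))
      }
      sp$alpha <- sp$alpha %||% rep(0, length(sp$rows))
      sp$beta <- sp$beta %||% rep(0, length(sp$cols))
      stopifnot(length(sp$alpha) == length(sp$rows),
                length(sp$beta) == length(sp$cols))
      sp
    })

    # additive background + planted layer effects
    g_eff <- stats::rnorm(n_genes, 0, gene_sd)
    s_eff <- stats::rnorm(n_tumor + n_normal, 0, sample_sd)
    signal <- matrix(grand_mean, n_genes, n_tumor + n_normal,
                     dimnames = list(gene_names, c(tumor_ids, normal_ids)))
    signal <- signal + g_eff + rep(s_eff, each = n_genes)
    for (sp in layers)
      signal[sp$rows, sp$cols] <- signal[sp$rows, sp$cols] +
        sp$mu + outer(sp$alpha, sp$beta, "+")

    clusters <- lapply(layers, function(sp) tumor_ids[sp$cols])
    names(clusters) <- as.character(seq_along(clusters))

    # mechanism signatures: up-shift intended genes in the cluster's tumors
    mechanisms <- list(); mech_genes <- list()
    if (!is.null(mechanism_plan)) {
      sigs <- mechanism_signature_genes()
      for (k in names(mechanism_plan)) {
        plan <- mechanism_plan[[k]]
        up <- unique(unlist(lapply(plan, function(p)
          if (p %in% names(sigs)) sigs[[p]] else p)))
        bad <- setdiff(up, vocab)
        if (length(bad)) stop("mechanism plan genes outside the vocabulary: ",
                              paste(bad, collapse = ", "))
        cols <- match(clusters[[k]], colnames(signal))
        if (length(up)) signal[up, cols] <- signal[up, cols] + mech_delta
        intended <- stats::setNames(ifelse(vocab %in% up, "up", "not_up"), vocab)
        mechanisms[[k]] <- call_mechanisms(intended, cluster = k)$mechanisms
        mech_genes[[k]] <- up
      }
    }

    # per-cluster marker genes for the classification tree
    marker_genes <- list()
    if (n_markers) {
      idx <- length(vocab)
      for (k in seq_along(layers)) {
        mk <- gene_names[idx + seq_len(marker_plan$n_per_cluster)]
        idx <- idx + marker_plan$n_per_cluster
        cols <- match(clusters[[as.character(k)]], colnames(signal))
        signal[mk, cols] <- signal[mk, cols] + marker_plan$delta
        marker_genes[[as.character(k)]] <- mk
      }
    }

    values <- signal + if (noise_sd > 0)
      stats::rnorm(length(signal), 0, noise_sd) * 1 else 0
    expr <- expr_matrix(values, c(rep("tumor", n_tumor), rep("normal", n_normal)))

    # cluster-biased categorical labels for the tumor samples
    clinical <- NULL
    if (!is.null(label_plan)) {
      vals <- label_plan$values
      base <- label_plan$base_probs %||% rep(1 / length(vals), length(vals))
      lab <- character(n_tumor)
      for (i in seq_len(n_tumor)) {
        k <- names(clusters)[vapply(clusters, function(cc) tumor_ids[i] %in% cc, logical(1))]
        p <- unlist(base)
        if (length(k) && !is.null(label_plan$odds[[k]])) {
          o <- unlist(label_plan$odds[[k]])
          p[match(names(o), vals)] <- p[match(names(o), vals)] * o
        }
        lab[i] <- sample(vals, 1L, prob = p / sum(p))
      }
      if (!is.null(label_plan$missing_rate) && label_plan$missing_rate > 0)
        lab[stats::runif(n_tumor) < label_plan$missing_rate] <- NA
      clinical <- data.frame(sample_id = tumor_ids,
                             label_name = label_plan$name %||% "label",
                             label_value = lab, stringsAsFactors = FALSE)
    }

    truth <- structure(list(
      layers = lapply(layers, function(sp)
        list(rows = sp$rows, cols = sp$cols,
             genes = gene_names[sp$rows], samples = tumor_ids[sp$cols],
             mu = sp$mu, alpha = sp$alpha, beta = sp$beta)),
      clusters = clusters, mechanisms = mechanisms,
      mechanism_genes = mech_genes, marker_genes = marker_genes,
      label_plan = label_plan, signal = signal, seed = seed),
      class = "cohort_truth")

    structure(list(expr = expr, clinical = clinical, truth = truth),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  role <- sample_roles(x$expr)
  cat(sprintf("synthetic_cohort: %d genes, %d tumor + %d normal samples, %d planted cluster(s)\n",
              nrow(x$expr), sum(role == "tumor"), sum(role == "normal"),
              length(x$truth$clusters)))
  invisible(x)
}

#' Write a synthetic cohort in the formats the loaders read
#'
#' Expression TSV, clinical TSV, and a JSON truth sidecar (index sets,
#' effects, mechanism sets, marker genes; the noise-free signal matrix is
#' omitted).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(sample_id = colnames(cohort$expr), role = sample_roles(cohort$expr)),
    file.path(dir, "sample_roles.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$clinical))
    utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  truth <- cohort$truth
  truth$signal <- NULL
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Jaccard recovery of a found bicluster against a planted one
#'
#' For row/column index-set pairs (lists with `rows` and `cols`), the
#' Jaccard similarity of the implied cell sets; for plain vectors, the
#' ordinary set Jaccard. An empty union is defined as 0.
#'
#' @param found,truth Lists with `rows` and `cols` components, or plain
#'   index/id vectors.
#' @return Jaccard similarity in `[0, 1]`.
#' @examples
#' recovery_jaccard(list(rows = 1:2, cols = 1), list(rows = 2:3, cols = 1))  # 1/3
#' @export
recovery_jaccard <- function(found, truth) {
  if (is.list(found) && is.list(truth)) {
    ri <- length(intersect(found$rows, truth$rows))
    ci <- length(intersect(found$cols, truth$cols))
    inter <- ri * ci
    uni <- length(unique(found$rows)) * length(unique(found$cols)) +
      length(unique(truth$rows)) * length(unique(truth$cols)) - inter
    if (uni == 0) return(0)
    inter / uni
  } else {
    set_jaccard(found, truth)
  }
}
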