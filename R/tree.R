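#' Gini impurity of a class count vector
#'
#' `1 - sum((count_c / total)^2)`; 0 for a pure node.
#'
#' @param class_counts Nonnegative integer vector with positive total.
#' @return Impurity in `[0, 1)`.
#' @export
gini_impurity <- function(class_counts) {
  n <- sum(class_counts)
  if (n <= 0) stop("class counts must have a positive total")
  1 - sum((class_counts / n)^2)
}

#' Best single-gene threshold split
#'
#' Exhaustive scan over candidate genes and midpoints between consecutive
#' distinct sorted values, maximizing the weighted Gini impurity decrease.
#' Ties break deterministically: lexicographically smallest gene, then
#' lowest threshold. Left child takes values below the threshold.
#'
#' @param X Numeric matrix, samples x genes (log2 expression).
#' @param y Class labels (cluster ids), length `nrow(X)`.
#' @param candidate_genes Columns to scan (default all).
#' @param min_leaf Minimum child size for a split to be eligible.
#' @return List with `gene`, `threshold`, `decrease` (impurity decrease in
#'   the parent), or `NULL` when no valid split exists.
#' @export
best_split <- function(X, y, candidate_genes = colnames(X), min_leaf = 1L) {
  y <- factor(y)
  n <- length(y)
  if (nlevels(droplevels(y)) < 2L) return(NULL)
  parent <- gini_impurity(tabulate(y, nlevels(y)))
  best <- NULL
  for (g in sort(candidate_genes)) {
    x <- X[, g]
    o <- order(x)
    xs <- x[o]
    ind <- stats::model.matrix(~ y[o] - 1)  # n x K class indicators
    cum <- apply(ind, 2L, cumsum)
    # candidate cut after position i: valid when the value changes there
    i <- which(xs[-n] < xs[-1L])
    i <- i[i >= min_leaf & (n - i) >= min_leaf]
    if (!length(i)) next
    nl <- i; nr <- n - i
    left <- cum[i, , drop = FALSE]
    right <- rep(colSums(ind), each = length(i)) - left
    gl <- 1 - rowSums((left / nl)^2)
    gr <- 1 - rowSums((right / nr)^2)
    dec <- parent - (nl * gl + nr * gr) / n
    j <- which.max(dec)  # lowest threshold among exact ties
    if (is.null(best) || dec[j] > best$decrease + 1e-12) {
      best <- list(gene = g, threshold = unname((xs[i[j]] + xs[i[j] + 1L]) / 2),
                   decrease = unname(dec[j]))
    }
  }
  best
}

majority_label <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # which.max takes the first = lexicographically smallest
}

#' Grow a classification tree over gene expression
#'
#' Binary recursive partitioning with the Gini criterion, predicting the
#' cluster a patient belongs to from log2 gene expression and exposing the
#' split genes as candidate biomarkers. A node is split only when it holds
#' at least `min_split` samples, both children hold at least `min_leaf`,
#' and the split's impurity decrease, weighted by the node's share of the
#' data, is at least `cp` times the root impurity. Defaults mirror the
#' usual recursive-partitioning settings (min_split 20, min_leaf 7,
#' cp 0.01). All tie-breaks are deterministic, so the tree needs no seed.
#'
#' @param X Numeric matrix, samples x genes.
#' @param y Cluster labels, length `nrow(X)`.
#' @param min_split Minimum node size to attempt a split.
#' @param min_leaf Minimum child size.
#' @param cp Complexity parameter.
#' @return Object of class `evasion_tree`: data.frame of nodes (id, depth,
#'   is_leaf, gene, threshold, pred, n, left, right) plus `class_counts`
#'   and training metadata.
#' @seealso [predict.evasion_tree()], [extract_biomarkers()], [cv_error()]
#' @export
grow_tree <- function(X, y, min_split = 20L, min_leaf = 7L, cp = 0.01) {
  if (!nrow(X)) stop("empty input")
  stopifnot(nrow(X) == length(y))
  y <- factor(y)
  root_gini <- gini_impurity(tabulate(y, nlevels(y)))
  n_total <- length(y)
  nodes <- list()
  counts <- list()
  build <- function(idx, depth) {
    id <- length(nodes) + 1L
    yk <- y[idx]
    cnt <- table(yk)
    node <- data.frame(id = id, depth = depth, is_leaf = TRUE,
                       gene = NA_character_, threshold = NA_real_,
                       pred = majority_label(yk), n = length(idx),
                       left = NA_integer_, right = NA_integer_)
    nodes[[id]] <<- node
    counts[[id]] <<- cnt
    sp <- NULL
    if (length(idx) >= min_split && length(unique(as.character(yk))) > 1L)
      sp <- best_split(X[idx, , drop = FALSE], yk, min_leaf = min_leaf)
    if (!is.null(sp) && root_gini > 0 &&
        (length(idx) / n_total) * sp$decrease >= cp * root_gini) {
      go_left <- X[idx, sp$gene] < sp$threshold
      lid <- build(idx[go_left], depth + 1L)
      rid <- build(idx[!go_left], depth + 1L)
      nodes[[id]]$is_leaf <<- FALSE
      nodes[[id]]$gene <<- sp$gene
      nodes[[id]]$threshold <<- sp$threshold
      nodes[[id]]$left <<- lid
      nodes[[id]]$right <<- rid
    }
    id
  }
  build(seq_len(n_total), 0L)
  structure(list(nodes = do.call(rbind, nodes), class_counts = counts,
                 levels = levels(y), genes = colnames(X),
                 params = list(min_split = min_split, min_leaf = min_leaf, cp = cp)),
            class = "evasion_tree")
}

#' @export
print.evasion_tree <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("evasion_tree: %d node(s), %d leaf/leaves, %d biomarker gene(s)\n",
              nrow(nd), sum(nd$is_leaf),
              length(unique(stats::na.omit(nd$gene)))))
  render <- function(id, indent) {
    n <- nd[id, ]
    pad <- strrep("  ", indent)
    if (n$is_leaf) {
      cat(sprintf("%s<leaf> predict cluster %s (n=%d)\n", pad, n$pred, n$n))
    } else {
      cat(sprintf("%s%s >= %.4g ?\n", pad, n$gene, n$threshold))
      cat(pad, " no:\n", sep = ""); render(n$left, indent + 1L)
      cat(pad, " yes:\n", sep = ""); render(n$right, indent + 1L)
    }
  }
  render(1L, 0L)
  invisible(x)
}

#' Predict cluster membership from an evasion tree
#'
#' @param object An `evasion_tree`.
#' @param newdata Numeric matrix, samples x genes, containing every split
#'   gene.
#' @param ... Unused.
#' @return Character vector of predicted cluster labels.
#' @export
predict.evasion_tree <- function(object, newdata, ...) {
  nd <- object$nodes
  route <- function(i) {
    id <- 1L
    while (!nd$is_leaf[id])
      id <- if (newdata[i, nd$gene[id]] < nd$threshold[id]) nd$left[id] else nd$right[id]
    nd$pred[id]
  }
  vapply(seq_len(nrow(newdata)), route, character(1))
}

#' Stratified cross-validated misclassification rate
#'
#' k-fold cross-validation with folds stratified by class so every fold
#' sees every cluster; the seed controls only the fold assignment.
#'
#' @param X Numeric matrix, samples x genes.
#' @param y Class labels.
#' @param folds Number of folds (>= 2).
#' @param min_split,min_leaf,cp Passed to [grow_tree()].
#' @param seed Integer seed for the fold assignment.
#' @return Misclassification rate in `[0, 1]`.
#' @export
cv_error <- function(X, y, folds = 5L, min_split = 20L, min_leaf = 7L,
                     cp = 0.01, seed = NULL) {
  stopifnot(folds >= 2L)
  y <- as.character(y)
  if (any(table(y) < folds))
    stop("every class needs at least `folds` samples for stratification")
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  wrong <- 0L
  for (f in seq_len(folds)) {
    test <- fold == f
    fit <- grow_tree(X[!test, , drop = FALSE], y[!test], min_split, min_leaf, cp)
    pred <- predict(fit, X[test, , drop = FALSE])
    wrong <- wrong + sum(pred != y[test])
  }
  wrong / n
}

#' Extract biomarker genes and cutoffs from a tree
#'
#' The unique genes used at internal nodes, in breadth-first order, each
#' with every log2 expression cutoff at which it splits and the depth of
#' its first use.
#'
#' @param tree An `evasion_tree`.
#' @return Data.frame with columns `gene`, `depth`, and list-column
#'   `thresholds`; zero rows for a single-leaf tree.
#' @export
extract_biomarkers <- function(tree) {
  nd <- tree$nodes
  internal <- nd[!nd$is_leaf, , drop = FALSE]
  internal <- internal[order(internal$depth, internal$id), , drop = FALSE]
  if (!nrow(internal))
    return(data.frame(gene = character(), depth = integer(),
                      thresholds = I(list())))
  genes <- unique(internal$gene)
  out <- data.frame(gene = genes,
                    depth = internal$depth[match(genes, internal$gene)])
  out$thresholds <- I(lapply(genes, function(g)
    unname(internal$threshold[internal$gene == g])))
  out
}

#' Serialize a tree to JSON with a plain-text rule rendering
#'
#' @param tree An `evasion_tree`.
#' @param path Output JSON path; a `.rules.txt` sibling holds the readable
#'   rendering.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  nd <- tree$nodes
  jsonlite::write_json(list(nodes = nd, levels = tree$levels,
                            params = tree$params),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  txt <- utils::capture.output(print(tree))
  writeLines(txt, sub("\\.json$", ".rules.txt", path))
  invisible(path)
}
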