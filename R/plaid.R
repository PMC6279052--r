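#' Plaid fitting parameters
#'
#' Controls for [fit_plaid()]. Defaults mirror the reference plaid
#' implementation commonly used for expression biclustering: full additive
#' layer model, release threshold 0.7 on both margins, 3 within-row shuffles
#' for the layer importance test, 5 startup iterations before the first
#' release and 10 iterations per layer, at most 20 layers.
#'
#' @param max_layers Maximum number of layers to extract.
#' @param iter_startup Iterations before release pruning begins.
#' @param iter_layer Total membership-update iterations per layer.
#' @param row_release,col_release Release thresholds in `[0, 1]`: a member
#'   row/column is dropped when its sum-of-squares contribution falls below
#'   `release * max` contribution. The useful range is 0.5-1.
#' @param n_shuffles Number of within-row permutations for the layer
#'   acceptance test; 0 accepts every fitted layer (escape hatch).
#' @param fit_model Layer model: `"m+a+b"` (mean + row + column effects),
#'   `"m+a"`, or `"m"`.
#' @return A list of class `plaid_params`.
#' @export
plaid_params <- function(max_layers = 20L, iter_startup = 5L, iter_layer = 10L,
                         row_release = 0.7, col_release = 0.7, n_shuffles = 3L,
                         fit_model = c("m+a+b", "m+a", "m")) {
  fit_model <- match.arg(fit_model)
  p <- list(max_layers = as.integer(max_layers), iter_startup = as.integer(iter_startup),
            iter_layer = as.integer(iter_layer), row_release = row_release,
            col_release = col_release, n_shuffles = as.integer(n_shuffles),
            fit_model = fit_model)
  stopifnot(p$max_layers >= 1L, p$iter_layer >= 1L, p$iter_startup >= 0L,
            p$row_release >= 0, p$row_release <= 1,
            p$col_release >= 0, p$col_release <= 1, p$n_shuffles >= 0L)
  class(p) <- "plaid_params"
  p
}

#' Fit the background layer of the plaid model
#'
#' Two-way additive fit spanning the whole matrix: grand mean, zero-sum row
#' effects, zero-sum column effects.
#'
#' @param Y Numeric matrix.
#' @return A `plaid_layer` list: `mu`, `alpha` (per row), `beta` (per
#'   column), `rows`, `cols`, `layer_ss`.
#' @export
fit_background <- function(Y) {
  if (length(Y) == 0L) stop("empty matrix")
  mu <- mean(Y)
  alpha <- rowMeans(Y) - mu
  beta <- colMeans(Y) - mu
  new_layer(mu, alpha, beta, seq_len(nrow(Y)), seq_len(ncol(Y)))
}

new_layer <- function(mu, alpha, beta, rows, cols) {
  theta_ss <- sum((mu + outer(alpha, beta, "+"))^2)
  structure(list(mu = mu, alpha = alpha, beta = beta,
                 rows = rows, cols = cols, layer_ss = theta_ss),
            class = "plaid_layer")
}

empty_layer <- function() {
  structure(list(mu = 0, alpha = numeric(), beta = numeric(),
                 rows = integer(), cols = integer(), layer_ss = 0),
            class = "plaid_layer")
}

layer_is_empty <- function(layer) length(layer$rows) == 0L || length(layer$cols) == 0L

# theta matrix of a layer on its member cells
layer_theta <- function(layer) layer$mu + outer(layer$alpha, layer$beta, "+")

#' Least-squares layer effects on a member submatrix
#'
#' Fits mu (+ alpha_i)(+ beta_j) to `Z[rows, cols]` with zero-sum
#' constraints on the row and column effects.
#'
#' @param Z Residual matrix.
#' @param rows,cols Member index sets (nonempty).
#' @param fit_model `"m+a+b"`, `"m+a"`, or `"m"`.
#' @return A `plaid_layer`.
#' @export
estimate_layer_effects <- function(Z, rows, cols, fit_model = "m+a+b") {
  if (!length(rows) || !length(cols)) stop("empty member set")
  S <- Z[rows, cols, drop = FALSE]
  mu <- mean(S)
  alpha <- if (fit_model %in% c("m+a", "m+a+b")) rowMeans(S) - mu else rep(0, length(rows))
  beta <- if (fit_model == "m+a+b") colMeans(S) - mu else rep(0, length(cols))
  new_layer(mu, alpha, beta, rows, cols)
}

#' One binary membership update pass
#'
#' Rows first, then columns. Row i is (re)included iff matching it to the
#' layer's effect field strictly reduces its residual sum of squares over
#' the member columns, i.e. `sum_j (Z_ij - theta_ij)^2 < sum_j Z_ij^2`;
#' ties exclude. `theta_ij = mu + alpha_i + beta_j` uses the fitted row
#' effect for current members and `alpha_i = 0` for candidate rows (a row
#' joining the layer is offered the layer profile, not a free parameter of
#' its own). Effects are re-estimated on the new row set before the
#' symmetric column pass.
#'
#' @param Z Residual matrix.
#' @param layer Current `plaid_layer`.
#' @param fit_model Layer model (see [plaid_params()]).
#' @return Updated `plaid_layer` (possibly empty).
#' @export
update_memberships <- function(Z, layer, fit_model = "m+a+b") {
  if (layer_is_empty(layer)) return(empty_layer())
  use_b <- fit_model == "m+a+b"
  cols <- layer$cols
  # row pass: alpha_i from the current fit for members, 0 for candidates
  a <- numeric(nrow(Z))
  a[layer$rows] <- layer$alpha
  beta_row <- if (use_b) layer$beta else rep(0, length(cols))
  M <- Z[, cols, drop = FALSE]
  Rfit <- M - layer$mu - outer(a, beta_row, "+")
  rows <- which(rowSums(Rfit^2) < rowSums(M^2))
  if (!length(rows)) return(empty_layer())
  lay <- estimate_layer_effects(Z, rows, cols, fit_model)
  # column pass against the refitted row effects; beta_j = 0 for candidates
  b <- numeric(ncol(Z))
  if (use_b) b[lay$cols] <- lay$beta
  M <- Z[rows, , drop = FALSE]
  Cfit <- M - lay$mu - outer(lay$alpha, b, "+")
  cols <- which(colSums(Cfit^2) < colSums(M^2))
  if (!length(cols)) return(empty_layer())
  estimate_layer_effects(Z, rows, cols, fit_model)
}

#' Release pruning of weakly contributing rows and columns
#'
#' Each member row's contribution is its residual sum-of-squares reduction
#' d_i = sum_j (Z_ij^2 - (Z_ij - theta_ij)^2) over member columns. Rows
#' whose contribution falls below `row_release` times the mean member
#' contribution are released; columns analogously (from the same pre-prune
#' fit); effects are re-estimated afterwards. The cutoff is relative to the
#' typical member: contributions of genuine members scatter around a common
#' mean, so a mean-relative cutoff releases free-riding rows while leaving
#' a homogeneous layer intact at any threshold below 1.
#'
#' @param Z Residual matrix.
#' @param layer Fitted `plaid_layer`.
#' @param row_release,col_release Thresholds in `[0, 1]`.
#' @param fit_model Layer model.
#' @return Pruned `plaid_layer` (empty when everything is released).
#' @export
release_prune <- function(Z, layer, row_release = 0.7, col_release = 0.7,
                          fit_model = "m+a+b") {
  if (layer_is_empty(layer)) return(empty_layer())
  theta <- layer_theta(layer)
  M <- Z[layer$rows, layer$cols, drop = FALSE]
  d_row <- rowSums(M^2) - rowSums((M - theta)^2)
  d_col <- colSums(M^2) - colSums((M - theta)^2)
  if (max(d_row) <= 0 || max(d_col) <= 0) return(empty_layer())
  keep_r <- d_row >= row_release * mean(d_row)
  keep_c <- d_col >= col_release * mean(d_col)
  if (!any(keep_r) || !any(keep_c)) return(empty_layer())
  estimate_layer_effects(Z, layer$rows[keep_r], layer$cols[keep_c], fit_model)
}

# Deterministic layer start: threshold the leading singular vector pair of
# the residual at zero; of the two sign-consistent candidate blocks, keep
# the one whose fitted layer captures more sum of squares.
init_layer <- function(Z, fit_model) {
  s <- svd(Z, nu = 1L, nv = 1L)
  u <- s$u[, 1L]; v <- s$v[, 1L]
  cand <- list(list(rows = which(u > 0), cols = which(v > 0)),
               list(rows = which(u < 0), cols = which(v < 0)))
  best <- empty_layer()
  for (cc in cand) {
    if (!length(cc$rows) || !length(cc$cols)) next
    lay <- estimate_layer_effects(Z, cc$rows, cc$cols, fit_model)
    if (lay$layer_ss > best$layer_ss) best <- lay
  }
  best
}

# Fit one layer on the residual: deterministic init, then iter_layer
# membership-update passes; release pruning runs after each pass once the
# iter_startup startup passes are over, and once more at the end if it has
# not run yet.
fit_one_layer <- function(Z, params) {
  layer <- init_layer(Z, params$fit_model)
  if (layer_is_empty(layer)) return(empty_layer())
  released <- FALSE
  for (t in seq_len(params$iter_layer)) {
    layer <- update_memberships(Z, layer, params$fit_model)
    if (layer_is_empty(layer)) return(empty_layer())
    if (t > params$iter_startup) {
      layer <- release_prune(Z, layer, params$row_release, params$col_release,
                             params$fit_model)
      if (layer_is_empty(layer)) return(empty_layer())
      released <- TRUE
    }
  }
  if (!released)
    layer <- release_prune(Z, layer, params$row_release, params$col_release,
                           params$fit_model)
  layer
}

#' Permutation importance test for a fitted layer
#'
#' Refits one layer (same iteration budget) on `n_shuffles` copies of the
#' residual with entries permuted independently within each row, preserving
#' row marginals. The layer is accepted iff its sum of squares exceeds every
#' shuffled layer's. `n_shuffles = 0` accepts unconditionally.
#'
#' @param Z Residual matrix the layer was fitted on.
#' @param layer Fitted `plaid_layer`.
#' @param params [plaid_params()].
#' @return `TRUE` to accept the layer. Consumes the current RNG stream.
#' @export
layer_importance <- function(Z, layer, params) {
  if (params$n_shuffles == 0L) return(TRUE)
  if (layer_is_empty(layer)) return(FALSE)
  for (k in seq_len(params$n_shuffles)) {
    Zs <- t(apply(Z, 1L, sample))
    shuf <- fit_one_layer(Zs, params)
    if (shuf$layer_ss >= layer$layer_ss) return(FALSE)
  }
  TRUE
}

#' Fit a plaid biclustering model
#'
#' Models a log2 expression matrix as a background two-way additive fit plus
#' a sum of additive layers (mu_k + alpha_ik + beta_jk) active only on
#' member cells. Layers are extracted greedily on the running residual:
#' deterministic singular-vector start, iterated binary membership updates,
#' release pruning, and a shuffle-based acceptance test. Extraction stops at
#' the first rejected layer or at `max_layers`. Layers may overlap; use
#' [sequential_bicluster()] for disjoint patient clusters.
#'
#' @param Y Numeric matrix (genes x samples), at least 2 x 2, or an
#'   [expr_matrix()].
#' @param params [plaid_params()].
#' @param seed Integer seed driving the shuffle test; `NULL` uses the
#'   current RNG stream.
#' @return Object of class `plaid`: list with `background`, `layers`
#'   (accepted, in discovery order), `params`, `seed`, `dim`, `residual`.
#' @seealso [sequential_bicluster()]
#' @examples
#' Y <- matrix(rnorm(400), 20, 20,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:20)))
#' Y[1:8, 1:6] <- Y[1:8, 1:6] + 4
#' fit <- fit_plaid(Y, seed = 1)
#' fit
#' @export
fit_plaid <- function(Y, params = plaid_params(), seed = NULL) {
  Y <- unclass(Y)
  if (!is.matrix(Y) || nrow(Y) < 2L || ncol(Y) < 2L) stop("Y must be a matrix with >= 2 rows and columns")
  if (!all(is.finite(Y))) stop("Y must be finite")
  with_seed(seed, {
    background <- fit_background(Y)
    Z <- Y - layer_theta(background)
    layers <- list()
    floor_ss <- 1e-12 * mean(Y^2) + 1e-300  # numerical-dust guard
    for (l in seq_len(params$max_layers)) {
      if (mean(Z^2) < floor_ss) break
      layer <- fit_one_layer(Z, params)
      if (layer_is_empty(layer)) break
      if (!layer_importance(Z, layer, params)) break
      Z[layer$rows, layer$cols] <- Z[layer$rows, layer$cols] - layer_theta(layer)
      layers[[length(layers) + 1L]] <- layer
    }
    structure(list(background = background, layers = layers, params = params,
                   seed = seed, dim = dim(Y), dimnames = dimnames(Y),
                   residual = Z),
              class = "plaid")
  })
}

#' @export
print.plaid <- function(x, ...) {
  cat(sprintf("plaid model: %d x %d matrix, %d accepted layer(s)\n",
              x$dim[1L], x$dim[2L], length(x$layers)))
  for (k in seq_along(x$layers)) {
    l <- x$layers[[k]]
    cat(sprintf("  layer %d: %d rows x %d cols, mu = %.3f, SS = %.1f\n",
                k, length(l$rows), length(l$cols), l$mu, l$layer_ss))
  }
  invisible(x)
}

#' @export
summary.plaid <- function(object, ...) {
  layers <- object$layers
  df <- data.frame(
    layer = seq_along(layers),
    n_rows = vapply(layers, function(l) length(l$rows), integer(1)),
    n_cols = vapply(layers, function(l) length(l$cols), integer(1)),
    mu = vapply(layers, function(l) l$mu, numeric(1)),
    layer_ss = vapply(layers, function(l) l$layer_ss, numeric(1))
  )
  structure(list(layers = df, dim = object$dim,
                 residual_ss = sum(object$residual^2)),
            class = "summary.plaid")
}

#' @export
print.summary.plaid <- function(x, ...) {
  cat(sprintf("plaid fit on %d x %d matrix; residual SS %.2f\n",
              x$dim[1L], x$dim[2L], x$residual_ss))
  if (nrow(x$layers)) print(x$layers, row.names = FALSE) else cat("  no layers\n")
  invisible(x)
}

#' @export
coef.plaid <- function(object, layer = NULL, ...) {
  if (is.null(layer)) {
    b <- object$background
    return(list(mu = b$mu, alpha = b$alpha, beta = b$beta))
  }
  l <- object$layers[[layer]]
  list(mu = l$mu, alpha = l$alpha, beta = l$beta, rows = l$rows, cols = l$cols)
}

#' @export
fitted.plaid <- function(object, ...) {
  fit <- layer_theta(object$background)
  for (l in object$layers)
    fit[l$rows, l$cols] <- fit[l$rows, l$cols] + layer_theta(l)
  dimnames(fit) <- object$dimnames
  fit
}

#' @export
residuals.plaid <- function(object, ...) {
  r <- object$residual
  dimnames(r) <- object$dimnames
  r
}

#' Serialize plaid layers to JSON
#'
#' Audit dump of every accepted layer (member indices, effects, sum of
#' squares), readable back as a plain list.
#'
#' @param fit A `plaid` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plaid_layers <- function(fit, path) {
  layers <- lapply(fit$layers, function(l)
    list(rows = l$rows, cols = l$cols, mu = l$mu,
         alpha = unname(l$alpha), beta = unname(l$beta),
         layer_ss = l$layer_ss, accepted = TRUE))
  jsonlite::write_json(layers, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
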