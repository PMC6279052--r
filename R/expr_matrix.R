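#' Construct an expression matrix with sample roles
#'
#' The container used throughout the package: a numeric genes-by-samples
#' matrix (log2 scale once transformed) with a tumor/normal role flag per
#' sample. Gene and sample identifiers live in `dimnames` and must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_role Character vector, one of `"tumor"` or `"normal"` per
#'   column, recycled if length 1.
#' @return An object of class `expr_matrix`: the matrix with a `sample_role`
#'   attribute.
#' @export
expr_matrix <- function(values, sample_role = "tumor") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (genes) and colnames (samples)")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  sample_role <- rep_len(as.character(sample_role), ncol(values))
  if (!all(sample_role %in% c("tumor", "normal")))
    stop("sample_role values must be 'tumor' or 'normal'")
  structure(values, sample_role = sample_role, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  role <- attr(x, "sample_role")
  cat(sprintf("expr_matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x), ncol(x), sum(role == "tumor"), sum(role == "normal")))
  cat(sprintf("  value range: [%.3g, %.3g]\n", min(x), max(x)))
  invisible(x)
}

gene_ids <- function(m) rownames(m)
sample_ids <- function(m) colnames(m)
sample_roles <- function(m) attr(m, "sample_role") %||% rep("tumor", ncol(m))

# Subset columns keeping the role attribute in sync.
expr_cols <- function(m, j) {
  role <- sample_roles(m)
  jj <- if (is.character(j)) match(j, colnames(m)) else j
  expr_matrix(unclass(m)[, jj, drop = FALSE], role[jj])
}

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix
#'
#' Expects one header row of sample ids and one leading id column. The
#' delimiter is inferred from the extension (.csv comma, otherwise tab)
#' unless given. All cells must parse as numbers; duplicated ids are an
#' error.
#'
#' @param path File path to a TSV/CSV matrix.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`;
#'   the returned matrix is always genes x samples.
#' @param sample_role Role flag(s) for the samples (`"tumor"`/`"normal"`),
#'   or a named character vector keyed by sample id.
#' @param sep Field delimiter override.
#' @return An [expr_matrix()].
#' @export
load_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                            sample_role = "tumor", sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"", comment.char = "")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s id: %s",
                 if (orientation == "genes_in_rows") "gene" else "sample",
                 paste(unique(dup), collapse = ", ")))
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                 body[bad[1L], bad[2L]], bad[1L], bad[2L], path))
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "samples_in_rows") num <- t(num)
  if (!is.null(names(sample_role))) {
    miss <- setdiff(colnames(num), names(sample_role))
    if (length(miss)) stop("no sample_role given for: ", paste(miss, collapse = ", "))
    sample_role <- sample_role[colnames(num)]
  }
  expr_matrix(num, sample_role)
}

#' Write an expression matrix to a delimited file
#'
#' @param m An [expr_matrix()] or plain named matrix.
#' @param path Output path; delimiter inferred from extension unless `sep` given.
#' @param id_col Name for the leading identifier column.
#' @param sep Field delimiter override.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_col = "gene_id", sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform an expression matrix
#'
#' Replaces each value v by log2(v + pseudocount). Values must be
#' nonnegative; a zero value with pseudocount 0 is an error. Matrices that
#' are already on the log2 scale should skip this step.
#'
#' @param m An [expr_matrix()] of nonnegative values.
#' @param pseudocount Nonnegative offset added before the log (default 1).
#' @return The transformed [expr_matrix()].
#' @export
log2_transform <- function(m, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(m < 0)) stop("negative expression value; log2 transform requires values >= 0")
  if (pseudocount == 0 && any(m == 0))
    stop("zero value with pseudocount 0 would produce -Inf")
  out <- log2(unclass(m) + pseudocount)
  expr_matrix(out, sample_roles(m))
}

#' Split an expression matrix into tumor and normal parts
#'
#' Column-disjoint submatrices with identical gene order. A missing normal
#' compartment is allowed (clustering needs tumors only) but triggers a
#' warning because differential expression against normal is then
#' unavailable.
#'
#' @param m An [expr_matrix()].
#' @return `list(tumor = , normal = )` of [expr_matrix()] objects; `normal`
#'   is `NULL` when no normal samples are present.
#' @export
split_by_role <- function(m) {
  role <- sample_roles(m)
  tumor <- expr_cols(m, which(role == "tumor"))
  normal <- NULL
  if (any(role == "normal")) {
    normal <- expr_cols(m, which(role == "normal"))
  } else {
    warning("no normal samples: differential expression vs normal unavailable")
  }
  list(tumor = tumor, normal = normal)
}

#' Read a clinical annotation table
#'
#' Accepts long format (columns `sample_id`, `label_name`, `label_value`) or
#' wide format (`sample_id` plus one column per label). Missing values are
#' kept as `NA` and later excluded from contingency denominators.
#'
#' @param path TSV/CSV path.
#' @param sep Field delimiter override.
#' @return A long-format data.frame with columns sample_id, label_name,
#'   label_value.
#' @export
load_clinical <- function(path, sep = NULL) {
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(df)) stop("clinical table needs a sample_id column")
  if (all(c("label_name", "label_value") %in% colnames(df)))
    return(df[, c("sample_id", "label_name", "label_value")])
  labs <- setdiff(colnames(df), "sample_id")
  if (!length(labs)) stop("clinical table has no label columns")
  long <- do.call(rbind, lapply(labs, function(l) {
    data.frame(sample_id = df$sample_id, label_name = l,
               label_value = as.character(df[[l]]), stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}
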