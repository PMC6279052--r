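#' Gene vocabulary of the immune evasion rules
#'
#' The gene symbols the six evasion-mechanism rules reason over. HGNC
#' symbols are used internally; common aliases (PD-1 = PDCD1, PD-L1 = CD274,
#' PD-L2 = PDCD1LG2, DcR3 = TNFRSF6B, TRAILR4 = TNFRSF10D) are resolved via
#' the synonym map shipped in the default rule config.
#'
#' @return Character vector of 21 gene symbols.
#' @export
mechanism_vocabulary <- function() {
  c("IL10", "TGFB1", "TGFB2",
    "CTLA4", "PDCD1", "CD274", "PDCD1LG2", "IFNG",
    "BIRC3", "TNFAIP3", "TRAF1", "TNFRSF10D",
    "TNFRSF6B",
    "B2M", "HLA-A", "HLA-B", "CD4", "CD8A", "GZMA", "GZMB", "PRF1")
}

# clause constructors for the boolean rule DSL
cl_any_up <- function(...) list(op = "any_up", genes = c(...))
cl_all_not_up <- function(...) list(op = "all_not_up", genes = c(...))
cl_any_not_up <- function(...) list(op = "any_not_up", genes = c(...))
cl_at_least_k_up <- function(genes, k) list(op = "at_least_k_up", genes = genes, k = k)
cl_and <- function(...) list(op = "and", args = list(...))
cl_or <- function(...) list(op = "or", args = list(...))

#' Default immune evasion rule set
#'
#' Declarative boolean rules over tumor-vs-normal direction calls, one per
#' mechanism:
#' \describe{
#'   \item{M1 immunosuppression}{any of IL10, TGFB1, TGFB2 up}
#'   \item{M2 tolerance}{CTLA4 up, or (PDCD1 up and PD-L1/2 up), or IFNG up}
#'   \item{M3 anti-apoptosis}{at least 2 of BIRC3, TNFAIP3, TRAF1, TNFRSF10D up}
#'   \item{M4 counterattack}{TNFRSF6B (DcR3) up}
#'   \item{M5 impaired antigen presentation}{some presentation gene
#'     (B2M/HLA-A/HLA-B) not up, and some T-cell gene (CD4/CD8A) not up,
#'     and (a cytotoxicity gene GZMA/GZMB/PRF1 up, or TGFB1 up)}
#'   \item{M6 ignorance}{all of B2M, HLA-A, HLA-B, CD4, CD8A, GZMA, GZMB,
#'     PRF1, TGFB1 not up (no danger signals)}
#' }
#' "Not up" means a call of `down` or `not_up`; down-regulation is not
#' required. M5's final clause is conjoined with the two negative clauses
#' (not a bare top-level alternative), which keeps M5 and M6 mutually
#' exclusive and M5 distinct from M1.
#'
#' @return A list of class `mechanism_rules`.
#' @export
default_mechanism_rules <- function() {
  rules <- list(
    M1 = cl_any_up("IL10", "TGFB1", "TGFB2"),
    M2 = cl_or(cl_any_up("CTLA4"),
               cl_and(cl_any_up("PDCD1"), cl_any_up("CD274", "PDCD1LG2")),
               cl_any_up("IFNG")),
    M3 = cl_at_least_k_up(c("BIRC3", "TNFAIP3", "TRAF1", "TNFRSF10D"), 2L),
    M4 = cl_any_up("TNFRSF6B"),
    M5 = cl_and(cl_any_not_up("B2M", "HLA-A", "HLA-B"),
                cl_any_not_up("CD4", "CD8A"),
                cl_or(cl_any_up("GZMA", "GZMB", "PRF1"), cl_any_up("TGFB1"))),
    M6 = cl_all_not_up("B2M", "HLA-A", "HLA-B", "CD4", "CD8A",
                       "GZMA", "GZMB", "PRF1", "TGFB1")
  )
  structure(list(rules = rules,
                 synonyms = c("PD-1" = "PDCD1", "PD-L1" = "CD274",
                              "PD-L2" = "PDCD1LG2", "DcR3" = "TNFRSF6B",
                              "TRAILR4" = "TNFRSF10D")),
            class = "mechanism_rules")
}

rule_genes <- function(clause) {
  if (!is.null(clause$genes)) return(clause$genes)
  unique(unlist(lapply(clause$args, rule_genes)))
}

eval_clause <- function(clause, calls) {
  up <- function(g) calls[g] == "up"
  switch(clause$op,
         any_up = any(up(clause$genes)),
         all_not_up = all(!up(clause$genes)),
         any_not_up = any(!up(clause$genes)),
         at_least_k_up = sum(up(clause$genes)) >= clause$k,
         and = all(vapply(clause$args, eval_clause, logical(1), calls = calls)),
         or = any(vapply(clause$args, eval_clause, logical(1), calls = calls)),
         stop("unknown rule operator: ", clause$op))
}

#' Call immune evasion mechanisms from direction calls
#'
#' Evaluates the boolean rule set against a cluster's tumor-vs-normal
#' direction calls and reports which of the six mechanisms are active,
#' with the supporting gene calls as evidence.
#'
#' @param calls Named character vector, gene -> `"up"`, `"down"`, or
#'   `"not_up"` (tumor-vs-normal comparison), or a `de_table` data.frame
#'   from [de_table()] (its tumor_vs_normal calls are used).
#' @param rules A `mechanism_rules` object; default [default_mechanism_rules()].
#' @param cluster Optional cluster id recorded in the result.
#' @return Object of class `mechanism_call`: list with `cluster`,
#'   `mechanisms` (character subset of M1..M6), `evidence` (per active
#'   mechanism, the calls of its rule genes), `calls`.
#' @examples
#' calls <- setNames(rep("not_up", 21), mechanism_vocabulary())
#' calls["TGFB1"] <- "up"
#' call_mechanisms(calls)$mechanisms  # M1 and M5
#' @export
call_mechanisms <- function(calls, rules = default_mechanism_rules(), cluster = NA) {
  if (is.data.frame(calls)) {
    de <- calls[calls$comparison == "tumor_vs_normal", ]
    calls <- stats::setNames(de$call, de$gene)
  }
  need <- unique(unlist(lapply(rules$rules, rule_genes)))
  missing <- setdiff(need, names(calls))
  if (length(missing))
    stop("calls missing for rule genes: ", paste(missing, collapse = ", "))
  if (!all(calls %in% c("up", "down", "not_up")))
    stop("calls must be 'up', 'down' or 'not_up'")
  active <- names(rules$rules)[vapply(rules$rules, eval_clause, logical(1), calls = calls)]
  evidence <- lapply(stats::setNames(active, active), function(m) {
    g <- rule_genes(rules$rules[[m]])
    as.list(calls[g])
  })
  structure(list(cluster = cluster, mechanisms = active,
                 evidence = evidence, calls = calls),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("mechanism_call (cluster %s): %s\n", as.character(x$cluster),
              if (length(x$mechanisms)) paste(x$mechanisms, collapse = ", ") else "none"))
  invisible(x)
}

#' Fraction of clustered patients whose cluster satisfies a predicate
#'
#' Cohort-level prevalence of an evasion mechanism (or any cluster-level
#' condition): the summed size of clusters satisfying the predicate divided
#' by the number of patients in any cluster (the `"other"` group is
#' excluded from both numerator and denominator).
#'
#' @param assignment A `cluster_assignment`.
#' @param calls List of `mechanism_call` objects, one per cluster, named by
#'   cluster id (or with `cluster` fields set).
#' @param predicate A mechanism id (e.g. `"M1"`), a gene symbol tested for
#'   an `"up"` call, or a function `mechanism_call -> logical`.
#' @return Fraction in `[0, 1]`.
#' @export
mechanism_prevalence <- function(assignment, calls, predicate) {
  ids <- cluster_ids(assignment)
  if (!length(ids)) stop("no clustered patients")
  if (is.null(names(calls)))
    names(calls) <- vapply(calls, function(x) as.character(x$cluster), character(1))
  miss <- setdiff(ids, names(calls))
  if (length(miss)) stop("no mechanism call for cluster(s): ", paste(miss, collapse = ", "))
  test <- if (is.function(predicate)) predicate
          else if (grepl("^M[1-6]$", predicate)) function(x) predicate %in% x$mechanisms
          else function(x) identical(unname(x$calls[predicate]), "up")
  sizes <- vapply(ids, function(k) length(cluster_members(assignment, k)), integer(1))
  hit <- vapply(ids, function(k) isTRUE(test(calls[[k]])), logical(1))
  sum(sizes[hit]) / sum(sizes)
}

#' Default mechanism-to-immunotherapy map
#'
#' Hypothesis-generating therapy suggestions per mechanism: blocking
#' antibodies against the immunosuppressive or checkpoint molecule where one
#' exists, dendritic-cell vaccination where antigen presentation is the
#' lesion, plus chemotherapy where no danger signals are present. M3
#' (anti-apoptosis) has no listed therapy. M2 suggestions are conditional
#' on which checkpoint predicate fired.
#'
#' @return Nested list keyed M1..M6.
#' @export
default_therapy_map <- function() {
  list(
    M1 = "anti-TGF-beta1",
    M2 = list(CTLA4 = "anti-CTLA4",
              PD1 = "anti-PD-1",
              IFNG = "anti-IFN-gamma"),
    M3 = "none listed",
    M4 = "anti-DcR3",
    M5 = "DC vaccine",
    M6 = "DC vaccine + chemotherapy"
  )
}

#' Therapy suggestions for a mechanism call
#'
#' Maps the active mechanisms of a cluster to candidate immunotherapies.
#' These are hypotheses for trial design, not clinical guidance.
#'
#' @param call A `mechanism_call`.
#' @param mapping Therapy map, default [default_therapy_map()].
#' @return Deduplicated character vector of suggestions (empty when no
#'   mechanism is active).
#' @export
therapy_suggestions <- function(call, mapping = default_therapy_map()) {
  out <- character()
  for (m in call$mechanisms) {
    entry <- mapping[[m]]
    if (is.null(entry)) next
    if (m == "M2" && is.list(entry)) {
      calls <- call$calls
      if (identical(unname(calls["CTLA4"]), "up")) out <- c(out, entry$CTLA4)
      if (identical(unname(calls["PDCD1"]), "up") &&
          (identical(unname(calls["CD274"]), "up") ||
           identical(unname(calls["PDCD1LG2"]), "up")))
        out <- c(out, entry$PD1)
      if (identical(unname(calls["IFNG"]), "up")) out <- c(out, entry$IFNG)
    } else {
      out <- c(out, unlist(entry, use.names = FALSE))
    }
  }
  unique(out)
}

# ---- rule serialization ----------------------------------------------------

#' Read or write a mechanism rule set as YAML
#'
#' The YAML mirrors the clause structure (`op`, `genes`/`args`/`k`) so a
#' rule set round-trips exactly; editing the file customizes the engine
#' without touching code.
#'
#' @param rules A `mechanism_rules` object.
#' @param path YAML file path.
#' @return `write_mechanism_rules` returns `path` invisibly;
#'   `read_mechanism_rules` returns a `mechanism_rules` object.
#' @export
write_mechanism_rules <- function(rules, path) {
  yaml::write_yaml(list(rules = rules$rules, synonyms = as.list(rules$synonyms)), path)
  invisible(path)
}

#' @rdname write_mechanism_rules
#' @export
read_mechanism_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  fix <- function(cl) {
    if (!is.null(cl$genes)) cl$genes <- as.character(unlist(cl$genes))
    if (!is.null(cl$k)) cl$k <- as.integer(cl$k)
    if (!is.null(cl$args)) cl$args <- lapply(cl$args, fix)
    cl
  }
  structure(list(rules = lapply(raw$rules, fix),
                 synonyms = unlist(raw$synonyms)),
            class = "mechanism_rules")
}
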