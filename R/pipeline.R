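#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file) describing one
#' end-to-end run. Required: an input block (`expression` + `sample_roles`
#' paths, or a `simulate` block of [generate_cohort()] arguments) and
#' `min_fraction`. Optional with defaults: `pseudocount` (`NULL` = data
#' already log2), `plaid` ([plaid_params()] overrides), `seed`,
#' `robustness_seeds`, `de` (`p_thresh`, `fc_thresh`), `tree`
#' (`min_split`, `min_leaf`, `cp`, `folds`), `labels` (clinical label
#' names to test; default all present), `rules_path`.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated, default-filled config (invisibly a plain list).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  has_files <- !is.null(config$expression)
  has_sim <- !is.null(config$simulate)
  if (!has_files && !has_sim)
    stop("config needs an `expression` path or a `simulate` block")
  if (is.null(config$min_fraction))
    stop("config is missing required field `min_fraction`")
  stopifnot(config$min_fraction > 0, config$min_fraction < 1)
  config$seed <- config$seed %||% 1L
  config$max_rounds <- config$max_rounds %||% 25L
  config$de <- utils::modifyList(list(p_thresh = 0.05, fc_thresh = 1), config$de %||% list())
  config$tree <- utils::modifyList(list(min_split = 20L, min_leaf = 7L, cp = 0.01, folds = 5L),
                                   config$tree %||% list())
  config$plaid <- do.call(plaid_params, config$plaid %||% list())
  config
}

resolve_input <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- sim$seed %||% config$seed
    if (!is.null(sim$layers))
      sim$layers <- lapply(sim$layers, as.list)
    coh <- do.call(generate_cohort, sim)
    return(list(expr = coh$expr, clinical = coh$clinical, truth = coh$truth))
  }
  roles <- "tumor"
  if (!is.null(config$sample_roles)) {
    rt <- utils::read.table(config$sample_roles, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    roles <- stats::setNames(rt$role, rt$sample_id)
  }
  expr <- load_expression(config$expression, sample_role = roles)
  if (!is.null(config$pseudocount)) expr <- log2_transform(expr, config$pseudocount)
  clinical <- if (!is.null(config$clinical)) load_clinical(config$clinical)
  list(expr = expr, clinical = clinical, truth = NULL)
}

#' Run the full immune evasion subtyping pipeline
#'
#' Load (or simulate) -> sequential biclustering -> optional multi-seed
#' robustness -> per-cluster differential expression -> mechanism calls and
#' therapy suggestions -> clinical label enrichment -> biomarker tree.
#' Every stage's outputs are written under `out_dir`; a failed stage is
#' recorded in the report and later stages that depend on it are skipped.
#' Identical config and seed give byte-identical reports.
#'
#' @param config Pipeline config (list or YAML path); see
#'   [validate_config()].
#' @param out_dir Output directory.
#' @return The run report (list, also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("ivrun")) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config[setdiff(names(config), "plaid")],
                 plaid_params = unclass(config$plaid), failed_stage = NULL)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      report$failed_stage <<- c(report$failed_stage, stats::setNames(conditionMessage(e), name))
      NULL
    })
  }

  input <- stage("input", resolve_input(config))
  if (is.null(input)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    return(invisible(report))
  }
  parts <- suppressWarnings(split_by_role(input$expr))
  rules <- stage("rules", {
    if (!is.null(config$rules_path)) read_mechanism_rules(config$rules_path)
    else default_mechanism_rules()
  })

  message("clustering ", ncol(parts$tumor), " tumor samples")
  assignment <- stage("cluster", {
    a <- sequential_bicluster(parts$tumor, config$min_fraction, config$max_rounds,
                              config$plaid, seed = config$seed)
    write_assignment(a, out_dir)
    a
  })
  if (is.null(assignment)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
    return(invisible(report))
  }
  ids <- sort(as.integer(cluster_ids(assignment)))
  report$cluster_sizes <- stats::setNames(
    lapply(ids, function(k) length(cluster_members(assignment, k))), as.character(ids))
  report$clustered_fraction <- 1 - sum(assignment$labels == "other") / assignment$n0

  if (length(config$robustness_seeds %||% c()) >= 2L) {
    message("robustness: ", length(config$robustness_seeds), " seeds")
    rob <- stage("robustness", robustness_assessment(
      parts$tumor, config$robustness_seeds, config$min_fraction,
      config$max_rounds, config$plaid))
    if (!is.null(rob)) report$gamma <- as.list(rob$gamma)
  }

  de_list <- list()
  mech <- list()
  if (length(ids)) {
    message("differential expression for ", length(ids), " cluster(s)")
    for (k in as.character(ids)) {
      de <- stage(paste0("de_cluster_", k), {
        d <- suppressWarnings(de_table(parts$tumor, assignment, k, parts$normal,
                                       config$de$p_thresh, config$de$fc_thresh))
        utils::write.table(d, file.path(out_dir, paste0("de_cluster", k, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        d
      })
      if (is.null(de)) next
      de_list[[k]] <- de
      if (is.null(rules)) next
      mc <- stage(paste0("mechanisms_cluster_", k), call_mechanisms(de, rules, cluster = k))
      if (!is.null(mc))
        mech[[k]] <- list(mechanisms = mc$mechanisms,
                          therapies = therapy_suggestions(mc),
                          call = mc)
    }
    report$mechanisms <- lapply(mech, function(m)
      list(mechanisms = m$mechanisms, therapies = m$therapies))
    if (length(mech) == length(ids) && length(mech)) {
      calls <- lapply(mech, `[[`, "call")
      report$prevalence <- stats::setNames(
        lapply(paste0("M", 1:6), function(m) mechanism_prevalence(assignment, calls, m)),
        paste0("M", 1:6))
    }
    jsonlite::write_json(report$mechanisms, file.path(out_dir, "mechanisms.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  }

  if (!is.null(input$clinical) && length(ids)) {
    labels <- config$labels %||% unique(input$clinical$label_name)
    report$enrichment <- list()
    for (lb in labels) {
      enr <- stage(paste0("enrichment_", lb), {
        e <- enrichment_scan(assignment, input$clinical, lb)
        utils::write.table(e, file.path(out_dir, paste0("enrichment_", lb, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        e
      })
      if (!is.null(enr)) {
        sig <- enr[enr$significant & enr$cluster != "other",
                   c("cluster", "label_value", "p_value")]
        rownames(sig) <- NULL
        report$enrichment[[lb]] <- sig
      }
    }
  }

  if (length(ids) >= 2L) {
    message("growing biomarker tree")
    tree <- stage("tree", {
      clustered <- names(assignment$labels)[assignment$labels != "other"]
      Xt <- t(unclass(parts$tumor)[, clustered, drop = FALSE])
      tr <- grow_tree(Xt, assignment$labels[clustered], config$tree$min_split,
                      config$tree$min_leaf, config$tree$cp)
      write_tree(tr, file.path(out_dir, "tree.json"))
      bm <- extract_biomarkers(tr)
      utils::write.table(
        data.frame(gene = bm$gene, depth = bm$depth,
                   thresholds = vapply(bm$thresholds, paste, character(1), collapse = ",")),
        file.path(out_dir, "biomarkers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      report$biomarkers <- bm$gene
      report$cv_error <- cv_error(Xt, assignment$labels[clustered],
                                  folds = config$tree$folds,
                                  min_split = config$tree$min_split,
                                  min_leaf = config$tree$min_leaf,
                                  cp = config$tree$cp, seed = config$seed)
      tr
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}
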