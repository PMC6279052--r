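test_that("canonical single-signal cases produce the documented mechanism sets", {
  # TGFB1 alone: immunosuppression, and the TGFB1 arm of impaired presentation
  expect_setequal(call_mechanisms(calls_with_up("TGFB1"))$mechanisms, c("M1", "M5"))
  # PD-1 without its ligands does not trigger tolerance; TGFB2 gives M1, and
  # with every danger-signal gene silent M6 also fires (M5 stays off:
  # cytotoxicity and TGFB1 are both silent)
  out <- call_mechanisms(calls_with_up(c("PDCD1", "TGFB2")))$mechanisms
  expect_setequal(out, c("M1", "M6"))
  expect_false("M2" %in% out)
  # PD-1 plus a ligand does
  expect_true("M2" %in% call_mechanisms(calls_with_up(c("PDCD1", "CD274")))$mechanisms)
  # nothing up: ignorance only
  expect_identical(call_mechanisms(calls_with_up())$mechanisms, "M6")
  # anti-apoptosis needs at least two of the four genes
  expect_false("M3" %in% call_mechanisms(calls_with_up("BIRC3"))$mechanisms)
  expect_true("M3" %in% call_mechanisms(calls_with_up(c("BIRC3", "TRAF1")))$mechanisms)
  # counterattack via the decoy receptor
  expect_true("M4" %in% call_mechanisms(calls_with_up("TNFRSF6B"))$mechanisms)
})

test_that("down-regulation counts as not up-regulated", {
  calls <- calls_with_up("GZMA")
  calls[c("B2M", "CD4")] <- "down"
  out <- call_mechanisms(calls)$mechanisms
  expect_true("M5" %in% out)
  expect_false("M6" %in% out)  # GZMA is up
})

test_that("the engine agrees with a brute-force rule evaluation on random states", {
  set.seed(100)
  rules <- default_mechanism_rules()
  for (i in 1:400) {
    up <- sample(mechanism_vocabulary(), rbinom(1, 10, 0.4))
    calls <- calls_with_up(up)
    # sprinkle in explicit down calls: they count as not up
    dn <- sample(setdiff(mechanism_vocabulary(), up), 2)
    calls[dn] <- "down"
    expect_identical(call_mechanisms(calls, rules)$mechanisms,
                     mechanisms_oracle(calls))
  }
})

test_that("impaired presentation and ignorance are mutually exclusive", {
  set.seed(101)
  for (i in 1:200) {
    genes <- sample(mechanism_vocabulary(), sample(0:8, 1))
    out <- call_mechanisms(calls_with_up(genes))$mechanisms
    expect_false(all(c("M5", "M6") %in% out))
  }
})

test_that("missing rule genes are reported by name", {
  calls <- calls_with_up("TGFB1")
  calls <- calls[setdiff(names(calls), c("GZMB", "PRF1"))]
  expect_error(call_mechanisms(calls), "GZMB, PRF1")
})

test_that("prevalence weights clusters by size over the clustered patients", {
  labels <- c(rep("1", 10), rep("2", 20), rep("3", 70), rep("other", 30))
  names(labels) <- sprintf("s%03d", seq_along(labels))
  asg <- structure(list(labels = labels, cluster_genes = list(), n0 = 130,
                        min_fraction = 0.05, seed = NULL),
                   class = "cluster_assignment")
  calls <- list(`1` = call_mechanisms(calls_with_up("TGFB1"), cluster = "1"),
                `2` = call_mechanisms(calls_with_up("TNFRSF6B"), cluster = "2"),
                `3` = call_mechanisms(calls_with_up(c("TNFRSF6B", "IL10")), cluster = "3"))
  expect_equal(mechanism_prevalence(asg, calls, "M4"), 0.9)
  expect_equal(mechanism_prevalence(asg, calls, "M1"), 0.8)
  expect_equal(mechanism_prevalence(asg, calls, "TNFRSF6B"), 0.9)
  expect_equal(mechanism_prevalence(asg, calls, function(x) TRUE), 1)
  expect_error(mechanism_prevalence(asg, calls[1:2], "M1"), "cluster")
})

test_that("therapy suggestions follow the mechanism-to-treatment map", {
  expect_equal(therapy_suggestions(call_mechanisms(calls_with_up("TGFB1"))),
               c("anti-TGF-beta1", "DC vaccine"))
  expect_equal(therapy_suggestions(call_mechanisms(calls_with_up())),
               "DC vaccine + chemotherapy")
  # M2 suggestions depend on which checkpoint fired
  sug <- therapy_suggestions(call_mechanisms(calls_with_up(c("CTLA4", "IFNG"))))
  expect_true(all(c("anti-CTLA4", "anti-IFN-gamma") %in% sug))
  expect_false("anti-PD-1" %in% sug)
  sug_pd <- therapy_suggestions(call_mechanisms(calls_with_up(c("PDCD1", "PDCD1LG2"))))
  expect_true("anti-PD-1" %in% sug_pd)
  # anti-apoptosis alone has no listed therapy
  sug3 <- therapy_suggestions(call_mechanisms(calls_with_up(c("BIRC3", "TNFAIP3",
                                                              "B2M", "HLA-A", "HLA-B",
                                                              "CD4", "CD8A"))))
  expect_true("none listed" %in% sug3)
})

test_that("rule sets round-trip through YAML and drive the engine identically", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mechanism_rules(default_mechanism_rules(), path)
  back <- read_mechanism_rules(path)
  expect_identical(back$rules, default_mechanism_rules()$rules)
  calls <- calls_with_up(c("TGFB1", "CTLA4"))
  expect_identical(call_mechanisms(calls, back)$mechanisms,
                   call_mechanisms(calls)$mechanisms)
  shipped <- system.file("extdata", "mechanism_rules.yaml", package = "immunevasion")
  expect_identical(read_mechanism_rules(shipped)$rules, default_mechanism_rules()$rules)
})

test_that("planted mechanisms are recovered end to end across seeds", {
  plans <- list(`1` = c("M1", "M4"), `2` = "M2", `3` = "M5")
  for (seed in 1:3) {
    coh <- generate_cohort(
      n_genes = 60, n_tumor = 160, n_normal = 40,
      layers = list(list(n_genes = 15, n_cols = 40, mu = 2),
                    list(n_genes = 15, n_cols = 40, mu = 2),
                    list(n_genes = 15, n_cols = 40, mu = 2)),
      mechanism_plan = plans, mech_delta = 2, noise_sd = 1, seed = seed)
    parts <- split_by_role(coh$expr)
    # evaluate the caller on the true clusters: this isolates DE + rules
    labels <- rep("other", ncol(parts$tumor))
    names(labels) <- colnames(parts$tumor)
    for (k in names(coh$truth$clusters)) labels[coh$truth$clusters[[k]]] <- k
    asg <- structure(list(labels = labels, cluster_genes = list(), n0 = length(labels),
                          min_fraction = 0.05, seed = NULL),
                     class = "cluster_assignment")
    for (k in names(plans)) {
      de <- de_table(parts$tumor, asg, k, parts$normal)
      called <- call_mechanisms(de, cluster = k)$mechanisms
      expect_setequal(called, coh$truth$mechanisms[[k]])
    }
  }
})
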