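test_that("zero-noise cohorts are exactly the planted additive model", {
  coh <- generate_cohort(n_genes = 50, n_tumor = 30, n_normal = 8,
                         layers = list(list(n_genes = 10, n_cols = 10, mu = 2)),
                         mechanism_plan = list(`1` = "M1"),
                         noise_sd = 0, seed = 3)
  expect_equal(max(abs(unclass(coh$expr) - coh$truth$signal)), 0)
})

test_that("a planted layer shifts member cells by exactly mu when noise-free", {
  coh <- generate_cohort(n_genes = 40, n_tumor = 20, n_normal = 4,
                         layers = list(list(n_genes = 8, n_cols = 6, mu = 2)),
                         noise_sd = 0, seed = 5)
  lay <- coh$truth$layers[[1]]
  bg <- coh$truth$signal
  bg[lay$rows, lay$cols] <- bg[lay$rows, lay$cols] - 2
  diff <- unclass(coh$expr)[lay$rows, lay$cols] - bg[lay$rows, lay$cols]
  expect_equal(unname(diff), matrix(2, length(lay$rows), length(lay$cols)))
})

test_that("identical seeds reproduce the cohort exactly; seeds leave no trace", {
  args <- list(n_genes = 60, n_tumor = 40, n_normal = 10,
               layers = list(list(n_genes = 10, n_cols = 15, mu = 2)),
               mechanism_plan = list(`1` = c("M1", "M4")),
               label_plan = list(name = "subtype", values = c("A", "B"),
                                 odds = list(`1` = c(A = 4))),
               seed = 77)
  c1 <- do.call(generate_cohort, args)
  set.seed(1); runif(3)  # unrelated RNG use in between
  c2 <- do.call(generate_cohort, args)
  expect_identical(unclass(c1$expr), unclass(c2$expr))
  expect_identical(c1$clinical, c2$clinical)
})

test_that("overlapping planted columns and non-positive up-shifts are rejected", {
  expect_error(generate_cohort(n_genes = 30, n_tumor = 20, n_normal = 4,
    layers = list(list(rows = 1:5, cols = 1:10, mu = 2),
                  list(rows = 6:10, cols = 8:15, mu = 2)), seed = 1),
    "overlap")
  expect_error(generate_cohort(n_genes = 30, n_tumor = 20, n_normal = 4,
    layers = list(list(n_genes = 5, n_cols = 10, mu = 2)),
    mechanism_plan = list(`1` = "M1"), mech_delta = 0, seed = 1),
    "positive")
})

test_that("planted mechanism truth reflects the rule implications of the calls", {
  coh <- generate_cohort(n_genes = 40, n_tumor = 30, n_normal = 6,
                         layers = list(list(n_genes = 5, n_cols = 10, mu = 2),
                                       list(n_genes = 5, n_cols = 10, mu = 2)),
                         mechanism_plan = list(`1` = "M1", `2` = "M6"),
                         noise_sd = 0, seed = 9)
  # M1 plants TGFB1 up, which also satisfies M5's TGFB1 clause
  expect_setequal(coh$truth$mechanisms[["1"]], c("M1", "M5"))
  # nothing up means ignorance
  expect_identical(coh$truth$mechanisms[["2"]], "M6")
})

test_that("label frequencies converge to the tilted distributions", {
  plan <- list(name = "subtype", values = c("A", "B"),
               base_probs = c(0.5, 0.5), odds = list(`1` = c(A = 3)))
  coh <- generate_cohort(n_genes = 10, n_tumor = 2000, n_normal = 2,
                         layers = list(list(n_genes = 4, n_cols = 1000, mu = 1)),
                         label_plan = plan, noise_sd = 0.5, seed = 21)
  members <- coh$truth$clusters[["1"]]
  lab <- setNames(coh$clinical$label_value, coh$clinical$sample_id)
  p_in <- mean(lab[members] == "A")
  p_out <- mean(lab[setdiff(coh$clinical$sample_id, members)] == "A")
  # planned: 0.75 inside the biased cluster, 0.5 outside (binomial 99.9% bands)
  expect_lt(abs(p_in - 0.75), 3.3 * sqrt(0.75 * 0.25 / 1000))
  expect_lt(abs(p_out - 0.5), 3.3 * sqrt(0.25 / 1000))
})

test_that("recovery_jaccard handles cell sets, plain sets, and degenerate input", {
  expect_equal(recovery_jaccard(list(rows = 1:2, cols = 1:3),
                                list(rows = 1:2, cols = 1:3)), 1)
  expect_equal(recovery_jaccard(list(rows = 1:2, cols = 1),
                                list(rows = 3:4, cols = 2)), 0)
  # cells: overlap 1, union 3
  expect_equal(recovery_jaccard(list(rows = 1:2, cols = 1),
                                list(rows = 2:3, cols = 1)), 1 / 3)
  expect_equal(recovery_jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(recovery_jaccard(integer(), integer()), 0)
})

test_that("written cohorts load back through the standard readers", {
  coh <- generate_cohort(n_genes = 25, n_tumor = 15, n_normal = 5,
                         layers = list(list(n_genes = 5, n_cols = 5, mu = 2)),
                         label_plan = list(name = "subtype", values = c("A", "B")),
                         seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  roles <- utils::read.table(file.path(dir, "sample_roles.tsv"), header = TRUE)
  back <- load_expression(file.path(dir, "expression.tsv"),
                          sample_role = setNames(roles$role, roles$sample_id))
  expect_equal(unclass(back), unclass(coh$expr), tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(sample_roles(back)[1], "tumor")
  cl <- load_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(nrow(cl), 15)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$clusters[["1"]], 5)
})
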