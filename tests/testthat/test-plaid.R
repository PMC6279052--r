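test_that("background layer is the closed-form two-way fit", {
  Y <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  bg <- fit_background(Y)
  expect_equal(bg$mu, 2.5)
  expect_equal(unname(bg$alpha), c(-1, 1))
  expect_equal(unname(bg$beta), c(-0.5, 0.5))
  expect_equal(Y - (bg$mu + outer(bg$alpha, bg$beta, "+")),
               matrix(0, 2, 2))

  const <- fit_background(matrix(7, 3, 4))
  expect_equal(const$mu, 7)
  expect_equal(unname(const$alpha), rep(0, 3))
  expect_equal(unname(const$beta), rep(0, 4))

  shifted <- fit_background(Y + 10)
  expect_equal(shifted$mu, 12.5)
  expect_equal(shifted$alpha, bg$alpha)
  expect_equal(shifted$beta, bg$beta)
})

test_that("layer effects are least-squares two-way means on the submatrix", {
  Z <- matrix(0, 4, 4)
  Z[2:3, 2:3] <- matrix(c(1, 3, 2, 4), 2, 2)
  lay <- estimate_layer_effects(Z, 2:3, 2:3)
  expect_equal(lay$mu, 2.5)
  expect_equal(unname(lay$alpha), c(-1, 1))
  expect_equal(unname(lay$beta), c(-0.5, 0.5))

  Z[2:3, 2:3] <- 5
  lay <- estimate_layer_effects(Z, 2:3, 2:3)
  expect_equal(lay$mu, 5)
  expect_equal(unname(lay$alpha), c(0, 0))

  lay <- estimate_layer_effects(matrix(c(1, 3), 1, 2), 1, 1:2, fit_model = "m")
  expect_equal(lay$mu, 2)
  expect_equal(unname(lay$beta), c(0, 0))
  expect_error(estimate_layer_effects(Z, integer(), 1:2), "empty")
})

test_that("membership updates include matching rows and exclude zero/tied rows", {
  # layer occupies rows 1-2, cols 1-3 with mu = 2; row 3 matches the layer
  # profile, row 4 is all zero (tie against theta = 0 columns is excluded)
  Z <- rbind(c(2, 2, 2, 0), c(2, 2, 2, 0), c(2, 2, 2, 0), c(0, 0, 0, 0))
  lay <- estimate_layer_effects(Z, 1:2, 1:3)
  up <- update_memberships(Z, lay)
  expect_setequal(up$rows, 1:3)   # matching row joins
  expect_false(4 %in% up$rows)    # zero row: inclusion would not reduce SS
  expect_setequal(up$cols, 1:3)   # zero column stays out (tie rule)
})

test_that("release pruning drops weak members relative to the typical one", {
  # rows 1-2 match theta strongly; row 3 contributes nothing
  Z <- rbind(c(3, 3, 3), c(3, 3, 3), c(0, 0, 0))
  lay <- estimate_layer_effects(Z, 1:3, 1:3)
  pruned <- release_prune(Z, lay, 0.7, 0.7)
  expect_setequal(pruned$rows, 1:2)
  expect_setequal(pruned$cols, 1:3)

  # homogeneous layer: all contributions equal the mean, nothing pruned
  Z2 <- matrix(2, 4, 4)
  lay2 <- estimate_layer_effects(Z2, 1:4, 1:4)
  pruned2 <- release_prune(Z2, lay2, 0.7, 0.7)
  expect_setequal(pruned2$rows, 1:4)
  expect_setequal(pruned2$cols, 1:4)
})

test_that("the shuffle importance test accepts planted signal and has an escape hatch", {
  set.seed(10)
  Z <- matrix(rnorm(100 * 100), 100, 100)
  Z[1:10, 1:10] <- Z[1:10, 1:10] + 5
  params <- plaid_params(n_shuffles = 3)
  lay <- estimate_layer_effects(Z, 1:10, 1:10)
  set.seed(11)
  expect_true(layer_importance(Z, lay, params))

  # a weak layer fitted on pure noise is rejected at this seed
  noise <- matrix(rnorm(100 * 100), 100, 100)
  weak <- estimate_layer_effects(noise, 1:5, 1:5)
  set.seed(12)
  expect_false(layer_importance(noise, weak, params))

  expect_true(layer_importance(noise, weak, plaid_params(n_shuffles = 0)))
})

test_that("noise-free planted blocks are recovered exactly", {
  coh <- generate_cohort(n_genes = 80, n_tumor = 60, n_normal = 5,
                         layers = list(list(rows = 11:25, cols = 1:12, mu = 3)),
                         noise_sd = 0, seed = 2)
  Y <- unclass(split_by_role(coh$expr)$tumor)
  fit <- fit_plaid(Y, plaid_params(), seed = 4)
  expect_length(fit$layers, 1)
  found <- list(rows = fit$layers[[1]]$rows, cols = fit$layers[[1]]$cols)
  expect_equal(recovery_jaccard(found, list(rows = 11:25, cols = 1:12)), 1)
})

test_that("a purely additive matrix yields no layers", {
  set.seed(6)
  Y <- 5 + outer(rnorm(40), rnorm(30), "+")
  fit <- fit_plaid(Y, plaid_params(), seed = 8)
  expect_length(fit$layers, 0)
  expect_lt(sum(residuals(fit)^2), 1e-18)
})

test_that("fitting is deterministic given the seed", {
  set.seed(14)
  Y <- matrix(rnorm(60 * 40), 60, 40)
  Y[1:15, 1:10] <- Y[1:15, 1:10] + 3
  f1 <- fit_plaid(Y, plaid_params(), seed = 99)
  f2 <- fit_plaid(Y, plaid_params(), seed = 99)
  expect_identical(f1$layers, f2$layers)
})

test_that("each accepted layer reduces the total residual sum of squares", {
  coh <- standard_cohort(seed = 31, n_genes = 200, n_tumor = 120)
  Y <- unclass(split_by_role(coh$expr)$tumor)
  bg <- fit_background(Y)
  Z <- Y - (bg$mu + outer(bg$alpha, bg$beta, "+"))
  fit <- fit_plaid(Y, plaid_params(), seed = 32)
  expect_gt(length(fit$layers), 0)
  ss <- sum(Z^2)
  for (lay in fit$layers) {
    theta <- lay$mu + outer(lay$alpha, lay$beta, "+")
    Z[lay$rows, lay$cols] <- Z[lay$rows, lay$cols] - theta
    new_ss <- sum(Z^2)
    expect_lt(new_ss, ss)
    ss <- new_ss
  }
  expect_equal(ss, sum(residuals(fit)^2))
})

test_that("fitted + residuals reconstructs the data and methods are consistent", {
  set.seed(15)
  Y <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  Y[1:10, 1:8] <- Y[1:10, 1:8] + 4
  fit <- fit_plaid(Y, plaid_params(), seed = 5)
  expect_equal(fitted(fit) + residuals(fit), Y)
  s <- summary(fit)
  expect_equal(nrow(s$layers), length(fit$layers))
  expect_named(coef(fit), c("mu", "alpha", "beta"))
  path <- withr::local_tempfile(fileext = ".json")
  write_plaid_layers(fit, path)
  dumped <- jsonlite::read_json(path)
  expect_length(dumped, length(fit$layers))
  expect_true(all(vapply(dumped, function(l) isTRUE(l$accepted), logical(1))))
})
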