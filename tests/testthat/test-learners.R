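test_that("MLR attains perfect test metrics on a realizable linear endpoint", {
  ds <- linear_dataset()
  plan <- make_vanilla_folds(ds, K = 5, R = 2, seed = 1)
  res <- run_cross_validation(ds, "Blk", plan, learner_spec("mlr"))
  agg <- aggregate_results(res)
  expect_equal(agg$mean_r2, 1, tolerance = 1e-10)
  expect_lt(agg$mean_rmse, 1e-8)
  expect_equal(agg$n_components, 10) # one per (repetition, fold), seed NA
  expect_false(agg$rank_deficient)
})

test_that("mean test R-squared is near zero when descriptors carry no signal", {
  set.seed(21)
  n <- 400
  x <- data.frame(matrix(rnorm(n * 5), ncol = 5))
  names(x) <- paste0("v", 1:5)
  ds <- qspr_dataset(sprintf("I%04d", 1:n), rnorm(n), x,
                     registry = list(Blk = names(x)),
                     endpoint_kind = "enthalpy")
  plan <- make_vanilla_folds(ds, K = 5, R = 2, seed = 3)
  agg <- aggregate_results(run_cross_validation(ds, "Blk", plan,
                                                learner_spec("mlr")))
  # R^2 = 1 - MSE/Var can be negative; null models sit at or below zero
  expect_lt(agg$mean_r2, 0.05)
  expect_gt(agg$mean_r2, -0.5)
})

test_that("random forests are reproducible per seed and degenerate seeds collapse", {
  sim <- tiny_solubility(n_materials = 10, temps = 3, seed = 8)
  plan <- make_vanilla_folds(sim$dataset, K = 3, R = 1, seed = 5)
  spec5 <- learner_spec("rfr", rfr_n_trees = 50, rfr_seeds = rep(11L, 5))
  res <- run_cross_validation(sim$dataset, c("MolA", "MP", "T"), plan, spec5)
  by_fold <- split(res$components$r2, res$components$fold)
  # identical seeds: zero across-seed variance
  expect_true(all(vapply(by_fold, function(v) diff(range(v)) == 0,
                         logical(1))))
  # same seeds, same run: bit-reproducible
  res2 <- run_cross_validation(sim$dataset, c("MolA", "MP", "T"), plan, spec5)
  expect_identical(res$components, res2$components)
})

test_that("across-seed variance shrinks as the forest grows", {
  sim <- tiny_solubility(n_materials = 12, temps = 3, seed = 12)
  plan <- make_vanilla_folds(sim$dataset, K = 3, R = 1, seed = 2)
  seed_var <- function(ntree) {
    res <- run_cross_validation(
      sim$dataset, c("MolA", "MolB", "MP", "T"), plan,
      learner_spec("rfr", rfr_n_trees = ntree, rfr_seeds = 1:5))
    mean(tapply(res$components$r2, res$components$fold, var))
  }
  expect_lt(seed_var(500), seed_var(20))
})

test_that("rank-deficient linear designs fall back to minimum-norm solutions", {
  set.seed(9)
  x <- matrix(rnorm(20), ncol = 2)
  x3 <- cbind(x, x[, 1]) # duplicated column
  y <- x %*% c(1, -2) + rnorm(10, 0, 0.01)
  fit <- fit_mlr(x3, y)
  expect_true(fit$rank_deficient)
  mags <- coefficient_magnitudes(fit)
  expect_true(attr(mags, "collinear"))
  # minimum-norm solution splits the duplicated coefficient evenly
  expect_equal(unname(mags[1]), unname(mags[3]), tolerance = 1e-6)
  # predictions still least-squares optimal
  expect_equal(drop(predict(fit, x3)), drop(predict(fit_mlr(x, y), x)),
               tolerance = 1e-6)
  # p > n design: fits rather than errors
  xw <- matrix(rnorm(5 * 12), nrow = 5)
  fitw <- fit_mlr(xw, rnorm(5))
  expect_true(fitw$rank_deficient)
  expect_true(all(is.finite(fitw$coefficients)))
})

test_that("coefficient magnitudes recover known slopes on scaled descriptors", {
  set.seed(15)
  x <- matrix(runif(200), ncol = 2)
  sc <- range_scale(x)
  y <- 2 * sc$train[, 1]
  fit <- fit_mlr(sc$train, y)
  mags <- coefficient_magnitudes(fit)
  expect_equal(unname(mags[1]), 2, tolerance = 1e-8)
  expect_lt(unname(mags[2]), 1e-8)
  # invariant to permuting row order
  p <- sample(nrow(x))
  mags2 <- coefficient_magnitudes(fit_mlr(sc$train[p, ], y[p]))
  expect_equal(unname(mags), unname(mags2), tolerance = 1e-8)
})

test_that("permutation importance ranks a perfect descriptor first", {
  set.seed(33)
  n <- 150
  x <- cbind(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), const = 1)
  y <- x[, "sig"]
  fit <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = 200,
                        seed = 1, num.threads = 1)
  imp <- permutation_importance(fit, x, y, n_permutations = 10, seed = 4)
  expect_equal(names(which.max(imp)), "sig")
  # constant column: permutation changes nothing
  expect_equal(unname(imp["const"]), 0)
  # invariance to column order up to relabeling
  x2 <- x[, c(3, 1, 4, 2)]
  fit2 <- ranger::ranger(x = as.data.frame(x2), y = y, num.trees = 200,
                         seed = 1, num.threads = 1)
  imp2 <- permutation_importance(fit2, x2, y, n_permutations = 10, seed = 4)
  expect_equal(names(which.max(imp2)), "sig")
  # directional cross-check against ranger's own permutation importance
  fit3 <- ranger::ranger(x = as.data.frame(x), y = y, num.trees = 200,
                         seed = 1, num.threads = 1,
                         importance = "permutation")
  expect_equal(names(which.max(fit3$variable.importance)), "sig")
})

test_that("seed-averaged final-model importance singles out informative blocks", {
  sim <- tiny_enthalpy(n_materials = 120, beta_scale = 0.9, noise_sd = 0.5,
                       seed = 44)
  imp <- final_model_importance(sim$dataset, c("MolA", "MolB"),
                                learner_spec("rfr", rfr_n_trees = 100))
  inf_names <- sim$dataset$registry$MolA
  noise_names <- sim$dataset$registry$MolB
  expect_gt(mean(imp[inf_names]), mean(imp[noise_names]))
})

test_that("aggregation is a plain arithmetic mean over components", {
  res <- structure(list(components = data.frame(
    repetition = 1, fold = 1:2, seed = NA, r2 = c(0.5, 0.7),
    rmse = c(1, 3)), rank_deficient = FALSE), class = "cv_result")
  agg <- aggregate_results(res)
  expect_equal(agg$mean_r2, 0.6)
  expect_equal(agg$mean_rmse, 2)
  # aggregate of aggregates equals aggregate of flattened components when
  # groups are equal-weight
  g1 <- mean(c(0.5, 0.7)); g2 <- mean(c(0.1, 0.3))
  expect_equal(mean(c(g1, g2)), mean(c(0.5, 0.7, 0.1, 0.3)))
})

test_that("nonlinear signal favours forests and linear signal favours MLR", {
  run_both <- function(nonlin) {
    sim <- simulate_qspr_dataset(sim_config(
      n_materials = 80, endpoint_kind = "enthalpy", noise_sd = 0.5,
      beta_scale = 0.95, nonlinear_weight = nonlin,
      n_informative = 4, n_noise = 2, seed = 55))
    plan <- make_vanilla_folds(sim$dataset, K = 5, R = 1, seed = 6)
    vapply(list(mlr = learner_spec("mlr"),
                rfr = learner_spec("rfr", rfr_n_trees = 200)),
           function(l) aggregate_results(
             run_cross_validation(sim$dataset, c("MolA", "MolB"), plan,
                                  l))$mean_rmse,
           numeric(1))
  }
  lin <- run_both(0)
  nl <- run_both(2)
  expect_lt(lin["mlr"], lin["rfr"]) # purely linear: MLR wins
  expect_lt(nl["rfr"], nl["mlr"])   # strong quadratic: RFR wins
})

test_that("the feature-selection stage sees only training rows", {
  sim <- tiny_solubility(n_materials = 10, temps = 3, seed = 66)
  plan <- make_vanilla_folds(sim$dataset, K = 3, R = 1, seed = 1)
  n_total <- nrow(sim$dataset$instances)
  seen <- integer(0)
  spy <- function(x_train, y_train) {
    seen <<- c(seen, nrow(x_train))
    expect_lt(nrow(x_train), n_total)
    seq_len(ncol(x_train))
  }
  invisible(run_cross_validation(sim$dataset, c("MolA", "MolB", "T"), plan,
                                 learner_spec("mlr"), feature_select = spy))
  expect_equal(length(seen), 3) # once per fold
  expect_true(all(seen < n_total))
})
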