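test_that("metrics match hand evaluation and handle degenerate cases", {
  y <- c(1, 2, 3)
  m <- compute_metrics(y, y)
  expect_equal(m$rmse, 0)
  expect_equal(m$r2, 1)
  # predicting the mean gives R^2 exactly 0
  m <- compute_metrics(y, rep(mean(y), 3))
  expect_equal(m$r2, 0)
  # hand case: mse = 1, population var = 1
  m <- compute_metrics(c(0, 2), c(1, 1))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0)
  # zero test variance: r2 undefined, rmse still valid
  m <- compute_metrics(c(2, 2), c(1, 3))
  expect_true(is.na(m$r2))
  expect_equal(m$rmse, 1)
})

test_that("the two algebraic forms of R-squared agree to machine precision", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(3:30, 1)
    y <- rnorm(n)
    p <- rnorm(n)
    r2 <- compute_metrics(y, p)$r2
    r2_resid <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
    expect_equal(r2, r2_resid, tolerance = 1e-12)
  }
})

test_that("model ranking follows the RMSE-same-folds / R2-cross-dataset rule", {
  s <- data.frame(label = c("B", "A"),
                  mean_r2 = c(0.92, 0.85), mean_rmse = c(0.70, 0.83))
  r <- rank_models(s, "same-folds")
  expect_equal(r$label[1], "B") # lower RMSE ranks first
  r <- rank_models(s, "cross-dataset")
  expect_equal(r$label[1], "B") # higher R2 ranks first
  # deterministic label tie-break
  s2 <- data.frame(label = c("z", "a"), mean_r2 = c(0.5, 0.5),
                   mean_rmse = c(1, 1))
  expect_equal(rank_models(s2, "same-folds")$label, c("a", "z"))
  # rule enforcement: RMSE is not comparable across datasets
  expect_error(rank_models(s, "cross-dataset", metric = "rmse"),
               "cross-dataset")
  expect_error(rank_models(s, "same-folds", metric = "r2"), "same-folds")
})

test_that("paired comparison detects shifts and degenerates gracefully", {
  # identical vectors: zero difference, not significant
  v <- rnorm(25)
  out <- paired_comparison(list(list(label = "same", a = v, b = v)))
  expect_equal(out$mean_diff, 0)
  expect_equal(out$p_raw, 1)
  expect_false(out$significant)
  # a clear shift over 25 aligned components is flagged after adjustment
  set.seed(88)
  a <- rnorm(25, 0, 0.1)
  b <- a + rnorm(25, 0.5, 0.1)
  out <- paired_comparison(list(list(label = "shift", a = b, b = a)))
  expect_gt(out$mean_diff, 0.3)
  expect_true(out$significant)
  expect_error(paired_comparison(list(list(a = 1:3, b = 1:4))))
})

test_that("Holm adjustment is monotone, conservative, and controls the family", {
  set.seed(99)
  p_raw <- runif(8, 0, 0.2)
  out <- paired_comparison(lapply(seq_along(p_raw), function(i) {
    # build pairs whose t-test p is irrelevant; check adjustment contract
    list(label = as.character(i), a = rnorm(10), b = rnorm(10))
  }))
  expect_true(all(out$p_adj >= out$p_raw))
  ord <- order(out$p_raw)
  expect_true(all(diff(out$p_adj[ord]) >= -1e-15))
  expect_equal(out$p_adj, p.adjust(out$p_raw, "holm"))
})

test_that("scenario pairing emits each single-factor pair exactly once", {
  cat <- expand.grid(dataset = "d1", two_d = "all", mp = c(TRUE, FALSE),
                     le = c(TRUE, FALSE), threeD = "none", fs = "off",
                     learner = c("mlr", "rfr"), protocol = c("v", "rt"),
                     stringsAsFactors = FALSE)
  cat$result_id <- sprintf("r%02d", seq_len(nrow(cat)))
  scen <- build_scenario_pairs(cat)
  # LE in/out: one pair per combination of the 3 other varying factors
  expect_equal(nrow(scen$lattice_energy_in_out), 8)
  expect_equal(nrow(scen$melting_point_in_out), 8)
  expect_equal(nrow(scen$cv_v_vs_cv_rt), 8)
  expect_null(scen$crystal_vs_conformer_3d)
  expect_null(scen$feature_selection_on_off)
  # brute-force scan: every emitted pair differs in exactly one factor
  factors <- c("dataset", "two_d", "mp", "le", "threeD", "fs", "learner",
               "protocol")
  for (nm in names(scen)) {
    sp <- scen[[nm]]
    if (is.null(sp)) next
    for (i in seq_len(nrow(sp))) {
      a <- cat[cat$result_id == sp$result_a[i], factors]
      b <- cat[cat$result_id == sp$result_b[i], factors]
      expect_equal(sum(mapply(function(x, y) !identical(x, y), a, b)), 1)
    }
  }
  # no pair appears twice
  keys <- unlist(lapply(scen, function(s) paste(s$result_a, s$result_b)))
  expect_false(anyDuplicated(keys) > 0)
  # models lacking a partner are excluded silently
  scen2 <- build_scenario_pairs(cat[-1, ])
  expect_equal(nrow(scen2$lattice_energy_in_out), 7)
  # duplicate factor rows are an error
  expect_error(build_scenario_pairs(rbind(cat, cat[1, ])), "duplicate")
})

test_that("the CV scenario compares R-squared and others compare RMSE", {
  cat <- data.frame(dataset = "d", two_d = "all", mp = TRUE,
                    le = c(TRUE, FALSE), threeD = "none", fs = "off",
                    learner = "rfr", protocol = "rt",
                    result_id = c("le_in", "le_out"),
                    stringsAsFactors = FALSE)
  scen <- build_scenario_pairs(cat)
  expect_equal(scen$lattice_energy_in_out$metric, "rmse")
  cat$le <- TRUE
  cat$protocol <- c("v", "rt")
  cat$result_id <- c("v", "rt")
  scen <- build_scenario_pairs(cat)
  expect_equal(scen$cv_v_vs_cv_rt$metric, "r2")
  # pairing is oriented: v (or factor "on") first
  expect_equal(scen$cv_v_vs_cv_rt$result_a, "v")
})
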