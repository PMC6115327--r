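six_subset_registry <- function() {
  blocks <- lapply(1:6, function(i) sprintf("S%d_%02d", i, 1:3))
  names(blocks) <- paste0("Sub", 1:6)
  c(blocks, list(MP = "MP", LE = "LE", T = "T"))
}

test_that("combination enumeration follows the with/without rules", {
  reg <- six_subset_registry()
  # six explicit 2D subsets, non-crystal: each subset x {+/- MP} = 12
  sets <- as.list(paste0("Sub", 1:6))
  combos <- enumerate_descriptor_combinations(reg, "solubility",
                                              crystal_integrated = FALSE,
                                              two_d_sets = sets)
  expect_length(combos, 12)
  # the temperature block rides along for solubility
  expect_true(all(vapply(combos, function(cb) "T" %in% cb$blocks,
                         logical(1))))
  # crystal dataset: every non-crystal combination also appears with +LE
  combos_cs <- enumerate_descriptor_combinations(reg, "solubility",
                                                 crystal_integrated = TRUE,
                                                 two_d_sets = sets)
  labels <- vapply(combos_cs, `[[`, character(1), "label")
  plain <- vapply(combos, `[[`, character(1), "label")
  expect_true(all(plain %in% labels))
  expect_true(all(paste(plain, "+LE") %in% labels))
  # enthalpy endpoint: no T block anywhere
  combos_e <- enumerate_descriptor_combinations(reg, "enthalpy",
                                                crystal_integrated = FALSE,
                                                two_d_sets = sets)
  expect_false(any(vapply(combos_e, function(cb) "T" %in% cb$blocks,
                          logical(1))))
})

test_that("3D descriptors attach only to the combined 2D set", {
  reg <- c(six_subset_registry(),
           list(X3D_crystal = paste0("C3_", 1:2),
                X3D_conformer = paste0("G3_", 1:2)))
  combos <- enumerate_descriptor_combinations(reg, "solubility",
                                              crystal_integrated = TRUE)
  with3d <- Filter(function(cb) cb$threeD != "none", combos)
  expect_gt(length(with3d), 0)
  combined <- paste0("Sub", 1:6)
  for (cb in with3d) {
    if (cb$threeD_mode == "add") {
      expect_true(all(combined %in% cb$blocks))
    } else {
      expect_false(any(combined %in% cb$blocks)) # substitution
    }
  }
  # no single-subset + 3D combination exists (brute-force scan)
  single_with_3d <- Filter(function(cb) {
    cb$threeD != "none" && length(intersect(cb$blocks, combined)) %in% 1:5
  }, combos)
  expect_length(single_with_3d, 0)
  # labels are unique and deterministic across calls
  l1 <- vapply(combos, `[[`, character(1), "label")
  l2 <- vapply(enumerate_descriptor_combinations(reg, "solubility", TRUE),
               `[[`, character(1), "label")
  expect_identical(l1, l2)
  expect_false(anyDuplicated(l1) > 0)
})

test_that("a small experiment matrix produces the full crossing and is reproducible", {
  sim <- tiny_solubility(n_materials = 10, temps = 3, seed = 14,
                         n_informative = 4, n_noise = 2)
  combos <- list(
    list(blocks = c("MolA", "T"), two_d = "MolA", mp = FALSE, le = FALSE,
         threeD = "none", threeD_mode = "none", label = "MolA"),
    list(blocks = c("MolA", "MP", "T"), two_d = "MolA", mp = TRUE,
         le = FALSE, threeD = "none", threeD_mode = "none",
         label = "MolA +MP"))
  learners <- list(mlr = learner_spec("mlr"),
                   rfr = learner_spec("rfr", rfr_n_trees = 30))
  m <- run_experiment_matrix(list(synth = sim$dataset), learners = learners,
                             protocols = c("v", "rt"), K = 3, R = 2,
                             seed = 10, combinations = list(synth = combos))
  # 1 dataset x 2 combinations x 2 learners x 2 protocols = 8 summary rows
  expect_equal(nrow(m$catalogue), 8)
  # component rows: MLR 6 folds, RFR 6 folds x 5 seeds, per combo/protocol
  expect_equal(nrow(m$components), 2 * 2 * (6 + 30))
  # means in the catalogue are recomputable from the long format
  for (i in seq_len(nrow(m$catalogue))) {
    rid <- m$catalogue$result_id[i]
    comp <- m$components[m$components$result_id == rid, ]
    expect_equal(m$catalogue$mean_rmse[i], mean(comp$rmse))
    expect_equal(m$catalogue$mean_r2[i], mean(comp$r2, na.rm = TRUE))
  }
  # rankings regenerate from the catalogue alone
  expect_equal(length(m$rankings), 2) # per dataset x protocol
  for (r in m$rankings) expect_equal(r$rank, seq_len(nrow(r)))
  # scenario comparisons cover the varying factors
  expect_true(all(c("melting_point_in_out", "cv_v_vs_cv_rt") %in%
                    names(m$comparisons)))
  # byte-identical rerun
  m2 <- run_experiment_matrix(list(synth = sim$dataset),
                              learners = learners, protocols = c("v", "rt"),
                              K = 3, R = 2, seed = 10,
                              combinations = list(synth = combos))
  expect_identical(m$catalogue, m2$catalogue)
})

test_that("lattice-energy surrogate modelling flags injected extreme outliers", {
  cfg <- sim_config(n_materials = 120, endpoint_kind = "enthalpy",
                    n_informative = 2, n_noise = 2,
                    le_descriptor_strength = 1, crystal_integrated = TRUE,
                    seed = 91)
  sim <- simulate_qspr_dataset(cfg)
  ds <- sim$dataset
  # one material is given the extreme lattice energy analogue
  victim <- ds$instances$material_key[7]
  ds$descriptors$LE[ds$instances$material_key == victim] <-
    kcal_to_kj(-2735.71)
  out <- lattice_energy_surrogate_analysis(
    ds, K = 5, R = 2, seed = 6, learner = learner_spec("rfr",
                                                       rfr_n_trees = 100))
  expect_true(victim %in% out$flagged)
  expect_equal(out$threshold_kj, 209.2)
  expect_gt(out$summary_filtered$mean_r2, out$summary$mean_r2)
  expect_error(
    lattice_energy_surrogate_analysis(
      simulate_qspr_dataset(sim_config(crystal_integrated = FALSE,
                                       n_materials = 10))$dataset),
    "LE")
})

test_that("lattice energy unrelated to descriptors yields null surrogate skill", {
  cfg <- sim_config(n_materials = 150, endpoint_kind = "enthalpy",
                    le_descriptor_strength = 0, crystal_integrated = TRUE,
                    seed = 92)
  sim <- simulate_qspr_dataset(cfg)
  out <- lattice_energy_surrogate_analysis(
    sim$dataset, K = 5, R = 1, seed = 2,
    learner = learner_spec("rfr", rfr_n_trees = 100),
    rerun_without_outliers = FALSE)
  expect_lt(out$summary$mean_r2, 0.1)
})

test_that("melting point deviation statistics match a brute-force oracle", {
  s <- melting_point_deviation_stats(c(400, 401, 300), c(399, 399, 385))
  expect_equal(s$median_abs, 2)
  expect_equal(s$max_abs, 85)
  # independent sort-based oracle on 17 random pairs
  set.seed(123)
  ref <- runif(17, 300, 500)
  desc <- ref + rnorm(17, 0, 20)
  s <- melting_point_deviation_stats(ref, desc)
  dev <- sort(abs(ref - desc))
  expect_equal(s$n, 17)
  expect_equal(s$median_abs, dev[9])
  h <- (17 - 1) * 0.95 + 1 # linear-interpolation percentile position
  expect_equal(s$p95_abs,
               dev[floor(h)] + (h - floor(h)) * (dev[floor(h) + 1] - dev[floor(h)]))
  expect_equal(s$max_abs, dev[17])
  # identical sources: all zeros
  s0 <- melting_point_deviation_stats(c(1, 2), c(1, 2))
  expect_equal(unlist(s0[c("median_abs", "p95_abs", "max_abs")]),
               c(median_abs = 0, p95_abs = 0, max_abs = 0))
  # range references collapse to their mean first
  s1 <- melting_point_deviation_stats(cbind(c(390, 400), c(410, 420)),
                                      c(400, 412))
  expect_equal(s1$median_abs, mean(c(0, 2)))
})
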