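# block names with reserved meaning; everything else in a registry is a 2D
# molecular descriptor subset
SPECIAL_BLOCKS <- c("MP", "LE", "T", "X3D_crystal", "X3D_conformer")

#' Enumerate the descriptor combinations of the experiment matrix
#'
#' Combinations are built from the registry's 2D molecular descriptor
#' subsets: by default each subset alone plus the combined pool of all
#' subsets, each with and without the melting point descriptor, always with
#' the inverse-temperature descriptor for solubility endpoints. For
#' crystal-structure integrated datasets the same combinations are emitted
#' with and without the lattice energy descriptor and, when 3D blocks exist,
#' the 3D descriptors are added to every combination involving the combined
#' 2D set, or substituted for it — separately for the crystal-derived and
#' conformer-derived variants. 3D blocks are never combined with single 2D
#' subsets. Order is deterministic.
#'
#' @param registry Descriptor registry of a `qspr_dataset`.
#' @param endpoint_kind `"solubility"` or `"enthalpy"`.
#' @param crystal_integrated Logical; lattice energy / 3D combinations
#'   apply.
#' @param two_d_sets Optional explicit list of character vectors of 2D
#'   subset block names (each one "combination of 2D descriptors").
#' @return List of combination descriptors: `blocks`, `two_d`, `mp`, `le`,
#'   `threeD` (`"none"`, `"crystal"`, `"conformer"`), `threeD_mode`
#'   (`"none"`, `"add"`, `"only"`), `label`.
#' @export
enumerate_descriptor_combinations <- function(registry,
                                              endpoint_kind = "solubility",
                                              crystal_integrated = FALSE,
                                              two_d_sets = NULL) {
  two_d_blocks <- setdiff(names(registry), SPECIAL_BLOCKS)
  if (length(two_d_blocks) == 0L) stop("registry has no 2D descriptor blocks")
  if (is.null(two_d_sets)) {
    two_d_sets <- as.list(two_d_blocks)
    if (length(two_d_blocks) > 1L) {
      two_d_sets <- c(two_d_sets, list(two_d_blocks))
    }
  }
  combined <- two_d_blocks
  has_3d <- crystal_integrated &&
    all(c("X3D_crystal", "X3D_conformer") %in% names(registry))
  le_opts <- if (crystal_integrated && "LE" %in% names(registry)) {
    c(FALSE, TRUE)
  } else {
    FALSE
  }
  t_block <- if (endpoint_kind == "solubility") "T" else character(0)
  combos <- list()
  emit <- function(two_d_set, mp, le, threeD, threeD_mode) {
    blocks <- character(0)
    if (threeD_mode != "only") blocks <- two_d_set
    if (threeD != "none") blocks <- c(blocks, paste0("X3D_", threeD))
    if (mp) blocks <- c(blocks, "MP")
    if (le) blocks <- c(blocks, "LE")
    blocks <- c(blocks, t_block)
    two_d_label <- if (threeD_mode == "only") {
      "(none)"
    } else {
      paste(two_d_set, collapse = "+")
    }
    label <- paste0(two_d_label,
                    if (threeD != "none") paste0(" 3D=", threeD, "(", threeD_mode, ")"),
                    if (mp) " +MP", if (le) " +LE")
    combos[[length(combos) + 1L]] <<- list(
      blocks = blocks, two_d = two_d_label, mp = mp, le = le,
      threeD = threeD, threeD_mode = threeD_mode, label = trimws(label))
  }
  for (set in two_d_sets) {
    for (mp in c(FALSE, TRUE)) {
      for (le in le_opts) {
        emit(set, mp, le, "none", "none")
        if (has_3d && setequal(set, combined)) {
          for (src in c("crystal", "conformer")) {
            emit(set, mp, le, src, "add")
            emit(set, mp, le, src, "only")
          }
        }
      }
    }
  }
  # substitution ("only") combinations coincide across 2D sets; dedupe
  labels <- vapply(combos, `[[`, character(1), "label")
  combos[!duplicated(labels)]
}

#' Correlation-filter feature selection stage
#'
#' A simple default plugin for the pluggable selection stage: keeps the
#' `n_keep` descriptors with the largest absolute Pearson correlation with
#' the training endpoint (constant columns rank last).
#'
#' @param n_keep Number of descriptors to retain.
#' @return A `function(x_train, y_train)` returning column indices.
#' @export
correlation_filter <- function(n_keep = 50L) {
  force(n_keep)
  function(x_train, y_train) {
    r <- suppressWarnings(abs(stats::cor(x_train, y_train)))
    r[is.na(r)] <- -Inf
    order(r, decreasing = TRUE)[seq_len(min(n_keep, ncol(x_train)))]
  }
}

#' Run the full experiment matrix
#'
#' Executes cross-validation for every dataset x descriptor combination x
#' learner x protocol cell (the remove-temperature protocol applies only to
#' solubility datasets), reusing one fold plan per dataset and protocol so
#' that same-fold comparisons are paired. Emits long-format components, a
#' summary catalogue, per-(dataset, protocol) rankings by mean RMSE, and the
#' paired significance analysis over the key comparison scenarios. Cell
#' failures are recorded and the matrix continues.
#'
#' @param datasets Named list of `qspr_dataset` objects.
#' @param learners Named list of [learner_spec()] objects (default MLR and
#'   RFR with defaults).
#' @param protocols Protocols to run (`"v"`, `"rt"`).
#' @param K,R,seed Fold-plan settings.
#' @param combinations Optional explicit combination list per dataset name;
#'   default [enumerate_descriptor_combinations()] on each registry.
#' @param feature_selection `"off"` or a selection function as accepted by
#'   [run_cross_validation()]; when a function is given, combinations using
#'   the combined 2D set (without 3D blocks) are additionally run with
#'   selection on.
#' @return List: `catalogue` (one row per cell with mean metrics and factor
#'   labels), `components` (long format), `rankings`, `comparisons`,
#'   `failures`.
#' @export
run_experiment_matrix <- function(datasets,
                                  learners = list(
                                    mlr = learner_spec("mlr"),
                                    rfr = learner_spec("rfr")),
                                  protocols = c("v", "rt"),
                                  K = 5L, R = 5L, seed = 1L,
                                  combinations = NULL,
                                  feature_selection = "off") {
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  catalogue <- list()
  components <- list()
  failures <- list()
  store <- list() # per-result component vectors for paired comparisons
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    ds_protocols <- protocols
    if (ds$endpoint_kind != "solubility") {
      ds_protocols <- setdiff(ds_protocols, "rt")
    }
    combos <- if (!is.null(combinations)) {
      combinations[[ds_name]] %||% combinations
    } else {
      crystal <- "LE" %in% names(ds$registry)
      enumerate_descriptor_combinations(ds$registry, ds$endpoint_kind,
                                        crystal_integrated = crystal)
    }
    plans <- lapply(stats::setNames(ds_protocols, ds_protocols), function(p) {
      if (p == "v") make_vanilla_folds(ds, K, R, seed)
      else make_rt_folds(ds, K, R, seed)
    })
    two_d_blocks <- setdiff(names(ds$registry), SPECIAL_BLOCKS)
    for (proto in ds_protocols) {
      for (ln in names(learners)) {
        for (cb in combos) {
          fs_variants <- list(off = NULL)
          if (is.function(feature_selection) &&
              cb$threeD == "none" && setequal(
                intersect(cb$blocks, two_d_blocks), two_d_blocks)) {
            fs_variants$on <- feature_selection
          }
          for (fs in names(fs_variants)) {
            rid <- paste(c(ds_name, proto, ln, cb$label,
                           if (fs == "on") "fs"), collapse = " | ")
            res <- tryCatch(
              run_cross_validation(ds, cb$blocks, plans[[proto]],
                                   learners[[ln]],
                                   feature_select = fs_variants[[fs]]),
              error = function(e) e)
            if (inherits(res, "error")) {
              failures[[length(failures) + 1L]] <- data.frame(
                result_id = rid, message = conditionMessage(res),
                stringsAsFactors = FALSE)
              next
            }
            agg <- aggregate_results(res)
            store[[rid]] <- res$components
            catalogue[[length(catalogue) + 1L]] <- data.frame(
              result_id = rid, dataset = ds_name, two_d = cb$two_d,
              mp = cb$mp, le = cb$le, threeD = cb$threeD, fs = fs,
              learner = ln, protocol = proto,
              mean_r2 = agg$mean_r2, mean_rmse = agg$mean_rmse,
              n_components = agg$n_components,
              rank_deficient = agg$rank_deficient,
              stringsAsFactors = FALSE)
            comp <- res$components
            comp$result_id <- rid
            components[[length(components) + 1L]] <- comp
          }
        }
      }
    }
  }
  catalogue <- do.call(rbind, catalogue)
  components <- do.call(rbind, components)
  rankings <- lapply(split(catalogue,
                           paste(catalogue$dataset, catalogue$protocol)),
                     function(d) {
                       d$label <- d$result_id
                       rank_models(d, context = "same-folds")
                     })
  comparisons <- run_scenario_comparisons(catalogue, store)
  list(catalogue = catalogue, components = components, rankings = rankings,
       comparisons = comparisons,
       failures = if (length(failures)) do.call(rbind, failures))
}

# assemble paired metric vectors for each key scenario and run the paired
# significance analysis
run_scenario_comparisons <- function(catalogue, store) {
  scen <- build_scenario_pairs(catalogue)
  out <- list()
  for (nm in names(scen)) {
    sp <- scen[[nm]]
    if (is.null(sp) || nrow(sp) == 0L) next
    pairs <- lapply(seq_len(nrow(sp)), function(i) {
      metric <- sp$metric[i]
      a <- store[[sp$result_a[i]]][[metric]]
      b <- store[[sp$result_b[i]]][[metric]]
      keep <- stats::complete.cases(a, b)
      list(label = sp$label[i], a = a[keep], b = b[keep])
    })
    out[[nm]] <- paired_comparison(pairs)
  }
  out
}

#' Cross-validated surrogate modelling of the lattice energy descriptor
#'
#' Builds seed-averaged random forest models predicting the lattice energy
#' from the combined 2D molecular descriptors, under repeated stratified
#' K-fold cross-validation at the material level (repeated material
#' occurrences from multiple temperatures are removed first). Instances
#' whose mean absolute cross-validated prediction error exceeds the
#' threshold (50 kcal/mol = 209.2 kJ/mol by default) are flagged as
#' prediction outliers, and the analysis is optionally rerun without them.
#'
#' @param dataset A `qspr_dataset` whose registry has an `LE` block.
#' @param K,R,seed Fold-plan settings.
#' @param learner Learner (default seed-averaged RFR).
#' @param threshold_kj Outlier threshold on absolute prediction error
#'   (kJ/mol).
#' @param rerun_without_outliers Rerun with flagged instances removed.
#' @return List: `summary` (aggregate of the full run), `errors`
#'   (per-instance mean absolute CV error), `flagged` (instance ids),
#'   `summary_filtered` (or `NULL`), `threshold_kj`.
#' @export
lattice_energy_surrogate_analysis <- function(dataset, K = 5L, R = 5L,
                                              seed = 1L,
                                              learner = learner_spec("rfr"),
                                              threshold_kj = kcal_to_kj(50),
                                              rerun_without_outliers = TRUE) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  if (!"LE" %in% names(dataset$registry)) {
    stop("dataset has no lattice energy (LE) descriptor block")
  }
  keep <- !duplicated(dataset$instances$material_key)
  two_d <- setdiff(names(dataset$registry), SPECIAL_BLOCKS)
  cols <- unlist(dataset$registry[two_d], use.names = FALSE)
  build <- function(rows) {
    qspr_dataset(dataset$instances$material_key[rows],
                 dataset$descriptors[rows, dataset$registry$LE],
                 dataset$descriptors[rows, cols, drop = FALSE],
                 registry = dataset$registry[two_d],
                 endpoint_kind = "enthalpy", units = "kJ/mol")
  }
  run <- function(ds) {
    plan <- make_vanilla_folds(ds, K, R, seed)
    run_cross_validation(ds, two_d, plan, learner, store_predictions = TRUE)
  }
  ds_mat <- build(which(keep))
  res <- run(ds_mat)
  pr <- res$predictions
  abs_err <- tapply(abs(pr$y_true - pr$y_pred), pr$instance_id, mean)
  flagged <- names(abs_err)[abs_err > threshold_kj]
  summary_filtered <- NULL
  if (rerun_without_outliers && length(flagged)) {
    rows <- which(keep)[!ds_mat$instances$instance_id %in% flagged]
    summary_filtered <- aggregate_results(run(build(rows)))
  }
  list(summary = aggregate_results(res),
       errors = abs_err,
       flagged = flagged,
       summary_filtered = summary_filtered,
       threshold_kj = threshold_kj)
}

#' Deviation statistics between two sources of melting point data
#'
#' Summarises absolute deviations between reference melting points (for
#' example crystal-structure specific values) and the melting point
#' descriptor values: count, median, 95th percentile (linear interpolation)
#' and maximum, all in Kelvin. A reference given as a range (two-column
#' matrix) is collapsed to its mean first.
#'
#' @param reference Numeric vector of reference melting points (K), or a
#'   two-column matrix of ranges.
#' @param descriptor Numeric vector of melting point descriptor values (K).
#' @return List: `n`, `median_abs`, `p95_abs`, `max_abs`.
#' @export
melting_point_deviation_stats <- function(reference, descriptor) {
  if (is.matrix(reference)) reference <- rowMeans(reference)
  stopifnot(length(reference) == length(descriptor), length(reference) >= 1L,
            all(is.finite(reference)), all(is.finite(descriptor)))
  dev <- abs(reference - descriptor)
  list(n = length(dev),
       median_abs = stats::median(dev),
       p95_abs = unname(stats::quantile(dev, 0.95, type = 7)),
       max_abs = max(dev))
}

#' Replicated comparison of CV=v and CV=rt performance estimates
#'
#' For each replicate: simulate a solubility dataset (fresh derived seed),
#' build vanilla and remove-temperature fold plans, cross-validate the same
#' learner on both, and record the mean test R-squared under each protocol.
#' With replicated temperatures per material and material-level signal, the
#' vanilla protocol lets materials leak across train/test folds and its
#' R-squared estimate is inflated relative to the grouped protocol.
#'
#' @param n_replicates Number of simulation replicates.
#' @param config Simulation configuration (the replicate seed is derived
#'   from `seed`, overriding `config$seed`).
#' @param learner Learner to evaluate (default RFR with 100 trees: forest
#'   size does not affect the leakage comparison).
#' @param blocks Descriptor blocks to model on (default: all non-3D blocks).
#' @param K,R Fold-plan settings.
#' @param seed Master seed.
#' @return data.frame: `replicate`, `r2_v`, `r2_rt`, `inflated`
#'   (`r2_v > r2_rt`).
#' @export
cv_inflation_study <- function(n_replicates = 20L,
                               config = sim_config(),
                               learner = learner_spec("rfr",
                                                      rfr_n_trees = 100L),
                               blocks = NULL, K = 5L, R = 5L, seed = 1L) {
  stopifnot(config$endpoint_kind == "solubility")
  rows <- lapply(seq_len(n_replicates), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, i)
    sim <- simulate_qspr_dataset(cfg)
    ds <- sim$dataset
    b <- blocks %||% setdiff(names(ds$registry),
                             c("X3D_crystal", "X3D_conformer"))
    plan_v <- make_vanilla_folds(ds, K, R, derive_seed(seed, 1000L + i))
    plan_rt <- make_rt_folds(ds, K, R, derive_seed(seed, 2000L + i))
    r2_v <- aggregate_results(
      run_cross_validation(ds, b, plan_v, learner))$mean_r2
    r2_rt <- aggregate_results(
      run_cross_validation(ds, b, plan_rt, learner))$mean_r2
    data.frame(replicate = i, r2_v = r2_v, r2_rt = r2_rt,
               inflated = r2_v > r2_rt)
  })
  do.call(rbind, rows)
}
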