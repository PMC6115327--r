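#' Learner specification
#'
#' Two learners are supported: ordinary multiple linear regression (`"mlr"`)
#' and random forest regression (`"rfr"`). Random forests are built once per
#' seed (five seeds by default) with each tree grown on a without-replacement
#' sample of the training rows rather than a bootstrap; all statistics and
#' importances are later averaged (arithmetic mean) across these seeds.
#'
#' @param kind `"mlr"` or `"rfr"`.
#' @param rfr_n_trees Trees per forest (default 500).
#' @param rfr_sample_fraction Fraction of training rows drawn without
#'   replacement per tree (default 0.632).
#' @param rfr_seeds Integer seeds for the seed-averaging convention
#'   (default 1:5).
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(kind = c("mlr", "rfr"), rfr_n_trees = 500L,
                         rfr_sample_fraction = 0.632, rfr_seeds = 1:5) {
  kind <- match.arg(kind)
  stopifnot(rfr_sample_fraction > 0, rfr_sample_fraction <= 1,
            is_count(rfr_n_trees), length(rfr_seeds) >= 1L)
  structure(list(kind = kind, rfr_n_trees = as.integer(rfr_n_trees),
                 rfr_sample_fraction = rfr_sample_fraction,
                 rfr_seeds = as.integer(rfr_seeds)),
            class = "learner_spec")
}

#' Fit multiple linear regression by (minimum-norm) least squares
#'
#' Full-rank designs are solved by QR. Rank-deficient designs (collinear
#' descriptors, or more descriptors than training rows) are solved by the
#' SVD pseudo-inverse, yielding the minimum-norm least-squares solution, and
#' flagged rather than refused: heavily over-parameterised linear fits are a
#' legitimate, if overfit, part of the experiment matrix.
#'
#' @param x Numeric descriptor matrix (rows = instances).
#' @param y Numeric response.
#' @return An `mlr_fit` with `coefficients` (intercept first) and
#'   `rank_deficient` flag.
#' @export
fit_mlr <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  design <- cbind(`(Intercept)` = 1, x)
  qrd <- qr(design)
  rank_deficient <- qrd$rank < ncol(design)
  if (!rank_deficient) {
    coefs <- qr.coef(qrd, y)
  } else {
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-10
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coefs <- stats::setNames(drop(coefs), colnames(design))
  }
  structure(list(coefficients = coefs, rank_deficient = rank_deficient),
            class = "mlr_fit")
}

#' @export
predict.mlr_fit <- function(object, newdata, ...) {
  drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
}

#' Absolute slope magnitudes of a fitted linear model
#'
#' On range-scaled descriptors the absolute slope coefficients (intercept
#' excluded) serve as a simple importance measure. Rank-deficient fits carry
#' a collinearity flag; their magnitudes come from the minimum-norm
#' pseudo-solution.
#'
#' @param fit An `mlr_fit`.
#' @return Named numeric vector of `|coefficient|` per descriptor, with
#'   attribute `collinear` when the design was rank deficient.
#' @export
coefficient_magnitudes <- function(fit) {
  stopifnot(inherits(fit, "mlr_fit"))
  out <- abs(fit$coefficients[-1L])
  attr(out, "collinear") <- fit$rank_deficient
  out
}

# one random forest at one seed; single-threaded for reproducibility
fit_rfr_single <- function(x, y, spec, seed) {
  ranger::ranger(x = as.data.frame(x), y = y,
                 num.trees = spec$rfr_n_trees,
                 sample.fraction = spec$rfr_sample_fraction,
                 replace = FALSE, seed = seed, num.threads = 1L)
}

predict_learner <- function(fit, x) {
  if (inherits(fit, "mlr_fit")) {
    predict(fit, x)
  } else {
    predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions
  }
}

#' Cross-validate a learner over a fold plan
#'
#' For every (repetition, fold): descriptors are assembled for the requested
#' blocks, the range scaler is fitted on the training rows only, both sides
#' are scaled, the learner is fitted (once for MLR; once per seed for random
#' forests) and the held-out fold is predicted. R-squared and RMSE are
#' recorded per (repetition, fold, seed); MLR results are constant across
#' the seed axis and stored once with seed `NA`.
#'
#' @param dataset A `qspr_dataset`.
#' @param blocks Character vector of descriptor block names.
#' @param plan A `fold_plan` for this dataset.
#' @param learner A [learner_spec()].
#' @param store_predictions Keep per-instance test predictions (needed for
#'   outlier diagnostics).
#' @param feature_select Optional pluggable selection stage: a
#'   `function(x_train, y_train)` returning column indices to keep. It is
#'   applied inside each fold and only ever sees training rows.
#' @return A `cv_result`: `components` data.frame (repetition, fold, seed,
#'   r2, rmse), optional `predictions`, `rank_deficient` flag, metadata.
#' @export
run_cross_validation <- function(dataset, blocks, plan, learner,
                                 store_predictions = FALSE,
                                 feature_select = NULL) {
  stopifnot(inherits(dataset, "qspr_dataset"), inherits(plan, "fold_plan"),
            inherits(learner, "learner_spec"))
  x_all <- assemble_descriptors(dataset, blocks)
  y_all <- dataset$instances$endpoint
  ids <- dataset$instances$instance_id
  comp <- list()
  preds <- list()
  rank_deficient <- FALSE
  for (r in seq_len(plan$R)) {
    a <- plan$assignment[plan$assignment$repetition == r, ]
    fold_of <- a$fold[match(ids, a$instance_id)]
    for (k in sort(unique(a$fold))) {
      test <- which(fold_of == k)
      train <- which(fold_of != k)
      x_tr <- x_all[train, , drop = FALSE]
      x_te <- x_all[test, , drop = FALSE]
      if (!is.null(feature_select)) {
        keep <- feature_select(x_tr, y_all[train])
        x_tr <- x_tr[, keep, drop = FALSE]
        x_te <- x_te[, keep, drop = FALSE]
      }
      sc <- range_scale(x_tr, x_te)
      y_tr <- y_all[train]
      y_te <- y_all[test]
      seeds <- if (learner$kind == "mlr") NA_integer_ else learner$rfr_seeds
      for (s in seeds) {
        fit <- if (learner$kind == "mlr") {
          f <- fit_mlr(sc$train, y_tr)
          rank_deficient <- rank_deficient || f$rank_deficient
          f
        } else {
          fit_rfr_single(sc$train, y_tr, learner, s)
        }
        y_hat <- predict_learner(fit, sc$other)
        m <- compute_metrics(y_te, y_hat)
        comp[[length(comp) + 1L]] <- data.frame(
          repetition = r, fold = k, seed = s, r2 = m$r2, rmse = m$rmse)
        if (store_predictions) {
          preds[[length(preds) + 1L]] <- data.frame(
            repetition = r, fold = k, seed = s,
            instance_id = ids[test], y_true = y_te, y_pred = y_hat,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(components = do.call(rbind, comp),
                 predictions = if (store_predictions) do.call(rbind, preds),
                 rank_deficient = rank_deficient,
                 learner = learner, blocks = blocks,
                 protocol = plan$protocol, K = plan$K, R = plan$R),
            class = "cv_result")
}

#' Aggregate a cross-validation result
#'
#' Plain arithmetic means of R-squared and RMSE over every (repetition,
#' fold, seed) component, matching the seed-averaging convention. Components
#' with undefined R-squared (zero test-fold variance) are excluded from the
#' R-squared mean only.
#'
#' @param result A `cv_result`.
#' @return List with `mean_r2`, `mean_rmse`, `n_components`,
#'   `rank_deficient`.
#' @export
aggregate_results <- function(result) {
  stopifnot(inherits(result, "cv_result"), nrow(result$components) > 0)
  comp <- result$components
  list(mean_r2 = mean(comp$r2, na.rm = TRUE),
       mean_rmse = mean(comp$rmse),
       n_components = nrow(comp),
       rank_deficient = isTRUE(result$rank_deficient))
}

#' Permutation importance of descriptors
#'
#' The importance of a descriptor is the mean increase in prediction error
#' (mean squared error) after randomly permuting its column, over
#' `n_permutations` permutations, evaluated on the supplied data. For the
#' seed-averaged convention, call once per seed-model and average.
#'
#' @param fit A fitted model (`mlr_fit` or a ranger forest).
#' @param x Descriptor matrix the model was built on (scaled as in
#'   training).
#' @param y True endpoint values.
#' @param n_permutations Permutations per descriptor (default 10).
#' @param seed Seed for the permutations.
#' @return Named numeric vector of importances (one per column of `x`).
#' @export
permutation_importance <- function(fit, x, y, n_permutations = 10L,
                                   seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2L)
  base_mse <- mean((y - predict_learner(fit, x))^2)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(n_permutations), function(k) {
        xp <- x
        xp[, j] <- xp[sample(nrow(xp)), j]
        mean((y - predict_learner(fit, xp))^2)
      }, numeric(1))) - base_mse
    }, numeric(1))
    stats::setNames(imp, colnames(x))
  })
}

#' Descriptor importance from a final model on the full dataset
#'
#' Builds the final model on the entirety of the dataset (range-scaled on
#' itself) and extracts importances: absolute coefficient magnitudes for
#' MLR, permutation importance averaged over the learner's seeds for random
#' forests.
#'
#' @param dataset A `qspr_dataset`.
#' @param blocks Descriptor block names.
#' @param learner A [learner_spec()].
#' @param n_permutations Permutations per descriptor for random forests.
#' @return Named numeric vector of importances.
#' @export
final_model_importance <- function(dataset, blocks, learner,
                                   n_permutations = 10L) {
  x <- assemble_descriptors(dataset, blocks)
  y <- dataset$instances$endpoint
  xs <- range_scale(x)$train
  if (learner$kind == "mlr") {
    coefficient_magnitudes(fit_mlr(xs, y))
  } else {
    imps <- lapply(learner$rfr_seeds, function(s) {
      fit <- fit_rfr_single(xs, y, learner, s)
      permutation_importance(fit, xs, y, n_permutations, seed = s)
    })
    Reduce(`+`, imps) / length(imps)
  }
}
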