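#' Validation statistics: R-squared and RMSE
#'
#' `rmse = sqrt(mean((y_true - y_pred)^2))` and
#' `r2 = 1 - MSE / Var(y_true)`, with Var the population variance (divide
#' by n) of the test-set endpoints. R-squared may be negative for models
#' worse than the test-set mean; with zero test-set variance it is undefined
#' and reported as `NA` while RMSE remains valid.
#'
#' @param y_true,y_pred Numeric vectors of equal non-zero length.
#' @return List with `r2` and `rmse`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  mse <- mean((y_true - y_pred)^2)
  v <- mean((y_true - mean(y_true))^2)
  list(r2 = if (v > 0) 1 - mse / v else NA_real_, rmse = sqrt(mse))
}

#' Rank model summaries under the comparison rules
#'
#' Models evaluated on the same dataset with the same cross-validation folds
#' are compared by mean RMSE (ascending); comparisons across datasets, or on
#' the same dataset with different folds, use mean R-squared (descending),
#' since RMSE is not comparable when the endpoint range differs. Requesting
#' the wrong metric for a context is an error. Ties break lexicographically
#' by model label.
#'
#' @param summaries data.frame with columns `label`, `mean_r2`, `mean_rmse`.
#' @param context `"same-folds"` or `"cross-dataset"`.
#' @param metric Optional explicit metric; must agree with the context
#'   (`"rmse"` for same-folds, `"r2"` for cross-dataset).
#' @return The summaries, ordered, with a `rank` column.
#' @export
rank_models <- function(summaries, context = c("same-folds", "cross-dataset"),
                        metric = NULL) {
  context <- match.arg(context)
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0,
            all(c("label", "mean_r2", "mean_rmse") %in% names(summaries)))
  required <- if (context == "same-folds") "rmse" else "r2"
  if (!is.null(metric) && metric != required) {
    stop(sprintf(
      "metric '%s' is not valid for context '%s': same-folds comparisons use mean RMSE, cross-dataset comparisons use mean R-squared",
      metric, context))
  }
  ord <- if (required == "rmse") {
    order(summaries$mean_rmse, summaries$label)
  } else {
    order(-summaries$mean_r2, summaries$label)
  }
  out <- summaries[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Paired significance analysis for one comparison scenario
#'
#' Each pair holds two aligned per-(repetition, fold, seed) metric vectors
#' from results differing only in the scenario factor. An approximate
#' two-sided paired t-test is run per pair and the p values are adjusted
#' within the scenario family (Holm by default); a pair is flagged
#' significant at adjusted p < `alpha`. Cross-validation components are not
#' independent, so these p values are approximate and tend to overstate
#' significance; they are reported with that caveat attached.
#'
#' @param pairs List of pairs, each a list with `label`, `a`, `b` (numeric
#'   vectors of equal length, aligned on (repetition, fold) and seed).
#' @param adjust Multiple-testing adjustment method (see
#'   [stats::p.adjust()]; default `"holm"`).
#' @param alpha Significance threshold on the adjusted p values.
#' @return data.frame: `label`, `mean_diff` (mean of a - b), `p_raw`,
#'   `p_adj`, `significant`; attribute `caveat` notes the approximation.
#' @export
paired_comparison <- function(pairs, adjust = "holm", alpha = 0.05) {
  stopifnot(length(pairs) >= 1L)
  rows <- lapply(pairs, function(p) {
    stopifnot(length(p$a) == length(p$b), length(p$a) >= 2L)
    d <- p$a - p$b
    if (stats::sd(d) == 0) {
      # identical (or uniformly shifted) vectors: t-test degenerate
      p_raw <- if (all(d == 0)) 1 else 0
    } else {
      p_raw <- stats::t.test(p$a, p$b, paired = TRUE)$p.value
    }
    data.frame(label = p$label %||% "", mean_diff = mean(d), p_raw = p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = adjust)
  out$significant <- out$p_adj < alpha
  attr(out, "caveat") <-
    "p values are approximate: cross-validation components are dependent, so significance may be overstated"
  out
}

# factor columns a results catalogue must carry for scenario pairing
SCENARIO_FACTORS <- c("dataset", "two_d", "mp", "le", "threeD", "fs",
                      "learner", "protocol")

# which factor each key scenario varies
SCENARIO_DEFS <- list(
  lattice_energy_in_out   = list(factor = "le",       metric = "rmse"),
  melting_point_in_out    = list(factor = "mp",       metric = "rmse"),
  crystal_vs_conformer_3d = list(factor = "threeD",   metric = "rmse",
                                 levels = c("crystal", "conformer")),
  feature_selection_on_off = list(factor = "fs",      metric = "rmse"),
  cv_v_vs_cv_rt           = list(factor = "protocol", metric = "r2",
                                 levels = c("v", "rt")))

#' Build the key comparison scenarios from a results catalogue
#'
#' Pairs results differing in exactly one factor, for the five key
#' scenarios: lattice energy in/out, melting point in/out, crystal- vs
#' conformer-derived 3D descriptors, feature selection on/off, and CV=v vs
#' CV=rt. Scenarios 1-4 compare paired RMSE values; the cross-validation
#' scenario compares paired R-squared values (the folds differ between
#' protocols, so RMSE pairing by fold is not meaningful there, and the
#' alignment is by component position). Results lacking a partner are
#' skipped; duplicate factor combinations are an error.
#'
#' @param catalogue data.frame with the factor columns `dataset`, `two_d`,
#'   `mp`, `le`, `threeD`, `fs`, `learner`, `protocol` and a `result_id`
#'   naming each result.
#' @return Named list (one per scenario) of data.frames with columns
#'   `result_a`, `result_b`, `label` and the scenario `metric`.
#' @export
build_scenario_pairs <- function(catalogue) {
  stopifnot(is.data.frame(catalogue),
            all(c(SCENARIO_FACTORS, "result_id") %in% names(catalogue)))
  key_all <- do.call(paste, c(catalogue[SCENARIO_FACTORS], sep = "|"))
  if (anyDuplicated(key_all)) stop("duplicate factor combinations in catalogue")
  out <- list()
  for (nm in names(SCENARIO_DEFS)) {
    def <- SCENARIO_DEFS[[nm]]
    others <- setdiff(SCENARIO_FACTORS, def$factor)
    key <- do.call(paste, c(catalogue[others], sep = "|"))
    pairs <- lapply(split(seq_len(nrow(catalogue)), key), function(idx) {
      lev <- as.character(catalogue[[def$factor]][idx])
      if (!is.null(def$levels)) {
        keep <- lev %in% def$levels
        idx <- idx[keep]
        lev <- lev[keep]
      }
      if (length(idx) != 2L || lev[1L] == lev[2L]) return(NULL)
      if (!is.null(def$levels)) {
        idx <- idx[match(def$levels, lev)]
      } else {
        idx <- idx[order(lev, decreasing = TRUE)] # TRUE/on first
      }
      data.frame(result_a = catalogue$result_id[idx[1L]],
                 result_b = catalogue$result_id[idx[2L]],
                 label = paste(catalogue$result_id[idx], collapse = " vs "),
                 metric = def$metric, stringsAsFactors = FALSE)
    })
    out[[nm]] <- do.call(rbind, Filter(Negate(is.null), unname(pairs)))
  }
  out
}
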