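#' Stratified fold assignment for a continuous endpoint
#'
#' Items are ranked by endpoint value, the ranked list is partitioned into
#' consecutive blocks of size `K` (the last block possibly smaller), and
#' within each block members are dealt to distinct folds uniformly at
#' random. This keeps every fold's endpoint distribution close to the
#' overall distribution. For a final partial block of size m < K, the
#' shuffled members are dealt to folds 1..m, so any size remainder goes to
#' the lowest fold indices.
#'
#' @param endpoints Numeric endpoint values (one per item).
#' @param K Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in 1..K, aligned with `endpoints`.
#' @export
stratified_folds_continuous <- function(endpoints, K, seed) {
  n <- length(endpoints)
  if (n < K) stop("need at least K items to build K folds")
  with_seed(seed, {
    ord <- order(endpoints, stats::runif(n)) # random tie-break
    fold <- integer(n)
    for (start in seq(1L, n, by = K)) {
      block <- ord[start:min(start + K - 1L, n)]
      m <- length(block)
      fold[block[sample.int(m)]] <- seq_len(m)
    }
    fold
  })
}

new_fold_plan <- function(protocol, K, R, seed, assignment) {
  structure(list(protocol = protocol, K = K, R = R, seed = seed,
                 assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: protocol CV=%s, K=%d, R=%d, seed=%d, %d instances\n",
              x$protocol, x$K, x$R, x$seed,
              length(unique(x$assignment$instance_id))))
  invisible(x)
}

#' Vanilla repeated stratified K-fold cross-validation plan (CV=v)
#'
#' R independent repetitions of stratified K-fold assignment over instance
#' identifiers. Instances of the same material measured at different
#' temperatures may land in different folds, so the same material can appear
#' in corresponding training and test sets.
#'
#' @param dataset A `qspr_dataset`.
#' @param K,R Folds and repetitions (defaults 5 and 5).
#' @param seed Master seed; repetition r uses a seed derived from it.
#' @return A `fold_plan` with protocol `"v"`.
#' @export
make_vanilla_folds <- function(dataset, K = 5L, R = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  inst <- dataset$instances
  assignment <- do.call(rbind, lapply(seq_len(R), function(r) {
    f <- stratified_folds_continuous(inst$endpoint, K, derive_seed(seed, r))
    data.frame(repetition = r, instance_id = inst$instance_id, fold = f,
               stringsAsFactors = FALSE)
  }))
  new_fold_plan("v", K, R, as.integer(seed), assignment)
}

#' Material-grouped "remove temperature" pseudo-cross-validation plan (CV=rt)
#'
#' Step 1: truncate instance identifiers to their material key, keeping one
#' row per material with the arithmetic mean endpoint over its instances.
#' Step 2: run stratified K-fold assignment on the truncated table (R
#' repetitions), stratifying on the material-mean endpoint. Step 3: every
#' original instance inherits its material's fold. No material ever
#' straddles folds, so a material measured at several temperatures can never
#' appear in corresponding training and test sets.
#'
#' @inheritParams make_vanilla_folds
#' @return A `fold_plan` with protocol `"rt"`.
#' @export
make_rt_folds <- function(dataset, K = 5L, R = 5L, seed = 1L) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  if (dataset$endpoint_kind != "solubility") {
    stop("the remove-temperature protocol applies only to temperature-dependent solubility datasets")
  }
  inst <- dataset$instances
  mat_mean <- deduplicate_instances(inst$material_key, inst$endpoint)
  assignment <- do.call(rbind, lapply(seq_len(R), function(r) {
    f <- stratified_folds_continuous(mat_mean$endpoint, K,
                                     derive_seed(seed, r))
    fold_of <- stats::setNames(f, mat_mean$instance_id)
    data.frame(repetition = r, instance_id = inst$instance_id,
               fold = unname(fold_of[inst$material_key]),
               stringsAsFactors = FALSE)
  }))
  new_fold_plan("rt", K, R, as.integer(seed), assignment)
}

#' Check a fold plan against its dataset
#'
#' Reports partition completeness, fold sizes, per-fold endpoint means, and
#' the number of materials straddling folds within a repetition (which must
#' be zero for the remove-temperature protocol).
#'
#' @param plan A `fold_plan`.
#' @param dataset The `qspr_dataset` it was built for.
#' @return List with `complete`, `fold_sizes`, `fold_endpoint_means`,
#'   `straddling_materials` (per repetition), `ok`.
#' @export
verify_fold_plan <- function(plan, dataset) {
  stopifnot(inherits(plan, "fold_plan"), inherits(dataset, "qspr_dataset"))
  inst <- dataset$instances
  a <- plan$assignment
  dangling <- setdiff(a$instance_id, inst$instance_id)
  if (length(dangling)) {
    stop("fold plan refers to unknown instance(s): ",
         paste(utils::head(dangling, 5L), collapse = ", "))
  }
  per_rep <- split(a, a$repetition)
  complete <- all(vapply(per_rep, function(d) {
    setequal(d$instance_id, inst$instance_id) &&
      !anyDuplicated(d$instance_id) &&
      length(unique(d$fold)) == plan$K && all(table(d$fold) > 0)
  }, logical(1)))
  straddle <- vapply(per_rep, function(d) {
    mk <- inst$material_key[match(d$instance_id, inst$instance_id)]
    sum(vapply(split(d$fold, mk), function(f) length(unique(f)) > 1L,
               logical(1)))
  }, integer(1))
  sizes <- lapply(per_rep, function(d) as.integer(table(factor(d$fold,
                                                               levels = seq_len(plan$K)))))
  means <- lapply(per_rep, function(d) {
    ep <- inst$endpoint[match(d$instance_id, inst$instance_id)]
    as.numeric(tapply(ep, factor(d$fold, levels = seq_len(plan$K)), mean))
  })
  list(complete = complete,
       fold_sizes = sizes,
       fold_endpoint_means = means,
       straddling_materials = straddle,
       ok = complete && (plan$protocol != "rt" || all(straddle == 0L)))
}

#' Serialize a fold plan to CSV
#'
#' @param plan A `fold_plan`.
#' @param path Output path; columns repetition, instance_id, fold.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(plan, path) {
  utils::write.csv(plan$assignment, path, row.names = FALSE)
  invisible(path)
}
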