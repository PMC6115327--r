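#' Parse a QSPR instance identifier
#'
#' Instance identifiers follow the `[material identity]_[temperature]`
#' template used for temperature-dependent solubility datasets: the final
#' underscore-delimited token is the measurement temperature in Kelvin, and
#' everything before it is the material key. Material keys may themselves
#' contain underscores (names, CAS numbers and polymorph descriptions
#' typically do), so only the final token is ever stripped. For endpoints
#' without a temperature dimension (enthalpy of solution) the whole
#' identifier is the material key.
#'
#' @param raw Character vector of raw instance identifiers.
#' @param has_temperature Logical; if `TRUE` the final token is parsed as a
#'   temperature in Kelvin.
#' @return A data.frame with columns `raw`, `material_key` and `temperature`
#'   (`NA` when absent).
#' @examples
#' parse_instance_id("M1_298.15", has_temperature = TRUE)
#' parse_instance_id("aspirin_50-78-2_none", has_temperature = FALSE)
#' @export
parse_instance_id <- function(raw, has_temperature) {
  stopifnot(is.character(raw), length(raw) >= 1L, !anyNA(raw))
  if (any(!nzchar(raw))) stop("instance identifiers must be non-empty")
  if (!has_temperature) {
    return(data.frame(raw = raw, material_key = raw,
                      temperature = NA_real_, stringsAsFactors = FALSE))
  }
  pos <- regexpr("_[^_]*$", raw)
  token <- ifelse(pos > 0L, substring(raw, pos + 1L), NA_character_)
  temp <- suppressWarnings(as.numeric(token))
  bad <- pos <= 0L | is.na(temp) | temp <= 0
  if (any(bad)) {
    stop(sprintf(
      "malformed instance identifier(s), no positive Kelvin temperature in final token: %s",
      paste(utils::head(raw[bad], 5L), collapse = ", ")))
  }
  data.frame(raw = raw,
             material_key = substring(raw, 1L, pos - 1L),
             temperature = temp,
             stringsAsFactors = FALSE)
}

#' Collapse duplicate instance identifiers to their arithmetic mean endpoint
#'
#' Where several endpoint measurements share one instance identifier, the
#' instance is kept once with the arithmetic mean endpoint value, preserving
#' the input order of first occurrence.
#'
#' @param ids Character vector of raw instance identifiers.
#' @param endpoints Numeric endpoint values, same length as `ids`.
#' @return A data.frame with columns `instance_id` and `endpoint`, one row
#'   per unique identifier.
#' @export
deduplicate_instances <- function(ids, endpoints) {
  stopifnot(length(ids) == length(endpoints), all(is.finite(endpoints)))
  first <- !duplicated(ids)
  means <- tapply(endpoints, factor(ids, levels = ids[first]), mean)
  data.frame(instance_id = ids[first],
             endpoint = as.numeric(means[ids[first]]),
             stringsAsFactors = FALSE)
}

#' Construct a QSPR dataset object
#'
#' Bundles validated instances (identifier, endpoint, parsed material key and
#' temperature), a numeric descriptor table, and a descriptor registry
#' grouping descriptor columns into named blocks (2D subsets, melting point
#' `MP`, lattice energy `LE`, inverse temperature `T`, 3D blocks). The
#' endpoint kind (`"solubility"` in log10[molar], temperature-dependent; or
#' `"enthalpy"` in kJ/mol) controls whether temperatures are parsed from the
#' identifiers and whether the `T` block is admissible.
#'
#' @param instance_id Character vector of unique instance identifiers (after
#'   deduplication).
#' @param endpoint Numeric endpoint values.
#' @param descriptors data.frame or matrix of numeric descriptor columns,
#'   rows aligned with `instance_id`.
#' @param registry Named list mapping block name to a character vector of
#'   descriptor column names; names must be unique across blocks and present
#'   in `descriptors`.
#' @param endpoint_kind `"solubility"` or `"enthalpy"`.
#' @param units Endpoint units label (default chosen from kind).
#' @return An object of class `qspr_dataset`.
#' @export
qspr_dataset <- function(instance_id, endpoint, descriptors, registry,
                         endpoint_kind = c("solubility", "enthalpy"),
                         units = NULL) {
  endpoint_kind <- match.arg(endpoint_kind)
  stopifnot(!anyDuplicated(instance_id), all(is.finite(endpoint)),
            length(instance_id) == length(endpoint))
  descriptors <- as.data.frame(descriptors)
  stopifnot(nrow(descriptors) == length(instance_id))
  all_names <- unlist(registry, use.names = FALSE)
  if (anyDuplicated(all_names)) {
    stop("descriptor names must be unique across registry blocks")
  }
  missing_cols <- setdiff(all_names, names(descriptors))
  if (length(missing_cols)) {
    stop("registry names absent from descriptor table: ",
         paste(missing_cols, collapse = ", "))
  }
  if (endpoint_kind != "solubility" && "T" %in% names(registry)) {
    stop("the inverse-temperature block applies only to temperature-dependent solubility datasets")
  }
  parsed <- parse_instance_id(instance_id,
                              has_temperature = endpoint_kind == "solubility")
  structure(
    list(
      instances = data.frame(instance_id = instance_id,
                             material_key = parsed$material_key,
                             temperature = parsed$temperature,
                             endpoint = endpoint,
                             stringsAsFactors = FALSE),
      descriptors = descriptors[, all_names, drop = FALSE],
      registry = registry,
      endpoint_kind = endpoint_kind,
      units = units %||%
        if (endpoint_kind == "solubility") "log10[molar]" else "kJ/mol"
    ),
    class = "qspr_dataset")
}

#' @export
print.qspr_dataset <- function(x, ...) {
  cat(sprintf("qspr_dataset: %d instances (%d materials), endpoint %s [%s]\n",
              nrow(x$instances), length(unique(x$instances$material_key)),
              x$endpoint_kind, x$units))
  sizes <- vapply(x$registry, length, integer(1))
  cat("descriptor blocks:",
      paste(sprintf("%s(%d)", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Replace the temperature block by reciprocal absolute temperature
#'
#' The experimental temperature (Kelvin, taken from the parsed instance
#' identifier) is transformed to 1/T for use as a descriptor, reflecting the
#' linear dependence of log10 solubility on reciprocal temperature under the
#' van't Hoff relationship. The original temperature is retained on the
#' instance table.
#'
#' @param dataset A `qspr_dataset` with endpoint kind `"solubility"`.
#' @return The dataset with descriptor column `T` equal to `1/temperature`.
#' @export
invert_temperature <- function(dataset) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  if (dataset$endpoint_kind != "solubility") {
    stop("temperature descriptor applies only to solubility datasets")
  }
  tk <- dataset$instances$temperature
  if (any(!is.finite(tk)) || any(tk <= 0)) {
    stop("all temperatures must be positive Kelvin")
  }
  dataset$descriptors[["T"]] <- 1 / tk
  if (!"T" %in% names(dataset$registry)) dataset$registry$T <- "T"
  dataset
}

#' Assemble a descriptor matrix from named registry blocks
#'
#' Columns are the concatenation of the requested blocks in registry order;
#' rows align with instance order. Missing values fail validation, naming the
#' offending instances.
#'
#' @param dataset A `qspr_dataset`.
#' @param blocks Character vector of registry block names.
#' @return Numeric matrix (instances x selected descriptors).
#' @export
assemble_descriptors <- function(dataset, blocks) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  unknown <- setdiff(blocks, names(dataset$registry))
  if (length(unknown)) {
    stop("unknown descriptor block(s): ", paste(unknown, collapse = ", "))
  }
  ordered <- intersect(names(dataset$registry), blocks)
  cols <- unlist(dataset$registry[ordered], use.names = FALSE)
  m <- as.matrix(dataset$descriptors[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- dataset$instances$instance_id[rowSums(is.na(m)) > 0]
    stop("missing descriptor values for instance(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  rownames(m) <- dataset$instances$instance_id
  m
}

#' Fit and apply range scaling using training ranges only
#'
#' Each descriptor is affinely rescaled to lie in \[0, 1\] on the training
#' rows: `(x - min_train) / (max_train - min_train)`. Test values may fall
#' outside \[0, 1\] and are not clipped. Descriptors constant on the training
#' rows map to 0 everywhere so column counts stay comparable across folds.
#' Ranges are learned from the training matrix alone; test information never
#' enters the transform.
#'
#' @param train Numeric training matrix.
#' @param other Optional numeric matrix scaled with the training ranges.
#' @return List with `train`, `other` (or `NULL`) and the `scaler` (an
#'   object of class `range_scaler` holding per-column min/max).
#' @export
range_scale <- function(train, other = NULL) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 1L)
  lo <- apply(train, 2L, min)
  hi <- apply(train, 2L, max)
  scaler <- structure(list(min = lo, max = hi), class = "range_scaler")
  list(train = apply_range_scaler(scaler, train),
       other = if (!is.null(other)) apply_range_scaler(scaler, other),
       scaler = scaler)
}

#' Apply a fitted range scaler to a matrix
#'
#' @param scaler A `range_scaler` from [range_scale()].
#' @param x Numeric matrix with the same columns the scaler was fitted on.
#' @return Scaled matrix; constant training columns become 0.
#' @export
apply_range_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "range_scaler"))
  x <- as.matrix(x)
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2L, scaler$min, "-")
  nonconst <- rng > 0
  out[, nonconst] <- sweep(out[, nonconst, drop = FALSE], 2L,
                           rng[nonconst], "/")
  out[, !nonconst] <- 0
  out
}

#' Read a QSPR-ready dataset from delimited text plus a sidecar config
#'
#' The delimited file must have a header with `instance_id`, `endpoint` and
#' descriptor columns. The sidecar YAML (or JSON readable by yaml) declares
#' `endpoint_kind`, optional `units`, and `blocks:` mapping block names to
#' descriptor column names. Duplicate identifiers are collapsed to their
#' arithmetic mean endpoint; for solubility datasets the inverse-temperature
#' descriptor is derived from the identifiers.
#'
#' @param path Path to the CSV/TSV file.
#' @param config Path to the sidecar YAML file, or an equivalent named list.
#' @param sep Field separator (default `,`).
#' @return A `qspr_dataset`.
#' @export
read_qspr_csv <- function(path, config, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("instance_id", "endpoint") %in% names(df)))
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dedup <- deduplicate_instances(df$instance_id, df$endpoint)
  df <- df[!duplicated(df$instance_id), , drop = FALSE]
  df$endpoint <- dedup$endpoint[match(df$instance_id, dedup$instance_id)]
  registry <- lapply(cfg$blocks, as.character)
  ds <- qspr_dataset(df$instance_id, df$endpoint,
                     df[, setdiff(names(df), c("instance_id", "endpoint")),
                        drop = FALSE],
                     registry = registry,
                     endpoint_kind = cfg$endpoint_kind,
                     units = cfg$units)
  if (ds$endpoint_kind == "solubility") ds <- invert_temperature(ds)
  ds
}

#' Write a QSPR dataset to canonical CSV
#'
#' @param dataset A `qspr_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qspr_csv <- function(dataset, path) {
  out <- cbind(dataset$instances[, c("instance_id", "endpoint")],
               dataset$descriptors)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Summarise a QSPR dataset
#'
#' @param dataset A `qspr_dataset`.
#' @return List with instance count, material count, block sizes and units.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "qspr_dataset"))
  list(n_instances = nrow(dataset$instances),
       n_materials = length(unique(dataset$instances$material_key)),
       endpoint_kind = dataset$endpoint_kind,
       units = dataset$units,
       block_sizes = vapply(dataset$registry, length, integer(1)))
}
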