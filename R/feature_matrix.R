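## Container for an untargeted LC-MS feature table: features (m/z,
## retention time) x samples (with roles: biological sample, extraction
## blank, pooled QC), plus a provenance trail of every filter applied.

#' Construct a feature matrix
#'
#' @param features Data frame with columns `feature_id` (unique), `mz`
#'   (Da) and `rt_min` (minutes).
#' @param samples Data frame with columns `sample_id`, `role` (one of
#'   `"sample"`, `"blank"`, `"pool"`) and `group` (e.g. `"ND"`/`"AD"` for
#'   biological samples, `"all"` otherwise).
#' @param intensity Non-negative numeric matrix, `nrow(features)` x
#'   `nrow(samples)`.
#' @param provenance List of filter-report entries (normally empty at
#'   construction).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, samples, intensity,
                           provenance = list()) {
  stopifnot(is.data.frame(features), is.data.frame(samples),
            is.matrix(intensity))
  if (anyDuplicated(features$feature_id)) stop("feature_ids must be unique")
  if (!all(samples$role %in% c("sample", "blank", "pool"))) {
    stop("sample roles must be 'sample', 'blank' or 'pool'")
  }
  if (nrow(intensity) != nrow(features) ||
      ncol(intensity) != nrow(samples)) {
    stop("intensity must be features x samples")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  dimnames(intensity) <- list(features$feature_id, samples$sample_id)
  structure(list(features = features, samples = samples,
                 intensity = intensity, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$features), "features x",
      nrow(x$samples), "columns (",
      sum(x$samples$role == "sample"), "samples,",
      sum(x$samples$role == "blank"), "blanks,",
      sum(x$samples$role == "pool"), "pools )\n")
  if (length(x$provenance)) {
    cat("filters applied:\n")
    print(filter_report(x))
  }
  invisible(x)
}

#' Filter provenance of a feature matrix
#'
#' Every filter appends an entry recording its name, parameters and
#' before/removed/after feature counts; the counts telescope (each step's
#' `before` equals the previous step's `after`).
#'
#' @param x A `feature_matrix`.
#' @return A data frame with columns `step`, `params`, `before`,
#'   `removed`, `after`; zero rows if no filter was applied.
#' @export
filter_report <- function(x) {
  stopifnot(inherits(x, "feature_matrix"))
  if (!length(x$provenance)) {
    return(data.frame(step = character(), params = character(),
                      before = integer(), removed = integer(),
                      after = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    step = vapply(x$provenance, `[[`, "", "step"),
    params = vapply(x$provenance, function(p) {
      paste(names(p$params), unlist(p$params), sep = "=", collapse = ", ")
    }, ""),
    before = vapply(x$provenance, `[[`, 0L, "before"),
    removed = vapply(x$provenance, function(p) length(p$removed_ids), 0L),
    after = vapply(x$provenance, `[[`, 0L, "after"),
    stringsAsFactors = FALSE
  )
}

## Drop features by logical keep vector, appending a provenance entry.
.subset_features <- function(fm, keep, step, params) {
  removed <- fm$features$feature_id[!keep]
  entry <- list(step = step, params = params,
                before = nrow(fm$features),
                removed_ids = removed,
                after = sum(keep))
  feature_matrix(fm$features[keep, , drop = FALSE],
                 fm$samples,
                 fm$intensity[keep, , drop = FALSE],
                 c(fm$provenance, list(entry)))
}

.role_cols <- function(fm, role) which(fm$samples$role == role)

#' Read or write a feature matrix CSV
#'
#' Layout: columns `feature_id`, `mz`, `rt_min`, then one intensity
#' column per sample named `<role>_<group>_<idx>` with role in
#' `sample`/`blank`/`pool`.
#'
#' @param path Path to the CSV file.
#' @return `read_feature_matrix_csv` returns a `feature_matrix` (with an
#'   empty provenance trail: filters applied before writing are not
#'   serialized).
#' @export
read_feature_matrix_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "mz", "rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  scols <- setdiff(names(df), need)
  parts <- strsplit(scols, "_", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L ||
                  !p[1] %in% c("sample", "blank", "pool"), TRUE)
  if (any(bad)) {
    stop("unparseable sample column name(s): ",
         paste(scols[bad], collapse = ", "))
  }
  samples <- data.frame(
    sample_id = scols,
    role = vapply(parts, `[`, "", 1L),
    group = vapply(parts, function(p) {
      paste(p[-c(1L, length(p))], collapse = "_")
    }, ""),
    stringsAsFactors = FALSE
  )
  feature_matrix(df[, need], samples,
                 as.matrix(df[, scols, drop = FALSE]))
}

#' @rdname read_feature_matrix_csv
#' @param fm A `feature_matrix`.
#' @export
write_feature_matrix_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- cbind(fm$features, as.data.frame(fm$intensity))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
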