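## Readers/writers for the two flat-file formats the pipeline consumes:
## litterbag tables and long-format trait tables. CSV dialect is fixed:
## comma separator, dot decimal, mandatory header, UTF-8.

.litterbag_cols <- c("forest", "species", "litter_type", "treatment",
                     "time_months", "replicate",
                     "initial_dry_mass_g", "final_dry_mass_g")

#' Validate a litterbag record table
#'
#' Checks column presence, factor levels, and the mass invariants
#' (`initial > 0`, `0 <= final <= initial`). Errors list the offending
#' row numbers. Factor columns are re-leveled to the canonical order.
#'
#' @param records A data frame with the columns listed in
#'   [read_litterbag_csv()].
#' @return The validated data frame, invisibly classed factors in
#'   canonical level order.
#' @export
validate_litterbags <- function(records) {
  miss <- setdiff(.litterbag_cols, names(records))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "))
  }
  lv <- design_levels()
  for (col in c("forest", "species", "litter_type", "treatment")) {
    vals <- as.character(records[[col]])
    bad <- which(!vals %in% lv[[col]])
    if (length(bad)) {
      stop("bad ", col, " level in row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "), ": ",
           paste(unique(vals[bad]), collapse = ", "))
    }
    records[[col]] <- factor(vals, levels = lv[[col]])
  }
  bad <- which(!records$time_months %in% lv$time_months)
  if (length(bad)) {
    stop("bad time_months in row(s) ", paste(utils::head(bad, 10L),
         collapse = ", "), " (must be 12 or 24)")
  }
  records$time_months <- as.integer(records$time_months)
  records$replicate <- as.integer(records$replicate)
  for (col in c("initial_dry_mass_g", "final_dry_mass_g")) {
    if (!is.numeric(records[[col]]) || anyNA(records[[col]])) {
      stop("unparseable number(s) in column ", col, ", row(s) ",
           paste(utils::head(which(is.na(suppressWarnings(
             as.numeric(records[[col]])))), 10L), collapse = ", "))
    }
  }
  bad <- which(records$initial_dry_mass_g <= 0)
  if (length(bad)) {
    stop("initial_dry_mass_g <= 0 in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  bad <- which(records$final_dry_mass_g < 0 |
               records$final_dry_mass_g > records$initial_dry_mass_g)
  if (length(bad)) {
    stop("final_dry_mass_g outside [0, initial_dry_mass_g] in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  invisible(records)
}

#' Read or write a litterbag CSV
#'
#' Columns: `forest,species,litter_type,treatment,time_months,replicate,`
#' `initial_dry_mass_g,final_dry_mass_g`. Masses are stored in grams;
#' percentages are always recomputed, never stored. Reading validates
#' every record and errors with the offending row numbers; the
#' write/read round trip is lossless.
#'
#' @param path Path to the CSV file.
#' @return `read_litterbag_csv` returns a validated data frame (possibly
#'   with zero rows).
#' @export
read_litterbag_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    miss <- setdiff(.litterbag_cols, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    df <- df[, .litterbag_cols]
    lv <- design_levels()
    for (col in c("forest", "species", "litter_type", "treatment")) {
      df[[col]] <- factor(character(), levels = lv[[col]])
    }
    df$time_months <- integer()
    df$replicate <- integer()
    df$initial_dry_mass_g <- numeric()
    df$final_dry_mass_g <- numeric()
    return(df)
  }
  out <- validate_litterbags(df)
  out[, .litterbag_cols]
}

#' @rdname read_litterbag_csv
#' @param records Litterbag data frame as returned by
#'   [generate_litterbags()] or [read_litterbag_csv()].
#' @export
write_litterbag_csv <- function(records, path) {
  records <- validate_litterbags(records)
  write.csv(records[, .litterbag_cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read or write a long-format litter trait CSV
#'
#' Columns: `species,litter_type,trait,value,unit` (plus `replicate` when
#' present). Concentrations must be non-negative.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_traits_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "litter_type", "trait", "value", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lv <- design_levels()
  for (col in c("species", "litter_type")) {
    bad <- which(!df[[col]] %in% lv[[col]])
    if (length(bad)) {
      stop("bad ", col, " level in row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    df[[col]] <- factor(df[[col]], levels = lv[[col]])
  }
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop("negative or unparseable trait value in row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  df
}

#' @rdname read_traits_csv
#' @param traits Trait data frame, e.g. from [generate_trait_samples()].
#' @export
write_traits_csv <- function(traits, path) {
  write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
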