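## Dereplication arithmetic for ESI-MS features: monoisotopic masses,
## adduct ion m/z, ppm mass error, ring-and-double-bond equivalents, and
## exhaustive CHO molecular-formula enumeration.

#' Monoisotopic mass constants (Da)
#'
#' Atomic and particle masses used throughout the annotation arithmetic.
#' The electron mass is carried explicitly, so ion m/z values are
#' physically exact for the charge state.
#'
#' @return Named numeric vector with `C`, `H`, `O`, `Na`, `proton`,
#'   `electron`, and the neutral formate radical `HCOO`.
#' @export
mass_constants <- function() {
  c(C = 12.0, H = 1.0078250319, O = 15.9949146221, Na = 22.98976928,
    proton = 1.00727646688, electron = 0.00054857990,
    HCOO = 44.9976542)
}

.supported_adducts <- c("[M-H]-", "[M+HCOO]-", "[M-2H]2-",
                        "[M+H]+", "[M+Na]+")

#' Parse a molecular formula string
#'
#' Accepts element counts for C, H, O and Na, e.g. `"C12H22O11"`; an
#' omitted count means 1 and an absent element means 0.
#'
#' @param formula Formula string, or an already-parsed named vector.
#' @return Named integer vector with components `C`, `H`, `O`, `Na`.
#' @examples
#' parse_formula("C12H22O11")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    out <- c(C = 0L, H = 0L, O = 0L, Na = 0L)
    out[names(formula)] <- as.integer(formula)
    return(out)
  }
  s <- gsub("\\s", "", formula)
  m <- gregexpr("(Na|C|H|O)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("(Na|C|H|O)([0-9]*)", s))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("cannot parse formula (C/H/O/Na only): ", formula)
  }
  out <- c(C = 0L, H = 0L, O = 0L, Na = 0L)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    ct <- sub("^[A-Za-z]+", "", p)
    out[el] <- out[el] + if (nzchar(ct)) as.integer(ct) else 1L
  }
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' @inheritParams parse_formula
#' @return Mass in Da.
#' @export
formula_mass <- function(formula) {
  cnt <- parse_formula(formula)
  mc <- mass_constants()
  sum(cnt * mc[c("C", "H", "O", "Na")])
}

#' Theoretical m/z of an adduct ion
#'
#' Supported adducts and their arithmetic on the neutral monoisotopic
#' mass M (electron mass included, z = charge magnitude):
#' \itemize{
#'   \item `[M-H]-`: `M - H + e`
#'   \item `[M+HCOO]-`: `M + 44.9976542 + e` (formate)
#'   \item `[M-2H]2-`: `(M - 2 H + 2 e) / 2`
#'   \item `[M+H]+`: `M + proton`
#'   \item `[M+Na]+`: `M + Na - e`
#' }
#'
#' @param formula Neutral formula (string or named counts).
#' @param adduct One of the supported adduct labels above.
#' @param isotope_peak Number of heavy-isotope substitutions: the m/z is
#'   shifted by `isotope_peak * 1.0033548378 / z` (the 13C-12C mass
#'   difference), for matching features picked on an A+1/A+2 isotopologue
#'   peak. Default 0 (monoisotopic).
#' @return Theoretical m/z in Da.
#' @examples
#' theoretical_mz("C12H22O11", "[M-H]-")
#' @export
theoretical_mz <- function(formula, adduct, isotope_peak = 0L) {
  M <- formula_mass(formula)
  mc <- mass_constants()
  z <- adduct_charge(adduct)
  mz <- switch(adduct,
    "[M-H]-" = M - mc[["H"]] + mc[["electron"]],
    "[M+HCOO]-" = M + mc[["HCOO"]] + mc[["electron"]],
    "[M-2H]2-" = (M - 2 * mc[["H"]] + 2 * mc[["electron"]]) / 2,
    "[M+H]+" = M + mc[["proton"]],
    "[M+Na]+" = M + mc[["Na"]] - mc[["electron"]],
    stop("unsupported adduct: ", adduct)
  )
  mz + isotope_peak * 1.0033548378 / z
}

#' @rdname theoretical_mz
#' @return `adduct_charge` returns the charge magnitude z of an adduct.
#' @export
adduct_charge <- function(adduct) {
  if (!adduct %in% .supported_adducts) {
    stop("unsupported adduct: ", adduct)
  }
  if (adduct == "[M-2H]2-") 2L else 1L
}

#' Relative mass error in parts per million
#'
#' @param observed_mz,theoretical_mz Observed and theoretical m/z (Da).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed_mz, theoretical_mz) {
  if (any(theoretical_mz <= 0)) stop("theoretical m/z must be > 0")
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Ring-and-double-bond equivalents of a CHO formula
#'
#' `RDBE = C - H/2 + 1`; non-negative and integer for an even-electron
#' neutral CHO species.
#'
#' @inheritParams parse_formula
#' @return A single number.
#' @export
rdbe <- function(formula) {
  cnt <- parse_formula(formula)
  cnt[["C"]] - cnt[["H"]] / 2 + 1
}

#' Exhaustive CHO molecular-formula enumeration for an observed ion
#'
#' Enumerates all neutral CxHyOz formulas within the element ranges whose
#' ion (under `adduct`, optionally on an isotopologue peak) falls within
#' `tol_ppm` of the observed m/z, requiring an even hydrogen count and
#' `RDBE >= 0` (even-electron neutral species). Candidates are ranked by
#' absolute ppm error.
#'
#' @param observed_mz Observed ion m/z (Da).
#' @param adduct Adduct assumed for the ion.
#' @param tol_ppm Mass tolerance in ppm (default 5).
#' @param c_range,h_range,o_range Inclusive element-count ranges
#'   (defaults C 1-60, H 0-120, O 0-40).
#' @param isotope_peak See [theoretical_mz()].
#' @return A data frame of candidates (possibly empty): `formula`, `C`,
#'   `H`, `O`, `adduct`, `theoretical_mz`, `ppm_error`, `rdbe`, ordered
#'   by `abs(ppm_error)`.
#' @examples
#' enumerate_cho_formulas(341.1089, "[M-H]-")[1, ]
#' @export
enumerate_cho_formulas <- function(observed_mz, adduct = "[M-H]-",
                                   tol_ppm = 5,
                                   c_range = c(1L, 60L),
                                   h_range = c(0L, 120L),
                                   o_range = c(0L, 40L),
                                   isotope_peak = 0L) {
  mc <- mass_constants()
  z <- adduct_charge(adduct)
  ## invert the adduct arithmetic: neutral mass window matching tol_ppm
  iso <- isotope_peak * 1.0033548378 / z
  neutral_of_mz <- function(mz) {
    mz <- mz - iso
    switch(adduct,
      "[M-H]-" = mz + mc[["H"]] - mc[["electron"]],
      "[M+HCOO]-" = mz - mc[["HCOO"]] - mc[["electron"]],
      "[M-2H]2-" = 2 * mz + 2 * mc[["H"]] - 2 * mc[["electron"]],
      "[M+H]+" = mz - mc[["proton"]],
      "[M+Na]+" = mz - mc[["Na"]] + mc[["electron"]])
  }
  tol_da <- observed_mz * tol_ppm / 1e6 * z  # per-unit-charge tolerance
  m_lo <- neutral_of_mz(observed_mz) - tol_da
  m_hi <- neutral_of_mz(observed_mz) + tol_da
  out <- list()
  for (C in seq(c_range[1], c_range[2])) {
    for (O in seq(o_range[1], o_range[2])) {
      rest_lo <- m_lo - C * mc[["C"]] - O * mc[["O"]]
      rest_hi <- m_hi - C * mc[["C"]] - O * mc[["O"]]
      if (rest_hi < h_range[1] * mc[["H"]]) break
      h_min <- max(h_range[1], ceiling(rest_lo / mc[["H"]] - 1e-9))
      h_max <- min(h_range[2], floor(rest_hi / mc[["H"]] + 1e-9))
      for (H in seq_len(max(0L, h_max - h_min + 1L)) + h_min - 1L) {
        if (H %% 2L != 0L) next              # even-electron neutral
        if (C - H / 2 + 1 < 0) next          # RDBE >= 0
        f <- c(C = C, H = H, O = O, Na = 0L)
        th <- theoretical_mz(f, adduct, isotope_peak)
        pe <- ppm_error(observed_mz, th)
        if (abs(pe) <= tol_ppm) {
          out[[length(out) + 1L]] <- data.frame(
            formula = paste0("C", C, "H", H, if (O > 0) paste0("O", O)
                             else ""),
            C = C, H = H, O = O, adduct = adduct,
            theoretical_mz = th, ppm_error = pe, rdbe = C - H / 2 + 1,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(formula = character(), C = integer(),
                      H = integer(), O = integer(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      rdbe = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(abs(res$ppm_error)), , drop = FALSE]
}

#' Annotate features with CHO formula candidates
#'
#' Runs [enumerate_cho_formulas()] for each feature and adduct and
#' returns a flat candidate table (one row per feature x adduct x
#' candidate), ranked by absolute ppm error within each feature.
#'
#' @param features Data frame with columns `feature_id` and `mz`
#'   (observed ion m/z); an `rt_min` column is carried through when
#'   present. The top-VIP table from [top_vips()] joined to feature
#'   metadata is a typical input.
#' @param adducts Character vector of adducts to try (default
#'   `"[M-H]-"`, the primary negative-mode species).
#' @param tol_ppm Mass tolerance in ppm.
#' @param ... Passed to [enumerate_cho_formulas()] (element ranges).
#' @return Data frame with columns `feature_id`, (`rt_min`,) `mz`,
#'   `adduct`, `formula`, `theoretical_mz`, `ppm_error`, `rdbe`.
#' @export
annotate_features <- function(features, adducts = "[M-H]-", tol_ppm = 5,
                              ...) {
  stopifnot(all(c("feature_id", "mz") %in% names(features)))
  out <- list()
  for (i in seq_len(nrow(features))) {
    for (ad in adducts) {
      cand <- enumerate_cho_formulas(features$mz[i], ad, tol_ppm, ...)
      if (!nrow(cand)) next
      base <- data.frame(feature_id = features$feature_id[i],
                         mz = features$mz[i],
                         stringsAsFactors = FALSE)
      if ("rt_min" %in% names(features)) {
        base$rt_min <- features$rt_min[i]
      }
      out[[length(out) + 1L]] <-
        cbind(base[rep(1L, nrow(cand)), , drop = FALSE],
              cand[, c("adduct", "formula", "theoretical_mz",
                       "ppm_error", "rdbe")])
    }
  }
  if (!length(out)) {
    return(data.frame(feature_id = character(), mz = numeric(),
                      adduct = character(), formula = character(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      rdbe = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Curated reference ions for oak-litter drought biomarkers
#'
#' Loads the package's curated table of reported negative-mode ions of
#' drought-discriminating metabolites from holm and downy oak litter
#' (flavonol and tannin derivatives, triterpenoid glycosides, a
#' disaccharide): observed m/z, adduct species, neutral CHO formula,
#' reported mass error, and putative identity. Rows whose printed m/z /
#' formula pair is internally inconsistent (verified against exhaustive
#' enumeration) carry `consistent = FALSE`; ions picked on an A+1
#' isotopologue peak carry `isotope_peak = 1`.
#'
#' @return The reference table as a data frame.
#' @export
reference_vip_ions <- function() {
  path <- system.file("extdata", "vip_reference_ions.csv",
                      package = "litterlab", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$consistent <- as.logical(df$consistent)
  df
}
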