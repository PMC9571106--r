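## Factorial linear modelling of litter mass remaining: treatment-coded
## design matrices, OLS fits summarised with an RSS-based AIC, AIC
## stepwise selection (delegated to MASS::stepAIC), and sequential
## (Type I) ANOVA tables reported as percentages of total sums of
## squares.

.model_factors <- c("species", "litter_type", "treatment", "forest",
                    "time_months")

## Records -> model frame with the five design factors and the response.
.model_frame <- function(records, response = c("remaining_mass_pct",
                                               "mass_loss_pct")) {
  response <- match.arg(response)
  records <- validate_litterbags(records)
  df <- records[, c("species", "litter_type", "treatment", "forest")]
  df$time_months <- factor(records$time_months,
                           levels = design_levels()$time_months)
  fun <- if (response == "remaining_mass_pct") remaining_mass_pct
         else mass_loss_pct
  df$.response <- fun(records$initial_dry_mass_g,
                      records$final_dry_mass_g)
  df
}

#' Build a treatment-coded design matrix for litterbag records
#'
#' Terms are drawn from the five design factors (`species`,
#' `litter_type`, `treatment`, `forest`, `time_months`) and their `:`
#' interactions; dummy columns use reference-level (treatment) coding and
#' are grouped by term.
#'
#' @param records Litterbag data frame.
#' @param formula_terms Character vector of terms, e.g.
#'   `c("species", "forest", "species:forest")`; empty for an
#'   intercept-only design.
#' @return A list with the design matrix `X`, `assign` (term index per
#'   column, 0 = intercept), `terms` and the model frame `data`.
#' @export
build_design <- function(records, formula_terms = character()) {
  if (anyDuplicated(formula_terms)) {
    stop("duplicate term(s): ",
         paste(unique(formula_terms[duplicated(formula_terms)]),
               collapse = ", "))
  }
  used <- unique(unlist(strsplit(formula_terms, ":", fixed = TRUE)))
  bad <- setdiff(used, .model_factors)
  if (length(bad)) {
    stop("unknown factor(s): ", paste(bad, collapse = ", "))
  }
  df <- .model_frame(records)
  rhs <- if (length(formula_terms)) paste(formula_terms, collapse = " + ")
         else "1"
  X <- model.matrix(as.formula(paste("~", rhs)), data = df)
  if (qr(X)$rank < ncol(X)) {
    asn <- attr(X, "assign")
    piv <- qr(X)$pivot
    aliased <- unique(asn[piv[-seq_len(qr(X)$rank)]])
    stop("rank-deficient design; aliased term(s): ",
         paste(c("(Intercept)", formula_terms)[aliased + 1L],
               collapse = ", "))
  }
  list(X = X, assign = attr(X, "assign"),
       terms = formula_terms, data = df)
}

#' Ordinary least squares fit of a design
#'
#' @param design A design list from [build_design()], or a plain numeric
#'   matrix (including an intercept column if wanted).
#' @param response Numeric response vector.
#' @return A list of class `massloss_fit` with `coefficients`, `rss`,
#'   `tss`, `n`, `k` (estimated mean parameters), `r2` and `aic` (see
#'   [aic_score()]).
#' @export
fit_ols <- function(design, response) {
  X <- if (is.list(design)) design$X else design
  if (nrow(X) <= ncol(X)) stop("need more observations than parameters")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("singular design matrix")
  coef <- qr.coef(qrx, response)
  res <- response - X %*% coef
  rss <- sum(res^2)
  tss <- sum((response - mean(response))^2)
  fit <- list(coefficients = coef, rss = rss, tss = tss,
              n = length(response), k = ncol(X),
              r2 = if (tss > 0) 1 - rss / tss else NA_real_,
              terms = if (is.list(design)) design$terms else NULL)
  fit$aic <- aic_score(fit)
  class(fit) <- "massloss_fit"
  fit
}

#' Gaussian AIC from the residual sum of squares
#'
#' `AIC = n * log(RSS / n) + 2 * (k + 1)`, counting the residual variance
#' as an estimated parameter. Only AIC differences between models fitted
#' to the same data are meaningful; a saturated fit (`RSS = 0`) is
#' flagged as `-Inf`.
#'
#' @param fit A `massloss_fit`, or a list with elements `n`, `rss`, `k`.
#' @return A single number (`-Inf` when `RSS` is numerically zero).
#' @examples
#' aic_score(list(n = 10, rss = 10, k = 1))
#' @export
aic_score <- function(fit) {
  if (fit$rss <= .Machine$double.eps * fit$n) return(-Inf)
  fit$n * log(fit$rss / fit$n) + 2 * (fit$k + 1)
}

#' AIC stepwise selection of the mass-remaining model
#'
#' Fits the full factorial model of the response on the five design
#' factors (all interactions up to `max_order`), then searches with both
#' forward and backward moves for the most parsimonious model by AIC
#' (`MASS::stepAIC`), respecting marginality (an interaction is only
#' considered when its margins are present). Deterministic given the
#' data.
#'
#' @param records Litterbag data frame.
#' @param response `"remaining_mass_pct"` (default) or
#'   `"mass_loss_pct"`.
#' @param max_order Highest interaction order in the scope (default 3).
#' @return A list with the selected `fit` (an `lm`), `formula`, the
#'   full-model `full_fit`, and `aic`/`r2` for both models under the
#'   [aic_score()] convention.
#' @export
stepwise_select <- function(records,
                            response = c("remaining_mass_pct",
                                         "mass_loss_pct"),
                            max_order = 3L) {
  response <- match.arg(response)
  df <- .model_frame(records, response)
  rhs <- if (max_order > 1L) {
    paste0("(", paste(.model_factors, collapse = " + "), ")^", max_order)
  } else {
    paste(.model_factors, collapse = " + ")
  }
  full <- lm(as.formula(paste(".response ~", rhs)), data = df)
  sel <- MASS::stepAIC(full,
                       scope = list(lower = ~1,
                                    upper = as.formula(paste("~", rhs))),
                       direction = "both", trace = 0)
  list(fit = sel,
       formula = formula(sel),
       full_fit = full,
       aic = .lm_aic_score(sel), r2 = summary(sel)$r.squared,
       full_aic = .lm_aic_score(full),
       full_r2 = summary(full)$r.squared)
}

.lm_aic_score <- function(fit) {
  aic_score(list(n = length(fit$residuals),
                 rss = sum(fit$residuals^2),
                 k = fit$rank))
}

#' Sequential (Type I) ANOVA with percent sums of squares
#'
#' Terms enter in their declared order; each row's SS is the RSS drop
#' when the term joins the model, F-tested against the residual mean
#' square of the full fit. `%SS` columns (terms + residual) sum to 100.
#'
#' @param fit An `lm` fit (e.g. `stepwise_select(...)$fit`), or a
#'   litterbag data frame (then `response` and `formula_terms` define the
#'   model).
#' @param response,formula_terms Used only when `fit` is a data frame.
#' @return A data frame with columns `term`, `df`, `ss`, `pct_ss`,
#'   `f_value`, `p_value`, ending with the residual row.
#' @export
sequential_anova <- function(fit, response = "remaining_mass_pct",
                             formula_terms = NULL) {
  if (is.data.frame(fit)) {
    df <- .model_frame(fit, response)
    rhs <- paste(formula_terms, collapse = " + ")
    fit <- lm(as.formula(paste(".response ~", rhs)), data = df)
  }
  if (fit$df.residual == 0L) stop("zero residual degrees of freedom")
  a <- anova(fit)
  ss <- a[["Sum Sq"]]
  data.frame(term = rownames(a), df = a$Df, ss = ss,
             pct_ss = 100 * ss / sum(ss),
             f_value = a[["F value"]], p_value = a[["Pr(>F)"]],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-way ANOVA of an initial litter trait
#'
#' Classical fixed-effects ANOVA of one trait on litter type, species and
#' their interaction, F-tested against the residual mean square —
#' the standard analysis of initial litter quality in a 2 x 3 design with
#' replicates.
#'
#' @param trait_records Long trait data frame (see
#'   [generate_trait_samples()]), already restricted to one trait, or
#'   carrying a `trait` column plus the `trait` argument.
#' @param trait Optional trait name to select.
#' @return A data frame with rows `litter_type`, `species`,
#'   `litter_type:species` and `Residuals` and columns `df`, `ss`,
#'   `f_value`, `p_value`, plus attribute `flagged` (TRUE when the
#'   interaction is untestable: fewer than 2 replicates per cell or zero
#'   residual variance).
#' @export
two_way_anova <- function(trait_records, trait = NULL) {
  df <- trait_records
  if (!is.null(trait)) df <- df[df$trait == trait, ]
  if (!is.null(df$trait) && length(unique(df$trait)) > 1L) {
    stop("several traits present; pass `trait` to select one")
  }
  df$litter_type <- droplevels(as.factor(df$litter_type))
  df$species <- droplevels(as.factor(df$species))
  cells <- table(df$litter_type, df$species)
  flagged <- any(cells < 2L)
  fit <- aov(value ~ litter_type * species, data = df)
  a <- anova(fit)
  if (a["Residuals", "Sum Sq"] <= .Machine$double.eps * nrow(df)) {
    flagged <- TRUE
  }
  out <- data.frame(term = rownames(a), df = a$Df, ss = a[["Sum Sq"]],
                    f_value = a[["F value"]], p_value = a[["Pr(>F)"]],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "flagged") <- flagged
  out
}
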