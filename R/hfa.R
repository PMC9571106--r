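## The additional-decomposition-at-home (ADH) statistic family for a
## reciprocal transplant of N species among their N home forests:
##
##   HDD_i = (D_iI - D_jI) + (D_iI - D_kI)        home decomposition diff.
##   ADD_i = (D_iJ - D_jJ) + (D_iK - D_kK)        away decomposition diff.
##   H     = (HDD_i + HDD_j + HDD_k) / (N - 1)    overall home effect
##   ADH_i = HDD_i - ADD_i - H
##
## where D_sF is the decomposition of species s litter in forest F and
## forest I/J/K is the home of species i/j/k. D is mass loss (%) by
## default, so ADH > 0 reads "decomposes faster at home" (home-field
## advantage) and ADH < 0 a home-field disadvantage.

.check_slice <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("cell-mean slice must be a square species x forest matrix")
  }
  if (anyNA(D)) {
    idx <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop("missing cell: species ", rownames(D)[idx[1]] %||% idx[1],
         " in forest ", colnames(D)[idx[2]] %||% idx[2])
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Home decomposition difference HDD for one species
#'
#' In the focal species' home forest, its decomposition is compared to
#' that of each foreign litter decomposing there:
#' `HDD_i = (D_iI - D_jI) + (D_iI - D_kI)`.
#'
#' @param cell_means Square numeric matrix of decomposition values, rows =
#'   litter species, columns = forests, with row `s` at home in column `s`
#'   (one precipitation treatment x time slice; see [cell_mean_slice()]).
#' @param species_i Row index or row name of the focal species.
#' @return A single number, in the units of `cell_means` (percentage
#'   points of mass loss by default).
#' @export
compute_hdd <- function(cell_means, species_i) {
  .check_slice(cell_means)
  i <- .species_index(cell_means, species_i)
  others <- setdiff(seq_len(nrow(cell_means)), i)
  sum(cell_means[i, i] - cell_means[others, i])
}

#' Away decomposition difference ADD for one species
#'
#' In each away forest, the focal litter is compared to the local home
#' litter: `ADD_i = (D_iJ - D_jJ) + (D_iK - D_kK)`.
#'
#' @inheritParams compute_hdd
#' @return A single number.
#' @export
compute_add <- function(cell_means, species_i) {
  .check_slice(cell_means)
  i <- .species_index(cell_means, species_i)
  others <- setdiff(seq_len(nrow(cell_means)), i)
  sum(cell_means[i, others] - cell_means[cbind(others, others)])
}

.species_index <- function(D, species_i) {
  if (is.character(species_i)) {
    i <- match(species_i, rownames(D))
    if (is.na(i)) stop("unknown species: ", species_i)
    return(i)
  }
  i <- as.integer(species_i)
  if (i < 1L || i > nrow(D)) stop("species index out of range: ", species_i)
  i
}

#' Total home-field effect H over all species
#'
#' `H = sum(HDD) / (N - 1)`; shared by all species of one treatment x
#' time slice.
#'
#' @param hdd_values Numeric vector, one HDD per species.
#' @param n_species Number of species `N` (defaults to
#'   `length(hdd_values)`); must be at least 2.
#' @return A single number.
#' @export
compute_total_h <- function(hdd_values, n_species = length(hdd_values)) {
  if (n_species < 2L) stop("n_species must be >= 2")
  sum(hdd_values) / (n_species - 1)
}

#' ADH statistic for every species of a transplant slice
#'
#' Computes `ADH_i = HDD_i - ADD_i - H` for each species from a complete
#' species x forest decomposition table. ADH is invariant under adding a
#' constant to every cell (and under per-forest or per-treatment shifts),
#' and flips sign exactly when mass loss is replaced by remaining mass.
#'
#' @inheritParams compute_hdd
#' @return A data frame with one row per species and columns `species`,
#'   `HDD`, `ADD`, `H`, `ADH`.
#' @examples
#' D <- matrix(c(50, 65, 70, 60, 52, 62, 55, 58, 48), 3, 3, byrow = TRUE,
#'             dimnames = list(design_levels()$species,
#'                             design_levels()$forest))
#' compute_adh_table(D)
#' @export
compute_adh_table <- function(cell_means) {
  .check_slice(cell_means)
  n <- nrow(cell_means)
  hdd <- vapply(seq_len(n), function(i) compute_hdd(cell_means, i), 0)
  add <- vapply(seq_len(n), function(i) compute_add(cell_means, i), 0)
  h <- compute_total_h(hdd, n)
  data.frame(
    species = rownames(cell_means) %||% as.character(seq_len(n)),
    HDD = hdd, ADD = add, H = h, ADH = hdd - add - h,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## ADH_i as a linear functional of the species x forest slice: returns the
## n x n weight matrix W with ADH_i = sum(W * D). Used by the calibration
## solver; equivalent to compute_adh_table (tested to 1e-12).
adh_weight_matrix <- function(i, n = 3L) {
  others <- setdiff(seq_len(n), i)
  W <- matrix(0, n, n)
  W[i, i] <- W[i, i] + (n - 1)            # HDD_i
  W[others, i] <- W[others, i] - 1
  W[i, others] <- W[i, others] - 1        # -ADD_i
  W[cbind(others, others)] <- W[cbind(others, others)] + 1
  for (s in seq_len(n)) {                 # -H = -sum(HDD)/(n-1)
    os <- setdiff(seq_len(n), s)
    W[s, s] <- W[s, s] - 1
    W[os, s] <- W[os, s] + 1 / (n - 1)
  }
  W
}

#' Resample replicate litterbags into ADH draws
#'
#' For one precipitation treatment and sampling date, each draw picks one
#' litterbag per species x forest cell (litter types pooled), forms the
#' 3 x 3 decomposition table and evaluates [compute_adh_table()]. Within a
#' cell, bags are assigned to draws without replacement for as long as
#' unused bags remain, so that draws are statistically independent
#' replicates; only when `n_draws` exceeds the number of bags per cell are
#' bags recycled (with a warning). The default design (2 litter types x 7
#' replicates = 14 bags per cell) supports the default 12 draws without
#' any reuse.
#'
#' @param records Litterbag data frame (see [read_litterbag_csv()]).
#' @param treatment `"ND"` or `"AD"`.
#' @param time_months 12 or 24.
#' @param n_draws Number of resampled ADH replicates (default 12).
#' @param seed Optional integer seed; fixes the draw assignment.
#' @param d_metric `"mass_loss_pct"` (default) or `"remaining_pct"`.
#' @return A list with `draws` (matrix, `n_draws` rows x one column per
#'   species), `treatment`, `time_months`, `d_metric`.
#' @export
draw_adh_replicates <- function(records, treatment, time_months,
                                n_draws = 12L, seed = NULL,
                                d_metric = c("mass_loss_pct",
                                             "remaining_pct")) {
  d_metric <- match.arg(d_metric)
  records <- validate_litterbags(records)
  sub <- records[records$treatment == treatment &
                 records$time_months == time_months, ]
  d <- if (d_metric == "mass_loss_pct") {
    mass_loss_pct(sub$initial_dry_mass_g, sub$final_dry_mass_g)
  } else {
    remaining_mass_pct(sub$initial_dry_mass_g, sub$final_dry_mass_g)
  }
  sp <- design_levels()$species
  fo <- design_levels()$forest
  cells <- vector("list", 9L)
  dim(cells) <- c(3L, 3L)
  for (s in 1:3) for (f in 1:3) {
    v <- d[sub$species == sp[s] & sub$forest == fo[f]]
    if (length(v) == 0L) {
      stop("empty cell: species ", sp[s], " in ", fo[f],
           " (treatment ", treatment, ", ", time_months, " months)")
    }
    cells[[s, f]] <- v
  }
  n_bags <- vapply(cells, length, 0L)
  if (n_draws > min(n_bags)) {
    warning("n_draws (", n_draws, ") exceeds bags per cell (",
            min(n_bags), "); bags are reused across draws")
  }
  draws <- with_seed(seed, {
    sel <- lapply(cells, function(v) {
      k <- length(v)
      idx <- unlist(lapply(seq_len(ceiling(n_draws / k)),
                           function(r) sample.int(k)))
      v[idx[seq_len(n_draws)]]
    })
    out <- matrix(NA_real_, n_draws, 3L, dimnames = list(NULL, sp))
    for (dr in seq_len(n_draws)) {
      D <- matrix(vapply(sel, `[`, 0, dr), 3L, 3L,
                  dimnames = list(sp, fo))
      out[dr, ] <- compute_adh_table(D)$ADH
    }
    out
  })
  list(draws = draws, treatment = treatment, time_months = time_months,
       d_metric = d_metric, n_draws = n_draws)
}

#' One-sample Student test of ADH draws against zero
#'
#' `t = mean(draws) / (sd(draws) / sqrt(n))` on `n - 1` degrees of
#' freedom, two-sided. Degenerate draws (zero variance, or fewer than two
#' values) are flagged instead of tested.
#'
#' @param draws Numeric vector of ADH replicate values.
#' @return A list with `t_value`, `p_value`, `df`, `n`, `mean` and the
#'   logical `flagged`.
#' @examples
#' adh_ttest(c(1, 2, 3))
#' @export
adh_ttest <- function(draws) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 2L || sd(draws) == 0) {
    return(list(t_value = NA_real_, p_value = NA_real_,
                df = NA_integer_, n = n,
                mean = if (n) mean(draws) else NA_real_, flagged = TRUE))
  }
  t <- mean(draws) / (sd(draws) / sqrt(n))
  list(t_value = t, p_value = 2 * pt(-abs(t), n - 1L),
       df = n - 1L, n = n, mean = mean(draws), flagged = FALSE)
}

#' Full home-field advantage analysis of a litterbag table
#'
#' For every precipitation treatment x sampling date present in the data,
#' computes the point ADH decomposition (from cell means over all bags,
#' litter types pooled) and tests it against zero with
#' [draw_adh_replicates()] + [adh_ttest()].
#'
#' @inheritParams draw_adh_replicates
#' @return A data frame with columns `treatment`, `time_months`,
#'   `species`, `HDD`, `ADD`, `H`, `ADH`, `t_value`, `p_value`, `n_draws`.
#' @export
hfa_analysis <- function(records, n_draws = 12L, seed = NULL,
                         d_metric = c("mass_loss_pct", "remaining_pct")) {
  d_metric <- match.arg(d_metric)
  records <- validate_litterbags(records)
  lv <- design_levels()
  out <- list()
  counter <- 0L
  for (tm in lv$time_months) for (tr in lv$treatment) {
    sub <- records[records$treatment == tr & records$time_months == tm, ]
    if (nrow(sub) == 0L) next
    counter <- counter + 1L
    D <- .cell_means_from_records(sub, d_metric)
    pt_est <- compute_adh_table(D)
    dr <- draw_adh_replicates(records, tr, tm, n_draws = n_draws,
                              seed = if (is.null(seed)) NULL
                                     else seed + counter,
                              d_metric = d_metric)
    tests <- apply(dr$draws, 2L, adh_ttest)
    out[[length(out) + 1L]] <- data.frame(
      treatment = tr, time_months = tm, species = pt_est$species,
      HDD = pt_est$HDD, ADD = pt_est$ADD, H = pt_est$H, ADH = pt_est$ADH,
      t_value = vapply(tests, `[[`, 0, "t_value"),
      p_value = vapply(tests, `[[`, 0, "p_value"),
      n_draws = n_draws, row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

## Species x forest matrix of mean decomposition for one data subset.
.cell_means_from_records <- function(sub, d_metric) {
  d <- if (d_metric == "mass_loss_pct") {
    mass_loss_pct(sub$initial_dry_mass_g, sub$final_dry_mass_g)
  } else {
    remaining_mass_pct(sub$initial_dry_mass_g, sub$final_dry_mass_g)
  }
  sp <- design_levels()$species
  fo <- design_levels()$forest
  D <- matrix(NA_real_, 3L, 3L, dimnames = list(sp, fo))
  for (s in 1:3) for (f in 1:3) {
    v <- d[sub$species == sp[s] & sub$forest == fo[f]]
    D[s, f] <- mean(v)
  }
  D
}
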