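# Independent oracles: literal scalar transcriptions of the reference
# formulas, kept free of the vectorized package code paths they check.

# ADH by direct substitution: HDD_i, ADD_i, H, ADH_i, one term at a time.
oracle_adh <- function(D) {
  stopifnot(nrow(D) == 3, ncol(D) == 3)
  hdd <- numeric(3)
  for (i in 1:3) {
    o <- setdiff(1:3, i)
    hdd[i] <- (D[i, i] - D[o[1], i]) + (D[i, i] - D[o[2], i])
  }
  add <- numeric(3)
  for (i in 1:3) {
    o <- setdiff(1:3, i)
    j <- o[1]; k <- o[2]
    add[i] <- (D[i, j] - D[j, j]) + (D[i, k] - D[k, k])
  }
  H <- (hdd[1] + hdd[2] + hdd[3]) / (3 - 1)
  hdd - add - H
}

# Brute-force CHO enumeration over the full grid, no arithmetic shortcuts.
oracle_enumerate_cho <- function(observed_mz, adduct, tol_ppm,
                                 c_range, h_range, o_range) {
  hits <- character()
  for (C in c_range[1]:c_range[2]) {
    for (H in h_range[1]:h_range[2]) {
      if (H %% 2 != 0 || C - H / 2 + 1 < 0) next
      for (O in o_range[1]:o_range[2]) {
        th <- theoretical_mz(c(C = C, H = H, O = O), adduct)
        if (abs(1e6 * (observed_mz - th) / th) <= tol_ppm) {
          hits <- c(hits, paste0("C", C, "H", H,
                                 if (O > 0) paste0("O", O) else ""))
        }
      }
    }
  }
  sort(hits)
}

# Minimal feature matrix built by hand for filter unit tests.
toy_feature_matrix <- function(intensity, rt = NULL,
                               roles = NULL, groups = NULL) {
  nf <- nrow(intensity)
  ns <- ncol(intensity)
  if (is.null(rt)) rt <- seq_len(nf)
  if (is.null(roles)) roles <- rep("sample", ns)
  if (is.null(groups)) groups <- ifelse(roles == "sample", "ND", "all")
  feature_matrix(
    features = data.frame(feature_id = sprintf("T%03d", seq_len(nf)),
                          mz = 100 + seq_len(nf), rt_min = rt,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = sprintf("%s_%s_%d", roles, groups,
                                             seq_len(ns)),
                         role = roles, group = groups,
                         stringsAsFactors = FALSE),
    intensity = intensity
  )
}

# Cell-mean table assembled directly from a function of the design cell,
# for simulations with known structure.
make_cell_table <- function(fun) {
  lv <- design_levels()
  grid <- expand.grid(species = lv$species, forest = lv$forest,
                      treatment = lv$treatment,
                      time_months = lv$time_months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$D <- mapply(fun, grid$species, grid$forest, grid$treatment,
                   grid$time_months)
  grid$species <- factor(grid$species, levels = lv$species)
  grid$forest <- factor(grid$forest, levels = lv$forest)
  grid$treatment <- factor(grid$treatment, levels = lv$treatment)
  structure(grid, residual_norm = 0, metric = "mass_loss_pct",
            class = c("cell_mean_table", class(grid)))
}
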