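## Seeded generators for the two kinds of synthetic data the pipeline is
## exercised on: litterbag tables drawn around a calibrated cell-mean
## table, and LC-MS feature matrices with planted ground truth
## (discriminating features, blank contamination, unstable-QC features,
## co-eluting redundant clusters).

#' Configuration for the litterbag generator
#'
#' Defaults reproduce the reciprocal transplant study conditions: 3
#' species x 3 forests x 2 litter types x 2 precipitation treatments
#' (= 36 modalities) x 2 sampling dates x 7 replicates = 504 bags of 10 g
#' air-dried litter. Within-cell noise is 4 percentage points of mass
#' loss; the litter-type (leaf origin) effect defaults to zero, matching
#' its observed non-significance.
#'
#' @param cell_means A `cell_mean_table`; default
#'   [calibrate_cell_means()].
#' @param noise_sd Within-cell SD of mass loss, percentage points (> 0).
#' @param replicates Bags per modality and date (>= 2).
#' @param initial_dry_mass_g Air-dried mass per bag, grams.
#' @param litter_type_effect Mass-loss shift (points) added when the
#'   litter originates from the amplified-drought plot.
#' @param seed Integer seed.
#' @return A list of class `litter_sim_config`.
#' @export
litter_sim_config <- function(cell_means = calibrate_cell_means(),
                              noise_sd = 4, replicates = 7L,
                              initial_dry_mass_g = 10,
                              litter_type_effect = 0, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (replicates < 2L) stop("replicates must be >= 2")
  if (initial_dry_mass_g <= 0) stop("initial_dry_mass_g must be > 0")
  structure(list(cell_means = cell_means, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 initial_dry_mass_g = initial_dry_mass_g,
                 litter_type_effect = litter_type_effect,
                 seed = seed),
            class = "litter_sim_config")
}

#' Generate a seeded litterbag dataset
#'
#' One record per modality x date x replicate. Per-bag mass loss is drawn
#' from a Normal centred on the cell mean (plus the litter-type effect),
#' truncated to `[0, 100]` by rejection; the final dry mass is derived
#' from the initial mass and rounded to a microgram so that the CSV round
#' trip is lossless. Identical seeds give identical output.
#'
#' @param config A [litter_sim_config()].
#' @return A litterbag data frame (see [read_litterbag_csv()] for the
#'   columns).
#' @examples
#' bags <- generate_litterbags(litter_sim_config(seed = 7))
#' nrow(bags)
#' @export
generate_litterbags <- function(config = litter_sim_config()) {
  stopifnot(inherits(config, "litter_sim_config"))
  tab <- config$cell_means
  if (attr(tab, "metric") == "remaining_pct") {
    tab$D <- 100 - tab$D
  }
  lv <- design_levels()
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      litter_type = lv$litter_type,
                      treatment = lv$treatment,
                      forest = lv$forest,
                      species = lv$species,
                      time_months = lv$time_months,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(sp, fo, tr, tm) paste(sp, fo, tr, tm, sep = "|")
  mu <- setNames(tab$D, key(tab$species, tab$forest, tab$treatment,
                            tab$time_months))
  m <- mu[key(grid$species, grid$forest, grid$treatment,
              grid$time_months)]
  if (anyNA(m)) stop("cell-mean table does not cover the full design")
  m <- m + config$litter_type_effect * (grid$litter_type == "AD")
  loss <- with_seed(config$seed, .rnorm_trunc(m, config$noise_sd, 0, 100))
  data.frame(
    forest = factor(grid$forest, levels = lv$forest),
    species = factor(grid$species, levels = lv$species),
    litter_type = factor(grid$litter_type, levels = lv$litter_type),
    treatment = factor(grid$treatment, levels = lv$treatment),
    time_months = as.integer(grid$time_months),
    replicate = as.integer(grid$replicate),
    initial_dry_mass_g = config$initial_dry_mass_g,
    final_dry_mass_g = round(config$initial_dry_mass_g * (1 - loss / 100),
                             6L),
    stringsAsFactors = FALSE
  )
}

## Normal draws truncated to [lo, hi] by rejection.
.rnorm_trunc <- function(mean, sd, lo, hi) {
  x <- rnorm(length(mean), mean, sd)
  for (it in 1:100) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- rnorm(length(bad), mean[bad], sd)
  }
  pmin(pmax(x, lo), hi)
}

## Initial litter quality of the three species by origin plot: means and
## SDs (on n = 5) for a representative trait panel; used as the default
## population for the trait-sample generator.
.default_trait_table <- function() {
  rows <- list(
    ## trait, unit, QilexND, QilexAD, QpubND, QpubAD, PhalND, PhalAD,
    ##              and matching SEs
    list("C", "mg/g", c(478.09, 477.26, 462.61, 462.11, 516.09, 518.47),
         c(1.35, 1.29, 2.65, 5.49, 1.60, 2.90)),
    list("N", "mg/g", c(9.62, 8.22, 6.39, 6.17, 5.36, 5.49),
         c(0.20, 0.18, 0.20, 0.12, 0.13, 0.09)),
    list("Ca", "mg/g", c(25.09, 21.68, 32.90, 28.89, 18.41, 16.10),
         c(0.56, 0.42, 0.77, 0.58, 0.18, 0.19)),
    list("phenolics", "mg/g", c(32.87, 58.48, 40.77, 44.18, 38.59, 39.96),
         c(1.58, 2.89, 2.59, 2.17, 1.17, 1.49)),
    list("WSC", "mg/g", c(187.61, 201.32, 293.38, 243.24, 340.02, 301.41),
         c(10.19, 13.36, 12.08, 6.00, 7.13, 6.07)),
    list("WHC", "%", c(137.24, 129.89, 146.90, 140.06, 113.89, 114.43),
         c(0.98, 1.70, 1.01, 0.75, 1.03, 1.38)),
    list("SLA", "cm2/g", c(51.50, 47.80, 133.13, 128.16, 83.50, 85.06),
         c(0.88, 0.87, 0.41, 1.36, 2.19, 2.64))
  )
  lv <- design_levels()
  cells <- expand.grid(litter_type = lv$litter_type,
                       species = lv$species,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = cells$species, litter_type = cells$litter_type,
               trait = r[[1]], unit = r[[2]],
               mean = r[[3]], sd = r[[4]] * sqrt(5),
               stringsAsFactors = FALSE)
  }))
}

#' Generate initial litter-quality samples
#'
#' Draws per-sample trait values around species x litter-type population
#' means (a built-in panel of C, N, Ca, phenolics, WSC, WHC and SLA with
#' realistic dispersions). With the default 5 replicates this emulates the
#' 3 species x 2 litter types x 5 replicates = 30 initial-quality
#' samples of the study design.
#'
#' @param replicates Samples per species x litter type (default 5).
#' @param traits Character vector restricting the trait panel; default
#'   all.
#' @param seed Integer seed.
#' @return A long data frame with columns `species`, `litter_type`,
#'   `replicate`, `trait`, `value`, `unit`.
#' @export
generate_trait_samples <- function(replicates = 5L, traits = NULL,
                                   seed = 1L) {
  pop <- .default_trait_table()
  if (!is.null(traits)) {
    bad <- setdiff(traits, unique(pop$trait))
    if (length(bad)) stop("unknown trait(s): ", paste(bad, collapse = ", "))
    pop <- pop[pop$trait %in% traits, ]
  }
  out <- pop[rep(seq_len(nrow(pop)), each = replicates), ]
  out$replicate <- rep(seq_len(replicates), nrow(pop))
  out$value <- with_seed(seed, {
    v <- rnorm(nrow(out), out$mean, out$sd)
    pmax(v, 0)  # concentrations cannot be negative
  })
  lv <- design_levels()
  data.frame(species = factor(out$species, levels = lv$species),
             litter_type = factor(out$litter_type,
                                  levels = lv$litter_type),
             replicate = out$replicate, trait = out$trait,
             value = out$value, unit = out$unit,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Configuration for the LC-MS feature-matrix generator
#'
#' Defaults emulate one negative-mode acquisition batch: 900 features
#' (m/z 50-1200, retention time 0-20 min) over 5 biological replicates
#' per litter type (ND/AD), 3 extraction blanks and 5 pooled-QC
#' injections. Planted structure, recorded as ground truth: 10% of
#' features discriminate the two groups (|log2 fold change| 1-3); 5% are
#' blank contaminants (sample/blank ratio 2-8, i.e. below the S/N-10
#' filter); 5% are technically unstable (pooled-QC CV about 1, against
#' 0.1 for stable features); and 20 co-eluting clusters of 3 mutually
#' correlated features each, of which the two lower-intensity members are
#' redundant.
#'
#' @param n_features,n_samples_per_group,n_blanks,n_pools Design counts.
#' @param groups Group labels of the biological samples.
#' @param frac_discriminating Fraction of discriminating features.
#' @param effect_log2_range Range of |log2 fold change| for those.
#' @param base_log_mean,base_log_sd Feature base intensity: log-normal
#'   parameters (natural-log scale).
#' @param sample_log_sd Per-sample biological + technical noise SD on the
#'   natural-log scale.
#' @param pool_cv Coefficient of variation of pooled-QC injections for
#'   stable features.
#' @param frac_high_cv,high_cv Fraction and CV of planted unstable
#'   features.
#' @param frac_blank_contaminated Fraction of blank-contaminated
#'   features.
#' @param blank_ratio_range Sample/blank intensity ratio range for
#'   contaminated features (below the filter threshold of 10).
#' @param n_clusters,cluster_size Co-eluting redundant clusters.
#' @param cluster_rt_jitter Max |RT offset| of members from the cluster
#'   apex, minutes.
#' @param cluster_member_ratios Relative intensities of cluster members
#'   (first = retained representative).
#' @param cluster_log_sd Residual log-scale noise between members.
#' @param mz_range,rt_range Acquisition windows (Da, minutes).
#' @param seed Integer seed.
#' @return A list of class `metabo_sim_config`.
#' @export
metabo_sim_config <- function(n_features = 900L, n_samples_per_group = 5L,
                              groups = c("ND", "AD"), n_blanks = 3L,
                              n_pools = 5L, frac_discriminating = 0.10,
                              effect_log2_range = c(1, 3),
                              base_log_mean = 10, base_log_sd = 1,
                              sample_log_sd = 0.4, pool_cv = 0.1,
                              frac_high_cv = 0.05, high_cv = 1.0,
                              frac_blank_contaminated = 0.05,
                              blank_ratio_range = c(2, 8),
                              n_clusters = 20L, cluster_size = 3L,
                              cluster_rt_jitter = 0.02,
                              cluster_member_ratios = c(1, 0.6, 0.3),
                              cluster_log_sd = 0.05,
                              mz_range = c(50, 1200), rt_range = c(0, 20),
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c(n_features, n_samples_per_group, n_blanks, n_pools)
  if (any(counts <= 0)) stop("all design counts must be positive")
  fr <- c(frac_discriminating, frac_high_cv, frac_blank_contaminated)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (length(cluster_member_ratios) != cluster_size) {
    stop("cluster_member_ratios must have length cluster_size")
  }
  n_planted <- n_clusters * cluster_size +
    round(n_features * sum(fr))
  if (n_planted > n_features) stop("planted features exceed n_features")
  structure(cfg, class = "metabo_sim_config")
}

#' Generate a seeded LC-MS feature matrix with known ground truth
#'
#' Intensities are log-normal: each feature has a base log-intensity,
#' per-sample noise, and (for discriminating features) a group shift.
#' Pooled-QC columns are the feature's mean sample intensity times
#' CV-controlled multiplicative noise; blanks are trace-level except for
#' planted contaminants. Cluster members share one latent profile and are
#' near-proportional, emulating adducts/isotopologues of one analyte.
#'
#' A ground-truth hygiene pass guarantees the planted labels are exact
#' under the documented filters: any unplanned feature pair that co-elutes
#' (RT gap <= 0.06 min) with Pearson r >= 0.85 across the sample columns
#' has one member's retention time resampled, so the autocorrelation
#' filter removes exactly the planted redundant members.
#'
#' @param config A [metabo_sim_config()].
#' @return A list with `matrix` (a [feature_matrix()]) and `truth`: ids
#'   of `discriminating` (with signed log2 effects), `blank_contaminated`,
#'   `high_cv`, a `clusters` data frame, and `redundant` (the cluster
#'   members the autocorrelation filter should remove).
#' @export
generate_feature_matrix <- function(config = metabo_sim_config()) {
  stopifnot(inherits(config, "metabo_sim_config"))
  with_seed(config$seed, .generate_feature_matrix_impl(config))
}

.generate_feature_matrix_impl <- function(cfg) {
  nf <- cfg$n_features
  nspg <- cfg$n_samples_per_group
  ns <- nspg * length(cfg$groups)
  ids <- sprintf("F%04d", seq_len(nf))
  group_of <- rep(cfg$groups, each = nspg)

  ## planted feature sets (disjoint)
  perm <- sample.int(nf)
  n_clu <- cfg$n_clusters * cfg$cluster_size
  n_bc <- round(nf * cfg$frac_blank_contaminated)
  n_hcv <- round(nf * cfg$frac_high_cv)
  n_disc <- round(nf * cfg$frac_discriminating)
  take <- function(n) {
    if (n == 0L) return(integer(0))
    idx <- perm[seq_len(n)]
    perm <<- perm[-seq_len(n)]
    idx
  }
  clu_idx <- take(n_clu)
  bc_idx <- take(n_bc)
  hcv_idx <- take(n_hcv)
  disc_idx <- take(n_disc)
  cluster_of <- rep(NA_integer_, nf)
  cluster_of[clu_idx] <- rep(seq_len(cfg$n_clusters),
                             each = cfg$cluster_size)

  ## log-scale sample intensities
  base <- rnorm(nf, cfg$base_log_mean, cfg$base_log_sd)
  L <- base + matrix(rnorm(nf * ns, 0, cfg$sample_log_sd), nf, ns)
  eff <- numeric(nf)
  eff[disc_idx] <- log(2) * runif(n_disc, cfg$effect_log2_range[1],
                                  cfg$effect_log2_range[2]) *
    sample(c(-1, 1), n_disc, replace = TRUE)
  L <- L + outer(eff, as.numeric(group_of == cfg$groups[2]))
  ## cluster members: near-proportional copies of one latent profile
  for (c in seq_len(cfg$n_clusters)) {
    members <- clu_idx[cluster_of[clu_idx] == c]
    master <- base[members[1]] + rnorm(ns, 0, cfg$sample_log_sd)
    for (j in seq_along(members)) {
      L[members[j], ] <- master + log(cfg$cluster_member_ratios[j]) +
        rnorm(ns, 0, cfg$cluster_log_sd)
    }
  }
  S <- exp(L)
  msamp <- rowMeans(S)

  ## pooled QCs: mean of samples x CV-controlled noise
  cv <- rep(cfg$pool_cv, nf)
  cv[hcv_idx] <- cfg$high_cv
  sdp <- sqrt(log(1 + cv^2))
  P <- msamp * exp(matrix(rnorm(nf * cfg$n_pools), nf) * sdp)

  ## blanks: trace level, except planted contaminants
  B <- msamp * 1e-4 * exp(matrix(rnorm(nf * cfg$n_blanks), nf))
  ratio <- runif(n_bc, cfg$blank_ratio_range[1], cfg$blank_ratio_range[2])
  B[bc_idx, ] <- (msamp[bc_idx] / ratio) *
    exp(matrix(rnorm(n_bc * cfg$n_blanks, 0, 0.2), n_bc))

  ## m/z and retention times; cluster apexes kept >= 0.2 min apart
  mz <- runif(nf, cfg$mz_range[1], cfg$mz_range[2])
  rt <- runif(nf, cfg$rt_range[1], cfg$rt_range[2])
  centers <- .spaced_uniform(cfg$n_clusters, cfg$rt_range, 0.2)
  rt[clu_idx] <- centers[cluster_of[clu_idx]] +
    runif(n_clu, -cfg$cluster_rt_jitter, cfg$cluster_rt_jitter)
  rt <- .rt_hygiene(rt, S, cluster_of, cfg$rt_range)

  features <- data.frame(feature_id = ids, mz = mz, rt_min = rt,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c(paste("sample", group_of,
                        rep(seq_len(nspg), length(cfg$groups)), sep = "_"),
                  paste("blank", "all", seq_len(cfg$n_blanks), sep = "_"),
                  paste("pool", "all", seq_len(cfg$n_pools), sep = "_")),
    role = c(rep("sample", ns), rep("blank", cfg$n_blanks),
             rep("pool", cfg$n_pools)),
    group = c(group_of, rep("all", cfg$n_blanks + cfg$n_pools)),
    stringsAsFactors = FALSE
  )
  fm <- feature_matrix(features, samples, cbind(S, B, P))

  clusters <- data.frame(
    cluster = cluster_of[clu_idx],
    feature_id = ids[clu_idx],
    ratio = cfg$cluster_member_ratios[
      (seq_along(clu_idx) - 1L) %% cfg$cluster_size + 1L],
    stringsAsFactors = FALSE
  )
  clusters$redundant <- clusters$ratio < stats::ave(
    clusters$ratio, clusters$cluster, FUN = max)
  truth <- list(
    discriminating = data.frame(feature_id = ids[disc_idx],
                                log2_effect = eff[disc_idx] / log(2),
                                stringsAsFactors = FALSE),
    blank_contaminated = ids[bc_idx],
    high_cv = ids[hcv_idx],
    clusters = clusters,
    redundant = clusters$feature_id[clusters$redundant]
  )
  list(matrix = fm, truth = truth)
}

## n uniform draws on `range` with pairwise separation >= min_sep.
.spaced_uniform <- function(n, range, min_sep) {
  for (it in 1:1000) {
    x <- sort(runif(n, range[1], range[2]))
    if (n < 2L || min(diff(x)) >= min_sep) return(sample(x))
  }
  stop("could not place ", n, " points with separation ", min_sep)
}

## Resample RTs until no unplanned co-eluting pair is correlated enough
## to be caught by the autocorrelation filter (margins: 0.06 min,
## r = 0.85 against the documented 0.05 min / 0.9 defaults).
.rt_hygiene <- function(rt, S, cluster_of, rt_range,
                        rt_guard = 0.06, r_guard = 0.85) {
  C <- suppressWarnings(cor(t(S)))
  C[!is.finite(C)] <- 0
  same <- outer(cluster_of, cluster_of,
                function(a, b) !is.na(a) & !is.na(b) & a == b)
  hot <- C >= r_guard & !same
  diag(hot) <- FALSE
  movable <- is.na(cluster_of)  # never move cluster members
  for (it in 1:200) {
    d <- abs(outer(rt, rt, "-"))
    bad <- which(hot & d <= rt_guard, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (!nrow(bad)) return(rt)
    move <- ifelse(movable[bad[, 2]], bad[, 2], bad[, 1])
    move <- unique(move)
    if (!all(movable[move])) {
      stop("co-eluting correlated cluster pair cannot be separated")
    }
    rt[move] <- runif(length(move), rt_range[1], rt_range[2])
  }
  stop("retention-time hygiene did not converge")
}
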