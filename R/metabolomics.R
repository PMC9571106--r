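## Post-processing of an untargeted feature matrix: the three technical
## filters (blank S/N, pooled-QC CV, co-elution autocorrelation),
## log/auto-scale transformation, PCA, permutation PERMANOVA, and PLS-DA
## VIP ranking.

#' Blank signal-to-noise filter
#'
#' Removes features whose mean intensity over biological samples is less
#' than `sn_threshold` times the mean over blanks — i.e. peaks that are
#' essentially present in the extraction blanks. A blank mean of exactly
#' zero counts as infinite S/N (feature kept).
#'
#' @param fm A [feature_matrix()].
#' @param sn_threshold Minimum sample/blank mean-intensity ratio
#'   (default 10).
#' @return The filtered `feature_matrix`, with a provenance entry
#'   appended (see [filter_report()]).
#' @export
blank_sn_filter <- function(fm, sn_threshold = 10) {
  stopifnot(inherits(fm, "feature_matrix"))
  bl <- .role_cols(fm, "blank")
  sa <- .role_cols(fm, "sample")
  if (!length(bl)) stop("no blank columns in the matrix")
  if (!length(sa)) stop("no sample columns in the matrix")
  blank_mean <- rowMeans(fm$intensity[, bl, drop = FALSE])
  sample_mean <- rowMeans(fm$intensity[, sa, drop = FALSE])
  keep <- blank_mean == 0 | sample_mean / blank_mean >= sn_threshold
  .subset_features(fm, keep, "blank_sn",
                   list(sn_threshold = sn_threshold))
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Removes technically unstable features: those whose CV (sample
#' standard deviation over mean) across pooled-QC injections exceeds
#' `cv_threshold`. A zero pool mean is treated as unstable (removed).
#'
#' @param fm A [feature_matrix()].
#' @param cv_threshold Maximum pooled-QC CV (default 0.3).
#' @return The filtered `feature_matrix` with provenance appended.
#' @export
qc_cv_filter <- function(fm, cv_threshold = 0.3) {
  stopifnot(inherits(fm, "feature_matrix"))
  po <- .role_cols(fm, "pool")
  if (length(po) < 2L) stop("need at least 2 pool columns")
  pm <- rowMeans(fm$intensity[, po, drop = FALSE])
  psd <- apply(fm$intensity[, po, drop = FALSE], 1L, sd)
  keep <- pm > 0 & psd / pm <= cv_threshold
  .subset_features(fm, keep, "qc_cv", list(cv_threshold = cv_threshold))
}

#' Co-elution autocorrelation filter
#'
#' Deduplicates co-eluting, mutually correlated features (adducts,
#' isotopologues, in-source fragments of one analyte): features whose
#' retention times differ by at most `rt_tol_min` and whose Pearson
#' correlation across the biological sample columns is at least
#' `r_threshold` are grouped by transitive closure, and only the member
#' with the highest mean sample intensity is retained (ties broken by
#' lowest feature id).
#'
#' @param fm A [feature_matrix()].
#' @param r_threshold Minimum Pearson correlation (default 0.9).
#' @param rt_tol_min Maximum retention-time gap in minutes (default
#'   0.05).
#' @return The filtered `feature_matrix` with provenance appended.
#' @export
autocorr_filter <- function(fm, r_threshold = 0.9, rt_tol_min = 0.05) {
  stopifnot(inherits(fm, "feature_matrix"))
  sa <- .role_cols(fm, "sample")
  if (length(sa) < 3L) stop("need at least 3 sample columns")
  S <- fm$intensity[, sa, drop = FALSE]
  n <- nrow(S)
  keep <- rep(TRUE, n)
  if (n > 1L) {
    C <- suppressWarnings(cor(t(S)))
    C[!is.finite(C)] <- 0
    adj <- C >= r_threshold &
      abs(outer(fm$features$rt_min, fm$features$rt_min, "-")) <= rt_tol_min
    diag(adj) <- FALSE
    comp <- .connected_components(adj)
    mean_int <- rowMeans(S)
    for (g in split(seq_len(n), comp)) {
      if (length(g) < 2L) next
      ord <- g[order(-mean_int[g], fm$features$feature_id[g])]
      keep[ord[-1L]] <- FALSE
    }
  }
  .subset_features(fm, keep, "autocorr",
                   list(r_threshold = r_threshold,
                        rt_tol_min = rt_tol_min))
}

## Union-find over a logical adjacency matrix.
.connected_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, 0L)
}

#' Apply the standard filter chain
#'
#' Blank S/N, then pooled-QC CV, then co-elution autocorrelation — the
#' documented post-processing order. Counts telescope in the provenance.
#'
#' @param fm A [feature_matrix()].
#' @param sn_threshold,cv_threshold,r_threshold,rt_tol_min Filter
#'   parameters, see the individual filters.
#' @return The filtered `feature_matrix`.
#' @export
apply_filter_chain <- function(fm, sn_threshold = 10, cv_threshold = 0.3,
                               r_threshold = 0.9, rt_tol_min = 0.05) {
  fm <- blank_sn_filter(fm, sn_threshold)
  fm <- qc_cv_filter(fm, cv_threshold)
  autocorr_filter(fm, r_threshold, rt_tol_min)
}

#' Log-transform and auto-scale a feature matrix
#'
#' `x -> log(x + 1)`, then each feature is centred to mean zero and
#' scaled to unit sample variance across the biological sample columns.
#' Zero-variance features carry no multivariate information and are
#' dropped (recorded in the `dropped` attribute).
#'
#' @param x A [feature_matrix()] (its sample-role columns are used) or a
#'   features x samples numeric matrix.
#' @return A features x samples matrix of transformed intensities with
#'   attributes `dropped` (feature ids/indices removed) and `groups`
#'   (sample group labels, when `x` was a `feature_matrix`).
#' @export
log_autoscale <- function(x) {
  groups <- NULL
  if (inherits(x, "feature_matrix")) {
    sa <- .role_cols(x, "sample")
    groups <- x$samples$group[sa]
    x <- x$intensity[, sa, drop = FALSE]
  }
  lx <- log(x + 1)
  mu <- rowMeans(lx)
  s <- apply(lx, 1L, sd)
  keep <- s > 0
  out <- (lx[keep, , drop = FALSE] - mu[keep]) / s[keep]
  attr(out, "dropped") <- rownames(x)[!keep] %||% which(!keep)
  attr(out, "groups") <- groups
  out
}

#' Principal component analysis of a transformed feature matrix
#'
#' Thin wrapper over the singular value decomposition of the
#' sample-centred data: explained-variance fractions are non-increasing
#' and sum to one over the full component set.
#'
#' @param transformed Features x samples matrix (e.g. from
#'   [log_autoscale()]).
#' @param n_components Number of components to return (default: all
#'   available, `min(n_samples - 1, n_features)`).
#' @return A list with `scores` (samples x components), `loadings`
#'   (features x components) and `explained` (variance fractions over all
#'   available components).
#' @export
pca_scores <- function(transformed, n_components = NULL) {
  X <- t(transformed)  # samples as observations
  if (nrow(X) < 2L) stop("need at least 2 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components %||% length(pc$sdev), length(pc$sdev))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl)
}

#' Permutation multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a Euclidean distance matrix (computed from
#' samples x features coordinates when needed):
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))` with the
#' sums of squares obtained from squared inter-point distances
#' (Gower-centring identity), and
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` under seeded label
#' permutations.
#'
#' @param x Samples x features numeric matrix, or a `dist` object.
#' @param labels Group label per sample (at least two groups, each with
#'   at least two samples).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A list with `pseudo_F`, `p_value`, `n_perm`, `df` (between,
#'   within) and the observed `ss` components.
#' @export
permanova <- function(x, labels, n_perm = 999L, seed = NULL) {
  D2 <- if (inherits(x, "dist")) as.matrix(x)^2
        else as.matrix(stats::dist(x))^2
  labels <- as.factor(labels)
  n <- nrow(D2)
  if (length(labels) != n) stop("labels must match the number of samples")
  g <- nlevels(droplevels(labels))
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 2L)) stop("each group needs >= 2 samples")
  sst <- sum(D2) / (2 * n)
  ssw_of <- function(lab) {
    ssw <- 0
    for (lv in levels(lab)) {
      idx <- which(lab == lv)
      ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  f_of <- function(ssw) ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  ssw_obs <- ssw_of(labels)
  f_obs <- f_of(ssw_obs)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm),
               function(i) f_of(ssw_of(labels[sample.int(n)])) >= f_obs,
               TRUE))
  })
  list(pseudo_F = f_obs, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, df = c(between = g - 1L, within = n - g),
       ss = c(total = sst, between = sst - ssw_obs, within = ssw_obs))
}

#' PLS-DA variable importance in projection (VIP)
#'
#' Fits a PLS1 regression of the 0/1 group indicator on the features
#' (NIPALS: iteratively extracts latent components maximising covariance
#' with the response, deflating X and y), then scores each feature j as
#' `VIP_j = sqrt( p * sum_a SSY_a w_ja^2 / sum_a SSY_a )` with unit-norm
#' weight vectors `w_a` and `SSY_a` the response variance captured by
#' component a. By construction `mean(VIP^2) = 1`.
#'
#' @param transformed Features x samples matrix (e.g. from
#'   [log_autoscale()]).
#' @param group_labels Two-level group label per sample.
#' @param n_components Number of latent components (default 2).
#' @return Named numeric vector of VIP scores (names = feature ids),
#'   with attribute `ssy` (response variance captured per component).
#' @export
plsda_vip <- function(transformed, group_labels, n_components = 2L) {
  labels <- as.factor(group_labels)
  if (nlevels(droplevels(labels)) != 2L) {
    stop("PLS-DA VIP requires exactly two groups")
  }
  X <- t(transformed)                      # n samples x p features
  y <- as.numeric(labels == levels(labels)[2L])
  y <- y - mean(y)
  if (all(y == 0)) stop("constant response")
  n <- nrow(X); p <- ncol(X)
  A <- min(n_components, n - 1L, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- matrix(0, p, A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(X, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t_a <- drop(X %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(X, t_a)) / tt
    q_a <- sum(y * t_a) / tt
    ssy[a] <- q_a^2 * tt                  # response SS captured
    X <- X - tcrossprod(t_a, p_a)
    y <- y - q_a * t_a
    W[, a] <- w
  }
  if (A < 1L) stop("no informative PLS component could be extracted")
  W <- W[, seq_len(A), drop = FALSE]
  ssy <- ssy[seq_len(A)]
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  names(vip) <- colnames(X) %||% rownames(transformed)
  attr(vip, "ssy") <- ssy
  vip
}

#' Top-k features by VIP
#'
#' @param vip_scores Named VIP vector from [plsda_vip()].
#' @param k How many features (default 15).
#' @return Data frame with `feature_id`, `vip`, `rank`, sorted by VIP
#'   descending, ties broken by feature id.
#' @export
top_vips <- function(vip_scores, k = 15L) {
  if (k > length(vip_scores)) stop("k exceeds the number of features")
  ord <- order(-vip_scores, names(vip_scores))
  sel <- ord[seq_len(k)]
  data.frame(feature_id = names(vip_scores)[sel],
             vip = unname(vip_scores[sel]), rank = seq_len(k),
             stringsAsFactors = FALSE)
}
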