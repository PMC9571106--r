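test_that("blank S/N filter applies the mean-ratio rule", {
  # three features: clean (ratio 20), contaminated (ratio 9), zero blank
  S <- rbind(c(1000, 1000, 1000), c(90, 90, 90), c(500, 500, 500))
  B <- rbind(c(50, 50), c(10, 10), c(0, 0))
  fm <- toy_feature_matrix(cbind(S, B),
                           roles = c(rep("sample", 3), rep("blank", 2)))
  out <- blank_sn_filter(fm, 10)
  expect_identical(out$features$feature_id, c("T001", "T003"))
  rep <- filter_report(out)
  expect_identical(rep$before, 3L)
  expect_identical(rep$removed, 1L)
  expect_identical(rep$after, 2L)
  no_blank <- toy_feature_matrix(S, roles = rep("sample", 3))
  expect_error(blank_sn_filter(no_blank), "no blank columns")
})

test_that("QC CV filter uses the sample-SD convention", {
  S <- matrix(100, 3, 3)
  P <- rbind(c(100, 100, 100),      # CV 0      -> kept
             c(100, 200, 300),      # CV 0.5    -> removed
             c(95, 100, 105))       # CV 0.05   -> kept
  fm <- toy_feature_matrix(cbind(S, P),
                           roles = c(rep("sample", 3), rep("pool", 3)))
  out <- qc_cv_filter(fm, 0.3)
  expect_identical(out$features$feature_id, c("T001", "T003"))
  expect_equal(sd(c(100, 200, 300)) / 200, 0.5)  # the rule it encodes
  one_pool <- toy_feature_matrix(cbind(S, P[, 1, drop = FALSE]),
                                 roles = c(rep("sample", 3), "pool"))
  expect_error(qc_cv_filter(one_pool), "at least 2 pool")
})

test_that("autocorrelation filter deduplicates co-eluting features", {
  x <- c(10, 14, 9, 22, 17)
  # f1 and f2: proportional and co-eluting -> drop the weaker f1;
  # f3 identical to f1 but 4 min away -> kept (RT gate)
  S <- rbind(x, 2 * x, x)
  fm <- toy_feature_matrix(S, rt = c(1.00, 1.02, 5.0))
  out <- autocorr_filter(fm, 0.9, 0.05)
  expect_identical(out$features$feature_id, c("T002", "T003"))

  # transitive closure: chain at rt 1.00/1.04/1.08 collapses to one
  S <- rbind(x, 2 * x, 3 * x)
  fm <- toy_feature_matrix(S, rt = c(1.00, 1.04, 1.08))
  out <- autocorr_filter(fm, 0.9, 0.05)
  expect_identical(out$features$feature_id, "T003")

  # intensity tie broken by lowest feature id
  S <- rbind(x, x)
  fm <- toy_feature_matrix(S, rt = c(1.0, 1.01))
  expect_identical(autocorr_filter(fm)$features$feature_id, "T001")
})

test_that("the filter chain telescopes and hits exactly the planted truth", {
  sim <- generate_feature_matrix(metabo_sim_config(seed = 2))
  out <- apply_filter_chain(sim$matrix)
  rep <- filter_report(out)
  expect_identical(rep$step, c("blank_sn", "qc_cv", "autocorr"))
  expect_equal(rep$before - rep$removed, rep$after)
  expect_equal(rep$before[-1], rep$after[-3])
  tr <- sim$truth
  expect_gte(mean(tr$blank_contaminated %in%
                    out$provenance[[1]]$removed_ids), 0.9)
  expect_gte(mean(tr$high_cv %in% out$provenance[[2]]$removed_ids), 0.9)
  expect_setequal(out$provenance[[3]]$removed_ids, tr$redundant)
})

test_that("log/auto-scaling standardizes features and drops constants", {
  S <- rbind(c(10, 20, 30, 40), rep(7, 4))
  fm <- toy_feature_matrix(S, roles = rep("sample", 4),
                           groups = c("ND", "ND", "AD", "AD"))
  X <- log_autoscale(fm)
  expect_identical(nrow(X), 1L)
  expect_identical(attr(X, "dropped"), "T002")
  expect_equal(mean(X[1, ]), 0, tolerance = 1e-12)
  expect_equal(var(X[1, ]), 1, tolerance = 1e-12)
  expect_identical(attr(X, "groups"), c("ND", "ND", "AD", "AD"))
  # monotone per cell
  expect_true(all(diff(X[1, ]) > 0))
})

test_that("PCA explained-variance fractions behave", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  X <- X - rowMeans(X)
  pc <- pca_scores(X)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(pc$explained) <= 1e-12))
  # rank-1 data: one component carries everything
  v <- rnorm(6)
  R1 <- outer(rnorm(10), v)
  pc1 <- pca_scores(R1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-9)
  # two well-separated groups part on PC1
  sim <- generate_feature_matrix(metabo_sim_config(seed = 3))
  Xs <- log_autoscale(apply_filter_chain(sim$matrix))
  sc <- pca_scores(Xs, 2)
  g <- attr(Xs, "groups")
  expect_false(any(sign(sc$scores[g == "ND", 1]) %in%
                     sign(sc$scores[g == "AD", 1])))
})

test_that("PERMANOVA matches its distance identity and vegan::adonis2", {
  set.seed(11)
  x <- matrix(rnorm(10 * 20), 10, 20)
  lab <- rep(c("a", "b"), each = 5)
  f_coord <- permanova(x, lab, n_perm = 49, seed = 1)
  f_dist <- permanova(stats::dist(x), lab, n_perm = 49, seed = 1)
  expect_equal(f_coord$pseudo_F, f_dist$pseudo_F, tolerance = 1e-9)
  expect_identical(f_coord$p_value, f_dist$p_value)
  ref <- vegan::adonis2(stats::dist(x) ~ lab, permutations = 199)
  expect_equal(f_coord$pseudo_F, ref$F[1], tolerance = 1e-9)

  # huge separation: only permutations reproducing the observed
  # partition (prob 1/126 for a 5+5 split) can match the statistic
  x2 <- x; x2[6:10, ] <- x2[6:10, ] + 10
  strong <- permanova(x2, lab, n_perm = 999, seed = 2)
  expect_lte(strong$p_value, 0.03)
  expect_error(permanova(x, rep("a", 10)), "at least 2 groups")
})

test_that("PLS-DA VIP satisfies its normalization and rank properties", {
  sim <- generate_feature_matrix(metabo_sim_config(seed = 4))
  X <- log_autoscale(apply_filter_chain(sim$matrix))
  g <- attr(X, "groups")
  vip <- plsda_vip(X, g, n_components = 2)
  expect_equal(mean(vip^2), 1, tolerance = 1e-9)

  # one-component VIP ranking equals the |correlation with y| ranking
  vip1 <- plsda_vip(X, g, n_components = 1)
  y <- as.numeric(g == "AD")
  r <- abs(apply(X, 1, function(f) cor(f, y)))
  expect_identical(order(-vip1), order(-r))

  # a feature carrying the whole group difference dominates
  set.seed(6)
  Z <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(sprintf("Z%02d", 1:30), NULL))
  lab <- rep(c("ND", "AD"), each = 6)
  Z[17, ] <- Z[17, ] + 8 * (lab == "AD")
  Zs <- t(scale(t(log(abs(Z) + 1))))
  vipz <- plsda_vip(Zs, lab)
  expect_identical(names(which.max(vipz)), "Z17")
  expect_identical(top_vips(vipz, 1)$feature_id, "Z17")
  expect_error(plsda_vip(X, rep("ND", ncol(X))), "two groups")
})

test_that("top_vips ranks, truncates and breaks ties by id", {
  v <- c(b = 2, a = 2, c = 1)
  out <- top_vips(v, 3)
  expect_identical(out$feature_id, c("a", "b", "c"))
  expect_identical(out$rank, 1:3)
  expect_error(top_vips(v, 4), "exceeds")
})
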