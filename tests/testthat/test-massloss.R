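test_that("design matrices are treatment-coded and term-grouped", {
  bags <- generate_litterbags(litter_sim_config(seed = 4))
  d <- build_design(bags, c("species", "forest", "treatment",
                            "litter_type", "time_months"))
  # 1 + 2 + 2 + 1 + 1 + 1 dummy columns
  expect_identical(ncol(d$X), 8L)
  expect_identical(max(d$assign), 5L)
  expect_identical(ncol(build_design(bags)$X), 1L)  # intercept only
  expect_error(build_design(bags, c("species", "species")), "duplicate")
  expect_error(build_design(bags, "soil"), "unknown factor")
})

test_that("OLS fit recovers closed-form toys", {
  # y = 1 + 2x exactly
  X <- cbind(1, c(0, 1, 2))
  fit <- fit_ols(X, c(1, 3, 5))
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_equal(fit$rss, 0, tolerance = 1e-20)
  expect_equal(fit$r2, 1)
  expect_identical(fit$aic, -Inf)
  # response orthogonal to the non-intercept column: R^2 = 0
  x <- c(-1, 0, 1, 0)
  y <- c(0, 1, 0, -1) + 2
  fit0 <- fit_ols(cbind(1, x), y)
  expect_equal(fit0$r2, 0)
  expect_error(fit_ols(cbind(1, c(1, 2)), c(1, 2)), "more observations")
  expect_error(fit_ols(cbind(1, 1, c(1, 2, 3, 4)), c(1, 2, 3, 4)),
               "singular")
})

test_that("AIC convention is n log(RSS/n) + 2(k+1)", {
  expect_equal(aic_score(list(n = 10, rss = 10, k = 1)), 4.0)
  base <- aic_score(list(n = 50, rss = 20, k = 3))
  expect_equal(aic_score(list(n = 50, rss = 20, k = 4)) - base, 2)
  # nested fits with equal RSS: bigger model never wins
  expect_gt(aic_score(list(n = 50, rss = 20, k = 5)), base)
})

test_that("adding columns never increases the RSS", {
  bags <- generate_litterbags(litter_sim_config(seed = 14))
  y <- remaining_mass_pct(bags$initial_dry_mass_g, bags$final_dry_mass_g)
  terms <- c("species", "forest", "treatment", "time_months",
             "species:forest")
  rss <- vapply(seq_along(terms), function(k) {
    fit_ols(build_design(bags, terms[seq_len(k)]), y)$rss
  }, 0)
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("stepwise selection keeps real effects and sheds null ones", {
  # main-effects-only truth: forest, treatment and time effects, zero
  # species effect and no interactions
  tab <- make_cell_table(function(sp, fo, tr, tm) {
    40 + 6 * (fo == "Qilex_forest") + 4 * (tr == "ND") + 10 * (tm == 24)
  })
  dropped_lt <- 0L
  for (s in 1:12) {
    bags <- generate_litterbags(litter_sim_config(cell_means = tab,
                                                  seed = 400 + s))
    sel <- stepwise_select(bags, max_order = 1L)
    kept <- attr(terms(sel$formula), "term.labels")
    expect_true(all(c("forest", "treatment", "time_months") %in% kept))
    if (!"litter_type" %in% kept) dropped_lt <- dropped_lt + 1L
  }
  # a 1-df null term survives AIC with prob ~0.16; real effects never drop
  expect_gte(dropped_lt, 7L)
})

test_that("stepwise selection retains a planted interaction", {
  tab <- make_cell_table(function(sp, fo, tr, tm) {
    40 + 5 * (tr == "ND") + 8 * (tm == 24) +
      9 * (sp == "Phalepensis") * (tm == 24)   # species x time interaction
  })
  bags <- generate_litterbags(litter_sim_config(cell_means = tab,
                                                seed = 77))
  sel <- stepwise_select(bags, max_order = 2L)
  kept <- attr(terms(sel$formula), "term.labels")
  expect_true("species:time_months" %in% kept)
})

test_that("a pure-noise response selects a near-empty model", {
  tab <- make_cell_table(function(sp, fo, tr, tm) 40)
  bags <- generate_litterbags(litter_sim_config(cell_means = tab,
                                                seed = 55))
  sel <- stepwise_select(bags, max_order = 1L)
  kept <- attr(terms(sel$formula), "term.labels")
  expect_lte(length(kept), 2L)
})

test_that("sequential ANOVA: Type I identities on toys", {
  # balanced single factor, means 0 and 2, zero within-cell noise
  df <- data.frame(g = factor(rep(c("a", "b"), each = 4)),
                   y = rep(c(0, 2), each = 4))
  # zero-noise toy: the "perfect fit" warning is the point
  out <- suppressWarnings(sequential_anova(lm(y ~ g, data = df)))
  expect_equal(out$ss[1], 4 * 1^2 * 2)   # n per group * (mean - grand)^2
  expect_equal(out$ss[2], 0)
  expect_equal(out$pct_ss[1], 100)
  expect_equal(sum(out$pct_ss), 100)

  # orthogonal balanced design: order does not matter
  bags <- generate_litterbags(litter_sim_config(seed = 6))
  a1 <- sequential_anova(bags, formula_terms = c("species", "forest"))
  a2 <- sequential_anova(bags, formula_terms = c("forest", "species"))
  expect_equal(sort(a1$ss), sort(a2$ss), tolerance = 1e-8)
  expect_equal(sum(a1$pct_ss), 100, tolerance = 1e-9)
  # SS decomposition is exact: term SS + residual = TSS
  y <- remaining_mass_pct(bags$initial_dry_mass_g, bags$final_dry_mass_g)
  expect_equal(sum(a1$ss), sum((y - mean(y))^2))
})

test_that("two-way trait ANOVA matches a hand-computed toy", {
  # 2 x 2 cells, 2 replicates, cell means 0,0,0,4, zero noise:
  # interaction SS = sum n*(cell - row - col + grand)^2 = 8
  df <- data.frame(
    litter_type = rep(c("ND", "AD"), each = 4),
    species = rep(rep(c("Qilex", "Qpubescens"), each = 2), 2),
    value = c(0, 0, 0, 0, 0, 0, 4, 4)
  )
  out <- suppressWarnings(two_way_anova(df))
  expect_equal(out$ss[out$term == "litter_type:species"], 8)
  expect_true(attr(out, "flagged"))  # zero residual variance
  # identical values everywhere: flagged, no spurious effects
  df$value <- 3
  expect_true(attr(suppressWarnings(two_way_anova(df)), "flagged"))
})

test_that("two-way ANOVA p-values are uniform under the null", {
  # resample a null trait (no species, type or interaction effect)
  set.seed(202)
  lv <- design_levels()
  pvals <- vapply(1:300, function(i) {
    df <- expand.grid(litter_type = lv$litter_type,
                      species = lv$species, rep = 1:5)
    df$value <- rnorm(nrow(df), 100, 5)
    out <- suppressWarnings(two_way_anova(df))
    out$p_value[out$term == "litter_type:species"]
  }, 0)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("full factorial selection reports both models' AIC and R2", {
  bags <- generate_litterbags(litter_sim_config(seed = 9))
  sel <- stepwise_select(bags)
  expect_lte(sel$aic, sel$full_aic)
  expect_true(sel$r2 > 0.3 && sel$r2 <= sel$full_r2)
  out <- sequential_anova(sel$fit)
  expect_equal(sum(out$pct_ss), 100, tolerance = 1e-9)
  expect_identical(out$term[nrow(out)], "Residuals")
})
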