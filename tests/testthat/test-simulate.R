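test_that("litterbag generator emits the full factorial design", {
  bags <- generate_litterbags(litter_sim_config(seed = 1))
  expect_identical(nrow(bags), 504L)
  modal <- unique(bags[, c("forest", "species", "litter_type",
                           "treatment")])
  expect_identical(nrow(modal), 36L)
  expect_true(all(table(bags$forest, bags$time_months) == 84L))
  expect_true(all(bags$initial_dry_mass_g == 10))
  expect_true(all(bags$final_dry_mass_g >= 0 &
                    bags$final_dry_mass_g <= bags$initial_dry_mass_g))
  one <- generate_litterbags(litter_sim_config(replicates = 2, seed = 1))
  expect_identical(nrow(one), 144L)  # 36 x 2 dates x 2 reps
})

test_that("litterbag generator is deterministic and mean-faithful", {
  cfg <- litter_sim_config(seed = 33)
  expect_identical(generate_litterbags(cfg), generate_litterbags(cfg))
  # vanishing noise: empirical cell means equal the cell-mean table
  tab <- calibrate_cell_means()
  tiny <- generate_litterbags(litter_sim_config(noise_sd = 1e-9,
                                                seed = 2))
  loss <- mass_loss_pct(tiny$initial_dry_mass_g, tiny$final_dry_mass_g)
  for (row in sample(nrow(tab), 8)) {
    sel <- tiny$species == tab$species[row] &
      tiny$forest == tab$forest[row] &
      tiny$treatment == tab$treatment[row] &
      tiny$time_months == tab$time_months[row]
    expect_equal(mean(loss[sel]), tab$D[row], tolerance = 1e-4)
  }
  # litter-type effect shifts the AD-origin bags only
  shifted <- generate_litterbags(litter_sim_config(
    noise_sd = 1e-9, litter_type_effect = 3, seed = 2))
  l2 <- mass_loss_pct(shifted$initial_dry_mass_g,
                      shifted$final_dry_mass_g)
  gap <- mean(l2[shifted$litter_type == "AD"]) -
    mean(l2[shifted$litter_type == "ND"])
  expect_equal(gap, 3, tolerance = 1e-4)
})

test_that("generated treatment gap is recovered across seeds", {
  # mean estimated ND-AD mass-loss gap at 24 months over 40 seeds
  est <- vapply(1:40, function(s) {
    b <- generate_litterbags(litter_sim_config(seed = 2000 + s))
    l <- mass_loss_pct(b$initial_dry_mass_g, b$final_dry_mass_g)
    at24 <- b$time_months == 24
    mean(l[at24 & b$treatment == "ND"]) -
      mean(l[at24 & b$treatment == "AD"])
  }, 0)
  # per-seed SE ~ 4 * sqrt(2/252) ~ 0.36 -> SE of the mean ~ 0.06
  expect_lt(abs(mean(est) - 4.0), 0.3)
})

test_that("trait generator emulates the initial-quality sampling", {
  tr <- generate_trait_samples(seed = 3)
  samples <- unique(tr[, c("species", "litter_type", "replicate")])
  expect_identical(nrow(samples), 30L)
  expect_true(all(tr$value >= 0))
  expect_identical(generate_trait_samples(seed = 3), tr)
  sub <- generate_trait_samples(traits = c("N", "WHC"), seed = 3)
  expect_setequal(unique(sub$trait), c("N", "WHC"))
  expect_error(generate_trait_samples(traits = "lead"), "unknown trait")
  # planted species effect is recoverable: N differs strongly by species
  out <- two_way_anova(sub, trait = "N")
  expect_lt(out$p_value[out$term == "species"], 1e-6)
})

test_that("feature-matrix generator obeys its configured geometry", {
  cfg <- metabo_sim_config(seed = 10)
  sim <- generate_feature_matrix(cfg)
  fm <- sim$matrix
  expect_identical(nrow(fm$features), 900L)
  expect_identical(nrow(fm$samples), 18L)  # 10 samples + 3 blanks + 5 pools
  expect_identical(sum(fm$samples$role == "sample"), 10L)
  expect_true(all(fm$features$mz >= 50 & fm$features$mz <= 1200))
  expect_true(all(fm$features$rt_min >= 0 & fm$features$rt_min <= 20))
  expect_true(all(fm$intensity >= 0))
  tr <- sim$truth
  expect_identical(nrow(tr$discriminating), 90L)
  expect_identical(length(tr$blank_contaminated), 45L)
  expect_identical(length(tr$high_cv), 45L)
  expect_identical(nrow(tr$clusters), 60L)
  expect_identical(length(tr$redundant), 40L)
  # planted sets are disjoint
  planted <- c(tr$discriminating$feature_id, tr$blank_contaminated,
               tr$high_cv, tr$clusters$feature_id)
  expect_identical(anyDuplicated(planted), 0L)
  # determinism
  sim2 <- generate_feature_matrix(metabo_sim_config(seed = 10))
  expect_identical(sim2$matrix$intensity, fm$intensity)
  # planted contaminants sit below the S/N threshold
  bl <- fm$samples$role == "blank"
  sa <- fm$samples$role == "sample"
  sn <- rowMeans(fm$intensity[, sa]) / rowMeans(fm$intensity[, bl])
  expect_gte(mean(sn[fm$features$feature_id %in%
                       tr$blank_contaminated] < 10), 0.9)
  # cluster members co-elute within the filter's RT gate
  for (cl in split(tr$clusters$feature_id, tr$clusters$cluster)) {
    rts <- fm$features$rt_min[match(cl, fm$features$feature_id)]
    expect_lte(diff(range(rts)), 0.04)
  }
})

test_that("feature matrix CSV round trip preserves the container", {
  sim <- generate_feature_matrix(metabo_sim_config(n_features = 60L,
                                                   n_clusters = 2L,
                                                   seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix_csv(sim$matrix, path)
  back <- read_feature_matrix_csv(path)
  expect_identical(back$samples, sim$matrix$samples)
  expect_equal(back$intensity, sim$matrix$intensity, tolerance = 1e-10)
})

test_that("a null feature matrix yields calibrated PERMANOVA p-values", {
  rejections <- vapply(1:10, function(s) {
    sim <- generate_feature_matrix(metabo_sim_config(
      n_features = 80L, frac_discriminating = 0, n_clusters = 0L,
      cluster_size = 0L, cluster_member_ratios = numeric(), seed = s))
    X <- log_autoscale(sim$matrix)
    permanova(t(X), attr(X, "groups"), n_perm = 199, seed = s)$p_value <
      0.05
  }, TRUE)
  expect_lte(sum(rejections), 2L)
})

test_that("simulation configs validate their inputs", {
  expect_error(litter_sim_config(noise_sd = 0), "noise_sd")
  expect_error(litter_sim_config(replicates = 1), "replicates")
  expect_error(metabo_sim_config(frac_discriminating = 1.2), "fractions")
  expect_error(metabo_sim_config(n_features = 50L), "planted")
  expect_error(metabo_sim_config(cluster_member_ratios = c(1, 0.5)),
               "cluster_member_ratios")
})
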