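test_that("generation is deterministic for a given spec and seed", {
  s1 <- generate_indicator_table(reference_factor_spec(seed = 7))
  s2 <- generate_indicator_table(reference_factor_spec(seed = 7))
  expect_identical(s1, s2)
  expect_false(identical(
    indicator_matrix(s1),
    indicator_matrix(generate_indicator_table(reference_factor_spec(seed = 8)))))
  inv1 <- generate_inventory(stand_sim_spec(patterns = "A", seed = 3))
  inv2 <- generate_inventory(stand_sim_spec(patterns = "A", seed = 3))
  expect_identical(inv1, inv2)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_indicator_table(reference_factor_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("designed factor loadings reproduce the implied correlations at large n", {
  spec <- recovery_factor_spec(seed = 21, plots_per_pattern = 2500)
  tab <- generate_indicator_table(spec)
  # two identity-scale indicators of the same factor, loadings 0.8 x 0.8
  m <- indicator_matrix(tab)
  expect_lt(abs(cor(m[, "SM"], m[, "TN"]) - 0.64), 0.05)
  # full latent correlation structure: compare on the latent (log) scale
  sc <- reference_indicator_scales()
  latent <- m
  for (j in which(sc$transform == "log")) {
    latent[, sc$name[j]] <- log(m[, sc$name[j]])
  }
  L <- spec$loadings
  implied <- L %*% t(L)
  diag(implied) <- 1
  emp <- cor(latent[, rownames(L)])
  expect_lt(max(abs(emp - implied)[upper.tri(implied)]), 0.05)
})

test_that("indicator scales hit their specified means, sds and medians", {
  spec <- reference_factor_spec(seed = 31, plots_per_pattern = 2000)
  m <- indicator_matrix(generate_indicator_table(spec))
  sc <- reference_indicator_scales()
  for (j in seq_len(nrow(sc))) {
    v <- m[, sc$name[j]]
    if (sc$transform[j] == "identity") {
      expect_lt(abs(mean(v) - sc$location[j]) / sc$location[j], 0.02)
      expect_lt(abs(sd(v) - sc$scale[j]) / sc$scale[j], 0.05)
    } else {
      expect_lt(abs(median(v) - sc$location[j]) / sc$location[j], 0.02)
    }
  }
})

test_that("a non-positive-definite loading plan is rejected", {
  expect_error(
    factor_model_spec(list(f1 = c(A = 1.0, B = 0.5)), patterns = "P",
                      seed = 1),
    "positive definite")
})

test_that("zero shifts leave pattern means indistinguishable", {
  spec <- reference_factor_spec(seed = 55, plots_per_pattern = 200,
                                patterns = c("A", "B"))
  m <- indicator_matrix(generate_indicator_table(spec))
  grp <- rep(c("A", "B"), each = 200)
  d <- colMeans(m[grp == "A", ]) - colMeans(m[grp == "B", ])
  se <- sqrt(apply(m, 2, var) * 2 / 200)
  expect_true(all(abs(d) < 5 * se))
})

test_that("quality gradients order patterns and reverse with the gradient", {
  spec <- reference_factor_spec(seed = 66, plots_per_pattern = 30,
                                patterns = c("low", "mid", "high"))
  up <- generate_quality_gradient(spec, c(0, 0.5, 1))
  res_up <- suppressWarnings(run_sqi_pipeline(up))
  m_up <- tapply(res_up$samples$sqi, res_up$samples$pattern_id,
                 mean)[c("low", "mid", "high")]
  expect_true(all(diff(m_up) > 0))
  down <- generate_quality_gradient(spec, c(1, 0.5, 0))
  res_down <- suppressWarnings(run_sqi_pipeline(down))
  m_down <- tapply(res_down$samples$sqi, res_down$samples$pattern_id,
                   mean)[c("low", "mid", "high")]
  expect_true(all(diff(m_down) < 0))
  expect_error(generate_quality_gradient(spec, c(0, 1, 0.5)), "monotone")
  # the shift respects orientation: bulk density moves down as quality rises
  expect_lt(mean(indicator_matrix(up)[up$pattern_id == "high", "BD"]),
            mean(indicator_matrix(up)[up$pattern_id == "low", "BD"]))
})

test_that("stand simulation honours its distributional parameters", {
  flat <- generate_inventory(stand_sim_spec(patterns = "A",
                                            plots_per_pattern = 1,
                                            trees_per_plot = 30,
                                            dbh_sdlog = 0, height_sdlog = 0,
                                            seed = 12))
  expect_equal(length(unique(flat$inventory$dbh)), 1L)
  sm <- stand_summary(flat$inventory, flat$coefs, flat$plot_meta)
  expect_equal(sm$cv_d, 0)
  expect_equal(sm$gini_d_standard, 0)
  expect_equal(sm$gini_d_dispersion, 0)

  broad <- generate_inventory(stand_sim_spec(patterns = "A",
                                             plots_per_pattern = 1,
                                             trees_per_plot = 50,
                                             broadleaf_fraction = 1, seed = 4))
  expect_equal(pbs(broad$inventory, broad$coefs), 100)

  big <- generate_inventory(stand_sim_spec(patterns = "A",
                                           plots_per_pattern = 1,
                                           trees_per_plot = 10000,
                                           dbh_meanlog = log(15),
                                           dbh_sdlog = 0.3, seed = 8))
  expect_lt(abs(median(big$inventory$dbh) - 15) / 15, 0.02)
  expect_error(stand_sim_spec(patterns = "A", trees_per_plot = 1, seed = 2),
               "at least 2")
})
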