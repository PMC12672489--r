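ref <- load_reference_pca()
ref_model <- as_pca_model(ref)

test_that("standardization yields unit-variance z-scores and rejects constants", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 8, 6))
  z <- standardize_indicators(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_true(all(abs(colMeans(z)) <= 1e-12))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_error(standardize_indicators(cbind(a = c(1, 2, 3), b = c(5, 5, 5))),
               "b")
  expect_error(standardize_indicators(m[1:2, ]), "at least 3")
})

test_that("KMO matches independent small-matrix oracles", {
  # p = 2: the only partial correlation equals the correlation, so KMO = 0.5
  for (r in c(0.3, -0.7, 0.95)) {
    R <- matrix(c(1, r, r, 1), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
    expect_equal(kmo(R)$statistic, 0.5, tolerance = 1e-12)
  }
  # p = 3 equicorrelated: partials from the 3-variable recursion formula
  r <- 0.5
  R3 <- matrix(r, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(R3) <- 1
  q <- (r - r * r) / (1 - r^2)
  oracle <- (6 * r^2) / (6 * r^2 + 6 * q^2)
  expect_equal(kmo(R3)$statistic, oracle, tolerance = 1e-12)
  # near-identity correlations: partials dominate, KMO small
  r <- 0.01
  R3 <- matrix(r, 3, 3)
  diag(R3) <- 1
  q <- (r - r * r) / (1 - r^2)
  oracle <- (6 * r^2) / (6 * r^2 + 6 * q^2)
  expect_equal(kmo(R3)$statistic, oracle, tolerance = 1e-10)
  expect_lt(kmo(R3)$statistic, 0.6)
})

test_that("Bartlett's sphericity test matches the direct formula", {
  p <- 4
  I4 <- diag(p)
  res <- bartlett_sphericity(I4, n = 30)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, p * (p - 1) / 2)
  R <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  res <- bartlett_sphericity(R, n = 30)
  expect_equal(res$chi2, -(30 - 1 - 9 / 6) * log(1 - 0.81), tolerance = 1e-12)
  expect_lt(res$p, 0.01)
  expect_error(bartlett_sphericity(matrix(c(1, 1, 1, 1), 2), n = 10),
               "determinant")
})

test_that("PCA of a rank-1 correlation structure gives a single unit component", {
  R <- matrix(1, 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  model <- run_pca(R)
  expect_equal(length(model$eigenvalues), 1L)
  expect_equal(unname(model$eigenvalues), 2)
  expect_equal(unname(model$loadings[, 1]), c(1, 1), tolerance = 1e-12)
  expect_equal(sort(model$all_eigenvalues), c(0, 2), tolerance = 1e-12)
})

test_that("PCA eigenvalues conserve total variance and loadings obey conventions", {
  set.seed(31)
  for (i in 1:5) {
    tab <- generate_indicator_table(reference_factor_spec(seed = 500 + i))
    model <- run_pca(standardize_indicators(tab))
    expect_equal(sum(model$all_eigenvalues), model$n_indicators,
                 tolerance = 1e-8)
    expect_equal(sum(model$all_eigenvalues / model$n_indicators * 100), 100,
                 tolerance = 1e-8)
    expect_true(all(diff(model$eigenvalues) <= 0))
    expect_true(all(model$eigenvalues >= 1))
    expect_true(all(model$communality >= 0 & model$communality <= 1 + 1e-12))
    # sign convention: dominant entry of every column is positive
    for (j in seq_len(ncol(model$loadings))) {
      expect_gt(model$loadings[which.max(abs(model$loadings[, j])), j], 0)
    }
    expect_equal(model$cumulative_rate, cumsum(model$contribution_rate),
                 ignore_attr = TRUE)
  }
})

test_that("norm values are eigenvalue-weighted loading lengths", {
  toy <- list(loadings = matrix(1, 1, 1, dimnames = list("x", "PC1")),
              eigenvalues = c(PC1 = 4))
  expect_equal(unname(norm_values(toy)), 2)
  nv <- norm_values(ref_model)
  expect_equal(unname(nv["SM"]),
               sqrt(sum(ref$loadings["SM", ]^2 * ref$eigenvalues)),
               tolerance = 1e-12)
})

test_that("group assignment follows the maximum absolute loading", {
  g <- assign_groups(ref_model)
  # dominant |loading| on PC3 beats a larger positive PC1 loading
  expect_equal(unname(g["NH4"]), 3L)
  # max |loading| below the conventional 0.5 still assigns a group
  expect_equal(unname(g["ACP"]), 2L)
  expect_equal(unname(g), unname(ref$group))
  # exact ties resolve to the lower component index
  tie <- list(loadings = matrix(c(0.5, 0.6, -0.5, 0.3), 2, 2,
                                dimnames = list(c("u", "v"), c("PC1", "PC2"))),
              eigenvalues = c(PC1 = 1.5, PC2 = 1.2))
  expect_equal(unname(assign_groups(tie)["u"]), 1L)
})

test_that("the 10% norm band reproduces the published group subsets", {
  norms <- norm_values(ref_model)
  groups <- assign_groups(ref_model)
  high <- select_high_norm(groups, norms)
  expect_setequal(high[["1"]], c("ALP", "SOC", "TN", "MBN", "MBC"))
  expect_setequal(high[["2"]], c("NO3", "CBH", "ACP", "BG"))
  expect_equal(high[["3"]], "NH4")
  expect_setequal(high[["4"]], c("POD", "BX"))
  expect_equal(high[["5"]], "NAG")
  expect_equal(high[["6"]], "TP")
})

test_that("correlation pruning keeps the highest-norm uncorrelated indicators", {
  sel <- build_mds(ref_model, ref$correlations)
  # group 1 collapses to its top-norm member, which correlates with the rest
  expect_equal(intersect(sel$mds, c("ALP", "SOC", "TN", "MBN", "MBC")), "ALP")
  # group 2 loses only CBH (correlated with the higher-norm nitrate)
  expect_setequal(intersect(sel$mds, c("NO3", "CBH", "ACP", "BG")),
                  c("NO3", "ACP", "BG"))
  # group 4 has no significant correlation: both kept
  expect_setequal(intersect(sel$mds, c("POD", "BX")), c("POD", "BX"))
  expect_setequal(sel$mds, c("ALP", "NO3", "ACP", "BG", "POD", "BX",
                             "NH4", "NAG", "TP"))
  expect_true(all(c("retained", "dropped_correlated", "below_norm_band") %in%
                    sel$audit$status))
  # a consulted pair with no recorded fact is an error naming the pair
  missing_edge <- ref$correlations[
    !(ref$correlations$a == "NO3" & ref$correlations$b == "ACP"), ]
  expect_error(build_mds(ref_model, missing_edge), "NO3 - ACP|ACP - NO3")
})

test_that("nonlinear scores follow the sigmoid and its limit conventions", {
  expect_equal(snl_score(3.7, 3.7, -2.5), 0.5)
  expect_equal(snl_score(3.7, 3.7, 2.5), 0.5)
  expect_equal(snl_score(2, 1, -2.5), 1 / (1 + 2^(-2.5)))
  expect_equal(snl_score(2, 1, 2.5), 1 / (1 + 2^(2.5)))
  expect_equal(snl_score(0, 1, -2.5), 0)  # worst case, more is better
  expect_equal(snl_score(0, 1, 2.5), 1)   # best case, less is better
  expect_error(snl_score(-0.1, 1, -2.5), "x must be")
  expect_error(snl_score(1, 0, -2.5), "x_m")
  set.seed(77)
  x <- sort(runif(50, 0.01, 5))
  s_more <- snl_score(x, 1.7, -2.5)
  s_less <- snl_score(x, 1.7, 2.5)
  expect_true(all(diff(s_more) > 0))        # strictly increasing
  expect_true(all(diff(s_less) < 0))        # strictly decreasing
  expect_true(all(s_more > 0 & s_more < 1))
  expect_equal(s_more + s_less, rep(1, 50), tolerance = 1e-12)
})

test_that("communality weights normalise to one", {
  expect_equal(unname(compute_weights(c(a = 2, b = 2, c = 2, d = 2))),
               rep(0.25, 4))
  w <- compute_weights(ref$communality[c("ALP", "NO3", "ACP")])
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))
  expect_error(compute_weights(numeric(0)), "empty")
  expect_error(compute_weights(c(a = 1, b = 0)), "> 0")
})

test_that("the additive index classifies with upper-inclusive bounds", {
  w <- c(a = 0.5, b = 0.5)
  s <- matrix(0.5, 2, 2, dimnames = list(c("s1", "s2"), c("a", "b")))
  res <- compute_sqi(s, w)
  expect_equal(res$sqi, c(0.5, 0.5))
  expect_equal(res$class, c("high", "high"))
  expect_equal(classify_sqi(c(0.65, 0.46, 0.2, 0.37, 0.55, 0.28)),
               c("very high", "high", "very low", "medium", "high", "low"))
  expect_error(compute_sqi(matrix(1.2, 1, 2, dimnames = list("s", c("a", "b"))),
                           w), "outside")
  expect_error(compute_sqi(s, c(a = 0.5, z = 0.5)), "disagree")
})

test_that("sensitivity index is the max/min ratio within patterns", {
  expect_equal(unname(sensitivity_index(c(0.5, 0.5, 0.5), rep("P", 3))), 1)
  expect_equal(unname(sensitivity_index(c(0.60, 0.50, 0.45), rep("P", 3))),
               0.60 / 0.45)
  perm <- sensitivity_index(c(0.45, 0.60, 0.50), rep("P", 3))
  expect_equal(unname(perm), 0.60 / 0.45)
  expect_error(sensitivity_index(c(0.5, 0.6, 0.7), c("P", "P", "Q")),
               "fewer than 2")
})

test_that("the full pipeline satisfies its invariants on synthetic surveys", {
  tab <- generate_indicator_table(reference_factor_spec(seed = 42))
  res <- suppressWarnings(run_sqi_pipeline(tab))
  expect_s3_class(res, "sqi_result")
  expect_equal(sum(res$weights), 1, tolerance = 1e-10)
  expect_true(all(res$weights > 0))
  expect_true(all(res$samples$sqi > 0 & res$samples$sqi < 1))
  expect_true(all(res$sensitivity >= 1))
  expect_equal(nrow(res$samples), 30L)
  expect_gt(length(res$selection$mds), 0)
  expect_true(any(grepl("MDS:", res$audit)))
})

test_that("scores and the index are invariant to duplicating every sample", {
  tab <- generate_indicator_table(reference_factor_spec(seed = 13))
  spec <- scoring_spec(tab, c("SOC", "TN", "BD"))
  scores <- score_indicators(tab, spec)
  w <- compute_weights(c(SOC = 0.8, TN = 0.7, BD = 0.5))
  sqi1 <- compute_sqi(scores, w)$sqi
  dup <- as.data.frame(rbind(as.data.frame(tab), as.data.frame(tab)))
  dup$sample_id <- paste0(dup$sample_id, "_", rep(1:2, each = nrow(tab)))
  dup <- as_indicator_table(dup, attr(tab, "specs"))
  spec2 <- scoring_spec(dup, c("SOC", "TN", "BD"))
  expect_equal(spec2$x_m, spec$x_m, tolerance = 1e-12)  # x_m unchanged
  sqi2 <- compute_sqi(score_indicators(dup, spec2), w)$sqi
  expect_equal(sqi2, rep(sqi1, 2), tolerance = 1e-12)
})

test_that("a uniform quality shift raises the shifted pattern's mean index", {
  spec <- reference_factor_spec(seed = 88, plots_per_pattern = 15,
                                patterns = c("base", "improved"))
  tab <- generate_quality_gradient(spec, c(0, 1))
  res <- suppressWarnings(run_sqi_pipeline(tab))
  m <- tapply(res$samples$sqi, res$samples$pattern_id, mean)
  expect_gt(m[["improved"]], m[["base"]])
})

test_that("retained components recover the designed factor count at n = 500", {
  hits <- 0
  for (s in 1:100) {
    spec <- recovery_factor_spec(seed = 5000 + s, plots_per_pattern = 500,
                                 patterns = "A")
    m <- standardize_indicators(generate_indicator_table(spec))
    if (length(run_pca(m)$eigenvalues) == 6L) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
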