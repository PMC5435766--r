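test_that("heritability reproduces the published worked examples", {
  h_hyb <- heritability(c(sigma2_genotype = 0.0267, sigma2_gxe = 0.0805,
                          sigma2_residual = 0.0211), n_env = 3, n_rep = 2)
  expect_equal(round(h_hyb, 2), 0.47)
  h_par <- heritability(c(sigma2_genotype = 0.0266, sigma2_gxe = 0.0770,
                          sigma2_residual = 0.0211), n_env = 3, n_rep = 2)
  expect_equal(round(h_par, 2), 0.48)
  expect_equal(heritability(c(sigma2_genotype = 0.1, sigma2_gxe = 0,
                              sigma2_residual = 0), n_env = 3, n_rep = 2), 1)
  expect_error(heritability(c(sigma2_genotype = 0, sigma2_gxe = 0,
                              sigma2_residual = 0), n_env = 3, n_rep = 2),
               class = "hybridqg_data_error")
})

test_that("heritability is monotone in its components", {
  grid <- expand.grid(g = c(0.01, 0.03, 0.09), ge = c(0.02, 0.08),
                      e = c(0.01, 0.04))
  h <- apply(grid, 1, function(r)
    heritability(c(sigma2_genotype = unname(r["g"]),
                   sigma2_gxe = unname(r["ge"]),
                   sigma2_residual = unname(r["e"])), n_env = 3, n_rep = 2))
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$g[i] > grid$g[j] && grid$ge[i] <= grid$ge[j] && grid$e[i] <= grid$e[j])
      expect_gt(h[i], h[j])
    if (grid$g[i] == grid$g[j] && grid$ge[i] > grid$ge[j] && grid$e[i] == grid$e[j])
      expect_lt(h[i], h[j])
  }
})

test_that("outlier detection flags planted outliers and spares clean data", {
  w <- panel_world()
  plots <- w$pheno
  i <- 25
  spiked <- plots
  spiked$value[i] <- mean(plots$value) + 10 * sd(plots$value)
  res <- detect_outliers(phenotype_table(as.data.frame(spiked), stage = "plot"))
  expect_true(any(res$removed$genotype_id == plots$genotype_id[i] &
                  res$removed$environment == plots$environment[i]))
  # all-identical values: nothing removed
  const <- phenotype_table(data.frame(genotype_id = rep(c("a", "b"), 4),
                                      environment = "E01",
                                      replicate = rep(1:4, each = 2),
                                      value = 1), stage = "plot")
  expect_equal(nrow(detect_outliers(const)$removed), 0)
  # null calibration: with the 1/250 premium, clean n = 60 tables rarely
  # lose more than one observation
  hits <- sapply(1:30, function(s) {
    set.seed(1000 + s)
    tb <- phenotype_table(data.frame(
      genotype_id = rep(sprintf("g%02d", 1:30), 2), environment = "E01",
      replicate = rep(1:2, each = 30), value = rnorm(60)), stage = "plot")
    nrow(detect_outliers(tb)$removed)
  })
  expect_gte(mean(hits <= 1), 0.9)
})

test_that("within-environment adjusted means equal per-cell least squares", {
  tb <- phenotype_table(data.frame(
    genotype_id = c("A", "A", "B", "B", "C"),
    environment = c("E1", "E1", "E1", "E1", "E1"),
    replicate = c(1, 2, 1, 2, 1),
    value = c(1, 3, 2, 6, 5)), stage = "plot")
  m <- adjust_means_within_env(tb)
  expect_equal(m$value[match(c("A", "B", "C"), m$genotype_id)], c(2, 4, 5))
  # unbalanced: 3 plots vs 1 plot still the closed-form LS solution (cell mean)
  tb2 <- phenotype_table(data.frame(
    genotype_id = c("A", "A", "A", "B"), environment = "E1",
    replicate = 1:4, value = c(1, 2, 6, 4)), stage = "plot")
  m2 <- adjust_means_within_env(tb2)
  expect_equal(m2$value[m2$genotype_id == "A"], 3)
  expect_equal(m2$value[m2$genotype_id == "B"], 4)
})

test_that("across-environment means: balanced case and GLS oracle", {
  w <- panel_world()
  across <- w$across
  # complete balanced data: equals the mean of within-environment means
  simple <- tapply(w$within$value, w$within$genotype_id, mean)
  expect_equal(across$value[match(names(simple), across$genotype_id)],
               as.numeric(simple), tolerance = 1e-8)
  # missing-cell toy: equals the GLS closed form at the fitted components
  tb <- phenotype_table(data.frame(
    genotype_id = c("A", "A", "B", "B", "C"),       # C misses environment E2
    environment = c("E1", "E2", "E1", "E2", "E1"),
    replicate = 1L, value = c(1.0, 2.0, 1.5, 3.1, 0.7)),
    stage = "within_env_means")
  m <- adjust_means_across_env(tb)
  gid <- factor(tb$genotype_id); env <- factor(tb$environment)
  X <- model.matrix(~ 0 + gid); Zl <- model.matrix(~ 0 + env)
  fit <- hybridqg:::mm_reml(tb$value, X, list(env = tcrossprod(Zl)))
  V <- fit$theta["env"] * tcrossprod(Zl) + fit$theta["residual"] * diag(5)
  V <- V + 1e-6 * mean(diag(V)) * diag(5)            # solver ridge
  beta_gls <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, tb$value))
  expect_equal(m$value, as.numeric(beta_gls), tolerance = 1e-6)
  # correlation with truth approaches 1 on calibrated data
  g_true <- hybridqg:::genetic_values(w$all$codes, w$truth)
  expect_gt(cor(across$value[match(w$all$ids, across$genotype_id)], g_true +
                  0.44 * (w$all$group == "hybrid")), 0.8)
})

test_that("one-step GCA/SCA fit is invariant to parent order and matches its oracle", {
  w <- panel_world()
  vc <- fit_gca_sca(w$pheno, w$design)
  # parent-order permutation invariance
  flipped <- crossing_design(w$design$parent2, w$design$parent1,
                             hybrid_id = w$design$hybrid_id)
  vc_f <- fit_gca_sca(w$pheno, flipped)
  expect_equal(vc$components, vc_f$components, tolerance = 1e-6)
  # H2 recomputes from stored components
  expect_equal(vc$heritability,
               heritability(vc$components[c("sigma2_genotype", "sigma2_gxe",
                                            "sigma2_residual")],
                            n_env = vc$n_env, n_rep = vc$n_rep))
  # decomposition conventions
  expect_equal(vc$components[["sigma2_genotype"]],
               vc$components[["sigma2_gca"]] + vc$components[["sigma2_sca"]])
  expect_equal(vc$components[["sigma2_gxe"]],
               vc$components[["sigma2_env_x_gca"]] +
                 vc$components[["sigma2_env_x_sca"]])
})

test_that("a zero-SCA world is not declared significant", {
  map <- default_map(n_chr = 6, n_markers = 8)
  hits <- sapply(1:8, function(s) {
    dh <- simulate_dh_population(map, 60, seed = 300 + s)
    des <- make_crossing_design(60, 90, seed = 300 + s, parent_ids = dh$ids)
    tr <- calibrate_truth(dh, des, n_qtl = 20, sigma2_sca = 0,
                          sigma2_env_x_sca = 0.02, seed = 300 + s)
    ph <- simulate_trait(dh, des, tr, n_env = 2, n_rep = 2)
    vc <- fit_gca_sca(ph, des, significance = "sca")
    vc$significance[["sca"]] < 0.05
  })
  expect_gte(mean(!hits), 0.85)
})
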