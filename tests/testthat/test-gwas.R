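test_that("Bonferroni-Holm step-down matches its definition", {
  expect_equal(holm_correct(c(0.001, 0.01, 0.03, 0.04, 0.2), alpha = 0.1),
               c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(holm_correct(rep(1, 4), alpha = 0.1), rep(FALSE, 4))
  expect_true(holm_correct(0.09, alpha = 0.1))
  # flags are a subset of the unadjusted flags
  set.seed(2)
  p <- runif(50)^2
  expect_true(all(!(holm_correct(p, 0.1) & p >= 0.1)))
})

test_that("main-effect scan localizes a planted additive QTL", {
  map <- default_map(n_chr = 5, n_markers = 12)
  hits <- sapply(1:3, function(s) {
    dh <- simulate_dh_population(map, 90, seed = 500 + s)
    des <- make_crossing_design(90, 130, seed = 500 + s, parent_ids = dh$ids)
    qtl <- 25
    tr <- sim_truth(qtl, additive_effects = 0.5, dominance_effects = 0,
                    env_effects = 0, residual_sd = 0.3, seed = 500 + s)
    ph <- simulate_trait(dh, des, tr, n_env = 1, n_rep = 2)
    means <- adjust_means_within_env(ph)
    all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
    dsg <- f_infinity_design(all)
    scan <- main_effect_scan(means, dsg, rogers_kinship(all))
    top <- which.min(scan$p_a)
    r2 <- cor(dsg$A[, top], dsg$A[, qtl])^2
    r2 > 0.9
  })
  expect_true(all(hits))
})

test_that("constant markers get P = 1 with a note", {
  w <- panel_world()
  mm <- w$all
  mm$codes[, 4] <- 1
  dsg <- f_infinity_design(mm)
  scan <- main_effect_scan(w$within, dsg, rogers_kinship(w$all))
  expect_equal(scan$p_a[4], 1)
  expect_equal(scan$note[4], "constant")
})

test_that("P3D and exact scans agree closely under a polygenic null", {
  map <- default_map(n_chr = 4, n_markers = 10)
  dh <- simulate_dh_population(map, 110, seed = 88)
  des <- make_crossing_design(110, 165, seed = 88, parent_ids = dh$ids)
  tr <- calibrate_truth(dh, des, n_qtl = 15, seed = 88)
  ph <- simulate_trait(dh, des, tr, n_env = 2, n_rep = 2)
  means <- adjust_means_within_env(ph)
  all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
  dsg <- f_infinity_design(all)
  K <- rogers_kinship(all)
  s1 <- main_effect_scan(means, dsg, K, mode = "p3d")
  s2 <- main_effect_scan(means, dsg, K, mode = "exact")
  ok <- is.finite(s1$p_a) & is.finite(s2$p_a) & s2$p_a > 1e-12
  rel <- abs(log10(s1$p_a[ok]) - log10(s2$p_a[ok])) /
    pmax(abs(log10(s2$p_a[ok])), 0.3)
  expect_gte(mean(rel < 0.1), 0.95)
})

test_that("two-locus scan coefficients equal a weighted-regression oracle", {
  map <- default_map(n_chr = 2, n_markers = 4)
  dh <- simulate_dh_population(map, 20, seed = 57)
  des <- make_crossing_design(20, 26, seed = 57, parent_ids = dh$ids)
  all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))   # 46 individuals
  dsg <- f_infinity_design(all)
  K <- rogers_kinship(all)
  set.seed(57)
  y <- 2 + 0.3 * dsg$A[, 1] * dsg$A[, 6] + rnorm(46, 0, 0.4)
  means <- phenotype_table(data.frame(genotype_id = all$ids,
                                      environment = "E1", replicate = 1,
                                      value = y), stage = "within_env_means")
  res <- epistasis_scan_2d(means, dsg, K, pairs = cbind(1, 6))
  # oracle: GLS with the scan's own null covariance
  s2u <- attr(res, "sigma2_u"); s2e <- attr(res, "sigma2_e")
  V <- s2u * unclass(K)[, ] + s2e * diag(46)
  M <- cbind(1, dsg$A[, 1], dsg$A[, 6], dsg$D[, 1], dsg$D[, 6],
             dsg$A[, 1] * dsg$A[, 6], dsg$A[, 1] * dsg$D[, 6],
             dsg$D[, 1] * dsg$A[, 6], dsg$D[, 1] * dsg$D[, 6])
  b <- solve(t(M) %*% solve(V, M), t(M) %*% solve(V, y))
  expect_equal(res$i11, b[6], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$i12, b[7], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$i21, b[8], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$i22, b[9], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("two-locus scan detects a planted dominance-by-dominance pair", {
  map <- default_map(n_chr = 4, n_markers = 12)      # 48 markers
  hits <- sapply(1:3, function(s) {
    dh <- simulate_dh_population(map, 90, seed = 700 + s)
    des <- make_crossing_design(90, 140, seed = 700 + s, parent_ids = dh$ids)
    ep <- data.frame(locus1 = 5, locus2 = 30, type = "DD", effect = 0.8)
    tr <- sim_truth(integer(0), numeric(0), numeric(0), epistatic_pairs = ep,
                    env_effects = 0, residual_sd = 0.25, seed = 700 + s)
    ph <- simulate_trait(dh, des, tr, n_env = 1, n_rep = 2)
    means <- adjust_means_within_env(ph)
    all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
    dsg <- f_infinity_design(all)
    res <- epistasis_scan_2d(means, dsg, rogers_kinship(all))
    top <- which.min(res$p_i22)
    setequal(c(res$marker1[top], res$marker2[top]),
             map$marker_id[c(5, 30)])
  })
  expect_gte(mean(hits), 2 / 3)
})

test_that("collinearity and proximity filters skip pairs with reasons", {
  w <- panel_world()
  dsg <- w$dsg
  res <- epistasis_scan_2d(w$within, dsg, rogers_kinship(w$all),
                           pairs = cbind(1, 2))       # adjacent, ~5.7 cM apart
  expect_true(res$note %in% c("proximal", "collinear", ""))
  res2 <- epistasis_scan_2d(w$within, dsg, rogers_kinship(w$all),
                            min_cM = 10, pairs = cbind(1, 2))
  expect_equal(res2$note, "proximal")
  expect_true(is.na(res2$p_i22))
})

test_that("permutation thresholds are reproducible and match their definition", {
  w <- panel_world()
  sub <- 1:12                                         # 66 pairs
  dsg_sub <- structure(list(A = w$dsg$A[, sub], D = w$dsg$D[, sub],
                            map = w$dsg$map[sub, ], ids = w$dsg$ids,
                            group = w$dsg$group), class = "design_matrices")
  thr1 <- permutation_threshold(w$within, dsg_sub, rogers_kinship(w$all),
                                n_perm = 50, alpha = 0.1, seed = 5)
  thr2 <- permutation_threshold(w$within, dsg_sub, rogers_kinship(w$all),
                                n_perm = 50, alpha = 0.1, seed = 5)
  expect_identical(thr1$thresholds, thr2$thresholds)
  k <- ceiling(0.1 * 50)
  expect_equal(unname(thr1$thresholds["i22"]),
               sort(thr1$minima[, "i22"])[k])
  expect_error(permutation_threshold(w$within, dsg_sub, rogers_kinship(w$all),
                                     n_perm = 20), class = "hybridqg_config_error")
})

test_that("explained variance decomposes sequentially and matches a direct fit", {
  set.seed(12)
  n <- 200
  x1 <- sample(c(-1, 1), n, TRUE)
  x2 <- sample(c(-1, 1), n, TRUE)                     # orthogonal in expectation
  x2 <- x2 - x1 * sum(x1 * x2) / sum(x1^2)            # force exact orthogonality
  y <- 0.4 * x1 + 0.3 * x2 + rnorm(n, 0, 0.5)
  map <- default_map(1, 2)
  dsg <- structure(list(A = cbind(x1, x2), D = matrix(0, n, 2), map = map,
                        ids = sprintf("g%03d", 1:n),
                        group = rep("inbred", n)), class = "design_matrices")
  means <- phenotype_table(data.frame(genotype_id = dsg$ids,
                                      environment = "E1", replicate = 1,
                                      value = y), stage = "within_env_means")
  det <- data.frame(marker_id = map$marker_id, term = "a", p = c(1e-8, 1e-5))
  ev <- explained_variance(means, det, dsg, h2 = 0.9)
  # orthogonal QTL: each increment equals that QTL's marginal gain
  adj_r2 <- function(X) {
    Xf <- if (is.null(X)) matrix(1, n, 1) else cbind(1, X)
    f <- lm.fit(Xf, y)
    1 - (sum(f$residuals^2) / (n - f$rank)) / var(y)
  }
  base <- adj_r2(NULL)
  expect_equal(ev$per_qtl$r2_increment[1], adj_r2(x1) - base, tolerance = 1e-10)
  # second increment differs from the marginal gain only through the
  # residual-df correction of adjusted R2, O(1/n)
  expect_equal(ev$per_qtl$r2_increment[2], adj_r2(x2) - base, tolerance = 0.02)
  # total equals the full-model fit to 1e-10
  full <- adj_r2(cbind(x1, x2)) - base
  expect_equal(ev$total_r2, full, tolerance = 1e-10)
  expect_equal(sum(ev$per_qtl$r2_increment), ev$total_r2, tolerance = 1e-10)
  # capping
  ev2 <- suppressWarnings(explained_variance(means, det, dsg, h2 = 0.01))
  expect_equal(ev2$pG, 1)
  expect_true(ev2$capped)
})

test_that("mapping cross-validation: determinism, perfect-QTL limit, dominance gain", {
  # perfect heritability, single known QTL: accuracy 1
  map <- default_map(2, 6)
  dh <- simulate_dh_population(map, 40, seed = 31)
  des <- make_crossing_design(40, 60, seed = 31, parent_ids = dh$ids)
  tr <- sim_truth(3, additive_effects = 0.5, dominance_effects = 0,
                  env_effects = 0, residual_sd = 0, seed = 31)
  ph <- simulate_trait(dh, des, tr, n_env = 1, n_rep = 1)
  means <- adjust_means_within_env(ph)
  all <- bind_individuals(dh, infer_hybrid_genotypes(dh, des))
  dsg <- f_infinity_design(all)
  acc <- cv_mapping_accuracy(means, dsg, h2 = 1, folds = 3, seed = 11,
                             models = "A")
  expect_true(all(abs(acc$accuracy - 1) < 1e-6 | acc$flagged))
  acc2 <- cv_mapping_accuracy(means, dsg, h2 = 1, folds = 3, seed = 11,
                              models = "A")
  expect_identical(acc$accuracy, acc2$accuracy)      # fold seed determinism
  # dominance-rich, detectable architecture: AD beats A on average
  map2 <- default_map(n_markers = 15)
  res <- lapply(1:3, function(s) {
    dh2 <- simulate_dh_population(map2, 100, seed = 900 + s)
    des2 <- make_crossing_design(100, 160, seed = 900 + s, parent_ids = dh2$ids)
    tr2 <- calibrate_truth(dh2, des2, n_qtl = 20, sigma2_gca = 0.011,
                           sigma2_sca = 0.030, sigma2_env_x_gca = 0.005,
                           sigma2_env_x_sca = 0.005, seed = 900 + s)
    ph2 <- simulate_trait(dh2, des2, tr2, n_env = 2, n_rep = 2)
    m2 <- adjust_means_across_env(adjust_means_within_env(ph2))
    all2 <- bind_individuals(dh2, infer_hybrid_genotypes(dh2, des2))
    cv_mapping_accuracy(m2, f_infinity_design(all2), h2 = 0.6, folds = 5,
                        seed = 900 + s, alpha = 0.1)
  })
  res <- do.call(rbind, res)
  mA <- mean(res$accuracy[res$model == "A"])
  mAD <- mean(res$accuracy[res$model == "AD"])
  expect_gt(mAD, mA)
})
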