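test_that("genotype simulation honours the LD profile and is deterministic", {
  cfg <- sim_config(n = 5000, m = 60, n_blocks = 2, ld_decay = 0.9,
                    h2g = 0.1)
  set.seed(1)
  g1 <- simulate_genotypes(cfg)
  set.seed(1)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$G, g2$G)
  # homogeneous AR(1): adjacent sample correlations near 0.9
  adj <- vapply(seq_len(29), function(j) cor(g1$G[, j], g1$G[, j + 1]), 0)
  expect_true(all(abs(adj - 0.9) < 0.05))
  # columns standardized
  expect_lt(max(abs(colMeans(g1$G))), 1e-12)
  expect_equal(unname(apply(g1$G, 2, sd)), rep(1, 60), tolerance = 1e-12)

  # near-zero decay: independent columns
  cfg0 <- sim_config(n = 5000, m = 40, n_blocks = 2, ld_decay = 1e-8,
                     h2g = 0.1)
  set.seed(2)
  g0 <- simulate_genotypes(cfg0)$G
  R <- cor(g0)
  expect_lt(max(abs(R[upper.tri(R)])), 4 / sqrt(5000) + 0.02)

  # dosage mode produces 0/1/2 before standardization (3 distinct values)
  cfgd <- sim_config(n = 2000, m = 20, n_blocks = 2, dosage = TRUE,
                     causal_fraction = 0.2, h2g = 0.1)
  set.seed(3)
  gd <- simulate_genotypes(cfgd)$G
  expect_true(all(apply(gd, 2, function(x) length(unique(x))) <= 3))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(h2g = 0.9, h2i = 0.2), "exceed")
  expect_error(sim_config(h2g = 0.1, h2i = 0.1, r_ig = 0.9,
                          heritable_e = TRUE, h2e = 0.1, r_ge = 0.9,
                          r_ie = -0.9), "semi-definite")
  expect_error(sim_config(m = 10, causal_fraction = 0.05), "at least 2")
  expect_error(sim_config(m = 100, n_blocks = 7), "n_blocks")
})

test_that("effect draws respect the variance budget and correlation", {
  cfg <- sim_config(n = 100, m = 2000, n_blocks = 10, causal_fraction = 0.5,
                    h2g = 0.25, h2i = 0.04, r_ig = 0.4)
  set.seed(4)
  reps <- 40
  sums <- matrix(NA, reps, 3)
  for (r in seq_len(reps)) {
    ef <- draw_effects(cfg)
    expect_length(ef$causal, 1000L)
    sums[r, ] <- c(sum(ef$beta^2), sum(ef$gamma^2),
                   cor(ef$beta[ef$causal], ef$gamma[ef$causal]))
  }
  expect_lt(abs(mean(sums[, 1]) - 0.25), 0.008)
  expect_lt(abs(mean(sums[, 2]) - 0.04), 0.0018)
  expect_lt(abs(mean(sums[, 3]) - 0.4), 0.02)
  # null interaction variance: gamma identically zero
  cfg0 <- sim_config(h2i = 0, r_ig = 0)
  ef0 <- draw_effects(cfg0)
  expect_true(all(ef0$gamma == 0))
  # scaling by all variants yields the diluted realized variance
  cfga <- sim_config(m = 1000, causal_fraction = 0.05, h2g = 0.2,
                     scale_by = "all")
  set.seed(5)
  s2 <- mean(replicate(40, sum(draw_effects(cfga)$beta^2)))
  expect_lt(abs(s2 - 0.2 * 0.05), 0.0015)
})

test_that("phenotype variance decomposes as configured", {
  cfg <- sim_config(n = 4000, m = 500, n_blocks = 5, h2g = 0.3, h2i = 0.05,
                    r_ig = 0.2, sigma1sq = 0.1, rho01 = 0.02)
  set.seed(6)
  geno <- simulate_genotypes(cfg)
  vy <- replicate(20, {
    ef <- draw_effects(cfg)
    e <- simulate_environment(geno$G, ef, cfg)
    var(simulate_phenotype(geno$G, ef, e, cfg))
  })
  expect_equal(mean(vy), 1, tolerance = 0.05)
  # pure-noise phenotype
  cfg0 <- sim_config(n = 4000, m = 500, n_blocks = 5, h2g = 0, h2i = 0)
  ef0 <- draw_effects(cfg0)
  e0 <- simulate_environment(geno$G, ef0, cfg0)
  y0 <- simulate_phenotype(geno$G, ef0, e0, cfg0)
  expect_equal(var(y0), 1, tolerance = 0.08)
  cfg_bad <- cfg0
  cfg_bad$sigma1sq <- 2
  expect_error(simulate_phenotype(geno$G, ef0, e0, cfg_bad), "negative")
})

test_that("a heritable environment carries the configured genetic share", {
  cfg <- sim_config(n = 6000, m = 500, n_blocks = 5, h2g = 0.2, h2i = 0.02,
                    r_ig = 0, heritable_e = TRUE, h2e = 0.3, r_ge = 0,
                    r_ie = 0)
  set.seed(7)
  geno <- simulate_genotypes(cfg)
  # average over effect draws: the realized genetic share of a sparse
  # causal architecture varies draw to draw
  reps <- 25
  stats <- t(replicate(reps, {
    ef <- draw_effects(cfg)
    e <- simulate_environment(geno$G, ef, cfg)
    c(var(e), cor(e, drop(geno$G %*% ef$alpha))^2)
  }))
  expect_lt(abs(mean(stats[, 1]) - 1), 0.06)
  expect_lt(abs(mean(stats[, 2]) - 0.3), 0.05)
})

test_that("association scans equal per-SNP least squares to machine precision", {
  set.seed(8)
  n <- 60; m <- 6
  G <- scale(matrix(rnorm(n * m), n, m))
  e <- rnorm(n)
  y <- rnorm(n) + 0.5 * G[, 1] + 0.3 * G[, 2] * e
  z_g <- association_scan(G, y, mode = "gwas_y")
  z_i <- association_scan(G, y, e, mode = "gwis")
  z_e <- association_scan(G, e = e, mode = "gwas_e")
  for (j in seq_len(m)) {
    f1 <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(z_g[j], f1[2, "t value"], tolerance = 1e-8)
    f2 <- summary(lm(y ~ G[, j] * e))$coefficients
    expect_equal(z_i[j], f2["G[, j]:e", "t value"], tolerance = 1e-8)
    f3 <- summary(lm(e ~ G[, j]))$coefficients
    expect_equal(z_e[j], f3[2, "t value"], tolerance = 1e-8)
  }
  expect_equal(attr(z_i, "n"), n)
  # a monomorphic variant is flagged as missing, not propagated as NaN
  Gc <- cbind(G[, 1:2], 0)
  zc <- association_scan(Gc, y, e, "gwis")
  expect_true(3L %in% attr(zc, "flagged"))
  expect_true(is.na(zc[3]))
  expect_true(all(is.finite(zc[1:2])))
})

test_that("null scans are calibrated: mean squared Z near one", {
  cfg <- sim_config(n = 2000, m = 500, n_blocks = 5, h2g = 0, h2i = 0)
  set.seed(9)
  sim <- simulate_study(cfg, ld = FALSE)
  expect_equal(mean(sim$sumstats$g$z^2), 1, tolerance = 0.15)
  expect_equal(mean(sim$sumstats$i$z^2), 1, tolerance = 0.15)
})

test_that("experiments are deterministic given the master seed", {
  grid <- data.frame(h2g = 0.2, h2i = 0.02, r_ig = 0.5, n = 400, m = 100,
                     n_blocks = 2)
  r1 <- run_experiment(grid, reps = 3, estimators = "eigen", seed = 42)
  r2 <- run_experiment(grid, reps = 3, estimators = "eigen", seed = 42)
  expect_identical(r1, r2)
  r3 <- run_experiment(grid, reps = 3, estimators = "eigen", seed = 43)
  expect_false(identical(r1$rho_ig, r3$rho_ig))
  sm <- summarize_experiment(r1)
  expect_equal(sm$n_reps, 3L)
  expect_true(all(c("rho_ig_bias", "rho_ig_sd", "rho_ig_rmse") %in%
                    names(sm)))
})

test_that("the PRS-by-E coefficient matches the covariance ratio", {
  cfg <- sim_config(n = 4000, m = 400, n_blocks = 4, h2g = 0.3, h2i = 0.03,
                    r_ig = 0.5, causal_fraction = 0.25)
  set.seed(10)
  geno <- simulate_genotypes(cfg)
  reps <- 30
  b3 <- exp_ratio <- b3_noisy <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_study(cfg, genotypes = geno, ld = FALSE)
    chk <- prs_by_e_check(sim)
    b3[r] <- chk$beta3
    exp_ratio[r] <- chk$expected
    b3_noisy[r] <- prs_by_e_check(sim, noise_var = 0.3)$beta3
  }
  mc_se <- sd(b3) / sqrt(reps)
  expect_lt(abs(mean(b3) - exp_ratio[1]), 3 * mc_se + 0.005)
  # attenuation: a noisy PRS shrinks the interaction coefficient toward 0
  expect_lt(abs(mean(b3_noisy)), abs(mean(b3)))
  # null case
  cfg0 <- sim_config(n = 2000, m = 200, n_blocks = 2, h2g = 0.3, h2i = 0,
                     r_ig = 0)
  set.seed(11)
  sim0 <- simulate_study(cfg0, ld = FALSE)
  chk0 <- prs_by_e_check(sim0)
  expect_lt(abs(chk0$beta3), 4 * chk0$se3)
})
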