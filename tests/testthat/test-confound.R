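test_that("the correction chain inverts a noise-free system exactly", {
  d <- rep(seq(0.1, 5, length.out = 40), 3)
  bid <- rep(1:3, each = 40)
  pars <- list(h2g = 0.3, h2i = 0.03, sigma1sq = 0, rho_ig = 0.0285,
               h2e = 0.3, rho_ie = 0.0474, rho_ge = 0.15)
  mt <- exact_moment_table(d, bid, h2g = pars$h2g, h2i = pars$h2i,
                           rho_ig = pars$rho_ig, h2e = pars$h2e,
                           rho_ie = pars$rho_ie, rho_ge = pars$rho_ge,
                           c1 = 0.2, ge_icpt = -0.1, gi_intercept = 0.15,
                           with_e = TRUE)
  f <- fit_gxe_corrected(mt)
  expect_equal(f$h2e, pars$h2e, tolerance = 1e-8)
  expect_equal(f$rho_ie, pars$rho_ie, tolerance = 1e-8)
  expect_equal(f$h2i, pars$h2i, tolerance = 1e-8)
  expect_equal(f$rho_ge, pars$rho_ge, tolerance = 1e-8)
  expect_equal(f$rho_ig, pars$rho_ig, tolerance = 1e-8)
  expect_equal(f$intercepts[["c1"]], 0.2, tolerance = 1e-8)
  # reconstructing the expected slope from the estimates reproduces the
  # input moment slope (self-consistency of the inversion)
  slope_ei_hat <- sqrt(2000 * 2000) * f$rho_ie * (1 + f$h2e) / 1000
  slope_ei_obs <- (mt$y_ei[2] - mt$y_ei[1]) / (d[2] - d[1])
  expect_equal(slope_ei_hat, slope_ei_obs, tolerance = 1e-10)
})

test_that("single-parameter correction operations invert their slopes", {
  d <- rep(seq(0.2, 4, length.out = 30), 2)
  bid <- rep(1:2, each = 30)
  mt <- exact_moment_table(d, bid, h2g = 0.2, h2i = 0.03, h2e = 0.3,
                           rho_ie = 0.1, rho_ge = 0.15, c1 = 0.05,
                           with_e = TRUE)
  expect_equal(estimate_h2e(mt)$h2e, 0.3, tolerance = 1e-8)
  rie <- estimate_rho_ie(mt, h2e = 0.3)
  expect_equal(rie$rho_ie, 0.1, tolerance = 1e-8)
  expect_equal(rie$c1, 0.05, tolerance = 1e-8)
  expect_error(estimate_rho_ie(mt, h2e = -1.5), "positive")
  ci <- corrected_h2i(mt, rho_ie = 0.1)
  expect_equal(ci$h2i_corrected, 0.03, tolerance = 1e-8)
  expect_equal(ci$h2i_uncorrected, 0.03 + 2 * 0.1^2, tolerance = 1e-8)
  expect_equal(estimate_rho_ge(mt)$rho_ge, 0.15, tolerance = 1e-8)
  # flat E-I product: zero covariance, intercept recovered
  mt0 <- exact_moment_table(d, bid, h2g = 0.2, c1 = 0.4, with_e = TRUE)
  r0 <- estimate_rho_ie(mt0, h2e = 0)
  expect_equal(r0$rho_ie, 0, tolerance = 1e-10)
  expect_equal(r0$c1, 0.4, tolerance = 1e-10)
})

test_that("rho_ge estimation is symmetric in the two GWAS scans", {
  sim <- tiny_study(n = 800, m = 200, h2g = 0.3, h2i = 0.02, r_ig = 0.3,
                    heritable_e = TRUE, h2e = 0.3, r_ge = 0.5, r_ie = 0.3,
                    seed = 11)
  mt <- moment_table_of(sim)
  r1 <- estimate_rho_ge(mt)$rho_ge
  mt2 <- mt
  mt2$y_gg <- mt$y_ee; mt2$y_ee <- mt$y_gg
  attr(mt2, "n") <- attr(mt, "n")[c("e", "i", "g")]
  names(attr(mt2, "n")) <- c("g", "i", "e")
  r2 <- estimate_rho_ge(mt2)$rho_ge
  expect_equal(r2, r1, tolerance = 1e-10)
})

test_that("corrected h2i never exceeds the uncorrected estimate", {
  # identically, because the correction subtracts 2 * rho_ie^2 >= 0
  for (seed in 1:4) {
    sim <- tiny_study(n = 600, m = 200, h2g = 0.3, h2i = 0.03, r_ig = 0.3,
                      heritable_e = TRUE, h2e = 0.3, r_ge = 0.5,
                      r_ie = 0.5, seed = seed)
    f <- fit_gxe_corrected(moment_table_of(sim))
    expect_lte(f$h2i, f$h2i_uncorrected)
  }
})

test_that("a null rho_ie leaves the corrected estimates unchanged", {
  d <- rep(seq(0.2, 4, length.out = 30), 2)
  bid <- rep(1:2, each = 30)
  mt <- exact_moment_table(d, bid, h2g = 0.2, h2i = 0.04, rho_ig = 0.02,
                           h2e = 0.3, rho_ie = 0, rho_ge = 0.15,
                           with_e = TRUE)
  f <- fit_gxe_corrected(mt)
  expect_equal(f$h2i, f$h2i_uncorrected, tolerance = 1e-10)
  expect_equal(f$rho_ig, f$rho_ig_uncorrected, tolerance = 1e-10)
})

test_that("confounding test is the two-sided Wald test of rho_ie", {
  expect_equal(confounding_test(0, 1), 1)
  expect_equal(confounding_test(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(confounding_test(0.5, 0.25), wald_test(0.5, 0.25))
  expect_error(confounding_test(1, 0), "positive")
})

test_that("with a non-heritable E, corrected and plain estimates agree on average", {
  cfg <- sim_config(n = 1500, m = 500, n_blocks = 5, h2g = 0.2, h2i = 0.03,
                    r_ig = 0.5, heritable_e = TRUE, h2e = 0)
  set.seed(12)
  geno <- simulate_genotypes(cfg)
  ids <- colnames(geno$G)
  ebs <- lapply(unique(geno$block), function(b) {
    idx <- which(geno$block == b)
    eigendecompose_ld(compute_block_ld(geno$G[, idx], ids[idx], b))
  })
  ref <- data.frame(snp = ids, a1 = "A", a2 = "G")
  nrep <- 40
  diffs <- matrix(NA, nrep, 2)
  for (r in seq_len(nrep)) {
    sim <- simulate_study(cfg, genotypes = geno, eigenblocks = ebs)
    mt <- build_moment_table(
      harmonize_sumstats(sim$sumstats, ref, verbose = FALSE), ebs)
    f <- fit_gxe_corrected(mt)
    diffs[r, ] <- c(f$h2i - f$h2i_uncorrected,
                    f$rho_ig - f$rho_ig_uncorrected)
  }
  mc_se <- apply(diffs, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(diffs)) < 3 * mc_se + 1e-3))
})

test_that("corrected estimation requires the E-GWAS products", {
  sim <- tiny_study(seed = 3)
  mt <- moment_table_of(sim)
  expect_error(fit_gxe_corrected(mt), "E-GWAS")
  expect_error(estimate_h2e(mt), "E-GWAS")
})
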