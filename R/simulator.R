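# Simulation engine: block-LD genotypes, bivariate/trivariate effect sizes,
# phenotypes with SNP-by-environment interactions, and in-process per-SNP
# association scans producing GWAS/GWIS/E-GWAS Z-scores.

#' Build a validated simulation configuration
#'
#' Defines one data-generating scenario: a standardized phenotype receiving
#' additive genetic effects (variance share `h2g`), SNP-by-environment
#' interaction effects (share `h2i`, effect correlation `r_ig` with the
#' additive effects) and, optionally, a heritable environment with
#' heritability `h2e` whose genetic effects correlate with the additive and
#' interaction effects (`r_ge`, `r_ie`).  Effects are Gaussian on a uniformly
#' drawn causal subset; genotypes have block-diagonal LD.
#'
#' @param n Number of subjects.
#' @param m Number of variants.
#' @param n_blocks Number of equally sized LD blocks.
#' @param causal_fraction Fraction of variants carrying effects.
#' @param h2g Narrow-sense heritability of the phenotype.
#' @param h2i G-by-E interaction proportion of the phenotype.
#' @param r_ig Correlation between additive and interaction effect sizes;
#'   the G-by-E genetic covariance is `rho_ig = sqrt(h2g * h2i) * r_ig`.
#' @param sigma1sq Variance of the residual component that interacts with
#'   the environment.
#' @param rho01 Covariance between the interacting and non-interacting
#'   residual components.
#' @param heritable_e Generate E with its own additive genetic component.
#' @param h2e Heritability of E (heritable case).
#' @param r_ge Correlation between the additive effects on Y and on E.
#' @param r_ie Correlation between the interaction effects and the additive
#'   effects on E.
#' @param ld_profile Within-block correlation structure: `"ar1"` (correlation
#'   `ld_decay^|j-k|`) or `"exchangeable"` (constant `ld_decay`).
#' @param ld_decay Correlation parameter of the block profile.  A length-2
#'   vector `c(lo, hi)` varies the adjacent-variant correlation smoothly
#'   from `lo` to `hi` and back within every block (a non-stationary AR(1)
#'   profile), emulating the genome's alternation of weak- and strong-LD
#'   regions -- every block then carries the same mixed eigenvalue spectrum
#'   and variant-to-variant LD-score variation, as no single genomic block
#'   dominates a genome-wide analysis.  A scalar gives every block a
#'   homogeneous profile; a length-`n_blocks` vector sets per-block
#'   homogeneous profiles explicitly.
#' @param dosage Draw genotypes as 0/1/2 allelic dosages via a thresholded
#'   latent Gaussian (MAF uniform on 0.05--0.5) instead of Gaussians.
#' @param scale_by `"causal"`: causal effect variance `h2 / M0` so the
#'   realized variance explained matches the nominal target; `"all"`:
#'   variance `h2 / m` on the causal subset only (realized variance
#'   `h2 * M0 / m`).
#' @param standardize_y Z-score the phenotype before association scans.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n = 2000L, m = 1000L, n_blocks = 10L,
                       causal_fraction = 0.05,
                       h2g = 0.2, h2i = 0, r_ig = 0,
                       sigma1sq = 0, rho01 = 0,
                       heritable_e = FALSE, h2e = 0, r_ge = 0, r_ie = 0,
                       ld_profile = c("ar1", "exchangeable"),
                       ld_decay = c(0.2, 0.9),
                       dosage = FALSE, scale_by = c("causal", "all"),
                       standardize_y = FALSE) {
  ld_profile <- match.arg(ld_profile)
  scale_by <- match.arg(scale_by)
  cfg <- list(n = as.integer(n), m = as.integer(m),
              n_blocks = as.integer(n_blocks),
              causal_fraction = causal_fraction,
              h2g = h2g, h2i = h2i, r_ig = r_ig,
              sigma1sq = sigma1sq, rho01 = rho01,
              heritable_e = isTRUE(heritable_e), h2e = h2e,
              r_ge = r_ge, r_ie = r_ie,
              ld_profile = ld_profile, ld_decay = ld_decay,
              dosage = isTRUE(dosage), scale_by = scale_by,
              standardize_y = isTRUE(standardize_y))
  if (!length(cfg$ld_decay) %in% c(1L, 2L, cfg$n_blocks)) {
    stop("ld_decay must have length 1, 2 or n_blocks", call. = FALSE)
  }
  if (any(abs(cfg$ld_decay) >= 1)) {
    stop("ld_decay parameters must lie in (-1, 1)", call. = FALSE)
  }
  if (length(cfg$ld_decay) == 2L && any(cfg$ld_decay <= 0)) {
    stop("a within-block ld_decay ramp requires parameters in (0, 1)",
         call. = FALSE)
  }
  stopifnot(cfg$n >= 10L, cfg$m >= 2L, cfg$n_blocks >= 1L,
            cfg$m %% cfg$n_blocks == 0L,
            cfg$causal_fraction > 0, cfg$causal_fraction <= 1,
            cfg$h2g >= 0, cfg$h2i >= 0, cfg$h2e >= 0,
            abs(cfg$r_ig) <= 1, abs(cfg$r_ge) <= 1, abs(cfg$r_ie) <= 1,
            cfg$sigma1sq >= 0)
  if (cfg$h2g + cfg$h2i + cfg$sigma1sq > 1) {
    stop("variance components h2g + h2i + sigma1sq exceed 1", call. = FALSE)
  }
  if (cfg$heritable_e && cfg$h2e > 1) stop("h2e > 1", call. = FALSE)
  m0 <- round(cfg$causal_fraction * cfg$m)
  if (m0 < 2L) stop("causal_fraction * m must be at least 2", call. = FALSE)
  cfg$m0 <- as.integer(m0)
  # implied effect correlation matrix must be PSD
  C <- .effect_correlation(cfg)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("implied effect-size correlation matrix is not positive ",
         "semi-definite", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

.effect_correlation <- function(cfg) {
  if (cfg$heritable_e) {
    matrix(c(1, cfg$r_ig, cfg$r_ge,
             cfg$r_ig, 1, cfg$r_ie,
             cfg$r_ge, cfg$r_ie, 1), 3L, 3L)
  } else {
    matrix(c(1, cfg$r_ig, cfg$r_ig, 1), 2L, 2L)
  }
}

#' Simulate standardized genotypes with block LD
#'
#' Within each block, columns follow the configured correlation profile
#' (cross-block independence); each column is then standardized to sample
#' mean 0 and variance 1.
#'
#' @param cfg A `sim_config`.
#' @return List with `G` (n x m standardized matrix, variant IDs as column
#'   names) and `block` (integer block index per variant).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  bs <- cfg$m %/% cfg$n_blocks
  chol_of <- function(rho) {
    # rho: scalar (stationary) or length bs-1 adjacent-pair correlations
    Sigma <- if (cfg$ld_profile == "exchangeable") {
      matrix(rho[1L], bs, bs) + diag(1 - rho[1L], bs)
    } else if (length(rho) == 1L) {
      rho^abs(outer(seq_len(bs), seq_len(bs), "-"))
    } else {
      # non-stationary Markov profile: r_jk = prod of adjacent correlations
      cp <- c(0, cumsum(log(rho)))
      exp(-abs(outer(cp, cp, "-")))
    }
    ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) {
      stop("infeasible within-block correlation profile (not PSD)",
           call. = FALSE)
    }
    chol(Sigma + diag(1e-12, bs))
  }
  decay <- cfg$ld_decay
  rho_list <- if (length(decay) == 2L && bs > 2L &&
                  cfg$ld_profile == "ar1") {
    # same within-block ramp lo -> hi -> lo for every block
    ramp <- c(seq(decay[1L], decay[2L],
                  length.out = ceiling((bs - 1L) / 2)),
              seq(decay[2L], decay[1L],
                  length.out = floor((bs - 1L) / 2)))
    rep(list(ramp), cfg$n_blocks)
  } else {
    as.list(rep_len(if (length(decay) == 2L) mean(decay) else decay,
                    cfg$n_blocks))
  }
  G <- matrix(0, cfg$n, cfg$m)
  for (b in seq_len(cfg$n_blocks)) {
    idx <- ((b - 1L) * bs + 1L):(b * bs)
    L <- chol_of(rho_list[[b]])
    X <- matrix(stats::rnorm(cfg$n * bs), cfg$n, bs) %*% L
    if (cfg$dosage) {
      maf <- stats::runif(bs, 0.05, 0.5)
      # latent-Gaussian thresholding to 0/1/2 dosages under HWE
      q <- stats::qnorm(cbind((1 - maf)^2, 1 - maf^2))
      D <- matrix(0, cfg$n, bs)
      for (j in seq_len(bs)) {
        D[, j] <- findInterval(X[, j], q[j, ])
      }
      X <- D
    }
    G[, idx] <- X
  }
  colnames(G) <- paste0("snp", seq_len(cfg$m))
  G <- scale(G)
  attr(G, "scaled:center") <- NULL
  attr(G, "scaled:scale") <- NULL
  if (anyNA(G)) {
    stop("zero-variance genotype column produced (monomorphic draw); ",
         "increase n or MAF range", call. = FALSE)
  }
  list(G = G, block = rep(seq_len(cfg$n_blocks), each = bs))
}

#' Draw per-variant effect sizes
#'
#' A causal subset of size `round(causal_fraction * m)` is drawn uniformly;
#' causal effects are i.i.d. multivariate normal with the configured
#' variance scaling and correlation structure; non-causal effects are zero.
#'
#' @param cfg A `sim_config`.
#' @return List with `beta` (additive), `gamma` (interaction), `alpha`
#'   (E's additive effects; zero vector when E is non-heritable) and
#'   `causal` (causal indices).
#' @export
draw_effects <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  denom <- if (cfg$scale_by == "causal") cfg$m0 else cfg$m
  vars <- c(cfg$h2g, cfg$h2i, if (cfg$heritable_e) cfg$h2e) / denom
  C <- .effect_correlation(cfg)
  S <- C * tcrossprod(sqrt(vars))
  k <- nrow(S)
  causal <- sort(sample.int(cfg$m, cfg$m0))
  ev <- eigen(S, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  E <- matrix(stats::rnorm(cfg$m0 * k), cfg$m0, k) %*% rt
  beta <- gamma <- alpha <- numeric(cfg$m)
  beta[causal] <- E[, 1L]
  gamma[causal] <- E[, 2L]
  if (cfg$heritable_e) alpha[causal] <- E[, 3L]
  list(beta = beta, gamma = gamma, alpha = alpha, causal = causal)
}

#' Simulate the environment variable
#'
#' Non-heritable: standard normal.  Heritable: `E = G alpha + resid` with
#' residual variance `1 - h2e`, giving unit variance in expectation.
#'
#' @param G Standardized genotype matrix.
#' @param effects Output of [draw_effects()].
#' @param cfg A `sim_config`.
#' @return Numeric vector of length n.
#' @export
simulate_environment <- function(G, effects, cfg) {
  if (!cfg$heritable_e) return(stats::rnorm(nrow(G)))
  drop(G %*% effects$alpha) +
    stats::rnorm(nrow(G), sd = sqrt(max(1 - cfg$h2e, 0)))
}

#' Simulate the phenotype
#'
#' `Y = G beta + (G * E) gamma + eps1 * E + eps0`, with residual variances
#' chosen so that `var(Y)` is 1 in expectation:
#' `var(eps0) = 1 - h2g - h2i - sigma1sq`.
#'
#' @param G Standardized genotype matrix.
#' @param effects Output of [draw_effects()].
#' @param e Environment vector.
#' @param cfg A `sim_config`.
#' @return Numeric phenotype vector.
#' @export
simulate_phenotype <- function(G, effects, e, cfg) {
  n <- nrow(G)
  sigma0sq <- 1 - cfg$h2g - cfg$h2i - cfg$sigma1sq
  if (sigma0sq < 0) stop("negative residual variance", call. = FALSE)
  cs <- effects$causal
  g_add <- drop(G[, cs, drop = FALSE] %*% effects$beta[cs])
  g_int <- drop((G[, cs, drop = FALSE] * e) %*% effects$gamma[cs])
  if (cfg$sigma1sq > 0 || cfg$rho01 != 0) {
    Sr <- matrix(c(sigma0sq, cfg$rho01, cfg$rho01, cfg$sigma1sq), 2L, 2L)
    if (min(eigen(Sr, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("residual covariance (sigma0sq, rho01, sigma1sq) not PSD",
           call. = FALSE)
    }
    ev <- eigen(Sr, symmetric = TRUE)
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    Eps <- matrix(stats::rnorm(2L * n), n, 2L) %*% rt
    resid <- Eps[, 1L] + Eps[, 2L] * e
  } else {
    resid <- stats::rnorm(n, sd = sqrt(sigma0sq))
  }
  y <- g_add + g_int + resid
  if (cfg$standardize_y) y <- drop(scale(y))
  y
}

#' Vectorized per-SNP association scans
#'
#' Computes per-variant t-statistics by closed-form least squares (no
#' per-SNP iterative fitting):
#' \describe{
#'   \item{`gwas_y`}{`y ~ 1 + g`, Z of the genotype coefficient.}
#'   \item{`gwis`}{`y ~ 1 + g + e + g:e`, Z of the interaction coefficient
#'     (the in-process analogue of a PLINK2 interaction scan).}
#'   \item{`gwas_e`}{`e ~ 1 + g`, Z of the genotype coefficient.}
#' }
#' A variant whose design is collinear (e.g. monomorphic after
#' standardization) gets `NA` and is reported via the `flagged` attribute.
#'
#' @param G Standardized genotype matrix (n x m).
#' @param y Phenotype vector (unused for `gwas_e`).
#' @param e Environment vector (required for `gwis` and `gwas_e`).
#' @param mode Scan type.
#' @return Numeric Z vector of length m with attributes `n` (sample size)
#'   and `flagged` (indices of collinear variants, possibly empty).
#' @export
association_scan <- function(G, y = NULL, e = NULL,
                             mode = c("gwas_y", "gwis", "gwas_e")) {
  mode <- match.arg(mode)
  n <- nrow(G)
  if (mode == "gwas_e") { y <- e; mode2 <- "simple" }
  else if (mode == "gwas_y") { mode2 <- "simple" }
  else {
    if (is.null(e)) stop("gwis scan requires the environment vector e",
                         call. = FALSE)
    mode2 <- "gwis"
  }
  if (is.null(y)) stop("response vector missing", call. = FALSE)

  if (mode2 == "simple") {
    # y ~ 1 + g_j for every j: t from the correlation, df = n - 2
    yc <- y - mean(y)
    gc_ss <- colSums(G^2) - n * colMeans(G)^2
    # sum(yc) = 0, so crossprod(G, yc) is already the centered cross-product
    r <- drop(crossprod(G, yc)) / sqrt(gc_ss * sum(yc^2))
    r[!is.finite(r)] <- NA_real_
    z <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  } else {
    # y ~ 1 + g_j + e + g_j e, interaction coefficient, via
    # Frisch-Waugh: residualize y, g_j and s_j = g_j*e on span(1, e)
    q1 <- rep(1 / sqrt(n), n)
    ec <- e - mean(e)
    q2 <- ec / sqrt(sum(ec^2))
    # projections of every column of G and S = G*e on (q1, q2)
    g_q1 <- drop(crossprod(G, q1))
    g_q2 <- drop(crossprod(G, q2))
    s_q1 <- drop(crossprod(G, e * q1))
    s_q2 <- drop(crossprod(G, e * q2))
    y_q1 <- sum(y * q1); y_q2 <- sum(y * q2)
    G2 <- G^2
    gg <- colSums(G2)                    - g_q1^2 - g_q2^2
    gs <- drop(crossprod(G2, e))         - g_q1 * s_q1 - g_q2 * s_q2
    ss <- drop(crossprod(G2, e^2))       - s_q1^2 - s_q2^2
    gy <- drop(crossprod(G, y))          - g_q1 * y_q1 - g_q2 * y_q2
    sy <- drop(crossprod(G, e * y))      - s_q1 * y_q1 - s_q2 * y_q2
    yy <- sum(y^2) - y_q1^2 - y_q2^2
    det <- gg * ss - gs^2
    coef_s <- (gg * sy - gs * gy) / det
    coef_g <- (ss * gy - gs * sy) / det
    rss <- yy - coef_g * gy - coef_s * sy
    df <- n - 4L
    se <- sqrt(pmax(rss, 0) / df * gg / det)
    z <- coef_s / se
    z[!is.finite(z) | det <= 0] <- NA_real_
  }
  flagged <- which(is.na(z))
  structure(as.numeric(z), n = n, flagged = flagged)
}

.scan_to_sumstats <- function(z, ids, n) {
  keep <- !is.na(z)
  validate_sumstats(data.frame(
    snp = ids[keep], a1 = "A", a2 = "G", z = z[keep], n = n,
    stringsAsFactors = FALSE))
}

#' Simulate a complete study
#'
#' Generates genotypes, effects, environment and phenotype for one
#' scenario, runs the in-process association scans, and (optionally) builds
#' the in-sample eigen-decomposed LD reference from the same genotypes.
#'
#' @param cfg A `sim_config`.
#' @param genotypes Optional pre-simulated output of [simulate_genotypes()]
#'   to reuse across replications (the LD panel is then fixed).
#' @param eigenblocks Optional pre-computed eigen blocks matching
#'   `genotypes`.
#' @param ld Build the in-sample LD reference if not supplied
#'   (`eigenblocks`).
#' @param tol Eigenvalue truncation tolerance for the LD reference.
#' @return List of class `sim_output` with elements `G`, `block`, `e`, `y`,
#'   `effects`, `truth` (named true parameter vector), `sumstats`
#'   (named list `g`, `i`, and `e` when E is heritable), and `eigenblocks`.
#' @export
simulate_study <- function(cfg, genotypes = NULL, eigenblocks = NULL,
                           ld = TRUE, tol = 1e-6) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(genotypes)) genotypes <- simulate_genotypes(cfg)
  G <- genotypes$G
  block <- genotypes$block
  effects <- draw_effects(cfg)
  e <- simulate_environment(G, effects, cfg)
  y <- simulate_phenotype(G, effects, e, cfg)
  ids <- colnames(G)
  n <- nrow(G)
  z_g <- association_scan(G, y, e, "gwas_y")
  z_i <- association_scan(G, y, e, "gwis")
  ss <- list(g = .scan_to_sumstats(z_g, ids, n),
             i = .scan_to_sumstats(z_i, ids, n))
  if (cfg$heritable_e) {
    z_e <- association_scan(G, e = e, mode = "gwas_e")
    ss$e <- .scan_to_sumstats(z_e, ids, n)
  }
  if (is.null(eigenblocks) && ld) {
    eigenblocks <- lapply(unique(block), function(b) {
      idx <- which(block == b)
      eigendecompose_ld(compute_block_ld(G[, idx, drop = FALSE],
                                         ids[idx], block_id = b), tol = tol)
    })
  }
  rho_ig <- sqrt(cfg$h2g * cfg$h2i) * cfg$r_ig
  truth <- c(h2g = cfg$h2g, h2i = cfg$h2i, rho_ig = rho_ig,
             sigma1sq = cfg$sigma1sq,
             h2e = if (cfg$heritable_e) cfg$h2e else 0,
             rho_ge = if (cfg$heritable_e)
               sqrt(cfg$h2g * cfg$h2e) * cfg$r_ge else 0,
             rho_ie = if (cfg$heritable_e)
               sqrt(cfg$h2i * cfg$h2e) * cfg$r_ie else 0)
  structure(list(G = G, block = block, e = e, y = y, effects = effects,
                 truth = truth, sumstats = ss, eigenblocks = eigenblocks,
                 cfg = cfg),
            class = "sim_output")
}
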