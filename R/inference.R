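# Delete-block jackknife covariance, Wald tests, the joint Mahalanobis
# test of (h2i, rho_ig), and the PRS-by-E coefficient ratio.

# Remove whole LD blocks from a moment table, keeping the per-variant
# attributes (used by the diagonal-LD baseline) in sync.  M and the sample
# sizes are deliberately left at their full-data values: the moment-slope
# estimands do not depend on which eigencomponents enter the regression.
.drop_blocks <- function(moments, drop_ids) {
  keep <- !(moments$block_id %in% drop_ids)
  out <- moments[keep, , drop = FALSE]
  z <- attr(moments, "z")
  if (!is.null(z)) {
    zkeep <- !(z$block_id %in% drop_ids)
    attr(out, "z") <- z[zkeep, , drop = FALSE]
    attr(out, "ld_scores") <- attr(moments, "ld_scores")[zkeep]
  }
  attr(out, "M") <- attr(moments, "M")
  attr(out, "n") <- attr(moments, "n")
  class(out) <- class(moments)
  out
}

#' Delete-block jackknife for a moment-table estimator
#'
#' Assigns the LD blocks (in genome order) to `n_groups` contiguous
#' jackknife groups, re-runs the full estimation chain with each group
#' deleted, and returns the delete-group jackknife covariance and standard
#' errors.
#'
#' @param moments A `moment_table`.
#' @param fit_fun Function taking a moment table and returning a named
#'   numeric vector of parameter estimates (e.g. built from
#'   [fit_gxe_eigen()]).
#' @param n_groups Number of jackknife groups; defaults to
#'   `min(200, number of blocks)`.
#' @return An object of class `jackknife_result`: list with `point` (full
#'   fit), `loo` (matrix of leave-group-out estimates), `pseudo_values`,
#'   `cov` (full parameter covariance), `se`, `sigma_hat` (2 x 2 covariance
#'   of `(h2i, rho_ig)` when both are estimated) and `n_groups` (usable
#'   groups).
#' @export
jackknife <- function(moments, fit_fun, n_groups = NULL) {
  blocks <- unique(moments$block_id)
  B <- length(blocks)
  if (is.null(n_groups)) n_groups <- min(200L, B)
  if (n_groups > B) {
    stop("n_groups (", n_groups, ") exceeds the number of blocks (", B, ")",
         call. = FALSE)
  }
  if (n_groups < 2L) stop("need at least 2 jackknife groups", call. = FALSE)
  grp <- split(blocks, ceiling(seq_along(blocks) / (B / n_groups)))
  point <- fit_fun(moments)
  loo <- matrix(NA_real_, length(grp), length(point),
                dimnames = list(NULL, names(point)))
  ok <- rep(TRUE, length(grp))
  for (g in seq_along(grp)) {
    est <- tryCatch(fit_fun(.drop_blocks(moments, grp[[g]])),
                    error = function(e) {
                      warning("jackknife group ", g, " excluded: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(est)) ok[g] <- FALSE else loo[g, ] <- est
  }
  loo <- loo[ok, , drop = FALSE]
  G <- nrow(loo)
  if (G < 2L) stop("fewer than 2 usable jackknife groups", call. = FALSE)
  ctr <- sweep(loo, 2L, colMeans(loo))
  covm <- crossprod(ctr) * (G - 1) / G
  pseudo <- sweep(-(G - 1) * loo, 2L, G * point, "+")
  sigma_hat <- if (all(c("h2i", "rho_ig") %in% names(point))) {
    covm[c("h2i", "rho_ig"), c("h2i", "rho_ig")]
  } else NULL
  structure(list(point = point, loo = loo, pseudo_values = pseudo,
                 cov = covm, se = sqrt(pmax(diag(covm), 0)),
                 sigma_hat = sigma_hat, n_groups = G),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat("Delete-block jackknife over", x$n_groups, "groups\n")
  out <- rbind(estimate = x$point, se = x$se)
  print(round(out, 6))
  invisible(x)
}

#' Two-sided (or one-sided) Wald test
#'
#' Tests a single parameter against zero using its jackknife standard
#' error.  With a finite number of jackknife groups the reference
#' distribution is Student's t with `n_groups - 1` degrees of freedom
#' (supply `df`); with `df = NULL` the asymptotic normal reference is used.
#'
#' @param estimate Point estimate.
#' @param se Standard error (`> 0`).
#' @param df Degrees of freedom for the t reference, or `NULL` for normal.
#' @param alternative `"two.sided"` (default; moment estimates of variance
#'   components can be negative), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
wald_test <- function(estimate, se, df = NULL,
                      alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  z <- estimate / se
  lower <- if (is.null(df)) stats::pnorm(z) else stats::pt(z, df)
  switch(alternative,
         two.sided = 2 * min(lower, 1 - lower),
         greater = 1 - lower,
         less = lower)
}

#' Joint Mahalanobis test of the interaction proportion and the G-by-E
#' genetic covariance
#'
#' Computes the squared Mahalanobis distance `d2 = v' solve(Sigma) v` of the
#' bivariate estimate `v = (h2i, rho_ig)` from the origin, using the
#' jackknife covariance `Sigma`, and converts it to a p-value.  With a
#' finite number of jackknife groups `G` the Hotelling-type reference
#' `d2 * (G - 2) / (2 (G - 1)) ~ F(2, G - 2)` is used; it converges to the
#' asymptotic chi-square(2) reference as `G` grows.
#'
#' @param v Numeric vector of length 2, `(h2i, rho_ig)`.
#' @param sigma 2 x 2 covariance matrix of `v`.
#' @param n_groups Number of jackknife groups behind `sigma` (enables the
#'   finite-sample reference); `NULL` for the chi-square(2) reference.
#' @param method `"finite"` or `"asymptotic"`; default `"finite"` when
#'   `n_groups` is supplied.
#' @return List of class `joint_test` with `d2`, `df = 2`, `p`, `method`.
#' @export
joint_test <- function(v, sigma, n_groups = NULL,
                       method = c("auto", "finite", "asymptotic")) {
  method <- match.arg(method)
  v <- as.numeric(v)
  sigma <- as.matrix(sigma)
  stopifnot(length(v) == 2L, all(dim(sigma) == 2L))
  sigma <- (sigma + t(sigma)) / 2
  if (rcond(sigma) < 1e-12) {
    stop("jackknife covariance is (near-)singular; ",
         "use more jackknife groups", call. = FALSE)
  }
  d2 <- drop(crossprod(v, solve(sigma, v)))
  d2 <- max(d2, 0)
  if (method == "auto") {
    method <- if (is.null(n_groups)) "asymptotic" else "finite"
  }
  if (method == "finite") {
    if (is.null(n_groups) || n_groups < 4L) {
      stop("finite-sample reference requires n_groups >= 4", call. = FALSE)
    }
    p <- stats::pf(d2 * (n_groups - 2) / (2 * (n_groups - 1)),
                   2, n_groups - 2, lower.tail = FALSE)
  } else {
    p <- stats::pchisq(d2, df = 2, lower.tail = FALSE)
  }
  structure(list(d2 = d2, df = 2L, p = p, method = method,
                 n_groups = n_groups),
            class = "joint_test")
}

#' @export
print.joint_test <- function(x, ...) {
  cat(sprintf("Joint Mahalanobis test: d2 = %.4f, p = %.4g (%s reference)\n",
              x$d2, x$p, x$method))
  invisible(x)
}

#' Expected PRS-by-E regression coefficient
#'
#' Under a perfectly fitted polygenic risk score, the coefficient of the
#' PRS-by-environment interaction term in the regression
#' `Y ~ PRS + E + PRS:E` equals the ratio of the G-by-E genetic covariance
#' to the narrow-sense heritability.
#'
#' @param rho_ig G-by-E genetic covariance.
#' @param h2g Narrow-sense heritability (`> 0`).
#' @return `rho_ig / h2g`.
#' @export
prs_by_e_ratio <- function(rho_ig, h2g) {
  if (!is.finite(h2g) || h2g <= 0) {
    stop("h2g must be positive for the PRS-by-E ratio", call. = FALSE)
  }
  rho_ig / h2g
}

#' Monte-Carlo null calibration of the Wald and Mahalanobis statistics
#'
#' With few LD blocks the jackknife-based test statistics are not well
#' approximated by their asymptotic references: the interaction-proportion
#' slope is a contrast of chi-square-distributed products and its
#' t-statistic is markedly left-skewed when only a handful of jackknife
#' groups is available.  Under the null hypothesis
#' `(h2i, rho_ig) = (0, 0)` the whitened GWIS components are i.i.d.
#' Gaussian with a constant variance that cancels from every test
#' statistic, so the exact finite-sample null distribution of the three
#' statistics depends only on the eigenvalue design, the block structure
#' and the (nuisance) GWAS signal profile.  This function simulates that
#' null distribution once per design; the resulting reference is exact up
#' to Monte-Carlo error and converges to the asymptotic t / chi-square
#' references as the block count grows.
#'
#' @param moments A `moment_table` (only its design -- eigenvalues, block
#'   labels, sample sizes, `M` -- is used).
#' @param h2g Plug-in GWAS signal used to shape the whitened GWAS variance
#'   profile; defaults to the value estimated from `moments`.  The null
#'   distributions are insensitive to it.
#' @param B Number of null draws.
#' @param n_groups Jackknife groups, as in [gxe_test()].
#' @return An object of class `gxe_null_cal`: list with sorted null draws
#'   of `t_h2i`, `t_rho` and `d2`, plus `B`.
#' @export
null_calibration <- function(moments, h2g = NULL, B = 800L,
                             n_groups = NULL) {
  d <- moments$d
  bid <- moments$block_id
  M <- attr(moments, "M")
  nvec <- attr(moments, "n")
  N_g <- nvec[["g"]]; N_i <- nvec[["i"]]
  if (is.null(h2g)) h2g <- estimate_h2g(moments)$h2g
  sd_g <- sqrt(.f_gg(d, h2g, N_g, M))
  t_h <- t_r <- d2 <- numeric(B)
  fitfun <- .fit_vector_fun("eigen")
  for (b in seq_len(B)) {
    zg <- stats::rnorm(length(d), sd = sd_g)
    zi <- stats::rnorm(length(d))
    mt <- data.frame(block_id = bid, d = d,
                     y_gg = zg^2, y_ii = zi^2, y_gi = zg * zi)
    attr(mt, "M") <- M
    attr(mt, "n") <- c(g = N_g, i = N_i)
    class(mt) <- c("moment_table", class(mt))
    jk <- jackknife(mt, fitfun, n_groups)
    t_h[b] <- jk$point[["h2i"]] / jk$se[["h2i"]]
    t_r[b] <- jk$point[["rho_ig"]] / jk$se[["rho_ig"]]
    v <- jk$point[c("h2i", "rho_ig")]
    d2[b] <- drop(crossprod(v, solve(jk$sigma_hat, v)))
  }
  structure(list(t_h2i = sort(t_h), t_rho = sort(t_r), d2 = sort(d2),
                 B = B, h2g = h2g),
            class = "gxe_null_cal")
}

.mc_pvalue <- function(stat, null_draws, two_sided = TRUE) {
  if (two_sided) {
    (1 + sum(abs(null_draws) >= abs(stat))) / (length(null_draws) + 1)
  } else {
    (1 + sum(null_draws >= stat)) / (length(null_draws) + 1)
  }
}

# Named-vector wrapper around fit_gxe_eigen / fit_gxe_ldsc for jackknifing.
.fit_vector_fun <- function(estimator = c("eigen", "ldsc"), ...) {
  estimator <- match.arg(estimator)
  fitter <- if (estimator == "eigen") fit_gxe_eigen else fit_gxe_ldsc
  function(mt) {
    f <- fitter(mt, ...)
    c(h2g = f$h2g, h2i = f$h2i, sigma1sq = f$sigma1sq, rho_ig = f$rho_ig)
  }
}

#' Estimates, jackknife and all three tests in one call
#'
#' Convenience wrapper running the full estimation chain
#' ([fit_gxe_eigen()] or [fit_gxe_ldsc()]), the delete-block jackknife, the
#' two univariate Wald tests of `h2i` and `rho_ig`, and the joint
#' Mahalanobis test.
#'
#' @param moments A `moment_table`.
#' @param estimator `"eigen"` (full LD) or `"ldsc"` (diagonal baseline).
#' @param n_groups Jackknife groups (default `min(200, blocks)`).
#' @param df_method `"finite"` (t / Hotelling-F references matched to the
#'   jackknife group count) or `"asymptotic"` (normal / chi-square).
#' @param alternative Sidedness of the univariate Wald tests.
#' @param null_cal Optional [null_calibration()] object for the same LD
#'   design: p-values are then read off the simulated exact null
#'   distributions instead of the t / F references.  Recommended whenever
#'   the analysis rests on fewer than a few dozen LD blocks.
#' @param ... Passed to the estimation chain.
#' @return List of class `gxe_result` with `fit`, `jackknife`, `se`,
#'   `sigma_hat`, `tests` (named p-values `h2i`, `rho_ig`, `joint`) and
#'   `d2`.
#' @export
gxe_test <- function(moments, estimator = c("eigen", "ldsc"),
                     n_groups = NULL,
                     df_method = c("finite", "asymptotic"),
                     alternative = "two.sided", null_cal = NULL, ...) {
  estimator <- match.arg(estimator)
  df_method <- match.arg(df_method)
  fit <- if (estimator == "eigen") fit_gxe_eigen(moments, ...)
         else fit_gxe_ldsc(moments, ...)
  jk <- jackknife(moments, .fit_vector_fun(estimator, ...), n_groups)
  G <- jk$n_groups
  jt <- joint_test(jk$point[c("h2i", "rho_ig")], jk$sigma_hat,
                   n_groups = G,
                   method = if (df_method == "finite") "finite"
                            else "asymptotic")
  if (!is.null(null_cal)) {
    stopifnot(inherits(null_cal, "gxe_null_cal"))
    if (alternative != "two.sided") {
      stop("Monte-Carlo calibration implements the two-sided tests",
           call. = FALSE)
    }
    p_h2i <- .mc_pvalue(jk$point[["h2i"]] / jk$se[["h2i"]],
                        null_cal$t_h2i)
    p_rho <- .mc_pvalue(jk$point[["rho_ig"]] / jk$se[["rho_ig"]],
                        null_cal$t_rho)
    p_joint <- .mc_pvalue(jt$d2, null_cal$d2, two_sided = FALSE)
  } else {
    df <- if (df_method == "finite") G - 1 else NULL
    p_h2i <- wald_test(jk$point[["h2i"]], jk$se[["h2i"]], df = df,
                       alternative = alternative)
    p_rho <- wald_test(jk$point[["rho_ig"]], jk$se[["rho_ig"]], df = df,
                       alternative = alternative)
    p_joint <- jt$p
  }
  structure(list(fit = fit, jackknife = jk, se = jk$se,
                 sigma_hat = jk$sigma_hat,
                 tests = c(h2i = p_h2i, rho_ig = p_rho, joint = p_joint),
                 d2 = jt$d2, estimator = estimator,
                 df_method = df_method,
                 calibrated = !is.null(null_cal)),
            class = "gxe_result")
}

#' @export
print.gxe_result <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  SE(h2i) = %.5f, SE(rho_ig) = %.5f  [%d jackknife groups]\n",
              x$se[["h2i"]], x$se[["rho_ig"]], x$jackknife$n_groups))
  cat(sprintf("  p(h2i) = %.4g, p(rho_ig) = %.4g, p(joint) = %.4g\n",
              x$tests[["h2i"]], x$tests[["rho_ig"]], x$tests[["joint"]]))
  invisible(x)
}
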