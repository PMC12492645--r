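# Moment-condition estimators on whitened Z-score products.
#
# For a block with LD eigen-decomposition R = U D U' and whitened scores
# Zt = D^(-1/2) U' Z, the retained eigencomponents satisfy (per component j
# with eigenvalue d_j, M variants genome-wide):
#
#   E[Zt_G,j^2]       = d_j N_G h2g / M + 1
#   E[Zt_I,j^2]       = d_j N_I h2i / M + 1 + 2 (h2i + sigma1sq)
#   E[Zt_G,j Zt_I,j]  = d_j sqrt(N_G N_I) rho_ig / M
#                       + 2 N_S (rho_ig + rho01) / sqrt(N_G N_I)
#
# so each parameter is the slope of a weighted regression of a per-component
# product on the eigenvalue d_j; the intercept absorbs sample overlap.

#' Build the per-eigencomponent moment table
#'
#' Whitens each scan's Z vector within every LD block and records, per
#' retained eigencomponent, the eigenvalue and the products of whitened
#' Z-scores that the moment conditions regress on it.
#'
#' @param pair A `harmonized_pair` from [harmonize_sumstats()] containing
#'   scans `g` and `i` (and optionally `e`).  Variant order must follow the
#'   LD reference.
#' @param eigenblocks List of `eigen_block` objects covering exactly the
#'   harmonized variants.
#' @return A data frame of class `moment_table` with columns `block_id`,
#'   `d`, `y_gg`, `y_ii`, `y_gi` and, when an `e` scan is present, `y_ee`,
#'   `y_ei`, `y_ge`.  Attributes: `M` (variant count), `n` (per-scan sample
#'   sizes), `ld_scores` and `z` (per-variant quantities for the
#'   diagonal-LD baseline, in block order).
#' @export
build_moment_table <- function(pair, eigenblocks) {
  stopifnot(inherits(pair, "harmonized_pair"))
  scans <- colnames(pair$z)
  if (!all(c("g", "i") %in% scans)) {
    stop("harmonized pair must contain scans named 'g' and 'i'",
         call. = FALSE)
  }
  has_e <- "e" %in% scans
  idx_of <- match(unlist(lapply(eigenblocks, `[[`, "variant_ids")),
                  pair$snp)
  rows <- vector("list", length(eigenblocks))
  ell_all <- vector("list", length(eigenblocks))
  z_rows <- vector("list", length(eigenblocks))
  pos <- 0L
  for (k in seq_along(eigenblocks)) {
    eb <- eigenblocks[[k]]
    idx <- idx_of[pos + seq_len(eb$original_dim)]
    pos <- pos + eb$original_dim
    if (anyNA(idx)) {
      stop("block ", eb$block_id,
           " contains variants absent from the harmonized scans; ",
           "harmonize against this LD reference first", call. = FALSE)
    }
    zg <- transform_z(eb, pair$z[idx, "g"])
    zi <- transform_z(eb, pair$z[idx, "i"])
    df <- data.frame(block_id = eb$block_id, d = eb$values,
                     y_gg = zg^2, y_ii = zi^2, y_gi = zg * zi)
    zb <- data.frame(block_id = eb$block_id,
                     z_g = pair$z[idx, "g"], z_i = pair$z[idx, "i"])
    if (has_e) {
      ze <- transform_z(eb, pair$z[idx, "e"])
      df$y_ee <- ze^2
      df$y_ei <- ze * zi
      df$y_ge <- zg * ze
      zb$z_e <- pair$z[idx, "e"]
    }
    rows[[k]] <- df
    ell_all[[k]] <- ld_scores(eb)
    z_rows[[k]] <- zb
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "M") <- length(pair$snp)
  attr(out, "n") <- pair$n
  attr(out, "ld_scores") <- unlist(ell_all)
  attr(out, "z") <- do.call(rbind, z_rows)
  class(out) <- c("moment_table", class(out))
  out
}

#' Weighted least-squares fit of a moment condition
#'
#' Fits `y ~ intercept + slope * x` by weighted least squares.
#'
#' @param x Regressor (eigenvalues or LD scores).
#' @param y Regressand (products of (whitened) Z-scores).
#' @param w Positive weights.
#' @return Named vector `c(slope, intercept)`.
#' @export
weighted_moment_regression <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x))
  if (any(w <= 0) || !all(is.finite(w))) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  sw <- sum(w)
  xb <- sum(w * x) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= .Machine$double.eps * sw * max(1, xb^2)) {
    stop("degenerate design: regressor has no variation", call. = FALSE)
  }
  yb <- sum(w * y) / sw
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  c(slope = slope, intercept = yb - slope * xb)
}

# Marginal mean factors of the moment conditions (used in weights).
.f_gg <- function(d, h2g, N, M) d * N * pmax(h2g, 0) / M + 1
.f_ii <- function(d, h2i, sigma1sq, N, M) {
  h <- pmax(h2i, 0); s <- pmax(sigma1sq, 0)
  d * N * h / M + 1 + 2 * (h + s)
}

# Iterated single-scan chi-square regression shared by h2g / h2e / h2i.
# shrink: "eigen" uses min(x,1); "ldsc" uses 1/max(x,1).
.h2_regression <- function(x, y, N, M, kind = c("gg", "ii"),
                           shrink = c("eigen", "ldsc"), n_iter = 3L) {
  kind <- match.arg(kind)
  shrink <- match.arg(shrink)
  base_w <- if (shrink == "eigen") pmin(x, 1) else 1 / pmax(x, 1)
  h2 <- 0; s1 <- 0
  fit <- NULL
  for (it in seq_len(n_iter)) {
    f <- if (kind == "gg") .f_gg(x, h2, N, M) else .f_ii(x, h2, s1, N, M)
    fit <- weighted_moment_regression(x, y, base_w / f^2)
    h2 <- unname(fit["slope"]) * M / N
    if (kind == "ii") s1 <- (unname(fit["intercept"]) - 1) / 2 - h2
  }
  list(h2 = h2, sigma1sq = if (kind == "ii") s1 else NULL,
       intercept = unname(fit["intercept"]))
}

#' Estimate the narrow-sense heritability
#'
#' Regresses squared whitened GWAS Z-scores on the eigenvalues:
#' `h2g = slope * M / N_g`.  The weights are refreshed from the current
#' estimate over a few iterations; the intercept is expected to be close to
#' 1 in the absence of confounding.
#'
#' @param moments A `moment_table`.
#' @param N_g GWAS sample size (defaults to the value stored in `moments`).
#' @param M Variant count (defaults likewise).
#' @param n_iter Weight-refresh iterations.
#' @return List with `h2g` and `intercept`.
#' @export
estimate_h2g <- function(moments, N_g = attr(moments, "n")[["g"]],
                         M = attr(moments, "M"), n_iter = 3L) {
  r <- .h2_regression(moments$d, moments$y_gg, N_g, M, "gg", "eigen", n_iter)
  list(h2g = r$h2, intercept = r$intercept)
}

#' Estimate the G-by-E interaction proportion and residual interaction
#' variance
#'
#' Regresses squared whitened GWIS Z-scores on the eigenvalues:
#' `h2i = slope * M / N_i`; the residual-interaction variance is recovered
#' from the intercept, `intercept = 1 + 2 (h2i + sigma1sq)`.  Raw (possibly
#' negative) moment estimates are returned; clipping at zero happens only
#' inside weight construction.
#'
#' @param moments A `moment_table`.
#' @param N_i GWIS sample size.
#' @param M Variant count.
#' @param n_iter Weight-refresh iterations.
#' @return List with `h2i`, `sigma1sq` and `intercept`.
#' @export
estimate_h2i <- function(moments, N_i = attr(moments, "n")[["i"]],
                         M = attr(moments, "M"), n_iter = 3L) {
  r <- .h2_regression(moments$d, moments$y_ii, N_i, M, "ii", "eigen", n_iter)
  list(h2i = r$h2, sigma1sq = r$sigma1sq, intercept = r$intercept)
}

#' Optimal regression weights for the cross-scan moment condition
#'
#' `w_j = min(d_j, 1) / T_jj`, where `T_jj` is proportional to the variance
#' of the whitened GWAS-GWIS Z-score product:
#' `T_jj = (d N_g h2g / M + 1)(d N_i h2i / M + 1 + 2 (h2i + sigma1sq))
#'         + (sqrt(N_g N_i) rho_ig d / M + c_gi)^2`,
#' with the currently fitted cross-regression intercept `c_gi` standing in
#' for the sample-overlap term (sample overlap and residual covariance need
#' not be known separately).  Variance plug-ins are clipped at zero; the
#' `min(d, 1)` factor shrinks high-eigenvalue components, balancing their
#' information against noise.
#'
#' @param d Eigenvalues.
#' @param h2g,h2i,sigma1sq,rho_ig Plug-in parameter values.
#' @param gi_intercept Current fitted intercept of the cross regression.
#' @param N_g,N_i Sample sizes.
#' @param M Variant count.
#' @return Positive weights, one per component.
#' @export
compute_weights <- function(d, h2g, h2i, sigma1sq, rho_ig, gi_intercept,
                            N_g, N_i, M) {
  stopifnot(M > 0, N_g > 0, N_i > 0)
  mu <- sqrt(N_g * N_i) * rho_ig * d / M + gi_intercept
  T_jj <- .f_gg(d, h2g, N_g, M) * .f_ii(d, h2i, sigma1sq, N_i, M) + mu^2
  if (any(T_jj <= 0)) {
    stop("nonpositive variance factor T_jj; invalid plug-in parameters",
         call. = FALSE)
  }
  pmin(d, 1) / T_jj
}

#' Estimate the G-by-E genetic covariance by iteratively reweighted least
#' squares
#'
#' Regresses the product of whitened GWAS and GWIS Z-scores on the
#' eigenvalues: `rho_ig = slope * M / sqrt(N_g N_i)`.  The weights depend on
#' `rho_ig` and the intercept themselves, so the fit alternates between
#' weight construction ([compute_weights()], initialized at zero) and
#' weighted least squares until the relative change falls below `rtol`.
#' The intercept absorbs the sample-overlap term, so overlapping (even
#' identical) GWAS and GWIS cohorts do not bias the slope.
#'
#' @param moments A `moment_table`.
#' @param h2g,h2i,sigma1sq Plug-in estimates (held fixed during the
#'   iteration).
#' @param N_g,N_i Sample sizes.
#' @param M Variant count.
#' @param max_iter Maximum IRLS iterations.
#' @param rtol Relative-change convergence tolerance.
#' @return List with `rho_ig`, `intercept`, `iterations`, `converged` and
#'   the per-iteration `trace`.
#' @export
estimate_rho_ig_irls <- function(moments, h2g, h2i, sigma1sq,
                                 N_g = attr(moments, "n")[["g"]],
                                 N_i = attr(moments, "n")[["i"]],
                                 M = attr(moments, "M"),
                                 max_iter = 10L, rtol = 1e-6) {
  d <- moments$d
  y <- moments$y_gi
  rho <- 0; icpt <- 0
  trace <- matrix(NA_real_, max_iter, 2L,
                  dimnames = list(NULL, c("rho_ig", "intercept")))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    w <- compute_weights(d, h2g, h2i, sigma1sq, rho, icpt, N_g, N_i, M)
    fit <- weighted_moment_regression(d, y, w)
    rho_new <- unname(fit["slope"]) * M / sqrt(N_g * N_i)
    icpt_new <- unname(fit["intercept"])
    trace[it, ] <- c(rho_new, icpt_new)
    delta <- max(abs(rho_new - rho), abs(icpt_new - icpt))
    scale <- max(abs(rho_new), abs(icpt_new), 1e-8)
    rho <- rho_new; icpt <- icpt_new
    if (delta <= rtol * scale) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("IRLS for rho_ig did not converge in ", max_iter, " iterations")
  }
  list(rho_ig = rho, intercept = icpt, iterations = it,
       converged = converged, trace = trace[seq_len(it), , drop = FALSE])
}

#' Full eigen-LD estimation chain
#'
#' Estimates, in order: the narrow-sense heritability `h2g`, the interaction
#' proportion `h2i` with the residual-interaction variance `sigma1sq`, and
#' the G-by-E genetic covariance `rho_ig` (IRLS with the former as fixed
#' plug-ins).  The G-by-E genetic correlation `r_ig` is derived as
#' `rho_ig / sqrt(h2g * h2i)` when both variance components are positive.
#'
#' @param moments A `moment_table`.
#' @param N_g,N_i,M Sample sizes and variant count.
#' @param max_iter,rtol IRLS controls, see [estimate_rho_ig_irls()].
#' @return List of class `gxe_fit` with the point estimates, intercepts,
#'   convergence metadata, `M`, `N_g`, `N_i`.
#' @export
fit_gxe_eigen <- function(moments, N_g = attr(moments, "n")[["g"]],
                          N_i = attr(moments, "n")[["i"]],
                          M = attr(moments, "M"),
                          max_iter = 10L, rtol = 1e-6) {
  fg <- estimate_h2g(moments, N_g, M)
  fi <- estimate_h2i(moments, N_i, M)
  fr <- estimate_rho_ig_irls(moments, fg$h2g, fi$h2i, fi$sigma1sq,
                             N_g, N_i, M, max_iter, rtol)
  r_ig <- if (fg$h2g > 0 && fi$h2i > 0) {
    fr$rho_ig / sqrt(fg$h2g * fi$h2i)
  } else NA_real_
  structure(list(h2g = fg$h2g, h2i = fi$h2i, sigma1sq = fi$sigma1sq,
                 rho_ig = fr$rho_ig, r_ig = r_ig,
                 intercepts = c(gg = fg$intercept, ii = fi$intercept,
                                gi = fr$intercept),
                 converged = fr$converged, iterations = fr$iterations,
                 M = M, N_g = N_g, N_i = N_i, estimator = "eigen"),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("G x E moment fit (%s LD)\n", x$estimator))
  cat(sprintf("  h2g     = %8.5f\n", x$h2g))
  cat(sprintf("  h2i     = %8.5f\n", x$h2i))
  cat(sprintf("  rho_ig  = %8.5f\n", x$rho_ig))
  if (!is.na(x$r_ig)) cat(sprintf("  r_ig    = %8.5f\n", x$r_ig))
  cat(sprintf("  sigma1^2= %8.5f\n", x$sigma1sq))
  cat(sprintf("  M = %d, N_g = %g, N_i = %g\n", x$M, x$N_g, x$N_i))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Diagonal-LD (LD score regression style) baseline

#' Diagonal-LD baseline estimate of the G-by-E genetic covariance
#'
#' The comparator estimator that uses only the diagonal of the squared LD
#' matrix: per-variant products `Z_G Z_I` are regressed on the LD scores
#' `l_j = (R'R)_jj`, with `rho_ig = slope * M / sqrt(N_g N_i)` and a free
#' intercept absorbing sample overlap.  Weights follow the LD score
#' regression convention (`1/max(l, 1)` shrink times the inverse variance
#' factor) and are refreshed by the same IRLS scheme as the eigen-LD
#' estimator.
#'
#' @param z_g,z_i Per-variant Z-scores, aligned.
#' @param ld_scores Per-variant LD scores (diagonal of the squared LD
#'   matrix); must vary across variants.
#' @param N_g,N_i Sample sizes.
#' @param M Variant count.
#' @param h2g,h2i,sigma1sq Optional plug-ins; estimated by the same
#'   LD-score machinery when `NULL`.
#' @param max_iter,rtol IRLS controls.
#' @return List with `rho_ig`, `intercept`, `converged`, `iterations`.
#' @export
baseline_ldsc_rho_ig <- function(z_g, z_i, ld_scores, N_g, N_i, M,
                                 h2g = NULL, h2i = NULL, sigma1sq = NULL,
                                 max_iter = 10L, rtol = 1e-6) {
  stopifnot(length(z_g) == length(z_i),
            length(ld_scores) == length(z_g))
  ell <- ld_scores
  if (max(ell) - min(ell) <= 1e-12 * max(1, max(abs(ell)))) {
    stop("degenerate design: LD scores are constant ",
         "(identity-LD input has no slope information)", call. = FALSE)
  }
  if (is.null(h2g)) {
    h2g <- .h2_regression(ell, z_g^2, N_g, M, "gg", "ldsc")$h2
  }
  if (is.null(h2i) || is.null(sigma1sq)) {
    fi <- .h2_regression(ell, z_i^2, N_i, M, "ii", "ldsc")
    h2i <- fi$h2; sigma1sq <- fi$sigma1sq
  }
  y <- z_g * z_i
  rho <- 0; icpt <- 0
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- sqrt(N_g * N_i) * rho * ell / M + icpt
    T_j <- .f_gg(ell, h2g, N_g, M) * .f_ii(ell, h2i, sigma1sq, N_i, M) + mu^2
    w <- (1 / pmax(ell, 1)) / T_j
    fit <- weighted_moment_regression(ell, y, w)
    rho_new <- unname(fit["slope"]) * M / sqrt(N_g * N_i)
    icpt_new <- unname(fit["intercept"])
    delta <- max(abs(rho_new - rho), abs(icpt_new - icpt))
    scale <- max(abs(rho_new), abs(icpt_new), 1e-8)
    rho <- rho_new; icpt <- icpt_new
    if (delta <= rtol * scale) { converged <- TRUE; break }
  }
  list(rho_ig = rho, intercept = icpt, h2g = h2g, h2i = h2i,
       sigma1sq = sigma1sq, converged = converged, iterations = it)
}

#' Full diagonal-LD baseline chain
#'
#' Mirrors [fit_gxe_eigen()] with LD-score regressions throughout, using the
#' per-variant Z-scores and LD scores stored on the moment table.
#'
#' @param moments A `moment_table`.
#' @param N_g,N_i,M Sample sizes and variant count.
#' @param max_iter,rtol IRLS controls.
#' @return List of class `gxe_fit` (with `estimator = "ldsc"`).
#' @export
fit_gxe_ldsc <- function(moments, N_g = attr(moments, "n")[["g"]],
                         N_i = attr(moments, "n")[["i"]],
                         M = attr(moments, "M"),
                         max_iter = 10L, rtol = 1e-6) {
  z <- attr(moments, "z")
  ell <- attr(moments, "ld_scores")
  if (is.null(z) || is.null(ell)) {
    stop("moment table lacks per-variant Z/LD-score attributes",
         call. = FALSE)
  }
  fg <- .h2_regression(ell, z$z_g^2, N_g, M, "gg", "ldsc")
  fi <- .h2_regression(ell, z$z_i^2, N_i, M, "ii", "ldsc")
  fr <- baseline_ldsc_rho_ig(z$z_g, z$z_i, ell, N_g, N_i, M,
                             h2g = fg$h2, h2i = fi$h2,
                             sigma1sq = fi$sigma1sq,
                             max_iter = max_iter, rtol = rtol)
  r_ig <- if (fg$h2 > 0 && fi$h2 > 0) fr$rho_ig / sqrt(fg$h2 * fi$h2)
          else NA_real_
  structure(list(h2g = fg$h2, h2i = fi$h2, sigma1sq = fi$sigma1sq,
                 rho_ig = fr$rho_ig, r_ig = r_ig,
                 intercepts = c(gg = fg$intercept, ii = fi$intercept,
                                gi = fr$intercept),
                 converged = fr$converged, iterations = fr$iterations,
                 M = M, N_g = N_g, N_i = N_i, estimator = "ldsc"),
            class = "gxe_fit")
}
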