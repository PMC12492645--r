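# Replicated simulation experiments: type-I error, power, estimator
# efficiency, and the PRS-by-E equivalence check.

#' Run a replicated simulation experiment over a scenario grid
#'
#' For each row of `grid` (columns are [sim_config()] arguments; unnamed
#' arguments take their defaults), simulates `reps` replicated studies,
#' estimates the G-by-E parameters with the requested estimator(s) on
#' identical data (paired design), and optionally runs the jackknife-based
#' tests.  Within a scenario the genotype panel -- and hence the in-sample
#' LD reference -- is drawn once and reused across replications
#' (`reuse_genotypes = TRUE`), mirroring an association study design where
#' the genotype panel is fixed while effects and noise vary; effects,
#' environment and residuals are redrawn every replication.
#'
#' All randomness derives from `seed`: each scenario receives a child seed,
#' and each replication a seed derived from the scenario seed and the
#' replication index, so runs are reproducible and individual replications
#' can be re-examined in isolation.
#'
#' @param grid Data frame of scenario parameters (one scenario per row).
#' @param reps Replications per scenario.
#' @param estimators Character subset of `c("eigen", "ldsc")`.
#' @param tests Run delete-block jackknife and report p-values
#'   (h2i, rho_ig and joint Mahalanobis).
#' @param corrected Run the heritable-environment correction chain instead
#'   of the plain chain (scenarios must set `heritable_e = TRUE`).
#' @param n_groups Jackknife groups (only with `tests = TRUE`).
#' @param df_method Reference distributions for the tests, see
#'   [gxe_test()].
#' @param calibrate_B If positive, build a [null_calibration()] reference
#'   once per scenario (the genotype panel, and hence the LD design, is
#'   shared within a scenario) with this many null draws, and use it for
#'   the eigen-estimator test p-values.
#' @param seed Master seed.
#' @param max_failures Maximum tolerated fraction of failed replications
#'   per scenario before the experiment errors.
#' @param verbose Print per-scenario progress.
#' @return A tidy data frame (class `gxe_experiment`): one row per
#'   scenario x replication x estimator with true parameters, estimates
#'   and (optionally) p-values.  Failed replications are recorded with
#'   `NA` estimates.
#' @seealso [summarize_experiment()]
#' @export
run_experiment <- function(grid, reps, estimators = c("eigen", "ldsc"),
                           tests = FALSE, corrected = FALSE,
                           n_groups = NULL,
                           df_method = c("finite", "asymptotic"),
                           calibrate_B = 0L,
                           seed = 1L, max_failures = 0.1, verbose = FALSE) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  df_method <- match.arg(df_method)
  grid <- as.data.frame(grid)
  stopifnot(nrow(grid) >= 1L, reps >= 1L)
  set.seed(seed)
  scen_seeds <- sample.int(2^31 - 2L, nrow(grid))
  rows <- vector("list", nrow(grid) * reps * length(estimators))
  ri <- 0L
  for (s in seq_len(nrow(grid))) {
    cfg <- do.call(sim_config, as.list(grid[s, , drop = FALSE]))
    if (corrected && !cfg$heritable_e) {
      stop("corrected = TRUE requires heritable_e scenarios", call. = FALSE)
    }
    set.seed(scen_seeds[s])
    geno <- simulate_genotypes(cfg)
    ids <- colnames(geno$G)
    ebs <- lapply(unique(geno$block), function(b) {
      idx <- which(geno$block == b)
      eigendecompose_ld(compute_block_ld(geno$G[, idx, drop = FALSE],
                                         ids[idx], block_id = b))
    })
    ref <- .reference_variants(ebs)
    ncal <- NULL
    if (tests && calibrate_B > 0L && "eigen" %in% estimators) {
      d_all <- unlist(lapply(ebs, `[[`, "values"))
      bid <- rep(vapply(ebs, `[[`, 1L, "block_id"),
                 vapply(ebs, `[[`, 1L, "retained_rank"))
      mtd <- data.frame(block_id = bid, d = d_all,
                        y_gg = 1, y_ii = 1, y_gi = 0)
      attr(mtd, "M") <- cfg$m
      attr(mtd, "n") <- c(g = cfg$n, i = cfg$n)
      class(mtd) <- c("moment_table", class(mtd))
      ncal <- null_calibration(mtd, h2g = cfg$h2g, B = calibrate_B,
                               n_groups = n_groups)
    }
    rho_ig_true <- sqrt(cfg$h2g * cfg$h2i) * cfg$r_ig
    n_fail <- 0L
    for (r in seq_len(reps)) {
      set.seed((scen_seeds[s] + r) %% (2^31 - 1L))
      rep_out <- tryCatch({
        sim <- simulate_study(cfg, genotypes = geno, eigenblocks = ebs)
        pair <- harmonize_sumstats(sim$sumstats, ref, verbose = FALSE)
        mt <- build_moment_table(pair, ebs)
        lapply(estimators, function(est) {
          if (corrected) {
            if (tests) {
              res <- gxe_test_corrected(mt, estimator = est,
                                        n_groups = n_groups,
                                        df_method = df_method)
              c(res$jackknife$point[c("h2g", "h2e", "rho_ie", "h2i",
                                      "h2i_uncorrected", "rho_ig",
                                      "rho_ig_uncorrected")],
                p_h2i = res$tests[["h2i"]],
                p_rho_ig = res$tests[["rho_ig"]],
                p_joint = res$tests[["joint"]],
                p_confounding = res$tests[["confounding"]])
            } else {
              f <- fit_gxe_corrected(mt, estimator = est)
              c(h2g = f$h2g, h2e = f$h2e, rho_ie = f$rho_ie, h2i = f$h2i,
                h2i_uncorrected = f$h2i_uncorrected, rho_ig = f$rho_ig,
                rho_ig_uncorrected = f$rho_ig_uncorrected)
            }
          } else {
            if (tests) {
              res <- gxe_test(mt, estimator = est, n_groups = n_groups,
                              df_method = df_method,
                              null_cal = if (est == "eigen") ncal)
              c(res$jackknife$point[c("h2g", "h2i", "sigma1sq", "rho_ig")],
                p_h2i = res$tests[["h2i"]],
                p_rho_ig = res$tests[["rho_ig"]],
                p_joint = res$tests[["joint"]])
            } else {
              f <- if (est == "eigen") fit_gxe_eigen(mt) else
                fit_gxe_ldsc(mt)
              c(h2g = f$h2g, h2i = f$h2i, sigma1sq = f$sigma1sq,
                rho_ig = f$rho_ig)
            }
          }
        })
      }, error = function(e) e)
      failed <- inherits(rep_out, "error")
      if (failed) n_fail <- n_fail + 1L
      for (k in seq_along(estimators)) {
        ri <- ri + 1L
        base <- data.frame(
          scenario = s, rep = r, estimator = estimators[k],
          h2g_true = cfg$h2g, h2i_true = cfg$h2i, r_ig_true = cfg$r_ig,
          rho_ig_true = rho_ig_true,
          h2e_true = if (cfg$heritable_e) cfg$h2e else 0,
          rho_ie_true = if (cfg$heritable_e)
            sqrt(cfg$h2i * cfg$h2e) * cfg$r_ie else 0,
          rho_ge_true = if (cfg$heritable_e)
            sqrt(cfg$h2g * cfg$h2e) * cfg$r_ge else 0,
          failed = failed, stringsAsFactors = FALSE)
        rows[[ri]] <- if (failed) base
                      else cbind(base, as.data.frame(as.list(rep_out[[k]])))
      }
    }
    if (n_fail > max_failures * reps) {
      stop("scenario ", s, ": ", n_fail, "/", reps,
           " replications failed", call. = FALSE)
    }
    if (verbose) {
      message(sprintf("scenario %d/%d done (%d reps, %d failures)",
                      s, nrow(grid), reps, n_fail))
    }
  }
  # failed replications lack the estimate columns: normalize before rbind
  all_cols <- Reduce(union, lapply(rows[seq_len(ri)], names))
  out <- do.call(rbind, lapply(rows[seq_len(ri)], function(x) {
    for (cn in setdiff(all_cols, names(x))) x[[cn]] <- NA_real_
    x[all_cols]
  }))
  rownames(out) <- NULL
  class(out) <- c("gxe_experiment", class(out))
  out
}

#' Summarize a replicated experiment
#'
#' Per scenario and estimator: mean estimate, bias, empirical SD and RMSE
#' for each estimated parameter with a matching `<param>_true` column, and
#' rejection rates at `alpha` for any p-value columns.
#'
#' @param results Output of [run_experiment()].
#' @param alpha Test level for rejection rates.
#' @return A data frame with one row per scenario x estimator.
#' @export
summarize_experiment <- function(results, alpha = 0.05) {
  results <- results[!results$failed, , drop = FALSE]
  params <- intersect(c("h2g", "h2i", "rho_ig", "h2e", "rho_ie", "rho_ge"),
                      names(results))
  pcols <- grep("^p_", names(results), value = TRUE)
  key <- interaction(results$scenario, results$estimator, drop = TRUE)
  pieces <- lapply(split(results, key), function(df) {
    row <- df[1L, c("scenario", "estimator",
                    grep("_true$", names(df), value = TRUE))]
    row$n_reps <- nrow(df)
    for (p in params) {
      tr <- df[[paste0(p, "_true")]][1L]
      est <- df[[p]]
      row[[paste0(p, "_mean")]] <- mean(est)
      row[[paste0(p, "_sd")]] <- stats::sd(est)
      if (!is.null(tr)) {
        row[[paste0(p, "_bias")]] <- mean(est) - tr
        row[[paste0(p, "_rmse")]] <- sqrt(mean((est - tr)^2))
      }
    }
    for (p in pcols) {
      row[[sub("^p_", "reject_", p)]] <- mean(df[[p]] < alpha)
    }
    row
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$scenario, out$estimator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' PRS-by-E equivalence check
#'
#' Computes the oracle polygenic score `PRS = G beta` from the true
#' additive effects of a simulated study, fits
#' `Y ~ PRS + E + PRS:E`, and compares the interaction coefficient with the
#' summary-statistics prediction `rho_ig / h2g`.  Adding measurement noise
#' to the PRS (`noise_var > 0`) demonstrates the attenuation bias of the
#' regression route that the summary-statistics route avoids.
#'
#' @param sim A `sim_output` from [simulate_study()].
#' @param noise_var Variance of independent noise added to the oracle PRS.
#' @return List with `beta3` (fitted interaction coefficient), `se3`,
#'   `expected` (`rho_ig / h2g`) and `prs_r2` (squared correlation of the
#'   noisy PRS with the oracle PRS).
#' @export
prs_by_e_check <- function(sim, noise_var = 0) {
  stopifnot(inherits(sim, "sim_output"))
  cs <- sim$effects$causal
  prs <- drop(sim$G[, cs, drop = FALSE] %*% sim$effects$beta[cs])
  prs_noisy <- prs + stats::rnorm(length(prs), sd = sqrt(noise_var))
  fit <- stats::lm(sim$y ~ prs_noisy + sim$e + prs_noisy:sim$e)
  cf <- summary(fit)$coefficients
  rho_ig <- sim$truth[["rho_ig"]]
  h2g <- sim$truth[["h2g"]]
  list(beta3 = cf["prs_noisy:sim$e", "Estimate"],
       se3 = cf["prs_noisy:sim$e", "Std. Error"],
       expected = if (h2g > 0) rho_ig / h2g else NA_real_,
       prs_r2 = if (noise_var > 0) stats::cor(prs, prs_noisy)^2 else 1)
}
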