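# End-to-end pipelines: harmonize -> whiten -> estimate -> jackknife ->
# test, with JSON results and provenance, plus a batch driver for many
# environment-phenotype pairs.

.as_sumstats_input <- function(x, dialect = "generic-tsv", ...) {
  if (inherits(x, "sumstats")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(read_sumstats(x, dialect = dialect, ...))
  }
  validate_sumstats(as.data.frame(x))
}

.as_ld_input <- function(ld) {
  if (is.character(ld) && length(ld) == 1L) return(read_ld_reference(ld))
  if (is.list(ld) && !is.null(ld$blocks)) return(ld)
  if (is.list(ld) && all(vapply(ld, inherits, TRUE, "eigen_block"))) {
    return(list(blocks = ld, variants = .reference_variants(ld)))
  }
  stop("ld must be a reference directory, a read_ld_reference() object, ",
       "or a list of eigen_block objects", call. = FALSE)
}

.provenance <- function(config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  list(package = "gxeldr",
       version = as.character(utils::packageVersion("gxeldr")),
       config_md5 = hash, config = config, seed = seed,
       r_version = as.character(getRversion()))
}

#' Estimate G-by-E parameters from GWAS and GWIS summary statistics
#'
#' The full pipeline: harmonize the two scans against the LD reference,
#' whiten block-wise, build the moment table, estimate `h2g`,
#' `(h2i, sigma1sq)` and `rho_ig`, jackknife, and run the two Wald tests
#' plus the joint Mahalanobis test.
#'
#' @param gwas,gwis Paths to summary-statistics files (generic TSV dialect)
#'   or `sumstats` data frames.  `gwis` holds the per-variant
#'   SNP-by-environment interaction Z-scores.
#' @param ld LD reference: a directory written by [make_ld_reference()], an
#'   object from [read_ld_reference()], or a list of `eigen_block`s.
#' @param out Optional path for a JSON results file.
#' @param estimator `"eigen"` or `"ldsc"`.
#' @param n_groups,df_method,alternative See [gxe_test()].
#' @param calibrate_B If positive, run the Monte-Carlo null calibration
#'   with this many draws and use it for the p-values (recommended when
#'   the reference has few blocks).
#' @param max_iter,rtol IRLS controls.
#' @param seed Seed for the calibration draws (ignored otherwise).
#' @return The `gxe_result`, with an added `provenance` element; written to
#'   `out` as JSON when requested.
#' @export
gxe_estimate <- function(gwas, gwis, ld, out = NULL,
                         estimator = c("eigen", "ldsc"),
                         n_groups = NULL,
                         df_method = c("finite", "asymptotic"),
                         alternative = "two.sided", calibrate_B = 0L,
                         max_iter = 10L, rtol = 1e-6, seed = NULL) {
  estimator <- match.arg(estimator)
  df_method <- match.arg(df_method)
  g <- .as_sumstats_input(gwas)
  i <- .as_sumstats_input(gwis)
  ldr <- .as_ld_input(ld)
  pair <- harmonize_sumstats(list(g = g, i = i), ldr$variants)
  mt <- build_moment_table(pair, ldr$blocks)
  if (!is.null(seed)) set.seed(seed)
  ncal <- if (calibrate_B > 0L) {
    null_calibration(mt, B = calibrate_B, n_groups = n_groups)
  }
  res <- gxe_test(mt, estimator = estimator, n_groups = n_groups,
                  df_method = df_method, alternative = alternative,
                  null_cal = ncal, max_iter = max_iter, rtol = rtol)
  res$n_variants <- length(pair$snp)
  res$dropped <- pair$dropped
  res$provenance <- .provenance(
    list(estimator = estimator, n_groups = res$jackknife$n_groups,
         df_method = df_method, alternative = alternative,
         calibrate_B = calibrate_B, max_iter = max_iter, rtol = rtol,
         n_variants = length(pair$snp)), seed)
  if (!is.null(out)) write_gxe_json(res, out)
  res
}

#' Confounding-corrected estimation from GWAS, GWIS and E-GWAS summary
#' statistics
#'
#' As [gxe_estimate()], with an additional GWAS of the environmental
#' variable driving the heritable-environment correction; reports corrected
#' and uncorrected estimates side by side plus the confounding test.
#'
#' @inheritParams gxe_estimate
#' @param egwas GWAS of the environmental variable (path or `sumstats`).
#' @param passes Plug-in refresh passes of the correction chain.
#' @return The `gxe_result_corrected` with provenance; JSON written to
#'   `out` when requested.
#' @export
gxe_correct <- function(gwas, gwis, egwas, ld, out = NULL,
                        estimator = c("eigen", "ldsc"),
                        n_groups = NULL,
                        df_method = c("finite", "asymptotic"),
                        alternative = "two.sided", passes = 3L,
                        max_iter = 10L, rtol = 1e-6, seed = NULL) {
  estimator <- match.arg(estimator)
  df_method <- match.arg(df_method)
  if (missing(egwas) || is.null(egwas)) {
    stop("the correction pipeline requires an E-GWAS (egwas argument)",
         call. = FALSE)
  }
  g <- .as_sumstats_input(gwas)
  i <- .as_sumstats_input(gwis)
  e <- .as_sumstats_input(egwas)
  ldr <- .as_ld_input(ld)
  pair <- harmonize_sumstats(list(g = g, i = i, e = e), ldr$variants)
  mt <- build_moment_table(pair, ldr$blocks)
  if (!is.null(seed)) set.seed(seed)
  res <- gxe_test_corrected(mt, estimator = estimator, n_groups = n_groups,
                            df_method = df_method,
                            alternative = alternative, passes = passes,
                            max_iter = max_iter, rtol = rtol)
  res$n_variants <- length(pair$snp)
  res$dropped <- pair$dropped
  res$provenance <- .provenance(
    list(estimator = estimator, n_groups = res$jackknife$n_groups,
         df_method = df_method, alternative = alternative, passes = passes,
         max_iter = max_iter, rtol = rtol,
         n_variants = length(pair$snp)), seed)
  if (!is.null(out)) write_gxe_json(res, out)
  res
}

#' Write an estimation result as JSON
#'
#' @param res A `gxe_result` or `gxe_result_corrected`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gxe_json <- function(res, path) {
  fit <- res$fit
  rec <- list(
    estimator = fit$estimator,
    estimates = Filter(Negate(is.null),
                       list(h2g = fit$h2g, h2i = fit$h2i,
                            sigma1sq = fit$sigma1sq, rho_ig = fit$rho_ig,
                            r_ig = fit$r_ig, h2e = fit$h2e,
                            rho_ie = fit$rho_ie, rho_ge = fit$rho_ge,
                            h2i_uncorrected = fit$h2i_uncorrected,
                            rho_ig_uncorrected = fit$rho_ig_uncorrected)),
    intercepts = as.list(fit$intercepts),
    se = as.list(res$se),
    sigma_hat = res$sigma_hat,
    d2 = res$d2,
    p_values = as.list(res$tests),
    n_groups = res$jackknife$n_groups,
    n_variants = res$n_variants,
    M = fit$M, N_g = fit$N_g, N_i = fit$N_i,
    converged = fit$converged,
    provenance = res$provenance)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a study and write it in the package's interchange formats
#'
#' Generates one synthetic study and writes GWAS/GWIS (and E-GWAS when the
#' environment is heritable) summary statistics as generic TSVs, the
#' in-sample eigen-decomposed LD reference, and a JSON file with the true
#' parameters -- a self-contained input set for [gxe_estimate()] /
#' [gxe_correct()].
#'
#' @param dir Output directory.
#' @param seed Seed for the generation.
#' @param ... Arguments to [sim_config()].
#' @return Invisibly, a list with the file paths and the truth vector.
#' @export
gxe_simulate <- function(dir, seed = NULL, ...) {
  cfg <- sim_config(...)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_study(cfg, ld = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ld_dir <- file.path(dir, "ld")
  make_ld_reference(sim$G, sim$block, ld_dir)
  paths <- list(ld = ld_dir)
  for (s in names(sim$sumstats)) {
    p <- file.path(dir, paste0(switch(s, g = "gwas", i = "gwis",
                                      e = "egwas"), ".tsv"))
    write_sumstats(sim$sumstats[[s]], p)
    paths[[s]] <- p
  }
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(c(as.list(sim$truth), list(seed = seed)),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth_values = sim$truth)))
}

#' Batch analysis of many environment-phenotype pairs
#'
#' Runs [gxe_estimate()] (or [gxe_correct()] when an `egwas` column is
#' present and non-empty) for each row of a manifest and collects one row
#' per pair with estimates, SEs, the three p-values and a
#' Bonferroni-adjusted significance flag.
#'
#' @param manifest Data frame with columns `name`, `gwas`, `gwis` and
#'   optionally `egwas` (file paths; empty string or `NA` to skip the
#'   correction for a pair).
#' @param ld LD reference (shared across pairs).
#' @param family_size Bonferroni family size; defaults to `nrow(manifest)`
#'   and is reported explicitly rather than inferred silently.
#' @param alpha Family-wise level for the Bonferroni flag.
#' @param out Optional TSV output path.
#' @param ... Passed to [gxe_estimate()] / [gxe_correct()].
#' @return Data frame, one row per pair.
#' @export
gxe_batch <- function(manifest, ld, family_size = NULL, alpha = 0.05,
                      out = NULL, ...) {
  manifest <- as.data.frame(manifest)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  stopifnot(all(c("name", "gwas", "gwis") %in% names(manifest)))
  if (is.null(family_size)) family_size <- nrow(manifest)
  message("Bonferroni family size: ", family_size)
  ldr <- .as_ld_input(ld)
  rows <- lapply(seq_len(nrow(manifest)), function(k) {
    row <- manifest[k, ]
    has_e <- "egwas" %in% names(manifest) && !is.na(row$egwas) &&
      nzchar(row$egwas)
    res <- if (has_e) {
      gxe_correct(row$gwas, row$gwis, row$egwas, ldr, ...)
    } else {
      gxe_estimate(row$gwas, row$gwis, ldr, ...)
    }
    data.frame(name = row$name, corrected = has_e,
               h2g = res$fit$h2g, h2i = res$fit$h2i,
               rho_ig = res$fit$rho_ig,
               se_h2i = res$se[["h2i"]], se_rho_ig = res$se[["rho_ig"]],
               p_h2i = res$tests[["h2i"]], p_rho_ig = res$tests[["rho_ig"]],
               p_joint = res$tests[["joint"]],
               p_confounding = if (has_e) res$tests[["confounding"]]
                               else NA_real_,
               joint_significant = res$tests[["joint"]] < alpha / family_size,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  attr(res, "family_size") <- family_size
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
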