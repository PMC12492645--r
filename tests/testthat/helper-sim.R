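# Shared fixtures: small simulated studies and noise-free moment tables.

# A small complete study (genotypes, scans, in-sample eigen blocks).
tiny_study <- function(n = 500, m = 100, n_blocks = 4, h2g = 0.2,
                       h2i = 0, r_ig = 0, seed = 1, ...) {
  cfg <- sim_config(n = n, m = m, n_blocks = n_blocks, h2g = h2g,
                    h2i = h2i, r_ig = r_ig, ...)
  set.seed(seed)
  simulate_study(cfg)
}

moment_table_of <- function(sim) {
  ref <- data.frame(snp = colnames(sim$G), a1 = "A", a2 = "G",
                    stringsAsFactors = FALSE)
  pair <- harmonize_sumstats(sim$sumstats, ref, verbose = FALSE)
  build_moment_table(pair, sim$eigenblocks)
}

# A bare moment table with chosen eigenvalues and noise-free regressands
# set exactly to their expected values under the moment conditions.
exact_moment_table <- function(d, block_id, N_g = 2000, N_i = 2000,
                               N_e = 2000, M = 1000,
                               h2g = 0, h2i = 0, sigma1sq = 0, rho_ig = 0,
                               gi_intercept = 0, h2e = 0, rho_ie = 0,
                               rho_ge = 0, c1 = 0, ge_icpt = 0, c3 = NULL,
                               with_e = FALSE) {
  mt <- data.frame(
    block_id = block_id, d = d,
    y_gg = d * N_g * h2g / M + 1,
    y_ii = d * N_i * (h2i + 2 * rho_ie^2) / M + 1 + 2 * (h2i + sigma1sq),
    y_gi = d * sqrt(N_g * N_i) * (rho_ig + rho_ge * rho_ie) / M +
      gi_intercept)
  if (with_e) {
    mt$y_ee <- d * N_e * h2e / M + 1
    mt$y_ei <- d * sqrt(N_e * N_i) * rho_ie * (1 + h2e) / M + c1
    mt$y_ge <- d * sqrt(N_g * N_e) * rho_ge / M + ge_icpt
  }
  attr(mt, "M") <- M
  attr(mt, "n") <- c(g = N_g, i = N_i, e = N_e)
  class(mt) <- c("moment_table", class(mt))
  mt
}

# Write a generic-TSV sumstats fixture and return its path.
write_sumstats_fixture <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
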