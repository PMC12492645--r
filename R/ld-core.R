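# Block LD matrices, their eigen-decomposition, and Z-score whitening.
#
# The estimators in this package never touch a whole-genome LD matrix:
# the genome is partitioned into approximately independent blocks, each
# block's correlation matrix R is eigen-decomposed as R = U D U', and
# Z-score vectors are whitened per block as D^(-1/2) U' Z.

#' Compute the LD (correlation) matrix of one genomic block
#'
#' @param genotypes An n x m matrix of genotype dosages (one column per
#'   variant).  Columns are standardized internally; a zero-variance column
#'   is an error.
#' @param variant_ids Optional variant IDs (defaults to column names).
#' @param block_id Integer block label.
#' @return An object of class `ld_block`: list with `block_id`,
#'   `variant_ids` and the correlation matrix `R` (unit diagonal).
#' @export
compute_block_ld <- function(genotypes, variant_ids = colnames(genotypes),
                             block_id = 1L) {
  G <- as.matrix(genotypes)
  if (ncol(G) < 1L) stop("block must contain at least one variant",
                         call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- paste0("v", seq_len(ncol(G)))
  sds <- apply(G, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance genotype column(s): ",
         paste(utils::head(variant_ids[sds == 0 | !is.finite(sds)], 3L),
               collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(G)
  diag(R) <- 1
  structure(list(block_id = as.integer(block_id),
                 variant_ids = as.character(variant_ids), R = R),
            class = "ld_block")
}

#' Eigen-decompose a block LD matrix
#'
#' Decomposes R = U D U' and drops near-null components: eigenvalues
#' `D_jj <= tol * max(D)` are discarded, because the whitening operator
#' D^(-1/2) U' amplifies noise on those directions without bound.
#' Eigenvalues are returned in decreasing order; each eigenvector's sign is
#' fixed so that its largest-magnitude element is positive, making output
#' reproducible across linear-algebra backends.
#'
#' @param block An `ld_block` (or a bare correlation matrix).
#' @param tol Relative eigenvalue truncation threshold (`>= 0`).
#' @return An object of class `eigen_block`: list with `block_id`,
#'   `variant_ids`, `values` (retained eigenvalues, decreasing), `vectors`
#'   (orthonormal columns), `original_dim`, `retained_rank`.
#' @export
eigendecompose_ld <- function(block, tol = 1e-6) {
  stopifnot(tol >= 0)
  if (inherits(block, "ld_block")) {
    R <- block$R
    ids <- block$variant_ids
    bid <- block$block_id
  } else {
    R <- as.matrix(block)
    ids <- if (!is.null(colnames(R))) colnames(R) else
      paste0("v", seq_len(ncol(R)))
    bid <- 1L
  }
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("LD matrix must be symmetric", call. = FALSE)
  }
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values)
  if (!any(keep)) stop("all eigenvalues below truncation threshold",
                       call. = FALSE)
  d <- ev$values[keep]
  U <- ev$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-|.| element of each eigenvector positive
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  structure(list(block_id = as.integer(bid), variant_ids = as.character(ids),
                 values = d, vectors = U,
                 original_dim = nrow(R), retained_rank = sum(keep)),
            class = "eigen_block")
}

#' Whiten a Z-score vector with a block's eigen-decomposition
#'
#' Computes `D^(-1/2) U' z` over the retained components.  For
#' `z ~ N(0, c R)` the transformed components are independent `N(0, c)`.
#'
#' @param eb An `eigen_block`.
#' @param z Numeric vector of length `eb$original_dim`.
#' @return Numeric vector of length `eb$retained_rank`.
#' @export
transform_z <- function(eb, z) {
  stopifnot(inherits(eb, "eigen_block"))
  if (length(z) != eb$original_dim) {
    stop("Z vector length ", length(z), " does not match block dimension ",
         eb$original_dim, call. = FALSE)
  }
  as.vector(crossprod(eb$vectors, z)) / sqrt(eb$values)
}

#' Per-variant LD scores of a block
#'
#' The LD score of variant j is the j-th diagonal element of R'R, i.e. the
#' sum of squared correlations of variant j with every variant in its block.
#' Computed from the eigen-decomposition as `rowSums(U^2 %*% diag(D^2))`;
#' exact when no eigenvalue was truncated.
#'
#' @param eb An `eigen_block`.
#' @return Numeric vector of length `eb$original_dim`.
#' @export
ld_scores <- function(eb) {
  stopifnot(inherits(eb, "eigen_block"))
  as.vector((eb$vectors^2) %*% (eb$values^2))
}

#' @export
print.eigen_block <- function(x, ...) {
  cat(sprintf("eigen_block %d: dim %d, rank %d, eigenvalues [%.3g .. %.3g]\n",
              x$block_id, x$original_dim, x$retained_rank,
              max(x$values), min(x$values)))
  invisible(x)
}

#' Assign variants to blocks from a genomic region table
#'
#' @param chrom,pos Per-variant chromosome and 1-based position.
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (1-based, inclusive).  Regions must not overlap.
#' @return Integer block index per variant (`NA` for unassigned variants).
#' @export
assign_blocks <- function(chrom, pos, regions) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  out <- rep(NA_integer_, length(pos))
  for (b in seq_len(nrow(regions))) {
    hit <- chrom == as.character(regions$chrom[b]) &
      pos >= regions$start[b] & pos <= regions$end[b]
    if (any(hit & !is.na(out))) {
      stop("variant assigned to two blocks (overlapping regions)",
           call. = FALSE)
    }
    out[hit] <- b
  }
  out
}

#' Build and persist an eigen-decomposed LD reference
#'
#' Partitions standardized genotypes into blocks, computes each block's
#' correlation matrix, eigen-decomposes it, and writes the result to `dir`:
#' one array container (`block_<id>.rds`) per block plus a plain-text JSON
#' manifest mapping block IDs to variant IDs, alleles and retained ranks.
#' The round trip through [read_ld_reference()] is bit-exact.
#'
#' @param genotypes n x m dosage matrix with variant IDs as column names.
#' @param blocks Either an integer/factor vector of length m assigning each
#'   variant to exactly one block, or a single integer giving a number of
#'   equal contiguous chunks.
#' @param dir Output directory (created if needed).
#' @param tol Eigenvalue truncation tolerance, see [eigendecompose_ld()].
#' @param alleles Optional data frame with columns `a1`, `a2` (per variant,
#'   in column order of `genotypes`); defaults to placeholder A/G pairs for
#'   simulated genotypes.
#' @return Invisibly, the list of `eigen_block` objects.
#' @export
make_ld_reference <- function(genotypes, blocks, dir, tol = 1e-6,
                              alleles = NULL) {
  G <- as.matrix(genotypes)
  m <- ncol(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  if (length(blocks) == 1L && is.numeric(blocks)) {
    if (blocks < 1L) stop("empty block list", call. = FALSE)
    blocks <- rep(seq_len(blocks), each = ceiling(m / blocks))[seq_len(m)]
  }
  if (length(blocks) != m) {
    stop("block assignment must cover every variant exactly once",
         call. = FALSE)
  }
  if (anyNA(blocks)) stop("unassigned variant(s) in block map", call. = FALSE)
  if (is.null(alleles)) {
    alleles <- data.frame(a1 = rep("A", m), a2 = rep("G", m))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ub <- unique(blocks)
  ebs <- vector("list", length(ub))
  manifest <- vector("list", length(ub))
  for (k in seq_along(ub)) {
    idx <- which(blocks == ub[k])
    lb <- compute_block_ld(G[, idx, drop = FALSE], ids[idx], block_id = k)
    eb <- eigendecompose_ld(lb, tol = tol)
    eb$a1 <- alleles$a1[idx]
    eb$a2 <- alleles$a2[idx]
    ebs[[k]] <- eb
    saveRDS(eb, file.path(dir, sprintf("block_%04d.rds", k)))
    manifest[[k]] <- list(block_id = k,
                          file = sprintf("block_%04d.rds", k),
                          variant_ids = eb$variant_ids,
                          a1 = eb$a1, a2 = eb$a2,
                          retained_rank = eb$retained_rank,
                          original_dim = eb$original_dim)
  }
  jsonlite::write_json(list(n_blocks = length(ub), tol = tol,
                            blocks = manifest),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(ebs)
}

#' Load an eigen-decomposed LD reference
#'
#' @param dir Directory written by [make_ld_reference()].
#' @return A list with `blocks` (list of `eigen_block`) and `variants`
#'   (data frame `snp`, `a1`, `a2`, `block_id` in reference order, suitable
#'   as the `reference` argument of [harmonize_sumstats()]).
#' @export
read_ld_reference <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir, call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  ebs <- lapply(mf$blocks$file, function(f) readRDS(file.path(dir, f)))
  variants <- do.call(rbind, lapply(ebs, function(eb) {
    data.frame(snp = eb$variant_ids, a1 = eb$a1, a2 = eb$a2,
               block_id = eb$block_id, stringsAsFactors = FALSE)
  }))
  list(blocks = ebs, variants = variants)
}

# In-memory counterpart of read_ld_reference() for eigen blocks built on
# the fly (e.g. inside the simulation engine).
.reference_variants <- function(eigenblocks) {
  do.call(rbind, lapply(eigenblocks, function(eb) {
    data.frame(snp = eb$variant_ids,
               a1 = if (!is.null(eb$a1)) eb$a1 else rep("A", eb$original_dim),
               a2 = if (!is.null(eb$a2)) eb$a2 else rep("G", eb$original_dim),
               block_id = eb$block_id, stringsAsFactors = FALSE)
  }))
}
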