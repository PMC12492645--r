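# Reading, validation and harmonization of association summary statistics.

.VALID_ALLELES <- c("A", "C", "G", "T")

#' Read an association summary-statistics table
#'
#' Reads per-variant association results for one scan -- a GWAS of the
#' phenotype, a genome-wide interaction scan (GWIS) of the SNP-by-environment
#' term, or a GWAS of the environmental variable -- into a validated
#' `sumstats` data frame with columns `snp`, `a1` (effect allele), `a2`
#' (other allele), `z` and `n`.
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`generic-tsv` / `ldsc-sumstats`}{a tab-separated table with columns
#'     `SNP`, `A1`, `A2`, `Z`, `N` (case-insensitive; the munged format used
#'     by LD score regression tools).  If `Z` is absent it is derived as
#'     `BETA/SE` when both are present.}
#'   \item{`plink2-glm-linear`}{a PLINK2 `.glm.linear`-style table with
#'     columns `ID`, `REF`, `ALT`, `A1`, `TEST`, `OBS_CT` and `T_STAT` (or
#'     `BETA`/`SE`).  The `TEST` column distinguishes additive rows (`ADD`)
#'     from interaction rows; set `interaction = TRUE` to keep the
#'     interaction-term rows instead of the additive rows, or pass an explicit
#'     `test` label.}
#' }
#'
#' Rows with missing `z` or `n` are dropped with a message reporting the
#' count.  Chromosome and position are retained as metadata columns when
#' present (1-based coordinates).
#'
#' @param path Path to the file.
#' @param dialect One of `"generic-tsv"`, `"ldsc-sumstats"`,
#'   `"plink2-glm-linear"`.
#' @param interaction For the PLINK2 dialect: keep interaction-term rows
#'   (those whose `TEST` label contains an `x`) rather than `ADD` rows.
#' @param test Optional explicit `TEST` label to select (PLINK2 dialect),
#'   overriding `interaction`.
#' @param verbose Report dropped-row counts via `message()`.
#' @return A data frame of class `sumstats`.
#' @seealso [harmonize_sumstats()], [write_sumstats()]
#' @export
read_sumstats <- function(path,
                          dialect = c("generic-tsv", "ldsc-sumstats",
                                      "plink2-glm-linear"),
                          interaction = FALSE, test = NULL, verbose = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  names(raw) <- toupper(sub("^#", "", names(raw)))

  if (dialect == "plink2-glm-linear") {
    need <- c("ID", "A1", "TEST")
    miss <- setdiff(need, names(raw))
    if (length(miss)) {
      stop("missing mandatory column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    if (is.null(test)) {
      keep <- if (interaction) grepl("x", raw$TEST, fixed = TRUE)
              else raw$TEST == "ADD"
    } else {
      keep <- raw$TEST == test
    }
    raw <- raw[keep, , drop = FALSE]
    if (nrow(raw) == 0L) {
      stop("no rows matching the requested TEST type in ", basename(path),
           call. = FALSE)
    }
    a1 <- toupper(raw$A1)
    # the other allele is whichever of REF/ALT is not the effect allele
    if (all(c("REF", "ALT") %in% names(raw))) {
      ref <- toupper(raw$REF); alt <- toupper(raw$ALT)
      a2 <- ifelse(a1 == alt, ref, alt)
    } else if ("A2" %in% names(raw)) {
      a2 <- toupper(raw$A2)
    } else {
      stop("missing mandatory column(s) in ", basename(path),
           ": REF/ALT (or A2)", call. = FALSE)
    }
    z <- if ("T_STAT" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$T_STAT))
    } else if (all(c("BETA", "SE") %in% names(raw))) {
      suppressWarnings(as.numeric(raw$BETA) / as.numeric(raw$SE))
    } else {
      stop("missing mandatory column(s) in ", basename(path),
           ": T_STAT (or BETA and SE)", call. = FALSE)
    }
    if (!"OBS_CT" %in% names(raw)) {
      stop("missing mandatory column(s) in ", basename(path), ": OBS_CT",
           call. = FALSE)
    }
    out <- data.frame(snp = as.character(raw$ID), a1 = a1, a2 = a2, z = z,
                      n = suppressWarnings(as.numeric(raw$OBS_CT)),
                      stringsAsFactors = FALSE)
    if ("CHROM" %in% names(raw)) out$chrom <- as.character(raw$CHROM)
    if ("POS" %in% names(raw)) out$pos <- as.integer(raw$POS)
  } else {
    need <- c("SNP", "A1", "A2", "N")
    miss <- setdiff(need, names(raw))
    if (!"Z" %in% names(raw) && !all(c("BETA", "SE") %in% names(raw))) {
      miss <- c(miss, "Z")
    }
    if (length(miss)) {
      stop("missing mandatory column(s) in ", basename(path), ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    z <- if ("Z" %in% names(raw)) suppressWarnings(as.numeric(raw$Z))
         else suppressWarnings(as.numeric(raw$BETA) / as.numeric(raw$SE))
    out <- data.frame(snp = as.character(raw$SNP),
                      a1 = toupper(raw$A1), a2 = toupper(raw$A2),
                      z = z, n = suppressWarnings(as.numeric(raw$N)),
                      stringsAsFactors = FALSE)
    if ("CHR" %in% names(raw)) out$chrom <- as.character(raw$CHR)
    for (pcol in c("POS", "BP")) {
      if (pcol %in% names(raw)) { out$pos <- as.integer(raw[[pcol]]); break }
    }
  }

  bad <- !is.finite(out$z) | !is.finite(out$n) | out$n <= 0
  if (any(bad)) {
    if (verbose) {
      message(sum(bad), " row", if (sum(bad) > 1L) "s" else "",
              " removed (missing or invalid Z/N) from ", basename(path))
    }
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0L) {
    stop("no usable rows in ", basename(path), call. = FALSE)
  }
  rownames(out) <- NULL
  validate_sumstats(out)
}

#' Validate a summary-statistics data frame
#'
#' Checks the `sumstats` invariants: unique variant IDs, finite Z-scores,
#' positive sample sizes and a valid, non-degenerate allele pair per variant.
#'
#' @param x A data frame with columns `snp`, `a1`, `a2`, `z`, `n`.
#' @return `x`, classed as `sumstats`, invisibly usable downstream.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("snp", "a1", "a2", "z", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("sumstats object missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$snp)) {
    stop("duplicate variant IDs in summary statistics: ",
         paste(utils::head(unique(x$snp[duplicated(x$snp)]), 3L),
               collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(x$z))) stop("non-finite Z-scores present", call. = FALSE)
  if (!all(is.finite(x$n) & x$n > 0)) {
    stop("sample sizes must be finite and positive", call. = FALSE)
  }
  if (!all(x$a1 %in% .VALID_ALLELES) || !all(x$a2 %in% .VALID_ALLELES)) {
    stop("alleles must be single characters A/C/G/T", call. = FALSE)
  }
  if (any(x$a1 == x$a2)) {
    stop("effect and other allele identical for variant(s): ",
         paste(utils::head(x$snp[x$a1 == x$a2], 3L), collapse = ", "),
         call. = FALSE)
  }
  class(x) <- unique(c("sumstats", class(x)))
  x
}

#' Write summary statistics in the generic TSV dialect
#'
#' @param x A `sumstats` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  x <- validate_sumstats(as.data.frame(x))
  out <- data.frame(SNP = x$snp, A1 = x$a1, A2 = x$a2, Z = x$z, N = x$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics against an LD reference
#'
#' Intersects one or more association scans with the variant list of an LD
#' reference, reorders them to the reference ordering, and flips Z-score
#' signs where a scan's effect allele is the reference's other allele.
#' Strand-ambiguous variants (A/T, C/G) are removed, as are variants whose
#' allele pair matches the reference in neither orientation.
#'
#' Per-variant sample sizes are summarized to one scalar per scan (median):
#' the moment conditions of the estimators use scan-wide sample sizes.
#'
#' @param scans A named list of `sumstats` data frames (e.g.
#'   `list(g = gwas, i = gwis)` or `list(g = , i = , e = )`), or a single
#'   `sumstats` object.
#' @param reference A data frame with columns `snp`, `a1`, `a2` describing
#'   the LD reference variants (in reference order), e.g. the `variants`
#'   element returned by [read_ld_reference()].
#' @param verbose Report removed-variant counts.
#' @return An object of class `harmonized_pair`: a list with elements
#'   `snp` (retained variant IDs in reference order), `a1`, `a2` (reference
#'   orientation), `z` (matrix, one column per scan), `n` (named vector of
#'   scan-level sample sizes), and `dropped` (named counts of removals).
#' @export
harmonize_sumstats <- function(scans, reference, verbose = TRUE) {
  if (is.data.frame(scans)) scans <- list(scan = scans)
  stopifnot(is.list(scans), length(scans) >= 1L)
  if (is.null(names(scans)) || any(names(scans) == "")) {
    names(scans) <- paste0("scan", seq_along(scans))
  }
  scans <- lapply(scans, function(s) validate_sumstats(as.data.frame(s)))
  ref <- as.data.frame(reference)
  need <- c("snp", "a1", "a2")
  if (!all(need %in% names(ref))) {
    stop("reference must provide columns snp, a1, a2", call. = FALSE)
  }
  ref$a1 <- toupper(ref$a1); ref$a2 <- toupper(ref$a2)

  amb_ref <- .is_ambiguous(ref$a1, ref$a2)
  n_amb <- sum(amb_ref)
  ref <- ref[!amb_ref, , drop = FALSE]

  keep <- ref$snp
  for (s in scans) keep <- intersect(keep, s$snp)
  if (length(keep) == 0L) {
    stop("no variants shared between the scans and the LD reference",
         call. = FALSE)
  }
  ref <- ref[match(keep, ref$snp), , drop = FALSE]

  m <- length(keep)
  zmat <- matrix(NA_real_, m, length(scans),
                 dimnames = list(NULL, names(scans)))
  nvec <- numeric(length(scans)); names(nvec) <- names(scans)
  mism <- rep(FALSE, m)
  n_amb_scan <- 0L
  for (k in seq_along(scans)) {
    s <- scans[[k]][match(keep, scans[[k]]$snp), , drop = FALSE]
    amb <- .is_ambiguous(s$a1, s$a2)
    n_amb_scan <- n_amb_scan + sum(amb)
    same <- s$a1 == ref$a1 & s$a2 == ref$a2
    swap <- s$a1 == ref$a2 & s$a2 == ref$a1
    mism <- mism | amb | !(same | swap)
    z <- s$z
    z[swap] <- -z[swap]
    zmat[, k] <- z
    nvec[k] <- stats::median(s$n)
  }
  if (any(mism)) {
    zmat <- zmat[!mism, , drop = FALSE]
    ref <- ref[!mism, , drop = FALSE]
  }
  if (nrow(ref) == 0L) {
    stop("no variants left after allele matching", call. = FALSE)
  }
  dropped <- c(ambiguous = n_amb + n_amb_scan,
               allele_mismatch = sum(mism) - n_amb_scan)
  if (verbose && (sum(dropped) > 0L)) {
    message("harmonization removed ", dropped[["ambiguous"]],
            " strand-ambiguous and ", dropped[["allele_mismatch"]],
            " allele-mismatched variant records")
  }
  structure(list(snp = ref$snp, a1 = ref$a1, a2 = ref$a2,
                 z = zmat, n = nvec, dropped = dropped),
            class = "harmonized_pair")
}

#' Convert one scan of a harmonized set back to a `sumstats` table
#'
#' @param pair A `harmonized_pair`.
#' @param scan Name or index of the scan column.
#' @return A `sumstats` data frame in reference orientation.
#' @export
as_sumstats <- function(pair, scan = 1L) {
  stopifnot(inherits(pair, "harmonized_pair"))
  validate_sumstats(data.frame(
    snp = pair$snp, a1 = pair$a1, a2 = pair$a2,
    z = pair$z[, scan], n = rep(unname(pair$n[scan]), length(pair$snp)),
    stringsAsFactors = FALSE))
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized summary statistics\n")
  cat("  scans:    ", paste(colnames(x$z), collapse = ", "), "\n")
  cat("  variants: ", length(x$snp), "\n")
  cat("  N:        ", paste(sprintf("%s=%g", names(x$n), x$n),
                            collapse = ", "), "\n")
  invisible(x)
}
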