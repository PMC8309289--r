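# Shared in-memory genotype container used by every pipeline stage.
#
# Calls are stored as an integer matrix (samples x sites) with the encoding
#   0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#   NA = missing.

GT_HOM_REF <- 0L
GT_HET <- 1L
GT_HOM_ALT <- 2L

#' Construct a genotype matrix
#'
#' The shared container for called genotypes: an ordered set of biallelic SNP
#' sites plus an integer call matrix (samples x sites; 0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing).
#'
#' @param sites A data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, sorted by (`chrom` block, `pos`) with no duplicate (`chrom`,
#'   `pos`).
#' @param samples Character vector of unique sample names.
#' @param calls Integer matrix, `length(samples)` rows x `nrow(sites)`
#'   columns, values in \{0, 1, 2, NA\}.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, calls) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample names must be unique")
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(sites))
    stop("`calls` must be samples x sites")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
    stop("calls must be 0 (hom-ref), 1 (het), 2 (hom-alt) or NA")
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stop("duplicate (chrom, pos) site")
  # sites must be sorted: positions increasing within each contiguous
  # chromosome block, and no chromosome split across blocks
  r <- rle(as.character(sites$chrom))
  if (anyDuplicated(r$values))
    stop("sites are unsorted: chromosome blocks are interleaved")
  if (nrow(sites) > 1) {
    same <- sites$chrom[-1] == sites$chrom[-nrow(sites)]
    if (any(same & diff(sites$pos) <= 0))
      stop("sites are unsorted: positions must increase within a chromosome")
  }
  dimnames(calls) <- list(if (length(samples)) samples else NULL,
                          if (nrow(sites))
                            paste0(sites$chrom, ":", sites$pos) else NULL)
  rownames(sites) <- NULL
  structure(list(sites = sites, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites (%s)\n",
              length(x$samples), nrow(x$sites),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Subset a genotype matrix by site index (internal).
.gm_subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE], gm$samples,
                  gm$calls[, idx, drop = FALSE])
}

#' Test equality of two genotype matrices
#'
#' Element-wise comparison of sites, sample names and calls (NA-safe); used
#' by the round-trip contracts of the VCF reader/writer.
#'
#' @param a,b `genotype_matrix` objects.
#' @return `TRUE` or `FALSE`.
#' @export
gm_identical <- function(a, b) {
  isTRUE(all.equal(a$sites[c("chrom", "pos", "ref", "alt")],
                   b$sites[c("chrom", "pos", "ref", "alt")],
                   check.attributes = FALSE)) &&
    identical(a$samples, b$samples) &&
    identical(is.na(a$calls), is.na(b$calls)) &&
    all(a$calls == b$calls, na.rm = TRUE)
}
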