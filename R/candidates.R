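# Candidate-gene and candidate-variant filtering within the fine-mapped
# interval.

#' Genes overlapping a candidate interval
#'
#' @param iv A [candidate_interval()].
#' @param gff A [read_gff()] gene model set.
#' @return The `genes` rows whose span overlaps the closed interval by at
#'   least 1 bp, sorted by start.
#' @export
genes_in_interval <- function(iv, gff) {
  stopifnot(inherits(iv, "candidate_interval"),
            inherits(gff, "gene_model_set"))
  if (!iv$chrom %in% gff$genes$chrom)
    stop(sprintf(
      "interval chromosome '%s' not found in gene models (chromosomes: %s)",
      iv$chrom, paste(unique(gff$genes$chrom), collapse = ", ")))
  g <- gff$genes
  hit <- g$chrom == iv$chrom & g$start <= iv$end & g$end >= iv$start
  out <- g[hit, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Feature class of a position: CDS > intron > UTR-unknown > intergenic.
# A position inside a gene but outside the CDS hull cannot be assigned
# UTR vs intron without UTR features, hence "UTR-unknown".
.classify_position <- function(chrom, pos, gff) {
  g <- gff$genes
  hits <- which(g$chrom == chrom & g$start <= pos & g$end >= pos)
  if (!length(hits)) return(c(feature = "intergenic", gene_id = NA_character_))
  best <- c(feature = "UTR-unknown", gene_id = g$gene_id[hits[1]])
  rank <- c(CDS = 1, intron = 2, `UTR-unknown` = 3)
  for (hidx in hits) {
    gid <- g$gene_id[hidx]
    cds <- gff$cds[gff$cds$gene_id == gid, , drop = FALSE]
    f <- if (!nrow(cds)) "UTR-unknown"
    else if (any(cds$start <= pos & cds$end >= pos)) "CDS"
    else if (pos >= min(cds$start) && pos <= max(cds$end)) "intron"
    else "UTR-unknown"
    if (rank[[f]] < rank[[best[["feature"]]]])
      best <- c(feature = f, gene_id = gid)
  }
  best
}

#' Filter variants co-segregating with the phenotype
#'
#' For every variant inside the candidate interval, computes the fraction of
#' typed individuals concordant under the recessive model: non-hairy iff
#' homozygous for the recurrent-parent allele, hairy iff carrying at least
#' one donor allele. Variants are ranked by concordance (descending), then
#' feature priority (CDS > intron > UTR-unknown > intergenic), then
#' position; every variant with concordance 1 is flagged as a candidate.
#'
#' @param gm A [genotype_matrix()] with both parents and the phenotyped
#'   individuals.
#' @param iv The fine-mapped [candidate_interval()].
#' @param gff A [read_gff()] gene model set (used to annotate the feature
#'   class of each variant).
#' @param phen A [phenotype_table()].
#' @param recurrent,nonrecurrent Parent sample names (the recurrent parent's
#'   homozygous call orients the recessive allele at each site; sites where
#'   it is heterozygous or missing are skipped and counted).
#' @return A data frame of class `candidate_variants`, ranked, with columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `feature`, `n_typed`,
#'   `n_concordant`, `concordance`, `candidate`; attribute `"skipped"` counts
#'   sites that could not be oriented. Empty (with a warning) when no variant
#'   falls inside the interval.
#' @export
filter_cosegregating_variants <- function(gm, iv, gff, phen,
                                          recurrent = "parent_recurrent",
                                          nonrecurrent = "parent_nonrecurrent") {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(iv, "candidate_interval"),
            inherits(gff, "gene_model_set"),
            inherits(phen, "phenotype_table"))
  if (!recurrent %in% gm$samples)
    stop("parent sample not present in genotype matrix: ", recurrent)
  lookup <- .phen_lookup(phen)
  ind <- intersect(setdiff(gm$samples, c(recurrent, nonrecurrent)),
                   names(lookup))
  if (!length(ind)) stop("no phenotyped individual shares the genotype matrix")

  in_iv <- which(gm$sites$chrom == iv$chrom & gm$sites$pos >= iv$start &
                   gm$sites$pos <= iv$end)
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      gene_id = character(0), feature = character(0),
                      n_typed = integer(0), n_concordant = integer(0),
                      concordance = numeric(0), candidate = logical(0),
                      stringsAsFactors = FALSE)
  if (!length(in_iv)) {
    warning("no variant inside the candidate interval")
    return(structure(empty, class = c("candidate_variants", "data.frame"),
                     skipped = 0L))
  }

  rcall <- gm$calls[recurrent, in_iv]
  orientable <- !is.na(rcall) & rcall != GT_HET
  skipped <- sum(!orientable)
  in_iv <- in_iv[orientable]
  if (!length(in_iv)) {
    warning("no variant in the interval could be oriented by the recurrent parent")
    return(structure(empty, class = c("candidate_variants", "data.frame"),
                     skipped = skipped))
  }
  rcall <- rcall[orientable]
  calls <- gm$calls[ind, in_iv, drop = FALSE]
  hom_rec <- sweep(calls, 2, rcall, "==")          # hom for recurrent allele
  carries_donor <- !hom_rec                        # het or hom donor
  is_hairy <- lookup[ind] == "hairy"
  conc <- (carries_donor & is_hairy) | (hom_rec & !is_hairy)
  typed <- !is.na(calls)
  n_typed <- colSums(typed)
  n_conc <- colSums(conc & typed, na.rm = TRUE)
  concordance <- ifelse(n_typed > 0, n_conc / n_typed, NA_real_)

  ann <- t(vapply(seq_along(in_iv), function(k)
    .classify_position(gm$sites$chrom[in_iv[k]], gm$sites$pos[in_iv[k]], gff),
    character(2)))
  feature <- ann[, "feature"]
  prio <- c(CDS = 1, intron = 2, `UTR-unknown` = 3, intergenic = 4)[feature]

  out <- data.frame(chrom = gm$sites$chrom[in_iv],
                    pos = gm$sites$pos[in_iv],
                    ref = gm$sites$ref[in_iv],
                    alt = gm$sites$alt[in_iv],
                    gene_id = ann[, "gene_id"],
                    feature = feature,
                    n_typed = n_typed,
                    n_concordant = n_conc,
                    concordance = concordance,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$concordance, prio, out$pos), , drop = FALSE]
  out$candidate <- !is.na(out$concordance) & out$concordance == 1
  rownames(out) <- NULL
  structure(out, class = c("candidate_variants", "data.frame"),
            skipped = skipped)
}
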