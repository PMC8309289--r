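# Readers and writers for the standard formats the pipeline touches.
# Coordinates are 1-based inclusive everywhere (VCF/GFF3 native); any
# half-open arithmetic is internal and never serialized.

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) and retains biallelic SNP records
#' only; multi-allelic records and indels are dropped and counted. Genotypes
#' are taken from the GT field: `0/0` is hom-ref, `0/1`/`1/0` het, `1/1`
#' hom-alt; `./.`, `.` and half-calls (e.g. `./1`) map to missing. Phased
#' separators (`|`) are accepted and treated as unphased.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A [genotype_matrix()]. The attribute `"dropped"` carries the named
#'   counts of excluded records (`multiallelic`, `indel`).
#' @examples
#' \dontrun{gm <- read_vcf("genotypes.vcf")}
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    # header-only file: recover sample names from the #CHROM line
    hdr <- grep("^#CHROM", readLines(path), value = TRUE)
    if (!length(hdr)) stop("VCF has no #CHROM header line: ", path)
    cols <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
    samples <- if (length(cols) > 9) cols[-(1:9)] else character(0)
    gm <- genotype_matrix(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      samples, matrix(integer(0), length(samples), 0))
    attr(gm, "dropped") <- c(multiallelic = 0L, indel = 0L)
    return(gm)
  }
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- character(0)

  rec_id <- paste0(fix$CHROM, ":", fix$POS)
  no_gt <- !vapply(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(no_gt))
    stop("record without GT field: ", rec_id[which(no_gt)[1]])

  is_multi <- grepl(",", fix$ALT, fixed = TRUE)
  bases <- c("A", "C", "G", "T")
  is_snp <- toupper(fix$REF) %in% bases & toupper(fix$ALT) %in% bases
  is_indel <- !is_multi & !is_snp
  keep <- !is_multi & is_snp
  dropped <- c(multiallelic = sum(is_multi), indel = sum(is_indel))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% "0/0"] <- GT_HOM_REF
  code[gt %in% c("0/1", "1/0")] <- GT_HET
  code[gt %in% "1/1"] <- GT_HOM_ALT
  known_missing <- is.na(gt) | gt %in% c(".", "./.", "./0", "0/.", "./1", "1/.")
  unknown <- is.na(code) & !known_missing
  if (any(unknown)) {
    i <- which(unknown, arr.ind = TRUE)[1, ]
    stop(sprintf("unrecognized GT '%s' at %s:%s (sample %s)",
                 gt[unknown][1], fix$CHROM[i[1]], fix$POS[i[1]],
                 samples[i[2]]))
  }

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = toupper(fix$REF), alt = toupper(fix$ALT),
                      stringsAsFactors = FALSE)
  gm <- tryCatch(
    genotype_matrix(sites, samples, t(code)),
    error = function(e) stop("VCF ", path, ": ", conditionMessage(e)))
  attr(gm, "dropped") <- dropped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' GT-only records; missing calls are written as `./.`. Round-trips exactly
#' through [read_vcf()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param genome Optional [genome_spec()] used to emit `##contig` header
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, genome = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=fuzzmap",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", genome$chrom,
                          as.integer(genome$length)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow(gm$calls), ncol(gm$calls))
  gt_str[is.na(gt_str)] <- "./."
  if (nrow(gm$sites)) {
    body <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                  gm$sites$alt, ".", "PASS", ".", "GT", sep = "\t")
    if (length(gm$samples))
      body <- paste(body, apply(gt_str, 2, paste, collapse = "\t"),
                    sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Two-column TSV, `individual<TAB>phenotype`, with an optional header line.
#' Phenotype strings are matched case-insensitively against the closed
#' vocabulary \{hairy, non-hairy\} (hyphen, underscore or space accepted).
#'
#' @param path Path to the TSV.
#' @return An object of class `phenotype_table`: a data frame with columns
#'   `individual` and `phenotype` (values `"hairy"` / `"non_hairy"`).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  start <- if (length(lines) && grepl("^individual\\t", lines[1],
                                      ignore.case = TRUE)) 2L else 1L
  if (start > length(lines)) stop("phenotype file is empty: ", path)
  ind <- character(0); phe <- character(0)
  for (i in start:length(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2)
      stop(sprintf("%s line %d: expected 2 tab-separated fields, got %d",
                   path, i, length(f)))
    p <- normalize_phenotype(f[2])
    if (is.na(p))
      stop(sprintf("%s line %d: unknown phenotype '%s' (expected hairy / non-hairy)",
                   path, i, f[2]))
    ind <- c(ind, f[1]); phe <- c(phe, p)
  }
  if (anyDuplicated(ind))
    stop("duplicate individual in phenotype table: ",
         ind[duplicated(ind)][1])
  phenotype_table(ind, phe)
}

#' Construct a phenotype table
#'
#' @param individuals Unique individual names.
#' @param phenotypes Values in \{`hairy`, `non_hairy`\} (normalized with
#'   [normalize_phenotype()]).
#' @return A `phenotype_table` data frame.
#' @export
phenotype_table <- function(individuals, phenotypes) {
  phenotypes <- vapply(phenotypes, function(p) {
    np <- normalize_phenotype(p)
    if (is.na(np)) stop("unknown phenotype: ", p)
    np
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(individuals))
    stop("individuals must be unique")
  structure(data.frame(individual = as.character(individuals),
                       phenotype = phenotypes, stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

#' Normalize a phenotype label
#'
#' @param x Character vector of raw labels.
#' @return `"hairy"`, `"non_hairy"`, or `NA` for labels outside the closed
#'   vocabulary.
#' @export
normalize_phenotype <- function(x) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[-_ ]+", "_", y)
  out <- rep(NA_character_, length(y))
  out[y == "hairy"] <- "hairy"
  out[y %in% c("non_hairy", "nonhairy")] <- "non_hairy"
  out
}

# named character vector individual -> phenotype
.phen_lookup <- function(phen) {
  stopifnot(inherits(phen, "phenotype_table"))
  setNames(phen$phenotype, phen$individual)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 (via \pkg{rtracklayer}) and assembles a gene model set:
#' `gene` features with their child `CDS` intervals (resolved through
#' `mRNA`/`transcript` parents, or attached directly to the gene). CDS
#' intervals outside their gene span are rejected.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gene_model_set`: a list of data frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`) and `cds` (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  get_id <- function(x) as.character(x$ID)
  gidx <- type == "gene"
  genes <- data.frame(
    gene_id = get_id(gr[gidx]),
    chrom = as.character(GenomicRanges::seqnames(gr[gidx])),
    start = GenomicRanges::start(gr[gidx]),
    end = GenomicRanges::end(gr[gidx]),
    strand = as.character(GenomicRanges::strand(gr[gidx])),
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ID in GFF: ", genes$gene_id[duplicated(genes$gene_id)][1])

  # transcript -> gene map
  tidx <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(
    vapply(as.list(gr[tidx]$Parent), function(p) as.character(p)[1],
           character(1)),
    get_id(gr[tidx]))

  cidx <- type == "CDS"
  if (any(cidx)) {
    cds_parent <- vapply(as.list(gr[cidx]$Parent),
                         function(p) as.character(p)[1], character(1))
    cds_gene <- ifelse(cds_parent %in% names(tx2gene),
                       tx2gene[cds_parent], cds_parent)
    unknown <- !cds_gene %in% genes$gene_id
    if (any(unknown))
      stop("CDS with unresolvable gene parent in GFF: ",
           cds_parent[unknown][1])
    cds <- data.frame(
      gene_id = unname(cds_gene),
      chrom = as.character(GenomicRanges::seqnames(gr[cidx])),
      start = GenomicRanges::start(gr[cidx]),
      end = GenomicRanges::end(gr[cidx]),
      stringsAsFactors = FALSE)
  } else {
    cds <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  }

  if (nrow(cds)) {
    gs <- genes[match(cds$gene_id, genes$gene_id), ]
    bad <- cds$start < gs$start | cds$end > gs$end | cds$chrom != gs$chrom
    if (any(bad))
      stop(sprintf("CDS %s:%d-%d lies outside the span of gene %s",
                   cds$chrom[bad][1], cds$start[bad][1], cds$end[bad][1],
                   cds$gene_id[bad][1]))
  }
  structure(list(genes = genes[order(genes$chrom, genes$start), ],
                 cds = cds),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d genes, %d CDS intervals\n",
              nrow(x$genes), nrow(x$cds)))
  invisible(x)
}

#' Read a marker panel
#'
#' TSV with header columns `marker`, `chrom`, `pos`, `allele_recurrent`,
#' `allele_nonrecurrent`. Markers are returned sorted by (chrom, pos).
#' Marker names of the form `Pp05-SNP-<pos>` are display names only; the
#' authoritative position is the `pos` column.
#'
#' @param path Path to the TSV.
#' @return A data frame of class `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  if (!file.exists(path)) stop("marker panel not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("marker", "chrom", "pos", "allele_recurrent",
            "allele_nonrecurrent")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("marker panel is missing column(s): ", paste(miss, collapse = ", "))
  df$pos <- as.numeric(df$pos)
  if (any(is.na(df$pos)))
    stop("marker panel has non-numeric positions (line ",
         which(is.na(df$pos))[1] + 1L, ")")
  if (anyDuplicated(df$marker))
    stop("duplicate marker name: ", df$marker[duplicated(df$marker)][1])
  df <- df[order(df$chrom, df$pos), need]
  rownames(df) <- NULL
  structure(df, class = c("marker_panel", "data.frame"))
}

#' Marker genotypes of fine-mapping individuals
#'
#' Builds the individuals-x-markers table the fine-mapping stage consumes.
#' Genotypes use the backcross coding `a` (homozygous recurrent), `h`
#' (heterozygous) or missing.
#'
#' @param panel A [read_marker_panel()] data frame (single chromosome).
#' @param genotypes Character matrix, individuals x markers, values in
#'   \{"a", "h", NA\}; column names must match panel markers.
#' @param phenotypes Named character vector or [phenotype_table()] covering
#'   the individuals (parent control rows may be absent from it).
#' @return An object of class `marker_genotype_table`.
#' @export
marker_genotype_table <- function(panel, genotypes, phenotypes) {
  stopifnot(inherits(panel, "marker_panel"))
  if (length(unique(panel$chrom)) != 1)
    stop("fine-mapping markers must lie on a single chromosome")
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)) ||
      !all(colnames(genotypes) %in% panel$marker))
    stop("genotype columns must be named after panel markers")
  genotypes <- genotypes[, panel$marker, drop = FALSE]  # position order
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c("a", "h")))
    stop("marker genotypes must be 'a', 'h' or missing (got '",
         setdiff(vals, c("a", "h"))[1], "')")
  if (inherits(phenotypes, "phenotype_table"))
    phenotypes <- .phen_lookup(phenotypes)
  structure(list(markers = panel,
                 individuals = rownames(genotypes),
                 genotypes = genotypes,
                 phenotypes = phenotypes),
            class = "marker_genotype_table")
}

#' Read marker genotypes from a wide TSV
#'
#' Expected layout: header `individual<TAB>phenotype<TAB><marker names...>`;
#' one row per individual; genotype cells `a`, `h`, or one of `-`, `.`, `NA`,
#' empty for missing. A phenotype cell may be empty for parent control rows.
#'
#' @param path Path to the TSV.
#' @param panel The matching [read_marker_panel()] panel.
#' @return A [marker_genotype_table()].
#' @export
read_marker_genotypes <- function(path, panel) {
  if (!file.exists(path)) stop("marker genotype table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!all(c("individual", "phenotype") %in% names(df)[1:2]))
    stop("first two columns must be 'individual' and 'phenotype'")
  mk <- setdiff(names(df), c("individual", "phenotype"))
  extra <- setdiff(mk, panel$marker)
  if (length(extra))
    stop("markers absent from panel: ", paste(extra, collapse = ", "))
  g <- as.matrix(df[, mk, drop = FALSE])
  g[g %in% c("-", ".", "", "NA")] <- NA_character_
  rownames(g) <- df$individual
  phen_raw <- normalize_phenotype(df$phenotype)
  phen <- setNames(phen_raw, df$individual)
  phen <- phen[!is.na(phen)]
  marker_genotype_table(panel[panel$marker %in% mk, , drop = FALSE], g, phen)
}
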