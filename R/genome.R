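#' Genome specification for the BC1 simulator
#'
#' Describes the chromosomes over which populations are simulated. The default
#' mirrors the geography of the peach reference assembly at desk scale: eight
#' chromosomes (`Pp01`--`Pp08`) of 25 Mb each.
#'
#' @param chromosomes Character vector of unique chromosome names.
#' @param lengths Integer-ish vector of chromosome lengths in bp (all > 0),
#'   one per chromosome.
#'
#' @return An object of class `genome_spec`: a list with elements `chrom`
#'   (names) and `length` (named numeric, bp).
#' @examples
#' g <- genome_spec()
#' g$length[["Pp05"]]
#' @export
genome_spec <- function(chromosomes = paste0("Pp0", 1:8),
                        lengths = rep(25e6, length(chromosomes))) {
  chromosomes <- as.character(chromosomes)
  lengths <- as.numeric(lengths)
  if (length(chromosomes) < 1L)
    stop("genome must have at least one chromosome")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  if (length(lengths) != length(chromosomes))
    stop("`lengths` must have one entry per chromosome")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be finite and > 0")
  structure(
    list(chrom = chromosomes, length = setNames(lengths, chromosomes)),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chrom), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Cross design for a simulated BC1 population
#'
#' Parameters of the backcross: an F1 (recurrent x donor) crossed back to the
#' homozygous recurrent parent. Every locus then segregates 1:1
#' heterozygous : homozygous-recurrent. A single causal locus with complete
#' penetrance controls the phenotype; the donor allele is dominant (`hairy`),
#' so an offspring is hairy iff it is heterozygous at the causal locus.
#'
#' @param n_offspring Number of BC1 offspring (>= 1). Default 38, the size of
#'   the primary mapping population this workflow is modelled on.
#' @param causal_chrom,causal_pos Location of the causal locus (1-based bp).
#' @param recombination_rate Expected crossovers per chromosome per meiosis
#'   (Morgans); Haldane model, no interference.
#' @param genotyping_error_rate Probability that a true offspring call is
#'   flipped (heterozygous <-> homozygous-recurrent), independently per call.
#' @param missing_rate Probability that an observed call is dropped.
#' @param seed Integer RNG seed; fixed seeds give byte-identical populations.
#'
#' @return An object of class `cross_spec` (a validated list).
#' @examples
#' cross_spec(n_offspring = 10, seed = 42)
#' @export
cross_spec <- function(n_offspring = 38,
                       causal_chrom = "Pp05",
                       causal_pos = 15900000,
                       recombination_rate = 1.0,
                       genotyping_error_rate = 0,
                       missing_rate = 0,
                       seed = 1L) {
  n_offspring <- as.integer(n_offspring)
  if (is.na(n_offspring) || n_offspring < 1L)
    stop("`n_offspring` must be >= 1")
  if (!is.finite(recombination_rate) || recombination_rate < 0)
    stop("`recombination_rate` must be >= 0")
  for (nm in c("genotyping_error_rate", "missing_rate")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm))
  }
  if (!is.finite(causal_pos) || causal_pos < 1)
    stop("`causal_pos` must be a positive coordinate")
  structure(
    list(n_offspring = n_offspring,
         causal_chrom = as.character(causal_chrom),
         causal_pos = as.numeric(causal_pos),
         recombination_rate = as.numeric(recombination_rate),
         genotyping_error_rate = as.numeric(genotyping_error_rate),
         missing_rate = as.numeric(missing_rate),
         seed = as.integer(seed)),
    class = "cross_spec"
  )
}

#' @export
print.cross_spec <- function(x, ...) {
  cat(sprintf(
    "<cross_spec> %d BC1 offspring; causal locus %s:%s; %.2f M/chrom; error %.3g; missing %.3g; seed %d\n",
    x$n_offspring, x$causal_chrom, format(x$causal_pos, big.mark = ","),
    x$recombination_rate, x$genotyping_error_rate, x$missing_rate, x$seed))
  invisible(x)
}

# Validate that the causal locus lies inside the genome.
.check_causal_locus <- function(genome, cross) {
  if (!cross$causal_chrom %in% genome$chrom)
    stop(sprintf("causal locus chromosome '%s' is not in the genome (%s)",
                 cross$causal_chrom, paste(genome$chrom, collapse = ", ")))
  len <- genome$length[[cross$causal_chrom]]
  if (cross$causal_pos > len)
    stop(sprintf("causal position %s exceeds length of %s (%s bp)",
                 format(cross$causal_pos, big.mark = ","),
                 cross$causal_chrom, format(len, big.mark = ",")))
  invisible(TRUE)
}
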