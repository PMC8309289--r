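# BC1 population simulator.
#
# Meiosis in the F1 follows the Haldane model: per chromosome the crossover
# count is Poisson(rate in Morgans) and crossover positions are uniform, with
# no interference. A BC1 offspring receives one F1 gamete (a mosaic of
# recurrent-parent and donor chromatin) plus one full recurrent-parent
# chromosome, so its state along a chromosome alternates between
# "a" (homozygous recurrent) and "h" (heterozygous donor introgression).

#' Simulate one F1 gamete's crossover positions
#'
#' Draws, for each chromosome, a Poisson(`rate`) number of crossovers placed
#' uniformly along the chromosome (Haldane, no interference). Uses the current
#' RNG state.
#'
#' @param genome A [genome_spec()].
#' @param rate Expected crossovers per chromosome per meiosis (Morgans, >= 0).
#'
#' @return Named list (one element per chromosome) of sorted numeric crossover
#'   positions in bp; zero-length when no crossover occurred.
#' @examples
#' set.seed(1)
#' xo <- simulate_gamete(genome_spec(), rate = 1)
#' lengths(xo)
#' @export
simulate_gamete <- function(genome, rate) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.finite(rate) || rate < 0) stop("`rate` must be >= 0")
  out <- lapply(genome$chrom, function(cn) {
    n <- rpois(1L, rate)
    if (n == 0L) return(numeric(0))
    sort(runif(n, min = 1, max = genome$length[[cn]]))
  })
  names(out) <- genome$chrom
  out
}

# State ("a"/"h") of an F1 gamete at positions `pos`, given crossovers `xo`
# on the chromosome and the state carried at the chromosome start.
.gamete_state_at <- function(pos, xo, start_h) {
  n_cross <- findInterval(pos, xo)
  h <- (n_cross + as.integer(start_h)) %% 2L == 1L
  ifelse(h, "h", "a")
}

# Segment decomposition of one offspring chromosome: integer bp segments that
# tile [1, len], alternating in state.
.gamete_segments <- function(len, xo, start_h) {
  # two crossovers within the same bp cancel: keep boundaries occurring an
  # odd number of times so the segment states match the per-site state count
  tab <- table(floor(xo))
  bnd <- sort(as.numeric(names(tab)[tab %% 2 == 1]))
  bnd <- bnd[bnd >= 1 & bnd < len]
  starts <- c(1, bnd + 1)
  ends <- c(bnd, len)
  states <- rep(c("a", "h"), length.out = length(starts))
  if (start_h) states <- rep(c("h", "a"), length.out = length(starts))
  data.frame(start = starts, end = ends, state = states,
             stringsAsFactors = FALSE)
}

#' Simulate a BC1 population
#'
#' Generates a full backcross population: two fully homozygous, fully
#' differential parents, `n_offspring` BC1 individuals with true introgression
#' segment structure, phenotypes under complete penetrance (hairy iff
#' heterozygous at the causal locus, the donor allele being dominant), and
#' observed genotype calls with independent per-call genotyping error
#' (symmetric a <-> h flip) and missingness.
#'
#' @param genome A [genome_spec()].
#' @param cross A [cross_spec()]; all randomness flows from `cross$seed`.
#' @param n_sites Number of informative sites placed uniformly at random per
#'   chromosome (>= 1). All simulated sites are parent-informative by
#'   construction.
#'
#' @return An object of class `simulated_population`: a list with elements
#'   `genome`, `cross`, `sites`, `samples` (recurrent parent, donor parent,
#'   then offspring), `calls` (observed, see [genotype_matrix()] encoding),
#'   `true_states` (offspring x sites, "a"/"h"), `segments` (true introgression
#'   segments per offspring), `phenotypes` (data frame `individual`,
#'   `phenotype`).
#' @examples
#' pop <- simulate_population(genome_spec(), cross_spec(n_offspring = 4, seed = 7),
#'                            n_sites = 20)
#' table(pop$phenotypes$phenotype)
#' @export
simulate_population <- function(genome, cross, n_sites = 1500) {
  stopifnot(inherits(genome, "genome_spec"), inherits(cross, "cross_spec"))
  if (n_sites < 1) stop("`n_sites` must be >= 1")
  .check_causal_locus(genome, cross)

  withr::with_seed(cross$seed, {
    ## informative sites, uniform per chromosome
    site_list <- lapply(genome$chrom, function(cn) {
      pos <- sort(unique(round(runif(n_sites, 1, genome$length[[cn]]))))
      data.frame(chrom = cn, pos = pos, stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, site_list)
    nsite <- nrow(sites)
    ref <- sample(c("A", "C", "G", "T"), nsite, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    sites$ref <- ref          # recurrent-parent allele
    sites$alt <- unname(alt)  # donor-parent allele

    offspring <- sprintf("BC1_%03d", seq_len(cross$n_offspring))
    samples <- c("parent_recurrent", "parent_nonrecurrent", offspring)

    true_states <- matrix(NA_character_, cross$n_offspring, nsite,
                          dimnames = list(offspring, NULL))
    seg_acc <- vector("list", cross$n_offspring)
    phen <- character(cross$n_offspring)
    site_idx <- split(seq_len(nsite), factor(sites$chrom, levels = genome$chrom))

    for (i in seq_len(cross$n_offspring)) {
      xo <- simulate_gamete(genome, cross$recombination_rate)
      start_h <- runif(length(genome$chrom)) < 0.5
      segs <- vector("list", length(genome$chrom))
      for (k in seq_along(genome$chrom)) {
        cn <- genome$chrom[k]
        idx <- site_idx[[cn]]
        true_states[i, idx] <- .gamete_state_at(sites$pos[idx], xo[[cn]],
                                                start_h[k])
        s <- .gamete_segments(genome$length[[cn]], xo[[cn]], start_h[k])
        s$chrom <- cn
        segs[[k]] <- s
        if (cn == cross$causal_chrom) {
          causal_state <- .gamete_state_at(cross$causal_pos, xo[[cn]],
                                           start_h[k])
          phen[i] <- if (causal_state == "h") "hairy" else "non_hairy"
        }
      }
      sg <- do.call(rbind, segs)
      sg$individual <- offspring[i]
      seg_acc[[i]] <- sg[, c("individual", "chrom", "start", "end", "state")]
    }
    segments <- do.call(rbind, seg_acc)
    rownames(segments) <- NULL

    ## observed calls: parents exact, offspring with error + missingness
    calls <- matrix(NA_integer_, length(samples), nsite,
                    dimnames = list(samples, NULL))
    calls["parent_recurrent", ] <- GT_HOM_REF
    calls["parent_nonrecurrent", ] <- GT_HOM_ALT
    obs <- ifelse(true_states == "h", GT_HET, GT_HOM_REF)
    if (cross$genotyping_error_rate > 0) {
      flip <- matrix(runif(length(obs)) < cross$genotyping_error_rate,
                     nrow(obs), ncol(obs))
      obs[flip] <- 1L - obs[flip]   # symmetric a <-> h flip
    }
    if (cross$missing_rate > 0) {
      drop <- matrix(runif(length(obs)) < cross$missing_rate,
                     nrow(obs), ncol(obs))
      obs[drop] <- NA_integer_
    }
    calls[offspring, ] <- obs

    structure(
      list(genome = genome, cross = cross, sites = sites,
           samples = samples, calls = calls, true_states = true_states,
           segments = segments,
           phenotypes = data.frame(individual = offspring, phenotype = phen,
                                   stringsAsFactors = FALSE)),
      class = "simulated_population"
    )
  })
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf(
    "<simulated_population> %d offspring, %d sites on %d chromosomes (%d hairy / %d non-hairy)\n",
    x$cross$n_offspring, nrow(x$sites), length(x$genome$chrom),
    sum(x$phenotypes$phenotype == "hairy"),
    sum(x$phenotypes$phenotype == "non_hairy")))
  invisible(x)
}

#' Genotype matrix of a simulated population
#'
#' @param pop A `simulated_population`.
#' @return The observed calls as a [genotype_matrix()] (parents first).
#' @export
sim_genotype_matrix <- function(pop) {
  stopifnot(inherits(pop, "simulated_population"))
  genotype_matrix(pop$sites, pop$samples, pop$calls)
}

#' Write simulated fixtures to disk
#'
#' Emits the standard-format files downstream stages consume: a VCF 4.2 with
#' the two parents first and all offspring, a phenotype TSV
#' (`individual<TAB>phenotype`, phenotype in \{hairy, non-hairy\}), a GFF3 of
#' synthetic gene models (one gene guaranteed to overlap the causal locus),
#' and a diagnostic marker-panel TSV centred on the causal locus.
#'
#' @param pop A `simulated_population`.
#' @param outdir Output directory (created if absent).
#' @param marker_offsets Offsets in bp (relative to the causal position) at
#'   which panel markers are placed.
#' @return Invisibly, a named list of file paths (`vcf`, `phenotypes`, `gff`,
#'   `markers`).
#' @export
emit_fixtures <- function(pop, outdir,
                          marker_offsets = c(-1200e3, -500e3, -150e3, 0,
                                             150e3, 500e3, 1200e3)) {
  stopifnot(inherits(pop, "simulated_population"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(outdir, "genotypes.vcf"),
                phenotypes = file.path(outdir, "phenotypes.tsv"),
                gff = file.path(outdir, "genes.gff3"),
                markers = file.path(outdir, "marker_panel.tsv"))

  write_vcf(sim_genotype_matrix(pop), paths$vcf, genome = pop$genome)

  phen <- pop$phenotypes
  phen$phenotype <- sub("_", "-", phen$phenotype, fixed = TRUE)
  writeLines(c("individual\tphenotype",
               paste(phen$individual, phen$phenotype, sep = "\t")),
             paths$phenotypes)

  writeLines(.synthetic_gff_lines(pop$genome, pop$cross), paths$gff)

  cp <- pop$cross$causal_pos
  cn <- pop$cross$causal_chrom
  pos <- round(cp + marker_offsets)
  pos <- pos[pos >= 1 & pos <= pop$genome$length[[cn]]]
  panel <- data.frame(
    marker = sprintf("%s-SNP-%d", cn, pos),
    chrom = cn, pos = pos,
    allele_recurrent = "T", allele_nonrecurrent = "G",
    stringsAsFactors = FALSE)
  write.table(panel, paths$markers, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

# Deterministic synthetic gene models: one gene every 500 kb (width 3 kb,
# two CDS exons), plus one gene straddling the causal locus.
.synthetic_gff_lines <- function(genome, cross) {
  lines <- c("##gff-version 3")
  gene_rows <- function(chrom, start, end, id) {
    mid <- floor((start + end) / 2)
    c(sprintf("%s\tfuzzmap\tgene\t%d\t%d\t.\t+\t.\tID=%s", chrom, start, end, id),
      sprintf("%s\tfuzzmap\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.1;Parent=%s",
              chrom, start, end, id, id),
      sprintf("%s\tfuzzmap\texon\t%d\t%d\t.\t+\t.\tID=%s.1.exon1;Parent=%s.1",
              chrom, start, mid - 200L, id, id),
      sprintf("%s\tfuzzmap\tCDS\t%d\t%d\t.\t+\t0\tID=%s.1.cds1;Parent=%s.1",
              chrom, start, mid - 200L, id, id),
      sprintf("%s\tfuzzmap\texon\t%d\t%d\t.\t+\t.\tID=%s.1.exon2;Parent=%s.1",
              chrom, mid + 200L, end, id, id),
      sprintf("%s\tfuzzmap\tCDS\t%d\t%d\t.\t+\t0\tID=%s.1.cds2;Parent=%s.1",
              chrom, mid + 200L, end, id, id))
  }
  for (k in seq_along(genome$chrom)) {
    cn <- genome$chrom[k]
    len <- genome$length[[cn]]
    starts <- seq(250001, len - 5000, by = 500000)
    for (j in seq_along(starts)) {
      s <- as.integer(starts[j])
      lines <- c(lines, gene_rows(cn, s, s + 2999L,
                                  sprintf("SYNG_%s_%03d", cn, j)))
    }
    if (cn == cross$causal_chrom) {
      s <- as.integer(cross$causal_pos - 1000)
      lines <- c(lines, gene_rows(cn, s, s + 2999L,
                                  sprintf("SYNG_%s_causal", cn)))
    }
  }
  lines
}
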