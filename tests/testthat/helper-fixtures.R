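# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# -- small constructed genotype matrices --------------------------------------

# Build a genotype matrix from a compact description: `calls` is a list of
# integer vectors (one per sample, 0/1/2/NA) over `positions` on one
# chromosome.
tiny_gm <- function(calls, positions = NULL, chrom = "Pp05",
                    ref = NULL, alt = NULL) {
  ns <- length(calls[[1]])
  if (is.null(positions)) positions <- seq(1e6, by = 1e4, length.out = ns)
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("G", ns)
  genotype_matrix(
    data.frame(chrom = chrom, pos = positions, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    names(calls),
    do.call(rbind, calls))
}

# Default two-parent header for tiny matrices: recurrent all hom-ref,
# donor all hom-alt.
parent_calls <- function(ns) {
  list(P_rec = rep(0L, ns), P_don = rep(2L, ns))
}

# -- small simulated populations ----------------------------------------------

small_pop <- function(seed = 1, n_offspring = 38, n_sites = 1500, ...) {
  simulate_population(genome_spec(),
                      cross_spec(n_offspring = n_offspring, seed = seed, ...),
                      n_sites = n_sites)
}

pop_phenotypes <- function(pop) {
  phenotype_table(pop$phenotypes$individual, pop$phenotypes$phenotype)
}

run_scan <- function(pop, bin_size = 1e5, min_sites = 3) {
  gm <- sim_genotype_matrix(pop)
  si <- screen_informative(gm, "parent_recurrent", "parent_nonrecurrent")
  cc <- recode_offspring(si, gm)
  imap <- segment_introgressions(
    call_bins(cc, pop$genome, bin_size = bin_size, min_sites = min_sites))
  cosegregation_scan(imap, pop_phenotypes(pop))
}

# -- segmentation oracle ------------------------------------------------------

# Independent route to the display segmentation: scan consecutive pairs of
# called bins; every state change between neighbours produces one boundary
# (shared bin edge when adjacent, bp midpoint of the missing gap otherwise).
# Leading/trailing missing adopts the nearest called state by construction.
oracle_segment <- function(s, bstart, bend) {
  called <- which(!is.na(s))
  if (!length(called)) return(NULL)
  st <- s[called[1]]
  starts <- bstart[1]
  ends <- numeric(0)
  states <- st
  if (length(called) > 1) {
    for (j in seq_len(length(called) - 1)) {
      a <- called[j]; b <- called[j + 1]
      if (s[a] == s[b]) next
      gap_l <- bend[a]; gap_r <- bstart[b]
      bp <- if (gap_r == gap_l + 1) gap_l else floor((gap_l + gap_r - 1) / 2)
      ends <- c(ends, bp)
      starts <- c(starts, bp + 1)
      states <- c(states, s[b])
    }
  }
  ends <- c(ends, bend[length(s)])
  list(state = states, start = starts, end = ends)
}

# All state sequences of length n over {a, h, NA}
enumerate_state_seqs <- function(n) {
  grid <- expand.grid(rep(list(c("a", "h", NA)), n),
                      stringsAsFactors = FALSE)
  as.matrix(grid)
}

# -- marker-table generator for fine-mapping properties -----------------------

# BC1 marker genotypes on one chromosome: crossovers ~ Poisson(rate) uniform,
# phenotype determined by the state at `causal` (complete penetrance).
random_marker_table <- function(n, panel, causal, chrom_len = 25e6,
                                rate = 1.0) {
  geno <- matrix(NA_character_, n, nrow(panel),
                 dimnames = list(sprintf("I%03d", seq_len(n)), panel$marker))
  phen <- character(n)
  for (i in seq_len(n)) {
    xo <- sort(runif(rpois(1, rate), 1, chrom_len))
    start_h <- runif(1) < 0.5
    state_at <- function(p)
      ifelse((findInterval(p, xo) + start_h) %% 2 == 1, "h", "a")
    geno[i, ] <- state_at(panel$pos)
    phen[i] <- if (state_at(causal) == "h") "hairy" else "non_hairy"
  }
  marker_genotype_table(panel, geno, setNames(phen, rownames(geno)))
}

# -- tiny hand-written files --------------------------------------------------

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

tiny_vcf_lines <- function(records,
                           samples = c("P_rec", "P_don", "O1")) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}
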