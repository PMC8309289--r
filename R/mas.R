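# Marker-assisted selection at a diagnostic SNP under the recessive model.
#
# The shipped default allele symbols follow the peach G-locus diagnostic SNP:
# mut = "T" (nectarine-associated, recessive), wt = "G" (hairy-associated,
# dominant). The three observable genotype classes are T/T (non-hairy),
# T/G and G/G (both hairy). Symbols are configurable because allele labels
# are fragile across strands and reports.

#' Allele configuration for the MAS genotyper
#'
#' @param mut Symbol of the trait-associated (recessive) allele; default
#'   `"T"`.
#' @param wt Symbol of the wild-type (dominant) allele; default `"G"`.
#' @return An object of class `mas_alleles`.
#' @examples
#' mas_alleles()           # the shipped T/G default
#' mas_alleles("A", "G")   # an alternative labelling
#' @export
mas_alleles <- function(mut = "T", wt = "G") {
  mut <- toupper(as.character(mut)); wt <- toupper(as.character(wt))
  if (length(mut) != 1 || length(wt) != 1 || !nzchar(mut) || !nzchar(wt))
    stop("`mut` and `wt` must be single allele symbols")
  if (mut == wt) stop("`mut` and `wt` must differ")
  structure(list(mut = mut, wt = wt), class = "mas_alleles")
}

.MISSING_GT <- c("", ".", "-", "./.", ".|.", "NA", "N/N")

# Classify raw genotype strings ("T/G", "G|T", ...) into
# {mut/mut, mut/wt, wt/wt, missing}; order-insensitive.
#' Classify diagnostic-SNP genotype strings
#'
#' @param genotype Character vector such as `"T/T"`, `"T/G"`, `"G/G"`;
#'   `NA`, empty, `"."`, `"-"` or `"./."` are missing. `|` separators are
#'   accepted.
#' @param alleles A [mas_alleles()] configuration.
#' @return Character vector over \{`"mut/mut"`, `"mut/wt"`, `"wt/wt"`,
#'   `"missing"`\}. An allele symbol outside the configuration is an error.
#' @export
mas_genotype_class <- function(genotype, alleles = mas_alleles()) {
  stopifnot(inherits(alleles, "mas_alleles"))
  g <- toupper(trimws(as.character(genotype)))
  out <- character(length(g))
  for (i in seq_along(g)) {
    if (is.na(g[i]) || g[i] %in% .MISSING_GT) { out[i] <- "missing"; next }
    al <- strsplit(gsub("|", "/", g[i], fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (length(al) != 2)
      stop("malformed genotype '", genotype[i], "' (expected two alleles)")
    bad <- setdiff(al, c(alleles$mut, alleles$wt))
    if (length(bad))
      stop(sprintf("unknown allele symbol '%s' in genotype '%s' (expected %s/%s)",
                   bad[1], genotype[i], alleles$mut, alleles$wt))
    n_mut <- sum(al == alleles$mut)
    out[i] <- c("wt/wt", "mut/wt", "mut/mut")[n_mut + 1L]
  }
  out
}

#' Predict phenotype from a diagnostic genotype
#'
#' The recessive-model MAS rule: homozygous for the trait allele
#' (`mut/mut`) predicts the recessive phenotype (non-hairy); any genotype
#' carrying a wild-type allele predicts the dominant phenotype (hairy);
#' missing predicts unknown. Total on the closed genotype vocabulary.
#'
#' @param genotype Raw genotype strings (see [mas_genotype_class()]) or
#'   already-classified values.
#' @param alleles A [mas_alleles()] configuration.
#' @return Character vector over \{`"non_hairy"`, `"hairy"`, `"unknown"`\}.
#' @examples
#' mas_predict(c("T/T", "T/G", "G/G", NA))
#' @export
mas_predict <- function(genotype, alleles = mas_alleles()) {
  cls <- if (all(genotype %in% c("mut/mut", "mut/wt", "wt/wt", "missing")))
    as.character(genotype) else mas_genotype_class(genotype, alleles)
  c(`mut/mut` = "non_hairy", `mut/wt` = "hairy", `wt/wt` = "hairy",
    missing = "unknown")[cls]
}

#' Build MAS calls for a set of individuals
#'
#' @param individuals Individual names.
#' @param genotype Raw genotype strings.
#' @param observed Optional observed phenotype labels (normalized with
#'   [normalize_phenotype()]).
#' @param alleles A [mas_alleles()] configuration.
#' @return A data frame of class `mas_calls` with columns `individual`,
#'   `genotype_class`, `predicted`, and (when observed labels are given)
#'   `observed` and `concordant`.
#' @export
mas_calls <- function(individuals, genotype, observed = NULL,
                      alleles = mas_alleles()) {
  cls <- mas_genotype_class(genotype, alleles)
  df <- data.frame(individual = as.character(individuals),
                   genotype_class = cls,
                   predicted = unname(mas_predict(cls)),
                   stringsAsFactors = FALSE)
  if (!is.null(observed)) {
    observed[!is.na(observed) & !nzchar(trimws(observed))] <- NA
    obs <- normalize_phenotype(observed)
    if (any(is.na(obs) & !is.na(observed)))
      stop("unknown observed phenotype label: ",
           observed[is.na(obs) & !is.na(observed)][1])
    df$observed <- obs
    df$concordant <- ifelse(df$genotype_class == "missing" | is.na(obs),
                            NA, df$predicted == obs)
  }
  structure(df, class = c("mas_calls", "data.frame"))
}

#' Genotype-phenotype concordance of MAS calls
#'
#' @param calls A [mas_calls()] data frame with observed labels.
#' @return A list of class `mas_concordance`: `n_typed` (calls with both a
#'   non-missing genotype and an observed label), `n_concordant`, `rate`
#'   (in `[0, 1]`), and `confusion` (predicted x observed counts over typed
#'   calls). Zero typed calls is an error, never `NaN`.
#' @examples
#' panel <- peach_cultivar_panel()
#' calls <- mas_calls(panel$cultivar, panel$genotype, panel$phenotype)
#' mas_concordance(calls)$rate
#' @export
mas_concordance <- function(calls) {
  stopifnot(inherits(calls, "mas_calls"))
  if (is.null(calls$observed))
    stop("calls carry no observed phenotype labels")
  typed <- calls$genotype_class != "missing" & !is.na(calls$observed)
  if (!any(typed))
    stop("no call has both a non-missing genotype and an observed label")
  tc <- calls[typed, , drop = FALSE]
  structure(list(
    n_typed = nrow(tc),
    n_concordant = sum(tc$predicted == tc$observed),
    rate = sum(tc$predicted == tc$observed) / nrow(tc),
    confusion = table(predicted = tc$predicted, observed = tc$observed)),
    class = "mas_concordance")
}

#' @export
print.mas_concordance <- function(x, ...) {
  cat(sprintf("<mas_concordance> %d/%d concordant (%.1f%%)\n",
              x$n_concordant, x$n_typed, 100 * x$rate))
  print(x$confusion)
  invisible(x)
}

# mut-gamete frequency for a parental genotype class
.mut_gamete_freq <- function(class) {
  switch(class,
         "mut/mut" = 1, "mut/wt" = 0.5, "wt/wt" = 0,
         stop("parent genotype must be mut/mut, mut/wt or wt/wt (got '",
              class, "')"))
}

#' Segregation report for a MAS-genotyped cross
#'
#' Tabulates observed hairy : non-hairy counts in a cross and compares them
#' with the Mendelian expectation from a Punnett square under the recessive
#' model (e.g. `mut/mut x mut/wt` gives 1:1, `mut/wt x mut/wt` gives 3:1
#' hairy : non-hairy). An exact binomial test p-value is attached as a
#' diagnostic only — it is not a pass/fail criterion.
#'
#' @param calls A [mas_calls()] data frame for the offspring of one cross.
#' @param parent1,parent2 Parent genotypes, raw strings (e.g. `"T/T"`) or
#'   classes (`"mut/mut"`, `"mut/wt"`, `"wt/wt"`).
#' @param alleles A [mas_alleles()] configuration.
#' @return A list of class `segregation_report`: `observed` (named counts),
#'   `expected_ratio` (string, hairy:non-hairy), `expected_non_hairy`
#'   (probability), `n`, and `p_value`.
#' @examples
#' off <- mas_calls(paste0("x", 1:30), rep(c("T/T", "T/G"), 15))
#' segregation_report(off, "T/T", "T/G")
#' @export
segregation_report <- function(calls, parent1, parent2,
                               alleles = mas_alleles()) {
  stopifnot(inherits(calls, "mas_calls"))
  p1 <- if (parent1 %in% c("mut/mut", "mut/wt", "wt/wt")) parent1 else
    mas_genotype_class(parent1, alleles)
  p2 <- if (parent2 %in% c("mut/mut", "mut/wt", "wt/wt")) parent2 else
    mas_genotype_class(parent2, alleles)
  q <- .mut_gamete_freq(p1) * .mut_gamete_freq(p2)  # P(offspring mut/mut)

  phen <- if (!is.null(calls$observed)) calls$observed else calls$predicted
  phen <- phen[phen %in% c("hairy", "non_hairy")]
  n <- length(phen)
  n_non <- sum(phen == "non_hairy")
  # q is p1*p2 with p in {0, 1/2, 1}, so (1-q)/q is integral when q <= 1/2
  ratio <- if (q == 0) "1:0" else if (q == 1) "0:1" else
    sprintf("%g:1", (1 - q) / q)
  p_value <- if (n == 0) NA_real_
  else if (q %in% c(0, 1)) {
    if ((q == 0 && n_non == 0) || (q == 1 && n_non == n)) 1 else 0
  } else stats::binom.test(n_non, n, q)$p.value
  structure(list(observed = c(hairy = n - n_non, non_hairy = n_non),
                 expected_ratio = ratio,
                 expected_non_hairy = q,
                 n = n, p_value = p_value,
                 parents = c(p1, p2)),
            class = "segregation_report")
}

#' @export
print.segregation_report <- function(x, ...) {
  cat(sprintf(
    "<segregation_report> %s x %s: observed %d hairy : %d non-hairy (expected %s, exact binomial p = %.3g)\n",
    x$parents[1], x$parents[2], x$observed[["hairy"]],
    x$observed[["non_hairy"]], x$expected_ratio, x$p_value))
  invisible(x)
}

#' The shipped 16-cultivar diagnostic panel
#'
#' Phenotype and diagnostic-SNP genotype for the two mapping parents and 14
#' further peach/nectarine cultivars and lines, as printed in the source
#' study's validation panel. All T/T lines are non-hairy nectarines; every
#' carrier of a G allele is hairy.
#'
#' @return Data frame with columns `cultivar`, `phenotype`, `genotype`.
#' @examples
#' head(peach_cultivar_panel())
#' @export
peach_cultivar_panel <- function() {
  path <- system.file("extdata", "cultivar_panel_hairiness.tsv",
                      package = "fuzzmap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' The shipped chromosome-5 fine-mapping marker panel
#'
#' Positions of the seven Sanger-typed SNP markers spanning the primary
#' mapping interval on chromosome Pp05 (14,562,747 - 16,563,677 bp).
#'
#' @return A [read_marker_panel()] data frame.
#' @export
pp05_marker_panel <- function() {
  read_marker_panel(system.file("extdata", "marker_panel_pp05.tsv",
                                package = "fuzzmap", mustWork = TRUE))
}

#' A synthetic recombinant table for the shipped marker panel
#'
#' Ten synthetic recombinant BC1 individuals (plus the two parent controls
#' and two non-recombinants) whose breakpoints bound the locus between the
#' third and sixth panel markers, leaving the two interior markers
#' completely linked. The genotype pattern is constructed, not observed:
#' the study's per-individual fine-mapping genotypes are not published.
#'
#' @return A [marker_genotype_table()].
#' @export
fine_mapping_example_table <- function() {
  read_marker_genotypes(
    system.file("extdata", "recombinants_pp05_synthetic.tsv",
                package = "fuzzmap", mustWork = TRUE),
    pp05_marker_panel())
}
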