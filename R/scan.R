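# Genotype-phenotype co-segregation scanning and recombinant-based interval
# narrowing.
#
# The concordance model is dominant-donor / recessive-recurrent throughout:
# a hairy individual must carry the donor introgression (state h) at the
# causal locus, a non-hairy individual must be homozygous recurrent (a).

#' Construct a candidate interval
#'
#' A 1-based inclusive genomic interval supported by co-segregation
#' evidence.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive bp bounds, `start <= end`.
#' @param n_supporting Number of individuals with informative, concordant
#'   genotype inside the interval.
#' @param evidence Free-form list of supporting evidence (bounding markers or
#'   breakpoints, recombinant individuals, linked markers, flags).
#' @return An object of class `candidate_interval`.
#' @examples
#' iv <- candidate_interval("Pp05", 15760886, 16242580)
#' interval_width_kb(iv)
#' @export
candidate_interval <- function(chrom, start, end, n_supporting = NA_integer_,
                               evidence = list()) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start > end)
    stop("invalid interval: require start <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 n_supporting = n_supporting, evidence = evidence),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  cat(sprintf("<candidate_interval> %s:%s-%s (%d kb%s)\n", x$chrom,
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              interval_width_kb(x),
              if (is.na(x$n_supporting)) ""
              else sprintf(", %d supporting individuals", x$n_supporting)))
  invisible(x)
}

#' Interval width in whole kb
#'
#' Width of a candidate interval as the outer coordinate difference,
#' truncated to whole kb: `floor((end - start) / 1000)`.
#'
#' @param iv A [candidate_interval()] (or any list with `start` and `end`).
#' @return Integer kb.
#' @examples
#' interval_width_kb(candidate_interval("Pp05", 15760886, 16242580))  # 481
#' @export
interval_width_kb <- function(iv) {
  as.integer(floor((iv$end - iv$start) / 1000))
}

#' Genome-wide genotype-phenotype co-segregation scan
#'
#' Finds all maximal genomic intervals in which every phenotyped individual
#' is concordant under the dominant-donor model (hairy iff heterozygous
#' donor state, non-hairy iff homozygous recurrent), with missing or
#' state-unknown genotypes being non-informative. Discordant evidence is
#' taken from segment cores (the called extent of a run minus one bin per
#' flank), so a breakpoint falling inside a bin can never exclude the true
#' locus; see the vignette for the resolution argument.
#'
#' @param imap A [segment_introgressions()] result.
#' @param phen A [phenotype_table()]. Individuals with genotypes but no
#'   phenotype are excluded with a warning.
#' @return A list of [candidate_interval()] objects ranked by decreasing
#'   span (empty when no concordant region survives). Each carries evidence
#'   `left_bound_by` / `right_bound_by` (individuals whose discordant cores
#'   set the bound) and a `whole_chromosome` flag; the attribute
#'   `"degenerate"` on the list marks scans run with fewer than two
#'   individuals per phenotype class.
#' @export
cosegregation_scan <- function(imap, phen) {
  stopifnot(inherits(imap, "introgression_map"),
            inherits(phen, "phenotype_table"))
  lookup <- .phen_lookup(phen)
  ind <- sort(imap$individuals)
  nophen <- setdiff(ind, names(lookup))
  if (length(nophen)) {
    warning("excluding ", length(nophen),
            " genotyped individual(s) without phenotype: ",
            paste(head(nophen, 5), collapse = ", "))
    ind <- setdiff(ind, nophen)
  }
  if (!length(ind)) stop("no individual has both genotype and phenotype")
  classes <- table(factor(lookup[ind], levels = c("hairy", "non_hairy")))
  degenerate <- any(classes < 2)
  if (degenerate)
    warning("fewer than 2 individuals in a phenotype class; ",
            "the scan is weakly constrained")

  expected <- ifelse(lookup[ind] == "hairy", "h", "a")
  segs <- imap$segments[imap$segments$individual %in% ind, , drop = FALSE]
  disc <- segs[segs$state != expected[segs$individual] &
                 !is.na(segs$core_start), , drop = FALSE]

  imp <- imap$impure
  out <- list()
  for (cn in imap$genome$chrom) {
    len <- imap$genome$length[[cn]]
    d <- disc[disc$chrom == cn, , drop = FALSE]
    ## per-individual definite discordance: cores minus that individual's
    ## impure (mixed-vote) bins, where a sub-bin sliver could hide
    per_ind <- lapply(unique(d$individual), function(id) {
      di <- d[d$individual == id, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(di$core_start, di$core_end))
      ii <- imp[imp$individual == id & imp$chrom == cn, , drop = FALSE]
      if (nrow(ii))
        ir <- IRanges::setdiff(ir, IRanges::IRanges(ii$start, ii$end))
      ir
    })
    names(per_ind) <- unique(d$individual)
    excl <- if (length(per_ind))
      IRanges::reduce(do.call(c, unname(per_ind))) else
        IRanges::IRanges()
    conc <- IRanges::setdiff(IRanges::IRanges(1, len), excl)
    if (!length(conc)) next
    cs <- segs[segs$chrom == cn & segs$state == expected[segs$individual], ,
               drop = FALSE]
    bound_by <- function(pos) {
      hits <- vapply(per_ind, function(ir)
        any(IRanges::start(ir) <= pos & IRanges::end(ir) >= pos),
        logical(1))
      names(per_ind)[hits]
    }
    for (j in seq_len(length(conc))) {
      s <- IRanges::start(conc)[j]; e <- IRanges::end(conc)[j]
      sup <- unique(cs$individual[cs$called_start <= e & cs$called_end >= s])
      out[[length(out) + 1L]] <- candidate_interval(
        cn, s, e, n_supporting = length(sup),
        evidence = list(
          left_bound_by = if (s > 1) bound_by(s - 1) else character(0),
          right_bound_by = if (e < len) bound_by(e + 1) else character(0),
          whole_chromosome = (s == 1 && e == len)))
    }
  }
  if (length(out))
    out <- out[order(vapply(out, function(iv) iv$end - iv$start,
                            numeric(1)), decreasing = TRUE)]
  structure(out, degenerate = degenerate)
}

#' Narrow a candidate interval with recombinant marker genotypes
#'
#' The fine-mapping step: each marker is tested for genotype-phenotype
#' discordance (hairy must be `h`, non-hairy must be `a`); markers with zero
#' discordant individuals are completely linked. The interval is closed at
#' the innermost discordant markers flanking the linked run: the new left
#' bound is the rightmost discordant marker left of the linked markers, the
#' right bound is symmetric, and a bound never moves outward from the prior
#' interval. Individuals missing at a marker cannot set a bound there.
#'
#' @param table A [marker_genotype_table()]; markers must lie on the prior
#'   interval's chromosome.
#' @param prior A [candidate_interval()] from the primary scan.
#' @param recurrent,nonrecurrent Optional names of parent control rows in the
#'   table. A marker at which a parent control fails its expected genotype
#'   (recurrent `a`, donor `h`) is excluded with a warning.
#' @return A [candidate_interval()] with evidence `linked_markers`,
#'   `bounding_markers`, `discordance` (per-marker counts), `recombinants`
#'   (individuals whose genotype vector switches state, with the flanking
#'   marker pair of each switch) and `excluded_markers`.
#' @export
fine_map <- function(table, prior, recurrent = NULL, nonrecurrent = NULL) {
  stopifnot(inherits(table, "marker_genotype_table"),
            inherits(prior, "candidate_interval"))
  mk <- table$markers
  if (unique(mk$chrom) != prior$chrom)
    stop(sprintf("markers are on %s but the prior interval is on %s",
                 unique(mk$chrom), prior$chrom))
  g <- table$genotypes

  ## parent controls
  excluded <- character(0)
  controls <- c(recurrent, nonrecurrent)
  for (p in controls) {
    if (!p %in% rownames(g)) next
    want <- if (!is.null(recurrent) && p == recurrent) "a" else "h"
    bad <- !is.na(g[p, ]) & g[p, ] != want
    if (any(bad)) {
      warning("excluding marker(s) failing the ", want,
              " parent control: ",
              paste(mk$marker[bad], collapse = ", "))
      excluded <- union(excluded, mk$marker[bad])
    }
  }
  keep_mk <- !(mk$marker %in% excluded)
  mk <- mk[keep_mk, , drop = FALSE]
  g <- g[, keep_mk, drop = FALSE]
  if (!nrow(mk)) stop("no marker survives the parent controls")

  ind <- setdiff(rownames(g), controls)
  ind <- ind[ind %in% names(table$phenotypes)]
  if (!length(ind)) stop("no phenotyped individual in the marker table")
  expected <- ifelse(table$phenotypes[ind] == "hairy", "h", "a")
  go <- g[ind, , drop = FALSE]
  disc_mat <- !is.na(go) & go != matrix(expected, length(ind), ncol(go))
  disc_n <- colSums(disc_mat)
  typed_n <- colSums(!is.na(go))

  informative <- typed_n > 0
  linked <- informative & disc_n == 0
  if (!any(linked)) {
    warning("no completely linked marker; interval not narrowed")
    return(candidate_interval(prior$chrom, prior$start, prior$end,
                              n_supporting = prior$n_supporting,
                              evidence = c(prior$evidence,
                                           list(fine_map_failed = TRUE))))
  }
  ## maximal contiguous run of linked markers among informative ones;
  ## ties broken toward the prior midpoint
  inf_idx <- which(informative)
  lr <- rle(linked[inf_idx])
  hi <- cumsum(lr$lengths); lo <- hi - lr$lengths + 1L
  runs <- which(lr$values)
  run_len <- lr$lengths[runs]
  best <- runs[run_len == max(run_len)]
  if (length(best) > 1) {
    midp <- (prior$start + prior$end) / 2
    run_mid <- vapply(best, function(rn) {
      ids <- inf_idx[lo[rn]:hi[rn]]
      mean(range(mk$pos[ids]))
    }, numeric(1))
    best <- best[which.min(abs(run_mid - midp))]
  } else best <- best[1]
  core_ids <- inf_idx[lo[best]:hi[best]]
  core_lo <- min(mk$pos[core_ids]); core_hi <- max(mk$pos[core_ids])

  disc_idx <- which(informative & disc_n > 0)
  left_d <- disc_idx[mk$pos[disc_idx] < core_lo]
  right_d <- disc_idx[mk$pos[disc_idx] > core_hi]
  left_marker <- if (length(left_d)) left_d[which.max(mk$pos[left_d])] else NA
  right_marker <- if (length(right_d)) right_d[which.min(mk$pos[right_d])] else NA
  new_start <- if (is.na(left_marker)) prior$start else
    max(prior$start, mk$pos[left_marker])
  new_end <- if (is.na(right_marker)) prior$end else
    min(prior$end, mk$pos[right_marker])
  if (new_start > new_end) {
    warning("discordant markers collapse the interval below zero width; ",
            "returning the prior interval")
    return(candidate_interval(prior$chrom, prior$start, prior$end,
                              evidence = list(fine_map_failed = TRUE)))
  }

  ## recombinants: genotype vector switches state within the panel
  recomb <- list()
  for (i in seq_along(ind)) {
    v <- go[i, ]
    typed <- which(!is.na(v))
    if (length(typed) < 2) next
    sw <- which(v[typed][-1] != v[typed][-length(typed)])
    for (s in sw) {
      recomb[[length(recomb) + 1L]] <- data.frame(
        individual = ind[i],
        left_marker = mk$marker[typed[s]],
        right_marker = mk$marker[typed[s + 1]],
        left_state = unname(v[typed[s]]),
        right_state = unname(v[typed[s + 1]]),
        stringsAsFactors = FALSE)
    }
  }
  recombinants <- if (length(recomb)) do.call(rbind, recomb) else
    data.frame(individual = character(0), left_marker = character(0),
               right_marker = character(0), left_state = character(0),
               right_state = character(0), stringsAsFactors = FALSE)

  candidate_interval(
    prior$chrom, new_start, new_end,
    n_supporting = length(ind),
    evidence = list(
      linked_markers = mk$marker[linked],
      bounding_markers = c(
        left = if (is.na(left_marker)) NA_character_ else mk$marker[left_marker],
        right = if (is.na(right_marker)) NA_character_ else mk$marker[right_marker]),
      discordance = data.frame(marker = mk$marker, pos = mk$pos,
                               n_typed = unname(typed_n),
                               n_discordant = unname(disc_n),
                               stringsAsFactors = FALSE),
      recombinants = recombinants,
      excluded_markers = excluded))
}
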