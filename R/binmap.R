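# Graphical genotyping: aggregate coded calls into fixed-width bins, call
# each bin a/h by majority vote, and segment each individual's chromosomes
# into introgression fragments.
#
# A deliberate resolution note: a bin containing a true crossover is a mixed
# bin, and its majority call can land on either side. Segment bounds are
# therefore reported at three levels --
#   start/end          display bounds (missing runs between opposite states
#                      are split at their bp midpoint),
#   called_start/end   the extent of the bins actually called for the run,
#   core_start/end     the called extent minus one bin on each flank: the
#                      region whose state is certain even if the flanking
#                      bins contain crossovers.
# The co-segregation scan excludes only cores, which keeps it sound.

#' Tile a genome into bins
#'
#' @param genome A [genome_spec()].
#' @param bin_size Bin width in bp (> 0).
#' @return Data frame `chrom`, `start`, `end`, `bin` (global index); bins
#'   tile each chromosome without overlap, the last bin truncated at the
#'   chromosome end.
#' @export
make_bins <- function(genome, bin_size = 1e5) {
  stopifnot(inherits(genome, "genome_spec"))
  if (!is.finite(bin_size) || bin_size <= 0) stop("`bin_size` must be > 0")
  out <- lapply(genome$chrom, function(cn) {
    len <- genome$length[[cn]]
    starts <- seq(1, len, by = bin_size)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + bin_size - 1, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  bins$bin <- seq_len(nrow(bins))
  bins
}

#' Call bin states from coded offspring calls
#'
#' Each bin's state per individual is the majority of the non-missing `a`/`h`
#' calls inside it; ties, or fewer than `min_sites` informative calls, give a
#' missing bin. `conflict` calls count as missing.
#'
#' @param coded A [recode_offspring()] result.
#' @param genome The [genome_spec()] providing chromosome lengths.
#' @param bin_size Bin width in bp; default 100 kb.
#' @param min_sites Minimum `a`/`h` calls needed to call a bin; default 3.
#' @return An object of class `bin_map`: list with `genome`, `bins`,
#'   `states` (individuals x bins, `"a"`/`"h"`/`NA`), `support` (number of
#'   informative calls per bin), `bin_size`, `min_sites`.
#' @export
call_bins <- function(coded, genome, bin_size = 1e5, min_sites = 3) {
  stopifnot(inherits(coded, "coded_calls"), inherits(genome, "genome_spec"))
  if (!is.finite(bin_size) || bin_size <= 0) stop("`bin_size` must be > 0")
  bins <- make_bins(genome, bin_size)
  sites <- coded$sites
  if (!all(sites$chrom %in% genome$chrom))
    stop("coded sites on chromosomes absent from the genome: ",
         paste(setdiff(sites$chrom, genome$chrom), collapse = ", "))
  # global bin id per site
  chrom_offset <- setNames(
    vapply(genome$chrom,
           function(cn) min(bins$bin[bins$chrom == cn]) - 1L, integer(1)),
    genome$chrom)
  site_bin <- chrom_offset[sites$chrom] +
    floor((sites$pos - 1) / bin_size) + 1L
  grp <- factor(site_bin, levels = bins$bin)

  ind <- rownames(coded$calls)
  a_cnt <- t(rowsum((t(coded$calls) == "a") * 1, grp,
                    na.rm = TRUE, reorder = FALSE))
  h_cnt <- t(rowsum((t(coded$calls) == "h") * 1, grp,
                    na.rm = TRUE, reorder = FALSE))
  # rowsum over a factor with empty levels drops them; rebuild full width
  full_a <- matrix(0, length(ind), nrow(bins),
                   dimnames = list(ind, bins$bin))
  full_a[, colnames(a_cnt)] <- a_cnt
  full_h <- matrix(0, length(ind), nrow(bins),
                   dimnames = list(ind, bins$bin))
  full_h[, colnames(h_cnt)] <- h_cnt
  tot <- full_a + full_h
  states <- matrix(NA_character_, length(ind), nrow(bins),
                   dimnames = list(ind, paste0(bins$chrom, ":", bins$start)))
  states[full_a > full_h & tot >= min_sites] <- "a"
  states[full_h > full_a & tot >= min_sites] <- "h"
  # a called bin is "pure" when it has no minority votes; only pure bins are
  # definite evidence of their state (a sub-bin introgression sliver can hide
  # wherever the bin's own votes disagree)
  pure <- !is.na(states) & (full_a == 0 | full_h == 0)
  structure(list(genome = genome, bins = bins, states = states,
                 support = tot, pure = pure,
                 bin_size = bin_size, min_sites = min_sites),
            class = "bin_map")
}

#' @export
print.bin_map <- function(x, ...) {
  cat(sprintf("<bin_map> %d individuals x %d bins (%s bp bins, min %d sites)\n",
              nrow(x$states), nrow(x$bins),
              format(x$bin_size, big.mark = ","), x$min_sites))
  invisible(x)
}

# Segment one chromosome's bin-state vector.
#
# s: states over the chromosome's bins ("a"/"h"/NA); bstart/bend their bp
# bounds. Returns NULL when no bin is called, otherwise a list of parallel
# vectors describing the runs of equal called state. Display bounds follow
# the absorption rules: interior missing runs bounded by equal states join
# that state (implicit in run-length encoding over called bins); bounded by
# opposite states, the boundary is the bp midpoint of the missing run;
# leading/trailing missing adopts the nearest called state.
.segment_states <- function(s, bstart, bend) {
  called <- which(!is.na(s))
  if (!length(called)) return(NULL)
  r <- rle(s[called])
  k <- length(r$values)
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  first_bin <- called[lo]
  last_bin <- called[hi]

  seg_start <- numeric(k); seg_end <- numeric(k)
  seg_start[1] <- bstart[1]
  seg_end[k] <- bend[length(s)]
  if (k > 1) {
    for (j in seq_len(k - 1)) {
      lend <- bend[last_bin[j]]
      rstart <- bstart[first_bin[j + 1]]
      b <- if (rstart == lend + 1) lend else floor((lend + rstart - 1) / 2)
      seg_end[j] <- b
      seg_start[j + 1] <- b + 1
    }
  }
  # the core drops one called bin at each flank that abuts another run
  # (that edge bin may contain the crossover and be called the wrong way);
  # outer flanks of the chromosome's first/last run keep their full extent
  core_start <- rep(NA_real_, k); core_end <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    cb <- called[lo[j]:hi[j]]
    shrink_l <- as.integer(j > 1L)
    shrink_r <- as.integer(j < k)
    if (r$lengths[j] >= 1L + shrink_l + shrink_r) {
      # outer flanks absorb leading/trailing missing bins to the chromosome
      # bounds, mirroring the display-bound absorption rule
      core_start[j] <- if (j == 1L) bstart[1L] else bstart[cb[1L + shrink_l]]
      core_end[j] <- if (j == k) bend[length(s)] else
        bend[cb[r$lengths[j] - shrink_r]]
    }
  }
  list(state = r$values, start = seg_start, end = seg_end,
       called_start = bstart[first_bin], called_end = bend[last_bin],
       core_start = core_start, core_end = core_end,
       n_bins = r$lengths)
}

#' Segment a bin map into introgression fragments
#'
#' Maximal runs of equal non-missing bin state become segments. Interior
#' missing runs bounded by equal states join that state; bounded by opposite
#' states, the breakpoint is placed at the bp midpoint of the missing run;
#' leading/trailing missing runs adopt the nearest called state. A chromosome
#' with zero called bins for an individual is reported in `$unknown`, never
#' fabricated.
#'
#' @param binmap A [call_bins()] result.
#' @return An object of class `introgression_map`: list with `genome`,
#'   `segments` (one row per fragment: `individual`, `chrom`, `start`, `end`,
#'   `state`, plus `called_start`/`called_end` and `core_start`/`core_end`,
#'   see the package vignette), `breakpoints` (`individual`, `chrom`, `pos`,
#'   and the bounding interval `left_bound`/`right_bound` between the last
#'   called bin of one state and the first of the next), `unknown`
#'   (state-unknown individual x chromosome pairs), `impure` (called bins
#'   with mixed votes, per individual — excluded from discordance cores by
#'   the scan), and `bin_size`.
#' @export
segment_introgressions <- function(binmap) {
  stopifnot(inherits(binmap, "bin_map"))
  ind <- rownames(binmap$states)
  pure <- binmap$pure
  if (is.null(pure)) pure <- !is.na(binmap$states)
  segs <- list(); bps <- list(); unk <- list(); imp <- list()
  for (cn in binmap$genome$chrom) {
    sel <- binmap$bins$chrom == cn
    bstart <- binmap$bins$start[sel]
    bend <- binmap$bins$end[sel]
    sm <- binmap$states[, sel, drop = FALSE]
    pm <- pure[, sel, drop = FALSE]
    impure_any <- which(!is.na(sm) & !pm, arr.ind = TRUE)
    if (nrow(impure_any)) {
      imp[[length(imp) + 1L]] <- data.frame(
        individual = ind[impure_any[, 1]], chrom = cn,
        start = bstart[impure_any[, 2]], end = bend[impure_any[, 2]],
        stringsAsFactors = FALSE)
    }
    for (i in seq_along(ind)) {
      res <- .segment_states(sm[i, ], bstart, bend)
      if (is.null(res)) {
        unk[[length(unk) + 1L]] <- data.frame(
          individual = ind[i], chrom = cn, stringsAsFactors = FALSE)
        next
      }
      k <- length(res$state)
      segs[[length(segs) + 1L]] <- data.frame(
        individual = ind[i], chrom = cn,
        start = res$start, end = res$end, state = res$state,
        called_start = res$called_start, called_end = res$called_end,
        core_start = res$core_start, core_end = res$core_end,
        n_bins = res$n_bins, stringsAsFactors = FALSE)
      if (k > 1) {
        bps[[length(bps) + 1L]] <- data.frame(
          individual = ind[i], chrom = cn,
          pos = res$end[-k],
          left_bound = res$called_end[-k],
          right_bound = res$called_start[-1],
          left_state = res$state[-k], right_state = res$state[-1],
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_seg <- data.frame(individual = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          state = character(0), called_start = numeric(0),
                          called_end = numeric(0), core_start = numeric(0),
                          core_end = numeric(0), n_bins = integer(0),
                          stringsAsFactors = FALSE)
  structure(list(
    genome = binmap$genome,
    individuals = ind,
    segments = if (length(segs)) do.call(rbind, segs) else empty_seg,
    breakpoints = if (length(bps)) do.call(rbind, bps) else
      data.frame(individual = character(0), chrom = character(0),
                 pos = numeric(0), left_bound = numeric(0),
                 right_bound = numeric(0), left_state = character(0),
                 right_state = character(0), stringsAsFactors = FALSE),
    unknown = if (length(unk)) do.call(rbind, unk) else
      data.frame(individual = character(0), chrom = character(0),
                 stringsAsFactors = FALSE),
    impure = if (length(imp)) do.call(rbind, imp) else
      data.frame(individual = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0),
                 stringsAsFactors = FALSE),
    bin_size = binmap$bin_size),
    class = "introgression_map")
}

#' @export
print.introgression_map <- function(x, ...) {
  cat(sprintf(
    "<introgression_map> %d individuals, %d segments, %d breakpoints (%d state-unknown chromosomes)\n",
    length(x$individuals), nrow(x$segments), nrow(x$breakpoints),
    nrow(x$unknown)))
  invisible(x)
}

#' Render graphical genotypes as a deterministic table
#'
#' The machine version of a graphical-genotype figure: one row per
#' individual (ordered by phenotype class then name), one column per bin,
#' cells `a`/`h`/`NA` taken from the segment covering the bin midpoint.
#'
#' @param imap A [segment_introgressions()] result.
#' @param phen A [phenotype_table()] covering the individuals.
#' @param path Optional TSV output path; the file is byte-identical across
#'   reruns on the same input.
#' @return Invisibly, the rendered data frame (first two columns
#'   `individual`, `phenotype`).
#' @export
render_graphical_genotypes <- function(imap, phen, path = NULL) {
  stopifnot(inherits(imap, "introgression_map"),
            inherits(phen, "phenotype_table"))
  lookup <- .phen_lookup(phen)
  ind <- imap$individuals
  if (!any(ind %in% names(lookup)))
    stop("no overlap between introgression map and phenotype table")
  ord <- order(factor(lookup[ind], levels = c("hairy", "non_hairy")), ind,
               method = "radix")
  ind <- ind[ord]
  bins <- make_bins(imap$genome, imap$bin_size)
  mid <- floor((bins$start + bins$end) / 2)
  out <- matrix(NA_character_, length(ind), nrow(bins),
                dimnames = list(ind, paste0(bins$chrom, ":", bins$start)))
  for (i in seq_along(ind)) {
    sg <- imap$segments[imap$segments$individual == ind[i], , drop = FALSE]
    for (r in seq_len(nrow(sg))) {
      hit <- bins$chrom == sg$chrom[r] & mid >= sg$start[r] &
        mid <= sg$end[r]
      out[i, hit] <- sg$state[r]
    }
  }
  df <- data.frame(individual = ind,
                   phenotype = unname(lookup[ind]),
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    tmp <- df
    tmp[is.na(tmp)] <- "-"
    write.table(tmp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}

#' Plot graphical genotypes
#'
#' Tile plot of the bin map, individuals ordered by phenotype then name,
#' coloured by state (`h` = donor introgression, `a` = recurrent background,
#' matching the usual red/blue convention).
#'
#' @inheritParams render_graphical_genotypes
#' @return A `ggplot` object (requires the \pkg{ggplot2} package).
#' @export
plot_graphical_genotypes <- function(imap, phen) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_graphical_genotypes() requires the ggplot2 package")
  df <- render_graphical_genotypes(imap, phen)
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    v <- unlist(df[i, -(1:2)])
    cp <- strsplit(names(v), ":", fixed = TRUE)
    data.frame(individual = df$individual[i], phenotype = df$phenotype[i],
               chrom = vapply(cp, `[`, "", 1),
               start = as.numeric(vapply(cp, `[`, "", 2)),
               state = unname(v), stringsAsFactors = FALSE)
  }))
  long$individual <- factor(long$individual, levels = rev(df$individual))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$start / 1e6,
                                     y = .data$individual,
                                     fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(
      values = c(a = "#3B6FB6", h = "#C0392B"), na.value = "grey85",
      labels = c(a = "a (homozygous recurrent)",
                 h = "h (heterozygous introgression)")) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "bin state") +
    ggplot2::theme_minimal(base_size = 9)
}
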