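# Parental informative-SNP screening: retain sites that are homozygous in
# both parents and differential between them (the classic AA x BB screen),
# then recode offspring calls onto the backcross alphabet
#   a = homozygous for the recurrent-parent allele
#   h = heterozygous
#   conflict = homozygous for the donor allele (impossible in a clean BC1).

#' Screen parent-informative sites
#'
#' Retains exactly the sites where both parents are homozygous and their
#' alleles differ. Sites are excluded when either parent is missing
#' (`parent_missing`), either parent is heterozygous (`parent_het`), or the
#' parents are homozygous for the same allele (`not_differential`); the
#' exclusion tally is attached to the result.
#'
#' @param gm A [genotype_matrix()] containing both parent samples.
#' @param recurrent,nonrecurrent Sample names of the recurrent and donor
#'   (non-recurrent) parent.
#' @return An object of class `informative_site_set`: the retained sites with
#'   `allele_recurrent`, `allele_nonrecurrent` and `recurrent_is_ref`
#'   columns; attributes `exclusions` (named counts), `parents`, and
#'   `site_index` (positions of retained sites in `gm`).
#' @examples
#' \dontrun{sites <- screen_informative(gm, "parent_recurrent", "parent_nonrecurrent")}
#' @export
screen_informative <- function(gm, recurrent, nonrecurrent) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (p in c(recurrent, nonrecurrent))
    if (!p %in% gm$samples)
      stop("parent sample not present in genotype matrix: ", p)
  r <- gm$calls[recurrent, ]
  n <- gm$calls[nonrecurrent, ]

  missing <- is.na(r) | is.na(n)
  het <- !missing & (r == GT_HET | n == GT_HET)
  same <- !missing & !het & r == n
  keep <- !missing & !het & !same

  sites <- gm$sites[keep, , drop = FALSE]
  rk <- r[keep]
  sites$recurrent_is_ref <- rk == GT_HOM_REF
  sites$allele_recurrent <- ifelse(sites$recurrent_is_ref, sites$ref,
                                   sites$alt)
  sites$allele_nonrecurrent <- ifelse(sites$recurrent_is_ref, sites$alt,
                                      sites$ref)
  rownames(sites) <- NULL
  structure(sites,
            class = c("informative_site_set", "data.frame"),
            exclusions = c(parent_missing = sum(missing),
                           parent_het = sum(het),
                           not_differential = sum(same)),
            parents = c(recurrent = recurrent, nonrecurrent = nonrecurrent),
            site_index = which(unname(keep)))
}

#' Exclusion tally of an informative-site screen
#'
#' @param sites An `informative_site_set`.
#' @return Named integer vector of exclusion counts.
#' @export
screen_exclusions <- function(sites) {
  stopifnot(inherits(sites, "informative_site_set"))
  attr(sites, "exclusions")
}

#' Recode offspring calls onto the backcross alphabet
#'
#' At each informative site, an offspring homozygous for the recurrent-parent
#' allele is coded `a`, a heterozygote `h`, and a homozygote for the donor
#' allele `conflict` (impossible in a clean BC1; flagged, never silently
#' dropped — downstream binning treats it as missing but its rate is
#' reported). Missing stays missing (`NA`).
#'
#' @param sites An [screen_informative()] result.
#' @param gm The [genotype_matrix()] the sites were screened from.
#' @param offspring Individuals to recode; default all non-parent samples.
#' @return An object of class `coded_calls`: a list with `sites` (the
#'   informative sites) and `calls` (character matrix, offspring x sites,
#'   values `"a"`, `"h"`, `"conflict"`, `NA`).
#' @export
recode_offspring <- function(sites, gm, offspring = NULL) {
  stopifnot(inherits(sites, "informative_site_set"),
            inherits(gm, "genotype_matrix"))
  parents <- attr(sites, "parents")
  if (is.null(offspring))
    offspring <- setdiff(gm$samples, parents)
  if (!all(offspring %in% gm$samples))
    stop("unknown offspring sample(s): ",
         paste(setdiff(offspring, gm$samples), collapse = ", "))
  idx <- attr(sites, "site_index")
  raw <- gm$calls[offspring, idx, drop = FALSE]
  rr <- matrix(rep(sites$recurrent_is_ref, each = length(offspring)),
               nrow = length(offspring))
  coded <- matrix(NA_character_, nrow(raw), ncol(raw),
                  dimnames = dimnames(raw))
  coded[raw == GT_HET] <- "h"
  coded[(raw == GT_HOM_REF & rr) | (raw == GT_HOM_ALT & !rr)] <- "a"
  coded[(raw == GT_HOM_ALT & rr) | (raw == GT_HOM_REF & !rr)] <- "conflict"
  structure(list(sites = as.data.frame(sites), calls = coded),
            class = "coded_calls")
}

#' @export
print.coded_calls <- function(x, ...) {
  tot <- length(x$calls)
  cat(sprintf(
    "<coded_calls> %d individuals x %d sites (a %.1f%%, h %.1f%%, conflict %.2f%%, missing %.2f%%)\n",
    nrow(x$calls), ncol(x$calls),
    100 * sum(x$calls == "a", na.rm = TRUE) / tot,
    100 * sum(x$calls == "h", na.rm = TRUE) / tot,
    100 * sum(x$calls == "conflict", na.rm = TRUE) / tot,
    100 * sum(is.na(x$calls)) / tot))
  invisible(x)
}

#' Conflict rate of recoded calls
#'
#' Fraction of non-missing coded calls that are `conflict` (homozygous for
#' the donor allele) — a direct readout of genotyping error or off-type
#' individuals.
#'
#' @param coded A [recode_offspring()] result.
#' @return Numeric scalar in `[0, 1]`.
#' @export
conflict_rate <- function(coded) {
  stopifnot(inherits(coded, "coded_calls"))
  nm <- sum(!is.na(coded$calls))
  if (nm == 0) return(0)
  sum(coded$calls == "conflict", na.rm = TRUE) / nm
}
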