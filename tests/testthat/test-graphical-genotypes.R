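# Bin map construction and introgression-fragment segmentation.

# one-chromosome bin map built directly from a state matrix
states_binmap <- function(states, bin_size = 1e5, chrom_len = NULL) {
  nb <- ncol(states)
  if (is.null(chrom_len)) chrom_len <- nb * bin_size
  genome <- genome_spec("Pp05", chrom_len)
  bins <- make_bins(genome, bin_size)
  structure(list(genome = genome, bins = bins, states = states,
                 support = matrix(10, nrow(states), nb),
                 bin_size = bin_size, min_sites = 3),
            class = "bin_map")
}

test_that("bin state is the majority vote with tie and min-sites rules", {
  # 1 chromosome of 3 bins (100 kb each); sites placed to hit each bin
  gm <- tiny_gm(c(parent_calls(12), list(
    O1 = c(rep(1L, 4), c(0L, 0L, 1L, NA), rep(0L, 2), 1L, NA))),
    positions = c(seq(10e3, 90e3, length.out = 4),     # bin 1: h x4
                  seq(110e3, 190e3, length.out = 4),   # bin 2: a,a,h,NA
                  seq(210e3, 290e3, length.out = 4)))  # bin 3: a,a,h,NA
  cc <- recode_offspring(screen_informative(gm, "P_rec", "P_don"), gm, "O1")
  bm <- call_bins(cc, genome_spec("Pp05", 3e5), bin_size = 1e5, min_sites = 3)
  expect_equal(unname(bm$states["O1", ]), c("h", "a", "a"))
  # tie -> missing
  gm2 <- tiny_gm(c(parent_calls(4), list(O1 = c(0L, 0L, 1L, 1L))),
                 positions = seq(10e3, 90e3, length.out = 4))
  cc2 <- recode_offspring(screen_informative(gm2, "P_rec", "P_don"), gm2, "O1")
  bm2 <- call_bins(cc2, genome_spec("Pp05", 1e5), bin_size = 1e5)
  expect_true(is.na(bm2$states["O1", 1]))
  # fewer than min_sites -> missing
  bm3 <- call_bins(cc2, genome_spec("Pp05", 1e5), bin_size = 1e5,
                   min_sites = 5)
  expect_true(is.na(bm3$states["O1", 1]))
  # conflict counts as missing evidence
  gm3 <- tiny_gm(c(parent_calls(4), list(O1 = c(2L, 2L, 1L, 1L))),
                 positions = seq(10e3, 90e3, length.out = 4))
  cc3 <- recode_offspring(screen_informative(gm3, "P_rec", "P_don"), gm3, "O1")
  bm4 <- call_bins(cc3, genome_spec("Pp05", 1e5), bin_size = 1e5, min_sites = 2)
  expect_equal(unname(bm4$states["O1", 1]), "h")
})

test_that("bins tile each chromosome without overlap", {
  bins <- make_bins(genome_spec(c("c1", "c2"), c(250e3, 1e5)), 1e5)
  expect_equal(bins$start[bins$chrom == "c1"], c(1, 100001, 200001))
  expect_equal(bins$end[bins$chrom == "c1"], c(1e5, 2e5, 250e3))
  expect_equal(bins$end[bins$chrom == "c2"], 1e5)
})

test_that("segmentation follows the stated absorption rules", {
  # a,a,h,h -> one breakpoint at the shared bin boundary
  im <- segment_introgressions(states_binmap(
    matrix(c("a", "a", "h", "h"), 1, dimnames = list("I1", NULL))))
  expect_equal(im$segments$state, c("a", "h"))
  expect_equal(im$segments$end, c(2e5, 4e5))
  expect_equal(im$breakpoints$pos, 2e5)
  # a,missing,h -> breakpoint at the midpoint of the missing bin
  im2 <- segment_introgressions(states_binmap(
    matrix(c("a", NA, "h"), 1, dimnames = list("I1", NULL))))
  expect_equal(im2$segments$end, c(150000, 3e5))
  # interior missing bounded by equal states joins that state
  im3 <- segment_introgressions(states_binmap(
    matrix(c("a", NA, "a"), 1, dimnames = list("I1", NULL))))
  expect_equal(nrow(im3$segments), 1)
  expect_equal(im3$segments$state, "a")
  # leading/trailing missing adopts the nearest called state
  im4 <- segment_introgressions(states_binmap(
    matrix(c(NA, "h", "a", NA), 1, dimnames = list("I1", NULL))))
  expect_equal(im4$segments$start, c(1, 200001))
  expect_equal(im4$segments$end, c(2e5, 4e5))
})

test_that("a chromosome with zero called bins is reported state-unknown", {
  im <- segment_introgressions(states_binmap(
    matrix(NA_character_, 1, 4, dimnames = list("I1", NULL))))
  expect_equal(nrow(im$segments), 0)
  expect_equal(im$unknown$individual, "I1")
  expect_equal(im$unknown$chrom, "Pp05")
})

test_that("segmentation agrees with the independent pairwise oracle", {
  set.seed(91)
  bin_size <- 1e5
  for (trial in 1:300) {
    L <- sample(1:12, 1)
    s <- sample(c("a", "h", NA), L, replace = TRUE)
    bstart <- seq(1, by = bin_size, length.out = L)
    bend <- bstart + bin_size - 1
    got <- fuzzmap:::.segment_states(s, bstart, bend)
    want <- oracle_segment(s, bstart, bend)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(unname(got$state), unname(want$state))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("error-free breakpoints match true crossover counts within one bin", {
  bin_size <- 1e5
  pop <- small_pop(seed = 29, n_offspring = 15, n_sites = 1500)
  gm <- sim_genotype_matrix(pop)
  cc <- recode_offspring(
    screen_informative(gm, "parent_recurrent", "parent_nonrecurrent"), gm)
  imap <- segment_introgressions(call_bins(cc, pop$genome, bin_size))
  for (id in pop$phenotypes$individual) {
    for (cn in pop$genome$chrom) {
      truth <- pop$segments[pop$segments$individual == id &
                              pop$segments$chrom == cn, ]
      true_bp <- truth$end[-nrow(truth)]
      est <- imap$breakpoints[imap$breakpoints$individual == id &
                                imap$breakpoints$chrom == cn, ]
      expect_equal(nrow(est), length(true_bp))
      if (length(true_bp))
        expect_true(all(abs(sort(est$pos) - sort(true_bp)) <= bin_size))
    }
  }
})

test_that("lowering genotyping error toward zero never increases breakpoint error", {
  # paired seeds; symmetric placement error: distance from every true
  # crossover to the nearest estimated breakpoint plus distance from every
  # estimated breakpoint to the nearest true crossover, so that both missed
  # and spurious breakpoints count (chromosome length when the other set is
  # empty)
  placement_error <- function(seed, err) {
    pop <- simulate_population(
      genome_spec(c("c1", "c2"), c(25e6, 25e6)),
      cross_spec(n_offspring = 10, causal_chrom = "c1", seed = seed,
                 genotyping_error_rate = err),
      n_sites = 1500)
    gm <- sim_genotype_matrix(pop)
    cc <- recode_offspring(
      screen_informative(gm, "parent_recurrent", "parent_nonrecurrent"), gm)
    imap <- segment_introgressions(call_bins(cc, pop$genome, 1e5))
    errs <- c()
    for (id in pop$phenotypes$individual) {
      for (cn in pop$genome$chrom) {
        truth <- pop$segments[pop$segments$individual == id &
                                pop$segments$chrom == cn, ]
        true_bp <- truth$end[-nrow(truth)]
        est <- imap$breakpoints$pos[imap$breakpoints$individual == id &
                                      imap$breakpoints$chrom == cn]
        if (!length(true_bp) && !length(est)) next
        to_nearest <- function(x, y) vapply(x, function(b)
          if (length(y)) min(abs(y - b)) else 25e6, numeric(1))
        errs <- c(errs, to_nearest(true_bp, est), to_nearest(est, true_bp))
      }
    }
    mean(errs)
  }
  seeds <- 1:50
  e0 <- mean(vapply(seeds, placement_error, numeric(1), err = 0))
  e1 <- mean(vapply(seeds, placement_error, numeric(1), err = 0.1))
  e2 <- mean(vapply(seeds, placement_error, numeric(1), err = 0.3))
  expect_lte(e0, e1)
  expect_lte(e1, e2)
})

test_that("rendering is deterministic and ordered by phenotype then name", {
  pop <- small_pop(seed = 33, n_offspring = 10, n_sites = 200)
  gm <- sim_genotype_matrix(pop)
  cc <- recode_offspring(
    screen_informative(gm, "parent_recurrent", "parent_nonrecurrent"), gm)
  imap <- segment_introgressions(call_bins(cc, pop$genome, 5e5))
  phen <- pop_phenotypes(pop)
  f1 <- tempfile(); f2 <- tempfile()
  df <- render_graphical_genotypes(imap, phen, f1)
  render_graphical_genotypes(imap, phen, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(df), 10)
  cls <- df$phenotype
  expect_true(!is.unsorted(match(cls, c("hairy", "non_hairy"))))
  expect_true(all(diff(order(cls, df$individual)) == 1))
})
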