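# shared tiny fixture: a digest plus a simulated library written to SAM
local_sam_fixture <- function(n_reads = 500, bias = bias_model(),
                              seed = 101, genome_len = 20000) {
  g <- simulate_genome(genome_len, seed = seed, topology = "circular")
  inv <- collapse_unique(digest(g, get_enzyme("XmnI")))
  lib <- simulate_library(inv, bias, n_reads, seed = seed + 1)
  sam <- tempfile(fileext = ".sam")
  write_sam(lib, inv, sam)
  list(inv = inv, lib = lib, sam = sam)
}

test_that("SAM records are loaded and classified by flag", {
  fx <- local_sam_fixture(n_reads = 200,
                          bias = bias_model(incomplete_digest_rate = 0.1))
  al <- load_alignments(fx$sam, fx$inv)
  expect_identical(nrow(al), nrow(fx$lib$reads))
  expect_setequal(unique(al$alignment_type), c("primary", "supplementary"))
  n_supp <- sum(fx$lib$reads$supplementary)
  expect_identical(sum(al$alignment_type == "supplementary"), n_supp)
  expect_true(all(al$ref_start < al$ref_end))
})

test_that("an empty SAM body yields zero alignments", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:f1\tLN:100"), sam)
  expect_identical(nrow(load_alignments(sam)), 0L)
})

test_that("alignments to unknown references are flagged unassigned", {
  fx <- local_sam_fixture(n_reads = 50)
  inv_drop <- fx$inv[-1, ]
  class(inv_drop) <- class(fx$inv)
  expect_warning(al <- load_alignments(fx$sam, inv_drop), "unassigned")
  expect_true(any(al$unassigned))
  expect_false(any(filter_reads(al)$unassigned))
})

test_that("reads with supplementary alignments are removed entirely", {
  reads <- data.frame(
    read_id = c("r1", "r2", "r2"),
    fragment_id = c("f1", "f1", "f2"),
    read_length = c(100L, 200L, 200L),
    alignment_type = c("primary", "primary", "supplementary"),
    ref_start = 0L, ref_end = 100L, unassigned = FALSE,
    stringsAsFactors = FALSE)
  kept <- filter_reads(reads)
  expect_identical(kept$read_id, "r1")
  # projection: filtering twice equals filtering once
  expect_identical(filter_reads(kept), kept)
  # all-supplementary input leaves nothing to count
  expect_identical(nrow(filter_reads(reads[reads$read_id == "r2", ])), 0L)
})

test_that("a read with two primary alignments is malformed input", {
  reads <- data.frame(
    read_id = c("r1", "r1"), fragment_id = c("f1", "f2"),
    read_length = 100L, alignment_type = "primary",
    ref_start = 0L, ref_end = 100L, unassigned = FALSE,
    stringsAsFactors = FALSE)
  expect_error(filter_reads(reads), "r1")
})

test_that("chimera filtering matches the simulation truth", {
  fx <- local_sam_fixture(n_reads = 1000,
                          bias = bias_model(incomplete_digest_rate = 0.05))
  al <- load_alignments(fx$sam, fx$inv)
  kept <- filter_reads(al)
  truth_non_chimeric <- length(unique(
    fx$lib$reads$read_id[!fx$lib$reads$is_chimeric]))
  expect_identical(nrow(kept), truth_non_chimeric)
})

test_that("normalizations follow their definitions and sum correctly", {
  tab <- make_count_table(c(1, 1, 2), c(500, 1000, 2000))
  expect_equal(tab$freq_pct, c(25, 25, 50))
  expect_equal(sum(tab$freq_pct), 100, tolerance = 1e-12)

  # c = 10, L = 1000, total 1e6 reads -> rpm = 10, rpkm = 10
  fx <- local_sam_fixture(n_reads = 400)
  al <- filter_reads(load_alignments(fx$sam, fx$inv))
  tab2 <- count_and_normalize(al, fx$inv)
  expect_equal(sum(tab2$freq_pct), 100, tolerance = 1e-9)
  expect_equal(sum(tab2$rpm), 1e6, tolerance = 1e-6)
  expect_equal(tab2$rpkm * tab2$length / 1000, tab2$rpm, tolerance = 1e-12)
  expect_true(all(tab2$count >= 0))
  # naive recount oracle: independent tabulation of the truth
  recount <- sapply(fx$inv$fragment_id,
                    function(f) sum(al$fragment_id == f))
  expect_identical(tab2$count, as.integer(unname(recount)))
  # zero-read fragments are retained
  expect_identical(nrow(tab2), nrow(fx$inv))
})

test_that("zero total reads make normalization fail loudly", {
  fx <- local_sam_fixture(n_reads = 10)
  al <- filter_reads(load_alignments(fx$sam, fx$inv))
  expect_error(count_and_normalize(al[0, ], fx$inv), "zero")
})

test_that("equimolar unbiased counts stay within binomial sampling error", {
  set.seed(77)
  nf <- 80
  lens <- rep(1000L, nf)
  inv <- data.frame(fragment_id = sprintf("f%02d", 1:nf),
                    genome_id = "sim", start = cumsum(c(0L, lens[-nf])),
                    end = cumsum(lens), length = lens,
                    sequence = vapply(1:nf, function(i)
                      paste(sample(c("A","C","G","T"), 1000, TRUE),
                            collapse = ""), character(1)),
                    end_bases_3p = "CG", end_dinucs_3p = "AG/CT",
                    copy_count = 1L, stringsAsFactors = FALSE)
  attr(inv, "genome_length") <- sum(lens)
  class(inv) <- c("fragment_inventory", "data.frame")
  b <- bias_model(end_efficiency_3p = c(A = 1, C = 1, G = 1, T = 1))
  lib <- simulate_library(inv, b, 5e4, seed = 3)
  tab <- count_and_normalize(
    data.frame(read_id = lib$reads$read_id,
               fragment_id = lib$reads$fragment_id,
               read_length = lib$reads$read_length,
               stringsAsFactors = FALSE), inv)
  p <- 1 / nf
  sd3 <- 3 * sqrt(p * (1 - p) / 5e4) * 100
  expect_true(all(abs(tab$freq_pct - 100 * p) < sd3 + 1e-9))
})

test_that("observed lengths equal expected lengths for intact libraries", {
  fx <- local_sam_fixture(n_reads = 300)   # no shearing in default bias
  al <- filter_reads(load_alignments(fx$sam, fx$inv))
  tab <- count_and_normalize(al, fx$inv)
  seen <- !is.na(tab$mean_obs_len)
  expect_true(any(seen))
  expect_equal(tab$mean_obs_len[seen], as.numeric(tab$length[seen]))
  lc <- length_concordance(tab)
  expect_false(any(lc$shear_suspect))
})

test_that("shearing caps mean observed length while the median resists", {
  g <- simulate_genome(60000, seed = 21, topology = "circular")
  inv <- collapse_unique(digest(g, get_enzyme("PshAI")))
  rate <- 1e-3                      # mean intact length 1 kb
  lib <- simulate_library(inv, bias_model(shear_rate = rate), 4000, seed = 22)
  al <- data.frame(read_id = lib$reads$read_id,
                   fragment_id = lib$reads$fragment_id,
                   read_length = lib$reads$read_length,
                   stringsAsFactors = FALSE)
  tab <- count_and_normalize(al, inv)
  long <- tab$length > 5 / rate & !is.na(tab$mean_obs_len)
  if (any(long)) {
    expect_true(all(tab$mean_obs_len[long] < tab$length[long]))
    # plateau: mean observed length stops tracking expected length
    expect_lt(max(tab$mean_obs_len[long]), 3 / rate)
  }
  short <- tab$length < 0.2 / rate & !is.na(tab$median_obs_len) &
    tab$count >= 10
  if (any(short)) {
    expect_true(all(tab$median_obs_len[short] >= 0.8 * tab$length[short]))
  }
})

test_that("coverage profiles are flat for intact reads and tile correctly", {
  inv <- data.frame(fragment_id = "f1", genome_id = "g", start = 0L,
                    end = 1000L, length = 1000L,
                    sequence = strrep("ACGT", 250), end_bases_3p = "CG",
                    end_dinucs_3p = "AG/CT", copy_count = 1L,
                    stringsAsFactors = FALSE)
  one <- data.frame(read_id = "r1", fragment_id = "f1", read_length = 1000L,
                    ref_start = 0L, ref_end = 1000L, stringsAsFactors = FALSE)
  prof <- coverage_profile(one, inv, n_bins = 10)
  expect_equal(prof$depth_norm, rep(1, 10))

  halves <- data.frame(read_id = c("a", "b"), fragment_id = "f1",
                       read_length = 500L, ref_start = c(0L, 500L),
                       ref_end = c(500L, 1000L), stringsAsFactors = FALSE)
  prof2 <- coverage_profile(halves, inv, n_bins = 10)
  expect_equal(prof2$depth_norm, rep(1, 10))

  none <- one[0, ]
  prof3 <- coverage_profile(none, inv, n_bins = 5)
  expect_equal(prof3$depth, rep(0, 5))
})

test_that("shearing plus length selection produces the mid-fragment coverage dip", {
  # one long fragment well past the efficiency peak: its broken molecules'
  # middle pieces are the longest and are lost preferentially
  set.seed(41)
  lens <- c(18000L, 2500L)
  inv <- data.frame(fragment_id = c("long", "short"), genome_id = "g",
                    start = c(0L, 18000L), end = c(18000L, 20500L),
                    length = lens,
                    sequence = vapply(lens, function(L)
                      paste(sample(c("A","C","G","T"), L, TRUE),
                            collapse = ""), character(1)),
                    end_bases_3p = "CG", end_dinucs_3p = "AG/CT",
                    copy_count = 1L, stringsAsFactors = FALSE)
  attr(inv, "genome_length") <- 20500L
  class(inv) <- c("fragment_inventory", "data.frame")
  b <- bias_model(length_efficiency = "short_prep", shear_rate = 1e-4)
  lib <- simulate_library(inv, b, 8000, seed = 42)
  reads <- lib$reads[lib$reads$fragment_id == "long", ]
  names(reads)[names(reads) == "start"] <- "ref_start"
  names(reads)[names(reads) == "end"] <- "ref_end"
  big <- inv[1, , drop = FALSE]
  class(big) <- class(inv)
  prof <- coverage_profile(reads, big, n_bins = 10, normalize = "fragment")
  centre <- mean(prof$depth[4:7])
  ends <- mean(prof$depth[c(1, 10)])
  expect_lt(centre, ends)
})

test_that("threshold summaries count strictly-above fragments and rank the top 20", {
  tab <- make_count_table(c(50, 49, 1), c(100, 200, 300))
  s <- threshold_summary(tab)
  expect_equal(unname(s$n_above), c(3, 3, 3))
  expect_true(s$top_truncated)

  tab2 <- make_count_table(c(rep(0, 24), 7), c(101:125))
  s2 <- threshold_summary(tab2)
  expect_equal(unname(s2$n_above), c(1, 1, 1))
  expect_equal(s2$max_pct, 100)

  # brute-force recount on a random table
  set.seed(5)
  counts <- rpois(40, 20)
  tabr <- make_count_table(counts, sample(200:9000, 40))
  sr <- threshold_summary(tabr)
  f <- 100 * counts / sum(counts)
  for (k in seq_along(c(0.001, 0.01, 0.1))) {
    expect_equal(unname(sr$n_above[k]),
                 sum(f > c(0.001, 0.01, 0.1)[k]))
  }
  ord <- order(-tabr$freq_pct, -tabr$length)
  expect_equal(sr$top_median_length, median(tabr$length[ord[1:20]]))
})

test_that("count ratios are one for identical tables and scale-invariant", {
  set.seed(9)
  counts <- rpois(30, 50) + 1
  lens <- sample(300:8000, 30)
  a <- make_count_table(counts, lens)
  b <- make_count_table(counts, lens)
  cr <- count_ratio(a, b)
  expect_equal(cr$per_fragment$ratio, rep(1, 30))
  scaled <- make_count_table(counts * 17, lens)
  cr2 <- count_ratio(scaled, b)
  expect_equal(cr2$per_fragment$ratio, rep(1, 30), tolerance = 1e-12)
  expect_error(count_ratio(a, make_count_table(counts, lens,
                                               ids = sprintf("x%d", 1:30))),
               "inventory")
})

test_that("an injected length-dependent ratio is recovered from binned output", {
  set.seed(10)
  nf <- 200
  lens <- sample(seq(500, 15000, by = 50), nf, replace = TRUE)
  base <- rep(1000, nf)
  r_true <- 1 + lens / 20000
  ca <- rmultinom(1, 2e5, base * r_true)[, 1]
  cb <- rmultinom(1, 2e5, base)[, 1]
  keep <- cb > 0
  a <- make_count_table(ca[keep], lens[keep])
  b <- make_count_table(cb[keep], lens[keep])
  cr <- count_ratio(a, b, bin_width = 2000)
  # normalization rescales all ratios by a common constant; compare shapes
  got <- cr$binned$mean_ratio / mean(cr$binned$mean_ratio)
  centers <- (cr$binned$bin_lo + cr$binned$bin_hi) / 2
  want <- (1 + centers / 20000)
  want <- want / mean(want)
  expect_lt(max(abs(got - want) / want), 0.1)
})

test_that("count tables round-trip through TSV", {
  fx <- local_sam_fixture(n_reads = 100)
  al <- filter_reads(load_alignments(fx$sam, fx$inv))
  tab <- count_and_normalize(al, fx$inv)
  tsv <- tempfile(fileext = ".tsv")
  write_count_table(tab, tsv)
  back <- read_count_table(tsv)
  expect_identical(back$fragment_id, tab$fragment_id)
  expect_identical(back$count, tab$count)
  expect_equal(back$freq_pct, tab$freq_pct)
  expect_identical(attr(back, "total_reads"), nrow(al))
})
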