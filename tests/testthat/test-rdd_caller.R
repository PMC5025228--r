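# Pileup construction and RDD calling.

make_perfect_reads <- function(refseq, n_each = 10L) {
  rl <- nchar(refseq)
  data.frame(flag = rep(c(0L, 16L), each = n_each), pos = 1L, mapq = 60L,
             cigar = paste0(rl, "M"), seq = refseq,
             qual = strrep("F", rl))
}

test_that("perfect reads give uniform strand-balanced pileups", {
  set.seed(3)
  ref <- make_reference(100, seed = 3, name = "chrM")
  sam <- write_test_sam(tempfile(fileext = ".sam"), "chrM", 100,
                        make_perfect_reads(ref[[1]]))
  pu <- build_pileup(sam, ref, edge_trim = 0L)
  expect_equal(nrow(pu), 100L)
  expect_true(all(pu$coverage == 20L))
  calls <- call_rdd(pu, min_coverage = 10L)
  expect_true(all(abs(1 - calls$rdd_level - 1) < 1e-12))
  expect_false(any(calls$is_rdd))  # no secondary base anywhere
})

test_that("base quality, MAPQ and edge trimming exclude calls", {
  ref <- c(chrM = strrep("A", 50))
  rl <- 30L
  mk <- function(seq, qual = strrep("F", rl), mapq = 60L, pos = 1L)
    data.frame(flag = 0L, pos = pos, mapq = mapq, cigar = paste0(rl, "M"),
               seq = seq, qual = qual)
  mismatch_at <- function(i) {
    s <- strsplit(strrep("A", rl), "")[[1]]; s[i] <- "T"
    paste(s, collapse = "")
  }
  # mismatch 2 nt from the 3' end is trimmed away at edge_trim = 5
  sam <- write_test_sam(tempfile(fileext = ".sam"), "chrM", 50,
                        mk(mismatch_at(rl - 2L)))
  pu5 <- build_pileup(sam, ref, edge_trim = 5L)
  expect_equal(sum(pu5$T_plus), 0L)
  pu0 <- build_pileup(sam, ref, edge_trim = 0L)
  expect_equal(sum(pu0$T_plus), 1L)
  # low base quality excluded
  lowq <- strrep("F", rl); substr(lowq, 15, 15) <- "#"
  sam2 <- write_test_sam(tempfile(fileext = ".sam"), "chrM", 50,
                         mk(strrep("A", rl), qual = lowq))
  pu2 <- build_pileup(sam2, ref, min_base_q = 30L, edge_trim = 0L)
  expect_equal(pu2$coverage[15], 0L)
  expect_equal(pu2$coverage[16], 1L)
  # low MAPQ excludes the whole read
  sam3 <- write_test_sam(tempfile(fileext = ".sam"), "chrM", 50,
                         mk(strrep("A", rl), mapq = 5L))
  pu3 <- build_pileup(sam3, ref, min_mapq = 20L, edge_trim = 0L)
  expect_true(all(pu3$coverage == 0L))
})

test_that("deletions are reported separately, not in base counts", {
  ref <- c(chrM = strrep("A", 30))
  rd <- data.frame(flag = 0L, pos = 1L, mapq = 60L, cigar = "10M5D10M",
                   seq = strrep("A", 20), qual = strrep("F", 20))
  pu <- build_pileup(write_test_sam(tempfile(fileext = ".sam"), "chrM", 30,
                                    rd), ref, edge_trim = 0L)
  expect_equal(pu$coverage[12], 0L)
  expect_equal(pu$del[12], 1L)
  expect_equal(pu$coverage[16], 1L)
})

test_that("filter verdicts are exact at every threshold boundary", {
  col_with <- function(cov_plus, cov_minus, sec_plus, sec_minus) {
    pileup_from_counts(
      pos = 1L, ref_base = "A",
      plus = c(cov_plus - sec_plus, 0L, 0L, sec_plus),
      minus = c(cov_minus - sec_minus, 0L, 0L, sec_minus))
  }
  # filter A boundary at 1000 reads
  r999 <- call_rdd(col_with(500L, 499L, 25L, 25L))
  expect_false(r999$pass_filter_A); expect_true(r999$pass_filter_B)
  expect_false(r999$is_rdd)
  r1000 <- call_rdd(col_with(500L, 500L, 25L, 25L))
  expect_true(r1000$pass_filter_A); expect_true(r1000$is_rdd)
  # total-fraction boundary at 1.6% (10000 reads)
  r159 <- call_rdd(col_with(5000L, 5000L, 80L, 79L))
  expect_false(r159$pass_filter_B)
  r160 <- call_rdd(col_with(5000L, 5000L, 80L, 80L))
  expect_true(r160$pass_filter_B)
  # per-strand boundary at 0.8% with the total held at 1.6%
  r_strand_fail <- call_rdd(col_with(5000L, 5000L, 121L, 39L))
  expect_equal(r_strand_fail$secondary_fraction_total, 0.016)
  expect_false(r_strand_fail$pass_filter_B)
  r_strand_pass <- call_rdd(col_with(5000L, 5000L, 120L, 40L))
  expect_true(r_strand_pass$pass_filter_B)
  # worked example: coverage 2000, 3% per strand
  r3 <- call_rdd(col_with(1000L, 1000L, 30L, 30L))
  expect_true(r3$is_rdd)
  expect_equal(r3$rdd_level, 0.03)
  # example: 2.0% total but 0.5% on the minus strand
  rX <- call_rdd(col_with(2500L, 2500L, 88L, 12L))
  expect_equal(rX$secondary_fraction_total, 0.02)
  expect_false(rX$pass_filter_B)
  # edge flag vetoes the call
  rE <- call_rdd(col_with(1000L, 1000L, 30L, 30L), edge_flags = TRUE)
  expect_false(rE$is_rdd)
  # empty input -> empty output
  expect_equal(nrow(call_rdd(pileup_from_counts(integer(0), character(0),
                                                matrix(0, 0, 4),
                                                matrix(0, 0, 4)))), 0L)
})

test_that("verdicts are invariant under strand swapping", {
  set.seed(19)
  for (i in 1:10) {
    plus <- rmultinom(1, sample(500:3000, 1), c(0.9, 0.02, 0.03, 0.05))
    minus <- rmultinom(1, sample(500:3000, 1), c(0.92, 0.01, 0.02, 0.05))
    a <- call_rdd(pileup_from_counts(1L, "A", t(plus), t(minus)))
    b <- call_rdd(pileup_from_counts(1L, "A", t(minus), t(plus)))
    expect_equal(a$is_rdd, b$is_rdd)
    expect_equal(a$pass_filter_A, b$pass_filter_A)
    expect_equal(a$pass_filter_B, b$pass_filter_B)
    expect_equal(a$rdd_level, b$rdd_level)
  }
})

test_that("edge-bias test flags edge-clustered variants only", {
  eb <- edge_bias_test(rep(c(0, 1, 2, 3, 4), 10), read_length = 100,
                       window = 5)
  expect_true(eb$flag)
  expect_lt(eb$p, 1e-10)
  set.seed(91)
  uniform <- sample(0:49, 60, replace = TRUE)
  expect_false(edge_bias_test(uniform, read_length = 100, window = 5)$flag)
  none <- edge_bias_test(integer(0), read_length = 100, window = 5)
  expect_false(none$flag)
  expect_equal(none$p, 1)
  expect_error(edge_bias_test(1, read_length = 10, window = 5), "window")
})

test_that("variant read offsets are extracted for the edge test", {
  ref <- c(chrM = strrep("A", 60))
  rl <- 20L
  s <- strsplit(strrep("A", rl), "")[[1]]
  s[3] <- "T"  # 2 from the 5' end of a read starting at 9 -> site 11
  rd <- data.frame(flag = 0L, pos = 9L, mapq = 60L,
                   cigar = paste0(rl, "M"),
                   seq = paste(s, collapse = ""), qual = strrep("F", rl))
  sam <- write_test_sam(tempfile(fileext = ".sam"), "chrM", 60, rd)
  offs <- variant_read_offsets(sam, site = 11L, variant_base = "T")
  expect_equal(offs, 2L)
})

test_that("the m1A signature combines mismatch rate and coverage drop", {
  n <- 51L
  plus <- matrix(rep(c(500L, 0L, 0L, 0L), each = n), ncol = 4)
  minus <- plus
  site <- 26L
  # site: A 25%, T 60%, G 12%, C 3% of 800; flanks at 1000
  plus[site, ] <- c(100L, 12L, 48L, 240L)   # A C G T
  minus[site, ] <- c(100L, 12L, 48L, 240L)
  pu <- pileup_from_counts(1:n, rep("A", n), plus, minus)
  sig <- m1a_signature(pu, site, flank = 25L)
  expect_equal(sig$mismatch_rate, 0.72)
  expect_equal(sig$coverage_drop, 0.2)
  expect_equal(sig$combined, 0.92)
  # unmodified site: score 0
  pu0 <- pileup_from_counts(1:n, rep("A", n),
                            matrix(rep(c(500L, 0L, 0L, 0L), each = n),
                                   ncol = 4),
                            matrix(rep(c(500L, 0L, 0L, 0L), each = n),
                                   ncol = 4))
  sig0 <- m1a_signature(pu0, site, flank = 25L)
  expect_equal(sig0$combined, 0)
  expect_error(m1a_signature(pu, site, flank = 5L), "flank")
  puC <- pu; puC$ref_base[site] <- "C"
  expect_error(m1a_signature(puC, site), "not A")
})

test_that("two-sample chi-square equals the first-principles oracle", {
  res <- compare_samples(c(750, 250), c(900, 100))
  expect_equal(res$chi2, oracle_chi2(750, 250, 900, 100), tolerance = 1e-9)
  expect_lt(res$p, 1e-10)
  same <- compare_samples(c(750, 250), c(750, 250))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  unit <- compare_samples(c(1, 0), c(0, 1))
  expect_equal(unit$chi2, 2.0)
  expect_equal(unit$method, "fisher")  # expected counts below 5
  # exhaustive small tables
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      next
    expect_equal(compare_samples(c(a, b), c(cc, d))$chi2,
                 oracle_chi2(a, b, cc, d), tolerance = 1e-9)
  }
  expect_error(compare_samples(c(0, 0), c(0, 0)), "empty|margin")
  expect_error(compare_samples(c(1, 0), c(2, 0)), "margin")
})

test_that("frequency tables are percentages of pooled coverage", {
  col <- pileup_from_counts(1L, "A", c(250L, 25L, 75L, 150L),
                            c(250L, 25L, 75L, 150L))
  expect_equal(frequency_table(col[1, ]),
               c(A = 50, C = 5, G = 15, T = 30))
  single <- pileup_from_counts(1L, "G", c(0L, 0L, 7L, 0L),
                               c(0L, 0L, 0L, 0L))
  expect_equal(unname(frequency_table(single[1, ])["G"]), 100)
  zero <- pileup_from_counts(1L, "A", rep(0L, 4), rep(0L, 4))
  expect_error(frequency_table(zero[1, ]), "zero coverage")
})
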