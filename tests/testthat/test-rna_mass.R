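test_that("masses of the published fragments are reproduced", {
  # methylated 12-mer, 16S 939-950
  m12 <- oligo_mass("UUCCUUAAm1AUAGp")
  expect_equal(round(m12, 1), 3833.5, tolerance = 0)
  expect_equal(mz(m12, 5), 765.7, tolerance = 0.05)
  # RNase A tetramers, 16S 945-948
  expect_equal(oligo_mass("AAm1AUp"), 1325.21, tolerance = 0.01)
  expect_equal(mz(oligo_mass("AAm1AUp"), 2), 661.60, tolerance = 0.01)
  expect_equal(mz(oligo_mass("AAm1AUp"), 1), 1324.20, tolerance = 0.01)
  expect_equal(oligo_mass("AAAUp"), 1311.19, tolerance = 0.01)
  expect_equal(mz(oligo_mass("AAAUp"), 2), 654.59, tolerance = 0.01)
  # Gm1145 dimer
  expect_equal(mz(oligo_mass("GmGp"), 1), 721.1, tolerance = 0.05)
  # mononucleotide sanity value
  expect_equal(oligo_mass("Ap"), 347.063, tolerance = 0.001)
})

test_that("oligo mass agrees with the elemental-composition oracle", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    fp <- sample(c("OH", "P"), 1)
    tp <- sample(c("OH", "P", "cyclicP"), 1)
    x <- random_mod_rna(n, five_prime = fp, three_prime = tp)
    nm <- sum(!is.na(x$residues$base_mod)) + sum(x$residues$sugar_2ome)
    expect_equal(oligo_mass(x),
                 oracle_oligo_mass(x$residues$base, nm, fp, tp),
                 tolerance = 1e-6)
  }
})

test_that("methyl additivity holds anywhere in a sequence", {
  set.seed(31)
  for (i in 1:20) {
    x <- random_mod_rna(sample(2:12, 1), p_m1a = 0, p_2ome = 0)
    j <- sample(seq_len(length(x)), 1)
    y <- x
    if (x$residues$base[j] == "A") {
      y$residues$base_mod[j] <- "m1A"
    } else {
      y$residues$sugar_2ome[j] <- TRUE
    }
    expect_equal(oligo_mass(y) - oligo_mass(x), 14.01565)
  }
})

test_that("m/z decreases strictly with charge and matches the formula", {
  m <- oligo_mass("UUCCUUAAm1AUAGp")
  zs <- 1:6
  v <- vapply(zs, function(z) mz(m, z), 0)
  expect_true(all(diff(v) < 0))
  expect_equal(mz(3833.493, 5), (3833.493 - 5 * 1.0072765) / 5)
  expect_error(mz(1, 5), "nonpositive")
})

test_that("RNase T1 and RNase A digestion follow base and 2'-O-methyl rules", {
  # RNase A on the methylated 12-mer: tetramer 945-948 among the products
  frags <- digest(parse_mod_string("UUCCUUAAm1AUAGp", start_pos = 939),
                  "RNaseA")
  shorthand <- vapply(frags, function(f) render_mod_string(f$seq), "")
  expect_equal(shorthand,
               c("Up", "Up", "Cp", "Cp", "Up", "Up", "AAm1AUp", "AGp"))
  tet <- frags[[7]]
  expect_equal(c(tet$start, tet$end), c(945L, 948L))

  # 2'-O-methyl blocks cleavage: the di-methylated 11-mer survives T1 intact
  frags2 <- digest("UUUmGmUUCAACGp", "RNaseT1")
  expect_equal(length(frags2), 1L)
  expect_equal(render_mod_string(frags2[[1]]$seq), "UUUmGmUUCAACGp")

  # no G: nothing to cut
  frags3 <- digest("AAAA", "RNaseT1")
  expect_equal(length(frags3), 1L)
  expect_equal(render_mod_string(frags3[[1]]$seq), "AAAA")

  # terminal chemistry: internal products 5'-OH/3'-P, parent termini kept
  fr <- digest(parse_mod_string("AGCGA"), "RNaseT1")
  expect_equal(vapply(fr, function(f) f$seq$three_prime, ""),
               c("P", "P", "OH"))
  frc <- digest(parse_mod_string("AGCGA"), "RNaseT1", cyclic = TRUE)
  expect_equal(frc[[1]]$seq$three_prime, "cyclicP")
})

test_that("digestion fragments tile the parent and conserve mass", {
  set.seed(41)
  for (i in 1:20) {
    x <- random_mod_rna(sample(5:25, 1),
                        three_prime = sample(c("OH", "P"), 1))
    for (enz in c("RNaseT1", "RNaseA")) {
      fr <- digest(x, enz)
      expect_equal(paste(vapply(fr, function(f) as.character(f$seq), ""),
                         collapse = ""), as.character(x))
      spans <- t(vapply(fr, function(f) c(unname(f$start), unname(f$end)),
                        c(0L, 0L)))
      expect_equal(spans[1, 1], x$start_pos)
      expect_equal(spans[nrow(spans), 2], x$start_pos + length(x) - 1L)
      if (nrow(spans) > 1)
        expect_equal(spans[-1, 1], spans[-nrow(spans), 2] + 1L)
      masses <- vapply(fr, function(f) oligo_mass(f$seq), 0)
      expect_equal(sum(masses) - (length(fr) - 1) * 18.010565,
                   oligo_mass(x), tolerance = 1e-6)
    }
  }
})

test_that("missed cleavages emit flagged unions of adjacent fragments", {
  fr <- digest("AGCGA", "RNaseT1", missed_cleavages = 1L)
  sh <- vapply(fr, function(f) render_mod_string(f$seq), "")
  ms <- vapply(fr, function(f) f$missed, 0L)
  expect_true("AGCGp" %in% sh[ms == 1])
  expect_true("CGAp" %in% sh[ms == 1] || "CGA" %in% sh[ms == 1])
  expect_equal(sort(sh[ms == 0]), sort(c("AGp", "CGp", "A")))
})

test_that("CID series obey the complementary-pair sum rules", {
  # frozen derived values for the methylated tetramer
  s <- cid_series("AAm1AUp", series = c("c", "y", "w", "a", "a-B"),
                  max_charge = 1)
  pick <- function(ser, idx)
    s$neutral_mass[s$series == ser & s$index == idx]
  expect_equal(pick("c", 1), 347.063, tolerance = 0.001)
  expect_equal(pick("y", 3), 996.156, tolerance = 0.001)
  expect_equal(pick("w", 3), 1076.123, tolerance = 0.001)
  expect_equal(pick("c", 1) + pick("y", 3), 1343.22, tolerance = 0.01)

  set.seed(57)
  h2o <- 18.010565
  for (i in 1:15) {
    x <- random_mod_rna(sample(2:10, 1),
                        five_prime = sample(c("OH", "P"), 1))
    m <- oligo_mass(x)
    ss <- cid_series(x, series = c("c", "y", "w", "a"), max_charge = 1)
    n <- length(x)
    for (k in 1:(n - 1)) {
      ci <- ss$neutral_mass[ss$series == "c" & ss$index == k]
      yk <- ss$neutral_mass[ss$series == "y" & ss$index == n - k]
      ai <- ss$neutral_mass[ss$series == "a" & ss$index == k]
      wk <- ss$neutral_mass[ss$series == "w" & ss$index == n - k]
      expect_equal(ci + yk, m + h2o, tolerance = 1e-6)
      expect_equal(ai + wk, m + h2o, tolerance = 1e-6)
    }
  }
})

test_that("a-B ions subtract the (methylated) nucleobase", {
  s <- cid_series("AAm1AUp", series = c("a", "a-B"), max_charge = 1)
  a3 <- s$neutral_mass[s$series == "a" & s$index == 3]
  ab3 <- s$neutral_mass[s$series == "a-B" & s$index == 3]
  expect_equal(a3 - ab3, 149.07015)  # 1-methyladenine, not adenine
  a1 <- s$neutral_mass[s$series == "a" & s$index == 1]
  ab1 <- s$neutral_mass[s$series == "a-B" & s$index == 1]
  expect_equal(a1 - ab1, 135.05450)
})

test_that("ion matching pairs observations within tolerance only", {
  m12 <- oligo_mass("UUCCUUAAm1AUAGp")
  precursor <- data.frame(series = "M", index = 0L, charge = 5L,
                          neutral_mass = m12, mz = mz(m12, 5))
  obs <- data.frame(mz = 765.69, charge = 5L)
  res <- match_ions(obs, precursor, tol_ppm = 20)
  expect_true(res$matched)
  expect_lt(abs(res$ppm), 20)

  expect_error(match_ions(obs, precursor[0, ]), "empty candidate")

  cand <- cid_series("AAm1AUp", max_charge = 1)
  far <- match_ions(data.frame(mz = 500.0, charge = 1L), cand, tol_ppm = 10)
  expect_false(far$matched)
})
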