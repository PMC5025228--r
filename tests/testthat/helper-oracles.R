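# Shared fixtures and independent oracles.

# Published sequences used as fixtures (all printed in the study's methods):
# the four T7 template assembly oligos and the two 90-nt MAGE editing oligos.
T7_TEMPLATE_OLIGOS <- c(
  "gctaatacgactcactataggcaccgcctgcccagtgacacatgtttaacggc",
  "gtgacacatgtttaacggccgcggtaccctaaccgtgcaaaggtagcataatcac",
  "gtgcaaaggtagcataatcacttgttccttaaatagggacctgtatgaatggctccacgagggtt",
  "aaccctcgtggagccattc"
)

MAGE_OLIGO_A <- paste0(  # G-to-A edit; oligo carries T at offset 46
  "GTGGAGACAGCCTGGCCATCATTACGCCATTCGTGCAGGTCGGAA", "T",
  "TTACCCGACAAGGAATTTCGCTACCTTAGGACCGTTATAGTTAC")
MAGE_OLIGO_T <- paste0(  # G-to-T edit; oligo carries A at offset 46
  "GTGGAGACAGCCTGGCCATCATTACGCCATTCGTGCAGGTCGGAA", "A",
  "TTACCCGACAAGGAATTTCGCTACCTTAGGACCGTTATAGTTAC")

# Monoisotopic oligo mass oracle built from elemental compositions, fully
# independent of the package's residue-mass table.
ATOM <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
          O = 15.9949146196, P = 30.97376163)
NMP_FORMULA <- list(  # nucleoside monophosphates
  A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
  C = c(C = 9, H = 14, N = 3, O = 8, P = 1),
  G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
  U = c(C = 9, H = 13, N = 2, O = 9, P = 1)
)
.formula_mass <- function(f) sum(ATOM[names(f)] * f)

# bases: character vector; n_methyl: total methyl count; termini as in the
# package. Linear 5'-OH/3'-P oligo = sum(NMP) - (n-1) H2O; other termini
# adjusted by HPO3 / H2O.
oracle_oligo_mass <- function(bases, n_methyl = 0,
                              five_prime = "OH", three_prime = "P") {
  h2o <- .formula_mass(c(H = 2, O = 1))
  hpo3 <- .formula_mass(c(H = 1, P = 1, O = 3))
  m <- sum(vapply(bases, function(b) .formula_mass(NMP_FORMULA[[b]]), 0)) -
    (length(bases) - 1) * h2o + n_methyl * .formula_mass(c(C = 1, H = 2))
  if (five_prime == "OH" && three_prime == "P") m
  else if (five_prime == "P" && three_prime == "OH") m
  else if (five_prime == "OH" && three_prime == "OH") m - hpo3
  else if (five_prime == "OH" && three_prime == "cyclicP") m - h2o
  else if (five_prime == "P" && three_prime == "P") m + hpo3
  else if (five_prime == "P" && three_prime == "cyclicP") m + hpo3 - h2o
  else stop("unsupported termini in oracle")
}

# First-principles Pearson chi-square on a 2x2 table.
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  (n * (a * d - b * c)^2) /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Random mod_rna generator for property tests.
random_mod_rna <- function(n, p_m1a = 0.2, p_2ome = 0.2,
                           five_prime = "OH", three_prime = "P") {
  base <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  bm <- ifelse(base == "A" & runif(n) < p_m1a, "m1A", NA_character_)
  so <- runif(n) < p_2ome
  mod_rna(base, bm, so, five_prime = five_prime, three_prime = three_prime)
}

# Minimal SAM writer for hand-built alignments.
write_test_sam <- function(path, ref_name, ref_len, reads) {
  # reads: data.frame with flag, pos, mapq, cigar, seq, qual
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  reads <- reads[order(reads$pos), , drop = FALSE]
  recs <- sprintf("r%03d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(reads)), reads$flag, ref_name, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(header, recs), path)
  path
}
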