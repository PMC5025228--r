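# Strand-aware pileup construction from aligned reads and RDD calling with
# the coverage filter (filter A, >= 1000 high-quality reads), the per-strand
# secondary-fraction filter (filter B, >= 1.6% total and >= 0.8% on each
# strand) and a read-edge artifact test; m1A signature scoring and
# two-sample enrichment testing.

# ---- SAM ingestion ---------------------------------------------------------

# Parse a SAM/BAM into a per-read list of aligned fields. SAM text is
# converted with Rsamtools::asBam; the CIGAR walk is done here because per
# call we need the distance from the nearer read end (edge trimming), which
# ready-made pileup engines do not expose.
.read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  res$seq <- as.character(res$seq)
  res$qual <- as.character(res$qual)
  res$rname <- as.character(res$rname)
  res
}

# Expand one CIGAR into per-aligned-base vectors.
# Returns ref positions, query indices for ops consuming both, plus deletion
# ref positions. Supports M/=/X, I, S, D, N, H, P.
.cigar_walk <- function(cigar, pos) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cigar)
  rpos <- integer(0); qidx <- integer(0); del <- integer(0)
  r <- pos; q <- 1L
  for (k in seq_along(ops)) {
    L <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      rpos <- c(rpos, r:(r + L - 1L))
      qidx <- c(qidx, q:(q + L - 1L))
      r <- r + L; q <- q + L
    } else if (op %in% c("I", "S")) {
      q <- q + L
    } else if (op %in% c("D", "N")) {
      if (op == "D") del <- c(del, r:(r + L - 1L))
      r <- r + L
    }  # H, P: no consumption
  }
  list(rpos = rpos, qidx = qidx, del = del, qlen = q - 1L)
}

#' Build a strand-aware, quality-filtered pileup from aligned reads
#'
#' Tallies per-position, per-strand, per-base counts over a reference
#' sequence. Calls are excluded when the base quality is below `min_base_q`,
#' the read MAPQ is below `min_mapq`, or the call lies within `edge_trim`
#' bases of either read end (where reverse-transcription and alignment
#' artifacts concentrate). Deletions are excluded from base counts but
#' reported in a separate column.
#'
#' @param sam Path to a SAM (or BAM) file of reads aligned to `reference`.
#' @param reference Path to a FASTA file, or a named character vector of
#'   sequences as returned by [read_fasta()].
#' @param min_base_q Minimum Phred base quality (default 30).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param edge_trim Calls within this many bases of a read end are ignored
#'   (default 5; 0 disables).
#' @return A data.frame of class `mod_pileup` with one row per reference
#'   position: `ref_name`, `pos`, `ref_base`, per-base/strand counts
#'   (`A_plus` .. `T_minus`), `del`, and `coverage` (sum of base counts).
#' @export
build_pileup <- function(sam, reference, min_base_q = 30L, min_mapq = 20L,
                         edge_trim = 5L) {
  ref <- if (is.character(reference) && length(reference) == 1L &&
             file.exists(reference)) read_fasta(reference) else reference
  stopifnot(!is.null(names(ref)))
  aln <- .read_alignments(sam)
  if (length(aln$pos) && !all(stats::na.omit(unique(aln$rname)) %in% names(ref)))
    stop("SAM references sequences absent from the reference FASTA")
  out <- list()
  for (rn in names(ref)) {
    L <- nchar(ref[[rn]])
    counts <- matrix(0L, nrow = 8L, ncol = L,
                     dimnames = list(c("A_plus", "C_plus", "G_plus", "T_plus",
                                       "A_minus", "C_minus", "G_minus",
                                       "T_minus"), NULL))
    delc <- integer(L)
    sel <- which(aln$rname == rn & !is.na(aln$pos) &
                   !bitwAnd(aln$flag, 4L))
    for (i in sel) {
      if (!is.na(aln$mapq[i]) && aln$mapq[i] < min_mapq) next
      w <- .cigar_walk(aln$cigar[i], aln$pos[i])
      if (length(w$del)) {
        dd <- w$del[w$del >= 1L & w$del <= L]
        delc[dd] <- delc[dd] + 1L
      }
      if (!length(w$rpos)) next
      bases <- strsplit(aln$seq[i], "")[[1]]
      quals <- utf8ToInt(aln$qual[i]) - 33L
      qlen <- length(bases)
      # distance from the nearer read end, 0-based (0 at the ends)
      dist_end <- pmin(w$qidx - 1L, qlen - w$qidx)
      keep <- w$rpos >= 1L & w$rpos <= L &
        quals[w$qidx] >= min_base_q &
        dist_end >= edge_trim &
        bases[w$qidx] %in% DNA_BASES
      if (!any(keep)) next
      strand_off <- if (bitwAnd(aln$flag[i], 16L)) 4L else 0L
      row <- match(bases[w$qidx[keep]], DNA_BASES) + strand_off
      idx <- cbind(row, w$rpos[keep])
      counts[idx] <- counts[idx] + 1L
    }
    df <- data.frame(ref_name = rn, pos = seq_len(L),
                     ref_base = strsplit(ref[[rn]], "")[[1]])
    for (r in rownames(counts)) df[[r]] <- counts[r, ]
    df$del <- delc
    df$coverage <- as.integer(colSums(counts))
    out[[rn]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("mod_pileup", "data.frame")
  res
}

#' Construct a pileup table directly from counts
#'
#' Convenience constructor used in tests and for boundary analyses where the
#' exact counts matter more than read-level provenance.
#'
#' @param pos Integer vector of positions.
#' @param ref_base Reference base per position.
#' @param plus,minus Matrices (positions x A,C,G,T) of per-strand counts.
#' @param ref_name Reference name.
#' @return A `mod_pileup` data.frame.
#' @export
pileup_from_counts <- function(pos, ref_base, plus, minus,
                               ref_name = "ref") {
  plus <- matrix(as.integer(plus), ncol = 4L,
                 dimnames = list(NULL, DNA_BASES))
  minus <- matrix(as.integer(minus), ncol = 4L,
                  dimnames = list(NULL, DNA_BASES))
  df <- data.frame(ref_name = rep(ref_name, length(pos)),
                   pos = as.integer(pos),
                   ref_base = as.character(ref_base),
                   A_plus = plus[, "A"], C_plus = plus[, "C"],
                   G_plus = plus[, "G"], T_plus = plus[, "T"],
                   A_minus = minus[, "A"], C_minus = minus[, "C"],
                   G_minus = minus[, "G"], T_minus = minus[, "T"],
                   del = rep(0L, length(pos)))
  df$coverage <- as.integer(rowSums(plus) + rowSums(minus))
  class(df) <- c("mod_pileup", "data.frame")
  df
}

.count_cols <- function(strand = c("both", "plus", "minus")) {
  strand <- match.arg(strand)
  switch(strand,
         both = c(paste0(DNA_BASES, "_plus"), paste0(DNA_BASES, "_minus")),
         plus = paste0(DNA_BASES, "_plus"),
         minus = paste0(DNA_BASES, "_minus"))
}

.base_counts <- function(col, strand = "both") {
  cols <- .count_cols(strand)
  v <- unlist(col[cols])
  out <- tapply(v, sub("_.*", "", cols), sum)[DNA_BASES]
  setNames(as.numeric(out), DNA_BASES)
}

# ---- RDD calling -----------------------------------------------------------

#' Call RNA-DNA differences with coverage and strand-fraction filters
#'
#' A site passes filter A when its quality-filtered coverage is at least
#' `min_coverage` reads, and filter B when the most frequent non-reference
#' base accounts for at least `min_total_fraction` of pooled coverage and at
#' least `min_strand_fraction` of the reads on each strand. A site is an RDD
#' call iff both filters pass and it is not flagged as a read-edge artifact.
#' Defaults are the thresholds used in the original analysis: 1000 reads,
#' 1.6% total, 0.8% per strand.
#'
#' @param columns A `mod_pileup` data.frame.
#' @param min_coverage Filter A threshold (reads).
#' @param min_total_fraction Filter B pooled-fraction threshold.
#' @param min_strand_fraction Filter B per-strand threshold.
#' @param edge_flags Optional logical vector (parallel to `columns`) marking
#'   sites whose variant calls concentrate at read edges (see
#'   [edge_bias_test()]); defaults to no flags.
#' @return A data.frame of class `rdd_calls`: per-site base frequencies,
#'   secondary base and fractions (pooled and per strand), filter verdicts,
#'   `edge_bias_flag`, `rdd_level` (1 - reference-base frequency) and the
#'   final `is_rdd` verdict.
#' @export
call_rdd <- function(columns, min_coverage = 1000L,
                     min_total_fraction = 0.016,
                     min_strand_fraction = 0.008,
                     edge_flags = NULL) {
  n <- nrow(columns)
  if (is.null(edge_flags)) edge_flags <- rep(FALSE, n)
  stopifnot(length(edge_flags) == n)
  if (n == 0L) {
    return(structure(data.frame(), class = c("rdd_calls", "data.frame")))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    col <- columns[i, ]
    cnt <- .base_counts(col, "both")
    cov <- sum(cnt)
    cp <- .base_counts(col, "plus"); cm <- .base_counts(col, "minus")
    covp <- sum(cp); covm <- sum(cm)
    freq <- if (cov > 0) cnt / cov else setNames(rep(NA_real_, 4), DNA_BASES)
    ref <- as.character(col$ref_base)
    nonref <- setdiff(DNA_BASES, ref)
    sec <- if (cov > 0) nonref[which.max(cnt[nonref])] else NA_character_
    sec_tot <- if (cov > 0) unname(cnt[sec] / cov) else NA_real_
    sec_p <- if (covp > 0) unname(cp[sec] / covp) else 0
    sec_m <- if (covm > 0) unname(cm[sec] / covm) else 0
    pass_a <- cov >= min_coverage
    pass_b <- isTRUE(cov > 0 && sec_tot >= min_total_fraction &&
                       sec_p >= min_strand_fraction &&
                       sec_m >= min_strand_fraction)
    rows[[i]] <- data.frame(
      ref_name = col$ref_name, pos = col$pos, ref_base = ref,
      coverage = cov,
      freq_A = unname(freq["A"]), freq_C = unname(freq["C"]),
      freq_G = unname(freq["G"]), freq_T = unname(freq["T"]),
      secondary_base = sec,
      secondary_fraction_total = sec_tot,
      secondary_fraction_plus = sec_p,
      secondary_fraction_minus = sec_m,
      pass_filter_A = pass_a, pass_filter_B = pass_b,
      edge_bias_flag = edge_flags[i],
      rdd_level = if (cov > 0) 1 - unname(freq[ref]) else NA_real_,
      is_rdd = pass_a && pass_b && !edge_flags[i]
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rdd_calls", "data.frame")
  res
}

#' Test whether variant calls concentrate at read edges
#'
#' Automates the manual read-edge inspection: under the null, a variant call
#' lands within `window` bases of either read end with probability
#' `2 * window / read_length`; a one-sided binomial test asks whether the
#' observed edge count exceeds that.
#'
#' @param variant_read_offsets Distances (0-based) of each variant call from
#'   the nearer end of its read.
#' @param read_length Read length (nt).
#' @param window Edge window (nt); must satisfy `window < read_length / 2`.
#' @param alpha Flagging level (default 0.01).
#' @return list with `flag` (logical) and `p` (binomial p-value; 1 when no
#'   variant calls were supplied).
#' @export
edge_bias_test <- function(variant_read_offsets, read_length, window = 5L,
                           alpha = 0.01) {
  if (window >= read_length / 2)
    stop("window must be smaller than read_length / 2")
  n <- length(variant_read_offsets)
  if (n == 0L) return(list(flag = FALSE, p = 1))
  stopifnot(all(variant_read_offsets >= 0),
            all(variant_read_offsets <= read_length / 2))
  k <- sum(variant_read_offsets < window)
  p0 <- 2 * window / read_length
  p <- binom.test(k, n, p = p0, alternative = "greater")$p.value
  list(flag = p < alpha, p = p)
}

#' Distances of variant-carrying calls from the nearer read end
#'
#' Scans the alignments for reads carrying `variant_base` at reference
#' position `site` and reports each call's distance from the nearer read
#' end, as consumed by [edge_bias_test()]. No edge trimming is applied.
#'
#' @inheritParams build_pileup
#' @param site 1-based reference position.
#' @param variant_base The variant base to trace.
#' @return Integer vector of 0-based offsets.
#' @export
variant_read_offsets <- function(sam, site, variant_base,
                                 min_base_q = 30L, min_mapq = 20L) {
  aln <- .read_alignments(sam)
  offs <- integer(0)
  for (i in seq_along(aln$pos)) {
    if (is.na(aln$pos[i]) || bitwAnd(aln$flag[i], 4L)) next
    if (!is.na(aln$mapq[i]) && aln$mapq[i] < min_mapq) next
    w <- .cigar_walk(aln$cigar[i], aln$pos[i])
    j <- which(w$rpos == site)
    if (!length(j)) next
    q <- w$qidx[j[1]]
    bases <- strsplit(aln$seq[i], "")[[1]]
    quals <- utf8ToInt(aln$qual[i]) - 33L
    if (bases[q] == variant_base && quals[q] >= min_base_q)
      offs <- c(offs, min(q - 1L, length(bases) - q))
  }
  offs
}

# ---- m1A signature ---------------------------------------------------------

#' Score the m1A misincorporation + coverage-drop signature at a site
#'
#' m1A blocks Watson-Crick pairing: reverse transcriptase misincorporates
#' (reads show T or G at the A site) and partially arrests (local coverage
#' dip). The score combines `mismatch_rate = freq(T) + freq(G)` at the site
#' with `coverage_drop = max(0, 1 - cov(site) / median flank coverage)`;
#' both lie in [0, 1], the combined score in [0, 2].
#'
#' @param columns A `mod_pileup` data.frame.
#' @param site 1-based position; its reference base must be A.
#' @param flank Flank half-width in nt (>= 10); the median is taken over
#'   `[site - flank, site + flank]` excluding the site itself.
#' @return list with `mismatch_rate`, `coverage_drop`, `combined`.
#' @export
m1a_signature <- function(columns, site, flank = 25L) {
  stopifnot(flank >= 10L)
  i <- which(columns$pos == site)
  if (length(i) != 1L) stop("site not found in pileup")
  if (columns$ref_base[i] != "A") stop("reference base at site is not A")
  cnt <- .base_counts(columns[i, ], "both")
  cov <- sum(cnt)
  if (cov == 0L) stop("no coverage at site")
  mism <- unname((cnt["T"] + cnt["G"]) / cov)
  win <- columns$pos >= site - flank & columns$pos <= site + flank &
    columns$pos != site
  med <- median(columns$coverage[win])
  if (!is.finite(med) || med <= 0) stop("insufficient flank coverage")
  drop <- max(0, 1 - cov / med)
  list(mismatch_rate = mism, coverage_drop = drop, combined = mism + drop)
}

#' Compare modification prevalence between two samples
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table of
#' (modified = non-reference, unmodified = reference) read counts in two
#' samples, e.g. total RNA vs purified mitoribosome. When any expected cell
#' falls below 5 a Fisher exact p-value is reported instead (the chi-square
#' statistic is still returned).
#'
#' @param counts_a,counts_b Length-2 vectors `c(modified, unmodified)`.
#' @return list with `chi2`, `df`, `p`, and `method` ("pearson" or "fisher").
#' @export
compare_samples <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2L, length(counts_b) == 2L,
            all(c(counts_a, counts_b) >= 0))
  tab <- rbind(a = counts_a, b = counts_b)
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a margin of the 2x2 table is zero")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  chi2 <- unname(ct$statistic)
  if (any(ct$expected < 5)) {
    p <- fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- unname(ct$p.value)
    method <- "pearson"
  }
  list(chi2 = chi2, df = 1L, p = p, method = method)
}

#' Per-base frequency table (percent) for one pileup column
#'
#' @param column One row of a `mod_pileup`.
#' @return Named numeric vector (A, C, G, T) of percentages of coverage,
#'   strands pooled.
#' @export
frequency_table <- function(column) {
  cnt <- .base_counts(column, "both")
  cov <- sum(cnt)
  if (cov == 0L) stop("zero coverage at position")
  100 * cnt / cov
}
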