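# Seed-deterministic synthetic-data generator: references with an embedded
# site motif, aligned SAM reads carrying a programmable single-site
# misincorporation + truncation signature, and logistic growth / reporter
# kinetics — each with machine-readable ground truth for parameter-recovery
# tests.

GENERATOR_VERSION <- "rnamodkit-sim-1"

#' Generate a reproducible pseudo-random reference sequence
#'
#' @param length Sequence length (nt).
#' @param gc_fraction Target GC content.
#' @param seed Integer seed.
#' @param embed Optional DNA motif to embed.
#' @param embed_pos 1-based start position for the embedded motif.
#' @param name Sequence name.
#' @return Named character vector of length 1 (a FASTA-ready sequence).
#' @export
make_reference <- function(length, gc_fraction = 0.44, seed = 1L,
                           embed = NULL, embed_pos = NULL, name = "ref") {
  stopifnot(length >= 1, gc_fraction >= 0, gc_fraction <= 1)
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  s <- sample(names(p), length, replace = TRUE, prob = p)
  if (!is.null(embed)) {
    embed <- toupper(embed)
    stopifnot(!is.null(embed_pos))
    if (embed_pos < 1L || embed_pos + nchar(embed) - 1L > length)
      stop("embedded motif does not fit in the reference")
    s[embed_pos:(embed_pos + nchar(embed) - 1L)] <-
      strsplit(embed, "")[[1]]
  }
  setNames(paste(s, collapse = ""), name)
}

#' Specify a single-site modification signature for read simulation
#'
#' @param pos 1-based site position (the reference base there should be A).
#' @param p_T,p_G Misincorporation probabilities at the site (A read as T /
#'   as G); `p_T + p_G <= 1`.
#' @param p_trunc Probability that a read covering the site is truncated at
#'   the site (producing the local coverage dip of RT arrest).
#' @param strand_split Fraction of reads simulated on the + strand.
#' @param seq_error Uniform per-base sequencing error rate.
#' @param coverage Target depth.
#' @param read_length Read length (nt).
#' @param seed Integer seed.
#' @return list of class `site_signature_spec`.
#' @export
site_signature_spec <- function(pos, p_T = 0, p_G = 0, p_trunc = 0,
                                strand_split = 0.5, seq_error = 0,
                                coverage = 1000L, read_length = 100L,
                                seed = 1L) {
  stopifnot(p_T >= 0, p_G >= 0, p_T + p_G <= 1,
            p_trunc >= 0, p_trunc <= 1,
            strand_split >= 0, strand_split <= 1,
            seq_error >= 0, seq_error < 1,
            coverage >= 1, read_length >= 1)
  structure(list(pos = as.integer(pos), p_T = p_T, p_G = p_G,
                 p_trunc = p_trunc, strand_split = strand_split,
                 seq_error = seq_error, coverage = as.integer(coverage),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "site_signature_spec")
}

.other_bases <- function(b) DNA_BASES[DNA_BASES != b]

#' Simulate aligned reads carrying a single-site modification signature
#'
#' Reads of fixed length are placed uniformly over the reference at the
#' target depth, split between strands by `strand_split`. Reads covering
#' `spec$pos` emit the site base from `(1 - p_T - p_G, p_T, p_G)` over
#' (ref, T, G) before sequencing error; with probability `p_trunc` such a
#' read is truncated so that its alignment ends just before the site (reads
#' starting at the site are dropped), which produces the coverage dip of RT
#' arrest. Uniform sequencing error is applied everywhere else. Reads carry
#' constant Q37 base qualities and MAPQ 60, and are written as a
#' coordinate-sorted SAM text file.
#'
#' @param reference Named character vector (as from [make_reference()]) or a
#'   FASTA path.
#' @param spec A `site_signature_spec`.
#' @param sam_path Output SAM path (default: tempfile).
#' @param truth_path Optional path to also serialize the truth as JSON.
#' @return list with `sam` (path) and `truth`: the spec parameters plus
#'   realized per-base/strand counts at the site (post-error, pre-filter),
#'   realized site coverage, number of truncated reads, generator version.
#' @export
simulate_reads <- function(reference, spec, sam_path = tempfile(fileext = ".sam"),
                           truth_path = NULL) {
  ref <- if (length(reference) == 1L && file.exists(reference))
    read_fasta(reference) else reference
  stopifnot(!is.null(names(ref)), inherits(spec, "site_signature_spec"))
  rn <- names(ref)[1]
  refseq <- strsplit(toupper(ref[[1]]), "")[[1]]
  L <- length(refseq)
  rl <- spec$read_length
  if (spec$pos < 1L || spec$pos > L) stop("site outside reference")
  if (L < rl) stop("reference shorter than the read length")
  set.seed(spec$seed)
  n_reads <- ceiling(spec$coverage * L / rl)
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
  is_plus <- runif(n_reads) < spec$strand_split
  site_counts <- matrix(0L, nrow = 4L, ncol = 2L,
                        dimnames = list(DNA_BASES, c("plus", "minus")))
  n_trunc <- 0L
  recs <- character(n_reads)
  keep <- logical(n_reads)
  for (i in seq_len(n_reads)) {
    st <- starts[i]
    en <- st + rl - 1L
    bases <- refseq[st:en]
    covers <- spec$pos >= st && spec$pos <= en
    truncated <- FALSE
    if (covers) {
      if (runif(1) < spec$p_trunc) {
        truncated <- TRUE
        n_trunc <- n_trunc + 1L
        if (spec$pos == st) next  # nothing aligned upstream of the site
        en <- spec$pos - 1L
        bases <- refseq[st:en]
      } else {
        u <- runif(1)
        j <- spec$pos - st + 1L
        if (u < spec$p_T) bases[j] <- "T"
        else if (u < spec$p_T + spec$p_G) bases[j] <- "G"
      }
    }
    if (spec$seq_error > 0) {
      err <- which(runif(length(bases)) < spec$seq_error)
      for (j in err) bases[j] <- sample(.other_bases(bases[j]), 1L)
    }
    if (covers && !truncated) {
      j <- spec$pos - st + 1L
      col <- if (is_plus[i]) "plus" else "minus"
      site_counts[bases[j], col] <- site_counts[bases[j], col] + 1L
    }
    qlen <- length(bases)
    recs[i] <- paste(
      sprintf("read%06d", i),
      if (is_plus[i]) 0L else 16L,
      rn, st, 60L, paste0(qlen, "M"), "*", 0L, 0L,
      paste(bases, collapse = ""),
      strrep(rawToChar(as.raw(37L + 33L)), qlen),
      sep = "\t")
    keep[i] <- TRUE
  }
  recs <- recs[keep]
  ord <- order(starts[keep])
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", rn, L))
  writeLines(c(header, recs[ord]), sam_path)
  truth <- list(
    spec = unclass(spec),
    generator = GENERATOR_VERSION,
    ref_name = rn, ref_length = L, n_reads_emitted = sum(keep),
    n_truncated = n_trunc,
    site_counts = list(
      plus = as.list(setNames(site_counts[, "plus"], DNA_BASES)),
      minus = as.list(setNames(site_counts[, "minus"], DNA_BASES))),
    site_coverage = sum(site_counts))
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(sam = sam_path, truth = truth)
}

#' Simulate logistic growth with a noisy proportional reporter
#'
#' OD follows logistic growth (carrying capacity `K`, rate `r` per minute,
#' lag `lag` minutes, inoculum `od0`); each interval's fluorescence
#' increment is `prod_rate * OD(t)` plus Gaussian noise, so the per-interval
#' production-rate statistic recovers `prod_rate` exactly in the noise-free
#' case. Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param K Carrying capacity (OD units).
#' @param r Growth rate (1/min).
#' @param lag Lag time (min).
#' @param prod_rate Per-interval reporter production per unit OD.
#' @param noise_sd Gaussian SD of the fluorescence increments (>= 0).
#' @param n_replicates Number of replicate wells.
#' @param seed Integer seed.
#' @param t_end,dt Time grid: `seq(0, t_end, by = dt)` minutes.
#' @param od0 Inoculum OD.
#' @return list with `tables` (list of `kinetics_table`) and `truth`
#'   (the parameters plus generator version).
#' @export
simulate_kinetics <- function(K = 1.0, r = 0.01, lag = 60, prod_rate = 50,
                              noise_sd = 0, n_replicates = 1L, seed = 1L,
                              t_end = 960, dt = 30, od0 = 0.01) {
  stopifnot(K > 0, r > 0, noise_sd >= 0, n_replicates >= 1)
  time <- seq(0, t_end, by = dt)
  od_of <- function(t_) {
    te <- pmax(0, t_ - lag)
    K * od0 * exp(r * te) / (K + od0 * (exp(r * te) - 1))
  }
  tables <- vector("list", n_replicates)
  for (rep_ in seq_len(n_replicates)) {
    set.seed(seed + rep_ - 1L)
    od <- od_of(time)
    inc <- prod_rate * od[-1L] + rnorm(length(time) - 1L, 0, noise_sd)
    fluo <- c(0, cumsum(inc))
    tables[[rep_]] <- kinetics_table(time, od, fluo,
                                     sprintf("rep%02d", rep_))
  }
  list(tables = tables,
       truth = list(K = K, r = r, lag = lag, prod_rate = prod_rate,
                    noise_sd = noise_sd, n_replicates = n_replicates,
                    seed = seed, t_end = t_end, dt = dt, od0 = od0,
                    generator = GENERATOR_VERSION))
}
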