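# Orthologous-position anchoring: locate the counterpart of human 16S rRNA
# position 947 (mtDNA 2617) in another species' mtDNA by local alignment of
# a window around the query position, then tabulate genotype (A vs T) against
# RDD presence across a species panel.

# Smith-Waterman with linear gaps, returning the full score matrix.
# Columns are computed with a cummax trick so only the subject loop is
# interpreted R code.
.sw_matrix <- function(p, s, match = 2, mismatch = -1, gap = -2) {
  m <- length(p); n <- length(s)
  H <- matrix(0, nrow = m + 1L, ncol = n + 1L)
  two_i <- -gap * seq_len(m)
  for (j in seq_len(n)) {
    subs <- ifelse(p == s[j], match, mismatch)
    cand <- pmax(0, H[1:m, j] + subs, H[2:(m + 1L), j] + gap)
    # vertical gap chain: H[i] = max over k<=i of cand[k] + gap*(i-k)
    H[2:(m + 1L), j + 1L] <- cummax(cand + two_i) - two_i
  }
  H
}

# Traceback from one cell; returns the subject column aligned (diagonally)
# to pattern index `centre`, or NA when the centre falls in a gap / outside
# the local alignment.
.sw_traceback_centre <- function(H, p, s, i, j, centre,
                                 match = 2, mismatch = -1, gap = -2) {
  centre_col <- NA_integer_
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0) {
    h <- H[i + 1L, j + 1L]
    subs <- if (p[i] == s[j]) match else mismatch
    if (h == H[i, j] + subs) {            # diagonal
      if (i == centre) centre_col <- j
      i <- i - 1L; j <- j - 1L
    } else if (h == H[i, j + 1L] + gap) { # gap in subject (consumes pattern)
      if (i == centre) return(NA_integer_)
      i <- i - 1L
    } else {                              # gap in pattern (consumes subject)
      j <- j - 1L
    }
  }
  if (i >= centre) NA_integer_ else centre_col
}

#' Anchor the ortholog of a query position in another genome
#'
#' Extracts an odd-length window centred on `query_pos` from the query
#' genome and aligns it locally (Smith-Waterman; match +2, mismatch -1,
#' linear gap -2) against the target genome. The anchored position is the
#' target column aligned to the window centre. Fails when the best score is
#' below `min_score_frac` of the perfect-match score, when the centre falls
#' in a gap, or when co-optimal alignments disagree on the anchored column.
#'
#' @param query Query genome: FASTA path or a (named) character sequence.
#' @param target Target genome, same forms accepted.
#' @param query_pos 1-based query position to anchor (default 2617, the
#'   human mtDNA coordinate of 16S rRNA position 947).
#' @param window Odd window length in nt (default 61, i.e. +/- 30).
#' @param min_score_frac Acceptance threshold as a fraction of the maximum
#'   attainable score (default 0.6).
#' @return list of class `ortholog_anchor`: `target_pos`, `score`,
#'   `max_score`, `query_window` (the window string), `window`.
#' @export
map_ortholog <- function(query, target, query_pos = 2617L, window = 61L,
                         min_score_frac = 0.6) {
  getseq <- function(x) {
    if (length(x) == 1L && file.exists(x)) x <- read_fasta(x)
    toupper(unname(x[[1]]))
  }
  q <- getseq(query); t_ <- getseq(target)
  window <- as.integer(window)
  if (window < 31L || window %% 2L == 0L)
    stop("window must be an odd length >= 31")
  half <- (window - 1L) %/% 2L
  if (query_pos - half < 1L || query_pos + half > nchar(q))
    stop("window around query_pos extends beyond the query sequence")
  win <- substr(q, query_pos - half, query_pos + half)
  p <- strsplit(win, "")[[1]]
  s <- strsplit(t_, "")[[1]]
  H <- .sw_matrix(p, s)
  best <- max(H)
  max_score <- 2 * window
  if (best < min_score_frac * max_score)
    stop(sprintf("low-identity alignment: score %g < %g", best,
                 min_score_frac * max_score))
  ends <- which(H == best, arr.ind = TRUE)
  centre <- half + 1L
  anchors <- unique(vapply(seq_len(min(nrow(ends), 50L)), function(k) {
    .sw_traceback_centre(H, p, s, ends[k, 1L] - 1L, ends[k, 2L] - 1L, centre)
  }, integer(1)))
  anchors <- anchors[!is.na(anchors)]
  if (length(anchors) == 0L)
    stop("window centre falls in an alignment gap")
  if (length(unique(anchors)) > 1L)
    stop("ambiguous anchor: co-optimal alignments disagree on the position")
  structure(list(target_pos = anchors[1L], score = best,
                 max_score = max_score, query_window = win, window = window),
            class = "ortholog_anchor")
}

#' @export
print.ortholog_anchor <- function(x, ...) {
  cat(sprintf("ortholog anchor: target position %d (score %g / %g)\n",
              x$target_pos, x$score, x$max_score))
  invisible(x)
}

#' Tabulate mtDNA genotype against RDD presence across a species panel
#'
#' For each species, the genotype base at the anchored position is paired
#' with the RDD verdict from its RNA pileup: RDD present iff [call_rdd()]
#' passes both filters at the anchored site. Species with an adenine
#' genotype and an m1A-style signature come out RDD-present; thymine
#' genotypes do not.
#'
#' @param panel A list; each entry a list with fields `species`,
#'   `genotype_base` (mtDNA base at the anchored position), `pileup` (a
#'   `mod_pileup`), `site` (anchored 1-based position), and optionally
#'   `min_coverage` to override filter A for that sample (the original
#'   analysis waived it for one species).
#' @param min_coverage,min_total_fraction,min_strand_fraction Thresholds
#'   passed to [call_rdd()].
#' @return data.frame (rows sorted by species) with `species`, `mtdna_base`,
#'   `coverage`, `rdd_level`, `rdd_present`.
#' @export
genotype_rdd_table <- function(panel, min_coverage = 1000L,
                               min_total_fraction = 0.016,
                               min_strand_fraction = 0.008) {
  rows <- lapply(panel, function(e) {
    stopifnot(!is.null(e$species), !is.null(e$pileup), !is.null(e$site),
              !is.null(e$genotype_base))
    cov_thr <- if (!is.null(e$min_coverage)) e$min_coverage else min_coverage
    col <- e$pileup[e$pileup$pos == e$site, , drop = FALSE]
    if (nrow(col) != 1L)
      stop("missing pileup column at anchored site for species ", e$species)
    call <- call_rdd(col, min_coverage = cov_thr,
                     min_total_fraction = min_total_fraction,
                     min_strand_fraction = min_strand_fraction)
    data.frame(species = e$species, mtdna_base = e$genotype_base,
               coverage = call$coverage, rdd_level = call$rdd_level,
               rdd_present = call$is_rdd)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}
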