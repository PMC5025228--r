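# In-silico genome-editing support: MAGE single-strand oligo design on the
# lagging strand, restriction-site scanning and RFLP fragment prediction
# (MluCI genotyping of edited 23S rRNA genes), overlap assembly of a T7
# transcription template, and run-off transcript prediction.

T7_PROMOTER <- "TAATACGACTCACTATA"

.check_dna <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (!nzchar(x)) stop(what, " is empty")
  ch <- strsplit(x, "")[[1]]
  if (!all(ch %in% DNA_BASES))
    stop(what, " contains non-ACGT characters")
  x
}

#' Design a MAGE single-strand editing oligo
#'
#' Builds an oligo of length `length` (default 90) targeting the lagging
#' strand: the reverse complement of the gene-strand window around
#' `target_pos`, with the edited base placed at oligo offset
#' `ceiling(length / 2) + 1` (offset 46 for a 90-mer) and phosphorothioate
#' bonds on the two outermost internucleotide linkages at each end
#' (protection against exonucleases).
#'
#' @param gene_strand Gene-strand DNA sequence.
#' @param target_pos 1-based position of the base to edit (gene-strand
#'   coordinates).
#' @param new_base Replacement base (gene-strand identity); must differ from
#'   the reference base.
#' @param length Oligo length (default 90).
#' @param lagging Reverse-complement the window (default TRUE).
#' @return list of class `mage_oligo`: `seq`, `target_offset`, `thio_bonds`
#'   (internucleotide linkage indices), `edit = c(ref, new)`.
#' @export
design_mage_oligo <- function(gene_strand, target_pos, new_base,
                              length = 90L, lagging = TRUE) {
  gene_strand <- .check_dna(gene_strand, "gene strand")
  new_base <- toupper(new_base)
  stopifnot(new_base %in% DNA_BASES)
  L <- as.integer(length)
  off <- ceiling(L / 2) + 1L  # edit offset within the final oligo
  # window chosen so the edit lands at `off` after (optional) revcomp
  win_off <- if (lagging) L - off + 1L else off
  start <- target_pos - win_off + 1L
  end <- start + L - 1L
  if (start < 1L || end > nchar(gene_strand))
    stop("target too close to the sequence end for a ", L, "-mer")
  ref_base <- substr(gene_strand, target_pos, target_pos)
  if (new_base == ref_base)
    stop("new_base equals the reference base; nothing to edit")
  win <- strsplit(substr(gene_strand, start, end), "")[[1]]
  win[win_off] <- new_base
  oligo <- paste(win, collapse = "")
  if (lagging) oligo <- revcomp(oligo)
  structure(list(seq = oligo,
                 target_offset = off,
                 thio_bonds = c(1L, 2L, L - 2L, L - 1L),
                 edit = c(ref = ref_base, new = new_base),
                 lagging = lagging),
            class = "mage_oligo")
}

#' @export
print.mage_oligo <- function(x, ...) {
  cat(sprintf("MAGE oligo (%d nt, edit %s>%s at offset %d, %s strand)\n",
              nchar(x$seq), x$edit["ref"], x$edit["new"], x$target_offset,
              if (x$lagging) "lagging" else "leading"))
  cat("  ", format_mage_oligo(x), "\n", sep = "")
  invisible(x)
}

#' Render a MAGE oligo with phosphorothioate linkages as asterisks
#' @param x A `mage_oligo`.
#' @return String with `*` inserted at each phosphorothioate linkage.
#' @export
format_mage_oligo <- function(x) {
  ch <- strsplit(x$seq, "")[[1]]
  out <- character(0)
  for (i in seq_along(ch)) {
    out <- c(out, ch[i])
    if (i %in% x$thio_bonds) out <- c(out, "*")
  }
  paste(out, collapse = "")
}

#' Define a restriction enzyme by its recognition site
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (ACGT only).
#' @param cut_offset 0-based cut position within/before the site on the top
#'   strand; 0 means the cut falls immediately before the recognition
#'   sequence (5'-overhang convention, as for MluCI/AATT).
#' @return list of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset = 0L) {
  recognition <- .check_dna(recognition, "recognition site")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
mlucI <- function() restriction_enzyme("MluCI", "AATT", 0L)

#' Find restriction sites on the given strand
#'
#' @param seq DNA string.
#' @param enzyme A `restriction_enzyme`.
#' @return Integer vector of 1-based site start positions (palindromic sites
#'   such as AATT make the scan strand-agnostic).
#' @export
find_sites <- function(seq, enzyme) {
  seq <- .check_dna(seq)
  hits <- gregexpr(enzyme$recognition, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Predict RFLP fragment lengths for an amplicon
#'
#' Cuts at every recognition site (`cut_offset` bases into the site on the
#' top strand) and reports the lengths between successive cut points.
#' Complete digestion of an edited amplicon that gained a site yields two
#' fragments where the wild type gives one.
#'
#' @param amplicon DNA string.
#' @param enzyme A `restriction_enzyme` (default MluCI/AATT).
#' @return Integer vector of fragment lengths, summing to the amplicon
#'   length; a single length when no site is present.
#' @export
predict_rflp <- function(amplicon, enzyme = mlucI()) {
  amplicon <- .check_dna(amplicon, "amplicon")
  n <- nchar(amplicon)
  starts <- find_sites(amplicon, enzyme)
  cuts <- starts - 1L + enzyme$cut_offset     # bases to the left of each cut
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  diff(c(0L, cuts, n))
}

#' Assemble overlapping oligos into a duplex top strand
#'
#' Greedy exact suffix/prefix merging over all orders and orientations
#' (each oligo may enter as given or reverse-complemented, so a terminal
#' primer supplied as the bottom strand is handled automatically). The
#' result must be unique up to reverse complement; the returned strand is
#' the lexicographically smaller of the assembly and its reverse complement,
#' making the output invariant to input order and per-oligo orientation.
#'
#' @param oligos Character vector of DNA oligos (>= 2).
#' @param min_overlap Minimum exact overlap (default 15 nt).
#' @return Assembled top-strand DNA string.
#' @export
assemble_overlap <- function(oligos, min_overlap = 15L) {
  oligos <- vapply(oligos, .check_dna, "", what = "oligo")
  n <- length(oligos)
  if (n < 2L) stop("need at least two oligos")
  if (n > 7L) stop("assembly search supports at most 7 oligos")
  overlap_len <- function(a, b) {
    kmax <- min(nchar(a), nchar(b))
    if (kmax < min_overlap) return(0L)
    for (k in kmax:min_overlap) {
      if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k))
        return(k)
    }
    0L
  }
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  orientations <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  assemblies <- character(0)
  for (ord in perms(seq_len(n))) {
    for (r in seq_len(nrow(orientations))) {
      seqs <- oligos[ord]
      flip <- unlist(orientations[r, ])[seq_len(n)]
      seqs <- ifelse(flip, vapply(seqs, revcomp, ""), seqs)
      acc <- seqs[[1]]
      ok <- TRUE
      for (i in 2:n) {
        k <- overlap_len(acc, seqs[[i]])
        if (k == 0L || k == nchar(seqs[[i]])) { ok <- FALSE; break }
        acc <- paste0(acc, substr(seqs[[i]], k + 1L, nchar(seqs[[i]])))
      }
      if (ok) assemblies <- c(assemblies, acc)
    }
  }
  canon <- unique(vapply(assemblies, function(s) min(s, revcomp(s)), ""))
  if (length(canon) == 0L)
    stop("no assembly with exact overlaps >= ", min_overlap, " nt")
  if (length(canon) > 1L)
    stop("ambiguous assembly: multiple incompatible layouts found")
  canon
}

#' Predict the T7 run-off transcript from a template top strand
#'
#' Locates the T7 class III promoter (`TAATACGACTCACTATA`) on the given
#' strand or its reverse complement, requires the +1 base immediately
#' following it to be G, and transcribes from that G to the template end
#' (T -> U). Templates assembled with [assemble_overlap()] may come back in
#' either orientation, hence the double-strand search.
#'
#' @param template_top Template DNA string.
#' @param start_pos,coord_name Optional anchoring of the transcript in a
#'   parent coordinate system (e.g. `start_pos = 866`, "human 16S rRNA").
#' @return The transcript as a `mod_rna` (5'-P, 3'-OH).
#' @export
t7_runoff <- function(template_top, start_pos = 1L, coord_name = "local") {
  tpl <- .check_dna(template_top, "template")
  hit <- regexpr(T7_PROMOTER, tpl, fixed = TRUE)
  if (hit == -1L) {
    tpl <- revcomp(tpl)
    hit <- regexpr(T7_PROMOTER, tpl, fixed = TRUE)
  }
  if (hit == -1L) stop("T7 promoter not found on either strand")
  plus1 <- as.integer(hit) + nchar(T7_PROMOTER)
  if (plus1 > nchar(tpl) || substr(tpl, plus1, plus1) != "G")
    stop("+1 position after the T7 promoter is not G")
  rna <- transcribe(substr(tpl, plus1, nchar(tpl)),
                    start_pos = start_pos, coord_name = coord_name)
  rna$five_prime <- "P"
  rna
}
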