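# Sequence data model: modified-RNA container, modification registry,
# coordinate maps, IUPAC scanning, FASTA helpers. All coordinates in this
# package are 1-based inclusive.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

# modification registry lives in a package environment so new marks can be
# registered at run time (label, base constraint, monoisotopic mass delta)
.mod_registry <- new.env(parent = emptyenv())

.init_registry <- function() {
  assign("m1A", list(base = "A", delta = 14.01565), envir = .mod_registry)
}

#' Register a base-modification label
#'
#' Adds a label to the modification registry. Each label carries the base it
#' may sit on and the monoisotopic mass delta (Da) it adds to the residue.
#' The package ships with `m1A` (1-methyladenosine, +CH2 on adenosine).
#'
#' @param label Modification label, e.g. `"m1A"`.
#' @param base Base the modification is restricted to (`A`, `C`, `G` or `U`).
#' @param delta Monoisotopic mass delta in Da.
#' @return Invisibly, the label.
#' @export
register_modification <- function(label, base, delta) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  if (!base %in% RNA_BASES)
    stop("base constraint must be one of A, C, G, U")
  assign(label, list(base = base, delta = as.numeric(delta)),
         envir = .mod_registry)
  invisible(label)
}

#' List registered base modifications
#' @return data.frame with columns `label`, `base`, `delta`.
#' @export
modification_registry <- function() {
  labs <- sort(ls(.mod_registry))
  data.frame(
    label = labs,
    base = vapply(labs, function(l) get(l, .mod_registry)$base, ""),
    delta = vapply(labs, function(l) get(l, .mod_registry)$delta, 0),
    row.names = NULL
  )
}

.mod_lookup <- function(label) {
  if (!exists(label, envir = .mod_registry, inherits = FALSE))
    stop("unknown modification label: ", label)
  get(label, envir = .mod_registry)
}

#' Construct a modified-RNA sequence object
#'
#' The central sequence container: an ordered run of residues, each an RNA
#' base optionally carrying a registered base modification (e.g. m1A) and/or
#' a 2'-O-methyl on the ribose, plus terminal chemistry and an anchor into a
#' named 1-based parent coordinate system (e.g. "human 16S rRNA").
#'
#' @param base Character vector of bases (`A`,`C`,`G`,`U`).
#' @param base_mod Optional character vector (NA = none) of registry labels.
#' @param sugar_2ome Logical vector: 2'-O-methylated ribose.
#' @param start_pos 1-based parent position of the first residue.
#' @param coord_name Name of the parent coordinate system.
#' @param five_prime One of `"OH"`, `"P"`.
#' @param three_prime One of `"OH"`, `"P"`, `"cyclicP"`.
#' @return An object of class `mod_rna`.
#' @export
mod_rna <- function(base, base_mod = NULL, sugar_2ome = NULL,
                    start_pos = 1L, coord_name = "local",
                    five_prime = "OH", three_prime = "OH") {
  base <- toupper(as.character(base))
  n <- length(base)
  if (n < 1L) stop("sequence must contain at least one residue")
  if (!all(base %in% RNA_BASES))
    stop("invalid RNA base(s): ", paste(setdiff(base, RNA_BASES), collapse = ", "))
  if (is.null(base_mod)) base_mod <- rep(NA_character_, n)
  if (is.null(sugar_2ome)) sugar_2ome <- rep(FALSE, n)
  stopifnot(length(base_mod) == n, length(sugar_2ome) == n)
  for (i in which(!is.na(base_mod))) {
    spec <- .mod_lookup(base_mod[i])
    if (spec$base != base[i])
      stop(sprintf("modification %s not allowed on base %s (residue %d)",
                   base_mod[i], base[i], i))
  }
  if (start_pos < 1L) stop("start_pos must be >= 1")
  five_prime <- match.arg(five_prime, c("OH", "P"))
  three_prime <- match.arg(three_prime, c("OH", "P", "cyclicP"))
  structure(
    list(
      residues = data.frame(base = base, base_mod = base_mod,
                            sugar_2ome = as.logical(sugar_2ome)),
      start_pos = as.integer(start_pos),
      coord_name = coord_name,
      five_prime = five_prime,
      three_prime = three_prime
    ),
    class = "mod_rna"
  )
}

#' @export
length.mod_rna <- function(x) nrow(x$residues)

#' @export
print.mod_rna <- function(x, ...) {
  n <- length(x)
  cat(sprintf("mod_rna: %d nt, 5'-%s ... 3'-%s\n", n, x$five_prime,
              x$three_prime))
  cat(sprintf("  parent: %s, positions %d-%d\n", x$coord_name,
              x$start_pos, x$start_pos + n - 1L))
  cat("  ", render_mod_string(x), "\n", sep = "")
  invisible(x)
}

#' Extract a sub-sequence of a `mod_rna`, keeping parent coordinates
#'
#' Internal residues of the slice get OH termini unless they coincide with
#' the parent's ends, whose chemistry is preserved.
#'
#' @param x A `mod_rna`.
#' @param from,to Local residue indices (1-based inclusive).
#' @keywords internal
mod_rna_slice <- function(x, from, to) {
  n <- length(x)
  stopifnot(from >= 1L, to <= n, from <= to)
  mod_rna(
    base = x$residues$base[from:to],
    base_mod = x$residues$base_mod[from:to],
    sugar_2ome = x$residues$sugar_2ome[from:to],
    start_pos = x$start_pos + from - 1L,
    coord_name = x$coord_name,
    five_prime = if (from == 1L) x$five_prime else "OH",
    three_prime = if (to == n) x$three_prime else "OH"
  )
}

#' Add (or remove) a base modification at a parent position
#'
#' @param x A `mod_rna`.
#' @param pos Position in the parent coordinate system of `x`.
#' @param label Registry label, or `NA` to strip a modification.
#' @return The modified `mod_rna`.
#' @export
set_base_mod <- function(x, pos, label = "m1A") {
  stopifnot(inherits(x, "mod_rna"))
  i <- pos - x$start_pos + 1L
  if (i < 1L || i > length(x))
    stop("position ", pos, " outside sequence span")
  if (!is.na(label)) {
    spec <- .mod_lookup(label)
    if (spec$base != x$residues$base[i])
      stop(sprintf("modification %s not allowed on base %s at position %d",
                   label, x$residues$base[i], pos))
  }
  x$residues$base_mod[i] <- label
  x
}

#' Re-anchor a `mod_rna` in a named parent coordinate system
#' @param x A `mod_rna`.
#' @param start_pos New 1-based parent position of residue 1.
#' @param coord_name New coordinate-system name.
#' @export
set_coordinates <- function(x, start_pos, coord_name = x$coord_name) {
  stopifnot(inherits(x, "mod_rna"), start_pos >= 1)
  x$start_pos <- as.integer(start_pos)
  x$coord_name <- coord_name
  x
}

#' Parse modified-sequence shorthand
#'
#' Shorthand conventions: an `m1` prefix marks a base methyl (`m1A` =
#' 1-methyladenosine); a lowercase `m` suffix marks a 2'-O-methyl ribose
#' (`Gm`); a trailing `p` marks a 3'-phosphate and a trailing `>p` a
#' 2',3'-cyclic phosphate; a leading `p` marks a 5'-phosphate. Without
#' trailing/leading `p` the termini default to OH. Examples:
#' `"UUCCUUAAm1AUAGp"`, `"GmGp"`, `"AAm1AUp"`.
#'
#' @param text Shorthand string.
#' @param start_pos,coord_name Parent anchoring (see [mod_rna()]).
#' @return A `mod_rna`.
#' @export
parse_mod_string <- function(text, start_pos = 1L, coord_name = "local") {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop("empty sequence string")
  ch <- strsplit(text, "")[[1]]
  n <- length(ch)
  five_prime <- "OH"
  three_prime <- "OH"
  i <- 1L
  if (ch[1] == "p") {
    five_prime <- "P"
    i <- 2L
  }
  last <- n
  if (n >= 2L && ch[n] == "p" && ch[n - 1L] == ">") {
    three_prime <- "cyclicP"
    last <- n - 2L
  } else if (ch[n] == "p") {
    three_prime <- "P"
    last <- n - 1L
  }
  if (last < i) stop("no residues in sequence string")
  is_digit <- function(c_) c_ %in% as.character(0:9)
  base <- character(0); base_mod <- character(0); sugar <- logical(0)
  while (i <= last) {
    bm <- NA_character_
    if (ch[i] == "m" && i + 1L <= last && is_digit(ch[i + 1L])) {
      # base-methyl prefix, e.g. m1A, m5C: m + digits + base
      j <- i + 1L
      while (j <= last && is_digit(ch[j])) j <- j + 1L
      if (j > last) stop("dangling modification prefix at character ", i)
      b <- toupper(ch[j])
      bm <- paste(ch[i:j], collapse = "")
      .mod_lookup(bm)  # errors on unregistered labels
      i <- j + 1L
    } else if (toupper(ch[i]) %in% RNA_BASES && ch[i] != "m") {
      b <- toupper(ch[i])
      i <- i + 1L
    } else {
      stop("cannot parse sequence shorthand at character ", i, ": '",
           ch[i], "'")
    }
    # 'm' suffix = 2'-O-methyl, unless it opens the next residue's m<digit>
    if (i <= last && ch[i] == "m" &&
        !(i + 1L <= last && is_digit(ch[i + 1L]))) {
      sugar <- c(sugar, TRUE)
      i <- i + 1L
    } else {
      sugar <- c(sugar, FALSE)
    }
    base <- c(base, b); base_mod <- c(base_mod, bm)
  }
  mod_rna(base, base_mod, sugar, start_pos = start_pos,
          coord_name = coord_name, five_prime = five_prime,
          three_prime = three_prime)
}

#' Render a `mod_rna` back to shorthand
#'
#' Exact inverse of [parse_mod_string()] for registry-valid sequences.
#'
#' @param x A `mod_rna`.
#' @return Shorthand string.
#' @export
render_mod_string <- function(x) {
  stopifnot(inherits(x, "mod_rna"))
  res <- x$residues
  tok <- ifelse(is.na(res$base_mod), res$base, res$base_mod)
  tok <- ifelse(res$sugar_2ome, paste0(tok, "m"), tok)
  paste0(
    if (x$five_prime == "P") "p" else "",
    paste(tok, collapse = ""),
    switch(x$three_prime, OH = "", P = "p", cyclicP = ">p")
  )
}

#' Plain base string of a `mod_rna`
#' @param x A `mod_rna`.
#' @param ... Unused.
#' @export
as.character.mod_rna <- function(x, ...) paste(x$residues$base, collapse = "")

#' Serialize / deserialize a `mod_rna` as JSON
#' @param x A `mod_rna`.
#' @return `mod_rna_to_json`: a JSON string; `mod_rna_from_json`: a `mod_rna`.
#' @export
mod_rna_to_json <- function(x) {
  stopifnot(inherits(x, "mod_rna"))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname mod_rna_to_json
#' @param json JSON string produced by [mod_rna_to_json()].
#' @export
mod_rna_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  mod_rna(l$residues$base,
          ifelse(is.na(l$residues$base_mod) | l$residues$base_mod == "NA",
                 NA_character_, l$residues$base_mod),
          l$residues$sugar_2ome,
          start_pos = l$start_pos, coord_name = l$coord_name,
          five_prime = l$five_prime, three_prime = l$three_prime)
}

#' Convert a DNA string to RNA (`T` -> `U`) and back
#'
#' The only sanctioned crossing between the DNA and RNA alphabets. All other
#' operations keep the alphabets distinct.
#'
#' @param dna DNA string.
#' @param start_pos,coord_name Parent anchoring for the transcript.
#' @return `transcribe`: a `mod_rna`; `rna_to_dna`: a DNA string.
#' @export
transcribe <- function(dna, start_pos = 1L, coord_name = "local") {
  dna <- toupper(as.character(dna))
  ch <- strsplit(dna, "")[[1]]
  if (!all(ch %in% DNA_BASES)) stop("invalid DNA base(s) in input")
  mod_rna(chartr("T", "U", ch), start_pos = start_pos,
          coord_name = coord_name)
}

#' @rdname transcribe
#' @param rna A `mod_rna` or RNA string.
#' @export
rna_to_dna <- function(rna) {
  s <- if (inherits(rna, "mod_rna")) as.character(rna) else toupper(rna)
  chartr("U", "T", s)
}

# ---- coordinate maps -------------------------------------------------------

#' Define an offset map between two 1-based coordinate systems
#'
#' `parent_pos = local_pos + offset`. The shipped convenience map
#' [human_16s_to_mtdna()] carries offset 1670, so 16S rRNA position 947 maps
#' to mtDNA position 2617.
#'
#' @param name Map label.
#' @param offset Integer offset.
#' @return An object of class `coord_map`.
#' @export
coord_map <- function(name, offset) {
  structure(list(name = name, offset = as.integer(offset)),
            class = "coord_map")
}

#' @rdname coord_map
#' @export
human_16s_to_mtdna <- function() coord_map("human 16S rRNA -> mtDNA", 1670L)

#' Map a local position to parent coordinates (or back)
#' @param pos 1-based position.
#' @param map A `coord_map`.
#' @return 1-based mapped position.
#' @export
map_coordinate <- function(pos, map) {
  stopifnot(inherits(map, "coord_map"), all(pos >= 1))
  out <- as.integer(pos) + map$offset
  if (any(out < 1L)) stop("mapped position below 1")
  out
}

#' @rdname map_coordinate
#' @export
unmap_coordinate <- function(pos, map) {
  stopifnot(inherits(map, "coord_map"))
  out <- as.integer(pos) - map$offset
  if (any(out < 1L)) stop("mapped position below 1")
  out
}

# ---- IUPAC scanning --------------------------------------------------------

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Scan a sequence for an IUPAC motif
#'
#' `U` and `T` are treated as equivalent on both sides; e.g. the weak
#' consensus `YMRAW` around m1A58-type sites matches `UAAAU`.
#'
#' @param seq Base string (RNA or DNA).
#' @param motif IUPAC motif string.
#' @return Integer vector of 1-based match start positions.
#' @export
iupac_scan <- function(seq, motif) {
  s <- chartr("U", "T", toupper(as.character(seq)))
  m <- chartr("U", "T", toupper(motif))
  sch <- strsplit(s, "")[[1]]
  mch <- strsplit(m, "")[[1]]
  if (!all(mch %in% names(IUPAC_SETS)))
    stop("invalid IUPAC code(s): ",
         paste(setdiff(mch, names(IUPAC_SETS)), collapse = ", "))
  n <- length(sch); k <- length(mch)
  if (k == 0L || n < k) return(integer(0))
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & sch[seq_len(n - k + 1L) + j - 1L] %in% IUPAC_SETS[[mch[j]]]
  }
  which(ok)
}

# ---- FASTA helpers ---------------------------------------------------------

#' Read / write FASTA files
#'
#' Thin wrappers over Biostrings that return plain named character vectors,
#' the representation the rest of the package works with.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param dna DNA string.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
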