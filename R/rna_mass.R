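# Modification-aware in-silico nuclease digestion, monoisotopic oligo mass,
# negative-mode m/z, CID product-ion series, tolerant ion matching.
#
# Residue masses are monoisotopic nucleoside-3'(or 5')-monophosphate residue
# masses, so a linear oligo with one terminal phosphate weighs
# sum(residues) + H2O. Methyl groups (base methyl or 2'-O-methyl) each add
# one CH2.

MASS <- list(
  residue = c(A = 329.05252, C = 305.04129, G = 345.04744, U = 306.02530),
  CH2 = 14.01565,
  H2O = 18.010565,
  HPO3 = 79.966331,
  proton = 1.0072765,
  # neutral nucleobase masses (BH), used for a-B ions
  baseBH = c(A = 135.05450, G = 151.04941, C = 111.04326, U = 112.02728,
             m1A = 149.07015)
)

.residue_masses <- function(x) {
  stopifnot(inherits(x, "mod_rna"))
  res <- x$residues
  m <- MASS$residue[res$base]
  n_methyl <- (!is.na(res$base_mod)) + res$sugar_2ome
  # registry deltas: all shipped marks are +CH2; honour custom deltas
  delta <- rep(0, nrow(res))
  idx <- which(!is.na(res$base_mod))
  if (length(idx))
    delta[idx] <- vapply(res$base_mod[idx],
                         function(l) .mod_lookup(l)$delta, 0)
  unname(m + delta + res$sugar_2ome * MASS$CH2)
}

.terminus_adjust <- function(five_prime, three_prime) {
  # residue masses carry one phosphate each; adjust for actual termini
  if (five_prime == "OH" && three_prime == "P") return(MASS$H2O)
  if (five_prime == "P" && three_prime == "OH") return(MASS$H2O)
  if (five_prime == "OH" && three_prime == "OH") return(MASS$H2O - MASS$HPO3)
  if (five_prime == "OH" && three_prime == "cyclicP") return(0)
  if (five_prime == "P" && three_prime == "P") return(MASS$H2O + MASS$HPO3)
  if (five_prime == "P" && three_prime == "cyclicP") return(MASS$HPO3)
  stop("unsupported terminus combination")
}

#' Monoisotopic mass of a modified oligonucleotide
#'
#' Sums monoisotopic residue masses (each methyl adds 14.01565 Da) and
#' adjusts for the terminal chemistry carried by the sequence object. The
#' methylated 12-mer `UUCCUUAAm1AUAGp` (5'-OH, 3'-phosphate) weighs
#' 3833.49 Da; the tetramer `AAm1AUp` 1325.21 Da.
#'
#' @param seq A `mod_rna` or shorthand string (see [parse_mod_string()]).
#' @return Neutral monoisotopic mass in Da.
#' @export
oligo_mass <- function(seq) {
  if (is.character(seq)) seq <- parse_mod_string(seq)
  sum(.residue_masses(seq)) + .terminus_adjust(seq$five_prime,
                                               seq$three_prime)
}

#' Negative-mode m/z for a given charge
#'
#' `(M - n * 1.0072765) / n` for charge state `n` in negative ion mode.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Charge state, integer >= 1.
#' @return m/z value.
#' @export
mz <- function(mass, charge = 1L) {
  stopifnot(mass > 0, charge >= 1)
  out <- (mass - charge * MASS$proton) / charge
  if (any(out <= 0)) stop("nonpositive m/z: charge too high for mass")
  out
}

# ---- digestion -------------------------------------------------------------

.cut_after <- function(x, enzyme) {
  res <- x$residues
  target <- switch(enzyme,
    RNaseT1 = res$base == "G",
    RNaseA = res$base %in% c("C", "U"),
    stop("unknown enzyme: ", enzyme)
  )
  # 2'-O-methyl on the residue 5' of the scissile bond blocks cleavage
  cut <- which(target & !res$sugar_2ome)
  cut[cut < length(x)]  # a cut after the last residue is a no-op
}

#' In-silico ribonuclease digestion
#'
#' RNase T1 cleaves 3' of guanosine, RNase A 3' of pyrimidines (C, U); a
#' 2'-O-methylated ribose on the residue 5' of the scissile bond blocks
#' cleavage. Internal products carry 5'-OH and 3'-phosphate (linear, the
#' default; pass `cyclic = TRUE` for 2',3'-cyclic phosphate); terminal
#' products keep the parent's terminal chemistry. With `missed_cleavages = k`
#' all unions of up to `k + 1` adjacent fragments are also emitted, flagged
#' by their `missed` count.
#'
#' @param seq A `mod_rna` or shorthand string.
#' @param enzyme `"RNaseT1"` or `"RNaseA"`.
#' @param missed_cleavages Integer >= 0.
#' @param cyclic Emit 2',3'-cyclic phosphate products instead of linear 3'-P.
#' @return List of `rna_fragment` objects: each has `$seq` (a `mod_rna`
#'   anchored in parent coordinates), `$start`, `$end` (parent 1-based
#'   inclusive), `$enzyme`, `$missed`.
#' @export
digest <- function(seq, enzyme = c("RNaseT1", "RNaseA"),
                   missed_cleavages = 0L, cyclic = FALSE) {
  if (is.character(seq)) seq <- parse_mod_string(seq)
  enzyme <- match.arg(enzyme)
  n <- length(seq)
  cuts <- .cut_after(seq, enzyme)
  bounds <- cbind(start = c(1L, cuts + 1L), end = c(cuts, n))
  k <- nrow(bounds)
  frags <- list()
  for (i in seq_len(k)) {
    jmax <- min(k, i + missed_cleavages)
    for (j in i:jmax) {
      from <- unname(bounds[i, "start"]); to <- unname(bounds[j, "end"])
      fs <- mod_rna_slice(seq, from, to)
      if (to < n) {
        fs$three_prime <- if (cyclic) "cyclicP" else "P"
      }
      frags[[length(frags) + 1L]] <- structure(
        list(seq = fs,
             start = seq$start_pos + from - 1L,
             end = seq$start_pos + to - 1L,
             enzyme = enzyme,
             missed = j - i),
        class = "rna_fragment")
    }
  }
  frags
}

#' @export
print.rna_fragment <- function(x, ...) {
  cat(sprintf("%s fragment %d-%d (%s)%s: %s  [M] %.4f\n", x$enzyme,
              x$start, x$end, x$seq$coord_name,
              if (x$missed > 0) sprintf(" missed=%d", x$missed) else "",
              render_mod_string(x$seq), oligo_mass(x$seq)))
  invisible(x)
}

#' Tabulate a digest
#'
#' @param fragments List returned by [digest()].
#' @param charges Charge states for which m/z columns are added.
#' @return data.frame with fragment shorthand, span, length, neutral mass and
#'   per-charge negative-mode m/z.
#' @export
digest_table <- function(fragments, charges = 1:2) {
  df <- data.frame(
    fragment = vapply(fragments, function(f) render_mod_string(f$seq), ""),
    start = vapply(fragments, function(f) f$start, 0L),
    end = vapply(fragments, function(f) f$end, 0L),
    length = vapply(fragments, function(f) length(f$seq), 0L),
    missed = vapply(fragments, function(f) f$missed, 0L),
    mass = vapply(fragments, function(f) oligo_mass(f$seq), 0)
  )
  for (z in charges) df[[paste0("mz", z)]] <- mz(df$mass, z)
  df
}

# ---- CID product ions ------------------------------------------------------

#' CID product-ion series of an oligonucleotide fragment
#'
#' Computes neutral masses and negative-mode m/z for the 5'-side `c` and `a`
#' (and `a-B`) series and the 3'-side `y` and `w` series, the ions typically
#' assigned in negative-mode CID of RNase digestion products. For a parent
#' with 5'-OH: `c_i = sum(res 1..i) + H2O`, `a_i = c_i - HPO3`,
#' `(a-B)_i = a_i - BH(base i)`; `y_k` is the mass of the last `k` residues
#' with 5'-OH and the parent's own 3' terminus, `w_k = y_k + HPO3`. For 5'-P
#' parents the 5'-side series gain one HPO3. Complementary pairs obey
#' `c_i + y_(n-i) = M + H2O` and `a_i + w_(n-i) = M + H2O`.
#'
#' @param frag A `rna_fragment`, `mod_rna`, or shorthand string.
#' @param series Subset of `c("c", "y", "w", "a", "a-B")`.
#' @param max_charge Charges 1..max_charge are reported.
#' @return data.frame with columns `series`, `index`, `charge`,
#'   `neutral_mass`, `mz`.
#' @export
cid_series <- function(frag, series = c("c", "y", "w"), max_charge = 2L) {
  x <- if (inherits(frag, "rna_fragment")) frag$seq
       else if (is.character(frag)) parse_mod_string(frag)
       else frag
  stopifnot(inherits(x, "mod_rna"))
  n <- length(x)
  if (n < 2L) stop("fragment must have length >= 2 for CID series")
  bad <- setdiff(series, c("c", "y", "w", "a", "a-B"))
  if (length(bad)) stop("unknown ion series: ", paste(bad, collapse = ", "))
  rm_ <- .residue_masses(x)
  p5 <- if (x$five_prime == "P") MASS$HPO3 else 0
  csum <- cumsum(rm_)
  out <- list()
  add <- function(s, i, m) {
    for (z in seq_len(max_charge)) {
      out[[length(out) + 1L]] <<- data.frame(
        series = s, index = i, charge = z, neutral_mass = m, mz = mz(m, z))
    }
  }
  idx5 <- seq_len(n - 1L)  # internal cleavage sites
  if ("c" %in% series)
    for (i in idx5) add("c", i, csum[i] + MASS$H2O + p5)
  if ("a" %in% series)
    for (i in idx5) add("a", i, csum[i] + MASS$H2O - MASS$HPO3 + p5)
  if ("a-B" %in% series) {
    res <- x$residues
    for (i in idx5) {
      bh <- if (!is.na(res$base_mod[i])) MASS$baseBH[[res$base_mod[i]]]
            else MASS$baseBH[[res$base[i]]]
      add("a-B", i, csum[i] + MASS$H2O - MASS$HPO3 + p5 - bh)
    }
  }
  if (any(c("y", "w") %in% series)) {
    t3 <- .terminus_adjust("OH", x$three_prime)
    for (k in seq_len(n - 1L)) {
      ym <- sum(rm_[(n - k + 1L):n]) + t3
      if ("y" %in% series) add("y", k, ym)
      if ("w" %in% series) add("w", k, ym + MASS$HPO3)
    }
  }
  do.call(rbind, out)
}

#' Match observed ions against candidate product ions
#'
#' Each observation is paired with the candidate of the same charge that
#' minimizes the absolute ppm deviation, provided it falls within
#' `tol_ppm`; otherwise the observation is reported unmatched.
#'
#' @param observed data.frame with columns `mz` and `charge`.
#' @param candidates data.frame as produced by [cid_series()] (needs columns
#'   `mz`, `charge`; other columns are carried through).
#' @param tol_ppm Matching tolerance in ppm (> 0).
#' @return `observed` augmented with the best candidate's columns, the signed
#'   `ppm` deviation and a logical `matched`.
#' @export
match_ions <- function(observed, candidates, tol_ppm = 20) {
  stopifnot(tol_ppm > 0, is.data.frame(observed),
            all(c("mz", "charge") %in% names(observed)))
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("empty candidate list")
  res <- observed
  res$matched <- FALSE
  res$ppm <- NA_real_
  carry <- setdiff(names(candidates), c("mz", "charge"))
  for (col in carry) res[[paste0("cand_", col)]] <- NA
  res$cand_mz <- NA_real_
  for (i in seq_len(nrow(observed))) {
    cc <- candidates[candidates$charge == observed$charge[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    ppm <- (observed$mz[i] - cc$mz) / cc$mz * 1e6
    j <- which.min(abs(ppm))
    if (abs(ppm[j]) <= tol_ppm) {
      res$matched[i] <- TRUE
      res$ppm[i] <- ppm[j]
      res$cand_mz[i] <- cc$mz[j]
      for (col in carry) res[[paste0("cand_", col)]][i] <- cc[[col]][j]
    }
  }
  res
}
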