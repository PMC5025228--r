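---
title: "Methods: detecting rRNA base modifications from sequencing and mass-spec signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting rRNA base modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnamodkit)
```

## The problem

A 1-methyladenosine (m¹A) in an rRNA cannot base-pair on its Watson–Crick
face. Two experimental readouts follow, and this package implements the
computation behind both. First, reverse transcriptase misincorporates
opposite the lesion, so RNA-seq reads over a DNA-encoded adenosine show a
mixture of A, T and G — an RNA–DNA difference (RDD) — together with a local
dip in coverage from partial RT arrest. Second, the methyl group adds
exactly one CH₂ (14.01565 Da monoisotopic) to a ribonuclease digestion
fragment, which LC/ESI-MS resolves. The package also covers the satellite
analyses these experiments need: anchoring the orthologous position in
other mitochondrial genomes, verifying genome-edited constructs in silico
(MAGE oligos, MluCI RFLP, T7 templates), and summarizing reporter kinetics
from growth experiments on edited bacterial strains.

## Sequence model and conventions

All coordinates are 1-based inclusive, everywhere — fragment spans,
pileups, restriction sites, anchor positions. The `mod_rna` container holds
RNA residues with an optional registered base modification, an optional
2′-O-methyl on the ribose, terminal chemistry at both ends, and an anchor
(`start_pos`, `coord_name`) into a named parent system such as
"human 16S rRNA". A fixed offset map converts between systems
(`parent = local + offset`; the shipped 16S→mtDNA map uses offset 1670, so
947 ↔ 2617). The RNA and DNA alphabets are kept strictly separate;
`transcribe()`/`rna_to_dna()` are the only crossings. This avoids the
class of bug where a T7 template (DNA, both strands in play) silently mixes
with its transcript (RNA, one strand) in coordinate arithmetic.

The modification registry (label, base constraint, mass delta) is
extensible at run time, so additional marks need no code change; shorthand
parsing accepts any registered `m<digits><base>` token.

## Masses, m/z and CID series

Residue masses are monoisotopic nucleoside-monophosphate residues
(A 329.05252, C 305.04129, G 345.04744, U 306.02530 Da), so a linear oligo
carrying one terminal phosphate weighs Σresidues + H₂O; terminal variants
differ by HPO₃ (79.966331) and H₂O (18.010565), and a 2′,3′-cyclic
phosphate is a dehydrated 3′-phosphate. Each methyl — base methyl or
2′-O-methyl alike — adds 14.01565 Da. Negative-mode m/z is
(M − n·1.0072765)/n.

Digestion products default to **linear 3′-phosphate** termini. RNase T1 and
RNase A proceed through a 2′,3′-cyclic intermediate that hydrolyses to the
linear phosphate; all the masses these instruments conventionally print for
such digests (e.g. 3833.5 for the methylated 12-mer, 1325.21/1311.19 for
the tetramers, 721.1 for GmGp) match the linear form, which is therefore
the default; `digest(..., cyclic = TRUE)` emits the cyclic form.

Cleavage specificity is strict single-nucleotide context: T1 cuts 3′ of G,
RNase A 3′ of C/U, and a 2′-O-methyl on the residue 5′ of the scissile
bond blocks the cut (the ribose 2′-OH is the attacking nucleophile). That
last rule is what lets the di-methylated 11-mer `UUUmGmUUCAACGp` survive T1
intact despite its internal G. No sequence-context weighting is modeled.

CID series follow the standard oligonucleotide nomenclature: for a 5′-OH
parent, `c_i = Σ(res 1..i) + H₂O`, `a_i = c_i − HPO₃`,
`(a−B)_i = a_i − BH(base i)` (with the methylated base mass when the base
is modified), `y_k` is the 3′ suffix with the parent's own 3′ terminus and
`w_k = y_k + HPO₃`; 5′-P parents add HPO₃ to the 5′-side series. The
complementary-pair identities `c_i + y_(n−i) = a_i + w_(n−i) = M + H₂O`
hold by construction and are property-tested against an oracle that builds
masses from elemental compositions. Default reported series are {c, y, w}
at charges 1–2, which is what gets assigned in practice for small
fragments.

One known discrepancy is documented rather than asserted: the triply
charged 11-mer `UUUmGmUUCAACGp` is conventionally quoted at m/z 1177.2,
while the monoisotopic prediction is 1177.14; whether the quoted figure is
an observed centroid or theoretical value is not stated at the source, so
it is excluded from exact checks.

## RDD calling

`build_pileup()` tallies per-position, per-strand, per-base counts from a
SAM/BAM. "High quality" is parameterized rather than hard-coded, since the
original analyses do not pin it down: defaults are base quality ≥ 30,
MAPQ ≥ 20, and exclusion of calls within 5 nt of either read end. These are
deliberately conservative; users comparing against differently filtered
pipelines should run a sensitivity sweep over these three knobs.

`call_rdd()` applies the two published filters exactly: **filter A**,
pooled quality-passing coverage ≥ 1000 reads; **filter B**, the most
frequent non-reference base reaches ≥ 1.6% of pooled coverage *and* ≥ 0.8%
of the reads on each strand separately (per-strand denominators). A site is
an RDD iff both pass and the edge-artifact flag is clear. Filter A can be
overridden per sample in the panel table (the original survey waived it for
one low-coverage species). The manual genome-browser inspection of
read-edge artifacts is automated as a one-sided binomial test: under the
null a variant call lands within `window` of a read end with probability
`2·window/read_length`; sites with excess edge calls at α = 0.01 are
flagged.

The m¹A signature at an A-reference site combines the misincorporation
rate, `f(T) + f(G)`, with the coverage drop
`max(0, 1 − cov(site)/median flank coverage)`. The flank median should be
taken over a window wider than a read length (the RT-arrest dip decays over
roughly one read length downstream of the site); the pipeline default is
±200 nt for 100-nt reads.

"Prevalence" of the modification in a sample is defined here as
`rdd_level = 1 − f(reference base)` at the site, pooled over strands; the
underlying per-class read counts are not published, so this definition is
the package's own and is used consistently on both sides of any
comparison. Two-sample comparisons use Pearson χ² on the 2×2
(non-reference, reference) table with 1 df and no continuity correction —
counts in this setting are in the thousands, where Yates' correction only
biases — with a Fisher exact fallback whenever an expected cell drops
below 5.

## Ortholog anchoring

The counterpart of a query position in another mitochondrial genome is
found by local alignment of a 61-nt window (±30) centred on the query
position: Smith–Waterman with match +2, mismatch −1, linear gap −2, no
affine gaps — indels immediately at this highly conserved site are rare
enough that affine gap modeling buys nothing. 61 nt is long enough to be
unique in a 16–17 kb mtDNA and short enough for exact DP. The anchor is
the target column aligned to the window centre; the call fails loudly when
the best score is below 60% of the perfect score, when the centre is
deleted in the alignment, or when co-optimal alignments disagree — silent
mis-anchoring is the failure mode to avoid. The DP score is cross-checked
in tests against `Biostrings::pairwiseAlignment` as an independent oracle.

## Construct design and verification

MAGE oligos are 90-mers against the lagging strand with the edited base at
offset 46 (= ⌈L/2⌉ + 1) and phosphorothioate bonds on the two outermost
linkages at each end; both placements are read off the published oligos
(the asterisk typography is interpreted as exactly two terminal
phosphorothioates per end — flagged as an inference). Un-editing a
designed oligo and reverse-complementing must recover a gene-strand
substring exactly, and does, by construction and by test.

MluCI is modeled as "cut immediately before AATT" (5′ overhang). Only
fragment lengths are reported, so overhang geometry does not affect any
output; lengths always partition the amplicon. Overlap assembly searches
all orders and orientations for a chain of exact suffix–prefix overlaps
(≥ 15 nt) and demands a unique result up to reverse complement; the
returned strand is canonicalized, and `t7_runoff()` therefore searches both
strands for the T7 promoter, requires G at +1 (class III promoters
initiate on G), and transcribes to the template end. The genomic rrlB
region around the edited position lives behind an external accession, so
RFLP verification runs on the published oligos and synthetic amplicons.

## Reporter kinetics

The production-rate statistic is taken as published: per-interval reporter
increment divided by the OD at the interval's end,
`r_t = (F_t − F_(t−1))/OD_t`, on the raw series (no smoothing by default —
whether the original curves were smoothed is unstated, and smoothing is
trivially composable upstream). "Total production" integrates that series
by the trapezoid rule on the measurement grid; the source defines it only
as "the area under it", and the trapezoid is the standard estimator on a
30-min grid. Maximal growth rate is the maximal 5-point sliding-window
slope of ln OD. No blank subtraction is applied by default. The published
relative percentages from the bacterial experiments (64.4/76.2, 75/83.6,
109/110.1) depend on unpublished raw plate data and are therefore
documentation examples only; what the tests verify instead is that a
simulated strain pair with a known per-cell production ratio is recovered
within five percentage points.

## What the simulator emulates — and what it does not

`simulate_reads()` places fixed-length reads uniformly over the reference,
splits them between strands, and at one site draws the emitted base from
(1 − p_T − p_G, p_T, p_G) before applying a uniform error rate; with
probability `p_trunc` a site-covering read is instead clipped so its
alignment ends just before the site, the proxy used for RT arrest (a
strand-directional variant is the obvious extension but is not the
default). Base qualities are constant Q37 and MAPQ 60, keeping the quality
filters deterministic in tests. Ground truth (parameters plus realized
per-strand counts) is serialized alongside the SAM, and an error-free
simulation round-trips exactly through `build_pileup()`.

The simulator does **not** model indels, quality miscalibration,
library-prep or strand biases beyond the site signature, mapping ambiguity,
or NUMT contamination. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated generative model, not that real
mitochondrial RNA-seq is free of those artifacts — that is exactly why the
edge-artifact test and the per-strand filter B exist.

`simulate_kinetics()` grows OD logistically (carrying capacity K, rate r,
lag, inoculum od0) and accumulates fluorescence increments
`prod_rate · OD_t` plus Gaussian noise, so the production-rate statistic
recovers `prod_rate` exactly at zero noise. Because the statistic divides
the increment by OD, additive noise is amplified by 1/OD at early time
points; recovery tests accordingly use a noise SD small relative to the
early-phase increment (`prod_rate · od0`), which is also the regime real
plate readers operate in for fluorescent reporters.

## Problem sizes and numerical choices

Test and demo simulations run at coverage 600–2000 over 200–600 nt
references with 50–100 nt reads, and 6–42 kinetics replicates — sizes at
which binomial standard errors make the 3·SE recovery criteria meaningful
while the whole suite stays fast on a laptop. Mass comparisons use
absolute tolerances of 0.01 Da (0.05 for values printed to one decimal);
reported values round half-up to the printed precision. Chi-square
verdicts are validated exhaustively against a closed-form oracle on small
tables. Seeds are fixed in every stochastic test; all generators are
seed-deterministic and version-stamped in their truth records.

## Known limitations

Single-site substitution signatures only (no indel RDDs, no
transcriptome-wide m¹A atlas); no spectrum deconvolution, isotope
envelopes or raw mzML parsing on the MS side; average (as opposed to
monoisotopic) masses are not implemented since every reference value here
is monoisotopic; ortholog anchoring assumes a locally alignable window and
will refuse rearranged or highly diverged targets rather than guess.
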