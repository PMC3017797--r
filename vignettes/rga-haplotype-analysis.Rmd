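---
title: "Comparing resistance-gene-analog cluster haplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing resistance-gene-analog cluster haplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplorga)
```

# The problem

Plant disease-resistance gene analogs (RGAs) of the CC-NB-LRR class sit in
tandem clusters that evolve fast: copies duplicate, degrade into
pseudogenes and remnants, exchange sequence by unequal recombination, and
accumulate transposable-element insertions. In a heterozygous diploid the
two haplotypes of such a cluster can differ substantially in gene content
while the flanking regions stay colinear at ~99% identity. `haplorga`
implements the comparative analysis of one such locus pair end to end:
structural comparison, molecular dating, repeat annotation, gene-family
analysis, and recombination detection — plus a simulator that generates
haplotype pairs with known ground truth, so every stage is testable
without any external data.

# Models and procedures

## Colinearity and divergence cataloguing

Anchors are maximal exact matches seeded by shared *k*-mers (default
`k = 15`), with seeds occurring more than `max_kmer_freq = 8` times in
either sequence discarded so that high-copy repeats do not flood the
dotplot. Anchors are chained by dynamic programming into the
highest-scoring monotone chain; chains break where the unanchored gap on
either sequence exceeds `max_gap = 5000` bases, and blocks shorter than
`min_block = 500` bases are dropped. Reverse-strand anchors are computed
and exported (they reveal inversions) but never chained into forward
blocks.

Blocks are refined to base level with an affine-gap global aligner
(match +1, mismatch −2, gap open −6, gap extend −1; a gap of length
*L* costs 6 + *L*). These scores are tuned for the ~99%-identity regime
of allelic comparisons. The kernel is a banded Needleman–Wunsch/Gotoh in
C++; the band auto-widens whenever the optimal path touches the band
edge, so results are never silently truncated, and drift-dominated
problems (one large indel) fall back to an exact full dynamic program.
Blocks too large for full DP are aligned piecewise through their
anchors. Identity is computed over aligned non-gap columns; gap runs are
reported separately as indel events with carrier haplotype — mirroring
the field's convention of reporting SNPs and indels separately.
Nucleotide diversity is substitutions divided by aligned non-gap
columns, optionally masked to coding columns.

## Molecular dating

Two neutral clocks:

* **Coding divergence.** For an allelic CDS pair, synonymous sites (S)
  and synonymous differences (Sd) are counted by the Nei–Gojobori
  pathway method: per codon, each position contributes the fraction of
  its three one-step changes that are synonymous (averaged between the
  two sequences); codon pairs differing at *d* positions average Sd/Nd
  over all *d*! substitution pathways, excluding pathways through stop
  codons and re-weighting the remainder equally. Codons containing gaps,
  ambiguity codes, or stop codons are skipped. The synonymous
  p-distance pS = Sd/S is left uncorrected by default (a Jukes–Cantor
  flag exists), and the divergence time is T = pS/(2r) with
  r = 4.5×10⁻⁹ synonymous substitutions/site/year, the rate established
  for banana coding sequences. The headline estimate uses the
  concatenation of all allelic pairs; per-pair rows are also reported.
  A worked example: pS = 0.0088 gives T ≈ 0.98 MY.

* **LTR retroelement insertion age.** The two long terminal repeats of
  an element are identical at insertion, so their Kimura 2-parameter
  distance K = −½ln(1−2P−Q) − ¼ln(1−2Q) dates the insertion as
  T = K/(2r) with r = 9×10⁻⁹/site/year (noncoding, twice the coding
  rate). Saturated alignments raise an explicit error rather than a
  number.

The pathway enumeration is verified in the test suite against an
independent brute-force enumerator, and K2P against `ape`'s K80
distance.

## LTR retroelement structure

A candidate region is compared against itself with the same *k*-mer
anchoring; a pair of direct repeats near the two ends of the region is
the LTR pair. The pair is refined by local alignment, and because a
local alignment can over- or under-run the true boundary by a few bases
when flanking bases match by chance, boundaries are snapped to the
canonical TG…CA termini when these are found within eight bases.
Flanks are then scanned for a 4–6-base target-site duplication (TSD),
longest first, exact by default (one mismatch allowed behind a flag, to
accommodate post-insertion mutation of one TSD copy). Only LTR pairs of
at least 300 bases are dated by default — shorter pairs give unstable
K2P estimates.

## SSR analysis

Maximal perfect tandem repeats with unit sizes 2–6 are reported;
homopolymers are excluded and nested reports suppressed by restricting
to primitive units (a (CTCT)ₙ run is one CT locus). Motifs are
canonicalised to the lexicographically minimal rotation over both
strands, making the scan strand-symmetric and collapsing CT/TC/AG/GA
into one class. Minimum repeat counts (di ≥ 6, tri ≥ 5, tetra–hexa ≥ 4)
follow common SSR-survey practice; published SSR censuses are
threshold-dependent, so these are configurable. Cross-haplotype matching
projects each locus through the colinear blocks via the nearest anchor
and pairs same-motif loci within a positional tolerance; loci inside RGA
coding sequence are excluded from the common-SSR report because
orthology there is ambiguous. Within coding sequence, a dedicated
scanner reports trinucleotide repeats with their encoded amino-acid
tract and merges adjacent same-frame units into compound reports.

## RGA family analysis

Gene models are classified by completeness with rules evaluated
most-degraded-first: **remnant** (Qcov < 0.3, or more than three
alignment fragments with Qcov < 0.5, or more than two
expression-preventing disruptions), else **pseudogene** (any
disruption: missing start/stop, non-canonical splice, frameshift,
in-frame stop, TE insertion), else **fragment** (Qcov < 0.8), else
**complete** (Qcov ≥ 0.8 and Scov ≥ 0.8). The precedence is a design
choice — the source rules carry no order — and most-degraded-first
prevents a Qcov-0.25 remnant from being labelled a fragment.

Allelic pairs are reciprocal best identities restricted to opposite
haplotypes at identity ≥ 0.90; when a gene's best and second-best
cross-haplotype identities are within `tie_margin = 0.01`, that gene is
flagged ambiguous instead of paired (the signature of a recent
within-haplotype duplication), but its tied partners keep their own
pairings if those are unambiguous — quarantining the whole tied set
proved wrong on simulated data, where a chimeric gene tied to two
parents would otherwise knock out the parents' true pairings. Clades
come from average-linkage clustering on 1 − identity cut at 0.80,
between the ~70% inter-clade and >90% intra-clade identities typical of
these clusters; labels are deterministic (ordered by smallest member
position).

NB-ARC motifs (P-loop, RNBS-A, kinase-2, RNBS-B, RNBS-C, GLPL, RNBS-D,
MHD) are located by ordered best match of configurable seed patterns —
the defaults are reasonable consensus regexes, not authoritative, and
can be overridden. LRR repeats are scanned against the consensus
`LxxLxxLxxLxLxx(N/C/T)x(x)LxxIPxx` (L = aliphatic L/I/V/M/F; one
optional extra x), scoring each candidate as the fraction of constrained
positions satisfied and accepting at 0.7 — the consensus is a
manual-curation guide, so a tolerance is required. The x positions of
the LxxLxLxx core are reported as solvent-exposed positions.

## Recombination breakpoints

The identity-shift procedure: candidate parents are globally aligned to
the putative recombinant, identity is computed in sliding windows
(default window 100, step 10) on recombinant coordinates with gap
columns counted as mismatches, and windows with under 50% parent
coverage masked. A breakpoint is called between adjacent runs of
different best-parent labels when both runs span ≥ `min_run = 3` windows
and the winner's mean advantage is ≥ `min_delta = 0.02` on both sides —
so isolated single-window flips never call. Breakpoint coordinates are
method-defined to window resolution (± window/2 + step). Statistical
recombination tests (RDP-style p-values) are deliberately out of scope.

For intergenic events, all occurrences of a duplicated ~1-kb intergenic
probe are located on both strands of both haplotypes (local alignment at
identity ≥ 0.7, non-overlapping best-first, one candidate region per
seed-diagonal cluster), and every colinearity discontinuity — block
boundary or indel cluster totalling ≥ 5 kb within 2 kb — lying within
`flank = 2000` bases of such an occurrence is reported, with an identity
profile of the two nearest copies against the fused junction attached.
Indels are clustered before thresholding because a large deletion
spanning paralogous genes is often split across bridging alignments; for
the same reason the reported event position can be displaced by a few
kilobases from the true junction when paralogs flank it. This is a
genuine resolution limit of identity-based breakpoint placement in
repeat-rich clusters, and the truth-table tests assert placement within
that resolution, not to the base.

# The simulator and what it does (and does not) show

`simulation_config()` defaults describe the study conditions the
pipeline targets: one ancestral locus of ~60 kb (sized so replicated
simulation studies remain fast while every structural feature keeps its
natural scale; all lengths are configurable), carrying four flanking
genes, a central
array of 8 RGA copies (two clades at ~70% template identity, ~6%
paralog divergence within clades, LRR/NB-ARC structure built from the
consensus so annotation ground truth is exact), one complete MTERF-like
gene plus fragments, a 1-kb intergenic repeat at 0.75–0.95 identity in
four copies, and six perfect SSR loci. Intergenic background is 40% GC,
and codon choice during reverse translation is weighted by the same base
composition so the whole locus meets the 40% target.

Divergence is site-independent Poisson with a 2:1
transition:transversion ratio (so K2P is well-specified): noncoding
sites at 9×10⁻⁹/site/yr × T per haplotype, and coding sites as
synonymous one-step changes with expectation 4.5×10⁻⁹ per synonymous
site per year — proposing from the exact synonymous-opportunity set
makes the recovery test unbiased in expectation while leaving protein
sequences intact. SSR slippage deltas are configured, not stochastic, so
heterozygosity truth is exact. LTR elements are inserted with an exact
LTR pair subsequently diverged to 2rT of the element age (termini
conserved) and a duplicated target site. One intragenic event replaces
the last RGA on haplotype B with a chimera of two paralogs; one
intergenic event deletes the span between two intergenic-repeat copies
on B, removing two genes.

What passing tests show: the pipeline recovers planted structure and
clock parameters under the model's own assumptions. What they do not
show: robustness to indel evolution within genes (the simulator plants
structural indels only), to nested or decayed transposable elements, to
imperfect/compound SSRs, to sequencing or assembly error, or to
selection (nonsynonymous divergence is configured, not evolved). Real
annotations also carry gene models with introns and fuzzy boundaries;
the simulator's RGAs are single-exon, as CC-NB-LRR genes typically are.

# Numerical choices and degenerate inputs

* Alignment scores: match +1 / mismatch −2 / gap −6 − L. Identity
  excludes gap columns everywhere except inside recombination windows,
  where gaps count as mismatches (conservative against indel-rich
  misalignments).
* Saturated K2P (log argument ≤ 0) and zero-eligible-column inputs
  raise errors; p-distance with zero synonymous sites raises an error
  rather than returning NaN.
* IUPAC ambiguity codes are accepted on input and excluded (treated as
  N) by every distance computation.
* CDS extraction flags, rather than rejects, lengths not divisible by
  three — such genes are pseudogene/fragment candidates.
* Ties: ambiguous allele ties are flagged (above); equal-identity
  windows in breakpoint labelling are left unlabelled; clade labels are
  ordered by smallest member position so output is permutation-stable.
* All randomness flows from the single configuration seed; a fixed
  configuration reproduces byte-identical fixtures.

# Problem sizes used in the checks

The bundled checks run the generator at its default 60-kb scale:
50 simulated haplotype pairs for clock recovery (divergence time from
~11 concatenated kilobases of allelic CDS per pair; element ages of
0.3/1.2/2.2 MY from 382–447-bp LTR pairs), 200 random 30-codon pairs
against the brute-force pathway enumerator, 100 random 2-kb chimeras
for breakpoint recovery, and full-grid classifier verification. A
single 382-bp LTR pair at 0.3 MY carries an expected ~2 substitutions,
so individual age estimates are noisy by construction; recovery is
therefore asserted on the mean across replicates within three standard
errors.

# Known limitations

* Block boundaries are algorithm-defined; published block lengths
  depend on the original authors' (unstated) dotplot parameters.
* Breakpoint placement degrades gracefully but measurably when the
  recombining region is flanked by high-identity paralogs (see above).
* The EMBL reader supports the ID/FT/SQ blocks and join/complement/order
  locations — enough for deposited genomic records; anything else
  errors loudly.
* SSR censuses are threshold-dependent; absolute counts are not
  comparable across tools without matching thresholds.
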