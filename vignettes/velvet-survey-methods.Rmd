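---
title: "Methods: a desk-scale velvet-domain family survey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale velvet-domain family survey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velvetsurvey)
```

## What the package models

Velvet proteins are fungal transcription regulators that share one
conserved, NF-κB-like DNA-binding domain of roughly 200 residues while
differing widely in overall length and in what else the protein carries.
A kingdom-scale survey of such a family asks a fixed sequence of
questions: which proteins in each proteome carry a *complete* domain; how
many domain genes a genome carries and how long the proteins and domains
are; where in the protein the domain sits; how the domain sequences group
into clades around the classical reference members (VeA, VelB, VelC,
VosA); and which residues stay conserved across all clades.

`velvetsurvey` implements that pipeline end to end at desk scale, paired
with a synthetic-proteome generator that plants a velvet-like family with
known ground truth. Every stage can therefore be scored against truth —
detection sensitivity, coordinate accuracy, clade recovery, conserved-site
recall — without downloading any external data. The generator is a test
harness for the pipeline, not an inference claim about velvet evolution.

## The synthetic family generator

The root domain is built from three conserved motif blocks of exactly 33,
44 and 36 residues (the "around" lengths reported for the three
characteristic velvet motifs are fixed to make truth checks crisp),
joined by an unconserved linker of 20–40 residues between motifs 1 and 2
and a short 6–12 residue spacer between motifs 2 and 3. Evolution is a
per-site substitution process: a lineage at divergence $r$ substitutes
each linker site with probability $r$ and each motif site with
probability $r/4$, drawing replacements uniformly from the 19 alternative
residues. A planted set of *invariant* motif sites (48 by default — a
realistic planting density for a domain with ~48 cross-clade conserved
sites) never changes in any lineage; these are the sites the
conserved-residue caller should recover. Single-residue
insertions/deletions (rate 0.01/site) are restricted to linker and spacer
positions, so motif blocks keep their length and the root coordinate
system remains a well-defined match-state frame. Because of this, each
member's true alignment to the root — its **true match string** — is
recorded as part of the ground truth.

A survey wraps family members into proteomes: per genome, a gene count is
drawn from a configurable distribution (default mode 4, matching the most
common per-genome count in the largest fungal group); each gene embeds a
clade member between random uniform-composition flanks whose lengths are
rejection-sampled (at most 1000 attempts) until the drawn N/middle/C
position class is realized under the midpoint rule; decoys are
composition-shuffled copies of domain proteins, at an expected 0.4 per
genome (~10% of domain genes). Everything is deterministic given the
seed; internal stages draw from decorrelated streams so that, e.g., flank
residues can never echo motif content.

The default *detection* conditions are five taxonomic groups × 10
genomes, four clades at between/within-clade divergence 0.30/0.05 (a 6×
ratio), giving ~200 domain proteins. The *motif* conditions use 21 clades
(the clade count of a kingdom-wide survey) × 10 members at between/within
divergence 0.90/0.05; the high between-clade divergence is what makes
non-invariant sites visibly differ across clades, so that dominant-site
calling has both signal and contrast. With 21 clades, a non-invariant
motif column keeps a single modal residue across all clades with
probability $(1-0.9/4)^{21} \approx 0.9\%$, which bounds the expected
false dominant calls below one against 48 true sites.

What the generator does **not** emulate: real amino-acid composition and
substitution preferences (uniform background, uniform exchanges), rate
heterogeneity beyond the motif/linker dichotomy, domain gain/loss and
shuffling, multi-domain architectures, and realistic taxon sampling.
Passing tests therefore demonstrate that the pipeline's logic recovers
planted structure under its stated model — not that it would match any
particular biological data set.

## Profile construction and scanning

The seed alignment (simulated: indel-free root descendants at divergence
0.3) is reduced to match columns by the usual occupancy rule (a column is
a match column when ≥ 50% of rows hold a residue). Per match column $c$
and residue $a$ the emission score in bits is

$$e(c,a) = \log_2 \frac{(n_{c,a} + \alpha\,b_a)/(N_c+\alpha)}{b_a},$$

with counts over non-gap rows, pseudocount $\alpha = 1$ and uniform
background $b$. With $\alpha = 0$, unseen residues receive a −1000
sentinel rather than $-\infty$ so arithmetic stays finite. Scanning is
Smith–Waterman-style local dynamic programming of profile columns against
the protein with affine gaps (open −4 bits, extend −0.5 bits — lenient
enough that planted linker indels survive inside one hit); a local
alignment starts and ends with a column aligned to a residue. The
traceback yields 1-based inclusive coordinates, a length-$L$ match string
(`-` for unoccupied columns) and coverage = occupied columns / $L$.
Secondary hits are extracted greedily best-first with their span excluded
from the next pass; the survey model expects one domain per protein, so
multi-hit handling is defensive. Non-canonical letters (X, B, Z, U, …)
are scored as the background expectation of the column scores and logged,
never fatal. "Complete domain" is operationalized as coverage ≥ 0.8 and
score ≥ 15 bits; the original filtering criterion is qualitative, so
these are declared substitutes, not reconstructions.

## Survey statistics

The domain position is the midpoint fraction
$((\text{start}+\text{end})/2)/\text{length}$: N-terminal below 0.40,
C-terminal above 0.60, otherwise middle, with strict inequalities (0.40
and 0.60 are middle). Midpoints of even spans stay fractional — the rule
is a ratio, not an index. Per group the package reports the percentage of
genomes with at least one surviving hit, the per-genome count mode
*among velvet-positive genomes* (zero-count genomes are excluded from
mode and histogram but included in the percentage), mean protein and
domain lengths (domain length = end − start + 1 of the filtered hit), and
the position-class percentages. Mode ties break toward the smaller count
and carry a flag.

## Distances, trees, clades

Match strings share the profile coordinate system, so they form an
implicit alignment. The p-distance is the mismatch fraction over columns
where both sequences hold a residue; the default Poisson correction is
$-\ln(1-p)$, capped at 5.0 as $p \to 1$; pairs sharing fewer than 20
columns are flagged, and zero shared columns is an error except inside
bootstrap resampling, where the cap is used.

Neighbor joining is the canonical Saitou–Nei agglomeration with two
pinned semantics: Q ties break toward the smallest index pair in the
current working order (determinism), and a negative branch length is
clamped to zero with the deficit moved to its sister so the joined pair
keeps its total length. Zero-distance (duplicate) taxa are aggregated
into zero-length cherries *before* the Q iterations; plain NJ can
otherwise leave such a pair unresolved in the final trifurcation, and
duplicate aggregation is standard practice. On additive matrices the
implementation provably recovers the generating topology (tested against
exhaustive topology enumeration with least-squares branch fitting for up
to six taxa, and cross-checked against an independent NJ implementation).
Distance-based NJ stands in for the original maximum-likelihood stage by
design: it is deterministic, desk-scale and oracle-testable — an
emulation, not a reproduction.

Bootstrap support resamples match columns with replacement and counts,
per internal edge of the point tree, the replicates containing the same
bipartition. Clade assignment roots the tree on the outgroup; each
reference's clade is the largest rooted subtree containing that reference,
no other reference, and not the outgroup. Remaining leaves fall into
maximal reference-free subtrees whose parent edge has support ≥ 50 (a
threshold the original procedure never states; subtrees without a stored
support value pass), numbered `Velvet1, Velvet2, …` by decreasing size.
Supports are matched by bipartition rather than by node label, because
rerooting does not preserve label order. Note two consequences of the
"largest subtree" rule: with no references at all, the whole ingroup is
one `Velvet1`; and an unanchored clade that nests inside a single
reference's neighborhood is absorbed by that reference clade — it emerges
as `VelvetN` only when at least two references (or the outgroup) bracket
it. Clade names follow the survey convention: first three letters of each
spanned taxonomic group, capitalized, hyphen-joined (alphabetically),
then the anchor — `Pez-VosA`, `Sac-Tap-VelB`, `Bla-Cry-Velvet1`.

The deep two-clan split midpoint-roots the clade-consensus tree (no
explicit rooting rule exists for that tree, and midpoint rooting needs no
extra input); the two child subtrees of the root are the clans, labelled
by which anchor each contains, and both anchors landing in one subtree is
an error rather than a silent guess.

## Consensus logos and conserved sites

Column frequencies exclude gaps from the denominator (the sequence-logo
convention) and occupancy is reported separately. Information content is
$\log_2 20 - H$ bits with an optional small-sample correction
$e_n = 19/(2 \ln 2\, n)$, off by default so closed-form tests stay exact.
The consensus residue is the modal residue (ties alphabetical), `x` where
occupancy falls below 0.5. A position is *conserved* when every clade
reaches information content ≥ 2 bits and occupancy ≥ 0.5 there, and
*dominant* when all clades additionally share one modal residue. The
Bayesian phylogenetic conservation score used by the original analysis is
deliberately not re-implemented; these frequency thresholds are a
declared substitute, and the package's conserved-site counts are
validated against planted truth, not against any published count.

Two design points deserve emphasis:

* **Motif segmentation uses a pooled logo.** With low within-clade
  divergence, *every* column clears the per-clade conservation bar (each
  clade is internally near-identical), so per-clade conservation cannot
  separate motif blocks from the linker. Segmentation therefore
  thresholds a logo pooled over all clades, where only columns conserved
  across the whole family keep high information content; maximal runs of
  such columns, bridging gaps of up to 3 columns (below the minimum
  spacer length), give the motif blocks, and the three longest runs are
  reported in profile order.
* **Motif-level recovery is scored on true match strings.** Local
  alignment at high divergence introduces a selection bias: the DP gaps
  out unconserved columns and keeps only profile-favored residues, which
  inflates apparent conservation at linker columns under gap-excluding
  frequencies and depresses per-clade occupancy at motif boundaries. The
  generator's true match-state alignments avoid conflating that scanner
  effect with the conservation statistics; scanner alignment quality is
  measured separately by the coordinate-accuracy check. The scan-derived
  strings remain the pipeline path for clade classification, which
  operates at much lower divergence.

## Statistics and reporting

Two-group comparisons use the unpaired Student t-test with pooled
variance by default (a bare "unpaired t-test" is read as the textbook
pooled test; Welch is available via a flag), with significance at
p < 0.05 and high significance at p < 0.001. Two equal constant groups
give t = 0, p = 1; zero variance with unequal means is reported as p = 0
and flagged degenerate. Pairwise clade comparisons report raw p-values —
matching the original convention — with a Bonferroni column added for
transparency only. Box summaries use type-7 (linear interpolation)
quantiles, Tukey 1.5·IQR whiskers at the most extreme data points within
the fences, and notches at median ± 1.58·IQR/√n. The report bundle is
deterministic: rerunning on identical inputs reproduces byte-identical
tables.

## Problem sizes and determinism

The shipped analyses and checks run at: 50 genomes / ~225 proteins for
detection and clade recovery (ten seeds for the recovery sweep), 21
clades × 10 members for motif analyses (ten seeds for segmentation), 20
seeded matrices of 4–6 taxa for the NJ oracle, 100 bootstrap replicates,
and 2000 null replicates for the t-test calibration — sizes chosen so the
full pipeline reruns from scratch in a couple of minutes while keeping
every recovery estimate's sampling error well inside its acceptance
margin. All randomness flows from explicit seeds through decorrelated
per-stage streams; identical seeds give byte-identical outputs.

## Known limitations

The profile is a position-specific score matrix, not a full profile HMM:
no state transitions, no forward-algorithm probabilities, no E-values.
Distance NJ replaces likelihood tree inference. Conservation is
frequency-based, not phylogenetically weighted, so it over-calls
conservation within recently radiated clades (visible as the large
conserved-site count at the default per-clade thresholds). The generator's
uniform composition makes decoy rejection easier than real proteomes
would; the decoy check validates the coverage/score filter logic, not a
false-discovery rate on real data. Structure-level analyses
(3D modeling, structural alignment, localization signals) are out of
scope.
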