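---
title: "Methods: detecting divergent rRNA operon types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting divergent rRNA operon types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnhet)
```

# The problem

Prokaryotic genomes usually carry several rRNA operon copies that are
kept near-identical by gene conversion. Occasionally one copy is
massively divergent — in the motivating cyanobacterial case, one of five
operons differs from the others by 7–9% in the 16S gene while both
remain structurally intact and apparently functional. Such
*macroheterogeneity* breaks the assumptions behind 16S-based species
delimitation: a clone library from a single strain can look like two
distantly related organisms. `rrnhet` packages the comparative analyses
needed to recognize and characterize this situation. This vignette
explains the models and rules each stage uses, the tunable parameters,
what the synthetic data generator does and does not emulate, and the
design choices made where the procedure was genuinely open.

# Distances and identity

All distances are uncorrected p-distances: the share of differing sites
among compared sites, with identity defined as $100(1-p)$ and divergence
as $100p$, so the two always sum to 100 exactly. Under the default
**pairwise deletion** policy a column is compared only when both
sequences carry an unambiguous base; gaps, N and partial IUPAC codes are
missing data. This mirrors the common default of distance software, but
it means each pair may be compared over a different site set, so the
resulting matrix need not obey the triangle inequality — range summaries
(min–max identity over labelled pairs) are therefore reported with the
pair count. An alternative `gaps_as_difference` policy scores one-sided
gaps as differences for users who want indels to count. Reports print
identity to one decimal; all internal computation is full precision.

# Operon typing

A **signature position** is an alignment column at which each operon
type has a consensus base and the two differ. The consensus at a column
exists when the modal base among non-missing residues is unique and its
frequency (the *saturation*) is at least the threshold, default
`saturation_threshold = 0.85`. The denominator excludes missing data, so
sparse columns can still be called while a genuinely polymorphic column
cannot. Classification of a query scores the share of non-missing
signature positions equal to each type's consensus; the triple
(type 1, type 2, other) is rounded to integer percents by the
largest-remainder method so it sums to exactly 100. Rounding each share
independently can produce 99 or 101, and published per-type breakdowns
of this kind are ambiguous at exactly that level, so the policy is
explicit and configurable (`rounding = "none"` gives full precision).

A **reversion** is a sequence of one type carrying the *other* type's
consensus base at a signature position — the expected footprint of
partial gene conversion between operon copies. Reversions are reported
per position and per sequence; note that a position at which many copies
revert simultaneously loses its consensus and drops out of the signature
itself, so reversion counts are conditional on the recovered signature.

Type-specific primer design scans windows of 20–30 columns (configurable)
that are fully conserved — every target-type sequence identical, no gaps
or ambiguity in any row — and differ from the other type's consensus at
≥ 3 positions. These thresholds are design conventions, not measured
constants: 3 mismatches over a 20-mer is a conservative discrimination
margin for PCR, and a 3′-terminal mismatch (flagged in the output) is
the most discriminating position. Windows are reported leftmost-first,
then shortest; reverse primers are emitted 5′→3′ as reverse complements.

# Helix-level structure comparison

Reference helix coordinates are supplied as a table (molecule, helix
name, 5′ and 3′ strand intervals in model coordinates). The package does
not ship curated comparative-model coordinates: published helix maps are
modified per organism in ways that are not recoverable from print, so
the map is an input. `inst/extdata/helix_map_16s_synthetic.tsv` is a
clearly-labelled synthetic demonstration map (12 regular 10-bp helices)
used by the generator and the examples.

Folding is positional: base $i$ of the 5′ strand is tested against base
$L-i+1$ of the 3′ strand; canonical means Watson–Crick plus G·U wobble
(wobble is standard in rRNA covariation work; a flag disables it). The
**closure rule** handles positions that are mismatched in the reference
model: such a position is drawn paired when the target bases pair
canonically, provided at most `max_closable = 2` closures are needed in
that helix; if more would be needed the helix is left as in the
reference (no closures). Strand pairs of unequal consensus length are
reported as structure-altering rather than force-folded.

Variability localization assigns every signature position, via the
alignment-to-model column map, to the helix whose strand intervals
contain its model position, or to the unpaired regions; insertion
columns (a gap in exactly one type's gap-aware consensus) are attributed
to the helix containing the model position they follow. The counts
conserve: helix totals plus unpaired totals equal signature positions
plus indel columns. A helix is flagged structure-altering when folding
the two type consensuses yields different pairing masks.

# ITS annotation

The ITS is dissected by an ordered template search. Motif domains are
located by leftmost IUPAC match; helix domains (D1-D1′, V2, Box-B, V3)
by the first foldable stem-loop — leftmost start, then largest stem,
then smallest loop — under canonical pairing, with D1-D1′ required to
start within the first 40 nt of the ITS. Mandatory motifs (D2, D3,
Box-A, D4, D5) are located sequentially; the optional tRNA-Ile / V2 /
tRNA-Ala block is searched only between D3 and Box-A, so an absent tRNA
cannot corrupt downstream boundaries. The D2–D3 spacer is derived, not
searched. D5 is anchored by a motif and extends to the ITS 3′ end,
which is what lets the two architectures differ in D5 length (6 vs
15–16 nt) while sharing one anchor.

Only the D3 variants (GGTAY vs GGTTC) and the ITS start are fixed by
comparative evidence for the motivating group; full domain motifs are
not published. The shipped template table is therefore a documented,
editable starting point whose non-D3 motifs are synthetic placeholders,
and every test uses either those quoted variants or templates the
generator itself planted. Users annotating real ITS data should replace
the placeholders with organism-specific templates. tRNAs are found by
template motif, not covariance models — adequate for architecture
comparison, not for tRNA discovery.

# Promoter scanning

Upstream regions (ending at the transcript start, ≥ 60 nt) are scanned
for σ70 elements: −10 `TATAAT`, −35 `TTGACA`, optional extended −52
`AWWWWWTTTTT`. The −10 window is chosen first, maximizing the match
count among windows ending 3–6 nt before the 3′ end; then the −35 within
a 16–19 nt spacer upstream of it; then the −52 within a 7–9 nt spacer
further upstream. The spacer ranges are read off the spacing observed in
published promoter comparisons of this kind and are configurable; ties
go to the window closest to the 3′ end. Matching is conservative: a
query base matches when it lies in the consensus position's IUPAC class,
and an ambiguous or missing query base (including N) never matches. The
functional call is `matches(−35) ∈ [3,6]` and `matches(−10) ∈ [3,6]`;
the −52 element is reported but never contributes to the call. Position
weight matrices are deliberately out of scope — the rule being modelled
is a count rule.

# Genospecies delimitation

Three criteria, applied as monotone refinement. (1) *Identity*: strains
are linked when identity exceeds the threshold (default 98.7%) in
**every** available operon type — identity at or below threshold in
either operon separates, and the boundary value itself separates;
candidate clusters are connected components (single linkage, the
minimal-assumption reading when no clustering procedure is specified).
(2) *Phylogeny*: components are split when members occupy different
labelled tree clades; clade labels are user input (`clades_from_tree()`
reads them off a labelled newick tree as each tip's smallest labelled
ancestor) because no support-value cutoff can be defended in general.
(3) *Morphology*: components containing different morphospecies labels
are split even when molecular separation is weak. Each split records its
criterion in the provenance table. Later criteria can only split, never
merge, so the species count is non-decreasing in the evidence supplied.

# The synthetic generator

`generate_dataset()` emulates the study design: `n_species` species ×
`strains_per_species` strains × `operons_per_strain` operon copies
(default 5, of which `n_type1 = 1` is divergent). The divergent type
differs from the majority type at exactly `signature_positions`
(default 123) sites over `len_16s = 1500`, sampled inside designated
helices of the helix map so that heterogeneity is helix-localized as
observed in real macroheterogeneity; supplying `between_type_divergence`
instead plants `round(d × len_16s)` sites. The exact-count planting is
deliberate: the empirically reported divergence band (7.3–9.0% around
8%) is narrower than an i.i.d. binomial site model would produce, which
is consistent with a fixed introduced haplotype plus small within-type
noise, and that is what the generator models. ITS regions follow the
two architectures (start AAC / TTT, spacer 10–11 / 4–6 nt, D3 GGTAY /
GGTTC, D5 6 / 15–16 nt), with tRNA presence varied across the majority
type's copies; promoters use the published element variants per type
(−35 TTGACA / CACACA, −10 TATATT / TACAAT). Plants are verified by
re-annotating/re-scanning and flanks are resampled on accidental earlier
matches, so round-trip recovery is exact by construction, not by luck;
resampling is bounded and seeded, keeping output byte-identical per
seed.

Two parameters are the package's own additions, chosen once. *Species
divergence* (default 0.02): each species receives private substitutions,
applied identically to both operon types and planted off the signature,
so that between-species 16S identity falls below the 98.7% threshold
(≈ 98%) while the signature and within-strain divergence are untouched;
without it, identity-based delimitation could not be exercised.
*Within-type site noise* (default 0.002 per site per copy): the scale of
ordinary microvariation among operon copies. Clone libraries are drawn
with replacement under per-operon weights; down-weighting the divergent
type reproduces the PCR bias that motivates type-specific primers.

What the generator does **not** emulate: indel evolution (the emitted
alignments are gapless by construction; indel handling is tested on
constructed alignments instead), realistic substitution models (sites
are i.i.d. uniform ACGT outside templates), chimeras, and sequencing
error. Passing the synthetic round-trips therefore demonstrates the
pipeline's internal correctness on data satisfying its assumptions, not
robustness to alignment error or model misspecification in real data.

# Numerical choices and degenerate inputs

Coordinates are 1-based with closed intervals throughout. RNA input is
accepted and normalized to DNA (U→T). A tie for the modal base yields no
consensus regardless of threshold. Empty signature, no qualifying primer
window, and an absent −52 window are empty results, not errors; zero
comparable sites, unlabelled sequences, unequal alignment lengths, and
missing pairwise identities are errors that name the offending inputs.
The aligner uses linear gap scoring with deterministic traceback
(diagonal, then vertical, then horizontal), so outputs are reproducible
across platforms.

Problem sizes in the shipped tests and the acceptance script were
chosen as the smallest that exercise each property: the default
3×3×5 design (45 operons, 1500-site genes) for end-to-end recovery,
21 strains where consensus robustness under noise is the property at
stake, 100 seeded replicates for the divergence-band check, and ≤ 10
sequences wherever a brute-force oracle provides the expected value.

# Known limitations

Identity ranges on real data depend on read trimming, which the package
does not standardize. The ITS annotator requires usable default or
user-supplied templates and fails (diagnostically) on ITS regions whose
leading helix cannot fold. Criterion 2 of delimitation is only as good
as the supplied clade labels. Secondary-structure comparison is
helix-local: terminal-loop geometry, pseudoknots and tertiary
interactions are out of scope, as is free-energy folding.
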