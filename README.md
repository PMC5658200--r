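# rrnhet

Detection and characterization of highly divergent ribosomal RNA (rrn)
operon types within single prokaryotic strains.

Most bacteria carry several copies of the rRNA operon (16S rRNA — 16S-23S
internal transcribed spacer (ITS) — 23S rRNA — 5S rRNA). Usually the
copies are nearly identical, but some lineages harbour one operon that is
massively divergent from the rest (macroheterogeneity), to the point that
single-sequence surveys would misread one organism as two genera. `rrnhet`
implements the comparative workflow needed to detect, quantify and
characterize such divergent operon types from cloned or assembled
sequences, for microbial systematists and people working on 16S-based
diversity estimates.

## What it computes

* **Operon typing.** Given an alignment with two operon-type labels, a
  *signature position* is a column where each type has its own consensus
  base (within-type agreement ≥ 85% of non-missing residues, the
  *consensus saturation*) and the two consensus bases differ. New
  sequences are scored as the percent of signature positions identical to
  each type's consensus; *reversions* (a copy carrying the other type's
  consensus base, the footprint of gene conversion) are counted per
  position. Fully conserved windows with ≥ 3 cross-type mismatches are
  proposed as type-specific primers.
* **Divergence.** Uncorrected p-distance with pairwise deletion;
  identity = 100·(1 − p), divergence = 100·p; min–max identity ranges
  over labelled groups (e.g. within-strain Type 1 vs Type 2).
* **ITS annotation.** Ordered template search dissecting an ITS into
  leader, D1-D1′ helix, D2, D2–D3 spacer, D3, optional tRNA-Ile / V2 /
  tRNA-Ala, Box-B helix, Box-A, D4, V3 helix and terminal D5, with a
  comparative feature table per operon type.
* **Secondary structure.** Helix-level comparison against a reference
  helix map: canonical pairing (Watson–Crick + G·U wobble) with a closure
  rule — reference-model mismatch positions are drawn paired when the
  target bases pair canonically, up to 2 closures per helix — and
  per-helix substitution/indel localization of the type signature.
* **Promoters.** σ70-style −10 (TATAAT), −35 (TTGACA) and optional −52
  (AWWWWWTTTTT) element scanning; a promoter is called likely functional
  when the −35 and −10 windows each match the consensus at 3–6 positions.
* **Genospecies delimitation.** Strains are linked when 16S identity
  exceeds 98.7% in *every* operon type; connected components are then
  split by labelled tree clades and by morphospecies labels (monotone
  refinement, with provenance).
* **Synthetic data.** A seeded generator emulating the whole study
  design — 5 operons per strain (1 divergent + 4 near-identical), 123
  helix-localized signature substitutions over 1500 16S sites,
  type-specific ITS architectures and promoters, species-private
  mutations, clone libraries with PCR bias — so every stage is testable
  without downloads.

## Worked example

```r
library(rrnhet)
ds <- generate_dataset(synthetic_config(seed = 42))
report <- run_pipeline(ds)
report
#> rrn_report:
#>   signature positions: 123
#>   typing accuracy: 100 %
#>   within-strain 16S identity: 90.9-91.7%
#>   genospecies: 3
```

All 123 planted between-type substitutions are recovered as signature
positions; every operon copy is typed correctly; the divergent operon is
90.9–91.7% identical to the majority type within strains (i.e. 8.3–9.1%
divergence, the planted 123/1500 plus within-type noise); and the three
simulated species are recovered as three genospecies:

```r
report$its_features[, c("label", "first3", "d3_motifs", "d5_min", "d5_max")]
#>   label first3 d3_motifs d5_min d5_max
#> 1 Type1    AAC     GGTAC      6      6
#> 2 Type2    TTT     GGTTC     15     16
report$partition
#> rrn_partition: 3 genospecies at > 98.7 % linkage
#>  - sp1_st1, sp1_st2, sp1_st3
#>  - sp2_st1, sp2_st2, sp2_st3
#>  - sp3_st1, sp3_st2, sp3_st3
```

The ITS feature table shows the two planted architectures (ITS starting
AAC vs TTT, D3 motif GGTAY vs GGTTC, terminal D5 of 6 vs 15–16 nt). Real
data enter through `read_fasta()` / `read_alignment()` plus a metadata
TSV, with the same stage functions (`find_signature()`,
`identity_matrix()`, `annotate_its()`, `scan_promoter()`,
`helix_variability()`, `delimit()`). A thin command-line wrapper over
`run_pipeline()` is provided in `inst/scripts/rrnhet-pipeline.R`.

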