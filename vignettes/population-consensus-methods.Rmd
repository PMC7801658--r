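---
title: "Methods: building and evaluating a population-consensus reference"
author: "popref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and evaluating a population-consensus reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A reference genome assembled from one individual inevitably carries that
individual's rare alleles, and a reference from a mismatched population
inflates variant calls that merely reflect ancestry. One remedy is to build
the reference from several de novo haploid assemblies of the target
population and, at every site where they disagree, keep the allele carried
by the majority. `popref` implements that construction and the analyses
used to judge how well the result represents the population: in-silico STS
PCR anchoring of scaffolds to chromosomes with genetic and radiation-hybrid
(RH) maps, liftover chain generation, structural-variant (SV) read-depth
contrasts, and an unfolded site-frequency spectrum (SFS) against a
population allele-frequency (AF) panel.

## Majority-vote allele substitution

Given a backbone assembly (any merged or single assembly serving as the
coordinate frame) and N haploid assemblies:

1. each assembly is aligned to the backbone (`align_genomes`, or imported
   PAF with cs tags), alignments are reduced to a one-to-one cover
   (`select_primary`), and variants are called (`call_variants`) as
   VCF-style records — SNVs, insertions, deletions; records with
   |len(ref) − len(alt)| ≥ 51 bp are flagged as SVs;
2. records are normalized (`normalize_variants`): indels are left-aligned
   to the smallest position with an identical alternate haplotype and
   reduced to a parsimonious, anchored representation. Voting happens
   *after* normalization so that allele identity is
   representation-invariant;
3. alleles supported by at least ⌊N/2⌋+1 assemblies become major alleles
   (`vote_major_alleles`). A site with two or more distinct alternate
   alleles but no majority is a tie site; a site where only one assembly
   deviates keeps the backbone allele. The majority threshold generalizes
   the two-of-three rule to any N;
4. tie sites are resolved by a uniform seeded random choice among the
   candidates (`break_ties`). The backbone allele is included as a
   candidate by default (`include_backbone = FALSE` restricts the draw to
   observed alternates). The seed is mandatory and every choice is logged;
5. the winning set is substituted into the backbone (`apply_variants`),
   which also returns a coordinate map. Overlapping records are resolved
   coordinate-sorted first-wins, with larger reference spans sorting first
   at equal positions; dropped records are returned and a warning raised.

`expected_tie_errors` scores the tie decisions against an AF panel: for a
site with m candidates the error probability of a uniform draw is
1 − (1/m) when the panel-major allele is among the candidates and 1
otherwise; sites absent from the panel are counted separately. This is the
package's own definition of the expected error count, stated here because
published error estimates for such random choices rarely come with a
reproducible formula.

## Pairwise alignment

The internal aligner is anchor–chain–extend: unique k-mers of the target
(default k = 19) seed maximal exact matches, which are chained by weighted
longest-increasing-subsequence (ties toward smaller target coordinates),
and inter-anchor gaps (≤ 50 kb) are closed by banded global alignment with
affine gap costs (match 0, mismatch 4, gap open 4, extend 2 — chosen to
behave like an asm5-class aligner on ≥ 95%-identity pairs). The band is
doubled while the optimal path touches its boundary; if the cell budget is
exhausted the pair is emitted as paired insertion+deletion. Traceback
prefers the leftmost placement of indels, and normalization canonicalizes
whatever residual representation freedom remains. N is scored as a
mismatch everywhere and variants whose alleles would contain N are never
emitted, so variant calls never cross N-gaps. External PAF (+cs) is
accepted as a drop-in replacement for the internal aligner.

Split alignments across contigs, repeat-aware multi-mapping and base
qualities are out of scope; one block per (query contig, target contig)
pair is kept on the better strand.

## In-silico PCR and anchoring

A marker amplifies (`epcr_scan`) where its forward primer and the reverse
complement of its reverse primer match on opposite strands, oriented
toward each other, each with at most 1 mismatch and an exact 3'-terminal
trinucleotide, and with an amplicon within ±50% of the expected size (≤5 kb
when no size is given). These defaults are deliberately conventional e-PCR
behaviour and are exposed as arguments, since published electronic-PCR
parameterizations are rarely complete.

Scaffolds are assigned to chromosomes by a weighted vote (genetic maps 5,
RH maps 1 — the weights used when both map types anchor a human-scale
assembly); exact weighted ties leave a scaffold unplaced. Markers that
amplify on more than one scaffold are ambiguous and excluded (counted in a
report). Ordering uses the weighted mean of marker map positions, after
rescaling every (map, chromosome) to [0, 1]: centimorgans and centirays
are incommensurable units, and without rescaling the maps with larger
numeric ranges would dominate the mean regardless of their weight.
Orientation is the sign of the weight-combined per-map Pearson correlation
between within-scaffold amplicon coordinate and map position; a pooled
correlation across maps was rejected for the same unit-mixing reason.
Scaffolds with fewer than two usable markers default to '+'. This
deterministic ordering replaces genetic-algorithm ordering; an exhaustive
permutation oracle over small instances verifies that it attains the
weighted per-map correlation optimum there.

`build_pseudomolecules` concatenates ordered, oriented scaffolds with
10 kb N gaps (the conventional pseudo-molecule gap) and emits AGP 2.1.
Finishing edits are `mask_intervals` (e.g. the Y-chromosome PAR1, to keep
a haploid reference), `rotate_circular` (mitochondrial start alignment)
and `resize_gaps` (declared heterochromatin gap lengths).

## Liftover

`blocks_to_chain` converts alignment blocks or a consensus coordinate map
to UCSC chain records; chain score is the number of aligned bases (no
published scoring exists for this use; the score is not load-bearing).
`lift_interval` is exact for intervals fully inside aligned blocks, snaps
ends through the nearest block otherwise ("partial"), and reports
"unmapped" below a minimum overlap (1.0 for variants, 0.95 for features —
common liftover practice). `lift_annotation` applies a strict policy to
multi-part gene models by default (one failing part rejects the group);
a per-feature mode keeps what lifts. Strand is flipped through '−' chains.

## SV and depth statistics

`filter_svs` keeps insertions/deletions ≥ 51 bp. `merge_svs` is
single-linkage clustering in which two records link iff they share a type
and both breakpoints lie within 1000 bp (inclusive — the conventional
reading of a "distance ≤ 1000" merge); an insertion's second breakpoint is
taken at start + length on the inserted-sequence frame, since insertions
occupy a 1-bp anchor on the reference. `accessible_regions` keeps
positions with cross-sample mean depth in [5, mean + 2SD] per contig.
`delta_avg_depth` takes the adjacent upstream window of the same length as
the SV as reference value and reports the signed difference at the most
deviant position inside the SV region; SVs whose upstream window leaves
the contig are skipped. We require the whole window to be accessible;
restricting to accessible positions inside the window is a noted
alternative. `paired_wilcoxon` wraps the two-sided signed-rank test (zero
differences dropped; exact for ≤ 25 untied pairs, normal approximation
with continuity correction otherwise).

## SFS against an AF panel

`employed_allele_freq` looks up, for each SNV between the consensus and an
external reference, the panel frequency of the allele employed in the
consensus; sites absent from the panel and allele mismatches are tracked
separately, and sites at AF ≈ 0 are kept (they flag alignment-edge
artifacts rather than being silently discarded). `build_sfs` bins at 0.01
with AF = 1.0 as its own closed bin, because the fully-fixed class is
reported separately from ≥ 0.99. `representativeness_summary` takes the
panel's own site counts at each threshold as explicit denominators, since
whether such denominators are genome-wide or alignment-restricted depends
on the study design.

## The synthetic-data generator

`simulate_population` draws a uniform-random ancestral genome, places
non-overlapping SNVs, short indels, and SVs (Poisson counts at per-bp
rates; SV lengths from a two-mode log-normal mixture centred near 300 bp
and 6 kb, the insertion-length modes characteristic of active Alu and
LINE1 elements), and assigns each site an allele frequency from
Beta(0.8, 0.8). The Beta default is structural, not demographic: it
produces both common and rare variants without claiming a coalescent
model. `sample_haploid_assembly` carries each alternate independently with
probability equal to its AF. `fragment_into_scaffolds` cuts chromosomes
into scaffold/gap alternations (gaps are unsequenced, dropped sequence)
with random orientations and a ground-truth placement table.
`simulate_marker_maps` places markers in variant-free windows with
genome-unique primers; a marker's map position refers to its amplicon
midpoint; genetic maps get low positional noise and RH maps higher (the
noise SD is a fraction of the chromosome's map length).
`simulate_depth_tracks` is Poisson per sample and position; a
sample-carried deletion absent from the track's frame zeroes its depth in
the region, a carried insertion absent from the frame piles up at the
anchor, and a frame-carried insertion receives depth only from carriers.
All stages draw from named substreams of one master seed.

What the generator does not emulate: read-level error, repeats and
segmental duplication, linkage disequilibrium, demographic AF spectra,
mapping bias. Passing tests therefore demonstrate algorithmic correctness
on clean, ground-truthed inputs — not performance on real assemblies.

## Problem sizes and numerical choices

The test-suite and acceptance-script fixtures are: "tiny" 3 × 100 kb and
"desk" 3 × 1 Mb genomes with three haploid samples (total variant density
about 1 per 700 bp, below the 1-per-500-bp regime in which the round-trip
recovery oracle is expected to be exact); the anchoring fixture uses
3 × 100 kb with 60 markers per chromosome and fragment gaps equal to the
10 kb anchoring gap, so pseudo-molecule coordinates reproduce ancestral
coordinates exactly and noiseless co-linearity is 1.0 to floating point;
the map-weighting fixture uses 3 × 200 kb, 150 markers per chromosome,
8 kb scaffolds, one noiseless genetic map and one RH map with positional
noise at 5% of map length (the regime in which the 5:1 weighting keeps the
order exact while RH-only ordering does not); the depth contrast uses 200
shared SVs at 90% carrier frequency over 200 samples at 30× mean depth.
The majority-recovery law is checked per AF bin at 3 binomial standard
errors; being a per-bin statistical criterion, its max-deviation statistic
across bins occasionally exceeds 3 SE by chance (about 3% of runs at 10
bins) — the acceptance script therefore reports both the maximum deviation
and the fraction of bins within 3 SE.

Degenerate inputs: empty variant sets vote to an empty major set; empty
anchors chain to empty blocks; a single-candidate tie is still drawn (and
flagged) for uniform bookkeeping; `wrap = 0` writes single-line FASTA;
contigs are validated to {A,C,G,T,N} after uppercasing, with soft-mask
case preserved through I/O and ignored by every algorithm.

## Known limitations

- The aligner is for desk-scale, high-identity genomes; it does not
  detect inversions or translocations (an inverted segment simply fails to
  anchor on the '+' strand and is either aligned on '−' as a whole contig
  or left unaligned).
- Voting assumes the assemblies are haploid and independent; quality-aware
  or phased voting is out of scope.
- `expected_tie_errors` depends on panel completeness; sites missing from
  the panel are excluded from the expectation rather than imputed.
- Chain generation covers two genomes; multi-hop composition is not
  implemented.
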