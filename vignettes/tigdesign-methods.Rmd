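---
title: "Designing endogenous Type I-G CRISPR editing experiments with tigdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing endogenous Type I-G CRISPR editing experiments with tigdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tigdesign)
```

## The editing strategy this package models

Many bifidobacteria — including the widely used probiotic *Bifidobacterium
animalis* subsp. *lactis* — are hard to edit with heterologous nucleases, but
most strains carry a native Type I-G CRISPR-Cas system whose interference
machinery (a crRNA-guided Cascade complex recruiting the Cas3
helicase-exonuclease) can be repurposed for genome editing. The approach
works by supplying, on a plasmid, a *synthetic CRISPR array* — the native
leader promoter, two consensus repeats flanking one targeting spacer, and a
Rho-independent transcriptional terminator — together with an *editing
template* of two homology arms that fuse the sequence flanking an intended
deletion. Homologous recombination produces the deletion allele; cells that
retain the wild-type allele are then killed by Cas3-mediated degradation of
the still-targetable chromosome. This counterselection is the core logic the
package validates computationally: a correct design has the property that the
wild-type allele *fails* escape validation for its own spacers while the
edited allele *passes*.

`tigdesign` implements the complete in-silico side of this workflow:

* PAM scanning and protospacer extraction (`scan_pam_sites()`,
  `extract_candidates()`): the Type I-G Cascade of this system recognizes a
  5'-TAT-3' PAM, and the 35 nt immediately 3' of the PAM on the PAM strand is
  the protospacer. Candidates are taken from either strand of the target.
* Off-target screening under the seed rule (`off_target_hits()`,
  `seed_equivalent()`): interference requires a perfect match in the
  PAM-proximal *seed* (positions 1-8 of the protospacer, numbered from the
  PAM); mismatches in the seed abolish targeting, mismatches outside it
  generally do not. A genomic site is *blocking* when the PAM is present and
  the seed matches perfectly within the overall mismatch budget.
* Deletion planning and template design (`plan_deletion()`,
  `extract_arms()`): deletions default to 100 bp upstream of the start codon
  plus 400 bp of coding sequence (500 bp total), expanding minimally when PAM
  availability forces a chosen protospacer outside the default window.
  Templates use 600 bp arms (1.2 kb total) or 1,000 bp arms (2 kb total).
* Vector assembly (`assemble_cassette()`, `assemble_vector()`): scar-free
  insertion of the cassette (and, for editing vectors, the template) into a
  circular backbone at unique restriction sites; three selected spacers and
  two arm presets yield six editing vectors per target gene.
* Comparative locus analytics (`detect_arrays()`, `build_spacer_catalog()`,
  `diff_arrays()`, `self_target_scan()`, `dedupe_proteins()`,
  `pairwise_identity()`): simplified, deterministic, fully testable
  equivalents of the comparative-genomics tooling used to characterize
  Type I-G loci across genome collections.

## Coordinates, orientations and tie-breaks

All internal coordinates are 0-based half-open; GenBank emission converts to
1-based inclusive locations (a bijection on valid intervals), with
minus-strand features in `complement()` notation. Protospacer position 1 is
the base immediately 3' of the PAM on the PAM strand, so "seed positions
1-8" always means PAM-proximal. Spacer sequences are stored 5'→3' on the PAM
strand (equivalently, leader→trailer when read out of an array of known
orientation).

Several operations need deterministic tie-breaks, chosen once for
reproducibility:

* `consensus_repeat()`: per-column majority, ties broken in fixed base order
  A < C < G < T.
* `diff_arrays()`: the longest-common-subsequence traceback matches each
  element of profile A at the leftmost feasible position, so the set of
  matched A-indices is lexicographically smallest among optimal alignments.
* `select_spacers()`: among all admissible k-subsets, maximize the minimum
  pairwise protospacer distance, then total separation, then genomic
  position; selection is invariant to input order.
* `pairwise_identity()`: Needleman-Wunsch with match +1, mismatch 0, linear
  gap -1, end gaps penalized. Identity is matches / alignment columns × 100.
  Among equally optimal alignments the one maximizing matches is used; with
  this scoring that also pins down the number of aligned columns, which makes
  the reported value symmetric and well defined without a traceback. The
  denominator includes gap columns — a design choice, since the matrices this
  emulates do not document their normalization.
* `assemble_vector()`: inserts go immediately 3' of the plus-strand site
  motif, cassette leader-first; the true insertion orientation in the
  reference constructs is not documented, so one convention is fixed.

## Array detection

The detector targets the regime it is used in — small or synthetic genomes
with recently active, highly conserved arrays — rather than the degenerate
relics general-purpose tools must handle. Exact 20-mer anchors recurring at
periods of 38-100 bp seed candidate repeat chains; the repeat is grown to
the maximal string shared *by every unit simultaneously* (capped at 50 bp
and by the minimum 18 bp spacer gap); spacers are the gaps between units and
must fall in 18-50 bp. Internal repeats must be exactly identical; one
degenerate terminal repeat with up to 2 substitutions is searched at both
ends of the chain (array orientation is usually unknown, so no end is
privileged). Arrays need at least 3 repeat units; overlapping candidates are
resolved greedily, most units first, then longest span. Every reported array
satisfies the reconstruction invariant: concatenating its units reproduces
the genome substring of its span exactly.

Leader-side orientation calling is deliberately out of scope (the reference
workflow resolved orientation by manual inspection, which is not
algorithmic); orientation is `"unknown"` unless supplied, and the spacer
catalog then canonicalizes each spacer to the lexicographically smaller of
sequence and reverse complement so that cross-genome ids stay stable.

## Off-target model

The screen reports every genomic window on either strand within
`max_total_mismatches` (default 5) substitutions of the spacer, annotated
with PAM presence and per-position mismatches. The published record of this
workflow states only that spacers were *checked* against the host genome;
the blocking rule used here — PAM present, zero seed mismatches, within the
total budget — is a conservative, configurable proxy for "still
targetable". Indels in the alignment and genomic context beyond the 3 nt
PAM are not modeled. The same engine drives `self_target_scan()` (spacers
vs their own source genome, hits inside the source array excluded) and
`validate_escape()` (spacers vs a candidate allele).

## The synthetic-fixture generator

`simulate_genome()` emulates exactly the features the design tools consume,
with every planted feature recorded in a truth table at exact coordinates:

* i.i.d. background at configurable GC (default 0.5, 60 kb) — deliberately
  repeat-free so that brute-force oracles are unambiguous;
* genes at deterministic, well-separated positions (defaults: three 1.5 kb
  genes on +, -, + strands, spaced so 1 kb arms plus a 300 bp primer search
  span always fit);
* one planted CRISPR array with the modal Type I-G architecture: a 36 bp
  repeat, 19 spacers of 34-37 nt (35 modal), spacers mutually distinct over
  the 8 nt seed so equivalence grouping has clean ground truth; optionally a
  mutated terminal repeat;
* TAT PAM sites planted inside each gene near the start codon in gene
  orientation (mirrored for minus-strand genes), on both strands;
* off-target decoys: single-substitution copies of a planted protospacer at
  a stated PAM-proximal position, with or without an upstream PAM.

What the generator does *not* emulate: real bifidobacterial base
composition, codon structure, repeated gene families, restriction-
methylation site landscapes, or degenerate ancient arrays. Passing the
planted-recovery suite therefore demonstrates correctness of the
coordinate arithmetic and scanning logic, not detector performance on
distant real genomes.

`make_backbone()` builds toy circular backbones: all occurrences of the
named cloning-site motifs are scrubbed, then one copy of each is planted, so
scar-free assembly preconditions (each site unique) hold by construction.
The real leader, consensus repeat, terminator and backbone sequences of the
reference system are not published as plain sequence, so fixtures use
synthetic sequences at the documented lengths (repeat 36 bp, spacer 35 bp);
users supply real sequences via configuration for actual designs.

## Verification primers

`design_screen_primers()` places both primers strictly outside the homology
arms, so only chromosomal alleles (never plasmid-borne template) amplify.
Scanning moves outward from each arm's outer boundary and accepts the first
window of 18-25 nt with GC between 40% and 60%; melting temperature uses
the Wallace rule 2(A+T) + 4(G+C). No primer-dimer or secondary-structure
screening is attempted — the emulated workflow states only the placement
constraint. The invariant `amplicon_WT − amplicon_edited = deletion length`
holds by construction and is asserted across 100 random fixtures in the
test suite.

## Numerical and scale choices in the test suite

Problem sizes were chosen to keep the full suite in the low minutes while
still exercising every code path at realistic scale: planted-recovery runs
20 fixtures at the default 60 kb; the off-target oracle comparison uses a
100 kb genome with planted near-copies at 0-6 mismatches; the
counterselection invariant runs 50 end-to-end designs on 20 kb single-gene
fixtures; exhaustive oracles (LCS on profiles ≤ 8 over 4 ids, alignment
enumeration for sequences ≤ 6) stay within enumeration reach. Tolerances are
not needed anywhere — every checked quantity is integer or exactly
reproducible.

## Known limitations

* Guide efficiency is not scored: the underlying experiments observed
  variable spacer efficiency without a predictive model, so the package
  selects for safety (no blocking off-targets) and spread, not activity.
* The deletion-window expansion rule (minimal one-sided extension to cover
  chosen protospacers plus PAM) reproduces the documented outcomes, but the
  original designs' exact expansion policy is not published.
* `pairwise_identity()` is a plain global aligner suited to the short,
  highly similar Cas proteins it is used on here, not a replacement for a
  profile aligner on divergent families.
* Restriction biology is motif counting only; methylation sensitivity and
  transformation-efficiency effects are out of scope.
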