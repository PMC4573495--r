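---
title: "Methods: mining and characterizing endogenous viral elements"
author: "paleovirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing endogenous viral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endogenous viral elements (EVEs) are fragments of viral genomes that
integrated into a host germline and are inherited vertically. Finding them in
a genome assembly is a translated-homology problem: the viral donor is often
an RNA or ssDNA virus whose genome never matches the host DNA at the
nucleotide level, so the assembly is compared with viral *proteins* across
all six reading frames. The calls must then survive three follow-up
questions. Is the fragment really chromosomal (host-derived flanks rather
than co-assembled virions)? How degraded is it (stop codons and frameshifts
accumulate after integration because most EVEs evolve neutrally)? And how
old is it (shared orthologous insertions in related species put a lower
bound on the integration date)?

`paleovirome` implements that entire workflow as composable, tested
functions, and couples it to a synthetic genome-pair simulator so every
stage can be verified against a known ground truth without downloading any
external assembly or virus database.

## The search model

Scaffolds are first masked for low complexity: sliding 64-nt windows whose
trinucleotide Shannon entropy falls below 1.5 bits are replaced by `N` (the
union of offending windows). This is DUST-like behaviour; entropy is
computed over non-`N` trinucleotides only and windows dominated by masked
positions are skipped, which makes masking idempotent. Masked codons
translate to `X` and can never seed a match.

The translated scan seeds exact 4-aa word matches between the six-frame
translation of each scaffold and the database proteins, clusters seeds by
diagonal, and extends each cluster with a Smith–Waterman local alignment
(BLOSUM62, gap open 11 / extend 1) in a ±90 aa window. Sparse seed
clusters are pre-screened with an ungapped diagonal score (Kadane maximum
subarray ≥ 35) before the affine extension — a pure speed heuristic that
cannot remove genuine homology, which always produces dense seed clusters.
Significance uses the Karlin–Altschul model `E = K·m·n·exp(−λS)` with the
canonical gapped defaults K = 0.041 and λ = 0.267 per score unit, m the
protein length and n the total translated search space; hits are kept at
E ≤ 1e-3. Entries of the substitution matrix involving the stop sentinel
`*` are forced to −4 so degenerate frames full of stops cannot extend an
alignment. The scan compares genome translations against database proteins
(tblastn-like) rather than translation-vs-translation: the detection target
— protein-level homology — is identical, at half the search space.

False positives (host genes with incidental viral similarity) are removed
by a reciprocal best-hit rule: each hit's translated segment is re-aligned
against the union of the viral proteins and a host decoy protein set, and
survives only when the single best score is viral. Exact ties are removed —
the conservative reading of "best hit must be a virus". Retained hits on
the same scaffold and strand within 100 bp merge into loci (transitive
closure, union hull); a locus inherits group and gene role from its
lowest-E hit, ties broken by score then protein id.

## Flank validation and duplications

A flank is the 150 bp adjacent to a locus; it is emitted only when the full
150 bp is available on that side. The package follows two printed screening
rules: a flank must show no viral similarity (re-scan at the same E-value
threshold), and host origin is certified by repeat evidence — a
microsatellite repeated at least 6 times, or an interspersed repeat longer
than 100 bp present at least 10 times genome-wide. Microsatellite arrays
are *exact* maximal tandem repeats of primitive motifs (1–6 bp), reported
in canonical rotation; exactness keeps the rule decidable and lets the
implementation be checked against a brute-force enumerator. Interspersed
copy counts come from nucleotide local alignment (≥ 80 % identity over
≥ 100 bp) of the flank against the whole assembly; the flank's own copy
counts as one occurrence.

Loci whose flanks align at ≥ 95 % identity over ≥ 100 bp are clustered by
single linkage into post-insertional duplication groups; a group of size k
counts k − 1 events, the minimum number of duplication acts. The 95 %/100 bp
rule is a design choice (no numeric rule is printed in the screening
literature this emulates); it tolerates the ≤ 2 % post-duplication
divergence the simulator produces by default with a wide margin.

## Degradation profiling

Each locus is aligned to its best reference protein by a three-frame
dynamic program. Reference residues are normally consumed with 3-nt codons;
consuming 2 or 4 nt instead costs a frameshift penalty of 12 score units
and counts one frameshift event. Stops are counted only on regular 3-nt
aligned codons, so a hybrid codon spanning a frameshift junction never
contributes a phantom stop, and a stop beyond the reference C-terminus
falls into a free end gap — the terminal stop of a complete ORF is never
counted. Codon and residue gaps cost 10; the locus is aligned
quasi-globally (at most two free nucleotides at each end) while reference
end gaps are free, so stops near the fragment edges are not clipped away.
Classes follow the printed spectrum: `intact` (no stops, no frameshifts),
`heavily_degraded` (more than 10 nonsense mutations), `disrupted` otherwise.

The DP core is compiled (Rcpp) and is cross-checked in the tests against an
independent R implementation of the same recurrence.

## Orthology and dating

Host-validated flanks of species-A loci are searched against the species-B
assembly by seeded nucleotide local alignment. A pair is called when a
flank matches uniquely — best score at least 1.5× the second best — which
guards against repeat-mediated spurious orthology. The EVE is flagged
present in B when the region adjacent to the matched flank itself yields a
translated viral hit of the same group; otherwise the pair records an empty
pre-insertion site (a presence/absence polymorphism).

Ages use the divergence of a neutral marker between the two host species:
`age = divergence / rate`. With the mitochondrial COI marker at 16 %
divergence and a crustacean COI rate of 1.4 % per million years, shared
insertions date to roughly 11.4 Myr. The quoted rate is treated as a
pairwise-divergence rate (age = d/r, not d/2r), matching how such decapod
calibrations are used; under the per-lineage reading the ages would halve,
which does not change the qualitative conclusion of maintenance over
millions of years.

## Lineage placement

For each (viral group, gene role) with at least one EVE, the EVE peptides
(translations of the best-hit segment) and the reference proteins are
aligned progressively: guide tree from pairwise alignment distances
(average linkage), profiles merged by affine-gap dynamic programming with
average-of-pairs column scores. Distances use the scoredist-style
correction `d = −ln(1 − p − 0.2 p²)` on the shared-ungapped-column mismatch
fraction p, capped at 5. Trees are built by canonical neighbor-joining with
deterministic tie-breaking (smallest index pair in the Q matrix) and
negative branch lengths clamped to zero with the deficit moved to the
sister edge — exact on additive matrices, which is what the test oracles
exploit. Supports come from a nonparametric bootstrap (100 column-resampling
replicates by default; bipartition comparison ignores branch lengths) and
are byte-for-byte reproducible under a fixed seed.

An EVE leaf is assigned the lineage of the smallest clade with support
strictly above 70 (the conventional display threshold) containing it and at
least one reference; supported pure-EVE clusters become `novel-lineage-k`,
and EVEs attached only through unsupported edges stay unassigned. Distance
NJ replaces maximum-likelihood inference here deliberately: the quantity
this package needs from the tree is cluster membership and support, not
likelihoods, and NJ keeps the whole placement in-repo and oracle-testable.
One known consequence of the deterministic tie-breaking: when an EVE, its
duplicate and their source protein are all *identical*, the two EVE copies
form the supported cherry and are labelled as a novel cluster rather than
with the source virus — on tiny trees there is simply no information to
separate these readings.

## The simulator and what it does (not) emulate

`simulateGenomePair()` generates the study conditions used throughout the
tests: 5 scaffolds of 10 kb i.i.d. background at GC 0.42 per genome, two
synthetic viruses per group for the five groups (Bunyaviridae,
Circoviridae, Mononegavirales, Parvoviridae, Totiviridae; long
polymerase-like and shorter structural ORFs), three insertions per group
cycling a degradation grid from intact (0, 0, 0) through mild
(2 % substitutions, 2 stops, 1 frameshift) to heavy (5 %, 12 stops, 2
frameshifts), one duplication group of two loci sharing an identical 200-bp
flank, three ortholog pairs of which one is an empty site in species B, and
5 % species divergence. Every insertion's upstream flank carries a planted
microsatellite; one interspersed family (120 bp × 10 copies, one copy
inside a flank) and scattered microsatellites complete the host features.
Planted mutations are spaced (stops ≥ 3 codons apart; frameshifts ≥ 30 nt
apart and ≥ 45 nt from fragment ends) so that the ground-truth counts are
well-defined: un-spaced indel pairs can cancel within an alignment and
mutations in the unalignable first/last codons of a fragment are invisible
to any homology-based profiler.

Species B is generated from the *pre-insertion coordinate map* of A —
shared host sequence point-mutated at the species divergence — which
guarantees a knowable homologous coordinate for every ortholog pair. The
flanks of A-specific insertions (and the first 200 bp of sequence
downstream of them) are replaced by B-private sequence, so an A-specific
locus genuinely has no homologous flank in B.

The simulator deliberately does **not** model realistic repeat landscapes,
transposable-element families, assembly gaps or sequencing error. Passing
its recovery tests therefore shows that the pipeline's logic is correct
under clean, unambiguous truth — not that recall on a real crustacean
assembly would be 100 %; on real data, assembly quality and repeat content
dominate sensitivity.

## Numerical and scale choices

All randomness flows from one master seed; stages derive child seeds by
hashing the stage name, so any stage can be re-run in isolation. Fixed
seeds reproduce byte-identical FASTA and report files. Problem sizes used
by the tests and the acceptance script — 50-kb genomes, 15 insertions, 100
bootstrap replicates, 1000 alignment oracle pairs, 500 tandem-array
strings, 50 random additive trees — were chosen as the smallest sets that
still exercise every rule and boundary; the oracle comparisons are exact,
so their power does not depend on size. Degenerate inputs follow explicit
conventions: sequences shorter than one codon translate to six empty frames
with a warning; an empty hit set produces empty but valid loci, flank and
report objects; alignment pairs with no shared ungapped columns receive the
capped distance with a warning.

## Known limitations

* The translated scan is tblastn-like; a true translated-vs-translated
  search could in principle detect homology via a third frame relationship
  that protein-vs-translation misses, though no such case arises for
  contiguous endogenized ORF fragments.
* Microsatellite arrays are exact; real microsatellites mutate internally,
  so the 6-copy rule here is conservative on real data.
* Ortholog detection assumes collinear orientation between the two
  assemblies (the simulator's orthologous-site model); inverted
  rearrangements between species would need reverse-strand flank matching.
* Lineage labels on tiny trees with identical sequences reflect
  tie-breaking, not signal (see above).
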