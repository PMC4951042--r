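---
title: "Genome-wide SSR marker development: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide SSR marker development: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmarkers)
```

# The problem

Microsatellites (simple sequence repeats, SSRs) are tandem repetitions of a
1–6 bp unit. Because their repeat counts mutate fast and are assayed by a
simple PCR, they remain a workhorse codominant marker in crops whose breeding
programmes lack dense genotyping resources. Building a marker set from a
draft assembly involves a chain of small, well-defined computations — repeat
detection, genomic-context classification, primer design, SNP annotation,
in silico validation — each easy to get subtly wrong at the boundaries.
`ssrmarkers` implements that chain with explicit, testable contracts.

# Mining model

A *perfect* SSR is a maximal run of a primitive unit (one that is not itself
a repetition of a shorter unit — `AT`, not `ATAT`). Runs are detected on the
forward strand only: a repeat's reverse-complement twin occupies the same
interval, so scanning both strands would double-count. Only complete unit
repetitions are counted; a trailing partial unit is excluded from the record
span. Any non-ACGT base breaks a run. Overlapping runs with different
primitive units (an `AAT` run sliding into an `AT` run) are both reported
when each independently meets maximality and its threshold; we define no
arbitration because any choice would be arbitrary and untestable.

The default thresholds are the classical genome-survey criteria: minimum 10
repeats for mononucleotides, 6 for dinucleotides and 5 for tri- through
hexanucleotides. Two repeats separated by at most `max_interruption = 100`
bases merge into one *compound* locus; chaining is greedy left-to-right,
which is equivalent to taking maximal chains because the gap relation is
evaluated pairwise on adjacent records. In all counters a compound locus
contributes its member count, so "total SSRs" counts constituent repeats.
(Whether a published total of this kind counts members or wrappers is usually
unstated; member counting matches the convention of the standard MISA miner,
and `summarize_mining()` exposes both numbers so the sensitivity is visible.)

The implementation is a vectorised lag-*k* run-length scan; the test suite
holds it equal to an independent brute-force scanner that examines every
(position, unit length) pair, on dozens of random 10–20 kb sequences.

# Context classification

A repeat is *exonic*, *intronic* or *intergenic*. Boundary-spanning repeats
are assigned by their start coordinate — a deterministic, order-independent
rule; a `majority` overlap rule is available behind a flag for users who
prefer base-weighted assignment. Overlapping gene spans are unioned before
computing genic bp so no base is counted twice; the first gene in sorted
order claims a repeat for gene-product annotation.

Per-Mb frequencies are reported with *truncation* at the printed precision
rather than round-half-up. This is deliberate: published genome-survey tables
of this kind are reproducible under truncation but not under half-up rounding
(e.g. 42,061 loci over 121,018,751 bp is 347.558 per Mb, printed 347.5). The
full-precision ratio is always kept alongside the printed value
(`freq_per_mb_raw`).

# Primer design

Candidates are enumerated exhaustively on each side of the repeat: every
start and length (18–27 bp) whose footprint lies fully within `search_flank =
400` bp of the repeat, contains no ambiguous base, and passes the GC
(20–80 %) and Tm (50–60 °C) windows. A pair's penalty is the summed deviation
from the optima (length 20, Tm 55 °C, GC 50 %, unit weights); pairs whose
product leaves 100–500 bp are discarded; the minimum-penalty pair wins, with
ties broken by smaller product, then leftmost forward primer, then shorter
primers — a total order, so the result is deterministic. Because the penalty
is separable across the two primers, the minimum over all feasible pairs is
found with a sliding-window minimum (monotonic deque) over forward
candidates as the reverse 3′ end advances; the test suite pins this against
full quadratic enumeration.

Melting temperatures use nearest-neighbour thermodynamics with the unified
SantaLucia (1998) parameter set, duplex-initiation terms, the entropic salt
correction 0.368 (N−1) ln[Na⁺] at 50 mM monovalent, and the CT/4
concentration factor at 50 nM total oligo — primer3-like conditions. The
design criteria name only an optimum (55 °C), not a formula; the
nearest-neighbour model is the field default, and a Wallace-rule mode exists
for cross-checks. The regression constant in the tests was computed once
with an independent nearest-neighbour implementation.

Full hairpin/self-dimer thermodynamics are out of scope; a lightweight guard
rejects any primer containing an 8-mer together with its reverse complement
(a self-complementary stretch able to fold back). `search_flank = 400` is
our choice, not a published value: it makes the whole 100–500 bp product
range reachable while bounding enumeration.

Not every repeat yields a pair — cramped geometry or hostile flank
composition returns "none" — which is exactly how a genome-wide design run
ends up with fewer pairs than repeats. Compound loci are targeted over their
full span. Genic pairs are numbered `Pd_G_SSR1..n` and intergenic pairs
`Pd_IG_SSR1..m` in (scaffold, start) order, so naming is independent of
processing order.

# SNP linkage

The *flanking region* of a marker is its amplicon minus the repeat motif
interval. SNPs inside the motif are excluded by default — repeat-interior
variation is what the marker itself assays — and restored with
`include_motif = TRUE`, since published region counts do not state the
convention. A SNP may link to several overlapping amplicons but is counted
once per region, consistent with reporting a per-region mean. Summary
percentages and means are truncated at two decimals, the same convention as
the frequencies above.

# In silico PCR

Binding sites are every template position, on both strands, where the primer
matches within `floor(mismatch_pct/100 × length)` mismatches — Hamming
distance, no indels, `N` never matches, exactly the semantics of the EMBOSS
primersearch tool traditionally used for this step. Products are enumerated
from every (plus-site, downstream minus-site) combination in both
primer-role orientations, with outer 5′-to-5′ coordinates (matching reported
product lengths), deduplicated, and capped at `max_amplimer = 5000` bp — a
loose bound, since real validation alleles run well under 1 kb. The default
mismatch budget is 0 %, the only reproducible choice when a published
setting is unknown; the flag exposes the EMBOSS-style percentage. Site
scanning itself is delegated to `Biostrings::matchPattern`; the tests hold
it equal to a naive sliding-window oracle.

# Codon analyses

The trinucleotide motif space contains 60 units: the 64 codons minus the
four homopolymers, which reduce to mononucleotide repeats. For exonic
trinucleotide repeats we report which units are one substitution from a stop
codon (TAA, TAG, TGA) under the standard nuclear code. Units are evaluated
in their literal frame by default (the reading frame of a repeat inside a
codon is unknown without transcript phase, and published tables list literal
units); a flag adds the two rotations. Exhaustive single-substitution
enumeration yields 18 convertible sense codons; note that TAC and TAT each
reach *two* stops (TAA and TAG), a fact that summary tables listing one stop
per codon omit.

# The simulator: what a green test establishes

`simulate_genome()` realises a stated world: plants repeats with requested
units, counts and contexts in independent locus blocks (450 bp clean flank
each side — a full primer search window), joined by >100 bp separators so
unrequested compounds cannot arise; compound loci are requested explicitly.
Background is i.i.d. with configurable GC (default 0.39, a palm-like
composition) and is rejection-sampled until free of threshold-meeting
incidental repeats; block boundary bases are additionally constrained so
they cannot phase-extend a plant, and each assembled scaffold is verified by
re-mining before acceptance. SNPs fall i.i.d. at `snp_rate` (default 0.009
per bp, the density of ~3.5 M SNPs over a ~381 Mb assembly) with reference
alleles read from the genome.

This gives exact ground truth, at a price worth stating: real genomes have
imperfect and nested repeats, compositional heterogeneity, and repeats in
cramped or low-complexity flanks. A green planted-truth test therefore
establishes correctness of the *contracts* (detection, classification,
design geometry, linkage, re-amplification), not field performance on any
particular assembly. The brute-force-oracle tests on unscreened random
sequence cover the messier detection cases; the "dirty" path is simply
random sequence fed straight to the miner.

# Numerical and degenerate-input choices

- All coordinates are 1-based inclusive everywhere; one convention, no
  off-by-one drift between modules.
- Empty sequence, empty record set, empty panel: empty results and zeroed
  counters, not errors (an empty primer panel is the one rejected input, as
  a summary over nothing is meaningless).
- Penalty ties in primer design are resolved by a stated total order;
  floating-point penalty comparisons use a 1e-9 tolerance.
- Records with repeat counts beyond the last bin edge of a count table are
  dropped with a logged count rather than silently pooled.
- The miner's record comparison treats units as equal up to rotation when
  scoring against planted truth, since a run's literal first unit depends on
  its phase.

# Known limitations

- Imperfect/approximate microsatellites and unit lengths above 6 are out of
  scope.
- Primer design models no cross-pair interactions (multiplexing) and no
  thermodynamic dimer scanning; the 8-mer self-complementarity guard is a
  heuristic stand-in.
- In silico PCR models substitutions only; primer-binding indels are not
  considered, matching primersearch.
- UTR/CDS subdivision of exons is not modelled; the annotation contract
  distinguishes exon vs intron only.
- Exact reproduction of a published genome-scale primer total would require
  the original (unpublished) primer3 parameter file; the native designer
  states its criteria fully instead.
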