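# ssrmarkers

Genome-wide development of microsatellite (SSR) markers from draft genome
assemblies, in R.

Microsatellites — tandem repeats of a 1–6 bp DNA unit — are among the most
informative codominant markers in plant breeding: they are abundant,
hypervariable and cheap to assay by PCR. Given a genome FASTA, a gene
annotation and a SNP list, `ssrmarkers` builds a complete marker resource:

1. **Mining.** Maximal perfect repeats of primitive units, with per-unit-length
   minimum repeat counts (mono ≥ 10, di ≥ 6, tri–hexa ≥ 5); repeats separated
   by ≤ 100 bp are merged into compound loci.
2. **Context.** Every repeat is classified exon / intron / intergenic from the
   gene models, giving per-compartment densities (SSRs per Mb), repeat-count
   bin tables and motif presence sets.
3. **Primer design.** One best flanking pair per repeat under the classical
   criteria — optimum length 20 bp (18–27), optimum Tm 55 °C (50–60,
   nearest-neighbour thermodynamics), optimum GC 50 % (20–80), product
   100–500 bp — scored by the summed deviation
   `w_len(|len−20|) + w_tm(|Tm−55|) + w_gc(|GC−50|)` over both primers.
   Genic pairs are named `Pd_G_SSRx`, intergenic pairs `Pd_IG_SSRx`.
4. **SNP linkage.** SNPs falling in the primer-bounded flanking region
   (amplicon minus the repeat motif) are attached to each marker.
5. **In silico PCR.** Panels are validated primersearch-style: exhaustive
   binding-site scans on both strands under a percent-mismatch budget
   (Hamming, no indels), and enumeration of all products ≤ 5 kb.
6. **Codon analyses.** The 60-unit trinucleotide motif space and the sense
   codons one substitution away from a stop (relevant for exonic triplet
   repeats).

A synthetic-genome simulator plants repeats, gene models and SNPs with exact
ground truth (screened background, no incidental repeats), so the entire
pipeline is testable offline.

## Worked example

```r
library(ssrmarkers)

spec <- simulation_spec(default_ssr_plants(24), n_scaffolds = 4, seed = 7)
sim  <- simulate_genome(spec)

run <- run_pipeline(sim$genome, sim$genes, sim$snps, run_ispcr = TRUE)
print(run)
#> SSR marker pipeline run
#>   24 SSRs on 4 sequence(s) (25656 bp)
#>   exon/intron/intergenic: 6/6/12
#>   primer pairs designed: 24; SNP occurrences linked: 68
```

All 24 planted repeats are mined, classified with their planted context, and
receive a primer pair; 68 simulated SNP occurrences fall in the 24 flanking
regions. Each designed pair re-amplifies its own locus in silico at 0 %
mismatch:

```r
glance(run$ispcr)
#> # A tibble: 1 × 5
#>   n_primers_tested n_primers_with_hits n_amplimers_total total_amplimer_bp
#>              <int>               <int>             <int>             <int>
#> 1               24                  24                24              9360
#> # ℹ 1 more variable: mean_amplimers_per_hitting_primer <dbl>

head(run$database, 1)
#> # A tibble: 1 × 16
#>   primer_name repeat_type repeat_sequence repeat_size repeat_start repeat_end ...
#> 1 Pd_IG_SSR1  mono        A                        10          305        314 ...
```

Per-Mb frequencies use the survey convention (truncation at the printed
precision), e.g.

```r
freq_per_mb(42061, 121018751, digits = 1)
#> [1] 347.5
```

Pieces can be used individually: `find_perfect_ssrs()`, `merge_compound()`,
`classify_context()`, `design_primers()`, `link_snps()`,
`predict_amplimers()`, `survey_exon_tri_stops()`, with
`plot_unit_length_distribution()`, `autoplot()` and `tidy()`/`glance()` for
inspection. A thin CLI (`inst/scripts/ssrpipe.R`) exposes `run`, `mine`,
`simulate` and `query` subcommands.

## File formats

- Genome: multi-record FASTA (IUPAC letters; `N` never matches anything).
- Gene annotation: GFF3 (`gene`/`mRNA`/`exon`) or a TSV dialect with columns
  `gene_id  scaffold_id  start  end  exons  product`, where `exons` is a
  semicolon-joined list of `start-end` intervals (empty = whole span).
- SNPs: VCF v4 subset (`CHROM POS ID REF ALT`, 1-based) or a TSV with
  `scaffold_id  position  ref  alt`.
- Output marker database: TSV with the fixed 16-column layout
  (`primer_name` … `snp_positions`); see `?write_primer_database`.

All coordinates are 1-based and inclusive throughout.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a genome from the seed, runs the full pipeline (mining, context
classification, primer design, SNP linkage, in silico PCR validation of the
designed panel) against the installed package, prints the run summary and
writes the JSON report to `--out`.
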