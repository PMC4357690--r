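# raavarms

Design of homology arms and targeting scenarios for rAAV-mediated genome
editing of human protein-coding genes.

## What it does

Gene targeting with recombinant adeno-associated virus (rAAV) inserts or
deletes sequence by homologous recombination between two *homology arms* —
700–1200 bp PCR products amplified from the target locus. `raavarms`
automates the design work between an annotation table and the bench:

* **Annotation databases** — parses CCDS-style tables (status `"Public"`
  records with a GeneID), compresses identical exons of a gene across
  transcript variants into *unique exons*, merges overlapping ones into
  *exon projections* (the knock-in design unit, safe for all isoforms), and
  derives the knock-out–eligible exon set (present in every transcript,
  length not divisible by 3).
* **Homology-arm enumeration** — a sliding window (SW 1300 nt, step SS 50)
  over each feature ± 3 kb drives a deterministic primer engine
  (nearest-neighbor melting temperature, 18–30 nt primers) through ten
  product-size bins tiling 700–1200 bp, retaining the NPP = 50 best pairs
  per window and bin, filtered so that no primer base is repeat-masked or
  N, no primer carries a mononucleotide run over 3, and no arm exceeds 25%
  repeat content.
* **Scenario design** — DBSCAN clustering of arms (Chebyshev metric on the
  product interval), cluster–cluster matching under the gap/exon-exclusion
  rules, similarity grouping, and ranking by smaller gap, smaller
  split-point distance, longer cumulative arm length. Knock-ins pair an
  exon-spanning arm with a left or right flank (≤ 5 scenarios per category);
  knock-outs delete part of an exon or excise a whole exon ≤ 700 bp, and
  knock-in scenarios double as stop-codon knock-out candidates.
* **Exports** — Gateway attB-tailed amplification primers, TSV/JSON/BED
  scenario tables, and a CLI (`inst/cli/raavarms`) covering simulate /
  build-db / design / coverage-stats / export.
* **Synthetic data** — a seeded generator for soft-masked genomes and
  CCDS-dialect tables with ground truth, so the whole pipeline is testable
  offline.

## Worked example

```r
library(raavarms)
options(raavarms.quiet = TRUE)

# simulated 60 kb locus set with 3 genes (seeded, reproducible)
sim <- simulate_dataset(sim_config(seed = 7, chrom_len = 60000, n_genes = 3),
                        tempfile())
res <- run_pipeline(sim$table, sim$fasta)
str(res$summary[c("n_arms", "knockin_scenarios", "knockout_scenarios",
                  "base_fraction_with_knockin")])
#> List of 4
#>  $ n_arms                    : int 72312
#>  $ knockin_scenarios         : int 92
#>  $ knockout_scenarios        : int 15
#>  $ base_fraction_with_knockin: num 0.686
```

72,312 candidate homology arms pass the filters across the three genes; the
designer condenses them into 92 ranked knock-in scenarios (at most 5 per
left–span / span–right category per exon projection) and 15 deletion
knock-out scenarios, and 68.6% of projected coding bases end up inside at
least one knock-in target feature. Per-scenario wet-lab primers:

```r
tail_primers(res$knockin[1, ])   # 4 attB-tailed amplification primers
```

The same pipeline runs from the shell:

```sh
Rscript inst/cli/raavarms simulate --out sim --seed 7 --chrom-len 60000 --genes 3
Rscript inst/cli/raavarms design-knockin --ccds sim/annotation.txt \
    --genome sim/genome.fa --out run
Rscript inst/cli/raavarms export --scenarios run/knockin.tsv --format bed \
    --out run/knockin.bed
```

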