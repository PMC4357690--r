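---
title: "Designing rAAV gene-targeting constructs with raavarms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing rAAV gene-targeting constructs with raavarms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raavarms)
options(raavarms.quiet = TRUE)
```

## The problem

Recombinant adeno-associated virus (rAAV) vectors edit human somatic
genomes by homologous recombination. A targeting construct carries two
*homology arms* — PCR products of 700–1200 bp amplified from the target
locus — flanking the payload (a selection cassette for knock-ins, or the
junction of a deletion for knock-outs). Designing such constructs by hand is
slow and repetitive: for every exon one must find arm pairs that amplify
well, avoid repeats, keep the integration scar away from splice junctions,
and place the split point close to the edited base, because the chance that
a knock-in mutation is retained decays with its distance from the
integration site.

`raavarms` automates this end to end for protein-coding genes annotated in
CCDS-style tables: it builds exon databases, enumerates candidate arms with
a sliding-window primer-design engine, filters and clusters them, and emits
ranked knock-in and knock-out scenarios plus Gateway attB-tailed
amplification primers.

## Annotation model

Only records whose CCDS status is exactly `"Public"` and that carry a
GeneID enter the database; withdrawn, putative and under-review records
(including compound statuses such as `"Public, under review"`) are dropped.
CCDS coordinates (0-based, inclusive end) are converted to 0-based
half-open internally; every exported BED interval uses the same convention.

Alternative transcripts complicate editing: a safe design must respect all
isoforms at once. Two derived features handle this:

* **Unique exons** — exon occurrences of one gene with identical
  coordinates are compressed to one entry that records the set of
  contributing transcripts.
* **Exon projections** — unique exons of a gene with different but
  overlapping coordinates are merged transitively, keeping the outermost
  boundaries. Projections are the unit of knock-in design: an arm pair
  spanning a projection spans the corresponding exon of every transcript
  variant. Adjacent-but-not-overlapping exons are *not* merged. The
  `commonality` field stores the *count* of transcripts contributing a
  member exon (a count, not a fraction — the simpler quantity that the
  downstream steps need).

Knock-out designs instead use the plain unique-exon database and are gated
by **eligibility**: the exon must be present in every transcript variant of
its gene (trivially true for single-transcript genes) and its length must
not be divisible by 3, so that exon skipping around the disrupted exon
cannot restore the reading frame. Eligibility is decided from the
annotation alone; the genome is never consulted.

```{r annotation}
fx <- micro_fixture("ko-eligible")
gms <- parse_ccds(fx$table)
gms
knockout_eligible_exons(gms, 2002)
```

## Homology-arm generation

Each exon or projection defines a *target region*: the feature plus 3 kb of
flanking sequence on each side (clipped at chromosome ends). A sliding
window of `sw = 1300` nt moves across the region in steps of `ss = 50` nt —
the window must exceed the largest arm (1200 bp) yet stay below twice the
smallest (1400 bp) so that primer placement retains freedom without
generating excessive redundancy; a final window is anchored at the region
end so tails are never systematically uncovered. Within every window the
primer engine is asked for up to `npp = 50` ranked primer pairs in each of
ten product-size bins tiling 700–1200 bp in 50 bp increments (half-open
bins, the last closed, so the range is covered without overlap).

The built-in engine is deterministic and self-contained. Primer candidates
of 18–30 nt are rejected outright if any base is repeat-masked (lowercase)
or N, or if they contain a mononucleotide run longer than 3. Survivors are
scored by

\[
\mathrm{penalty} = |T_m - 60| + |\ell - 20|, \qquad
\mathrm{pair} = \mathrm{penalty}_{fwd} + \mathrm{penalty}_{rev}
  + 0.1\,|T_{m,fwd} - T_{m,rev}|,
\]

with melting temperatures from unified nearest-neighbor thermodynamics
(duplex initiation and terminal A/T terms, entropy salt correction, 25 nM
primer / 25 nM template, 50 mM Na+). The engine API is a plug-in contract —
`prepare()` + `design()` over windows — so a wrapper around an external
primer designer can be substituted; every filter is re-applied to plug-in
output by `filter_pairs()`, which also enforces the third arm criterion:
at most 25% of the product may be repeat-masked (25.0% exactly is kept,
matching the "not more than 25%" reading).

Arms surviving the filters are deduplicated on the primer-interval
quadruple (coordinates, not sequence case), keeping the lowest penalty, and
stored per gene. Numerical detail: penalties and melting temperatures are
rounded to $10^{-6}$ before ranking so that tie-breaking (penalty, then
leftmost product) is stable against floating-point summation order; this
makes window-level and region-level computation of the same candidate table
bit-identical, which the test suite asserts.

### Tuning SS and NPP

`coverage_sweep()` reports, for a grid of step sizes and retained-pair
counts, the fraction of target bases inside at least one arm
(*sequence coverage*), the mean per-base arm count (*average depth*), the
mean pair penalty, and depth per unit penalty. Because the engine is
deterministic, window sets at coarser steps are subsets of the finest step
and top-$k$ lists are prefixes of top-$N$ lists, so the whole grid is
derived exactly from one fine-grained run (verified against independent
runs in the tests). Coverage is essentially flat in both knobs while depth
grows with NPP — which is why the production defaults maximize NPP at 50
and use a moderate SS of 50.

## Knock-in scenarios

For a target feature the designer:

1. collects **span arms** — arms covering the feature with at least 20
   bases outside each border (so the integration scar stays clear of the
   splice junctions);
2. collects left/right **flank arms** within 700 bases of a span-arm end;
3. clusters each role with **DBSCAN** on the point (product start, product
   end) under the Chebyshev metric — two arms are neighbours when both
   endpoints differ by at most `eps`. Defaults `eps = 50` (one step size)
   and `min_pts = 1` (no arm is discarded as noise) are the package's own
   choice, exposed in `design_params()` and logged on every CLI run;
4. screens every arm pair of every (span cluster × flank cluster): the gap
   between adjacent arm ends must lie in `[0, 700)` (arms never overlap),
   no other exon of the gene may intersect the gap, no arm terminus may
   fall strictly inside another exon, and the split distance must be at
   least 20. Exactly one best candidate per cluster pair survives;
5. groups similar scenarios — sharing an identical arm, or both
   corresponding arms within 5 bases at each end — as an undirected graph
   and keeps the best scenario per connected component;
6. ranks by **smaller gap, then smaller split distance, then larger
   cumulative arm length**, with genomic position as a deterministic
   tie-break, and stores at most 5 scenarios per category (left–span and
   span–right; at most 10 per feature).

The *split point* is taken as the junction between the gap and the span arm
— the cassette inserts between the arms, and this junction is where
integration-site proximity to the exon matters; the alternative reading
(gap midpoint) differs only for wide gaps and is not used. The
cluster-pair pre-selection is a pruning heuristic: it always contains the
global optimum (the best pair is the best of its own cluster pair), but a
lower-ranked brute-force scenario can be pruned before global ranking. The
tests therefore assert exact equality with exhaustive enumeration on
well-separated fixtures and rank-1 equality plus never-better-than-oracle
on dense ones.

## Knock-out scenarios

Two deletion modes per eligible exon, both reusing the clustering,
smallest-gap-per-cluster-pair, similarity-grouping and top-5 machinery
(ranking by gap, then cumulative length — there is no split distance, the
split point is the deletion itself):

* **Partial deletion** — left arms end strictly inside the exon, right
  arms start strictly inside it; the deleted segment is the gap
  (`[0, 700)`). The deleted length modulo 3 is *reported* (`gap_mod3`) but
  not filtered on: eligibility already guarantees frame disruption for
  whole-exon loss, and partial deletions are left to user judgement.
* **Whole-exon excision** — attempted only for exons of at most 700 bp;
  left arms must end *more than* 20 bases before the exon start and right
  arms start more than 20 bases after its end (strict margins; the
  "more than 20" reading was chosen over "at least 20" — they differ by one
  base — and the margin is configurable), with inner arm ends within 700
  bases of the exon borders, mirroring the knock-in flank rule.

Knock-in scenarios of the feature containing an eligible exon double as
stop-codon knock-out candidates (`complementary_knockin()`); an exon is
counted as "covered" for knock-out when it has a deletion design or such a
complementary scenario.

First/last-exon down-weighting is deliberately not applied — which exon to
target is a biological judgement (3'-proximal exons disrupt protein
function poorly, first exons may have alternative starts), so the exon
ordinal is exported and the choice left to the user.

## Construct export

`tail_primers()` prefixes the four genomic amplification primers of a
scenario with Gateway attB tails — canonical attB1/attB2 for arm 1 and
attB3/attB4 for arm 2 by default, both user-replaceable in the
configuration — by pure concatenation, so stripping a tail recovers the
stored primer byte-for-byte. Scenario tables export as TSV (lossless
round-trip), JSON, and BED (arms and gap/deletion intervals, 0-based
half-open). The `cli()` entry point (installed wrapper
`inst/cli/raavarms`) drives simulation, database building, design and
export from the shell and logs every effective parameter.

## Parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `sw` | 1300 | nt | > max arm (1200), < 2 × min arm (1400) |
| `ss` | 50 | nt | coverage nearly flat in SS; moderate redundancy |
| `npp` | 50 | pairs | depth grows with NPP; 10 × typical engine default |
| `size_min`–`size_max` | 700–1200 | bp | established rAAV arm length range |
| `primer_len` | 18–30 | nt | standard PCR primer bounds |
| `max_monorun` | 3 | nt | amplification reliability |
| `max_product_repeat_fraction` | 0.25 | — | ≤ 25% repeat content per arm |
| `flank_size` | 3000 | nt | arm search space around the feature |
| `max_gap` | 700 | nt | integration efficiency decays with gap |
| `span_margin` | 20 | nt | scar clearance from exon borders |
| `whole_exon_max_len` | 700 | bp | excision only for exons ≤ 700 bp |
| `cluster_eps` / `cluster_min_pts` | 50 / 1 | nt / pts | one step size; keep every arm |
| `end_tolerance` | 5 | nt | similarity radius for grouping |
| `max_scenarios` | 5 | — | per category per exon (≤ 10 total) |

## The synthetic-data generator

`simulate_dataset()` emits a soft-masked FASTA, a CCDS-dialect annotation
table and a ground-truth JSON. It emulates the *structural* features the
pipeline depends on: multi-transcript genes whose alternative transcripts
share, boundary-shift or drop exons (defaults 60/20/20%), log-normal exon
lengths with median 123 bp (the median coding-exon length), non-Public
decoy records including the `"Public, under review"` trap, and repeat
tracts of geometric length (mean 300 nt) merged and lowercased to a target
density (default 20%). Every truth field is recomputable from the emitted
files by the corresponding pipeline operation, and identical seeds give
byte-identical files.

It does **not** model splice-site sequence, codon structure, GC
heterogeneity, or realistic repeat families — so passing tests demonstrate
algorithmic correctness of parsing, projection, arm generation, filtering,
clustering and ranking, not performance on real human sequence. Statistics
that depend on the masking library and primer-engine version of a
production run (genome-wide arm counts, exact coverage percentages) are
emergent quantities, not fixture-reproducible constants.

## Problem sizes and runtime choices

The test suite exercises the full pipeline on 30–80 kb chromosomes with
1–4 genes (seconds per stage at reduced `ss`/`npp`); the parameter-sweep
check uses a 200 kb chromosome with two genes across the full
`ss ∈ {25, 50, 100} × npp ∈ {5, 10, 25, 50}` grid; the acceptance script
simulates a 120 kb, 8-gene locus set and runs the production parameters
(SW 1300 / SS 50 / NPP 50). These sizes are the package's validation
choices: large enough that every rule (masking, clustering, grouping,
ranking, caps) is exercised with thousands of arms per gene, small enough
to iterate on.

## Known limitations

* The built-in engine scores primers by melting temperature and length
  only; it does not model hairpins, self-dimers or cross-dimers. An
  external engine honouring the plug-in contract can replace it where
  those criteria matter.
* Exons of *other, overlapping genes* are ignored by the exclusion rules
  (only the target gene's own exons are checked), mirroring the per-gene
  database design.
* Repeat masking is an input property; the package performs no masking
  itself, and results inherit whatever masking convention the input FASTA
  uses.
* Scenario stores are per-gene TSV files rather than embedded database
  files; the schema is identical and documented in `export_scenarios()`.
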