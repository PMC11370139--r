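---
title: "Genotyping single cells at known SNV sites: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping single cells at known SNV sites: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropgeno)
```

## The setting

Tumors driven by a recurrent point mutation offer a shortcut for annotating
single-cell RNA-seq data: instead of inferring malignancy from expression
alone, one can read the driver allele directly off each cell's reads. The
canonical example is adamantinomatous craniopharyngioma, where every tumor
carries a *CTNNB1* exon-3 point mutation known in advance from bulk
whole-exome or RNA sequencing. `dropgeno` implements that read-off: a
splice-aware pileup at user-supplied SNV loci, a three-way per-cell call,
cluster-level summaries, and the analytic expectation those summaries
should meet if the mutation is heterozygous.

## The classification model

Let a cell have $n_{ref}$, $n_{alt}$ and $n_{other}$ quality-passing
observations of the reference, variant and any third base at the site. The
cell is labelled

* **ALT** if $n_{alt} \ge m$ (default $m = 1$: a single variant observation
  suffices),
* **REF** if not ALT and $n_{ref} \ge 1$,
* **UNKNOWN** otherwise.

The rule is deliberately asymmetric — variant evidence trumps co-occurring
reference evidence, because a heterozygous cell is *expected* to show both
alleles. Two cases the trichotomy leaves open are exposed as parameters
rather than silently decided:

* `other_policy`: a cell whose only observations are a third base is
  `UNKNOWN` by default (a discordant base says nothing about the known
  variant). The alternative `"ref"` reads the wildtype definition literally
  as "no variant allele found in the aligned reads".
* `min_alt_evidence`: the default 1 maximises sensitivity but a single alt
  read is vulnerable to sequencing error; the false-ALT rate it implies is
  quantified below and in the test suite. Raising it to 2 suppresses
  error-driven false positives at a sensitivity cost at low depth.

When several candidate sites are genotyped for one sample, per-site labels
combine by priority: any ALT makes the cell ALT, else any REF makes it REF,
else UNKNOWN; counts are summed.

## The pileup

Observations are extracted from a coordinate-sorted, indexed BAM whose
reads carry 10x-style `CB` (cell barcode) and `UB` (UMI) tags. For each
read overlapping a site, the CIGAR string is walked: `M`, `=`, `X` consume
reference and query; `I`, `S` consume query only; `D`, `N` consume
reference only; `H`, `P` neither. The query base aligned to the site is the
observation; a site under `D`, `N`, a clip, or outside the aligned span
yields none. The `N` case is what makes the walk splice-aware — in
transcriptome alignments many reads cross exon-exon junctions, and a
junction read whose gap spans the site must contribute nothing rather than
a wrong base.

Filters, all exposed as function arguments and CLI flags:

* flag-based: unmapped, secondary, supplementary and QC-fail reads never
  count. Duplicate-flagged reads are *kept* — 10x duplicate marking is
  UMI-based and duplicate handling belongs to the UMI layer.
* `min_base_quality` (default Phred 20) at the interrogated base;
  `min_mapping_quality` (default 0; MAPQ 255 = "unavailable" always
  passes). The defaults follow common single-cell allele-counting practice;
  raising base quality can only remove observations (a tested monotonicity
  invariant).
* `require_cb` (default on): reads without a cell barcode cannot be
  assigned and are skipped.

**Evidence level.** With `umi_mode = "consensus"` (the default whenever
`UB` tags are present) all quality-passing observations sharing
`(barcode, UMI)` collapse to one molecule-level observation by majority
base; a tied vote discards the molecule — a perfectly split duplex is
uninformative, and discarding is deterministic and conservative. Reads
lacking a `UB` tag each count as their own molecule. `umi_mode = "read"`
counts every read; under it, overlapping evidence from the same molecule
counts multiply (documented, not merged). Every output table carries its
evidence level, since cluster-level fractions can shift slightly between
the two.

## The heterozygosity expectation

A covered heterozygous cell is *not* expected to be called mutated 50% of
the time unless its depth is exactly 1. With $d$ independent informative
observations, each sampling the variant allele with probability $p$
(default 0.5) and being miscalled toward it with probability $\varepsilon$,
the per-observation alt probability is $q = p + (1-p)\varepsilon$ and

$$E \;=\; \sum_d w_d \, P\!\left(\mathrm{Binom}(d, q) \ge m\right)$$

over the realized depth histogram $w_d$ of covered cells.
`expected_het_fraction()` evaluates this exactly (no simulation), so an
observed cluster fraction can be judged against the coverage actually
achieved; an optional exact binomial test per cluster is provided, without
multiplicity correction since it is one descriptive comparison per cluster.
Two limits matter in practice: at $d = 1$, $\varepsilon = 0$ the
expectation is $p$ — the familiar 50% for a balanced heterozygote — and
with $p = 0$ the formula yields the false-ALT rate of
homozygous-reference cells, $1 - (1 - e/3)^d$ at $m = 1$ for uniform
substitution error $e$.

A modelling note: $q = p + (1-p)\varepsilon$ counts miscalls *toward* the
variant allele but neglects the second-order loss of true variant
observations miscalled away (a $p\,e$ term). At sequencing error rates
($e \lesssim 10^{-2}$) the neglected term is far below the sampling noise
of any realistic cell population. `p` is a parameter because allele-specific
expression can skew RNA-derived allele sampling away from 0.5.

The `mutated_fraction` reported per cluster uses covered cells
(`ALT + REF`) as its denominator; the per-all-cells fraction is emitted as
a separate column (`mutated_fraction_all`) to avoid any ambiguity about
which is which.

## Gene-set activity scoring

The recovery-AUC scorer ranks each cell's genes (rank 1 = highest
expression) and measures how early a gene set is "recovered" along that
ranking: with threshold $T = \lfloor \theta n \rfloor$ and
$H(k) = |\{g \in S : \mathrm{rank}(g) \le k\}|$,

$$auc = \frac{\sum_{k=1}^{T} H(k)}{\sum_{k=1}^{T} \min(k, |S|)}.$$

Design choices, each of which differs between published implementations and
is therefore pinned down explicitly:

* **Normalisation** uses $\min(k, |S|)$, so a set occupying the very top
  ranks scores exactly 1 regardless of whether $|S| \le T$.
* **Ties** — dominated by the zero block of droplet matrices — are broken
  by a seeded uniform shuffle, not by average ranks: average ranks would
  award fractional recovery to wholly unexpressed sets. The tie-break seed
  for each cell derives from the user seed and the cell's barcode, so
  scores are reproducible *and* independent of column order. The seed is
  recorded in the output.
* $\theta$ defaults to 0.05, the customary top-5% window; it is a flag, and
  because scoring is rank-based the scores are invariant under any strictly
  monotone transform of a cell's values (raw counts and log-normalised data
  agree exactly — a tested invariant).
* Set genes absent from the matrix are dropped with a logged count; a set
  with no overlap scores `NA` with a warning, never a silent 0.

## The simulators

`simulate_bam()` generates the data the genotyper consumes, with truth
attached, emulating a 10x library over one SNV. Defaults were fixed once to
describe a realistic shallow 10x experiment at a moderately expressed
locus: 500 cells, an even hom-ref/het mix, per-cell molecule depth
Poisson($\lambda = 2$) *including* the zero class (so `UNKNOWN` is
exercised), substitution error $10^{-3}$ (about Q30), on average 0.5 extra
reads per molecule, 20% of reads spliced over the site, balanced allele
sampling, 91-bp single-end reads (10x R2-like; mates add nothing to the
genotyping contract and are omitted). The error model is substitution-only,
matching the SNV-only scope. All randomness flows from one seed;
truth-table and record content re-runs are bit-identical.

What the simulator does *not* emulate — and hence what passing tests do not
establish about real data: ambient RNA and barcode swapping, doublets,
allele-specific expression drift across cell states, alignment artifacts
(the simulated CIGARs are clean `M`/`N` geometries), strand biases, and
non-uniform error profiles. The oracle-equivalence tests instead guarantee
the *mechanics* (CIGAR walk, counting, consensus) are exact, and the
law-recovery tests guarantee the statistics behave as derived under the
stated model.

`simulate_expression()` plants an active set: inactive cells draw all genes
from a negative-binomial law with lognormal gene means; active cells draw
set genes with means inflated $2^{effect}$-fold. `effect = 0` is an exact
null; the default `effect = 2` (4-fold) produces a clear but not saturated
separation.

## Numerical and interface choices

* Coordinates are 1-based (VCF convention) everywhere user-facing;
  conversion to the 0-based convention of alignment internals happens in
  one place.
* Barcodes are normalised by stripping a trailing `-<int>` GEM-well suffix
  (CellRanger emits it, user cluster tables often lack it); a flag disables
  this.
* Indels and multi-base alleles are rejected with an error naming the
  record rather than mis-genotyped; multi-allelic VCF records split into
  one site per alternate allele.
* `N` base calls count as "other" only if they pass quality (at the default
  Q20 they effectively never do).
* Degenerate inputs fail loudly: empty variant files, empty cluster tables,
  duplicate barcodes, missing BAM indexes (the error names the expected
  `.bai`), chromosomes absent from the header (the error lists available
  contigs), gene sets with no overlap.
* The CLI accepts `--threads` for interface stability but the
  implementation is single-threaded; results are trivially independent of
  the value. Outputs are plain TSVs with stable column names plus a JSON
  manifest per run (version, parameters, input MD5s, seed) sufficient to
  reproduce the command.

## Problem sizes used in validation

The shipped validation suite runs at desk scale, chosen to keep each check
statistically decisive: 1,000+ randomized CIGAR geometries against a
per-base expander; 100 simulated libraries of 25 cells against a naive
full-scan recount; populations of 2,000 heterozygous, 2,000 and 5,000
homozygous-reference cells at $\lambda = 2$ for the law-recovery checks
(3-standard-error bands); 50 random 200-gene matrices for AUC
oracle-equivalence at $10^{-12}$; and 20-seed null batches for the
planted-signature separation. The acceptance script
(`scripts/acceptance.R`) re-runs the same conditions end-to-end from a
single user seed.

## Known limitations

* Genotyping is evidence counting, not probabilistic genotype likelihoods:
  no copy-number awareness, no tumor-purity inference, no realignment or
  base-quality recalibration.
* A cell's label depends on coverage; at shallow depth most cells are
  `UNKNOWN` and cluster fractions should always be read jointly with
  `covered_fraction`.
* UMI consensus treats mate pairs sharing a UMI as one molecule only in
  consensus mode; in read mode both mates count.
* The recovery AUC compares cells against their own transcriptome ranking;
  it is not a between-cell normalised enrichment statistic, and AUC values
  are comparable across cells only under similar library complexity.
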