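---
title: "Methods: sequence-based STR/SNP panel statistics with strpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based STR/SNP panel statistics with strpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpanel)
```

## Scope and data model

`strpanel` implements the population-genetic workup of a massively parallel
sequencing (MPS) forensic identity panel, starting from *called* genotypes:
the package deliberately contains no read-level processing, alignment or
allele calling. Its reference panel shape is a 306-marker kit — 66 autosomal
STRs, 29 X-STRs, 75 Y-STRs (three of them multi-copy "a/b" markers that
amplify two paralogous sites per Y chromosome), 132 autosomal SNPs and 3
Y-SNPs — typed in 100 unrelated individuals, 50 male and 50 female.

Three tables drive everything:

* a **locus catalogue** (`locus_catalogue()`): name, chromosome class,
  canonical motif length, copy count, marker type;
* a **genotype table** (`genotype_table()`): one row per sample with sex and
  one cell per locus, validated against ploidy rules — two calls per
  autosomal locus, two (females) or one (males) at X loci, `copy_count`
  calls in males and none in females at Y loci; empty cells are null calls
  and are excluded from both numerator and denominator everywhere;
* a **coverage table**: long-form valid read counts per locus and sample.

## Bracketed nomenclature and length designations

Sequence-based (SB) alleles use the ISFG bracket convention:
`[SEQ]n` repeat blocks, uppercase runs for interruptions inside the repeat
region (RR), `N<k>` spacers for uncounted stretches, lowercase runs for
flanking-region (FR) sequence, and optional FR variant tokens
(`GRCh38-chr2:68011829-C`) after `;` separators. `parse_bracket()` enforces
this grammar strictly — malformed brackets, mixed-case runs and unknown
characters are rejected with the offending token named — and every parsed
allele round-trips through a canonical rendering that serves as its
identity key. Two alleles identical in the RR but differing in FR
annotation are distinct SB alleles; this is what lets FR variation drive
unique-allele gains.

The length designation (`designation_from_bracket()`) counts the
repeat-region length `L` in nucleotides — bracketed blocks plus uppercase
interruptions, with lowercase flanks and `N` spacers excluded — and names
the allele `floor(L/m)` with a `.(L mod m)` suffix, `m` being the canonical
motif length. The inclusion rules are forced by worked examples in the
bundled allele catalogue: a 1-nt interruption (`[AGAA]5 A [AGAA]12` = 17.1)
and a 5-nt leading interruption (`TTTTT [TTTTA]11 ...` = 23.4) must count,
while `N6`/`N27` spacers (`... [AAAG]4 N6 [AAAG]12 N27 [AAGG]4` = 38) must
not.

### Known nomenclature discordances

The bundled catalogue of 96 novel RR variant alleles
(`novel_allele_catalogue()`) stores each printed designation *verbatim*
alongside the recomputed one and flags disagreements instead of guessing
intent. 28 rows are discordant — all TCA-interrupted D13S325 rows print the
full-unit count without the `.3` remainder, all D8S1132 rows (including the
well-known 21.3 whose motif sums to 22.2), and single rows at D17S1290,
D3S1744, D21S1270, DYS518, DYS710 and DXS10135. Cross-platform designation
discordance of exactly this kind (e.g. at D9S925 and D14S608) is a known
hazard when MPS and CE calls are integrated, so the package treats the
printed designation as data about the source platform, not as ground truth
for the length rule. No attempt is made to reverse-engineer per-locus
counting conventions from 96 examples.

## Frequencies, haplotypes and denominators

`compute_allele_frequencies()` divides observed counts by observed
chromosomes: `2N` (autosomal), `2F + M` (X, sexes pooled), `M x copy_count`
(Y). Pooling male and female X frequencies is the default reporting
convention; `pool_sex_frequencies_check()` provides the supporting
exact/Monte-Carlo homogeneity test but never gates pooling. Null alleles
are dropped from the locus's denominator and never form an allele class.
One caveat is documented rather than "fixed": the bundled catalogue's two
X-STR rows print frequencies equal to `count/200`, which cannot arise from
150 X chromosomes in a 50/50 sample; the package computes `count/150` and
the acceptance tests assert both identities explicitly.

Y haplotypes (`assemble_y_haplotypes()`) are ordered allele tuples across
the requested Y loci, multi-copy loci contributing their unordered pair
sorted; counting is by exact tuple equality and males missing any call are
dropped with a warning.

## Forensic parameters

With `a_k = sum(p_i^k)` over allele frequencies and `n` observed
chromosomes:

* gene diversity `GD = n(1 - a_2)/(n - 1)`;
* `PIC = 1 - a_2 - a_2^2 + a_4`;
* match probability `MP = sum(f_g^2)` over **observed** genotype
  frequencies (the PowerStats-style convention; not HWE-expected), with
  `PD = 1 - MP`;
* from observed heterozygosity `h` (homozygosity `H = 1 - h`):
  `PE = h^2(1 - 2hH^2)` and `TPI = 1/(2H)` (infinite at `h = 1`);
* X discrimination: `PD_M = 1 - a_2` (hemizygous males) and
  `PD_F = 1 - (2 a_2^2 - a_4)` (diploid females under HWE);
* Y haplotype diversity `HD = N(1 - sum p_i^2)/(N - 1)` and discrimination
  capacity `DC = k/N`.

On the reference configuration of 50 males with 49 haplotypes (48
singletons, one doubleton) the formulas give `HD = 0.99918` and a unique
fraction of `48/49 = 97.96%`; summary values sometimes quoted as 0.9996 and
97.92% are not consistent with the formulas on that configuration, and the
package asserts the formula values.

### X-chromosomal mean exclusion chances

The four standard MEC variants are defined operationally as the probability
of excluding a random non-relative under a pedigree scenario, and each
closed form is gated in the tests by an exhaustive enumeration over founder
genotypes weighted by frequency (agreement to 1e-10 on a 0.05-grid of
spectra up to five alleles):

* **Kishida** and **Desmarais** (mother–daughter–alleged father trio; the
  daughter's X is obligately paternal): `1 - a_2 - a_2^2 + a_4`. The two
  published derivations are algebraically equivalent and equal the PIC, so
  both fields carry the same value.
* **Desmarais Duo** (daughter–alleged father, mother untyped):
  `1 - 2a_2 + a_3`.
* **Krüger** (deficiency case): the scenario convention is genuinely open
  in the source literature, so the package fixes it to the ChrX database
  convention — the alleged father is unavailable and his mother, the
  paternal grandmother, is typed as a *diploid* excludee — giving
  `1 - 2(a_2 + a_2^2 - a_4) + a_3 + 3(a_2 a_3 - a_5)`. This is the design
  decision most worth re-examining against a specific casework convention;
  the enumeration oracle makes any alternative scenario easy to gate the
  same way.

### Combined panel statistics

`combine_panel()` accumulates in log10 space, because a 66-locus combined
match probability sits around 1e-70 and underflows double precision if
multiplied naively: `CMP = prod(MP)`, `CPD = 1 - CMP`,
`CPE = 1 - prod(1 - PE)`, `CPI = prod(TPI)`. Rendered strings mirror the
reporting style of the field (`"1-2.411e-73"`, CPE as a many-nines
percentage).

## Equilibrium tests

**HWE** (`hwe_exact()`): conditional exact test on the genotype array given
allele counts (Levene's distribution), p-value = probability mass of arrays
no more probable than the observed one. For at most 4 alleles and 15
diploids the array space is enumerated exactly; otherwise Monte-Carlo
shuffling of the allele vector into pairs estimates the mass with the
add-one rule `(hits + 1)/(steps + 1)`. The two routes are required to agree
within 3 Monte-Carlo standard errors on every enumerable fixture, and the
Monte-Carlo route is additionally validated against an all-permutations
oracle at tiny n. A Markov-chain sampler is deliberately out of scope:
shuffling plus small-case enumeration covers panel-scale use. Default
100 000 steps for production runs; pipeline and test runs scale this down
(see *Problem sizes* below). X-locus HWE uses females only by default,
since hemizygous males carry no HWE information.

**LD** (`ld_pairwise()`): for unphased diploid pairs, two-locus haplotype
frequencies are fitted by gene-counting EM (log-likelihood tolerance 1e-8,
cap 1000 iterations; only double heterozygotes are phase-ambiguous) and the
likelihood-ratio statistic against the allele-frequency independence model
is calibrated by permuting one locus's genotypes across individuals. For
haploid (Y) data the G statistic of the haplotype contingency table is
permuted directly. `p = (exceedances + 1)/(permutations + 1)`, so p is
never exactly zero. The EM fit is checked against direct one-parameter
likelihood maximization on a biallelic pair, and the permutation p-values
are checked for null uniformity (Kolmogorov distance below 0.1 over 500
replicates).

`bonferroni_plan()` keeps the family bookkeeping honest: 66 loci pairwise
give 2145 tests, 29 give 406, 132 give 8646, with
`alpha' = alpha / n_tests`. LD was historically run only within chromosomes,
but the reported correction denominators count *all* pairs, so all-pairs is
the package default; `ld_test_panel(max_pairs = ...)` can cap the tests
actually executed on large panels without touching the denominator.

## SB vs LB accounting

`compare_locus()` de-duplicates SB alleles by identity key, collapses them
to length classes, and classifies the source of the SB gain by inspecting
within-class variation: `RR_only`, `FR_only`, `both`, or `none` (a locus
with a single observed allele is `none` by definition). `panel_summary()`
reports totals per chromosome class and overall — and reports the
percentage gain under *both* conventions (ratio of summed totals, and mean
of per-locus percentages), because the two differ whenever locus allele
counts differ and a silent choice between them would be misleading.

## Coverage QC

Depth of coverage of a locus is the sum of valid reads in a sample,
averaged over samples. `doc_summary()` reports per-locus means, the
highest-to-lowest ratio (integer-rounded for reports, exact internally,
undefined with an error if any locus mean is zero), and the loci below the
flagging threshold, default 650x. Run-level quality metrics such as Q30 are
pass-through metadata: no read-level data enters the package.

## Synthetic population generator

`simulate_population()` exists so every stage is testable without any
external download; it emulates the statistical structure the analysis
assumes and nothing more:

* unrelated individuals, Hardy-Weinberg genotypes, chromosome-correct
  ploidy (including multi-copy Y loci drawing two alleles);
* per-locus spectra drawn once from a symmetric Dirichlet (concentration 2
  over 8 length classes for STRs — typical of Han Chinese STR diversity —
  and 2 over 2 alleles for SNPs), or supplied explicitly;
* SB decoration: each length class receives 1–3 bracket variants that keep
  the repeat-region length fixed (a mutated internal unit), and FR SNP
  annotations with probability 0.15, so length collapse and RR/FR
  classification have realistic work to do;
* coverage: per-locus lognormal with meanlog ~ Normal(8.5, 1.0), giving the
  heavy cross-locus tail (max/min well above 10) seen in amplicon panels.

A single global seed expands into per-locus streams by a stable hash of
the locus name, so adding a locus never perturbs another's draws, and a
fixed seed reproduces the draw byte-for-byte. What the generator does *not*
emulate — stutter, allele imbalance, null-allele mechanisms, relatedness,
population structure — bounds what passing tests can show: they validate
the estimators and tests on clean HWE data, not robustness to artefacts of
real MPS chemistry.

`simulate_panel_study()` layers the bundled novel-allele catalogue on top:
each of the 96 recorded alleles is planted in exactly its recorded number
of chromosome slots (background collisions are swept to a distinct token
first), so the frequency engine must reproduce the recorded frequencies
exactly — the package's strongest end-to-end check.

## Problem sizes and numerical choices

Default test and pipeline sizes were chosen to keep the full suite
comfortable on a single CPU while leaving the estimators' behaviour
visible: HWE calibration uses 1000 replicates of 50 diploids at 1000
Monte-Carlo steps each; LD uniformity uses 500 haploid replicates at 199
permutations; parameter-recovery simulations use 10 000 individuals;
pipeline smoke runs use 300 Monte-Carlo steps and 49 permutations.
Production defaults are higher (100 000 steps, 1000 permutations).
Tie-break tolerance when comparing array probabilities is 1e-9 on the log
scale, protecting the "no more probable than observed" mass against
floating-point noise. Degenerate inputs have defined behaviour throughout:
monomorphic loci give p = 1 with a `degenerate` tag, `TPI` is reported as
`Inf` at full heterozygosity, and a zero-coverage locus makes the coverage
ratio an error rather than an infinity.

## Pipeline and reproducibility

`run_pipeline()` orders the stages — frequencies, forensic statistics,
HWE/LD, SB/LB comparison, coverage QC — reading and writing only the plain
TSV/CSV/JSON dialects defined by the modules (the kit vendor's XLSX report
schema is proprietary; converting it to the genotype TSV is a one-off
adapter left outside the package). Every output is re-readable by the
package's own readers; a failed stage aborts with a stage-named error and
removes partial outputs; and the manifest (package version, seed, config
echo, output checksums) fully determines a reproduction — re-running with
the same seed yields identical checksums. A thin command-line wrapper over
these functions ships in `inst/scripts/strpanel-cli.R`; the exported
functions are the primary interface.
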