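---
title: "Methods: collapsing burden analysis, cosegregation and evidence combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsing burden analysis, cosegregation and evidence combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The statistical model

The package tests whether rare, novel, predicted-damaging variants in one
gene are enriched among affected subjects. Because qualifying variants are
individually near-singleton, per-variant association is powerless; the
collapsing approach instead reduces each subject to a binary carrier
indicator — *does this subject carry at least one qualifying variant?* —
and tests the resulting 2×2 table of carrier status against cohort
membership. This is the CAST family of burden tests: it is powerful when
qualifying variants act in the same direction (here, presumed
risk-conferring under a dominant model) and loses power when the
qualifying set mixes risk and benign variation, which is why the
qualifying definition (novelty, QC, deleteriousness stratification) does
most of the scientific work.

Conditioning on both margins of the table, the number of case carriers
under the null is hypergeometric, and the one-sided exact P value is the
upper tail

$$P = \sum_{k \ge a} \frac{\binom{n_1}{k}\binom{n_2}{(a+c)-k}}{\binom{n_1+n_2}{a+c}},$$

computed via the hypergeometric distribution function. The alternative is
one-sided by design — the screen asks only about enrichment in cases. The
one-sided chi-square option is defined as half the two-sided 1-df Pearson
P when the observed case carrier fraction exceeds the control fraction
and one minus that half otherwise; a perfectly proportional table
therefore gives exactly 0.5. The published analyses this package
re-implements name both tests without stating the one-sided chi-square
recipe; the halved-Pearson convention is the common one and is surfaced
in the report configuration, with the Yates correction off by default
(also configurable). Effect size is the cross-product odds ratio with a
Woolf log-scale interval; a zero cell renders OR and CI undefined, shown
as "-" in reports rather than infinity.

Two counting conventions exist for such tables. The default is
subject-level counting (denominators $n_1, n_2$ subjects), which is the
convention under which the packaged case study's printed statistics
(OR 3.9, one-sided Fisher P 0.03 at 8/574 vs 3/828) reproduce exactly.
Allele-level counting (denominators $2n_1, 2n_2$) is available behind
the `counting = "allele"` flag.

### The burden-row variant count

In the rendered table the `Nvar` column counts qualifying *carrier
observations* per stratum, not distinct variants: a doubleton counts
twice. This is the convention under which the case study's printed
inventory (30 total = 16 case + 14 control observations; 11
damaging-missense = 8 + 3, with one variant recurring in two cases) is
internally consistent; the distinct-variant count is carried in the
`n_distinct` column for transparency.

### Stratum layout

The table layout places every variant that is not damaging-missense in
the below-threshold group, with mutation-type sub-rows (frameshift,
splicing, missense, and any other consequence present); the
at-or-above-threshold group contains the damaging missense set. LGD
variants (which may lack meaningful CADD annotations) therefore appear in
the first group, mirroring the layout of the published table this
renderer replicates. Fisher's exact test is forced for any row whose
smallest expected carrier cell is below 5, regardless of the configured
test.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cadd_threshold` | 20 | CADD PHRED score | inclusive (≥ 20); ≈ top 1% predicted deleteriousness, the conventional damaging-missense cutoff |
| `max_abs_diff` | 0.10 | coverage fraction (percentage points / 100) | strict `>` on the absolute difference of adequate-coverage fractions; a site at exactly 0.10 is retained |
| `min_depth` (`adequate_fraction`) | 10 | reads | common exome QC convention for "adequate coverage"; the source analyses leave it unstated, so it is an explicit argument, never silent |
| `novelty_resources` | 1KG, ESP, ExAC, dbSNP, UMD | — | presence-based novelty; gnomAD is annotated but excluded from the default list (a variant can be novel despite a gnomAD record), and the list is fully configurable |
| `test` / `correct` | fisher / FALSE | — | exact tail by default; halved-Pearson chi-square optional |
| `counting` | subject | — | CAST-style carrier indicator; allele-level optional |
| `tolerated_unaffected_carriers` | 0 | subjects | full penetrance for the dominant screen; raise for reduced-penetrance screens |

Two deliberate readings of under-specified rules: "differed by more than
10%" is taken as 10 *percentage points* of absolute difference, not a
ratio (the literal reading; the boundary case is tested), and novelty is
*presence*-based — a record present at allele frequency 0 in a listed
resource is not novel, because the defining texts say "not present",
never naming a frequency cutoff.

## The dominant cosegregation filter

A candidate cosegregates iff every genotyped affected family member is a
heterozygous carrier and every genotyped unaffected member a non-carrier.
Missing genotypes are non-informative rather than violations, but a
verdict resting on fewer than two informative members is negative — a
proband-only "segregation" carries no information. Phenocopies are out of
model (an affected non-carrier is a hard violation), matching the
full-penetrance assumption; the tolerated-unaffected-carriers knob
relaxes the other direction only. Ranking of surviving candidates is LGD
before damaging missense before the rest, then descending CADD, stable
for ties.

## ACMG evidence combination

The combining rules are shipped as a data file
(`inst/extdata/acmg_combining_rules.tsv`) transcribed from the published
2015 ACMG/AMP combining criteria: 8 Pathogenic rows, 6 Likely-pathogenic
rows, 2 Benign and 2 Likely-benign rows, each a vector of minimum counts
per evidence strength evaluated with ≥ semantics. Keeping the table as
data makes rule provenance auditable and the combiner free of hard-coded
branching. The strongest fired class within a direction wins; if rules
fire in both directions the evidence is contradictory and the call is
VUS, as is firing nothing. PP5/BP6 (reputable source without shared data)
remain in the vocabulary although ClinGen later recommended their
retirement, because classifications in the literature this package
reproduces use PP5; users can simply not supply them.

## The synthetic-data generator

`simulate_cohort()` emulates the study design the pipeline targets: 574
cases vs 828 controls; control carrier probability 14/828 ≈ 0.017 with
case carriage at odds `planted_or` times the control odds (so
`planted_or = 1` is the exact null); heterozygous singleton variants (a
`recurrence_rate` knob produces case doubletons, emulating the recurrent
variant in the packaged study); consequences drawn 28:1:1
missense:frameshift:splicing; CADD scores from a two-component normal
mixture straddling 20 (weight 11/30 above, matching the observed D-mis
share); exactly `round(frac_imbalanced_sites × n_sites)` coverage-imbalanced
sites (an exact count, not an expectation, so pruning tests are stable),
default 4.8% of 1000 sites; and a `novelty_leak_rate` (default 0.1)
probability that a variant surfaces in a novelty resource and is removed
by the filter. Qualifying variants are placed on coverage-balanced sites,
so the planted association survives harmonization by construction.
Every quantity is reproducible from the config seed, and the `truth`
record suffices to recompute each planted parameter.

What the generator does **not** emulate: linkage disequilibrium,
population structure, relatedness between cohort subjects, sequencing
error, genotype uncertainty, or covariates — carrier indicators are drawn
independently per subject. Passing the recovery and error-rate tests
therefore demonstrates the statistical machinery is correct under the
stated sampling model, not that real exome data meet that model; in
particular the coverage harmonization's observed exclusion fraction on
real data is data-dependent and only its mechanism (exact recovery of a
planted imbalance fraction) is testable here.

## Numerical and degenerate-input choices

- Exact test via the hypergeometric distribution function; verified in
  the suite against exhaustive enumeration of binomial coefficients for
  every table with total size ≤ 60 (tolerance 1e-12).
- Chi-square cells are cast to double before forming cross-products
  (integer overflow territory at cohort scale).
- Zero carrier margin: chi-square P is 1 with a warning, never an error;
  Fisher handles it natively (P = 1 when a = 0).
- Degenerate OR cells give `NA` everywhere and "-" in renders.
- Empty strata produce rows with zero counts and undefined P.
- Coordinates are 1-based throughout (genomic GRCh37-style, protein
  residues); exported BED intervals are converted to the 0-based
  half-open BED convention.
- Truncation distance counts the stop position itself
  (`length − stop + 1`): a stop at codon 883 of 2871 residues removes
  1989.

## Simulation study sizes

The packaged checks use 2000 replicates for the null type-I error bound
(α = 0.05, bound nominal + 3·SE ≈ 0.065), 400 replicates per planted OR
∈ {1, 2, 4, 8} for power monotonicity and median-OR recovery (within 25%
of the planted value), and full enumeration of all 2×2 tables with
N ≤ 60 for the exact-test oracle. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while keeping the default
suite fast.

## Known limitations

- The "Total" row of the replicated study table is documented as not
  exactly recoverable by the standard cross-product/Woolf/halved-Pearson
  recipes (the published 1.6 / 0.15 versus computed 1.7 / 0.11); the
  computed values are reported as-is. Likewise the published CI bounds
  are close to but not exactly Woolf (1.0–14.6 vs 1.0–14.7), so only
  point ORs and P values are treated as reproducible; and the published
  one-sided P for a row whose only carrier is a control (printed 0.60)
  is not the enrichment-in-cases tail (which is 1.0) — this package
  always reports the enrichment-in-cases tail.
- Domain intervals in the packaged domain map are synthetic
  approximations; only the residue-to-domain assignments of the printed
  records are authoritative.
- HGVS handling extracts the protein residue integer only; no transcript
  mapping, no splice-distance recomputation (splice-site status is taken
  from the input annotation).
- Single-gene focus: the API takes any gene label but performs no
  genome-wide multiplicity correction.
- No covariate adjustment (the underlying design has none).
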