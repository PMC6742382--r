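---
title: "Estimating false-negative and false-positive rates in mutation callsets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating false-negative and false-positive rates in mutation callsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnscope)
```

## The problem

Two laboratories sequence the same cell lines and publish mutation callsets;
the callsets disagree on a third or more of the calls. Is the disagreement
caused by genuine genetic divergence of the cultured lines, by false-positive
calls, or by false negatives — real mutations that one pipeline simply failed
to call? `fnscope` implements a framework for answering this with a third,
deeper measurement: targeted sequencing (T-NGS) of the same samples at high
depth, whose high-allele-frequency calls serve as a *possible-truth* set.

Because no absolute gold standard exists for these samples, every rate the
package reports is a "possible" rate, conditioned on one explicit assumption:

> calls with mutant allele frequency (mAF) at or above 10% in the deep
> reference are treated as true mutations.

The assumption is itself testable within the framework: technical replicates
of the deep reference agree almost perfectly above 10% mAF and increasingly
poorly below it, which is exactly what the replicate-consistency module
measures.

## Definitions

For a database callset $D$ and a truth set $T$ (reference calls with
$\mathrm{mAF} \ge c$, default $c = 0.10$), with $R$ the full reference
callset:

* **P-TP** $= |D \cap T| / |D|$ — fraction of database calls confirmed by
  the truth set.
* **P-FP** $= |D \setminus T| / |D| = 1 - \text{P-TP}$.
* **adjusted P-FP** — as P-FP, after *rescuing* database-only calls that the
  reference does detect at sub-cutoff frequency
  ($0 < \mathrm{mAF} < c$ in $R$); such calls are plausibly true and are
  removed from the false-positive numerator.
* **positive identification rate** $= |D \cap T| / |T|$ — sensitivity of the
  database against the truth set.
* **P-FN** $= 1 -$ identification rate.
* **consistency rate** of two callsets $= |A \cap B| / |A \cup B|$;
  inconsistency is its complement.

All comparisons run on a configurable key: genomic
(sample, chromosome, position, ref, alt) by default, or protein
(sample, gene, protein change) for cross-build comparisons. Databases
rarely document their matching rule, so both schemes are first-class and
the choice is a configuration field.

Two denominator conventions circulate for rates of this kind: the truth-set
size and the database's own call count. The package uses the database's own
call count for P-TP and P-FP and the truth-set size for the identification
rate and P-FN — the standard precision/recall convention, and the one under
which published worked ratios such as 307/337 reproduce.

## Filtering

Raw annotated callsets are reduced to the analysis callset by, in order:

1. **class filter** — keep exonic non-silent classes plus splice-site calls
   (silent, intronic and intergenic calls are dropped; so is `Other`);
2. **population-allele-frequency filter** — drop calls with population AF
   $\ge$ 1% (known polymorphisms); calls with *missing* population AF are
   kept, because an unreported variant is novel until proven common;
3. **recurrent-germline removal** — a locus carried by *more than* 80% of
   samples is almost certainly a germline polymorphism even when population
   databases do not report it; flagging runs on the post-class-filter
   callset so that silent/intronic calls never drive recurrence, and the
   comparison is strict (`>`) following the "more than 80%" rule, with a
   configuration flag for `>=`;
4. **blacklist** — an explicit locus list (e.g. recurrent short indels),
   supplied as data because it is dataset-specific.

In the end-to-end pipeline the reference's recurrent loci are additionally
blacklisted from every database callset: a database may carry a germline
contaminant in too few of its samples to flag it from that database alone,
and leaving such calls in place would masquerade as false positives.

Every filter attributes each removed call to the first rule that removed it,
and the log always satisfies `input = survivors + removals`.

## Replicate consistency and the truth cutoff

`binned_consistency()` partitions the union of two replicate callsets into
mAF bins (default edges 0.01, 0.02, 0.05, 0.10; half-open `[lo, hi)` with
the last bin closed at 1) and reports per-bin intersection-over-union. Two
binning modes are reported side by side because the assignment of a shared
call observed at two different frequencies is genuinely ambiguous:

* `either` — a call is binned by the *maximum* of its two observed
  frequencies (it counts wherever either replicate would pass the cutoff);
* `lowest` — by the *minimum* across the sources where it appears (the bin
  it falls in when the lowest observed value is the cutoff).

`maf_regression()` quantifies frequency agreement by ordinary least squares
over shared calls, excluding pairs where either side has depth below 20
reads; restricted to pairs with both frequencies at or above the cutoff
("hmAF") or to pairs with at least one below it ("low"). Both $r$ and $r^2$
are reported, since published correlation figures are frequently labeled
ambiguously between the two. Regression uses shared calls only: a scatter
needs two coordinates.

## Stratified statistics

The 2×2 association tests (CpG-island membership × FN status; gene group ×
FN status) use a deterministic, always-reported selection rule: **Fisher's
exact test when any expected cell count is below 5, otherwise the Pearson
chi-square test without continuity correction**. The continuity-corrected
chi-square was considered and rejected: like Fisher's exact test it is
conservative at the table sizes this analysis produces (a few hundred truth
calls), and in null simulations it pushes the empirical type-I error below
the 3–7% band that a nominal-5% test should occupy; the uncorrected Pearson
test holds its size there. Odds ratios with a zero cell are reported as the
raw `Inf`/`0` alongside a Haldane–Anscombe corrected value (+0.5 per cell).

The CpG annotation takes intervals in 0-based half-open BED convention and
flags a 1-based call position $p$ as inside an island $(s, e]$ iff
$s < p \le e$; the conversion lives in one place, `annotate_cpg()`.

Read-count comparisons use the two-sided Mann–Whitney test on the
mutation-supporting read count (`t_alt_count` semantics; total depth is a
configuration alternative, since "read count of a mutation" is used both
ways in the field — the default is a documented choice, not an assertion
about any particular dataset). When
$n_A n_B \le 10^4$ the exact tie-aware null distribution of the rank sum is
enumerated by dynamic programming over doubled midranks (R's `wilcox.test`
cannot compute exact p-values in the presence of ties); otherwise the normal
approximation with tie and continuity correction is used, and the method is
reported in the result. `median_count_test()` implements Mood's median test
via the same 2×2 machinery.

## The synthetic-data generator

The generator exists so that every estimator can be validated by parameter
recovery with no external data. Its defaults are the study conditions and
are not adjusted per analysis:

| parameter | default | meaning |
|---|---|---|
| `n_samples`, `n_genes` | 35, 151 | study scale |
| `mut_rate` | 0.235 | truth mutations per gene per sample (Poisson) |
| `clonal_weight` | 0.5 | clonal `Beta(8,8)` vs subclonal `Beta(2,64)` mAF mixture; yields ~620 high-frequency truth calls and a comparable low-frequency tail |
| `cpg_fraction` | 0.15 | truth calls inside CpG islands |
| `high_fn_gene_fraction` | 0.5 | genes assigned to the low-coverage group |
| `depth_mean_low/high`, `depth_size` | 150 / 60, 4 | platform depth (negative binomial); the high-FN group is the low-coverage group |
| `base_detection` | 0.55 | marginal platform detection of high-frequency truth calls (injected P-FN = 45%) |
| `cpg_or` | 0.35 | detection odds multiplier for CpG calls |
| `depth_coef` | 0.8 | detection log-odds per SD of log depth |
| `low_maf_penalty` | −4 | detection log-odds shift for sub-cutoff calls |
| `fp_rate` | 0.6 | false calls per sample per platform (Poisson), at low mAF (`Beta(2,38)`) |
| `overdispersion` | 0.01 | beta-binomial ICC of re-measured mAF |
| `n_contaminants` | 3 | germline frameshift loci planted in 82–97% of samples with missing population AF |
| `rep_hmaf_detect`, `rep_detect_intercept`, `rep_detect_slope` | 0.99, 8.0, 3.8 | replicate detection: ~0.99 above 10% mAF, `plogis(8 + 3.8 log10 mAF)` below |

Modeling choices worth stating explicitly:

* Platform detection is logistic in standardized log-depth plus a binary CpG
  term plus a sub-cutoff penalty. The study establishes only directionality
  (higher FN for CpG calls and for low-coverage genes; databases carry very
  few sub-10% calls), so the functional form is this package's choice. The
  strongly negative `low_maf_penalty` is what keeps simulated database
  callsets dominated by high-frequency calls — without it a simulated
  database would "detect" subclones at nearly the clonal rate and its P-TP
  would sit near 50% instead of the observed ~90%.
* The detection intercept is calibrated (by root-finding) so that the
  *marginal* detection over high-frequency truth calls equals
  `base_detection` exactly. This makes "injected P-FN" a well-defined
  quantity for recovery tests despite the CpG and depth covariates.
* False-positive mAFs are drawn low so that the rescue pathway of the
  adjusted P-FP is exercised: injected FPs are *not* rescuable (novel loci),
  while boundary-flipped subclonal detections are.
* The replicate detection curve is tuned so per-bin replicate consistency
  climbs from ~20% below 1% mAF to ~98% at 10%, the qualitative pattern the
  cutoff choice rests on.
* Platforms are conditionally independent given the truth. Real databases
  share samples, pipelines and annotation sources, so real between-database
  consistency (~61%) exceeds what independence predicts (~38% at 55%
  detection). Estimators conditioned on the truth set are unaffected, but
  simulated between-database consistency should not be compared to the
  published one.
* What the generator does *not* emulate: read-level errors, alignment
  artifacts, shared (correlated) platform failures, mutation hotspots,
  sample contamination or mislabeling. Passing recovery tests therefore
  shows estimator correctness under the stated model, not robustness to
  those real-world effects.

Scenario presets: `paper_like` (the defaults), `null_no_cpg_effect`
(`cpg_or = 1`), `null_no_group_effect` (equal depth means across gene
groups), `high_fp` (`fp_rate = 6`). The null presets exist for type-I-error
calibration of the association tests.

## Numerical conventions and degenerate inputs

* Percentages are rounded half-up to one decimal, the convention used for
  every printed ratio; all rates are carried as fractions internally and every
  report keeps numerator and denominator alongside the rate.
* Undefined rates (zero denominators) raise typed errors or render as `NA`,
  never as 0.
* Duplicate keys within a callset collapse to the maximum-depth record.
* Truth-set membership is inclusive at the cutoff (`maf >= 0.10`).
* Per-gene P-FN is clamped to [0, 1]; with protein-scheme matching a
  database can confirm more calls for a gene than the truth set holds.
* Gene grouping uses `>=` for the high-FN group ("P-FN ≥ 60%") and requires
  at least 5 truth calls; smaller genes are `excluded`, not forced into a
  group.
* Validation-candidate gene ranking breaks ties lexicographically, making
  the selection deterministic.

## Test problem sizes

The shipped test-suite and acceptance script re-derive every headline
quantity at sizes chosen to balance statistical resolution against runtime:
worked-ratio checks are exact set constructions (instant); set-algebra
oracles run at $10^3$ keys; parameter recovery uses 250 samples × 180 genes
(≥ 5000 high-frequency truth calls, so 3 binomial SEs of the injected 45%
P-FN is about ±2 points); null calibration runs 2000 replicates at 25
samples × 80 genes per preset; replicate-consistency structure pools three
study-scale simulations.

## Worked example

```{r example}
cfg <- scenario_preset("paper_like", seed = 1L)
study <- simulate_study(cfg)
run <- run_config(
  replicates = setNames(study$replicates, c("TarSeq1", "TarSeq2")),
  databases = study$platforms
)
report <- run_pipeline(run)
report$error_reports$DB1
report$replicate_concordance$binned_either
```

## Known limitations

* The truth set inherits any systematic blind spot of the deep reference:
  a region invisible to both the reference and the databases contributes to
  no estimator. The rates are lower bounds on agreement with biology, which
  is why they are "possible" rates.
* Cross-database comparisons at different genome builds require the protein
  key scheme, which cannot distinguish distinct genomic events with the same
  protein annotation.
* The evolution-model summary quantifies which discordance pattern the data
  favor; it is a descriptive decomposition, not a formal test of the
  evolution hypothesis.
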