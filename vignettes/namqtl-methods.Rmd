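---
title: "Methods: simulation, phenotype aggregation and cross-validated QTL detection in a BC1S3 NAM population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`namqtl` implements the complete analysis chain used for multi-parent
barley-style nested association mapping (NAM) populations: many wild
donors each crossed to one recurrent elite parent, the F1 backcrossed
once and selfed three times (BC1S3), phenotyped over several years, and
scanned with a multiple-regression association model. Because such
genotype matrices are usually not redistributable, the package ships a
first-class simulator whose output has the statistical structure every
downstream stage assumes, so the whole chain is testable offline.

## Population simulator

**Meiosis.** Crossovers follow the Haldane model: the recombination
fraction between loci $d$ cM apart is $r = \tfrac12(1 - e^{-2d/100})$, with
no interference. A gamete is generated as a Markov chain along each
chromosome: the starting haplotype is a fair coin, and the haplotype
switches between adjacent markers with probability $r$. Chromosomes are
separated by a forced switch probability of $\tfrac12$ (independent
assortment). This count-location construction is exactly checkable in
closed form, which the tests exploit.

**Breeding scheme.** The donor is homozygous for the wild allele at every
marker, the recurrent parent homozygous cultivated. Each line descends from
its own BC1 plant (one F1 gamete plus a recurrent gamete) followed by three
generations of selfing with independent meioses. Consequences used as test
oracles:

* the wild-allele frequency is $\tfrac14$ at every locus (invariant under
  selfing);
* residual heterozygosity halves per selfing generation:
  $\tfrac12 \cdot (\tfrac12)^3 = \tfrac1{16}$;
* per-locus genotype frequencies are
  $P(0) = \tfrac{23}{32},\; P(1) = \tfrac1{16},\; P(2) = \tfrac7{32}$,
  where the dosage codes the number of wild alleles.

**Families and polymorphism.** A population concatenates independently
simulated families. Each marker segregates in a Bernoulli-masked subset of
families (rate configurable, default 1); in a masked-out family the marker
carries dosage 0 everywhere. This reproduces the family-monomorphic markers
that make nested family-specific effects estimable only where the marker
segregates.

**Phenotypes.** Plot values are
$y_{ijk} = \mu + \sum_q \beta_q d_{iq} + g_i + t_j + (gt)_{ij} + e_{ijk}$
with polygene $g_i \sim N(0, V_G)$ drawn per line independently of the
markers (so genuine genetic variance exists beyond the mapped QTLs), year
main effects $t_j \sim N(0, V_Y)$, interaction
$(gt)_{ij} \sim N(0, V_{GY})$ and plot error $e \sim N(0, V_R)$. QTLs may
carry a family mask (the donor allele is functional only in a strict subset
of families). The design is balanced by default; an optional per-year
replicate pattern such as (1, 2, 2, 1) mimics unbalanced trials. Family
sizes default to equal because only the population total is ever published.

## Phenotype aggregation

**Variance components** come from the all-random one-step model
$y = \mu + g + t + gt + e$. The default estimator is REML (lme4). For
balanced designs a deterministic Henderson III / expected-mean-squares
solution is provided and doubles as the independent second route in the
tests ($V_R = MS_E$, $V_{GY} = (MS_{GY} - MS_E)/r$,
$V_G = (MS_G - MS_{GY})/(yr)$, negatives clamped to 0). If the REML
optimizer fails on degenerate (for instance noise-free) data, the balanced
EMS solution is used with a message.

**Heritability** across years is
$h^2 = V_G / (V_G + V_{GY}/y + V_R/(yr))$, the genotypic share of the
variance among line means; clamping keeps it in $[0, 1]$.

**BLUEs** use fixed genotype effects with random year and genotype-by-year
terms. For balanced data the generalized-least-squares solution reduces
exactly to the per-line mean (the year terms are orthogonal to genotype),
which is used as a deterministic fast path; unbalanced data are fitted with
lme4. An optional replicate-within-year term is off by default, since the
reference analysis does not state one.

**GDD.** Growing degree days with a 0 °C base cumulate the mean daily
temperatures of all days above 0 °C from sowing to the event day. The
sowing day itself is included by default (configurable), reading "days from
sowing" as counting sowing as the day of origin. Developmental traits can
be analysed in days or GDD; the shoot-elongation phase is conventionally
analysed in GDD, other developmental traits in days.

## Association scan

The scan is a fixed-effects multiple regression per marker:
intercept + family (one-hot, first family as reference) + selected
cofactors + marker dosage, estimated by OLS via QR residualization (exactly
equivalent to `lm()`, verified marker-by-marker in the tests). The additive
effect is the dosage coefficient $\beta$; the reported QTL effect is the
homozygous difference $2\beta$. Single-marker $R^2$ comes from the
marker-only regression without family or cofactors.

**Cofactor selection** is greedy forward selection over all markers
simultaneously, minimizing $SBC = n\ln(RSS/n) + k\ln n$ (with $k$ counting
all coefficients, intercept and family included; the constant offset does
not affect the order). Selection stops when no marker decreases the
criterion; ties break by map position, then marker id. Forward-only was
chosen because the source protocol states only that the criterion was
minimized, and forward selection is the deterministic standard for this
model family. Under the global null the admission threshold corresponds to
$|t| \gtrsim \sqrt{\ln n} \approx 2.5$, so an occasional chance cofactor is
expected: the measured null distribution at $n = 500$, 300 markers is
$P(0) = 0.28$, $P(\le 2) = 0.75$, $P(\le 5) = 0.97$.

**Exclusion rule.** Cofactors on the same chromosome strictly closer than
1 cM to the tested marker are dropped for that test, including the tested
marker itself when it was selected; cofactors on other chromosomes are
always retained (genetic distance across chromosomes is undefined). Note
that on sparse desk-scale maps (several cM between markers) the 1-cM window
excludes nothing, whereas on the dense maps the protocol was designed for
it removes the tightly linked proxies of the tested marker; this scale
mismatch is visible in the recovery experiments below.

**Multiple testing** uses the Bonferroni–Holm step-down (own
implementation: sort, multiply the $i$-th smallest by $m - i + 1$, running
maximum, cap at 1), with significance at adjusted $p < 0.05$. The
implementation is checked exactly against a brute-force oracle and against
`stats::p.adjust` on random vectors.

**Missing dosages** are imputed by the within-family mean dosage just
before the scan (never at read time), preserving family structure.

## Resampling layer

Each of `n_runs` (protocol value 200; tests scale down to 8–20 and say so)
runs draws, per family, round(0.8 · n) training lines (round half up,
always leaving at least one hold-out line per family) and re-runs the
*entire* procedure — cofactor selection, scan, Holm — on the training set
only, so no hold-out information leaks into selection. Per marker the
detection rate is the share of runs in which it was significant; effect,
adjusted p and $R^2$ are averaged over exactly those runs. Per run, all
significant markers are jointly re-fitted with the family term;
$R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - k - 1)$ (Ezekiel) is reported with
$k$ counting marker coefficients only (the family-inclusive convention is
recorded alongside as `r2_adj_full`), and the hold-out predictive ability
$R^2_{pred}$ is the squared Pearson correlation between observed and
predicted hold-out BLUEs. Runs with rank-deficient joint models drop the
offending columns and continue.

Markers reaching a 10% detection rate qualify as putative QTLs and are
chained per chromosome by single linkage with a strict < 4 cM merge rule.
The summary table reports, per QTL and trait, the signed homozygous
difference ($2\bar\beta$) with the largest absolute value among the QTL's
qualifying markers, a blank cell when the QTL was not detected for a trait,
and the peak marker chosen by the reference trait's smallest mean adjusted
p. When several traits are tabulated together, intervals are consolidated
from the pooled qualifying markers so that one interval set aligns all
traits (an interval-overlap heuristic; peak markers can differ per trait).

## Numerical choices

* OLS throughout the scan; rank deficiency is detected via pivoted QR and
  the affected coefficient dropped with a warning.
* Monomorphic markers are flagged untested rather than erroring the scan;
  identical marker columns receive identical statistics independently.
* Negative variance estimates are clamped to zero before the heritability
  formula.
* A single base seed fans out to per-stage and per-run child seeds by an
  affine counter scheme modulo $2^{31} - 1$ (`derive_seed`); identical
  configuration and seed reproduce every output file byte for byte (no
  timestamps are written).
* Cofactor-selection ties (identical SBC gain) break deterministically by
  map position then marker id.

## What the simulator does and does not establish

The generator reproduces dosage coding, family structure,
family-monomorphic markers, Haldane linkage, BC1S3 genotype frequencies,
additive (optionally family-specific) QTLs and the two-way
genotype-by-year phenotype decomposition. It does not model dominance,
epistasis, selection during line development, genotyping error, shared
donor haplotypes between families, or spatial field trends. A green test
therefore establishes correctness of the statistical machinery on data
satisfying the model's own assumptions — not robustness to the ways real
field data violate them.

## Known limitations and measured behaviour

Two properties of the faithful procedure are worth stating plainly, both
measured with this package (seeds fixed, details in the test suite):

1. **Post-selection inflation.** Because cofactors are selected on the
   same data that is scanned, the scan is anti-conservative under the
   global null: with 300 markers and $n = 500$ the measured family-wise
   error rate per run is about 22% rather than the nominal 5% (2% for the
   same scan without cofactor selection). Forward selection finds chance
   suppressor pairs, and a selected cofactor tested with its partner
   retained can reach Holm significance. Since subsample runs share 80% of
   the lines, such signals recur across runs and can clear the 10%
   detection threshold, producing occasional false consolidated QTLs in
   null genomes.
2. **Proxy shrinkage on sparse maps.** A chance-selected cofactor tightly
   correlated with a true QTL but outside the 1-cM exclusion window
   shrinks the causal effect estimate (about 10% in a measured case at
   7.9 cM marker spacing). The exclusion rule presupposes the dense maps
   of the original protocol.

Both are properties of the published procedure, not implementation
artifacts: scan estimates match `lm()` exactly and selection matches a
brute-force SBC oracle exactly.
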