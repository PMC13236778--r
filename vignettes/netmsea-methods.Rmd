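---
title: "Methods: marker-set enrichment, key-driver analysis and the synthetic validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-set enrichment, key-driver analysis and the synthetic validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmsea)
```

## Scope and model

netmsea implements an integration chain for GWAS summary statistics:
LD pruning, eQTL-guided marker-to-gene mapping per tissue, marker-set
enrichment analysis (MSEA) with cross-cohort meta-analysis, redundancy
merging of significant gene sets into supersets, key-driver analysis (KDA)
on gene regulatory and protein–protein interaction networks, two
drug-signature repositioning filters, an EMR pre/post biomarker screen, and
a strain-panel cross-check of key-driver genes. Co-expression modules and
regulatory networks are *consumed* as gene sets and edge lists; building
them (WGCNA, Bayesian network learning) is out of scope, as is any
acquisition of real GWAS, eQTL, network, drug-signature or EMR data.

## LD pruning and marker-to-gene mapping

Markers are pruned greedily in ascending GWAS p-value order (ties broken by
marker id): a marker is removed when its LD with an already-retained marker
exceeds r² = 0.7, strictly. The convention of keeping the *most significant*
marker of an LD-redundant group is a design choice: the threshold rule only
says redundant markers in LD with a chosen marker are removed, and retaining
the strongest association is the standard, information-preserving resolution.
The result is audited, not assumed: tests check against a brute-force oracle
that no retained pair exceeds the threshold and that every removed marker
conflicts with a retained one (maximality), and that pruning is idempotent.

Mapping joins retained markers to one tissue's eQTL records. Markers without
any eQTL gene in a tissue are excluded from that tissue's marker universe, so
MSEA expectations are computed over mappable markers only — including
unmappable markers would deflate every expected count and inflate the
statistic.

## The MSEA statistic and its null

Scores are s = −log10(p). For quantiles Q = {0.50, 0.75, 0.90, 0.95, 0.99}
of the universe score distribution (type-7 sample quantiles), the statistic
is

$$X = \sum_{q \in Q} \frac{O_q - E_q}{\sqrt{E_q + \kappa}},
\qquad E_q = n_{\text{member}} (1 - q), \; \kappa = 1.$$

Markers are counted once even when mapped through several member genes;
double-counting would reward marker sharing rather than association
strength. The exact quantile vector, κ and the permutation count are exposed
in `msea_config()` and echoed with every run; the defaults above are the
package's declared operating point. X is invariant to monotone rescaling of
scores (only ranks relative to the thresholds matter) and each term
decreases strictly as a below-threshold member is added, both of which are
tested.

The null permutes *set membership over mappable genes*, keeping each gene's
marker list intact. This preserves the markers-per-gene structure: permuting
marker p-values instead would break the correlation between a gene's marker
count and its chance of carrying an extreme score, producing an
anti-conservative null. The permutation moments give
z = (X − mean X_b)/sd X_b and an upper-tail Gaussian p — needed to resolve
p ≪ 1/B for strongly enriched sets — while the empirical permutation p is
reported alongside (`p_emp`) as a diagnostic. A degenerate null (zero
permutation variance) yields p = 1 with a warning. FDR is Benjamini–Hochberg
within each (tissue, cohort) run; a set is called significant when it passes
FDR < 5% in at least one mapping set. Sets with fewer than 10 or more than
500 mapped genes are excluded, the usual enrichment-practice bounds, both
configurable.

Cohorts are combined per set by the unweighted Stouffer sum
z_meta = Σ z_c/√C. Whether the original analyses weighted cohorts by sample
size is not stated anywhere we could verify, so the unweighted form was
chosen and flagged; with two cohorts of broadly comparable information
content the difference is second-order. Confirmation of merged supersets on
the combined cohorts is implemented as this same meta-analysis run on the
superset catalog.

## Superset merging

Significant sets are agglomerated iteratively: all current pairs are scored
by overlap ratio ρ(A,B) = |A∩B|/min(|A|,|B|) and a one-sided Fisher
(hypergeometric upper-tail) test over the gene universe; a pair qualifies at
ρ ≥ 0.33 and p below 0.05/(pairs tested this iteration); the highest-ρ
qualifying pair merges (ties broken by lexicographically smallest id pair),
and scores are recomputed until no pair qualifies. The thresholds are a
reconstruction — the merging procedure we mirror is specified only at the
level of "merge overlapping sets" — so both are config-exposed. Each merge
reduces the set count by one, so termination is immediate; the tests
additionally audit that no qualifying pair remains, that the gene union is
conserved, and — by exhaustively enumerating all merge orders on small
instances — that the final partition does not depend on merge order.

## KDA

Candidates are nodes with degree ≥ 3 (leaves excluded, configurable). The
neighborhood is all nodes within K = 1 hops, direction ignored even for
regulatory networks (a `respect_direction` flag exists, default off):
depth and directed handling are unstated in the source analyses, and hub
detection by local connectivity is the established default. The statistic is
X = (O − E)/√(E + κ) with E = |N(v)|·|S∩V|/|V|. The null relabels superset
membership uniformly over nodes; under this null the overlap is exactly
hypergeometric, so the implementation draws the Monte-Carlo null directly
from that distribution — the tests verify the empirical p against the exact
hypergeometric tail on small graphs. Degree-preserving rewiring would be the
stricter alternative null but is deliberately out of scope. FDR is computed
across candidates within each superset; key drivers pass FDR < 5%, and the
top five per (superset, tissue, network) are reported, ordered by p, then
descending X, then node id. Key drivers are not required to be outside the
superset; no such exclusion is applied.

Because the Gaussian tail is applied to a discrete null, candidates with
very small neighborhoods can receive anti-conservative p-values; the
empirical `p_emp` column is the conservative companion. Hub calls in
practice rest on neighborhoods large enough that the distinction is
immaterial, and the planted-hub recovery tests exercise exactly that regime.

## Drug filters

The connectivity-map style filter keeps (drug, tissue-group) records with
|median tau| ≥ 90 and scores each drug by the *mean of absolute* median tau
over its retained groups. "Absolute mean" is ambiguous between
mean-of-absolutes and absolute-of-mean; both are implemented
(`aggregate = "mean_abs"` default, `"abs_mean"` alternative) and the default
is the variant that cannot cancel opposite-signed matches — appropriate
because drug directionality is deliberately not inferred. The recurrence
filter keeps, per tissue, drugs with p < 0.05 (strict) and rank ≤ 100, then
requires ≥ 5 surviving tissues. Both filters are row-order invariant and are
tested to recover exactly the planted true drugs on synthetic tables.

## EMR screen

Prescription rows collapse to one episode per (patient, drug) from earliest
start to latest end; episodes under 30 days are dropped (30 itself is kept).
Windows are encoded in days — 183, 365, 730 for 6 months, 1 and 2 years —
rather than calendar months, for determinism. The pre window is
[start − w, start) and the post window (end, end + w]: half-open at the
treatment boundaries, so a measurement on the start date belongs to neither
window (boundary inclusion is unstated in the source design; the half-open
convention is declared here and tested). The post window anchors at
treatment cessation. Patients lacking a measurement in either window are
excluded per window — per-window cohorts may differ, a choice made because
requiring all three windows would discard most of a sparse lab record. The
test is a one-sided paired t test on post − pre means with the two-sided 95%
CI reported alongside; drugs with fewer than five paired patients are marked
untestable, never flagged. Zero-variance differences get p = 0, 1 or 0.5 by
the sign of the mean, with a warning.

## Strain validation

The NOD-vs-B6 contrast uses the classic equal-variance Student t test
(Welch available by flag), two-sided, with direction reported separately —
the source wording names Student's test but not sidedness, and reporting
direction separately keeps the two questions apart. Sexes are stratified by
default with a pooling flag, since per-panel pooling practice is unstated.
DEG cross-referencing is an exact, case-folded symbol intersection — no
orthology mapping, matching how human symbols are conventionally compared
against title-case mouse symbols.

## The synthetic-data module

The generators define the package's study conditions; they are first-class,
tested code, not fixtures. Defaults: 3000 markers in 1000 LD blocks
(within-block r² = 0.9, so pruning keeps one marker per block — the pipeline
only consumes thresholded r², so block-constant LD suffices and a decay
model would add nothing it could observe); 600 genes, each receiving 1–6
markers per tissue from a tissue-specific 70% marker pool (tissues overlap
partially); 50 gene sets of 20–40 genes with one causal set; association
z-scores Normal(effect_mu, 1) on markers mapped to causal-set genes,
Normal(0, 1) elsewhere, converted to two-sided p-values — Gaussian z-scores
match standard GWAS summary-statistic behavior and give analytic control of
the effect size; two cohorts sharing the same causal sets with independent
noise. These sizes were chosen so that a typical set retains enough mapped
genes after pruning to pass the [10, 500] size filter and each run completes
in seconds; a whole-genome-scale simulation would test nothing additional
about the statistics. Networks are preferential-attachment graphs
(500 nodes, m = 2) with one hub per causal set planted by relabeling ≥ 80%
of the hub's neighbors to member genes, an audit enforced at generation.
Drug tables plant true drugs passing both filters (|tau| ≥ 90 in all five
tau groups; p < 0.05 and top-100 rank in five of seven tissues) and decoys
passing neither. EMR cohorts give every exposure three pre and three post
C-peptide values around a patient-specific baseline (0.5 ± 0.15 nmol/l,
measurement sd 0.15), with responder drugs shifting the post window by
0.3 nmol/l by default. The strain panel plants a two-standard-deviation
NOD-only upshift on designated key-driver genes.

What the generators deliberately do *not* emulate: realistic human LD decay
and allele frequencies, genotype-level data, polygenic background
correlation between gene sets, confounding in EMR records (indication bias,
concurrent medication), and batch structure in expression panels. Passing
tests therefore demonstrate that the chain's statistics are calibrated and
its filters exact under their own stated models — not that the pipeline is
robust to the epidemiological biases of real observational data.

## Numerical choices

Quantile thresholds use R's type-7 sample quantiles. Overlap-enrichment and
merging Fisher p-values are computed in the log domain (`phyper(log.p =
TRUE)`) so values near 1e-116 neither underflow nor lose leading digits.
Gaussian-tail p-values below the double floor are reported as 0; rankings
use z, which never ties at the floor. All randomness flows from explicit
seeds (`withr::with_seed`) with fixed per-generator offsets, so every
generator and both analysis nulls are byte-reproducible; the pipeline writes
an md5 manifest and two runs with one seed produce identical files. Ties are
broken lexicographically everywhere a sort order matters.

## Problem sizes used in the checks

The test-suite and acceptance script operate at desk scale: the null
calibration run uses 500 gene sets at 1000 permutations; ranking power and
hub recovery use 30–50 seeded replicates at 400–500 permutations; the EMR
size check uses 200 null drug screens and the power check 30–50 replicates
at 30 exposed patients; end-to-end determinism uses a reduced configuration
(600 markers, 150 genes, two tissues). These sizes are the package's own
choice of validation design: large enough for the Monte-Carlo error bands
quoted in the tests, small enough that the entire validation runs in
minutes.

## Known limitations

FDR is controlled within each (tissue, cohort) MSEA run and within each
(superset, network) KDA run, matching the per-analysis control of the
staged design; no pipeline-wide FDR is attempted. The Gaussian tail on
permutation z-scores assumes approximate normality of the null statistic,
which holds for the multi-quantile sum but degrades for tiny neighborhoods
in KDA (see above). The headline discovery counts of a real multi-cohort
analysis (hundreds of significant pathways, hundreds of key drivers,
specific gene names) depend on restricted GWAS, eQTL and network resources
and are not reproducible from synthetic data; what the package validates is
the machinery: exact overlap enrichments, calibrated type-I error, high
recovery of planted truth, and deterministic orchestration.
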