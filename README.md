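# netmsea

**netmsea** is a tidyverse-native R implementation of a multi-tissue,
multi-omics integration chain for complex-disease genetics, of the kind used
to dissect type 1 diabetes: GWAS summary statistics are combined with
tissue-specific eQTLs, curated gene-set catalogs and gene networks to find
disease-associated pathways, merge them into non-redundant supersets, pinpoint
key-driver (KD) genes whose network neighborhoods concentrate disease signal,
filter drug-signature tables for repositioning candidates, and finally screen
those candidates in EMR-style records for a pre-to-post rise in C-peptide, a
biomarker of residual beta cell function.

It is written for statistical geneticists and systems-biology analysts who
want each stage as a composable, testable function operating on plain tibbles,
plus a synthetic-data module that generates every input with planted ground
truth so the whole chain runs and validates with no external data.

## The statistics at the core

**Marker-set enrichment analysis (MSEA).** For a gene set, let the member
markers be the LD-pruned GWAS markers mapped to its genes through a tissue's
eQTLs, scored by s = −log10(p). For each quantile q in Q (default
{0.50, 0.75, 0.90, 0.95, 0.99}) of the mappable-marker score distribution,
with O_q the observed member-marker count at or above that quantile and
E_q = n·(1−q) its expectation,

    X = Σ_q (O_q − E_q) / √(E_q + κ),     κ = 1.

The null is built by permuting set membership over mappable genes (each gene
keeps its marker list), giving z = (X − mean X_b)/sd X_b and an upper-tail
Gaussian p, with Benjamini–Hochberg FDR per (tissue, cohort) run. Cohorts are
combined per set by unweighted Stouffer meta-analysis,
z_meta = Σ_c z_c / √C.

**Key-driver analysis (KDA).** For a network node with neighborhood N(v) and
a gene superset S, X = (O − E)/√(E + κ) with O = |N(v) ∩ S| and
E = |N(v)|·|S|/|V|; the null relabels superset membership uniformly over
nodes. Nodes at FDR < 5% are key drivers; the top five per (superset, tissue,
network) are reported.

Supporting stages: greedy LD pruning at r² > 0.7 (keeping the most
significant marker); superset merging of overlapping significant sets
(overlap ratio ≥ 0.33 plus a Bonferroni-corrected one-sided Fisher test,
merged highest-ratio-first to a fixed point); drug filters (|median tau| ≥ 90
for connectivity-map style tables; p < 0.05, rank ≤ 100, and ≥ 5 tissue
appearances for recurrence-style tables); and a one-sided paired t test on
pre/post window means of C-peptide (≥ 30-day exposures, 6-month/1-year/2-year
windows, ≥ 5 patients per drug).

## Worked example

```r
library(netmsea)

# cross-cohort reproducibility of significant pathways: 1827 tested,
# 187 and 143 significant per cohort, 121 shared
overlap_enrichment(1827, 187, 143, 121)
#>   universe_n  n1  n2 k_overlap expected  fold   fisher_p log10_fisher_p
#> 1       1827 187 143       121    14.64 8.267 5.836e-116         -115.2
```

The observed overlap is 8.27-fold its expectation under independence, with a
hypergeometric upper-tail p of 5.8e-116 — the two cohorts find essentially
the same pathways. Running the whole chain on synthetic data with planted
truth:

```r
cfg <- sim_config(seed = 42)   # one causal set, 3 true drugs, 1 responder
run_pipeline(cfg, "demo_run",
             msea_cfg = msea_config(n_perm = 500, seed = 42),
             kda_cfg = kda_config(n_perm = 500, seed = 42))
pipeline_report("demo_run")
#> Pipeline run (seed 42)
#> # A tibble: 9 × 2
#>   metric                value
#>   <chr>                 <int>
#> 1 stages_completed          9
#> 2 tissues                   3
#> 3 cohorts                   2
#> 4 significant_sets_meta     3
#> 5 supersets                 3
#> 6 top_key_drivers          58
#> 7 lincs_candidates          3
#> 8 pharmomics_candidates     3
#> 9 emr_flagged_drugs         1
#>
#> Cohort overlap: 2 / expected 0.08 -> fold 25.00 (p = 0.000816)
#>
#> Recovered planted truth:
#> # A tibble: 3 × 3
#>   check                   planted recovered
#>   <chr>                     <int>     <int>
#> 1 causal_sets_significant       1         1
#> 2 true_drugs_recovered          3         3
#> 3 responder_drugs_flagged       1         1
```

All nine stages complete; the planted causal gene set is significant in the
cross-cohort meta-analysis, both drug filters recover exactly the three
planted true drugs, and the EMR screen flags the one planted responder drug.
Result tables are tibbles; `autoplot()` methods draw the enrichment chart,
key-driver lollipops and the EMR forest plot, and `glance()` summarizes each
result type.

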