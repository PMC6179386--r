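# coabnet

Condition-specific co-abundance networks and network-proximity drug-target
prioritization.

## What it does, and for whom

Literature-curated protein–protein interaction (PPI) networks are
context-free: they pool every interaction ever reported, in any tissue and
state. Time-course proteomics of one cellular state — the motivating case
is macrophages driven toward pro- or anti-inflammatory programs — carries
the complementary signal: proteins whose abundance profiles move together
over time are likely to act together *in that state*. `coabnet` is for
systems biologists who want to fold that condition-specific signal into
network-based target discovery and to quantify, against proper null
models, how much it helps.

The pipeline:

1. **Co-abundance networks.** From per-condition abundance ratios
   (optionally aggregated from PSM-level tables by time-zero normalization
   and per-protein medians, proteins with > 10 PSMs), pairwise Pearson
   correlations (biweight midcorrelation and baseline-controlled partial
   correlation as alternatives) are tested by profile permutation:
   P\* = r\_> / N over N = 300 shuffles of the time order, BH-adjusted to
   Q\*. Edges: r ≥ 0.90 and Q\* ≤ 0.01, the highest threshold that
   maintains network density in a sensitivity scan.
2. **Integration.** Co-abundance edges are superimposed on the (optionally
   de-noised) PPI backbone with class-specific traversal weights, so the
   shortest-path cost is d\*\_cs = Σ w_C·n_C + Σ w_P·n_P; the weight ratio
   w_C/w_P is tuned by 7-fold cross-validated AUROC.
3. **Prioritization.** Every protein is ranked by proximity to seed drug
   targets: PS(c) = Σ_s I(s)/(d\*\_cs + 1), kernel distance
   dk(c) = −ln[Σ_s e^{−(d\*\_cs+1)}/|S|], random walk with restart, or its
   degree-aware ratio correction.
4. **Evaluation.** Paired-t comparison of fold AUROCs between PPI and
   PPI+CoA, and an empirical test against degree-preserving random-edge
   controls (logarithmic degree bins).
5. **Selection.** Youden-cutoff on the CV ROC, triple evidence filter
   (network rank ∩ top-500 baseline-relative abundance ∩ top-500
   expression fold change, seeds removed), combined rank
   R_comb = (N_prior + N_abun + N_expr)/3, and candidate-to-target distance
   statistics (z, empirical p) under a degree-matched node null.
6. **Enrichment.** Fisher edge-overlap validation against reference edge
   sets, a rank-permutation cutoff for the "top prioritized" set,
   hypergeometric gene-set enrichment with BH control, and a Jaccard
   pathway network.

A synthetic-data module (`simulate_scenario()`) generates a scale-free PPI
network, planted correlated modules in which a configurable fraction of
members are seed targets, PSM tables, fold changes and pathway
annotations, with full ground truth — every downstream claim is testable
without any external download.

## Worked example

```r
library(coabnet)

sc <- simulate_scenario(n_nodes = 600, mean_degree = 8, n_seeds = 60,
                        module_sizes = c(25, 25),
                        conditions = c("M0", "MIFNg"), rng_seed = 7)
corr <- permutation_significance(sc$abundance$MIFNg, n_perm = 300, rng_seed = 8)
coa  <- build_coabundance_network(corr, r_threshold = 0.90, q_max = 0.01)
ppi  <- extract_lcc(sc$network)
net  <- combine_networks(ppi, coa, w_ppi = 1, w_coa = 0.4)

ev <- compare_networks_cv(ppi, net, sc$seeds, k = 7, rng_seed = 9)
glance(ev)
#> # A tibble: 1 × 7
#>   mean_auroc_ppi mean_auroc_ppi_plus_coa auroc_gain t_stat    df p_value
#>            <dbl>                   <dbl>      <dbl>  <dbl> <dbl>   <dbl>
#> 1          0.707                   0.824      0.117   3.80     6 0.00899

ctrl <- random_edge_control(ppi, coa, sc$seeds, n_real = 20,
                            rng_seed = 10, w_coa = 0.4)
glance(ctrl)
#> # A tibble: 1 × 6
#>   auroc_coa auroc_ppi mean_auroc_random sd_auroc_random p_emp n_real
#>       <dbl>     <dbl>             <dbl>           <dbl> <dbl>  <int>
#> 1     0.825     0.693             0.566          0.0255     0     20

head(proximity_score(net, sc$seeds), 5)
#> # A tibble: 5 × 4
#>   protein score  rank percentile
#>   <chr>   <dbl> <int>      <dbl>
#> 1 P0006    29.6     1      100
#> 2 P0109    29.6     2       99.8
#> 3 P0014    29.0     3       99.7
#> 4 P0024    29.0     4       99.5
#> 5 P0018    28.9     5       99.3
```

Reading the numbers: held-out seed targets are recovered with mean AUROC
0.824 on the PPI network enriched with 604 co-abundance edges versus 0.707
on the PPI alone (paired t over the same 7 folds, p = 0.009), and the gain
is specific to the measured co-abundance structure — the same number of
degree-preserving random edges reaches only 0.566 ± 0.026 (empirical
p = 0 over 20 realizations). The ranking lists every protein with its
proximity score, deterministic rank and percentile.

The whole pipeline — abundance aggregation through pathway networks, with
a provenance manifest and per-stage seeds — runs from one call:

```r
run_pipeline(coab_config(rng_seed = 1), out_dir = "run", simulate = TRUE)
```

`autoplot()` methods cover the ROC curves (`coab_evaluation`), the density
sensitivity scan, the weight-ratio scan and the candidate-target
path-length histograms; `tidy()`/`glance()` methods give tibble views of
correlation results, evaluations and proximity statistics.

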