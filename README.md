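# splicemod

Tumors do not deregulate alternative splicing one event at a time:
groups of splicing events shift together, and those co-perturbed
groups — *splicing modules* — carry prognostic and functional signal
that per-event tests miss. `splicemod` implements a network-based
module-discovery pipeline for percent-spliced-in (PSI) data from
tumor/normal cohorts (e.g. TCGA-style exon-level splicing tables), for
computational biologists who want module-level rather than event-level
splicing analysis.

## What it computes

Starting from an event × sample PSI matrix (values in [0, 1], six
splice classes ES/RI/AD/AA/ME/AT) with tumor/normal labels:

1. **Filtering & imputation** — events missing in >10% of normals or
   >1% of tumors are dropped, tumor samples with >0.1% missing data
   are removed, and remaining gaps are filled by k-nearest-neighbor
   imputation over events (k = 10).
2. **Differential splicing** — per-event Wilcoxon rank test (exact for
   small samples, tie-corrected normal approximation otherwise), kept
   when Benjamini–Hochberg FDR < 0.1 and |ΔPSI| > 0.1, where
   ΔPSI = mean(tumor) − mean(normal).
3. **Network reconstruction** — Pearson correlations between
   differential events over tumor samples become edge weights of an
   undirected graph (|r| by default, so anticorrelated splicing
   switches stay connected).
4. **Module identification** — Pons–Latapy walktrap: vertices are
   compared by their t-step random-walk profiles (t = 4),
   r²(C₁,C₂) = Σₖ (P^t_{C₁k} − P^t_{C₂k})²/d(k), and communities are
   agglomerated greedily by the smallest
   Δσ = (1/n)·|C₁||C₂|/(|C₁|+|C₂|)·r². The merge tree is cut at the
   level maximizing weighted modularity
   Q = Σ_c (e_c/m − (d_c/2m)²), and modules are named M1, M2, …
   by decreasing event count.
5. **Module scoring** — for every tumor sample, the signed deviation
   of each module event from the normal reference is averaged:
   score(s) = mean_e (PSI_{e,s} − ref_e). Positive scores mean the
   module is spliced in above the normal baseline.
6. **Prognosis** — samples are split at the median module score;
   overall survival (OS) and progression-free interval (PFI) are
   compared by Kaplan–Meier curves and the log-rank test, with hazard
   ratios from a Cox model (Breslow ties). Modules with P ≤ 0.05 for
   either endpoint (plus near-significant OS candidates,
   0.05 < P < 0.1) are retained.

On top of that: Fisher's-exact (hypergeometric) gene-set enrichment of
module genes against the spliced-gene background, and pan-cancer
summaries — per-type "+"/"−" calls when ≥80% of samples score above
or below normal, commonality flags when one sign holds in ≥15/16
cancer types, and hierarchical clustering of cancer types by their
module-score profiles.

A synthetic-cohort generator (`generate_cohort()`,
`generate_multitype()`) plants correlated event modules, tumor PSI
shifts, missingness, and score-linked exponential survival, so the
entire pipeline is exercisable and testable without any external
download.

## Worked example

```r
library(splicemod)

cfg <- synthetic_config(seed = 42, n_events = 800, n_tumor = 200,
                        n_normal = 20, loading_strength = 1.5, delta = 2,
                        beta = c(3, 0, 0), missing_rate = 0)
sim <- generate_cohort(cfg)           # 3 planted modules of 60 events
run <- run_pipeline(sim$psi, sim$clinical)
run$manifest
#>   stage              n
#> 1 filter_impute    800
#> 2 differential     176
#> 3 network_edges  15400
#> 4 modules            3
#> 5 scored_samples   200
#> 6 survival_tests     6
run$modules
#> <module_set> 3 modules over 176 events (Q = 0.5210)
#>   module genes events  AA  AD  AT  ES  ME  RI
#> 1 M1         54     60   8   6  13  17   0  16
#> 2 M2         53     59   5   1  16  19   0  18
#> 3 M3         51     57   3   1  20  15   0  18
retain_prognostic(run$survival)
#>   module      os_p       pfi_p reason retained
#> 1 M1     0.0000560 0.000000460 both   TRUE
#> 2 M2     0.392     0.611       <NA>   FALSE
#> 3 M3     0.475     0.753       <NA>   FALSE
```

The three detected modules recover the three planted ones exactly
(adjusted Rand index 1.0); M1, whose true score was linked to the
hazard (β = 3), is the only retained module, with OS hazard ratio 2.06
(95% CI 1.44–2.94) for high- versus low-score samples — high scores
on this module roughly double the death hazard, and the module is
significant for both endpoints (`reason = "both"`).

The package also ships two reference tables
(`tcga_module_census()`, `tcga_module_prognosis()`): the 51-module
census across 16 TCGA cancer types and the per-module OS/PFI summary,
used to exercise the accounting and retention logic on published
numbers (10 OS-significant, 8 PFI-significant, 5 in both, 15
retained).

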