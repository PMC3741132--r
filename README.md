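# ocmann

Case-control analysis of one-carbon (folate) metabolism variables —
genotypes of nine biallelic polymorphisms (*MTHFR* 677C>T and 1298A>C,
*TYMS* 28-bp repeat and 1494 6-bp ins/del, *MTRR* 66A>G, *MTR* 2756A>G,
*RFC1* 80G>A, *DNMT3B* -149C>T and -579G>T) plus serum folate, plasma
homocysteine and serum vitamin B12 — in Alzheimer's disease (AD) patients
versus matched controls. The package is aimed at genetic-epidemiology
groups who want the whole pipeline reproducible end to end: coding,
classifier validation, evolutionary variable selection, and an
association map, driven either by a user cohort CSV or by a synthetic
cohort generator parameterized from published group summaries.

## What it computes

**Coding.** Each polymorphism becomes three indicator columns (wild
type / heterozygous / mutant; 1 if the genotype class is present, 0 if
absent), giving 27 one-hot columns; the three biomarkers are min-max
scaled to [0, 1] over the pooled cohort. The supervised input is the
resulting 30-column matrix. For association mapping, each scaled
biomarker `x` additionally gets its complement `1 - x` (so "low folate"
is its own node) and the AD/control class enters as two one-hot columns:
35 columns in total.

**Validation protocols.** Per-class accuracy, arithmetic mean, weighted
mean `W = 100·(1 - errors/N)` and raw error count, under stratified
10-fold cross-validation, a stratified random split, or the two-subset
protocol (train A → test B and train B → test A, errors summed over both
testing phases).

**Evolutionary selection (TWIST-style).** A genetic algorithm over
genomes `[variable mask | record bipartition]` maximizing the blind
two-way accuracy of a k-nearest-neighbour classifier (Euclidean metric,
k = 1) restricted to the masked variables, minus small penalties for mask
size and for distributional divergence between the two subsets — jointly
finding a minimal informative variable set and two statistically
equivalent record subsets.

**Semantic connectivity map (Auto-CM + MST).** An Auto-Contractive Map
is trained on the 35-column matrix; its converged second-layer weights
`w_ij` measure association strength. Distances `d_ij = C - (w_ij +
w_ji)/2` are filtered by a Kruskal minimum spanning tree; each kept edge
carries a link strength `ls ∈ [0, 1]` (symmetrized weight over the global
maximum), and nodes of maximal tree degree are the map's hubs.

**Synthetic cohorts.** Genotypes are drawn from published per-group
frequencies; biomarkers from a lognormal moment-matched to the published
mean and the standard deviation implied by the 95% CI half-width at
n = 40 (`sd = hw·√n/1.96`); optional rank correlations (e.g.
folate↔homocysteine −0.5) enter through a Gaussian copula.

## Worked example

```r
library(ocmann)

cohort <- generate_cohort(n_per_group = 40, seed = 1,
                          coupling = coupling_preset_literature())
x <- assemble_classification_matrix(cohort)
labels <- attr(x, "class_labels")

kfold_protocol(x, labels, knn_classifier()$fit_predict, K = 10, seed = 1)
#> protocol: kfold | Control 50.00%  Alzheimer 45.00%  A.Mean 47.50%  W.Mean 47.50%  Error 42/80

evo <- twist_evolve(unclass(x), labels, evolution_config(seed = 1))
sum(evo$best$variable_mask)
#> [1] 12
run_battery(list(knn_classifier()), "two_subset",
            unclass(x)[, evo$best$variable_mask], labels,
            assignment = evo$best$record_assignment)
#>   nickname control alzheimer a_mean w_mean error status
#> 1      IBk      85        95     90     90     8     ok

map <- build_map(train_autocm(unclass(assemble_autocm_matrix(cohort))))
map
#> semantic connectivity map: 35 nodes, 34 MST edges
#> hubs: folate_LOW
#>   folate_LOW -- vitamin_b12_LOW  ls=1.00
#>   MTR_A2756G_wild_type -- folate_LOW  ls=0.98
#>   homocysteine_LOW -- vitamin_b12_LOW  ls=0.96
#>   MTR_A2756G_wild_type -- RFC1_A80G_heterozygous  ls=0.90
#>   folate_LOW -- AD  ls=0.85
```

Reading the output: k-fold KNN on all 30 variables sits at chance on
this synthetic cohort (the generator plants only weak marginal group
differences), while the evolved 12-variable mask + bipartition reaches a
90% blind two-way weighted mean *on its own optimized split* — selection
bias is real and quantified in the methods vignette, so treat that
figure as an upper bound, not an unbiased estimate. In the map, the
coupled low-folate/low-B12 states bind most strongly (ls = 1.00) and
`folate_LOW`, the map's hub, connects to the AD node — the qualitative
pattern the coupling preset plants. All numbers above were printed by
this code at seed 1.

## Command line

```sh
inst/exec/ocm-ann simulate --n 40 --seed 1 --out cohort.csv
inst/exec/ocm-ann validate --cohort cohort.csv
inst/exec/ocm-ann run-study --seed 1 --out study_out/
```

`run-study` writes the full report bundle: k-fold and random-split
battery tables on all 30 variables, the selection report, k-fold and
two-subset tables on the selected variables, the connectivity map
(CSV/GraphML/DOT) and a hash manifest.

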