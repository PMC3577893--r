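# otudelim

Species delimitation and identification from DNA barcodes by threshold
clustering, for symbiont/host systems where classical taxonomy runs dry.

## The problem

Fungal symbionts of fungus-farming termites (and many other microbial
and fungal groups) rarely form the fruiting bodies that formal species
descriptions require.  Diversity in such groups is therefore estimated
from barcode sequences — ITS rDNA for the fungi, mitochondrial COII for
the insect hosts — by grouping sequences into molecular operational
taxonomic units (OTUs) that approximate species.  Two choices dominate
the outcome: the dissimilarity threshold *t* and the clustering
criterion.  `otudelim` treats both as parameters of an estimator and
fits them against a reference partition, instead of adopting a fixed
conventional cutoff.

## The estimator

**F-linkage clustering.** Two sequences are *linked* when their
uncorrected p-distance satisfies d ≤ t.  Starting from singletons, a
cluster pair (A, B) is merged when the linked fraction of its cross
pairs, f = |{(i, j) ∈ A × B : d(i, j) ≤ t}| / (|A|·|B|), satisfies
f ≥ F (and f > 0).  F = 0 is single linkage (connected components of
the link graph), F = 1 is complete linkage (every within-cluster pair
linked), intermediate F interpolates the cluster shape.  The greedy
agglomeration order (largest f; ties by smaller maximal, then mean,
cross-distance, then lexicographic ids) is deterministic.

**Fitting.** `fit_thresholds(d, reference)` scans a grid of (F, t),
scores every clustering against a — possibly only partially labelled —
reference partition with a pair-counting agreement index (default the
modified Rand index, MRI = 2·Rand − 1, maximum 1.0 exactly at
agreement), and reports per F the maximal agreement and the optimal
threshold range with its median.  Unlabelled elements are ignored, so
sparse database annotations impose no penalty.

**Reference from phenotype, when labels are missing.** Where database
annotation is too sparse to fit against, a species reference is
estimated from cultured isolates: a maximum-parsimony tree is inferred
from combined DNA + coded phenotype characters (exact branch-and-bound
search), and every branch on which culture macromorphology or
physiology contributes more changes (DELTRAN branch lengths) or more
partitioned Bremer support than the DNA marker is interpreted as
*within-species* diversification — phenotype drifts faster than the
marker below the species level.  Contracting the marked and zero-length
branches partitions the leaves into species
(`annotate_tree()` → `mark_within_species()` → `species_partition()`).

**Downstream.** Queries are identified by cluster co-membership with
labelled references (`identify_queries()`, or `predict()` on a fit):
one label = identified, several = ambiguous, none = a putatively novel
taxon.  `coverage_series()` / `sensitivity_grid()` tabulate the
temporal accumulation of OTUs and host associations over deposition
years, across a parameter grid to expose threshold sensitivity.

## Worked example

```r
library(otudelim)

sim <- simulate_dataset(synth_config(n_species = 4, seqs_per_species = 4,
                                     label_fraction = 0.5, seed = 42))
d   <- p_distance_matrix(sim$msa)
fit <- fit_thresholds(d, sim$labels)
fit
#> Threshold-clustering fit (modified_rand agreement, 8 labelled of 16 elements)
#>
#>    F agreement  t_min  t_max t_median n_optimal
#>  0.0         1 0.0050 0.0495  0.02725        90
#>  0.5         1 0.0050 0.0530  0.02900        97
#>  1.0         1 0.0085 0.0580  0.03325       100
coef(fit)
#>     F=0   F=0.5     F=1
#> 0.02725 0.02900 0.03325
head(predict(fit, F = 0.5), 4)
#>     query cluster    labels     status
#> 1 SP01_04      C1 species01 identified
#> 2 SP02_01      C2 species02 identified
#> 3 SP02_02      C2 species02 identified
#> 4 SP02_03      C2 species02 identified
```

The generator plants a guaranteed divergence gap (within-species
p-distance ≤ 1%, between-species ≥ 5%); the fit finds agreement 1.0
over a threshold range spanning that gap for each cluster shape, with
median optima between 2.7% and 3.3% — read `coef(fit)` as "the
threshold to use at this F".  All eight unlabelled sequences are then
identified correctly from the eight labelled ones.  A full pipeline run
(simulation → distances → parsimony/boundaries → fitting →
identification → coverage) is available as `run_pipeline()` with a
plain list or YAML config.

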