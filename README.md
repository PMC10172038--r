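# fmmap — Functional Mapping Matrices for network embedding spaces

Molecular interaction networks can be embedded into low-dimensional vector
spaces, but the resulting gene coordinates are hard to interpret and two
embedding spaces (say, a cancer tissue and its healthy counterpart) cannot
be compared coordinate-by-coordinate. `fmmap` takes a function-centric view:
it embeds biological annotations (e.g. Gene Ontology Biological Process
terms) into a gene embedding space and summarises the space by the
**Functional Mapping Matrix (FMM)** — the matrix of pairwise cosine
distances between annotation vectors. FMMs are scale-normalised, so the
functional organisation of two condition-specific spaces can be compared
directly, annotation by annotation, to find the biological functions a
condition perturbs and the genes driving that perturbation.

The package is aimed at systems-biology researchers working with
protein–protein interaction (PPI) networks and ontology annotations, and at
anyone who wants a quantitative handle on "what does this region of an
embedding space mean, and how does it differ between conditions?".

## Method

For a network with adjacency matrix A, degree matrix D and volume
vol = Σᵢ dᵢ, the network is represented by its random-walk PPMI matrix

    X = max(0, log [ vol / (b·T) · Σ_{r=1..T} (D⁻¹A)ʳ D⁻¹ ]),    T = 10, b = 1,

which captures co-occurrence of genes within T steps of a random walk. X is
decomposed by non-negative matrix tri-factorization with an orthonormal
basis factor,

    min_{P,S,G ≥ 0} ‖X − P S Gᵀ‖²_F   s.t.  GᵀG = I,

solved by SVD-initialised multiplicative updates with relative-square-error
(RSE) stopping. Rows of P·S are the gene embedding vectors; columns of G are
the basis of the space. A binary annotation×gene matrix A is projected into
the space via the Moore–Penrose pseudoinverse, U = A·pinv(Gᵀ) (equal to A·G
when GᵀG = I), and the FMM is FMM[i,j] = cosine distance(uᵢ, uⱼ).

Comparing a control and a case space: the movement matrix
D = FMM_control − FMM_case (positive entries = pair moved closer in the
case space); pairs beyond the 5th/95th percentiles of the movement
distribution move significantly; the total movement of an annotation is the
Euclidean norm of its row of D; annotations ≥ 2 sd above the mean total
movement are *shifted*, ≤ 2 sd below are *stable*. Genes are scored by their
maximum absolute change of cosine distance to any shifted annotation, and
genes at or above the 95th score percentile are predicted as
condition-related.

Supporting machinery: Lin semantic similarity over an OBO ontology with
corpus-derived information content, k-medoids clustering of FMMs with
intra/inter-cluster similarity folds (to test whether a space is
functionally organised at all), hypergeometric enrichment with
Benjamini–Hochberg correction, and a planted-partition scenario generator
with known ground truth for validation.

## Worked example

```r
library(fmmap)

sc   <- synthetic_scenario(seed = 42)     # planted case/control pair
ctrl <- embedding_space(sc$control, sc$table, k = 15)
case <- embedding_space(sc$case,    sc$table, k = 15)

ic  <- information_content(sc$ontology, sc$table)
organization_report(ctrl$fmm, ic, sc$ontology, seed = 42)
#> fmm_organization_report: 5 clusters
#>   intra = 0.153, inter = 0.014, fold = 11.02
#>   Mann-Whitney p = 1.79e-54, Pearson r(distance, Lin) = -0.901

cmp <- compare_spaces(ctrl, case)
cmp$movement
#> fmm_movement_report: 60 annotations
#>   closer pairs: 89, apart pairs: 89
#>   total movement: mean 0.6273, sd 0.4145
#>   shifted: 6, stable: 0
cmp$movement$shifted
#> [1] "TOY:0001001" "TOY:0001002" "TOY:0001003" "TOY:0001004" "TOY:0001005"
#> [6] "TOY:0001023"
cmp$genes
#> fmm_gene_movement: 240 genes scored, 12 predicted (threshold 0.8538)
```

The control space is functionally organised: annotations that cluster
together on their FMM distances are 11 times more semantically similar
(Lin) than annotations that do not, with a strongly negative
distance–similarity correlation. Comparing the spaces recovers the planted
signal: the scenario perturbs module M1, whose five annotations are
`TOY:0001001`–`TOY:0001005` — all five are called shifted (plus one false
positive), and all 12 predicted genes belong to the perturbed module.

The same stages are scriptable: `Rscript inst/cli/fmm.R simulate --out d`,
then `ppmi`, `embed`, `fmm`, `choose-dim`, `organization`, `movement`,
`predict-genes`, `enrich` with a YAML config and/or `--key value` overrides.

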