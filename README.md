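# revtax

Reverse-taxonomy analysis of COI barcode surveys: MOTU delimitation,
between-site genetic similarity, richness extrapolation, and concordance
with morphology.

## The problem

Abyssal macrofaunal surveys (epibenthic-sledge sampling of polychaetes and
isopods from polymetallic-nodule license areas, for example) recover highly
diverse assemblages in which most species are undescribed and many occur as
singletons. *Reverse taxonomy* delimits units genetically first — clustering
mitochondrial COI sequences into molecular operational taxonomic units
(MOTUs) — and attaches morphological identities afterwards. `revtax`
implements that workflow end to end for two-region survey designs:

* **Sequence handling** — FASTA/newick/TSV ingestion, pseudogene screening
  by stop-codon translation (invertebrate mitochondrial code, any forward
  frame may be stop-free).
* **Distances** — global pairwise alignment (or MSA columns), identity with
  a minimum length-coverage rule, uncorrected *p*-distance, and the Kimura
  2-parameter distance
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`
  with `P`, `Q` the transition/transversion proportions; within- and
  between-group mean distances in percent.
* **MOTU delimitation** — greedy incremental clustering: sequences sorted by
  decreasing length, each assigned to the first representative with
  identity ≥ threshold (default 0.97) over ≥ 400 aligned bases, otherwise
  founding a new cluster.
* **Community structure** — unweighted UniFrac on midpoint-rooted
  neighbor-joining trees (fraction of branch length unique to one sample),
  cosine similarity of MOTU abundance vectors
  `S(a,b) = x_a · x_b / (|x_a||x_b|)`, non-metric multidimensional scaling
  (Kruskal stress-1), one-way ANOSIM `R = (r̄_B - r̄_W) / (n(n-1)/4)`, and
  Mantel permutation tests (Pearson *r*, 5000 permutations by default).
* **Richness** — Chao1, Chao2 and first-order jackknife extrapolation with
  percent registration (`100 · S_obs / estimate`).
* **Concordance** — one-to-one matching of genotypic clusters against
  morpho-species labels, with verdicts (concordant / split / lumped),
  adjusted Rand index, and threshold sweeps (0.97 → 0.90 → 0.80).
* **Synthetic data** — a K80 sequence simulator that generates two-region,
  singleton-heavy surveys with distance-decaying station occupancy and full
  ground truth, so every stage is testable without downloading data.

## Worked example

```r
library(revtax)

sim   <- simulate_dataset(sim_config(seed = 42))     # 146 COI-like sequences
motus <- greedy_cluster(sim$records,
                        cluster_config(threshold = 0.97, min_overlap = 400),
                        aligned = TRUE)
motus
#> MOTU table: 79 clusters over 146 sequences (threshold 0.97, min overlap 400)
#>  singletons: 46

am <- setNames(sim$stations$license_area, sim$stations$station_id)
sm <- setNames(sim$records$station_id, sim$records$id)
summarize_motus(motus, sm, am)[c("shared", "exclusive")]
#> shared: 5    german-only: 55    french-only: 19

cm  <- build_abundance_matrix(motus, sm)
cos <- cosine_similarity_matrix(cm[rowSums(cm) > 0, ])
geo <- geographic_distance_matrix(sim$stations)[rownames(cos), rownames(cos)]
mantel(cos, geo, n_permutations = 5000, seed = 1)
#> Mantel (Pearson r): statistic = -0.4219, p = 0.0004 (5000 permutations, seed 1)

chao1(colSums(cm))
#> Chao1: S_obs = 79, estimate = 137.8 +/- 23.5 (%registration 57.3)
```

79 of the generator's 260-MOTU pool were observed (58% as singletons); MOTU
composition grows more dissimilar with distance (negative Mantel *r*
between cosine similarity and geographic distance, permutation *p* <
0.001); Chao1 extrapolates roughly twice the observed richness, i.e. the
survey registered about half of the estimable species pool — the typical
regime for sledge samples of abyssal macrofauna.

The full analysis (screen → cluster → tree → UniFrac → ordination → tests →
richness → concordance) is one call:

```r
res <- run_pipeline(sim$records, sim$stations,
                    pipeline_config(aligned = TRUE, seed = 1))
write_results_bundle(res, "results_dir")
```

or, from a shell, `Rscript scripts/run_pipeline.R run --fasta seqs.fasta
--metadata meta.tsv --stations stations.tsv --out results_dir`
(`scripts/run_pipeline.R simulate --preset paper-like --seed 1 --out d`
emits a synthetic two-taxon study).

## Vignette

`vignettes/reverse-taxonomy-pipeline.Rmd` documents the models, the
generator's design and calibration, numerical conventions, and known
limitations.
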