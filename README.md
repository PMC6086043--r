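# mirem

Prioritizing miRNAs from gene sets by hypergeometric filtering and
expectation-maximization.

## What it does, and for whom

Given a list of differentially expressed genes and one or more
miRNA-target prediction databases, `mirem` ranks the miRNAs most likely
to drive the expression signature.  It is aimed at analysts who have a
DEG list from RNA-seq or microarray data and want candidate regulators,
but who know that plain over-representation tests drown the true miRNA
in a tail of correlated hits caused by overlapping target predictions.

The pipeline:

1. **Identifier unification** — RefSeq / Ensembl / UCSC IDs and gene
   symbols are mapped onto one canonical gene key through a local
   mapping table (version suffixes stripped, case-insensitive).
2. **Compendium view** — per-database interaction tables are combined;
   a `(miRNA, gene)` pair is kept when it appears in at least
   `min_db_count` distinct selected databases (1 = union), optionally
   restricted to conserved interactions.
3. **Hypergeometric filter** — for each miRNA with at least one target
   in the gene set, the upper-tail hypergeometric probability
   `P(X >= n_overlap)` of its target overlap is computed against the
   universe of database-covered genes and adjusted by
   Benjamini–Hochberg; miRNAs with adjusted p below the threshold
   (default 0.01) become candidates.  A lone survivor is reported
   directly (`HP_ONLY`) and the EM stage is skipped.
4. **EM re-scoring** — for the surviving candidates jointly, the
   proportions `p_k` of the gene set attributable to each miRNA are
   estimated by EM on the binary prediction matrix `Y`:
   E-step `z_ik = y_ik p_k / Σ_k' y_ik' p_k'` (each gene is shared
   among its predicted miRNAs), M-step `p_k = Σ_i z_ik / N`, from the
   uniform start `p_k = 1/K` until the max-norm change drops below the
   convergence parameter (default 0.001).  The converged `p_k` are the
   EM scores (they sum to 1) and define the ranking.
5. **Seed clustering** — reported miRNAs are clustered by Hamming
   distance on their 6-nt seeds (mature positions 2–7) with UPGMA;
   seed-identical groups are flagged as duplicated predictions and a
   Newick dendrogram is written.

A synthetic-data module generates spike-in benchmarks (compendium +
mapping + gene set with a known driver miRNA) so the whole method is
testable offline.

## Worked example

Simulate a knock-in-style benchmark (50 miRNAs, 2000-gene universe,
3 databases; miRNA #1 is the spiked driver whose targets seed the gene
set), then run the pipeline on it:

```sh
Rscript inst/cli/mirem simulate --out demo --seed 5
Rscript inst/cli/mirem run \
  --genes demo/genes.txt --mapping demo/mapping.tsv \
  --db db1=demo/db1.tsv,db2=demo/db2.tsv,db3=demo/db3.tsv \
  --out demo/out
```

or equivalently in R:

```r
library(mirem)
spec  <- sim_spec(rng_seed = 5)
truth <- simulate_compendium(spec, "demo")
gs    <- simulate_spiked_gene_set(spec, truth)
cfg   <- mirem_config(genes = gs$path, mapping = truth$mapping_path,
                      databases = truth$db_paths)
report <- run_pipeline(cfg)
write_outputs(report, "demo/out")
```

`demo/out/results.tsv` then begins:

```
mirna_id	em_score	em_rank	p_raw	p_adj	n_overlap	n_targets	seed	cluster_id	flag
sim-miR-001-5p	0.947193	1	1.29313e-31	2.97419e-30	23	30	CACUUU	1	EM
sim-miR-002-5p	0.052807	2	8.63893e-05	9.93477e-04	6	24	GCACUU	2	EM
```

Reading: the spiked miRNA is ranked first with an EM score of 0.95 —
the model attributes 95% of the (covered) gene set to it — while the
runner-up, significant under the hypergeometric test alone
(`p_adj ≈ 1e-3`), keeps only the 5% share its non-overlapping targets
support.  `run_metadata.txt` records every stage count (50 input genes,
41 in the universe, 24 in EM, 2 selected of 23 tested miRNAs, 5 EM
iterations) and the full configuration; `heatmap.tsv`, `scatter.tsv`,
`clusters.tsv` and `seeds.nwk` carry the miRNA-gene incidence matrix,
the p-value-vs-EM-score plot coordinates, the seed clusters and the
seed dendrogram.

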