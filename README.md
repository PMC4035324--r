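# tagdge — tag-based digital gene expression profiling

`tagdge` is an R toolkit for 3'-tag digital gene expression (DGE) analysis
of the SAGE/NlaIII–MmeI type, built around a four-stage developmental
design (mushroom stipe stages button → egg → elongation → maturation). It
is aimed at analysts who have a gene catalog (FASTA) and per-stage tag
libraries (FASTQ or tag-count tables) and want the complete, tested chain
from raw tags to differentially expressed genes, plus a seeded synthetic
generator so every step can be validated without any external download.

The pipeline:

* **Reference construction** — each gene's *canonical tag* is the 21-mer
  `CATG` + 17 bp at the 3'-most NlaIII site with a full MmeI tail; tags
  shared verbatim by several genes are flagged ambiguous.
* **Cleaning** — adaptor-only → wrong length / missing anchor → low quality
  (N or Phred < 10) → singleton removal, in fixed priority, so the
  categories partition the raw input.
* **Quantification** — observed tags map to the index allowing one mismatch
  in the 17-bp variable region (anchor exact, ambiguous assignments
  excluded); gene counts are normalized to transcripts per million clean
  tags, TPM = count × 10⁶ / N. Saturation curves come from seeded
  subsampling without replacement.
* **DEG screen** — the exact two-library count test
  P(y|x) = (N₂/N₁)^y · (x+y)!/(x!y!) · (1+N₂/N₁)^-(x+y+1)
  (negative binomial, evaluated in log space), Benjamini–Hochberg FDR per
  transition, thresholds q ≤ 0.001 and |log₂FC| ≥ 1, fold classes [2,4),
  [4,8), [8,∞) plus on/off for genes expressed on one side only.
* **Stage sets** — expressed-gene sets, the 15-region four-way Venn
  partition, percent-of-genome / percent-of-expressed accounting.
* **Category report** — up/down DEG tallies per functional category from a
  user-supplied gene→category map (COG/KEGG style, no database access).
* **qPCR verification** — Livak 2^-ΔΔCt relative quantification against a
  reference gene and calibrator stage.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (10,000 genes, four libraries of 2 million tags, 1% sequencing error,
3% malformed reads, differential design mirroring the three stipe
transitions). `Rscript analysis/01_simulate.R` through
`05_function_qpcr.R` regenerate everything under `results/`; the whole
sequence takes about two minutes. Highlights of one run (root seed
20140527):

```
Tag index: 9700 genes with a canonical tag of a 10000 gene catalog
BU: clean fraction 0.881 (1,762,776 of 2e+06 tags kept)
Expression profile [EG]: 9290 of 9700 genes detected, 1,759,822 clean tags
  tag fates - exact: 9290  1-mismatch: 50411  ambiguous: 2  unmapped: 211
expressed in >=1 stage: 9659 (96.6% of the genome)
expressed in all four: 8665 (86.7% of genome, 89.7% of expressed)

Transition T1: 744 DEGs (587 up = 78.9%, 157 down); on: 50, off: 48
Transition T2: 1445 DEGs (326 up = 22.6%, 1119 down); on: 44, off: 181
Transition T3: 1099 DEGs (463 up = 42.1%, 636 down); on: 98, off: 83
qPCR concordance with DGE: 8/8 verification genes
```

Reading these: cleaning keeps 88% of tags (uniform sequencing error makes
every errored singleton a casualty — real quality-filtered libraries sit
higher); detection saturates well below full depth; the three transitions
reproduce the designed regime — up-dominated, then strongly down-dominated
with many genes switched off, then balanced — and the screen's false-label
fraction against the known truth stays below 0.1%. Every 2^-ΔΔCt
verification gene changes in the same direction as its DGE fold change.

A minimal interactive session:

```r
library(tagdge)
cfg <- sim_config(n_genes = 1000, library_sizes = rep(2e5, 4), seed = 1)
catalog <- generate_catalog(cfg)
truth   <- generate_truth(cfg, catalog)
index   <- build_index(catalog)
libs    <- simulate_libraries(catalog, truth, cfg)
prof    <- lapply(libs, function(l) map_tags(clean_reads(l)$table, index))
deg     <- screen(prof$BU, prof$EG, transition = "T1")
summarize_transition(deg)
```

`run_pipeline()` orchestrates the same steps from a single configuration
list (or JSON file) and writes every table plus a reproducible run
manifest.

## Repository layout

```
R/                  package code (simulation, reference, cleaning,
                    quantification, DEG screen, stage sets, categories,
                    qPCR, pipeline orchestration)
analysis/           numbered workflow scripts (the study, end to end)
tests/testthat/     unit, property and acceptance tests with independent
                    brute-force oracles
scripts/            acceptance script
vignettes/          methods vignette (model, design choices, limitations)
```
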