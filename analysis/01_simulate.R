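#!/usr/bin/env Rscript
# Stage 1: build the synthetic four-stage stipe experiment.
#
# Conditions: a 10,000-gene catalog (3% without a CATG site), four stage
# libraries (BU, EG, EL, MA) of 2e6 tags each -- the depth at which gene
# detection saturates -- with 1% per-base substitution error and 3%
# malformed reads; the differential design mirrors the study's transition
# profile (T1 up-dominant, T2 down-dominant, T3 balanced, plus on/off and
# stage-specific genes). Everything is reproducible from one root seed.

suppressPackageStartupMessages(library(tagdge))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(library_sizes = rep(2e6, 4), seed = 20140527L)
print(cfg)

catalog <- generate_catalog(cfg)
truth <- generate_truth(cfg, catalog)
write_catalog_fasta(catalog, "results/data/catalog.fasta")
write_truth_tsv(truth, "results/data/truth.tsv")

tags <- extract_canonical_tags(catalog$sequence)
message(sprintf("catalog: %d genes, %d with a canonical tag",
                nrow(catalog), sum(!is.na(tags))))
message("designed class tallies per transition:")
print(truth_label_counts(truth))

for (i in seq_along(cfg$stages)) {
  s <- cfg$stages[i]
  lib <- simulate_library(catalog, truth, s, cfg$library_sizes[i],
                          error_rate = cfg$error_rate,
                          seed = derive_seed(cfg$seed, "library", i),
                          malformed_frac = cfg$malformed_frac)
  raw <- tag_counts(table(lib$reads) |> c(), library_id = s)
  write_counts_tsv(raw, sprintf("results/data/raw_tags_%s.tsv", s))
  message(sprintf("%s: %s raw reads, %d distinct raw tags",
                  s, format(length(lib$reads), big.mark = ","),
                  length(raw$counts)))
}
message("wrote results/data/")
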