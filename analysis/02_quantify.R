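#!/usr/bin/env Rscript
# Stage 2: reference construction, read cleaning, tag mapping, TPM, and
# saturation. Raw tag tables from 01_simulate.R are cleaned (adaptor /
# length / quality / singleton cascade), mapped against the in-silico
# CATG+17bp index with at most one mismatch in the variable region, and
# normalized to transcripts per million clean tags.

suppressPackageStartupMessages(library(tagdge))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
stages <- c("BU", "EG", "EL", "MA")

catalog <- read_catalog_fasta("results/data/catalog.fasta")
index <- build_index(catalog)
print(index)
write_index_tsv(index, "results/tables/tag_index.tsv")

profiles <- list()
clean_stats <- list()
for (s in stages) {
  raw <- read_counts_tsv(sprintf("results/data/raw_tags_%s.tsv", s),
                         library_id = s)
  cl <- clean_reads(raw)
  clean_stats[[s]] <- unclass(cl$stats)
  message(sprintf("%s: clean fraction %.3f (%s of %s tags kept)",
                  s, cl$stats$clean_fraction,
                  format(cl$stats$n_clean, big.mark = ","),
                  format(cl$stats$n_raw, big.mark = ",")))
  write_counts_tsv(cl$table, sprintf("results/tables/clean_tags_%s.tsv", s))
  profiles[[s]] <- map_tags(cl$table, index)
  print(profiles[[s]])
  write_profile_tsv(profiles[[s]],
                    sprintf("results/tables/profile_%s.tsv", s))
}
jsonlite::write_json(clean_stats, "results/tables/cleaning_stats.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
write.table(expression_matrix(profiles, "tpm"),
            "results/tables/tpm_matrix.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# saturation: does detection plateau by 2e6 tags?
eg <- read_counts_tsv("results/tables/clean_tags_EG.tsv", library_id = "EG")
depths <- unique(c(round(seq(0, eg$total, length.out = 21))))
sat <- saturation(eg, index, depths, seed = 1L)
write.table(sat, "results/tables/saturation_EG.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
half <- sat$genes_detected[which.min(abs(sat$depth - eg$total / 2))]
message(sprintf("saturation (EG): %d genes at half depth vs %d at full depth",
                half, sat$genes_detected[nrow(sat)]))
message("wrote results/tables/")
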