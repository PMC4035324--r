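#!/usr/bin/env Rscript
# Stage 3: expressed-gene sets per stage and the four-way co-expression
# partition, with percent-of-genome / percent-of-expressed accounting.

suppressPackageStartupMessages(library(tagdge))
stages <- c("BU", "EG", "EL", "MA")

catalog <- read_catalog_fasta("results/data/catalog.fasta")
index <- build_index(catalog)
profiles <- lapply(stages, function(s) {
  cnt <- read_counts_tsv(sprintf("results/tables/clean_tags_%s.tsv", s), s)
  map_tags(cnt, index)
})
names(profiles) <- stages

sets <- lapply(profiles, expressed_set, min_count = 1)
part <- venn_partition(sets, genome_size = attr(index, "genome_size"))
pct <- percentages(part)
write.table(format(pct, digits = 10),
            "results/tables/venn_partition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

message("expressed genes per stage: ",
        paste(sprintf("%s=%d", stages, lengths(sets)), collapse = ", "))
u <- attr(part, "union_size")
message(sprintf("expressed in >=1 stage: %d (%.1f%% of the genome)",
                u, 100 * u / attr(part, "genome_size")))
all4 <- pct[pct$item == "BU&EG&EL&MA", ]
message(sprintf("expressed in all four: %d (%.1f%% of genome, %.1f%% of expressed)",
                all4$n, all4$pct_genome, all4$pct_expressed))
print(pct)
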