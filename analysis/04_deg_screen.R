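#!/usr/bin/env Rscript
# Stage 4: DEG screening over the three successive transitions with the
# exact two-library count test, BH FDR <= 0.001 and |log2FC| >= 1, plus
# fold-change classing and recovery scoring against the simulation truth.

suppressPackageStartupMessages(library(tagdge))
stages <- c("BU", "EG", "EL", "MA")

catalog <- read_catalog_fasta("results/data/catalog.fasta")
index <- build_index(catalog)
truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)
profiles <- lapply(stages, function(s) {
  cnt <- read_counts_tsv(sprintf("results/tables/clean_tags_%s.tsv", s), s)
  map_tags(cnt, index)
})
names(profiles) <- stages

summaries <- list()
for (t in 1:3) {
  tr <- paste0("T", t)
  rec <- screen(profiles[[stages[t]]], profiles[[stages[t + 1]]],
                transition = tr)
  write.table(rec, sprintf("results/tables/deg_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- summarize_transition(rec)
  summaries[[tr]] <- s
  print(s)

  # recovery against the designed truth
  cls <- truth[[paste0("class_T", t)]]
  truth_de <- cls != "none"
  called <- truth$gene_id %in% rec$gene_id
  message(sprintf(
    "%s (%s->%s): sensitivity vs designed DEGs %.2f, false-label fraction %.4f",
    tr, stages[t], stages[t + 1],
    mean(called[truth_de]),
    sum(cls[match(rec$gene_id, truth$gene_id)] == "none") / max(nrow(rec), 1)))
}
jsonlite::write_json(
  lapply(summaries, function(s)
    list(n_up = s$n_up, n_down = s$n_down, n_total = s$n_total,
         n_on = s$n_on, n_off = s$n_off, pct_up = s$pct_up)),
  "results/tables/deg_summaries.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
message("wrote results/tables/deg_T*.tsv")
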