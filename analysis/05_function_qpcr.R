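#!/usr/bin/env Rscript
# Stage 5: functional-category aggregation over a synthetic annotation and
# 2^-ddCt verification of selected DEGs.
#
# The category map assigns each gene up to two of 20 COG-like letters at
# random (synthetic stand-in for a real COG/KEGG annotation; the aggregation
# logic is annotation-agnostic). Verification Ct values are derived from the
# truth abundances (one PCR cycle per doubling) with 0.1-cycle replicate
# noise and a constant reference gene, emulating a GAPDH-normalized assay.

suppressPackageStartupMessages(library(tagdge))
stages <- c("BU", "EG", "EL", "MA")
set.seed(99L)

truth <- read.delim("results/data/truth.tsv", stringsAsFactors = FALSE)
degs <- lapply(1:3, function(t)
  read.delim(sprintf("results/tables/deg_T%d.tsv", t),
             stringsAsFactors = FALSE))
names(degs) <- paste0("T", 1:3)

# synthetic annotation: ~85% of genes annotated, 1-2 categories each
annotated <- sample(truth$gene_id, round(0.85 * nrow(truth)))
cmap <- do.call(rbind, lapply(annotated, function(g)
  data.frame(gene_id = g,
             category = sample(LETTERS[1:20], sample(1:2, 1)),
             stringsAsFactors = FALSE)))

tables <- lapply(degs, aggregate_categories, cmap = cmap)
tables <- filter_categories(tables, min_total = 4)
for (tr in names(tables)) {
  write.table(tables[[tr]], sprintf("results/tables/categories_%s.tsv", tr),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("%s: %d categories, %d DEGs unannotated", tr,
                  nrow(tables[[tr]]), attr(tables[[tr]], "n_unannotated")))
}

# qPCR verification of 8 designed T2 DEGs with decent expression
cand <- which(truth$class_T2 %in% c("up2-4", "up4-8", "up8+", "down2-4",
                                    "down4-8", "down8+") &
                truth$abund_EG * 1e6 >= 20)
verify <- sample(cand, 8)
rows <- list()
for (g in verify) {
  for (s in stages) {
    a <- truth[[paste0("abund_", s)]][g]
    if (a == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = truth$gene_id[g], stage = s, replicate = 1:3,
      ct = 30 - log2(a * 1e6) + rnorm(3, 0, 0.1))
  }
}
for (s in stages)
  rows[[length(rows) + 1]] <- data.frame(
    gene_id = "GAPDH", stage = s, replicate = 1:3,
    ct = 18 + rnorm(3, 0, 0.1))
ct_tab <- do.call(rbind, rows)
write.table(ct_tab, "results/tables/qpcr_ct.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

concord <- 0L
for (g in verify) {
  gid <- truth$gene_id[g]
  rq <- relative_expression(ct_tab, gid, "GAPDH", "EG")
  qfold <- log2(rq$rq[rq$stage == "EL"])
  dge <- degs$T2$log2fc[degs$T2$gene_id == gid]
  hit <- length(dge) == 1 && sign(qfold) == sign(dge)
  message(sprintf("%-12s qPCR log2(RQ EL/EG) = %+.2f, DGE log2FC = %+.2f %s",
                  gid, qfold, if (length(dge)) dge else NA,
                  if (hit) "[concordant]" else ""))
  concord <- concord + as.integer(isTRUE(hit))
}
message(sprintf("qPCR concordance with DGE: %d/%d verification genes",
                concord, length(verify)))
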