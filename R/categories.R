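#' Aggregate DEG counts per functional category
#'
#' Tallies up- and down-regulated DEGs per category of a user-supplied
#' gene-to-category mapping (COG letters, KEGG subgroups, or any vocabulary).
#' A DEG annotated with k categories contributes once to each of them
#' (multi-counting across categories, single-counting within); DEGs absent
#' from the mapping are tallied separately as unannotated.
#'
#' @param records DEG records from [screen()] for one transition.
#' @param cmap Category map: data frame with columns `gene_id` and
#'   `category` (one row per gene/category pair).
#' @param drop_empty Omit categories with zero DEGs (default TRUE; set
#'   FALSE to keep every category of the map).
#' @return Data frame `category`, `n_up`, `n_down`, `n_total`, with
#'   attribute `n_unannotated`.
#' @export
aggregate_categories <- function(records, cmap, drop_empty = TRUE) {
  if (!all(c("gene_id", "category") %in% names(cmap)))
    stop("`cmap` needs columns gene_id and category", call. = FALSE)
  if (any(!nzchar(cmap$category)))
    stop("empty category labels in the map", call. = FALSE)
  tr <- unique(records$transition)
  if (length(tr) > 1)
    stop("records mix transitions", call. = FALSE)
  if (nrow(records) && "significant" %in% names(records))
    records <- records[records$significant, , drop = FALSE]
  cmap <- unique(cmap[, c("gene_id", "category")])
  cats <- sort(unique(cmap$category))

  hit <- merge(records[, c("gene_id", "direction")], cmap, by = "gene_id")
  tab <- table(factor(hit$category, levels = cats),
               factor(hit$direction, levels = c("up", "down")))
  out <- data.frame(category = cats,
                    n_up = as.integer(tab[, "up"]),
                    n_down = as.integer(tab[, "down"]),
                    stringsAsFactors = FALSE)
  out$n_total <- out$n_up + out$n_down
  if (drop_empty) out <- out[out$n_total > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- sum(!records$gene_id %in% cmap$gene_id)
  out
}

#' Drop sparsely populated categories across transitions
#'
#' Mirrors the reporting rule of excluding categories with fewer than
#' `min_total` DEGs summed over all stage transitions together.
#'
#' @param tables Named list of per-transition tables from
#'   [aggregate_categories()].
#' @param min_total Minimum total DEG count over all transitions (default 4).
#' @return The list with sparse categories removed from every table.
#' @export
filter_categories <- function(tables, min_total = 4) {
  all_cat <- unique(unlist(lapply(tables, `[[`, "category")))
  totals <- vapply(all_cat, function(cat)
    sum(vapply(tables, function(tb)
      sum(tb$n_total[tb$category == cat]), numeric(1))), numeric(1))
  keep <- all_cat[totals >= min_total]
  lapply(tables, function(tb) {
    out <- tb[tb$category %in% keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "n_unannotated") <- attr(tb, "n_unannotated")
    out
  })
}

#' Read a gene-to-category mapping from TSV
#'
#' @param path Two-column TSV (`gene_id`, `category`), with or without
#'   header.
#' @return Data frame with columns `gene_id`, `category`.
#' @export
read_category_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene_id", first, fixed = TRUE)
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!header) names(df)[1:2] <- c("gene_id", "category")
  df[, c("gene_id", "category")]
}
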