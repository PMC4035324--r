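TAG_ANCHOR <- "CATG"
TAG_LENGTH <- 21L

#' Extract the canonical CATG-anchored tag of a transcript
#'
#' An NlaIII/MmeI tag library releases, for each poly-A primed cDNA, the tag
#' anchored at the CATG site nearest the 3' end: the four anchor bases plus
#' the 17 bases immediately downstream. This function returns that 21-mer
#' for the 3'-most CATG occurrence that still has 17 downstream bases;
#' occurrences whose 21-mer would overlap an `N` are skipped. Returns `NA`
#' when no eligible site exists.
#'
#' @param sequence Uppercase DNA string over `{A,C,G,T,N}`.
#' @return The 21-mer tag, or `NA_character_`.
#' @export
extract_canonical_tag <- function(sequence) {
  if (length(sequence) != 1L)
    stop("`sequence` must be a single string; see extract_canonical_tags()",
         call. = FALSE)
  extract_canonical_tags(sequence)
}

#' Vectorized canonical tag extraction
#'
#' @param sequences Character vector of uppercase DNA strings.
#' @return Character vector of 21-mer tags (`NA` where no eligible site).
#' @export
extract_canonical_tags <- function(sequences) {
  if (!is.character(sequences))
    stop("sequences must be character", call. = FALSE)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N} (first offender: ",
         which(bad)[1], ")", call. = FALSE)
  L <- nchar(sequences)
  hits <- gregexpr(TAG_ANCHOR, sequences, fixed = TRUE)
  vapply(seq_along(sequences), function(i) {
    pos <- hits[[i]]
    if (pos[1] == -1L) return(NA_character_)
    pos <- pos[pos + TAG_LENGTH - 1L <= L[i]]
    for (p in rev(pos)) {
      tag <- substr(sequences[i], p, p + TAG_LENGTH - 1L)
      if (!grepl("N", tag, fixed = TRUE)) return(tag)
    }
    NA_character_
  }, character(1))
}

#' Build the in-silico tag index from a gene catalog
#'
#' One entry per gene with an extractable canonical tag. Genes whose
#' canonical tags are verbatim-identical are all flagged `ambiguous`
#' (reference-side ambiguity); tags carried by a single gene are `unique`.
#'
#' @param catalog A `gene_catalog` (or data frame with `gene_id`,
#'   `sequence`).
#' @return A `tag_index`: data frame with columns `tag`, `gene_id`, `status`;
#'   attributes `genome_size` (catalog gene count) and `stats` (genes with
#'   tag, unique tags, ambiguous tags, genes without CATG).
#' @export
build_index <- function(catalog) {
  if (NROW(catalog) == 0)
    stop("empty catalog", call. = FALSE)
  if (anyDuplicated(catalog$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  tags <- extract_canonical_tags(catalog$sequence)
  keep <- !is.na(tags)
  tag <- tags[keep]
  dup <- duplicated(tag) | duplicated(tag, fromLast = TRUE)
  idx <- data.frame(tag = tag,
                    gene_id = catalog$gene_id[keep],
                    status = ifelse(dup, "ambiguous", "unique"),
                    stringsAsFactors = FALSE)
  attr(idx, "genome_size") <- NROW(catalog)
  attr(idx, "stats") <- list(
    n_genes_with_tag = sum(keep),
    n_unique_tags = sum(!dup),
    n_ambiguous_tags = length(unique(tag[dup])),
    n_genes_no_catg = sum(!keep))
  class(idx) <- c("tag_index", "data.frame")
  idx
}

#' @export
print.tag_index <- function(x, ...) {
  s <- attr(x, "stats")
  cat("Tag index:", s$n_genes_with_tag, "genes with a canonical tag of a",
      attr(x, "genome_size"), "gene catalog\n")
  cat("  unique tags:", s$n_unique_tags,
      " ambiguous tags:", s$n_ambiguous_tags,
      " genes without CATG:", s$n_genes_no_catg, "\n")
  invisible(x)
}

#' Write / read a tag index as TSV
#'
#' @param index A `tag_index`.
#' @param path Output file.
#' @export
write_index_tsv <- function(index, path) {
  utils::write.table(as.data.frame(index), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
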