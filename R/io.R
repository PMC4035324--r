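#' Write / read a gene catalog as FASTA
#'
#' @param catalog A `gene_catalog`.
#' @param path FASTA file path.
#' @export
write_catalog_fasta <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(catalog$sequence)
  names(x) <- catalog$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_catalog_fasta
#' @export
read_catalog_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- data.frame(gene_id = names(x), sequence = as.character(x),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Write raw tag reads as FASTQ (dummy quality "I")
#'
#' @param reads A `raw_reads` object.
#' @param path FASTQ file path.
#' @export
write_reads_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "raw_reads"))
  x <- Biostrings::BStringSet(reads$reads)
  names(x) <- sprintf("%s_read%07d", reads$library_id, seq_along(x))
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read raw tag reads from FASTQ
#'
#' @param path FASTQ file path.
#' @param library_id Library label (defaults to the file name).
#' @return A `raw_reads` object with a `qualities` element.
#' @export
read_reads_fastq <- function(path, library_id = NULL) {
  x <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ (", path, "): ",
                             conditionMessage(e), call. = FALSE))
  structure(list(reads = unname(as.character(x)),
                 qualities = unname(as.character(S4Vectors::mcols(x)$qualities)),
                 library_id = library_id %||% sub("\\.[^.]*$", "", basename(path)),
                 stage = NULL),
            class = "raw_reads")
}

#' Write / read a tag count table as two-column TSV
#'
#' @param table A `tag_counts` object.
#' @param path TSV file path.
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "tag_counts"))
  utils::write.table(data.frame(tag = names(table$counts),
                                count = as.integer(table$counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param library_id Library label.
#' @export
read_counts_tsv <- function(path, library_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  tag_counts(structure(as.integer(df$count), names = df$tag),
             library_id = library_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write the truth table as TSV
#'
#' @param truth A `truth_table`.
#' @param path TSV file path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an expression profile as TSV (gene, count, tpm)
#'
#' @param profile An `expression_profile`.
#' @param path TSV file path.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(data.frame(gene_id = names(profile$counts),
                                count = as.numeric(profile$counts),
                                tpm = profile$tpm),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge per-stage profiles into one expression matrix
#'
#' @param profiles Named list of `expression_profile` objects.
#' @param value `"tpm"` or `"count"`.
#' @return Data frame: `gene_id` plus one column per library.
#' @export
expression_matrix <- function(profiles, value = c("tpm", "count")) {
  value <- match.arg(value)
  genes <- names(profiles[[1]]$counts)
  for (p in profiles)
    if (!identical(names(p$counts), genes))
      stop("profiles have mismatched gene universes", call. = FALSE)
  cols <- lapply(profiles, function(p)
    if (value == "tpm") p$tpm else as.numeric(p$counts))
  out <- data.frame(gene_id = genes, cols, stringsAsFactors = FALSE)
  names(out) <- c("gene_id", names(profiles))
  out
}
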