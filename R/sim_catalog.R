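DNA_BASES <- c("A", "C", "G", "T")

rand_seq <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Destroy every CATG occurrence by rewriting its first base; substitution can
# create new occurrences upstream, so iterate until none remain.
strip_catg <- function(seq) {
  repeat {
    hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    repl <- sample(c("A", "G", "T"), length(hits), replace = TRUE)
    for (i in seq_along(hits)) substr(seq, hits[i], hits[i]) <- repl[i]
  }
}

#' Generate a synthetic gene catalog
#'
#' Random sense-strand gene sequences. Exactly
#' `floor(frac_no_catg * n_genes)` genes carry no CATG site at all; every
#' other gene is guaranteed an NlaIII site with at least 17 bases downstream
#' (planted 21 bp from the 3' end), so a canonical tag is always extractable.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `gene_catalog`: data frame with columns `gene_id` and
#'   `sequence`, plus a logical attribute `has_catg`.
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "catalog"))
  n <- config$n_genes
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  n_nocatg <- floor(config$frac_no_catg * n)
  no_catg <- sort(sample.int(n, n_nocatg))
  has_catg <- !(seq_len(n) %in% no_catg)
  seqs <- vapply(lens, rand_seq, character(1))
  for (i in seq_len(n)) {
    if (has_catg[i]) {
      # plant an anchored site with exactly 17 bases downstream; any CATG
      # arising closer to the 3' end lacks a full tail and is ineligible, so
      # the canonical tag is always the terminal 21-mer
      L <- lens[i]
      substr(seqs[i], L - 20L, L - 17L) <- "CATG"
    } else {
      seqs[i] <- strip_catg(seqs[i])
    }
  }
  out <- data.frame(gene_id = sprintf("gene_%05d", seq_len(n)),
                    sequence = seqs, stringsAsFactors = FALSE)
  attr(out, "has_catg") <- has_catg
  class(out) <- c("gene_catalog", "data.frame")
  out
}
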