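# Synthetic adaptor junk: reads consisting of ligation adaptor only, with no
# CATG anchor. The exact sequence is schematic; cleaning recognizes these
# structurally, not by alignment.
SIM_ADAPTOR <- "TCGTATGCCGTCTTCTGCTTG"

# substitute k[i] >= 1 random positions of each 21-mer with a different base
mutate_tags <- function(tags, k) {
  m <- length(tags)
  if (m == 0) return(tags)
  chars <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
                  nrow = m, byrow = TRUE)
  pos <- unlist(lapply(k, function(ki) sample.int(TAG_LENGTH, ki)),
                use.names = FALSE)
  rows <- rep.int(seq_len(m), k)
  cells <- cbind(rows, pos)
  old <- chars[cells]
  # each base has three substitution alternatives, chosen uniformly
  alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  chars[cells] <- alt[cbind(match(old, rownames(alt)),
                            sample.int(3L, length(old), replace = TRUE))]
  do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
}

tally_tags <- function(x) {
  u <- unique(x)
  structure(tabulate(match(x, u), length(u)), names = u)
}

#' Simulate one stage's tag library
#'
#' Draws `size` tag observations from the stage's true abundance vector
#' (multinomially), emits each as the gene's canonical 21-mer, substitutes
#' every base independently with probability `error_rate`, and optionally
#' replaces a fraction of reads with malformed records (half adaptor-only,
#' half wrong-length) so the cleaning stage is exercised. Deterministic given
#' `seed`.
#'
#' @param catalog A `gene_catalog`.
#' @param truth A `truth_table` from [generate_truth()].
#' @param stage Stage label (one of the truth's stages).
#' @param size Number of reads (tags) to draw.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for this library.
#' @param malformed_frac Fraction of reads replaced by malformed records.
#' @param as_counts If `TRUE`, return the tallied `tag_counts` table instead
#'   of individual reads (equivalent up to tabulation; much lighter).
#' @return A `raw_reads` object (`list(reads, library_id, stage)`) or, with
#'   `as_counts = TRUE`, a `tag_counts` table.
#' @export
simulate_library <- function(catalog, truth, stage, size, error_rate = 0,
                             seed = 1L, malformed_frac = 0,
                             as_counts = FALSE) {
  stopifnot(inherits(truth, "truth_table"))
  stages <- attr(truth, "stages")
  if (!stage %in% stages)
    stop("unknown stage: ", stage, call. = FALSE)
  a <- truth[[paste0("abund_", stage)]]
  expressed <- which(a > 0)
  if (length(expressed) == 0)
    stop("no gene expressed in stage ", stage, call. = FALSE)
  tags <- extract_canonical_tags(catalog$sequence[expressed])
  if (anyNA(tags))
    stop("expressed gene without a canonical tag: ",
         catalog$gene_id[expressed[which(is.na(tags))[1]]], call. = FALSE)
  set.seed(seed)
  gene_n <- as.vector(stats::rmultinom(1, size, a[expressed]))

  if (as_counts && error_rate == 0 && malformed_frac == 0) {
    # no read-level noise: tabulate directly (identical canonical tags of
    # distinct genes collapse, as they would after sequencing)
    cnt <- tapply(gene_n, tags, sum)
    keep <- cnt > 0
    return(tag_counts(structure(as.integer(cnt[keep]),
                                names = names(cnt)[keep]),
                      library_id = stage))
  }

  reads <- rep.int(tags, gene_n)
  if (error_rate > 0) {
    k <- stats::rbinom(length(reads), TAG_LENGTH, error_rate)
    mut <- which(k > 0)
    if (length(mut)) reads[mut] <- mutate_tags(reads[mut], k[mut])
  }
  if (malformed_frac > 0) {
    bad <- which(stats::runif(length(reads)) < malformed_frac)
    if (length(bad)) {
      adaptor_only <- bad[seq_len(ceiling(length(bad) / 2))]
      wrong_len <- setdiff(bad, adaptor_only)
      reads[adaptor_only] <- SIM_ADAPTOR
      if (length(wrong_len))
        reads[wrong_len] <- substr(reads[wrong_len], 1L, 15L)
    }
  }
  if (as_counts) {
    warning("as_counts with read-level noise tabulates raw reads without cleaning")
    return(tag_counts(tally_tags(reads), library_id = stage))
  }
  structure(list(reads = reads, library_id = stage, stage = stage),
            class = "raw_reads")
}

#' Simulate all four stage libraries of a configured experiment
#'
#' Per-stage seeds are derived from the config's root seed
#' ([derive_seed()]), so each library is independently reproducible.
#'
#' @param catalog,truth As for [simulate_library()].
#' @param config The [sim_config()] holding stage labels, library sizes,
#'   error rate and malformed-read fraction.
#' @param as_counts Passed through to [simulate_library()].
#' @return Named list (by stage) of `raw_reads` or `tag_counts`.
#' @export
simulate_libraries <- function(catalog, truth, config, as_counts = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_along(config$stages), function(i)
    simulate_library(catalog, truth,
                     stage = config$stages[i],
                     size = config$library_sizes[i],
                     error_rate = config$error_rate,
                     seed = derive_seed(config$seed, "library", i),
                     malformed_frac = config$malformed_frac,
                     as_counts = as_counts))
  names(out) <- config$stages
  out
}

#' @export
print.raw_reads <- function(x, ...) {
  cat("Raw tag reads:", length(x$reads), "reads, library",
      x$library_id, "\n")
  invisible(x)
}
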