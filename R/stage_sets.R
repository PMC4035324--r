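#' Expressed-gene set of a library
#'
#' @param profile An `expression_profile`.
#' @param min_count Detection threshold; genes with unambiguous count >=
#'   `min_count` are called expressed (default 1, shared with [screen()]).
#' @return Character vector of gene ids.
#' @export
expressed_set <- function(profile, min_count = 1) {
  stopifnot(inherits(profile, "expression_profile"))
  if (min_count < 1) stop("`min_count` must be >= 1", call. = FALSE)
  names(profile$counts)[profile$counts >= min_count]
}

#' Four-way Venn partition of expressed-gene sets
#'
#' Tabulates each union gene's membership pattern over the four stages,
#' giving exact counts for the 15 non-empty regions. Patterns are ordered
#' canonically by the stage order of the input list.
#'
#' @param sets Named list of exactly four gene-id character vectors (names
#'   are the stage labels, in canonical order).
#' @param genome_size Total gene count of the catalog (>= union size).
#' @return A `venn_partition` data frame with columns `pattern` (e.g.
#'   `"BU&EG"`), one logical column per stage, and `count`; attributes
#'   `union_size`, `stage_totals`, `genome_size`.
#' @export
venn_partition <- function(sets, genome_size) {
  if (!is.list(sets) || length(sets) != 4L)
    stop("`sets` must be a list of exactly 4 gene sets", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be uniquely named by stage", call. = FALSE)
  sets <- lapply(sets, unique)
  union_genes <- unique(unlist(sets, use.names = FALSE))
  if (genome_size < length(union_genes))
    stop("`genome_size` smaller than the union of the sets", call. = FALSE)
  stages <- names(sets)

  member <- vapply(sets, function(s) union_genes %in% s,
                   logical(length(union_genes)))
  if (length(union_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                  dimnames = list(NULL, stages))
  # region code: bit i set iff the gene belongs to stage i
  code <- as.integer(member %*% 2^(seq_len(4L) - 1L))

  masks <- 1:15
  bits <- t(vapply(masks, function(m) bitwAnd(m, 2^(0:3)) > 0, logical(4)))
  colnames(bits) <- stages
  pattern <- apply(bits, 1L, function(b) paste(stages[b], collapse = "&"))
  count <- as.integer(table(factor(code, levels = masks)))

  out <- data.frame(pattern = pattern, bits, count = count,
                    stringsAsFactors = FALSE, check.names = FALSE)
  # canonical order: by number of stages, then stage order
  ord <- order(rowSums(bits), apply(bits, 1, function(b)
    sum((!b) * 2^(4 - seq_len(4)))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "union_size") <- length(union_genes)
  attr(out, "stage_totals") <- vapply(sets, length, integer(1))
  attr(out, "genome_size") <- as.integer(genome_size)
  class(out) <- c("venn_partition", "data.frame")
  out
}

#' Percent-of-genome and percent-of-expressed summary
#'
#' For every Venn region, every stage total, and the expressed union,
#' reports the raw count together with its percentage of the genome and of
#' the expressed union. Ratios are stored at full precision; rounding to one
#' decimal happens only when printing.
#'
#' @param part A `venn_partition`.
#' @return A `venn_percentages` data frame with columns `item`, `n`,
#'   `pct_genome`, `pct_expressed`.
#' @export
percentages <- function(part) {
  stopifnot(inherits(part, "venn_partition"))
  genome <- attr(part, "genome_size")
  union_size <- attr(part, "union_size")
  if (genome <= 0 || union_size <= 0)
    stop("zero genome or union size", call. = FALSE)
  totals <- attr(part, "stage_totals")
  items <- c(part$pattern, paste0("total:", names(totals)), "expressed")
  n <- c(part$count, unname(totals), union_size)
  out <- data.frame(item = items, n = n,
                    pct_genome = 100 * n / genome,
                    pct_expressed = 100 * n / union_size,
                    stringsAsFactors = FALSE)
  class(out) <- c("venn_percentages", "data.frame")
  out
}

#' @export
print.venn_percentages <- function(x, ...) {
  y <- x
  y$pct_genome <- sprintf("%.1f", x$pct_genome)
  y$pct_expressed <- sprintf("%.1f", x$pct_expressed)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
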