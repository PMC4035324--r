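# Assign each observed tag to a gene (or NA) following the mapping priority:
# exact match to a unique reference tag; exact match to an ambiguous
# reference tag -> excluded; otherwise all reference tags at Hamming distance
# 1 within the 17 bp variable region (anchor must match exactly) -> assigned
# iff they belong to exactly one gene; else unmapped. Returns a data frame
# with the assigned gene and the fate of every tag.
assign_tags <- function(obs_tags, index) {
  u <- index$status == "unique"
  utags <- index$tag[u]
  ugenes <- index$gene_id[u]
  amb_tags <- unique(index$tag[!u])

  n <- length(obs_tags)
  gene <- rep(NA_character_, n)
  fate <- rep("unmapped", n)

  hit <- match(obs_tags, utags)
  exact <- !is.na(hit)
  gene[exact] <- ugenes[hit[exact]]
  fate[exact] <- "exact_unique"
  exact_amb <- !exact & obs_tags %in% amb_tags
  fate[exact_amb] <- "ambiguous_excluded"

  todo <- which(!exact & !exact_amb)
  if (length(todo)) {
    cand <- obs_tags[todo]
    n_hit <- integer(length(cand))
    hit_gene <- rep(NA_character_, length(cand))
    amb_hit <- logical(length(cand))
    for (p in (nchar(TAG_ANCHOR) + 1L):TAG_LENGTH) {
      orig <- substr(cand, p, p)
      for (b in DNA_BASES) {
        variant <- cand
        substr(variant, p, p) <- b
        same <- orig == b  # identical to the observed tag: not a mismatch
        vh <- match(variant, utags)
        got <- !is.na(vh) & !same
        if (any(got)) {
          n_hit[got] <- n_hit[got] + 1L
          hit_gene[got] <- ugenes[vh[got]]
        }
        av <- variant %in% amb_tags & !same
        amb_hit <- amb_hit | av
      }
    }
    ok <- n_hit == 1L & !amb_hit
    gene[todo[ok]] <- hit_gene[ok]
    fate[todo[ok]] <- "mm1_unique"
    fate[todo[n_hit > 1L | amb_hit]] <- "ambiguous_excluded"
  }
  data.frame(tag = obs_tags, gene_id = gene, fate = fate,
             stringsAsFactors = FALSE)
}

#' Map clean tags to the reference index and quantify expression
#'
#' Each observed clean tag is assigned by priority: (1) exact match to a
#' unique reference tag; (2) exact match to an ambiguous reference tag is
#' excluded; (3) with no exact match, all reference tags at Hamming distance
#' one over the 17 bp variable region (the CATG anchor must match exactly)
#' are collected and the tag is counted only if they belong to exactly one
#' gene; (4) anything else is unmapped. Gene expression is the sum of
#' assigned tag counts, normalized to transcripts per million clean tags
#' (TPM) with the library's total clean tags as denominator.
#'
#' @param table A `tag_counts` table of clean tags.
#' @param index A `tag_index` from [build_index()].
#' @return An `expression_profile`: `list(library_id, counts, tpm,
#'   total_clean, tallies)` where `counts`/`tpm` are named vectors over all
#'   genes in the index and `tallies` counts distinct observed tags by fate
#'   (`exact_unique`, `mm1_unique`, `ambiguous_excluded`, `unmapped`).
#' @export
map_tags <- function(table, index) {
  stopifnot(inherits(table, "tag_counts"), inherits(index, "tag_index"))
  if (nrow(index) == 0) stop("empty index", call. = FALSE)
  obs <- names(table$counts)
  if (length(obs) && any(nchar(obs) != TAG_LENGTH))
    stop("observed tag with length != 21; run clean_reads() first",
         call. = FALSE)
  asg <- assign_tags(obs, index)

  genes <- unique(index$gene_id)
  counts <- structure(numeric(length(genes)), names = genes)
  mapped <- !is.na(asg$gene_id)
  if (any(mapped)) {
    add <- tapply(as.numeric(table$counts[mapped]), asg$gene_id[mapped], sum)
    counts[names(add)] <- add
  }
  total <- table$total
  structure(list(
    library_id = table$library_id,
    counts = counts,
    tpm = counts * 1e6 / total,
    total_clean = total,
    tallies = as.list(table(factor(asg$fate,
      levels = c("exact_unique", "mm1_unique", "ambiguous_excluded",
                 "unmapped"))))
  ), class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile [", x$library_id, "]: ",
      sum(x$counts > 0), " of ", length(x$counts),
      " genes detected, ", format(x$total_clean, big.mark = ","),
      " clean tags\n", sep = "")
  t <- x$tallies
  cat("  tag fates - exact:", t$exact_unique, " 1-mismatch:", t$mm1_unique,
      " ambiguous:", t$ambiguous_excluded, " unmapped:", t$unmapped, "\n")
  invisible(x)
}

#' Sequencing saturation curve
#'
#' Subsamples the library's tag observations without replacement at each
#' requested depth (one shared seeded permutation, so the curve is a nested
#' rarefaction) and records how many genes are detected (mapped count >= 1).
#' At full depth the curve reproduces the profile's detected-gene count.
#'
#' @param table A `tag_counts` table of clean tags.
#' @param index A `tag_index`.
#' @param depths Increasing integer vector of subsampling depths, each
#'   at most the library total.
#' @param seed Integer seed for the permutation.
#' @return A `saturation_curve` data frame with columns `depth` and
#'   `genes_detected`.
#' @export
saturation <- function(table, index, depths, seed = 1L) {
  stopifnot(inherits(table, "tag_counts"))
  total <- table$total
  depths <- sort(unique(as.numeric(depths)))
  if (any(depths < 0) || any(depths > total))
    stop("depths must lie in [0, total clean tags]", call. = FALSE)
  asg <- assign_tags(names(table$counts), index)
  gene_code <- match(asg$gene_id, unique(index$gene_id))  # NA if unassigned
  obs_gene <- rep.int(gene_code, table$counts)
  set.seed(seed)
  obs_gene <- obs_gene[sample.int(length(obs_gene))]
  new_gene <- !is.na(obs_gene) & !duplicated(obs_gene)
  cum <- cumsum(new_gene)
  detected <- ifelse(depths == 0, 0L, cum[pmax(depths, 1)])
  structure(data.frame(depth = depths, genes_detected = detected),
            class = c("saturation_curve", "data.frame"))
}
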