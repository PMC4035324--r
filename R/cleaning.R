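#' Tag count table
#'
#' Per-library map from 21-mer tag to its observed copy number.
#'
#' @param counts Named integer vector (names are tags).
#' @param library_id Library label.
#' @return A `tag_counts` object: `list(library_id, counts, total)`.
#' @export
tag_counts <- function(counts, library_id = "lib") {
  if (is.null(names(counts)) && length(counts) > 0)
    stop("counts must be named by tag", call. = FALSE)
  counts <- structure(as.integer(counts), names = names(counts))
  structure(list(library_id = library_id, counts = counts,
                 total = sum(as.numeric(counts))),
            class = "tag_counts")
}

#' @export
print.tag_counts <- function(x, ...) {
  cat("Tag counts [", x$library_id, "]: ", length(x$counts),
      " distinct tags, ", format(x$total, big.mark = ","),
      " clean tags\n", sep = "")
  invisible(x)
}

low_quality_pattern <- function(threshold) {
  # Phred+33: qualities below `threshold` encode as chars 33..(32+threshold)
  chars <- intToUtf8(33:(32 + threshold), multiple = TRUE)
  paste0("[", gsub("([][\\^-])", "\\\\\\1", paste(chars, collapse = "")), "]")
}

#' Clean raw tag reads into a count table
#'
#' Applies the tag-library cleaning cascade in a fixed priority order, so the
#' categories partition the input: (1) adaptor-only/empty reads, (2) wrong
#' length or missing CATG anchor, (3) low quality (any `N`, or any base call
#' below the Phred threshold when qualities are available), then the
#' survivors are aggregated per tag and (4) tags seen exactly once in the
#' whole library are dropped as singletons.
#'
#' A pre-tabulated `tag_counts` table may also be cleaned: structural filters
#' apply per tag weighted by its count, and the singleton rule applies to the
#' aggregate counts; cleaning an already-clean table is a no-op.
#'
#' @param reads A `raw_reads` object, a character vector of read sequences,
#'   or a `tag_counts` table.
#' @param qualities Optional character vector of Phred+33 quality strings,
#'   parallel to the reads.
#' @param quality_threshold Minimum acceptable Phred score (default 10).
#' @param remove_singletons Drop tags with aggregate copy number 1
#'   (default TRUE, the standard tag-library rule).
#' @param adaptor Adaptor sequence whose reads count as adaptor-only.
#' @param library_id Library label for the output table.
#' @return `list(table = tag_counts, stats = cleaning_stats)`.
#' @export
clean_reads <- function(reads, qualities = NULL, quality_threshold = 10,
                        remove_singletons = TRUE, adaptor = SIM_ADAPTOR,
                        library_id = NULL) {
  if (inherits(reads, "tag_counts")) {
    cnt <- reads$counts
    if (length(cnt) == 0) stop("empty input", call. = FALSE)
    tags <- names(cnt)
    n_raw <- sum(as.numeric(cnt))
    is_adapt <- !nzchar(tags) | startsWith(tags, adaptor)
    is_badlen <- !is_adapt &
      (nchar(tags) != TAG_LENGTH | !startsWith(tags, TAG_ANCHOR))
    is_lowq <- !is_adapt & !is_badlen & grepl("N", tags, fixed = TRUE)
    keep <- !(is_adapt | is_badlen | is_lowq)
    agg <- cnt[keep]
    n_adapt <- sum(as.numeric(cnt[is_adapt]))
    n_badlen <- sum(as.numeric(cnt[is_badlen]))
    n_lowq <- sum(as.numeric(cnt[is_lowq]))
    lib <- library_id %||% reads$library_id
  } else {
    if (inherits(reads, "raw_reads")) {
      lib <- library_id %||% reads$library_id
      reads <- reads$reads
    } else {
      lib <- library_id %||% "lib"
    }
    if (length(reads) == 0) stop("empty input", call. = FALSE)
    n_raw <- length(reads)
    is_adapt <- !nzchar(reads) | startsWith(reads, adaptor)
    is_badlen <- !is_adapt &
      (nchar(reads) != TAG_LENGTH | !startsWith(reads, TAG_ANCHOR))
    is_lowq <- !is_adapt & !is_badlen & grepl("N", reads, fixed = TRUE)
    if (!is.null(qualities)) {
      if (length(qualities) != n_raw)
        stop("qualities must parallel reads", call. = FALSE)
      is_lowq <- is_lowq | (!is_adapt & !is_badlen &
                              grepl(low_quality_pattern(quality_threshold),
                                    qualities))
    }
    keep <- !(is_adapt | is_badlen | is_lowq)
    agg <- tally_tags(reads[keep])
    n_adapt <- sum(is_adapt)
    n_badlen <- sum(is_badlen)
    n_lowq <- sum(is_lowq)
  }

  singleton <- if (remove_singletons) agg == 1L else rep(FALSE, length(agg))
  n_singleton <- sum(as.numeric(agg[singleton]))
  agg <- agg[!singleton]
  n_clean <- sum(as.numeric(agg))

  stats <- structure(list(
    n_raw = n_raw,
    n_adaptor_only = n_adapt,
    n_bad_length = n_badlen,
    n_low_quality = n_lowq,
    n_singleton_removed = n_singleton,
    n_clean = n_clean,
    clean_fraction = n_clean / n_raw
  ), class = "cleaning_stats")

  list(table = tag_counts(agg, library_id = lib), stats = stats)
}

#' @export
print.cleaning_stats <- function(x, ...) {
  cat("Cleaning:", format(x$n_raw, big.mark = ","), "raw ->",
      format(x$n_clean, big.mark = ","), "clean tags (",
      sprintf("%.1f%%", 100 * x$clean_fraction), ")\n")
  cat("  adaptor-only:", x$n_adaptor_only,
      " bad length/anchor:", x$n_bad_length,
      " low quality:", x$n_low_quality,
      " singletons:", x$n_singleton_removed, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
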