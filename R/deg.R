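#' Exact two-library tag count test
#'
#' Tests whether a gene's tag counts `x` and `y`, from libraries of `N1` and
#' `N2` clean tags, are compatible with equal underlying expression. The test
#' is the classical exact conditional test for two tag libraries: given `x`,
#' the second count follows
#' \deqn{P(y \mid x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!}
#'       \left(1 + N_2/N_1\right)^{-(x+y+1)},}
#' a negative binomial with size `x + 1` and success probability
#' `N1 / (N1 + N2)`, evaluated in log space via `pnbinom`. The two-sided
#' p-value is `2 * min(lower tail, upper tail)` capped at 1. Because the
#' conditional construction is not exactly invariant under exchanging the
#' libraries (the conditioned count enters as `x + 1`), the reported tails
#' average the two conditioning orientations, which makes
#' `count_test(x, y, N1, N2) == count_test(y, x, N2, N1)` hold exactly.
#'
#' @param x,y Non-negative tag counts in the two libraries (vectorized).
#' @param N1,N2 Positive clean-tag library sizes.
#' @return Two-sided p-values in (0, 1].
#' @export
count_test <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0))
    stop("library sizes must be > 0", call. = FALSE)
  p1 <- N1 / (N1 + N2)
  p2 <- N2 / (N1 + N2)
  loA <- stats::pnbinom(y, size = x + 1, prob = p1)
  upA <- stats::pnbinom(y - 1, size = x + 1, prob = p1, lower.tail = FALSE)
  loB <- stats::pnbinom(x, size = y + 1, prob = p2)
  upB <- stats::pnbinom(x - 1, size = y + 1, prob = p2, lower.tail = FALSE)
  lower <- (loA + upB) / 2
  upper <- (upA + loB) / 2
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j >= i} m p_(j) / j`,
#' ties preserved and input order restored. Thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

FC_CLASS_LEVELS <- c("lt2", "2-4", "4-8", "8plus", "on", "off")

fold_class <- function(abs_fc) {
  cut(abs_fc, breaks = c(-Inf, 2, 4, 8, Inf), right = FALSE,
      labels = c("lt2", "2-4", "4-8", "8plus"))
}

#' Screen differentially expressed genes between two successive stages
#'
#' Every gene expressed (count >= `min_count`) in at least one of the two
#' stages is tested with [count_test()]; q-values are Benjamini-Hochberg
#' adjusted over all tested genes of the transition. A DEG must satisfy both
#' `q <= fdr` and `|log2 fold change| >= min_log2fc`, where the fold change
#' is computed on TPM. Genes expressed in exactly one stage get class
#' `on`/`off` with infinite log2 fold change (they always pass the fold
#' criterion; the p-value is still computed from the counts). Finite folds
#' are binned into half-open classes `[2,4)`, `[4,8)`, `[8,Inf)`.
#'
#' @param earlier,later `expression_profile` objects sharing one gene
#'   universe.
#' @param fdr FDR threshold (default 0.001).
#' @param min_log2fc Minimum absolute log2 fold change (default 1).
#' @param min_count Detection threshold defining "expressed" (default 1).
#' @param transition Optional transition label stored in the records.
#' @param keep_all If `TRUE`, return all tested genes with a `significant`
#'   column instead of only the DEGs.
#' @return Data frame of DEG records: `gene_id`, `transition`, `count_x`,
#'   `count_y`, `tpm_x`, `tpm_y`, `log2fc`, `p_value`, `q_value`,
#'   `direction`, `fc_class` (and `significant` with `keep_all`).
#' @export
screen <- function(earlier, later, fdr = 0.001, min_log2fc = 1,
                   min_count = 1, transition = NULL, keep_all = FALSE) {
  stopifnot(inherits(earlier, "expression_profile"),
            inherits(later, "expression_profile"))
  if (!identical(names(earlier$counts), names(later$counts)))
    stop("profiles have mismatched gene universes", call. = FALSE)
  if (earlier$total_clean <= 0 || later$total_clean <= 0)
    stop("profiles must have positive clean-tag totals", call. = FALSE)
  if (fdr <= 0 || fdr > 1) stop("`fdr` must lie in (0, 1]", call. = FALSE)
  if (min_log2fc < 0) stop("`min_log2fc` must be >= 0", call. = FALSE)
  if (is.null(transition))
    transition <- paste0(earlier$library_id, "->", later$library_id)

  x <- earlier$counts; y <- later$counts
  tested <- which(x >= min_count | y >= min_count)
  if (length(tested) == 0) {
    out <- data.frame(gene_id = character(), transition = character(),
                      count_x = numeric(), count_y = numeric(),
                      tpm_x = numeric(), tpm_y = numeric(),
                      log2fc = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      fc_class = character(), stringsAsFactors = FALSE)
    if (keep_all) out$significant <- logical()
    return(out)
  }
  x <- x[tested]; y <- y[tested]
  tpm_x <- earlier$tpm[tested]; tpm_y <- later$tpm[tested]
  p <- count_test(x, y, earlier$total_clean, later$total_clean)
  q <- bh_adjust(p)
  log2fc <- log2(tpm_y / tpm_x)  # +-Inf when one side is zero

  cls <- as.character(fold_class(2^abs(log2fc)))
  on_gene <- x < min_count & y >= min_count
  off_gene <- y < min_count & x >= min_count
  cls[on_gene] <- "on"
  cls[off_gene] <- "off"
  direction <- ifelse(log2fc > 0 | on_gene, "up", "down")
  pass_fold <- on_gene | off_gene |
    (is.finite(log2fc) & abs(log2fc) >= min_log2fc)
  sig <- q <= fdr & pass_fold

  out <- data.frame(
    gene_id = names(earlier$counts)[tested], transition = transition,
    count_x = as.numeric(x), count_y = as.numeric(y),
    tpm_x = tpm_x, tpm_y = tpm_y, log2fc = log2fc,
    p_value = p, q_value = q, direction = direction, fc_class = cls,
    stringsAsFactors = FALSE, row.names = NULL)
  if (keep_all) {
    out$significant <- sig
    out
  } else {
    out[sig, , drop = FALSE]
  }
}

#' Summarize one transition's DEG records
#'
#' Exact tallies by direction and fold-change class, plus on/off counts and
#' direction percentages.
#'
#' @param records DEG records from [screen()] for a single transition.
#' @return A `transition_summary`: list with `transition`, `n_up`, `n_down`,
#'   `n_total`, `n_on`, `n_off`, `pct_up`, `pct_down` and a `class_counts`
#'   data frame (direction x fc_class).
#' @export
summarize_transition <- function(records) {
  tr <- unique(records$transition)
  if (length(tr) > 1)
    stop("records mix transitions: ", paste(tr, collapse = ", "),
         call. = FALSE)
  if (length(tr) == 0) tr <- NA_character_
  if (nrow(records) && "significant" %in% names(records))
    records <- records[records$significant, , drop = FALSE]
  dir <- factor(records$direction, levels = c("up", "down"))
  cls <- factor(records$fc_class, levels = FC_CLASS_LEVELS)
  tab <- as.data.frame(table(direction = dir, fc_class = cls),
                       responseName = "n")
  n_up <- sum(dir == "up"); n_down <- sum(dir == "down")
  n_total <- n_up + n_down
  structure(list(
    transition = tr,
    n_up = n_up, n_down = n_down, n_total = n_total,
    n_on = sum(cls == "on"), n_off = sum(cls == "off"),
    pct_up = if (n_total > 0) 100 * n_up / n_total else NA_real_,
    pct_down = if (n_total > 0) 100 * n_down / n_total else NA_real_,
    class_counts = tab
  ), class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Transition ", x$transition, ": ", x$n_total, " DEGs (",
      x$n_up, " up", if (!is.na(x$pct_up))
        sprintf(" = %.1f%%", x$pct_up), ", ",
      x$n_down, " down); on: ", x$n_on, ", off: ", x$n_off, "\n", sep = "")
  wide <- stats::xtabs(n ~ direction + fc_class, data = x$class_counts)
  print(wide)
  invisible(x)
}
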