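# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: position-by-position scans, one-hot matrix products,
# direct log-space pmf summation, and nested-loop tabulations.

# -- canonical tag: scan every position, keep the right-most eligible site --
oracle_extract_tag <- function(seq) {
  L <- nchar(seq)
  best <- NA_character_
  p <- 1L
  while (p + 20L <= L) {
    if (substr(seq, p, p + 3L) == "CATG") {
      tag <- substr(seq, p, p + 20L)
      if (!grepl("N", tag, fixed = TRUE)) best <- tag
    }
    p <- p + 1L
  }
  best
}

# -- tag-to-gene assignment via exhaustive Hamming distances ----------------
onehot_tags <- function(tags) {
  lv <- c("A", "C", "G", "T", "N")
  ch <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
               nrow = length(tags), byrow = TRUE)
  code <- matrix(match(ch, lv), nrow = nrow(ch))
  X <- matrix(0, nrow(ch), 21L * 5L)
  for (p in 1:21)
    X[cbind(seq_len(nrow(ch)), (p - 1L) * 5L + code[, p])] <- 1
  X
}

oracle_assign <- function(obs, index) {
  Xo <- onehot_tags(obs)
  Xr <- onehot_tags(index$tag)
  anchor <- 1:(4 * 5)
  varreg <- (4 * 5 + 1):(21 * 5)
  Ma <- Xo[, anchor, drop = FALSE] %*% t(Xr[, anchor, drop = FALSE])
  Mv <- Xo[, varreg, drop = FALSE] %*% t(Xr[, varreg, drop = FALSE])
  genes <- index$gene_id
  gene <- rep(NA_character_, length(obs))
  fate <- rep("unmapped", length(obs))
  for (i in seq_along(obs)) {
    exact <- which(Ma[i, ] == 4 & Mv[i, ] == 17)
    if (length(exact)) {
      g <- unique(genes[exact])
      if (length(g) == 1L) {
        gene[i] <- g
        fate[i] <- "exact_unique"
      } else {
        fate[i] <- "ambiguous_excluded"
      }
      next
    }
    mm1 <- which(Ma[i, ] == 4 & Mv[i, ] == 16)
    if (length(mm1)) {
      g <- unique(genes[mm1])
      if (length(g) == 1L) {
        gene[i] <- g
        fate[i] <- "mm1_unique"
      } else {
        fate[i] <- "ambiguous_excluded"
      }
    }
  }
  data.frame(tag = obs, gene_id = gene, fate = fate, stringsAsFactors = FALSE)
}

# -- exact count test by direct tail summation of the conditional pmf ------
ac_pmf_log <- function(yv, x, N1, N2) {
  r <- N2 / N1
  yv * log(r) + lgamma(x + yv + 1) - lgamma(x + 1) - lgamma(yv + 1) -
    (x + yv + 1) * log1p(r)
}

oracle_tail_lower <- function(x, y, N1, N2) {
  if (y < 0) return(0)
  sum(exp(ac_pmf_log(0:y, x, N1, N2)))
}

oracle_tail_upper <- function(x, y, N1, N2) {
  mu <- (x + 1) * N2 / N1
  hi <- max(y, ceiling(mu + 20 * sqrt(mu + 1))) + 400L
  sum(exp(ac_pmf_log(y:hi, x, N1, N2)))
}

oracle_count_test <- function(x, y, N1, N2) {
  lower <- (oracle_tail_lower(x, y, N1, N2) +
              oracle_tail_upper(y, x, N2, N1)) / 2
  upper <- (oracle_tail_upper(x, y, N1, N2) +
              oracle_tail_lower(y, x, N2, N1)) / 2
  min(1, 2 * min(lower, upper))
}

# cumulative tail tables conditioning on 0..cmax, other count 0..omax
oracle_tail_tables <- function(N1, N2, cmax, omax) {
  TL <- TU <- matrix(0, cmax + 1, omax + 1)
  for (x in 0:cmax) {
    mu <- (x + 1) * N2 / N1
    hi <- max(omax, ceiling(mu + 20 * sqrt(mu + 1))) + 400L
    pm <- exp(ac_pmf_log(0:hi, x, N1, N2))
    TL[x + 1, ] <- cumsum(pm)[1:(omax + 1)]
    TU[x + 1, ] <- rev(cumsum(rev(pm)))[1:(omax + 1)]
  }
  list(L = TL, U = TU)
}

# -- BH step-up by the textbook formula ------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# -- Venn regions by per-gene membership tabulation ------------------------
oracle_venn <- function(sets) {
  genes <- unique(unlist(sets))
  patterns <- list()
  for (g in genes) {
    members <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    patterns[[key]] <- (patterns[[key]] %||% 0L) + 1L
  }
  patterns
}

# -- category tallies by nested loops --------------------------------------
oracle_categories <- function(records, cmap) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    g <- records$gene_id[i]
    cats <- unique(cmap$category[cmap$gene_id == g])
    for (cc in cats) {
      if (is.null(out[[cc]])) out[[cc]] <- c(up = 0L, down = 0L)
      out[[cc]][[records$direction[i]]] <- out[[cc]][[records$direction[i]]] + 1L
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
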