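TRUTH_LABELS <- c(up2_4 = "up2-4", up4_8 = "up4-8", up8 = "up8+",
                  down2_4 = "down2-4", down4_8 = "down4-8", down8 = "down8+",
                  on = "on", off = "off")

# Draw a fold change inside the half-open class interval, uniform on log2
# scale; the 8+ class spans [8, 32).
draw_fold <- function(class, k) {
  switch(class,
    up2_4 = 2^stats::runif(k, 1, 2),
    up4_8 = 2^stats::runif(k, 2, 3),
    up8 = 2^stats::runif(k, 3, 5),
    down2_4 = 1 / 2^stats::runif(k, 1, 2),
    down4_8 = 1 / 2^stats::runif(k, 2, 3),
    down8 = 1 / 2^stats::runif(k, 3, 5),
    stop("no fold for class ", class))
}

#' Generate the ground-truth expression table
#'
#' Builds per-stage relative abundances for every catalog gene together with
#' per-transition class labels. Genes without a CATG site have zero abundance
#' everywhere. A configurable fraction is expressed in exactly one stage
#' (labelled `on` entering and `off` leaving it); per transition, disjoint
#' gene sets receive designed fold changes drawn inside their class interval
#' (`[2,4)`, `[4,8)`, `[8,32)` on the fold scale, both directions) or are
#' switched fully on or off.
#'
#' Designed folds are imposed exactly on the per-stage relative abundances:
#' differentially expressed genes get `a * fold`, and the non-DE remainder
#' absorbs the compensating probability mass through one common scaling
#' factor per transition, so all non-DE genes share an identical abundance
#' ratio and each stage's abundances sum to one.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog from [generate_catalog()].
#' @return A `truth_table`: data frame with `gene_id`, one abundance column
#'   per stage (`abund_<stage>`), and class labels `class_T1..class_T3` in
#'   `{none, up2-4, up4-8, up8+, down2-4, down4-8, down8+, on, off}`.
#' @export
generate_truth <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "gene_catalog"))
  set.seed(derive_seed(config$seed, "truth"))
  n <- nrow(catalog)
  has_catg <- attr(catalog, "has_catg")
  if (is.null(has_catg))
    has_catg <- !is.na(extract_canonical_tags(catalog$sequence))
  stages <- config$stages

  masses <- stats::rlnorm(n, meanlog = 0, sdlog = 1.5)

  pool <- which(has_catg)
  # induced and turned-on genes come from the low-abundance stratum so the
  # designed flux stays approximately mass-balanced and the compositional
  # factor on the non-DE remainder remains near one; repressed and
  # turned-off genes are drawn from the whole pool
  low_cut <- stats::median(masses[pool])
  n_ss <- floor(config$stage_specific_frac * n)
  labels <- matrix("none", n, 3,
                   dimnames = list(NULL, c("class_T1", "class_T2", "class_T3")))

  ss_idx <- integer(0)
  ss_stage <- integer(0)
  if (n_ss > 0) {
    low_pool <- pool[masses[pool] < low_cut]
    if (n_ss > length(low_pool))
      stop("stage_specific_frac too large for the low-abundance stratum",
           call. = FALSE)
    ss_idx <- sample(low_pool, n_ss)
    ss_stage <- sample(rep(seq_along(stages), length.out = n_ss))
    pool <- setdiff(pool, ss_idx)
  }

  # disjoint role assignment: each core gene plays at most one part across
  # all transitions so labels stay unambiguous
  low_classes <- c("up2_4", "up4_8", "up8", "on")
  roles <- vector("list", 3)
  for (t in 1:3) {
    fr <- config$de_design[[t]]
    roles[[t]] <- list()
    for (cl in DE_CLASSES) {
      k <- floor(fr[[cl]] * n)
      from <- if (cl %in% low_classes) pool[masses[pool] < low_cut] else pool
      if (k > length(from))
        stop("de_design too dense: not enough unassigned genes for ",
             names(config$de_design)[t], " class ", cl, call. = FALSE)
      picked <- if (k > 0) sample(from, k) else integer(0)
      roles[[t]][[cl]] <- picked
      pool <- setdiff(pool, picked)
      if (k > 0) labels[picked, t] <- TRUTH_LABELS[[cl]]
    }
  }
  for (t in 1:3) {
    entering <- ss_idx[ss_stage == t + 1L]
    leaving <- ss_idx[ss_stage == t]
    if (length(entering)) labels[entering, t] <- "on"
    if (length(leaving)) labels[leaving, t] <- "off"
  }

  # genes silent at stage 1: on-genes of any transition and stage-specific
  # genes of later stages
  silent1 <- unique(c(unlist(lapply(roles, `[[`, "on")),
                      ss_idx[ss_stage != 1L]))
  expressed1 <- setdiff(which(has_catg), silent1)
  if (length(expressed1) == 0)
    stop("degenerate design: no gene expressed at stage 1", call. = FALSE)

  A <- matrix(0, n, 4, dimnames = list(NULL, stages))
  M0 <- sum(masses[expressed1])
  A[expressed1, 1] <- masses[expressed1] / M0

  for (t in 1:3) {
    a_prev <- A[, t]
    a_new <- numeric(n)
    special <- logical(n)

    for (cl in c("up2_4", "up4_8", "up8", "down2_4", "down4_8", "down8")) {
      g <- roles[[t]][[cl]]
      if (length(g)) {
        a_new[g] <- a_prev[g] * draw_fold(cl, length(g))
        special[g] <- TRUE
      }
    }
    turn_on <- c(roles[[t]][["on"]], ss_idx[ss_stage == t + 1L])
    if (length(turn_on)) {
      a_new[turn_on] <- masses[turn_on] / M0
      special[turn_on] <- TRUE
    }
    turn_off <- c(roles[[t]][["off"]], ss_idx[ss_stage == t])
    special[turn_off] <- TRUE  # stays at zero

    s_special <- sum(a_new)
    if (s_special >= 1)
      stop("de_design too strong: designed abundances exceed the library at ",
           names(config$de_design)[t], call. = FALSE)
    carry <- which(a_prev > 0 & !special)
    s_carry <- sum(a_prev[carry])
    if (s_carry > 0)
      a_new[carry] <- a_prev[carry] * (1 - s_special) / s_carry
    A[, t + 1] <- a_new
  }

  out <- data.frame(gene_id = catalog$gene_id, A,
                    labels, stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[2:5] <- paste0("abund_", stages)
  attr(out, "stages") <- stages
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Per-transition truth label tallies
#'
#' @param truth A `truth_table`.
#' @return A table of label counts per transition (labels x transitions).
#' @export
truth_label_counts <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  lv <- c("none", unname(TRUTH_LABELS))
  sapply(c("class_T1", "class_T2", "class_T3"), function(cn)
    table(factor(truth[[cn]], levels = lv)))
}
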