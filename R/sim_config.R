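#' Default differential-expression design
#'
#' Per-transition fractions (of the whole gene catalog) assigned to each
#' fold-change class in each direction, plus genes switched fully on or off.
#' The defaults emulate the study conditions of a four-stage stipe
#' development series: the first transition is dominated by moderate
#' up-regulation, the second by strong down-regulation, and the third is more
#' balanced with a sizeable turned-on contingent.
#'
#' Class intervals are half-open on the fold scale: `2_4` is \[2,4), `4_8` is
#' \[4,8), `8` is \[8,Inf). `on`/`off` genes have zero abundance on one side
#' of the transition.
#'
#' @return Named list with elements `T1`, `T2`, `T3`, each a named numeric
#'   vector with entries `up2_4`, `up4_8`, `up8`, `down2_4`, `down4_8`,
#'   `down8`, `on`, `off`.
#' @export
default_de_design <- function() {
  list(
    T1 = c(up2_4 = 0.063, up4_8 = 0.017, up8 = 0.008,
           down2_4 = 0.012, down4_8 = 0.005, down8 = 0.002,
           on = 0.003, off = 0.0013),
    T2 = c(up2_4 = 0.035, up4_8 = 0.007, up8 = 0.003,
           down2_4 = 0.068, down4_8 = 0.047, down8 = 0.028,
           on = 0.002, off = 0.0117),
    T3 = c(up2_4 = 0.028, up4_8 = 0.011, up8 = 0.0126,
           down2_4 = 0.050, down4_8 = 0.020, down8 = 0.010,
           on = 0.0084, off = 0.004)
  )
}

DE_CLASSES <- c("up2_4", "up4_8", "up8", "down2_4", "down4_8", "down8",
                "on", "off")

#' Simulation configuration for a four-stage tag-DGE experiment
#'
#' Bundles all knobs of the synthetic-data generator: catalog size and gene
#' lengths, the four ordered stage labels, per-stage sequencing depths, the
#' per-base substitution error rate, the fraction of genes lacking a CATG
#' anchor, the differential-expression design, and the root seed from which
#' all component seeds are derived.
#'
#' @param n_genes Number of genes in the catalog.
#' @param gene_length_range Integer pair, minimum and maximum gene length in
#'   bp (minimum must be at least 30 so an anchored tag fits).
#' @param stages Ordered character vector of exactly four stage labels.
#' @param library_sizes Numeric vector of four per-stage library sizes
#'   (number of sequenced tags).
#' @param error_rate Per-base substitution probability, in \[0, 0.05\].
#' @param frac_no_catg Fraction in \[0,1) of genes built without any CATG
#'   site (these can never be expressed or detected).
#' @param de_design Per-transition class fractions, see
#'   [default_de_design()]. Fractions must sum to < 1 per transition.
#' @param stage_specific_frac Fraction of genes expressed in exactly one
#'   stage.
#' @param malformed_frac Fraction of simulated reads replaced by malformed
#'   records (adaptor-only or wrong-length) so the cleaning stage has work.
#' @param seed Integer root seed; component seeds are derived from it, see
#'   [derive_seed()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       gene_length_range = c(300L, 3000L),
                       stages = c("BU", "EG", "EL", "MA"),
                       library_sizes = rep(5e6, 4),
                       error_rate = 0.01,
                       frac_no_catg = 0.03,
                       de_design = default_de_design(),
                       stage_specific_frac = 0.02,
                       malformed_frac = 0.03,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  if (is.na(n_genes) || n_genes < 1L)
    stop("`n_genes` must be a positive integer", call. = FALSE)
  gene_length_range <- as.integer(gene_length_range)
  if (length(gene_length_range) != 2L || anyNA(gene_length_range))
    stop("`gene_length_range` must be an integer pair", call. = FALSE)
  if (gene_length_range[1] < 30L)
    stop("minimum gene length must be >= 30 bp (CATG + 17 bp must fit)",
         call. = FALSE)
  if (gene_length_range[1] > gene_length_range[2])
    stop("`gene_length_range`: min > max", call. = FALSE)
  if (length(stages) != 4L || anyDuplicated(stages))
    stop("`stages` must be exactly 4 distinct labels", call. = FALSE)
  if (length(library_sizes) != 4L || any(library_sizes < 1))
    stop("`library_sizes` must be 4 positive values", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.05)
    stop("`error_rate` must lie in [0, 0.05]", call. = FALSE)
  if (frac_no_catg < 0 || frac_no_catg >= 1)
    stop("`frac_no_catg` must lie in [0, 1)", call. = FALSE)
  if (stage_specific_frac < 0 || stage_specific_frac >= 1)
    stop("`stage_specific_frac` must lie in [0, 1)", call. = FALSE)
  if (malformed_frac < 0 || malformed_frac >= 1)
    stop("`malformed_frac` must lie in [0, 1)", call. = FALSE)
  if (!is.list(de_design) || length(de_design) != 3L)
    stop("`de_design` must be a list of 3 transitions", call. = FALSE)
  names(de_design) <- c("T1", "T2", "T3")
  for (tr in names(de_design)) {
    fr <- de_design[[tr]]
    if (!all(DE_CLASSES %in% names(fr)))
      stop("`de_design$", tr, "` must name all classes: ",
           paste(DE_CLASSES, collapse = ", "), call. = FALSE)
    fr <- fr[DE_CLASSES]
    if (any(fr < 0) || sum(fr) >= 1)
      stop("`de_design$", tr, "` fractions must be non-negative and sum to < 1",
           call. = FALSE)
    de_design[[tr]] <- fr
  }
  structure(list(
    n_genes = n_genes,
    gene_length_range = gene_length_range,
    stages = as.character(stages),
    library_sizes = as.numeric(library_sizes),
    error_rate = error_rate,
    frac_no_catg = frac_no_catg,
    de_design = de_design,
    stage_specific_frac = stage_specific_frac,
    malformed_frac = malformed_frac,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Derive a component seed from the root seed
#'
#' All randomness in the generator flows from one root seed. Components get
#' fixed offsets so that each piece (catalog, truth, per-stage libraries) is
#' independently reproducible: catalog uses the root itself, the truth uses
#' root + 1, and the library of stage i uses root + 10 + i. Results are
#' reduced mod 2^31 - 1 to stay within R's integer range.
#'
#' @param seed Integer root seed.
#' @param component One of `"catalog"`, `"truth"`, `"library"`.
#' @param stage_index Stage number (1-4), required for `"library"`.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, component = c("catalog", "truth", "library"),
                        stage_index = NULL) {
  component <- match.arg(component)
  off <- switch(component,
                catalog = 0L,
                truth = 1L,
                library = {
                  if (is.null(stage_index))
                    stop("`stage_index` required for library seeds", call. = FALSE)
                  10L + as.integer(stage_index)
                })
  as.integer((as.numeric(seed) + off) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Tag-DGE simulation config\n")
  cat("  genes:", x$n_genes, " lengths:", x$gene_length_range[1], "-",
      x$gene_length_range[2], "bp  no-CATG fraction:", x$frac_no_catg, "\n")
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  cat("  library sizes:", paste(format(x$library_sizes, big.mark = ","),
                                collapse = ", "), "tags\n")
  cat("  error rate:", x$error_rate, " malformed fraction:",
      x$malformed_frac, " seed:", x$seed, "\n")
  invisible(x)
}
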