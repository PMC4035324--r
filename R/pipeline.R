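#' Run the full tag-DGE pipeline
#'
#' Orchestrates simulate (optional) -> build reference -> clean -> quantify
#' -> expressed-set Venn -> DEG screen -> category aggregation, writing every
#' table under `out_dir` together with a JSON run manifest that records the
#' seed, thresholds and per-stage tallies. Reruns with the same configuration
#' and inputs are bit-identical.
#'
#' The configuration is a list with components:
#' \describe{
#'   \item{out_dir}{Output directory (created if missing).}
#'   \item{sim}{A [sim_config()]; when present the input data are simulated.}
#'   \item{catalog_fasta, reads}{Alternatively, a catalog FASTA path and a
#'     named list (by stage, in order) of FASTQ or tag-count TSV paths.}
#'   \item{category_map}{Optional gene-to-category TSV path.}
#'   \item{min_count, fdr, min_log2fc, quality_threshold,
#'     remove_singletons}{Thresholds; defaults 1, 0.001, 1, 10, TRUE.}
#' }
#'
#' @param config Configuration list (or path to a JSON file holding one).
#' @param quiet Suppress progress messages.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  say <- function(...) if (!quiet) message(...)
  min_count <- config$min_count %||% 1
  fdr <- config$fdr %||% 0.001
  min_log2fc <- config$min_log2fc %||% 1
  qthr <- config$quality_threshold %||% 10
  rm_single <- config$remove_singletons %||% TRUE
  if (fdr <= 0 || fdr > 1) stop("config: `fdr` must lie in (0, 1]", call. = FALSE)
  if (min_log2fc < 0) stop("config: `min_log2fc` must be >= 0", call. = FALSE)
  if (min_count < 1) stop("config: `min_count` must be >= 1", call. = FALSE)
  out_dir <- config$out_dir %||% stop("config: `out_dir` required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    say("simulate: generating catalog, truth and libraries")
    sim <- config$sim
    if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
    catalog <- step("simulate", generate_catalog(sim))
    truth <- step("simulate", generate_truth(sim, catalog))
    libs <- step("simulate", simulate_libraries(catalog, truth, sim))
    stages <- sim$stages
    write_catalog_fasta(catalog, file.path(out_dir, "catalog.fasta"))
    write_truth_tsv(truth, file.path(out_dir, "truth.tsv"))
  } else {
    say("load: reading catalog and reads")
    catalog <- step("load", read_catalog_fasta(config$catalog_fasta))
    stages <- names(config$reads)
    libs <- lapply(stages, function(s) {
      p <- config$reads[[s]]
      if (grepl("\\.(fq|fastq)$", p)) read_reads_fastq(p, library_id = s)
      else read_counts_tsv(p, library_id = s)
    })
    names(libs) <- stages
  }

  say("build-ref: extracting canonical tags")
  index <- step("build-ref", build_index(catalog))

  say("clean: filtering raw reads")
  cleaned <- lapply(stages, function(s)
    step("clean", clean_reads(libs[[s]], quality_threshold = qthr,
                              remove_singletons = rm_single,
                              library_id = s)))
  names(cleaned) <- stages

  say("quantify: mapping tags (<=1 mismatch) and computing TPM")
  profiles <- lapply(cleaned, function(cl)
    step("quantify", map_tags(cl$table, index)))
  for (s in stages) {
    write_counts_tsv(cleaned[[s]]$table,
                     file.path(out_dir, paste0("clean_tags_", s, ".tsv")))
    write_profile_tsv(profiles[[s]],
                      file.path(out_dir, paste0("profile_", s, ".tsv")))
  }
  mat <- expression_matrix(profiles, "tpm")
  utils::write.table(mat, file.path(out_dir, "tpm_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("venn: expressed-set partition")
  sets <- lapply(profiles, expressed_set, min_count = min_count)
  part <- step("venn", venn_partition(sets, attr(index, "genome_size")))
  pct <- percentages(part)
  utils::write.table(pct, file.path(out_dir, "venn_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("deg: screening successive transitions")
  transitions <- paste0("T", 1:3)
  degs <- list()
  summaries <- list()
  for (t in 1:3) {
    rec <- step("deg", screen(profiles[[stages[t]]], profiles[[stages[t + 1]]],
                              fdr = fdr, min_log2fc = min_log2fc,
                              min_count = min_count,
                              transition = transitions[t]))
    degs[[transitions[t]]] <- rec
    summaries[[transitions[t]]] <- summarize_transition(rec)
    utils::write.table(rec, file.path(out_dir,
                                      paste0("deg_", transitions[t], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cat_tables <- NULL
  if (!is.null(config$category_map)) {
    say("categories: aggregating functional annotation")
    cmap <- read_category_map(config$category_map)
    cat_tables <- lapply(degs, aggregate_categories, cmap = cmap)
    cat_tables <- filter_categories(cat_tables,
                                    min_total = config$category_min_total %||% 4)
    for (t in names(cat_tables))
      utils::write.table(cat_tables[[t]],
                         file.path(out_dir, paste0("categories_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tagdge")),
    stages = stages,
    thresholds = list(min_count = min_count, fdr = fdr,
                      min_log2fc = min_log2fc, quality_threshold = qthr,
                      remove_singletons = rm_single),
    seed = if (!is.null(config$sim)) config$sim$seed else NULL,
    cleaning = lapply(cleaned, function(cl) unclass(cl$stats)),
    mapping = lapply(profiles, function(p)
      c(p$tallies, total_clean = p$total_clean,
        genes_detected = sum(p$counts > 0))),
    expressed_union = attr(part, "union_size"),
    deg_totals = lapply(summaries, function(s)
      list(n_up = s$n_up, n_down = s$n_down, n_total = s$n_total,
           n_on = s$n_on, n_off = s$n_off))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: outputs in ", out_dir)
  invisible(list(manifest = manifest, index = index, profiles = profiles,
                 partition = part, degs = degs, summaries = summaries,
                 categories = cat_tables, truth = truth))
}
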