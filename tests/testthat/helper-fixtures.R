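# Fixture builders, all programmatic.

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# a random 21-mer tag: CATG + 17 random bases
rand_tag <- function(n = 1) {
  paste0("CATG", rand_dna(n, 17))
}

make_catalog <- function(sequences, gene_ids = sprintf("g%03d",
                                                       seq_along(sequences))) {
  out <- data.frame(gene_id = gene_ids, sequence = sequences,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

make_truth <- function(gene_ids, abund, stages = c("BU", "EG", "EL", "MA")) {
  out <- data.frame(gene_id = gene_ids, abund, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("abund_", stages)
  out$class_T1 <- out$class_T2 <- out$class_T3 <- "none"
  attr(out, "stages") <- stages
  class(out) <- c("truth_table", "data.frame")
  out
}

make_profile <- function(counts, total, library_id = "lib") {
  structure(list(library_id = library_id,
                 counts = counts,
                 tpm = counts * 1e6 / total,
                 total_clean = total,
                 tallies = list()),
            class = "expression_profile")
}

small_cfg <- function(...) {
  defaults <- list(n_genes = 250L, gene_length_range = c(80L, 300L),
                   library_sizes = rep(4e4, 4), error_rate = 0,
                   frac_no_catg = 0.04, stage_specific_frac = 0.02,
                   malformed_frac = 0, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# One shared full-scale synthetic experiment (four stages at recovery depth),
# computed once per test run and reused by the DEG-property and acceptance
# tests.
.shared_env <- new.env(parent = emptyenv())
shared_recovery_experiment <- function() {
  if (!is.null(.shared_env$exp)) return(.shared_env$exp)
  cfg <- sim_config(library_sizes = rep(2e6, 4), error_rate = 0,
                    malformed_frac = 0, seed = 42L)
  catalog <- generate_catalog(cfg)
  index <- build_index(catalog)
  truth <- generate_truth(cfg, catalog)
  libs <- simulate_libraries(catalog, truth, cfg, as_counts = TRUE)
  profiles <- lapply(cfg$stages, function(s)
    map_tags(clean_reads(libs[[s]], library_id = s)$table, index))
  names(profiles) <- cfg$stages
  degs <- lapply(1:3, function(t)
    screen(profiles[[cfg$stages[t]]], profiles[[cfg$stages[t + 1]]],
           transition = paste0("T", t)))
  names(degs) <- paste0("T", 1:3)
  .shared_env$exp <- list(cfg = cfg, catalog = catalog, index = index,
                          truth = truth, profiles = profiles, degs = degs)
  .shared_env$exp
}
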