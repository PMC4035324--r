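test_that("configuration validation rejects impossible designs", {
  expect_error(small_cfg(gene_length_range = c(20L, 100L)), ">= 30")
  expect_error(small_cfg(gene_length_range = c(400L, 100L)), "min > max")
  expect_error(small_cfg(error_rate = 0.2), "error_rate")
  expect_error(small_cfg(stages = c("A", "B", "C")), "4 distinct")
  heavy <- default_de_design()
  heavy$T2["down2_4"] <- 0.99
  expect_error(small_cfg(de_design = heavy), "sum to < 1")
})

test_that("catalog honours CATG composition and the no-CATG quota", {
  cfg <- small_cfg(n_genes = 100L, frac_no_catg = 0.1)
  cat_ <- generate_catalog(cfg)
  tags <- extract_canonical_tags(cat_$sequence)
  expect_equal(sum(is.na(tags)), 10L)
  expect_false(any(grepl("CATG", cat_$sequence[is.na(tags)], fixed = TRUE)))
  expect_true(all(nchar(tags[!is.na(tags)]) == 21L))
  L <- nchar(cat_$sequence)
  expect_true(all(L >= 80L & L <= 300L))

  one <- generate_catalog(small_cfg(n_genes = 1L, frac_no_catg = 0))
  expect_false(is.na(extract_canonical_tag(one$sequence)))
})

test_that("catalog, truth and reads are deterministic given the seed", {
  cfg <- small_cfg(seed = 99L)
  c1 <- generate_catalog(cfg)
  c2 <- generate_catalog(cfg)
  expect_identical(c1, c2)
  t1 <- generate_truth(cfg, c1)
  expect_identical(t1, generate_truth(cfg, c2))
  r1 <- simulate_library(c1, t1, "EG", 5000, error_rate = 0.02, seed = 3L,
                         malformed_frac = 0.05)
  r2 <- simulate_library(c1, t1, "EG", 5000, error_rate = 0.02, seed = 3L,
                         malformed_frac = 0.05)
  expect_identical(r1$reads, r2$reads)
})

test_that("truth labels tally to the designed counts (bookkeeping oracle)", {
  cfg <- small_cfg(n_genes = 600L, stage_specific_frac = 0, seed = 21L)
  cat_ <- generate_catalog(cfg)
  truth <- generate_truth(cfg, cat_)
  counts <- truth_label_counts(truth)
  n <- cfg$n_genes
  lab <- c(up2_4 = "up2-4", up4_8 = "up4-8", up8 = "up8+",
           down2_4 = "down2-4", down4_8 = "down4-8", down8 = "down8+",
           on = "on", off = "off")
  for (t in 1:3) {
    fr <- cfg$de_design[[t]]
    for (cl in names(lab))
      expect_equal(unname(counts[lab[[cl]], t]), floor(fr[[cl]] * n),
                   info = paste("T", t, cl))
  }
})

test_that("stage-specific genes appear in exactly one stage with on/off labels", {
  zero <- default_de_design()
  for (t in 1:3) zero[[t]][c("on", "off")] <- 0
  cfg <- small_cfg(n_genes = 500L, stage_specific_frac = 0.04,
                   de_design = zero, seed = 27L)
  truth <- generate_truth(cfg, generate_catalog(cfg))
  expr <- as.matrix(truth[, 2:5]) > 0
  single <- rowSums(expr) == 1
  expect_equal(sum(single), floor(0.04 * 500))
  ss_stage <- apply(expr[single, , drop = FALSE], 1, which)
  counts <- truth_label_counts(truth)
  for (t in 1:3) {
    expect_equal(unname(counts["on", t]), sum(ss_stage == t + 1))
    expect_equal(unname(counts["off", t]), sum(ss_stage == t))
  }
})

test_that("truth folds lie inside their labelled class interval (exhaustive)", {
  cfg <- small_cfg(n_genes = 800L, seed = 31L)
  truth <- generate_truth(cfg, generate_catalog(cfg))
  A <- as.matrix(truth[, 2:5])
  intervals <- list("up2-4" = c(2, 4), "up4-8" = c(4, 8), "up8+" = c(8, Inf),
                    "down2-4" = c(1 / 4, 1 / 2), "down4-8" = c(1 / 8, 1 / 4),
                    "down8+" = c(0, 1 / 8))
  for (t in 1:3) {
    cls <- truth[[paste0("class_T", t)]]
    fold <- A[, t + 1] / A[, t]
    for (lab in names(intervals)) {
      f <- fold[cls == lab]
      expect_true(all(f >= intervals[[lab]][1] - 1e-12 &
                        f < intervals[[lab]][2] + 1e-12),
                  info = paste("T", t, lab))
    }
    expect_true(all(A[cls == "on", t] == 0 & A[cls == "on", t + 1] > 0))
    expect_true(all(A[cls == "off", t] > 0 & A[cls == "off", t + 1] == 0))
    # non-DE expressed genes share one common abundance ratio
    none <- cls == "none" & A[, t] > 0 & A[, t + 1] > 0
    expect_lt(diff(range(fold[none])), 1e-9)
  }
  # conservation: per-stage abundances of expressed genes sum to one
  expect_true(all(abs(colSums(A) - 1) < 1e-9))
})

test_that("a degenerate all-zero design yields one shared abundance vector", {
  zero <- lapply(1:3, function(i) setNames(numeric(8), tagdge:::DE_CLASSES))
  cfg <- small_cfg(de_design = zero, stage_specific_frac = 0,
                   frac_no_catg = 0)
  truth <- generate_truth(cfg, generate_catalog(cfg))
  expect_true(all(truth$class_T1 == "none" & truth$class_T2 == "none" &
                    truth$class_T3 == "none"))
  A <- as.matrix(truth[, 2:5])
  expect_equal(A[, 2], A[, 1])
  expect_equal(A[, 4], A[, 1])
})

test_that("a single expressed gene yields size identical canonical reads", {
  cat_ <- make_catalog(paste0(strrep("A", 10), "CATG",
                              strrep("ACGTT", 4), "AG"))
  tag <- extract_canonical_tag(cat_$sequence)
  truth <- make_truth(cat_$gene_id, matrix(1, 1, 4))
  lib <- simulate_library(cat_, truth, "BU", 1000, error_rate = 0, seed = 1L)
  expect_length(lib$reads, 1000)
  expect_true(all(lib$reads == tag))
})

test_that("an expressed gene without a canonical tag aborts with its name", {
  cat_ <- make_catalog(c(paste0("AA", rand_tag(), "TT"), strrep("ACT", 30)),
                       gene_ids = c("good", "tagless"))
  truth <- make_truth(cat_$gene_id, matrix(0.5, 2, 4))
  expect_error(simulate_library(cat_, truth, "BU", 100, seed = 1L), "tagless")
})

test_that("observed tag frequencies converge to the truth abundances", {
  # multinomial sampling bound at depth 1e6, checked over 10 seeds
  cfg <- small_cfg(n_genes = 200L, frac_no_catg = 0, seed = 13L)
  cat_ <- generate_catalog(cfg)
  truth <- generate_truth(cfg, cat_)
  a <- truth$abund_BU
  tags <- extract_canonical_tags(cat_$sequence)
  truth_by_tag <- tapply(a[a > 0], tags[a > 0], sum)
  for (s in 1:10) {
    lib <- simulate_library(cat_, truth, "BU", 1e6, error_rate = 0,
                            seed = 100L + s, as_counts = TRUE)
    freq <- lib$counts / lib$total
    dev <- abs(freq[names(truth_by_tag)] - truth_by_tag)
    expect_lt(max(dev, na.rm = TRUE), 5e-3)
  }
})

test_that("per-base substitution rate matches the Bernoulli complement", {
  # expected fraction of reads with >= 1 substitution: 1 - (1-e)^21
  cat_ <- make_catalog(paste0("GG", rand_tag(), "AACC"))
  truth <- make_truth(cat_$gene_id, matrix(1, 1, 4))
  tag <- extract_canonical_tag(cat_$sequence)
  lib <- simulate_library(cat_, truth, "BU", 1e5, error_rate = 0.01,
                          seed = 7L)
  frac_mut <- mean(lib$reads != tag)
  expect_lt(abs(frac_mut - (1 - 0.99^21)), 0.01)
})
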