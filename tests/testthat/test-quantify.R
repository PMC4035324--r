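test_that("exact unique match counts to its gene with TPM scaling", {
  cat_ <- make_catalog(c(paste0("AA", rand_tag()), paste0("TT", rand_tag())))
  idx <- build_index(cat_)
  tag1 <- idx$tag[idx$gene_id == "g001"]
  prof <- map_tags(tag_counts(setNames(7L, tag1)), idx)
  expect_equal(unname(prof$counts["g001"]), 7)
  expect_equal(unname(prof$tpm["g001"]), 1e6)
  expect_equal(prof$tallies$exact_unique, 1L)

  # count 5 in a million clean tags -> tpm 5
  big <- tag_counts(setNames(c(5L, 999995L), c(tag1, idx$tag[2])))
  prof2 <- map_tags(big, idx)
  expect_equal(unname(prof2$tpm["g001"]), 5)
})

test_that("one-mismatch assignment is unambiguous-only with exact anchor", {
  base <- rand_dna(1, 17)
  v1 <- base; substr(v1, 3, 3) <- if (substr(base, 3, 3) == "A") "C" else "A"
  v2 <- base; substr(v2, 9, 9) <- if (substr(base, 9, 9) == "G") "T" else "G"
  cat_ <- make_catalog(c(paste0("AA", "CATG", v1), paste0("TT", "CATG", v2)))
  idx <- build_index(cat_)
  # observed tag at Hamming distance 1 from both genes' reference tags
  obs <- paste0("CATG", base)
  prof <- map_tags(tag_counts(setNames(4L, obs)), idx)
  expect_equal(prof$tallies$ambiguous_excluded, 1L)
  expect_true(all(prof$counts == 0))

  # one mismatch from a single gene: assigned
  v3 <- v1; substr(v3, 15, 15) <- if (substr(v1, 15, 15) == "T") "G" else "T"
  prof2 <- map_tags(tag_counts(setNames(3L, paste0("CATG", v3))), idx)
  expect_equal(unname(prof2$counts["g001"]), 3)
  expect_equal(prof2$tallies$mm1_unique, 1L)

  # anchor mismatch is never tolerated
  anchor_off <- paste0("CTTG", v1)
  prof3 <- map_tags(tag_counts(setNames(2L, anchor_off)), idx)
  expect_equal(prof3$tallies$unmapped, 1L)

  expect_error(map_tags(tag_counts(setNames(1L, "CATGAA")), idx),
               "length != 21")
})

test_that("mapping agrees with the exhaustive Hamming oracle", {
  set.seed(4)
  n_genes <- 120
  tags <- rand_tag(n_genes)
  tags[5] <- tags[6]  # a reference-side ambiguity
  cat_ <- make_catalog(paste0(rand_dna(n_genes, 8), tags))
  idx <- build_index(cat_)

  obs <- character(800)
  src <- sample(n_genes, 800, replace = TRUE)
  for (i in 1:800) {
    tg <- tags[src[i]]
    nmut <- sample(0:2, 1, prob = c(0.55, 0.35, 0.10))
    if (nmut > 0) {
      pos <- sample(1:21, nmut)
      for (p in pos) {
        cur <- substr(tg, p, p)
        substr(tg, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
    }
    obs[i] <- tg
  }
  obs <- unique(obs)
  got <- tagdge:::assign_tags(obs, idx)
  want <- oracle_assign(obs, idx)
  expect_identical(got$gene_id, want$gene_id)
  expect_identical(got$fate, want$fate)

  cnt <- tag_counts(setNames(sample(2:9, length(obs), replace = TRUE), obs))
  prof <- map_tags(cnt, idx)
  mapped <- !is.na(want$gene_id)
  oracle_counts <- tapply(as.numeric(cnt$counts[mapped]),
                          want$gene_id[mapped], sum)
  expect_equal(as.numeric(prof$counts[names(oracle_counts)]),
               as.numeric(oracle_counts))
  # tallies sum to the number of distinct observed tags
  expect_equal(sum(unlist(prof$tallies)), length(obs))
  # sum of TPM never exceeds a million, equality iff everything maps
  expect_lte(sum(prof$tpm), 1e6 + 1e-6)
  expect_equal(sum(prof$tpm),
               1e6 * sum(cnt$counts[mapped]) / cnt$total)
})

test_that("saturation is anchored at zero and at the full library", {
  cat_ <- make_catalog(paste0(rand_dna(40, 6), rand_tag(40)))
  idx <- build_index(cat_)
  set.seed(6)
  cnt <- tag_counts(setNames(sample(2:60, 40, replace = TRUE), idx$tag))
  prof <- map_tags(cnt, idx)
  sat <- saturation(cnt, idx, c(0, 50, 200, cnt$total), seed = 2L)
  expect_equal(sat$genes_detected[1], 0L)
  expect_equal(sat$genes_detected[nrow(sat)], sum(prof$counts > 0))
  expect_true(all(diff(sat$genes_detected) >= 0))
  expect_error(saturation(cnt, idx, cnt$total + 1), "depths")
})

test_that("detection probability follows the closed form 1-(1-p)^d", {
  # library with a wide range of known tag proportions; the expected number
  # of detected genes at depth d is sum_g 1-(1-p_g)^d (with-replacement
  # closed form, accurate for shallow subsamples of a deep library)
  cat_ <- make_catalog(paste0(rand_dna(60, 6), rand_tag(60)))
  idx <- build_index(cat_)
  set.seed(8)
  raw <- c(stats::rlnorm(60, meanlog = 4, sdlog = 1.5))
  cnt <- tag_counts(setNames(pmax(2L, as.integer(round(raw * 1e5 / sum(raw)))),
                             idx$tag))
  p <- cnt$counts / cnt$total
  depths <- c(500, 2000, 10000)
  det <- vapply(1:20, function(s)
    saturation(cnt, idx, depths, seed = s)$genes_detected, numeric(3))
  expected <- vapply(depths, function(d) sum(1 - (1 - p)^d), numeric(1))
  # mean per-gene detection deviation over 20 seeds within +-0.05
  expect_true(all(abs(rowMeans(det) - expected) / length(p) < 0.05))
})
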