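test_that("count test handles degenerate and textbook cases", {
  expect_equal(count_test(0, 0, 1e6, 1e6), 1.0)
  expect_equal(count_test(5, 5, 1e6, 1e6),
               oracle_count_test(5, 5, 1e6, 1e6), tolerance = 1e-10)
  expect_error(count_test(-1, 2, 10, 10), ">= 0")
  expect_error(count_test(1, 2, 0, 10), "> 0")
  p <- count_test(c(0, 3, 50), c(10, 3, 5), 1e6, 2e6)
  expect_true(all(p > 0 & p <= 1))
})

test_that("count test is exactly symmetric under swapping the libraries", {
  set.seed(3)
  for (i in 1:50) {
    x <- sample(0:500, 1); y <- sample(0:500, 1)
    N1 <- sample(c(1e5, 1e6, 2.3e6), 1); N2 <- sample(c(5e5, 1e6, 3e6), 1)
    expect_lt(abs(count_test(x, y, N1, N2) - count_test(y, x, N2, N1)),
              1e-12)
  }
  expect_lt(abs(count_test(3, 9, 1e6, 2e6) - count_test(9, 3, 2e6, 1e6)),
            1e-12)
})

test_that("count test matches direct tail summation on spot checks", {
  for (case in list(c(0, 7), c(12, 3), c(40, 90), c(200, 160))) {
    for (r in c(0.5, 1, 2)) {
      expect_equal(count_test(case[1], case[2], 1e6, r * 1e6),
                   oracle_count_test(case[1], case[2], 1e6, r * 1e6),
                   tolerance = 1e-10)
    }
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:5) {
    p <- stats::runif(sample(5:200, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("screening applies both thresholds with on/off classing", {
  genes <- sprintf("g%02d", 1:6)
  # g1: 3x up, strong counts; g2: on; g3: off; g4: big but <2-fold;
  # g5: 4x but underpowered; g6: unchanged
  e <- make_profile(setNames(c(100, 0, 50, 2000, 3, 500, 0), c(genes, "g07")),
                    total = 1e5, library_id = "BU")
  l <- make_profile(setNames(c(300, 50, 0, 2900, 12, 500, 0), c(genes, "g07")),
                    total = 1e5, library_id = "EG")
  rec <- screen(e, l, transition = "T1")
  expect_setequal(rec$gene_id, c("g01", "g02", "g03"))
  r1 <- rec[rec$gene_id == "g01", ]
  expect_equal(r1$direction, "up")
  expect_equal(r1$fc_class, "2-4")
  expect_equal(r1$log2fc, log2(3))
  expect_equal(rec$fc_class[rec$gene_id == "g02"], "on")
  expect_equal(rec$direction[rec$gene_id == "g02"], "up")
  expect_equal(rec$fc_class[rec$gene_id == "g03"], "off")
  expect_true(is.infinite(rec$log2fc[rec$gene_id == "g02"]))
  # all tested genes carry q >= p and the never-expressed gene is untested
  all_rec <- screen(e, l, keep_all = TRUE)
  expect_false("g07" %in% all_rec$gene_id)
  expect_true(all(all_rec$q_value >= all_rec$p_value - 1e-15))

  e2 <- make_profile(setNames(1:3, c("a", "b", "c")), 100)
  expect_error(screen(e2, e), "mismatched")
  expect_error(screen(e, l, fdr = 2), "fdr")
})

test_that("identical libraries yield an empty DEG list", {
  set.seed(12)
  cnt <- setNames(rpois(400, 40) + 1, sprintf("g%03d", 1:400))
  e <- make_profile(cnt, sum(cnt), "A")
  l <- make_profile(cnt, sum(cnt), "B")
  expect_equal(nrow(screen(e, l)), 0L)
})

test_that("transition summaries tally directions, classes and percentages", {
  mk <- function(n, direction, fc_class)
    data.frame(gene_id = sprintf("x%04d", seq_len(n)), transition = "T1",
               direction = direction, fc_class = fc_class,
               stringsAsFactors = FALSE)
  rec <- rbind(mk(723, "up", "2-4"), mk(200, "up", "4-8"),
               mk(57, "up", "8plus"), mk(37, "up", "on"),
               mk(163, "down", "2-4"), mk(40, "down", "4-8"),
               mk(17, "down", "8plus"), mk(15, "down", "off"))
  s <- summarize_transition(rec)
  expect_equal(s$n_up, 1017)
  expect_equal(s$n_down, 235)
  expect_equal(s$n_total, 1252)
  expect_equal(s$n_on, 37)
  expect_equal(s$n_off, 15)
  expect_equal(round(s$pct_up, 1), 81.2)
  cc <- s$class_counts
  expect_equal(cc$n[cc$direction == "up" & cc$fc_class == "2-4"], 723)

  empty <- summarize_transition(rec[0, ])
  expect_equal(empty$n_total, 0)
  rec2 <- rec; rec2$transition[1] <- "T2"
  expect_error(summarize_transition(rec2), "mix")
})

test_that("designed fold-change classes are recovered from deep libraries", {
  # >= 90% of recovered 8-or-more-fold truth DEGs must land in the 8plus
  # group of the standard accounting, which brackets on/off genes inside
  # the >= 8-fold class; boundary genes (true fold within half a class
  # width of 8) may shift one class down
  exp <- shared_recovery_experiment()
  truth <- exp$truth
  stages <- exp$cfg$stages
  A <- as.matrix(truth[, 2:5])
  for (t in 1:3) {
    cls <- truth[[paste0("class_T", t)]]
    rec <- exp$degs[[t]]
    strong <- which(cls %in% c("up8+", "down8+"))
    hit <- match(truth$gene_id[strong], rec$gene_id)
    found <- !is.na(hit)
    f_meas <- rec$fc_class[hit[found]]
    true_mag <- (A[strong, t + 1] / A[strong, t])[found]
    true_mag <- ifelse(true_mag < 1, 1 / true_mag, true_mag)
    ok <- f_meas %in% c("8plus", "on", "off") |
      (f_meas == "4-8" & true_mag < 8 * sqrt(2))
    expect_gt(mean(ok), 0.90)
    # moderate designed classes land in their own or an adjacent class
    tpm_earlier <- A[, t] * 1e6
    mid <- which(cls %in% c("up4-8", "down4-8") & tpm_earlier >= 20)
    hm <- match(truth$gene_id[mid], rec$gene_id)
    okmid <- rec$fc_class[hm[!is.na(hm)]] %in% c("2-4", "4-8", "8plus")
    expect_gt(mean(okmid), 0.95)
  }
})

test_that("mixed simulations keep the realized FDR small", {
  exp <- shared_recovery_experiment()
  truth <- exp$truth
  for (t in 1:3) {
    cls <- truth[[paste0("class_T", t)]]
    rec <- exp$degs[[t]]
    is_false <- cls[match(rec$gene_id, truth$gene_id)] == "none"
    fdr_hat <- sum(is_false) / max(nrow(rec), 1)
    expect_lte(fdr_hat, 0.05)
  }
})
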