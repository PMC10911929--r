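test_that("cell-line stratification applies the closed CN threshold", {
  cn <- matrix(c(2.4, 2.4, 1.8, 2.4,
                 2.0, 1.2, 1.0, NA),
               ncol = 2, dimnames = list(sprintf("L%d", 1:4),
                                         c("MYCN", "DDX1")))
  g <- classify_cell_lines(cn, "MYCN", "DDX1")
  expect_equal(g$coamp_ids, "L1")       # 2.4 and 2.0: both >= 2
  expect_equal(g$onc_only_ids, "L2")    # 2.4 but 1.2 < 2
  expect_equal(g$excluded$reason[g$excluded$id == "L3"], "not_amplified")
  expect_equal(g$excluded$reason[g$excluded$id == "L4"], "missing")
  # groups partition the matrix rows
  expect_setequal(c(g$coamp_ids, g$onc_only_ids, g$excluded$id), rownames(cn))
  expect_error(classify_cell_lines(cn, "MYCN", "NOSUCH"), "absent")
})

test_that("a planted shift is recovered with the smallest p and right size", {
  set.seed(101)
  groups <- make_two_arm_groups(10L)
  dep <- make_dep_matrix(10L, n_genes = 100L, sd = 0.1,
                         shifted = "DG0042", delta = 1)
  scr <- coamp_screen(dep, groups)
  res <- scr$results
  hit <- res[res$gene == "DG0042", ]
  expect_equal(hit$median_diff, -1, tolerance = 0.15)
  expect_equal(hit$p_value, min(res$p_value))
  expect_equal(hit$n_coamp, 10L)
  expect_equal(hit$n_onc_only, 10L)
  expect_true(all(res$q_value >= res$p_value))
})

test_that("identical arms give zero differences and p = 1", {
  groups <- make_two_arm_groups(4L)
  block <- matrix(stats::rnorm(4 * 20, 0, 1), 4, 20)
  dep <- rbind(block, block)
  dimnames(dep) <- list(sprintf("L%02d", 1:8), sprintf("DG%04d", 1:20))
  scr <- coamp_screen(dep, groups)
  expect_true(all(scr$results$median_diff == 0))
  expect_true(all(scr$results$p_value == 1))
})

test_that("genes under the minimum group size are skipped, not tested", {
  set.seed(7)
  groups <- make_two_arm_groups(3L)
  dep <- make_dep_matrix(3L, n_genes = 5L, sd = 0.5)
  dep[1:2, "DG0001"] <- NA  # only 1 coamp value left
  scr <- coamp_screen(dep, groups, min_group = 3L)
  expect_false("DG0001" %in% scr$results$gene)
  expect_true("DG0001" %in% scr$skipped_genes)
  expect_equal(nrow(scr$results), 4L)

  dep_all_na <- dep; dep_all_na[1:2, ] <- NA
  expect_error(coamp_screen(dep_all_na, groups, min_group = 3L),
               "insufficient stratification")
})

test_that("screen output is invariant to row and column order", {
  set.seed(23)
  groups <- make_two_arm_groups(5L)
  dep <- make_dep_matrix(5L, n_genes = 30L, sd = 0.3,
                         shifted = "DG0010", delta = 0.8)
  scr1 <- coamp_screen(dep, groups)
  perm <- dep[sample(nrow(dep)), sample(ncol(dep))]
  scr2 <- coamp_screen(perm, groups)
  r1 <- scr1$results[order(scr1$results$gene), ]
  r2 <- scr2$results[order(scr2$results$gene), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("null screens reject at the nominal rate", {
  set.seed(207)
  groups <- make_two_arm_groups(10L)
  dep <- make_dep_matrix(10L, n_genes = 2000L, sd = 0.3)
  scr <- coamp_screen(dep, groups)
  rate <- mean(scr$results$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lte(abs(rate - 0.05), 3 * se)
})

test_that("rejection rate grows with effect size and sample size", {
  set.seed(31)
  rate_at <- function(n, delta, reps = 200L) {
    mean(vapply(seq_len(reps), function(i) {
      x <- stats::rnorm(n, -delta, 1); y <- stats::rnorm(n, 0, 1)
      wilcoxon_rank_sum(x, y)$p_value < 0.05
    }, logical(1)))
  }
  by_delta <- vapply(c(0, 0.25, 0.5, 1), rate_at, numeric(1), n = 10L)
  expect_true(all(diff(by_delta) >= -0.05))  # non-decreasing up to MC noise
  expect_gt(by_delta[4], by_delta[1])
  by_n <- vapply(c(5L, 10L, 20L), function(n) rate_at(n, 0.5), numeric(1))
  expect_true(all(diff(by_n) >= -0.05))
  expect_gt(by_n[3], by_n[1])
})

test_that("BH at q < 0.1 controls the empirical FDR on mixed simulations", {
  set.seed(77)
  groups <- make_two_arm_groups(10L)
  n_genes <- 2000L
  true_idx <- sprintf("DG%04d", sample(n_genes, n_genes * 0.05))
  dep <- make_dep_matrix(10L, n_genes = n_genes, sd = 0.3,
                         shifted = true_idx, delta = 1)
  scr <- coamp_screen(dep, groups)
  disc <- scr$results$gene[scr$results$q_value < 0.1]
  if (length(disc) > 0) {
    fdr <- mean(!disc %in% true_idx)
    expect_lte(fdr, 0.15)
  }
  expect_gt(length(disc), 0)
})

test_that("multi-pair screening flags the pair with the planted target", {
  set.seed(55)
  lines <- sprintf("L%02d", 1:24)
  # three oncogene-passenger pairs with disjoint coamplified line sets
  cn <- matrix(1, 24, 6, dimnames = list(
    lines, c("ONC1", "PAS1", "ONC2", "PAS2", "ONC3", "PAS3")))
  cn[, c("ONC1", "ONC2", "ONC3")] <- 8
  cn[1:8, "PAS1"] <- 8; cn[9:16, "PAS2"] <- 8; cn[17:24, "PAS3"] <- 8
  dep <- matrix(stats::rnorm(24 * 50, 0, 0.2), 24, 50,
                dimnames = list(lines, sprintf("DG%04d", 1:50)))
  dep[1:8, "DG0007"] <- dep[1:8, "DG0007"] - 1.5  # collateral to ONC1-PAS1 only

  pairs <- data.frame(oncogene = c("ONC1", "ONC2", "ONC3", "ONC1"),
                      passenger = c("PAS1", "PAS2", "PAS3", "PAS1"))
  ss <- screen_all_oncogenes(cn, dep, pairs, min_group = 3L, alpha = 0.001)
  expect_length(ss$screens, 3L)  # duplicate pair deduplicated
  expect_equal(ss$n_significant_pairs, 1L)
  top <- ss$screens[["ONC1:PAS1"]]$results
  expect_equal(top$gene[which.min(top$p_value)], "DG0007")

  # tiny cohort: every pair untestable, reported rather than fatal
  tiny_cn <- cn[1:2, , drop = FALSE]
  tiny_dep <- dep[1:2, , drop = FALSE]
  ss2 <- screen_all_oncogenes(tiny_cn, tiny_dep, pairs, min_group = 3L)
  expect_length(ss2$screens, 0L)
  expect_length(ss2$untestable, 3L)
})
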