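test_that("segment status obeys the platform-specific cutoffs", {
  co <- platform_cutoffs()
  expect_equal(call_segment_status(1.6, "affymetrix", co), "amplified")
  expect_equal(call_segment_status(1.6, "agilent", co), "neutral")
  expect_equal(call_segment_status(-2.5, "illumina", co), "homozygous_deletion")
  expect_equal(call_segment_status(0.0, "nimblegen", co), "neutral")
  # closed comparison at the threshold; strict below -2
  expect_equal(call_segment_status(2.0, "agilent", co), "amplified")
  expect_equal(call_segment_status(-2.0, "illumina", co), "neutral")
  expect_equal(call_segment_status(0.7, "illumina", co), "amplified")
  expect_error(call_segment_status(1, "unknown-array",
                                   platform_cutoffs()), "unknown-array")
  expect_error(platform_cutoffs(agilent = -1), "positive")
  expect_error(platform_cutoffs(homdel = 1), "negative")
})

test_that("gene status comes from the maximum-overlap segment", {
  ann <- genome_annotation(data.frame(
    gene = "G1", chromosome = "1", start = 10001L, end = 60000L,
    stringsAsFactors = FALSE))
  # amplified overlap 10 kb, neutral overlap 40 kb -> neutral wins
  seg <- segment_set(data.frame(
    sample = "S1", chromosome = "1",
    start = c(1L, 20001L), end = c(20000L, 100000L),
    log2_ratio = c(2.5, 0), platform = "affymetrix",
    stringsAsFactors = FALSE))
  calls <- gene_level_calls(seg, ann)
  expect_equal(calls$calls$status, "neutral")
})

test_that("gene-level calls agree with a brute-force overlap oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n_genes <- 6L
    ann <- genome_annotation(data.frame(
      gene = sprintf("G%d", 1:n_genes), chromosome = "1",
      start = seq(1L, by = 50000L, length.out = n_genes),
      end = seq(30000L, by = 50000L, length.out = n_genes),
      stringsAsFactors = FALSE))
    # random non-overlapping segments for two samples
    segs <- do.call(rbind, lapply(c("S1", "S2"), function(smp) {
      cuts <- sort(sample(seq(1L, 400000L, by = 1000L), 4))
      data.frame(sample = smp, chromosome = "1",
                 start = c(cuts[1], cuts[2] + 1L, cuts[3] + 1L),
                 end = c(cuts[2], cuts[3], cuts[4]),
                 log2_ratio = round(stats::rnorm(3, 0, 2), 2),
                 platform = sample(c("affymetrix", "illumina"), 1),
                 stringsAsFactors = FALSE)
    }))
    seg <- segment_set(segs)
    calls <- gene_level_calls(seg, ann)$calls
    oracle <- brute_gene_status(seg, ann)
    key <- paste(calls$sample, calls$gene)
    expect_identical(calls$status,
                     oracle$status[match(key, paste(oracle$sample, oracle$gene))])
  }
})

test_that("genes with no overlapping segment are missing and counts partition", {
  ann <- toy_annotation()  # includes FAR1 on chromosome 3
  seg <- segment_set(data.frame(
    sample = c("S1", "S2"), chromosome = "2", start = 1L, end = 2000000L,
    log2_ratio = c(2.5, 0), platform = "affymetrix",
    stringsAsFactors = FALSE))
  calls <- gene_level_calls(seg, ann)$calls
  expect_equal(calls$status[calls$gene == "FAR1"], c("missing", "missing"))
  # per sample, statuses partition the annotated genes
  tab <- table(calls$sample)
  expect_true(all(tab == nrow(ann)))
  expect_error(gene_level_calls(seg, ann[0, ]), "empty")
})

test_that("calls are invariant under segment order permutation", {
  seg <- toy_cohort_segments()
  ann <- toy_annotation()
  shuffled <- segment_set(as.data.frame(seg)[c(4, 1, 6, 2, 5, 3), ])
  expect_identical(gene_level_calls(seg, ann)$calls,
                   gene_level_calls(shuffled, ann)$calls)
})

test_that("amplified segments merge across small gaps only, idempotently", {
  ann <- toy_annotation()
  mk <- function(gap) segment_set(data.frame(
    sample = "S1", chromosome = "2",
    start = c(100001L, 200001L + gap),
    end = c(200000L, 300000L + gap),
    log2_ratio = 2.5, platform = "affymetrix", stringsAsFactors = FALSE))

  near <- merge_amplified_intervals(gene_level_calls(mk(5000L), ann),
                                    gap_tolerance = 10000L)
  expect_equal(nrow(near$intervals), 1L)
  expect_equal(near$intervals$start, 100001L)
  expect_equal(near$intervals$end, 305000L)

  far <- merge_amplified_intervals(gene_level_calls(mk(50000L), ann),
                                   gap_tolerance = 10000L)
  expect_equal(nrow(far$intervals), 2L)

  # single amplified segment maps to itself
  single <- segment_set(data.frame(
    sample = "S1", chromosome = "2", start = 100001L, end = 200000L,
    log2_ratio = 2.5, platform = "affymetrix", stringsAsFactors = FALSE))
  iv <- merge_amplified_intervals(gene_level_calls(single, ann))$intervals
  expect_equal(iv[, c("start", "end")],
               data.frame(start = 100001L, end = 200000L))

  # idempotence: merged intervals are already maximal under the tolerance
  iv2 <- near$intervals
  remerged <- merge_amplified_intervals(near, gap_tolerance = 10000L)$intervals
  expect_identical(iv2, remerged)

  expect_error(merge_amplified_intervals(near, gap_tolerance = -1),
               "non-negative")
})

test_that("amplicon members split into oncogenes, passengers and orphans", {
  ann <- genome_annotation(data.frame(
    gene = c("DDX1", "NBAS", "MYCN"), chromosome = "2",
    start = c(400001L, 600001L, 1000001L),
    end = c(500000L, 700000L, 1100000L), stringsAsFactors = FALSE),
    oncogenes = "MYCN")
  seg <- segment_set(data.frame(
    sample = c("S1", "S2", "S3"), chromosome = "2",
    start = c(300001L, 350001L, 950001L),
    end = c(1200000L, 750000L, 1150000L),
    log2_ratio = 2.5, platform = "affymetrix", stringsAsFactors = FALSE))
  comp <- classify_passengers(
    merge_amplified_intervals(gene_level_calls(seg, ann)))

  s1 <- comp[comp$sample == "S1", ]
  expect_equal(s1$oncogene_members[[1]], "MYCN")
  expect_setequal(s1$passenger_members[[1]], c("DDX1", "NBAS"))
  expect_false(s1$orphan)

  s2 <- comp[comp$sample == "S2", ]  # passengers without the oncogene
  expect_true(s2$orphan)
  expect_length(s2$oncogene_members[[1]], 0L)

  s3 <- comp[comp$sample == "S3", ]  # oncogene alone
  expect_length(s3$passenger_members[[1]], 0L)
  expect_false(s3$orphan)

  expect_equal(attr(comp, "orphan_passenger_count"), 2L)
})

test_that("pre-labelled gene-level data bypasses the thresholds", {
  ann <- toy_annotation()
  m <- matrix(c(2, 0, 0, 0, -2, 1), 2, 3,
              dimnames = list(c("P1", "P2"), c("DDX1", "MYCN", "FAR1")))
  calls <- calls_from_labels(m, ann)$calls
  expect_equal(calls$status[calls$sample == "P1" & calls$gene == "DDX1"],
               "amplified")
  expect_equal(calls$status[calls$sample == "P1" & calls$gene == "FAR1"],
               "homozygous_deletion")
  expect_equal(calls$status[calls$sample == "P2" & calls$gene == "FAR1"],
               "neutral")
})
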