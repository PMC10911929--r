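# Shared fixtures and independent oracles. All fixtures are built in code at
# test time; the oracles deliberately avoid the code paths they check.

# --- independent oracles ----------------------------------------------------

# full label-enumeration oracle for the exact Wilcoxon rank-sum p-value:
# enumerate every assignment of nx pooled values to group x
enum_wilcox_p <- function(x, y, alternative = "two_sided") {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  labelings <- utils::combn(length(pooled), nx)
  u_null <- apply(labelings, 2L, u_of)
  p_le <- mean(u_null <= u_obs)
  p_ge <- mean(u_null >= u_obs)
  switch(alternative,
         two_sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# brute-force per-gene status oracle: loop over every segment, pick the one
# with the largest overlap (ties toward larger |log2 ratio|)
brute_gene_status <- function(seg, ann, cutoffs = platform_cutoffs()) {
  out <- expand.grid(sample = unique(seg$sample), gene = ann$gene,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$status <- vapply(seq_len(nrow(out)), function(i) {
    g <- ann[ann$gene == out$gene[i], ]
    best_ov <- 0; best_l2 <- NA; best_pf <- NA
    for (j in seq_len(nrow(seg))) {
      if (seg$sample[j] != out$sample[i] || seg$chromosome[j] != g$chromosome)
        next
      ov <- min(g$end, seg$end[j]) - max(g$start, seg$start[j]) + 1
      if (ov <= 0) next
      if (ov > best_ov ||
          (ov == best_ov && abs(seg$log2_ratio[j]) > abs(best_l2))) {
        best_ov <- ov; best_l2 <- seg$log2_ratio[j]; best_pf <- seg$platform[j]
      }
    }
    if (best_ov == 0) return("missing")
    call_segment_status(best_l2, best_pf, cutoffs)
  }, character(1))
  out
}

# direct combinatorial hypergeometric tail, independent of phyper
enum_hyper_p <- function(N, K, n, x) {
  k <- x:min(K, n)
  sum(choose(K, k) * choose(N - K, n - k)) / choose(N, n)
}

# --- fixtures ---------------------------------------------------------------

write_seg_file <- function(lines, path = tempfile(fileext = ".seg")) {
  writeLines(c("sample\tchromosome\tstart\tend\tnum.mark\tseg.mean", lines),
             path)
  path
}

# a two-gene chromosome-2 toy: MYCN-style oncogene with a DDX1-style
# passenger 0.5 Mb upstream
toy_annotation <- function() {
  genome_annotation(
    data.frame(gene = c("DDX1", "MYCN", "FAR1"),
               chromosome = c("2", "2", "3"),
               start = c(400001L, 1000001L, 100001L),
               end = c(500000L, 1100000L, 200000L),
               stringsAsFactors = FALSE),
    oncogenes = "MYCN")
}

# 4-sample cohort: S1 amplifies MYCN+DDX1, S2 amplifies MYCN alone,
# S3/S4 are neutral everywhere
toy_cohort_segments <- function() {
  segment_set(data.frame(
    sample = c("S1", "S1", "S2", "S2", "S3", "S4"),
    chromosome = c("2", "3", "2", "3", "2", "2"),
    start = c(300001L, 1L, 900001L, 1L, 1L, 1L),
    end = c(1200000L, 2000000L, 1200000L, 2000000L, 2000000L, 2000000L),
    log2_ratio = c(2.5, 0, 2.5, 0, 0, 0.1),
    platform = "affymetrix",
    stringsAsFactors = FALSE))
}

toy_composition <- function() {
  calls <- gene_level_calls(toy_cohort_segments(), toy_annotation())
  classify_passengers(merge_amplified_intervals(calls))
}

# dependency screen fixture with exactly n coamplified and n oncogene-only
# lines: copy number on the DepMap-like relative scale (diploid ~ 1)
make_two_arm_groups <- function(n_per_arm = 10L) {
  lines <- sprintf("L%02d", seq_len(2 * n_per_arm))
  cn <- cbind(ONC = rep(8, 2 * n_per_arm),
              PASS = rep(c(8, 1), each = n_per_arm))
  rownames(cn) <- lines
  classify_cell_lines(cn, "ONC", "PASS", cn_threshold = 2)
}

make_dep_matrix <- function(n_per_arm = 10L, n_genes = 100L, sd = 0.1,
                            shifted = character(), delta = 1) {
  lines <- sprintf("L%02d", seq_len(2 * n_per_arm))
  genes <- sprintf("DG%04d", seq_len(n_genes))
  dep <- matrix(stats::rnorm(length(lines) * n_genes, 0, sd),
                length(lines), n_genes, dimnames = list(lines, genes))
  coamp <- seq_len(n_per_arm)  # first arm, matching make_two_arm_groups()
  for (g in shifted) dep[coamp, g] <- dep[coamp, g] - delta
  dep
}
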