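# Synthetic tumor-cohort generator. Emulates the statistical structure the
# analysis assumes: oncogene-anchored amplicons of 1-3 Mb whose endpoints
# include a neighboring passenger gene with a controlled probability,
# platform log2-ratio noise, dosage-driven expression, and a cell-line
# dependency matrix with planted collateral dependency shifts in
# coamplified lines. Full ground truth is returned for recovery testing.

#' Simulation configuration
#'
#' Defaults mirror the cohort structure the pipeline is designed around:
#' an oncogene amplified in 43\% of samples (as MYCN is in ~238/556
#' neuroblastomas) with the primary passenger riding on the amplicon in
#' 58\% of amplified samples (as DDX1 does in ~138/238), amplicon widths
#' uniform on 1-3 Mb, and a CERES-like dependency matrix in which planted
#' collateral targets are shifted by \code{-delta} in coamplified lines.
#'
#' @param seed integer seed driving all randomness (mandatory).
#' @param n_samples tumor samples in the copy-number cohort.
#' @param n_chromosomes,genes_per_chromosome,gene_length,gene_spacing genome
#'   layout: genes of \code{gene_length} bp placed every \code{gene_spacing}
#'   bp (start to start) on each chromosome.
#' @param oncogene_index index (on chromosome 1) of the oncogene.
#' @param passenger_indices indices (chromosome 1) of passenger genes; the
#'   first is the primary passenger whose inclusion frequency is controlled.
#' @param f_amp probability a sample (or cell line) carries the oncogene
#'   amplification.
#' @param f_coamp probability the primary passenger is included on the
#'   amplicon, given amplification.
#' @param amplicon_width length-2 range (bp) of amplicon widths.
#' @param log2_amp_mean mean segment log2 ratio inside the amplicon.
#' @param log2_noise_sd segment log2-ratio noise standard deviation; either
#'   a scalar or a named vector per platform.
#' @param platform_mix named probability vector over profiling platforms.
#' @param n_lines cell lines in the dependency arm.
#' @param delta planted collateral dependency shift (subtracted from the
#'   dependency scores of planted targets in coamplified lines).
#' @param n_collateral_targets number of planted collateral target genes.
#' @param dep_noise_sd dependency-score noise standard deviation.
#' @param dosage_beta slope of expression on gene copy number.
#' @param expr_baseline,expr_noise_sd expression baseline and noise.
#' @param line_cn_noise_sd log2 copy-number noise for cell lines.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed,
                              n_samples = 200L,
                              n_chromosomes = 2L,
                              genes_per_chromosome = 25L,
                              gene_length = 1e5,
                              gene_spacing = 5e5,
                              oncogene_index = 10L,
                              passenger_indices = c(9L, 11L),
                              f_amp = 0.43,
                              f_coamp = 0.58,
                              amplicon_width = c(1e6, 3e6),
                              log2_amp_mean = 3,
                              log2_noise_sd = 0.1,
                              platform_mix = c(affymetrix = 0.25,
                                               nimblegen = 0.25,
                                               agilent = 0.25,
                                               illumina = 0.25),
                              n_lines = 40L,
                              delta = 1,
                              n_collateral_targets = 3L,
                              dep_noise_sd = 0.3,
                              dosage_beta = 0.5,
                              expr_baseline = 5,
                              expr_noise_sd = 1,
                              line_cn_noise_sd = 0.1) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  if (cfg$f_amp < 0 || cfg$f_amp > 1 || cfg$f_coamp < 0 || cfg$f_coamp > 1)
    stop("f_amp and f_coamp must lie in [0, 1]", call. = FALSE)
  if (length(cfg$amplicon_width) != 2L || any(cfg$amplicon_width <= 0) ||
      diff(cfg$amplicon_width) < 0)
    stop("amplicon_width must be a positive, ordered range", call. = FALSE)
  if (cfg$delta < 0) stop("delta must be non-negative", call. = FALSE)
  if (abs(sum(cfg$platform_mix) - 1) > 1e-8)
    stop("platform_mix must sum to 1", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# overlap (bp) of gene [gs, ge] with interval [a, b]
interval_overlap <- function(gs, ge, a, b) pmax(0, pmin(ge, b) - pmax(gs, a) + 1)

# zero-noise inclusion rule: the gene is called amplified iff its overlap
# with the amplicon exceeds its overlap with flanking neutral segments;
# overlap ties go to the amplified segment (larger |log2 ratio|)
gene_included <- function(gs, ge, a, b) {
  ov <- interval_overlap(gs, ge, a, b)
  glen <- ge - gs + 1
  ov > 0 & 2 * ov >= glen
}

#' Simulate a tumor cohort with planted coamplification structure
#'
#' Per sample, with probability \code{f_amp} an amplicon containing the
#' oncogene is placed: its width is uniform on \code{amplicon_width} and its
#' left endpoint uniform among positions keeping the oncogene inside;
#' endpoints are rejection-sampled against a Bernoulli(\code{f_coamp})
#' target so that the primary passenger is included with exactly that
#' probability. Segment log2 ratios are \code{log2_amp_mean} plus noise
#' inside the amplicon and pure noise outside; gene copy number is
#' \eqn{2 \cdot 2^{log2 ratio}}; expression follows a linear dosage model.
#' Cell lines are grouped (coamplified / oncogene-only / not amplified) with
#' the same frequencies, receive a DepMap-like relative copy-number matrix
#' (diploid around 1), and a dependency matrix in which the planted
#' collateral targets are shifted by \code{-delta} in coamplified lines.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return a \code{synthetic_cohort} list: \code{segments}
#'   (\code{segment_set}), \code{annotation}, \code{platform_map},
#'   \code{cn} (cohort linear copy number), \code{expression},
#'   \code{line_cn} (cell-line relative copy number), \code{dependency},
#'   \code{truth} (per-sample and per-line labels, planted targets) and the
#'   \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  set.seed(cfg$seed)

  m <- cfg$genes_per_chromosome
  n_genes <- cfg$n_chromosomes * m
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  chrom <- as.character(rep(seq_len(cfg$n_chromosomes), each = m))
  gstart <- rep((seq_len(m) - 1) * cfg$gene_spacing + 1, cfg$n_chromosomes)
  gend <- gstart + cfg$gene_length - 1
  chrom_len <- m * cfg$gene_spacing
  oncogene <- genes[cfg$oncogene_index]
  passengers <- genes[cfg$passenger_indices]
  primary <- passengers[1L]
  annotation <- genome_annotation(
    data.frame(gene = genes, chromosome = chrom, start = gstart, end = gend,
               strand = "+", stringsAsFactors = FALSE),
    oncogenes = oncogene)

  os <- gstart[cfg$oncogene_index]; oe <- gend[cfg$oncogene_index]
  ps <- gstart[cfg$passenger_indices[1L]]; pe <- gend[cfg$passenger_indices[1L]]
  # midpoint of the primary passenger must be reachable within the widest amplicon
  pm <- ps + ceiling((pe - ps + 1) / 2) - 1
  if (cfg$f_coamp > 0 &&
      (max(oe, pm) - min(os, pm) + 1) > cfg$amplicon_width[2L])
    stop("unachievable inclusion: primary passenger lies farther from the oncogene than the maximum amplicon width",
         call. = FALSE)

  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  platform <- sample(names(cfg$platform_mix), cfg$n_samples, replace = TRUE,
                     prob = cfg$platform_mix)
  noise_sd <- if (is.null(names(cfg$log2_noise_sd))) {
    rep(cfg$log2_noise_sd, cfg$n_samples)
  } else unname(cfg$log2_noise_sd[platform])

  amplified <- stats::runif(cfg$n_samples) < cfg$f_amp
  onc_chrom <- chrom[cfg$oncogene_index]
  on_onc_chrom <- chrom == onc_chrom

  seg_rows <- vector("list", cfg$n_samples)
  cn <- matrix(NA_real_, cfg$n_samples, n_genes,
               dimnames = list(samples, genes))
  amp_a <- rep(NA_real_, cfg$n_samples); amp_b <- rep(NA_real_, cfg$n_samples)
  incl <- matrix(FALSE, cfg$n_samples, length(passengers),
                 dimnames = list(samples, passengers))

  for (i in seq_len(cfg$n_samples)) {
    sd_i <- noise_sd[i]
    rows <- list()
    for (ch in unique(chrom)) {
      if (amplified[i] && ch == onc_chrom) {
        target <- stats::runif(1) < cfg$f_coamp
        ok <- FALSE
        for (iter in seq_len(10000L)) {
          w <- round(stats::runif(1, cfg$amplicon_width[1L],
                                  cfg$amplicon_width[2L]))
          a <- round(stats::runif(1, oe - w + 1, os))
          a <- max(1, min(a, os))
          b <- min(a + w - 1, chrom_len)
          if (b < oe) next
          if (gene_included(ps, pe, a, b) == target) { ok <- TRUE; break }
        }
        if (!ok)
          stop("unachievable inclusion target for the primary passenger",
               call. = FALSE)
        amp_a[i] <- a; amp_b[i] <- b
        l2 <- c(left = stats::rnorm(1, 0, sd_i),
                amp = cfg$log2_amp_mean + stats::rnorm(1, 0, sd_i),
                right = stats::rnorm(1, 0, sd_i))
        piece <- data.frame(
          sample = samples[i], chromosome = ch,
          start = c(if (a > 1) 1, a, if (b < chrom_len) b + 1),
          end = c(if (a > 1) a - 1, b, if (b < chrom_len) chrom_len),
          log2_ratio = c(if (a > 1) l2[["left"]], l2[["amp"]],
                         if (b < chrom_len) l2[["right"]]),
          stringsAsFactors = FALSE)
        rows[[ch]] <- piece
        # gene copy number on this chromosome: max-overlap piece wins
        gi <- which(on_onc_chrom)
        for (j in gi) {
          ovs <- interval_overlap(gstart[j], gend[j], piece$start, piece$end)
          l2rs <- piece$log2_ratio
          pick <- order(-ovs, -abs(l2rs))[1L]
          cn[i, j] <- 2 * 2^l2rs[pick]
        }
        incl[i, ] <- gene_included(gstart[cfg$passenger_indices],
                                   gend[cfg$passenger_indices], a, b)
      } else {
        l2 <- stats::rnorm(1, 0, sd_i)
        rows[[ch]] <- data.frame(sample = samples[i], chromosome = ch,
                                 start = 1, end = chrom_len, log2_ratio = l2,
                                 stringsAsFactors = FALSE)
        cn[i, chrom == ch] <- 2 * 2^l2
      }
    }
    seg_rows[[i]] <- do.call(rbind, rows)
  }
  seg_df <- do.call(rbind, seg_rows)
  seg_df$platform <- platform[match(seg_df$sample, samples)]
  segments <- segment_set(seg_df)

  expression <- cfg$expr_baseline + cfg$dosage_beta * cn +
    matrix(stats::rnorm(length(cn), 0, cfg$expr_noise_sd), nrow(cn))
  dimnames(expression) <- dimnames(cn)

  # cell lines: same amplification frequencies, DepMap-like relative CN
  lines <- sprintf("LINE%03d", seq_len(cfg$n_lines))
  line_amp <- stats::runif(cfg$n_lines) < cfg$f_amp
  line_coamp <- line_amp & (stats::runif(cfg$n_lines) < cfg$f_coamp)
  line_cn <- matrix(2^stats::rnorm(cfg$n_lines * n_genes, 0,
                                   cfg$line_cn_noise_sd),
                    cfg$n_lines, n_genes, dimnames = list(lines, genes))
  line_cn[line_amp, oncogene] <-
    2^(cfg$log2_amp_mean + stats::rnorm(sum(line_amp), 0, cfg$line_cn_noise_sd))
  line_cn[line_coamp, primary] <-
    2^(cfg$log2_amp_mean + stats::rnorm(sum(line_coamp), 0, cfg$line_cn_noise_sd))

  dependency <- matrix(stats::rnorm(cfg$n_lines * n_genes, 0, cfg$dep_noise_sd),
                       cfg$n_lines, n_genes, dimnames = list(lines, genes))
  eligible <- setdiff(genes, c(oncogene, passengers))
  targets <- if (cfg$n_collateral_targets > 0)
    sample(eligible, cfg$n_collateral_targets) else character()
  if (length(targets) && any(line_coamp))
    dependency[line_coamp, targets] <-
      dependency[line_coamp, targets] - cfg$delta

  attr(cn, "value_scale") <- "linear_cn"
  attr(expression, "value_scale") <- "expression"
  attr(line_cn, "value_scale") <- "linear_cn"
  attr(dependency, "value_scale") <- "dependency_score"

  truth <- list(
    samples = data.frame(sample = samples, platform = platform,
                         amplified = amplified,
                         coamplified = amplified & incl[, primary],
                         amplicon_start = amp_a, amplicon_end = amp_b,
                         stringsAsFactors = FALSE),
    passenger_inclusion = incl,
    lines = data.frame(line = lines,
                       group = ifelse(line_coamp, "coamp",
                                      ifelse(line_amp, "onc_only",
                                             "not_amplified")),
                       stringsAsFactors = FALSE),
    collateral_targets = targets,
    oncogene = oncogene, passengers = passengers, primary_passenger = primary)

  structure(list(segments = segments, annotation = annotation,
                 platform_map = stats::setNames(platform, samples),
                 cn = cn, expression = expression, line_cn = line_cn,
                 dependency = dependency, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "synthetic_cohort: %d samples (%d amplified, %d coamplified), %d genes, %d cell lines\n",
    nrow(tr$samples), sum(tr$samples$amplified), sum(tr$samples$coamplified),
    nrow(x$annotation), nrow(tr$lines)))
  cat(sprintf("  oncogene %s, primary passenger %s; %d planted collateral target(s); seed %d\n",
              tr$oncogene, tr$primary_passenger,
              length(tr$collateral_targets), x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the same formats the readers consume: SEG-style segments, BED
#' annotation, CSV matrices, a platform map and the ground-truth tables.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(segments = file.path(dir, "segments.seg"),
         genes = file.path(dir, "genes.bed"),
         platforms = file.path(dir, "platforms.tsv"),
         cn = file.path(dir, "cohort_cn.csv"),
         expression = file.path(dir, "expression.csv"),
         line_cn = file.path(dir, "line_cn.csv"),
         dependency = file.path(dir, "dependency.csv"),
         truth_samples = file.path(dir, "truth_samples.tsv"),
         truth_lines = file.path(dir, "truth_lines.tsv"))
  write_segments(cohort$segments, p[["segments"]])
  write_gene_annotation(cohort$annotation, p[["genes"]])
  utils::write.table(data.frame(sample = names(cohort$platform_map),
                                platform = cohort$platform_map),
                     p[["platforms"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix(cohort$cn, p[["cn"]])
  write_matrix(cohort$expression, p[["expression"]])
  write_matrix(cohort$line_cn, p[["line_cn"]])
  write_matrix(cohort$dependency, p[["dependency"]])
  utils::write.table(cohort$truth$samples, p[["truth_samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$lines, p[["truth_lines"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Recovery metrics against the planted truth
#'
#' Compares pipeline outputs computed on a synthetic cohort with the
#' cohort's ground truth: precision and recall of oncogene amplification
#' and of primary-passenger coamplification calls, the confusion of
#' cell-line group assignments, and the rank and rejection status of every
#' planted collateral target in the screen.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param calls optional \code{amplification_calls} computed on the
#'   cohort's segments.
#' @param groups optional \code{cell_line_groups} from the cohort's
#'   \code{line_cn}.
#' @param screen optional \code{coamp_screen} from the cohort's
#'   \code{dependency}.
#' @param alpha significance threshold used for target rejection status.
#' @return a \code{truth_report} list; precision/recall are \code{NA}
#'   (not applicable) when the truth or prediction set is empty.
#' @export
truth_report <- function(cohort, calls = NULL, groups = NULL, screen = NULL,
                         alpha = 0.05) {
  tr <- cohort$truth
  out <- list(alpha = alpha)

  if (!is.null(calls)) {
    cc <- calls$calls
    onc_amp <- cc$sample[cc$gene == tr$oncogene & cc$status == "amplified"]
    pas_amp <- cc$sample[cc$gene == tr$primary_passenger &
                           cc$status == "amplified"]
    pred_amp <- tr$samples$sample %in% onc_amp
    pred_coamp <- pred_amp & tr$samples$sample %in% pas_amp
    pr <- function(pred, truth) {
      tp <- sum(pred & truth)
      c(precision = if (sum(pred)) tp / sum(pred) else NA_real_,
        recall = if (sum(truth)) tp / sum(truth) else NA_real_)
    }
    out$amplification <- pr(pred_amp, tr$samples$amplified)
    out$coamplification <- pr(pred_coamp, tr$samples$coamplified)
  }

  if (!is.null(groups)) {
    pred <- rep("excluded", nrow(tr$lines))
    pred[tr$lines$line %in% groups$coamp_ids] <- "coamp"
    pred[tr$lines$line %in% groups$onc_only_ids] <- "onc_only"
    out$group_confusion <- table(truth = tr$lines$group, predicted = pred)
  }

  if (!is.null(screen)) {
    res <- screen$results
    if (length(tr$collateral_targets) == 0L) {
      out$targets <- NA  # recall not applicable: nothing planted
    } else {
      ranks <- rank(res$p_value, ties.method = "min")
      idx <- match(tr$collateral_targets, res$gene)
      out$targets <- data.frame(
        gene = tr$collateral_targets,
        median_diff = res$median_diff[idx],
        p_value = res$p_value[idx],
        rank = ranks[idx],
        is_min_p = !is.na(idx) & res$p_value[idx] <= min(res$p_value),
        significant = !is.na(idx) & res$p_value[idx] < alpha,
        stringsAsFactors = FALSE)
    }
  }
  structure(out, class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat("truth_report\n")
  if (!is.null(x$amplification))
    cat(sprintf("  amplification calls: precision %.3f, recall %.3f\n",
                x$amplification[["precision"]], x$amplification[["recall"]]))
  if (!is.null(x$coamplification))
    cat(sprintf("  coamplification calls: precision %.3f, recall %.3f\n",
                x$coamplification[["precision"]], x$coamplification[["recall"]]))
  if (!is.null(x$group_confusion)) {
    cat("  cell-line group confusion:\n")
    print(x$group_confusion)
  }
  if (!is.null(x$targets)) {
    if (identical(x$targets, NA)) {
      cat("  planted targets: none (recovery not applicable)\n")
    } else {
      cat("  planted collateral targets:\n")
      print(x$targets, row.names = FALSE)
    }
  }
  invisible(x)
}
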