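# Amplification calling from copy-number segments.
#
# Segment-level calls use platform-specific log2-ratio cutoffs chosen to
# separate high-level amplification from gain on each array type; segments
# below the homozygous-deletion threshold are called homozygously deleted.
# Gene-level status is inherited from the overlapping segment with the
# largest base-pair overlap; amplified segments separated by small gaps are
# merged into amplicon intervals whose gene members are then split into
# oncogenes and passengers.

#' Platform-specific amplification cutoffs
#'
#' Log2-ratio thresholds above which a segment is called high-level amplified,
#' per profiling platform, plus the homozygous-deletion threshold. Defaults:
#' 1.5 for Affymetrix and NimbleGen arrays, 2 for Agilent arrays, 0.7 for
#' Illumina arrays; segments with log2 ratio below -2 are called homozygous
#' deletion. Unknown platforms fall back to the \code{other} cutoff.
#'
#' @param affymetrix,nimblegen,agilent,illumina,other amplification thresholds
#'   (log2 ratio, must be positive).
#' @param homdel homozygous-deletion threshold (log2 ratio, must be negative);
#'   the comparison is strict (\code{log2_ratio < homdel}).
#' @return a \code{platform_cutoffs} list.
#' @examples
#' platform_cutoffs()
#' platform_cutoffs(illumina = 0.9)
#' @export
platform_cutoffs <- function(affymetrix = 1.5, nimblegen = 1.5, agilent = 2,
                             illumina = 0.7, other = 1.5, homdel = -2) {
  amp <- c(affymetrix = affymetrix, nimblegen = nimblegen, agilent = agilent,
           illumina = illumina, other = other)
  if (any(!is.finite(amp)) || any(amp <= 0))
    stop("amplification thresholds must be positive", call. = FALSE)
  if (!is.finite(homdel) || homdel >= 0)
    stop("homozygous-deletion threshold must be negative", call. = FALSE)
  structure(list(amplification = amp, homdel = homdel),
            class = "platform_cutoffs")
}

#' @export
print.platform_cutoffs <- function(x, ...) {
  cat("platform_cutoffs (log2 ratio):\n")
  cat(sprintf("  %-10s >= %.2f\n", names(x$amplification), x$amplification),
      sep = "")
  cat(sprintf("  homozygous deletion < %.2f\n", x$homdel))
  invisible(x)
}

#' Call the copy-number status of segments
#'
#' Amplified iff the log2 ratio is at or above the platform's threshold
#' (closed comparison); homozygous deletion iff strictly below the deletion
#' threshold; neutral otherwise.
#'
#' @param log2_ratio numeric vector of segment log2 ratios.
#' @param platform character vector (recycled) of platform labels.
#' @param cutoffs a \code{\link{platform_cutoffs}} object.
#' @return character vector of statuses: \code{"amplified"},
#'   \code{"neutral"} or \code{"homozygous_deletion"}.
#' @examples
#' call_segment_status(c(1.6, 1.6, -2.5), c("affymetrix", "agilent", "illumina"),
#'                     platform_cutoffs())
#' @export
call_segment_status <- function(log2_ratio, platform, cutoffs = platform_cutoffs()) {
  platform <- rep_len(as.character(platform), length(log2_ratio))
  unknown <- setdiff(unique(platform), names(cutoffs$amplification))
  if (length(unknown))
    stop("no cutoff for platform(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  thr <- unname(cutoffs$amplification[platform])
  ifelse(log2_ratio < cutoffs$homdel, "homozygous_deletion",
         ifelse(log2_ratio >= thr, "amplified", "neutral"))
}

segments_as_granges <- function(segments) {
  GenomicRanges::GRanges(
    seqnames = segments$chromosome,
    ranges = IRanges::IRanges(segments$start, segments$end),
    sample = segments$sample,
    log2_ratio = segments$log2_ratio,
    platform = segments$platform
  )
}

annotation_as_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    gene = annotation$gene
  )
}

#' Lift segment status to genes
#'
#' Each annotated gene inherits, per sample, the status of the overlapping
#' segment with the largest base-pair overlap; ties are broken toward the
#' segment with the larger absolute log2 ratio. Genes with no overlapping
#' segment in a sample are \code{"missing"}.
#'
#' @param segments a \code{\link{segment_set}}.
#' @param annotation a \code{\link{genome_annotation}}.
#' @param cutoffs a \code{\link{platform_cutoffs}} object.
#' @return an \code{amplification_calls} object: a list with a long-format
#'   \code{calls} data frame (sample, gene, status, log2_ratio), the cohort
#'   sample ids, the annotation and the cutoffs. Amplicon intervals are added
#'   by \code{\link{merge_amplified_intervals}}.
#' @export
gene_level_calls <- function(segments, annotation, cutoffs = platform_cutoffs()) {
  if (nrow(annotation) == 0L) stop("annotation is empty", call. = FALSE)
  samples <- sort(unique(segments$sample))

  seg_gr <- segments_as_granges(segments)
  gene_gr <- annotation_as_granges(annotation)
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gene_gr[q], seg_gr[s]))

  h <- data.frame(gene = annotation$gene[q],
                  sample = segments$sample[s],
                  overlap = ov,
                  log2_ratio = segments$log2_ratio[s],
                  platform = segments$platform[s],
                  stringsAsFactors = FALSE)
  h <- h[order(h$gene, h$sample, -h$overlap, -abs(h$log2_ratio)), ]
  h <- h[!duplicated(paste(h$gene, h$sample, sep = "\r")), ]
  h$status <- call_segment_status(h$log2_ratio, h$platform, cutoffs)

  # complete grid: absent (gene, sample) combinations are "missing"
  grid <- expand.grid(sample = samples, gene = annotation$gene,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$gene, grid$sample, sep = "\r")
  m <- match(key, paste(h$gene, h$sample, sep = "\r"))
  grid$status <- ifelse(is.na(m), "missing", h$status[m])
  grid$log2_ratio <- h$log2_ratio[m]

  structure(list(calls = grid, samples = samples, annotation = annotation,
                 cutoffs = cutoffs, segments = segments, intervals = NULL),
            class = "amplification_calls")
}

#' @export
print.amplification_calls <- function(x, ...) {
  tab <- table(factor(x$calls$status, levels = STATUS_LEVELS))
  cat(sprintf("amplification_calls: %d samples x %d genes\n",
              length(x$samples), nrow(x$annotation)))
  cat("  status counts: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  if (!is.null(x$intervals))
    cat(sprintf("  %d merged amplified interval(s)\n", nrow(x$intervals)))
  invisible(x)
}

#' Merge amplified segments into amplicon intervals
#'
#' Per sample and chromosome, amplified segments whose gap does not exceed
#' \code{gap_tolerance} are merged into a single interval; the interval's
#' member genes are the annotated genes overlapping the merged span. High-level
#' amplicons on arrays are often split by probe gaps; merging recovers the
#' contiguous amplicon (e.g. the 1-3 Mb region typically amplified around
#' MYCN in neuroblastoma).
#'
#' @param callset an \code{amplification_calls} object from
#'   \code{\link{gene_level_calls}}.
#' @param gap_tolerance maximum gap (bp) across which amplified segments are
#'   joined; non-negative. Default 10 kb.
#' @return the \code{callset} with an \code{intervals} data frame filled in
#'   (sample, chromosome, start, end, members as a list column).
#' @export
merge_amplified_intervals <- function(callset, gap_tolerance = 10000L) {
  if (!is.numeric(gap_tolerance) || gap_tolerance < 0)
    stop("gap_tolerance must be non-negative", call. = FALSE)
  segments <- callset$segments
  status <- call_segment_status(segments$log2_ratio, segments$platform,
                                callset$cutoffs)
  amp <- segments[status == "amplified", , drop = FALSE]

  rows <- list()
  for (smp in unique(amp$sample)) {
    a <- amp[amp$sample == smp, , drop = FALSE]
    gr <- GenomicRanges::reduce(segments_as_granges(a),
                                min.gapwidth = gap_tolerance + 1)
    rows[[smp]] <- data.frame(
      sample = smp,
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  }
  iv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), chromosome = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(iv) <- NULL

  ann <- callset$annotation
  iv$members <- lapply(seq_len(nrow(iv)), function(i) {
    ann$gene[ann$chromosome == iv$chromosome[i] &
               ann$start <= iv$end[i] & ann$end >= iv$start[i]]
  })
  callset$intervals <- iv
  callset$gap_tolerance <- gap_tolerance
  callset
}

#' Split amplicon members into oncogenes and passengers
#'
#' Flags every member gene of each merged amplified interval as oncogene or
#' passenger and marks intervals harboring no oncogene as orphan amplicons.
#' Passenger amplification essentially always rides along with an oncogene;
#' the cohort-wide count of passenger genes sitting on orphan amplicons is
#' exposed as the \code{orphan_passenger_count} attribute.
#'
#' @param callset an \code{amplification_calls} object with intervals filled
#'   (see \code{\link{merge_amplified_intervals}}).
#' @param annotation optional \code{genome_annotation}; defaults to the one
#'   stored in \code{callset}.
#' @return an \code{amplicon_composition} data frame: one row per interval
#'   with \code{oncogene_members} and \code{passenger_members} list columns
#'   and an \code{orphan} flag. Attributes carry the cohort samples, the
#'   per-gene status calls and the annotation for downstream summaries.
#' @export
classify_passengers <- function(callset, annotation = callset$annotation) {
  if (is.null(callset$intervals))
    stop("intervals not computed; run merge_amplified_intervals() first",
         call. = FALSE)
  iv <- callset$intervals
  onco <- annotation$gene[annotation$is_oncogene]
  iv$oncogene_members <- lapply(iv$members, intersect, x = onco)
  iv$passenger_members <- Map(setdiff, iv$members, iv$oncogene_members)
  iv$orphan <- lengths(iv$oncogene_members) == 0L
  comp <- iv[, c("sample", "chromosome", "start", "end",
                 "oncogene_members", "passenger_members", "orphan")]
  rownames(comp) <- NULL
  structure(comp,
            class = c("amplicon_composition", "data.frame"),
            samples = callset$samples,
            calls = callset$calls,
            annotation = annotation,
            orphan_passenger_count = sum(lengths(comp$passenger_members[comp$orphan])))
}

#' @export
print.amplicon_composition <- function(x, ...) {
  cat(sprintf(
    "amplicon_composition: %d interval(s) across %d sample(s); %d orphan; %d passenger amplification(s) on orphan amplicons\n",
    nrow(x), length(unique(x$sample)), sum(x$orphan),
    attr(x, "orphan_passenger_count")))
  invisible(x)
}

#' Amplification calls from pre-labelled gene-level data
#'
#' Some repositories distribute gene-level copy-number where high-level
#' amplification is already encoded as the discrete label 2 (and homozygous
#' deletion as -2). This loader bypasses the log2-ratio thresholds and takes
#' the labels as given.
#'
#' @param m samples-by-genes matrix of discrete labels.
#' @param annotation a \code{genome_annotation} covering the columns.
#' @param amplified_label,homdel_label labels mapped to amplified and
#'   homozygously deleted status; all other non-missing values are neutral.
#' @return an \code{amplification_calls} object (without intervals).
#' @export
calls_from_labels <- function(m, annotation, amplified_label = 2,
                              homdel_label = -2) {
  genes <- intersect(colnames(m), annotation$gene)
  if (length(genes) == 0L) stop("no annotated genes in matrix", call. = FALSE)
  grid <- expand.grid(sample = rownames(m), gene = annotation$gene,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  val <- ifelse(grid$gene %in% genes,
                m[cbind(grid$sample, grid$gene)], NA_real_)
  grid$status <- ifelse(is.na(val), "missing",
                        ifelse(val == amplified_label, "amplified",
                               ifelse(val == homdel_label,
                                      "homozygous_deletion", "neutral")))
  grid$log2_ratio <- NA_real_
  structure(list(calls = grid, samples = rownames(m), annotation = annotation,
                 cutoffs = NULL, segments = NULL, intervals = NULL),
            class = "amplification_calls")
}
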