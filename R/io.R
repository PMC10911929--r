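# Readers and writers for the tabular formats the pipeline touches:
# SEG-style segment tables, BED gene annotation, CSV sample-by-gene matrices,
# GMT gene-set collections and per-residue disorder tracks.
# Internal genomic coordinates are 1-based closed (the SEG dialect); BED's
# 0-based half-open coordinates are converted at the boundary.

new_segment_set <- function(df) {
  df <- df[, c("sample", "chromosome", "start", "end", "log2_ratio", "platform")]
  rownames(df) <- NULL
  class(df) <- c("segment_set", "data.frame")
  df
}

validate_segment_set <- function(df, lines = NULL) {
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$log2_ratio) |
                 df$start > df$end)
  if (length(bad)) {
    where <- if (is.null(lines)) bad[1L] else lines[bad[1L]]
    stop(sprintf("malformed segment on line %d (missing field or start > end)",
                 where), call. = FALSE)
  }
  # same-sample overlap check, per chromosome
  key <- split(seq_len(nrow(df)), paste(df$sample, df$chromosome, sep = "\r"))
  for (idx in key) {
    if (length(idx) < 2L) next
    o <- idx[order(df$start[idx])]
    prev_end <- df$end[o][-length(o)]
    next_start <- df$start[o][-1L]
    hit <- which(next_start <= prev_end)
    if (length(hit)) {
      i <- o[hit[1L]]; j <- o[hit[1L] + 1L]
      stop(sprintf(
        "overlapping segments for sample '%s' on chromosome %s: [%d, %d] and [%d, %d]",
        df$sample[i], df$chromosome[i], df$start[i], df$end[i],
        df$start[j], df$end[j]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a SEG-style copy-number segment file
#'
#' Reads a tab-delimited segment table (sample, chromosome, start, end,
#' log2 ratio; a \code{num.mark} column is tolerated and ignored), normalizes
#' chromosome names to a single dialect, and attaches a profiling platform to
#' every sample. Coordinates are interpreted as 1-based closed intervals.
#'
#' @param path path to the tab-delimited file (header required).
#' @param platform_map named character vector mapping sample id to platform
#'   (\code{"affymetrix"}, \code{"nimblegen"}, \code{"agilent"},
#'   \code{"illumina"} or \code{"other"}). Samples absent from the map are
#'   assigned \code{"other"}.
#' @param col_map optional named list of column-name synonyms, with elements
#'   \code{sample}, \code{chromosome}, \code{start}, \code{end},
#'   \code{log2_ratio}, each a character vector of acceptable header names.
#' @return a \code{segment_set}: a data frame with columns \code{sample},
#'   \code{chromosome}, \code{start}, \code{end}, \code{log2_ratio},
#'   \code{platform}.
#' @export
read_segments <- function(path, platform_map = character(),
                          col_map = NULL) {
  defaults <- list(
    sample     = c("sample", "sample_id", "id", "track"),
    chromosome = c("chromosome", "chrom", "chr"),
    start      = c("start", "loc.start", "start_pos", "chromstart"),
    end        = c("end", "loc.end", "end_pos", "chromend"),
    log2_ratio = c("log2_ratio", "seg.mean", "seg_mean", "log2ratio", "logratio")
  )
  for (nm in names(col_map %||% list())) defaults[[nm]] <- col_map[[nm]]

  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  idx <- vapply(defaults, function(s) match_column(names(raw), s), integer(1))
  missing_cols <- names(idx)[is.na(idx)]
  if (length(missing_cols))
    stop("segment file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  df <- data.frame(
    sample     = as.character(raw[[idx[["sample"]]]]),
    chromosome = normalize_chromosomes(raw[[idx[["chromosome"]]]]),
    start      = suppressWarnings(as.integer(raw[[idx[["start"]]]])),
    end        = suppressWarnings(as.integer(raw[[idx[["end"]]]])),
    log2_ratio = suppressWarnings(as.numeric(raw[[idx[["log2_ratio"]]]])),
    stringsAsFactors = FALSE
  )
  # data line i sits on file line i + 1 (header)
  validate_segment_set(df, lines = seq_len(nrow(df)) + 1L)

  platform_map <- unlist(platform_map)
  pf <- unname(platform_map[df$sample])
  pf[is.na(pf)] <- "other"
  bad_pf <- setdiff(unique(pf), PLATFORMS)
  if (length(bad_pf))
    stop("unknown platform(s): ", paste(bad_pf, collapse = ", "), call. = FALSE)
  df$platform <- pf
  new_segment_set(df)
}

#' Construct a segment set from a data frame
#'
#' @param df data frame with columns \code{sample}, \code{chromosome},
#'   \code{start}, \code{end}, \code{log2_ratio} and optionally
#'   \code{platform}.
#' @param platform_map named sample-to-platform vector used when \code{df}
#'   carries no platform column.
#' @return a \code{segment_set}.
#' @export
segment_set <- function(df, platform_map = character()) {
  df$chromosome <- normalize_chromosomes(df$chromosome)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (is.null(df$platform)) {
    pf <- unname(unlist(platform_map)[df$sample])
    pf[is.na(pf)] <- "other"
    df$platform <- pf
  }
  validate_segment_set(df)
  new_segment_set(df)
}

#' Write a segment set as SEG-style TSV
#'
#' @param x a \code{segment_set}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_segments <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("segment_set: %d segments, %d samples, %d chromosomes\n",
              nrow(x), length(unique(x$sample)),
              length(unique(x$chromosome))))
  NextMethod()
}

#' Read gene annotation from a BED file
#'
#' Loads a BED4+ file (chrom, start, end, name, and optionally score and
#' strand), converts the on-disk 0-based half-open coordinates to the internal
#' 1-based closed convention, and flags the provided oncogene symbols.
#'
#' @param path path to the BED file.
#' @param oncogenes character vector of oncogene symbols. Symbols not present
#'   in the BED raise a warning and are ignored.
#' @return a \code{genome_annotation}: a data frame with columns
#'   \code{gene}, \code{chromosome}, \code{start}, \code{end}, \code{strand},
#'   \code{is_oncogene}, sorted by position.
#' @export
read_gene_annotation <- function(path, oncogenes = character()) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L)
    stop("BED file must have at least 4 columns (chrom, start, end, name)",
         call. = FALSE)
  df <- data.frame(
    gene       = as.character(raw[[4L]]),
    chromosome = normalize_chromosomes(raw[[1L]]),
    start      = as.integer(raw[[2L]]) + 1L,  # 0-based half-open -> 1-based closed
    end        = as.integer(raw[[3L]]),
    strand     = if (ncol(raw) >= 6L) as.character(raw[[6L]]) else ".",
    stringsAsFactors = FALSE
  )
  genome_annotation(df, oncogenes = oncogenes)
}

#' Construct a genome annotation from a data frame
#'
#' @param df data frame with columns \code{gene}, \code{chromosome},
#'   \code{start}, \code{end} (1-based closed) and optionally \code{strand}.
#' @param oncogenes character vector of oncogene symbols.
#' @return a \code{genome_annotation}.
#' @export
genome_annotation <- function(df, oncogenes = character()) {
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbol(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "),
         call. = FALSE)
  if (any(df$start > df$end))
    stop("gene annotation has start > end", call. = FALSE)
  unknown <- setdiff(oncogenes, df$gene)
  if (length(unknown)) {
    warning("oncogene symbol(s) not in annotation, ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    oncogenes <- intersect(oncogenes, df$gene)
  }
  df$chromosome <- normalize_chromosomes(df$chromosome)
  df$strand <- df$strand %||% "."
  df$is_oncogene <- df$gene %in% oncogenes
  df <- df[order(df$chromosome, df$start, df$end),
           c("gene", "chromosome", "start", "end", "strand", "is_oncogene")]
  rownames(df) <- NULL
  class(df) <- c("genome_annotation", "data.frame")
  df
}

#' Write gene annotation as BED6
#'
#' Converts the internal 1-based closed coordinates back to BED's 0-based
#' half-open convention.
#'
#' @param x a \code{genome_annotation}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_gene_annotation <- function(x, path) {
  bed <- data.frame(x$chromosome, x$start - 1L, x$end, x$gene, 0L,
                    ifelse(x$strand %in% c("+", "-"), x$strand, "."))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes (%d oncogenes) on %d chromosome(s)\n",
              nrow(x), sum(x$is_oncogene), length(unique(x$chromosome))))
  NextMethod()
}

#' Read a samples-by-genes matrix from CSV
#'
#' First column holds the row ids (samples or cell lines), the header row the
#' gene symbols. Empty cells are read as missing values, which are kept
#' distinct from zero.
#'
#' @param path path to the CSV file.
#' @param value_scale one of \code{"linear_cn"}, \code{"log2_ratio"},
#'   \code{"dependency_score"}, \code{"expression"}, \code{"ic50"}.
#' @return a numeric matrix with a \code{value_scale} attribute.
#' @export
read_matrix <- function(path,
                        value_scale = c("linear_cn", "log2_ratio",
                                        "dependency_score", "expression",
                                        "ic50")) {
  value_scale <- match.arg(value_scale)
  raw <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  attr(m, "value_scale") <- value_scale
  m
}

#' Write a samples-by-genes matrix as CSV
#'
#' Missing values are written as empty cells.
#'
#' @param m numeric matrix with row and column names.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; set descriptions are kept in the
#'   \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s) in GMT", call. = FALSE)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Read a per-residue disorder-score track
#'
#' @param path two-column whitespace/tab-delimited file: residue index
#'   (1-based) and score. A header line is detected and skipped.
#' @return numeric vector of scores indexed by residue.
#' @export
read_disorder_track <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\\s+")[[1L]][1L])))
  tab <- utils::read.table(path, header = has_header)
  idx <- as.integer(tab[[1L]])
  if (!identical(idx, seq_along(idx)))
    stop("disorder track residues must be 1..L without gaps", call. = FALSE)
  as.numeric(tab[[2L]])
}

# TSV writer with "#"-prefixed metadata lines
write_tsv_with_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
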