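#' @keywords internal
"_PACKAGE"

STATUS_LEVELS <- c("amplified", "neutral", "homozygous_deletion", "missing")
PLATFORMS <- c("affymetrix", "nimblegen", "agilent", "illumina", "other")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome names to a single dialect
#'
#' Strips a leading \code{"chr"} prefix from autosomes and sex chromosomes so
#' that \code{"chr2"} and \code{"2"} refer to the same sequence. Mitochondrial
#' and alternate contigs are passed through verbatim.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector in the canonical (prefix-free) dialect.
#' @examples
#' normalize_chromosomes(c("chr2", "2", "chrX", "chrM_alt"))
#' @export
normalize_chromosomes <- function(chrom) {
  chrom <- as.character(chrom)
  stripped <- sub("^chr", "", chrom)
  canonical <- stripped %in% c(as.character(1:22), "X", "Y")
  ifelse(canonical, stripped, chrom)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
}

# pick the first matching column name from a synonym list; NA if absent
match_column <- function(cols, synonyms) {
  hit <- which(tolower(cols) %in% tolower(synonyms))
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}
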