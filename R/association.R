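# Correlation analyses linking passenger copy number to dependency scores
# or drug response (e.g. DDX1 copy number vs RAPTOR dependency, or vs
# rapamycin IC50).

#' Correlate copy number with response features across shared lines
#'
#' For each (copy-number gene, response feature) pair, restricts to the cell
#' lines shared between the two matrices, drops missing values pairwise, and
#' runs \code{\link{pearson_corr_test}}. Pairs with fewer than 3 complete
#' shared lines are skipped (recorded in the \code{skipped} attribute).
#'
#' @param cn samples-by-genes copy-number matrix.
#' @param response samples-by-features matrix (dependency scores, IC50s, ...)
#'   or a data frame with row names.
#' @param pairs data frame with columns \code{cn_gene} and \code{feature},
#'   or a list of length-2 character vectors.
#' @param sidedness passed to \code{\link{pearson_corr_test}}.
#' @return data frame with one row per computed pair: \code{cn_gene},
#'   \code{feature}, \code{r}, \code{p_value}, \code{n}.
#' @export
feature_correlation_table <- function(cn, response, pairs,
                                      sidedness = c("two_sided", "one_sided")) {
  sidedness <- match.arg(sidedness)
  if (is.data.frame(pairs))
    pairs <- Map(c, as.character(pairs$cn_gene), as.character(pairs$feature))
  response <- as.matrix(response)
  shared <- intersect(rownames(cn), rownames(response))

  rows <- list(); skipped <- character()
  for (pr in pairs) {
    key <- paste(pr, collapse = ":")
    if (!pr[1L] %in% colnames(cn) || !pr[2L] %in% colnames(response)) {
      skipped[key] <- "feature absent"
      message("skipping ", key, ": feature absent")
      next
    }
    x <- cn[shared, pr[1L]]; y <- response[shared, pr[2L]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) {
      skipped[key] <- sprintf("only %d shared line(s)", sum(ok))
      message("skipping ", key, ": ", skipped[key])
      next
    }
    ct <- pearson_corr_test(x[ok], y[ok], sidedness)
    rows[[key]] <- data.frame(cn_gene = pr[1L], feature = pr[2L],
                              r = ct$r, p_value = ct$p_value, n = ct$n,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cn_gene = character(), feature = character(), r = numeric(),
               p_value = numeric(), n = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "sidedness") <- sidedness
  out
}
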