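# Differential dependency screen: stratify CRISPR-screened cell lines by
# coamplification status of an oncogene-passenger pair and test every gene
# for a shift in dependency scores (CERES convention: more negative = more
# dependent) between the coamplified and oncogene-only arms.

#' Stratify cell lines by coamplification status
#'
#' A line is coamplified iff both the oncogene's and the passenger's
#' copy-number values are at or above the threshold (closed comparison);
#' oncogene-only iff the oncogene is at or above but the passenger below.
#' Lines without oncogene amplification are excluded (reason
#' \code{"not_amplified"}); lines missing copy number for either gene are
#' excluded (reason \code{"missing"}).
#'
#' @param cn samples-by-genes copy-number matrix (e.g. DepMap gene-level
#'   copy number), rows = cell lines.
#' @param oncogene,passenger gene symbols; both must be matrix columns.
#' @param cn_threshold amplification threshold applied to the matrix values
#'   as provided (default 2).
#' @return a \code{cell_line_groups} list: \code{coamp_ids},
#'   \code{onc_only_ids}, \code{excluded} (data frame of id and reason),
#'   plus the pair and threshold.
#' @export
classify_cell_lines <- function(cn, oncogene, passenger, cn_threshold = 2) {
  for (g in c(oncogene, passenger))
    if (!g %in% colnames(cn))
      stop(sprintf("gene '%s' absent from copy-number matrix", g),
           call. = FALSE)
  ids <- rownames(cn)
  co <- cn[, oncogene]; cp <- cn[, passenger]
  miss <- is.na(co) | is.na(cp)
  not_amp <- !miss & co < cn_threshold
  coamp <- !miss & co >= cn_threshold & cp >= cn_threshold
  onc_only <- !miss & co >= cn_threshold & cp < cn_threshold
  excluded <- rbind(
    data.frame(id = ids[miss], reason = rep("missing", sum(miss)),
               stringsAsFactors = FALSE),
    data.frame(id = ids[not_amp], reason = rep("not_amplified", sum(not_amp)),
               stringsAsFactors = FALSE))
  structure(list(coamp_ids = ids[coamp], onc_only_ids = ids[onc_only],
                 excluded = excluded, oncogene = oncogene,
                 passenger = passenger, cn_threshold = cn_threshold),
            class = "cell_line_groups")
}

#' @export
print.cell_line_groups <- function(x, ...) {
  cat(sprintf("cell_line_groups for %s-%s (CN >= %g):\n", x$passenger,
              x$oncogene, x$cn_threshold))
  cat(sprintf("  coamplified: %d, oncogene-only: %d, excluded: %d (%s)\n",
              length(x$coamp_ids), length(x$onc_only_ids), nrow(x$excluded),
              paste(sprintf("%s=%d", names(table(x$excluded$reason)),
                            table(x$excluded$reason)), collapse = ", ")))
  invisible(x)
}

#' Differential dependency screen between coamplified and oncogene-only lines
#'
#' For every gene with at least \code{min_group} non-missing dependency
#' scores in each arm, computes the difference of median dependency
#' (coamplified minus oncogene-only; negative = stronger dependency in
#' coamplified lines) and a Wilcoxon rank-sum p-value, with
#' Benjamini-Hochberg q-values across all tested genes. Nominal p-values are
#' retained alongside q.
#'
#' @param dep cell-lines-by-genes dependency-score matrix (CERES-like).
#' @param groups a \code{\link{classify_cell_lines}} result.
#' @param min_group minimum per-arm group size for a gene to be tested
#'   (default 3).
#' @return a \code{coamp_screen} object; its \code{results} data frame has
#'   one row per tested gene: \code{gene}, \code{median_diff},
#'   \code{p_value}, \code{q_value}, \code{n_coamp}, \code{n_onc_only}.
#'   Untested genes and cell lines absent from \code{dep} are recorded in
#'   \code{skipped_genes} and \code{dropped_lines}.
#' @seealso \code{\link{summary.coamp_screen}}, \code{\link{plot.coamp_screen}}
#' @export
coamp_screen <- function(dep, groups, min_group = 3L) {
  ids_c <- intersect(groups$coamp_ids, rownames(dep))
  ids_o <- intersect(groups$onc_only_ids, rownames(dep))
  dropped <- setdiff(c(groups$coamp_ids, groups$onc_only_ids), rownames(dep))
  if (length(dropped))
    message(length(dropped), " grouped line(s) absent from dependency matrix, dropped")

  genes <- colnames(dep)
  mc <- dep[ids_c, , drop = FALSE]
  mo <- dep[ids_o, , drop = FALSE]
  n_c <- colSums(!is.na(mc))
  n_o <- colSums(!is.na(mo))
  testable <- n_c >= min_group & n_o >= min_group
  if (!any(testable))
    stop("insufficient stratification: no gene has >= min_group scores in both arms",
         call. = FALSE)

  idx <- which(testable)
  md <- numeric(length(idx)); pv <- numeric(length(idx))
  for (k in seq_along(idx)) {
    j <- idx[k]
    xc <- mc[, j]; xc <- xc[!is.na(xc)]
    xo <- mo[, j]; xo <- xo[!is.na(xo)]
    md[k] <- stats::median(xc) - stats::median(xo)
    pv[k] <- wilcoxon_rank_sum(xc, xo)$p_value
  }
  res <- data.frame(gene = genes[idx], median_diff = md, p_value = pv,
                    q_value = bh_adjust(pv), n_coamp = n_c[idx],
                    n_onc_only = n_o[idx], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(results = res, groups = groups, min_group = min_group,
                 skipped_genes = genes[!testable], dropped_lines = dropped),
            class = "coamp_screen")
}

#' @export
print.coamp_screen <- function(x, ...) {
  g <- x$groups
  cat(sprintf("coamp_screen: %s-%s coamplified (n=%d) vs %s-only (n=%d)\n",
              g$passenger, g$oncogene,
              length(setdiff(g$coamp_ids, x$dropped_lines)),
              g$oncogene, length(setdiff(g$onc_only_ids, x$dropped_lines))))
  cat(sprintf("  %d gene(s) tested, %d skipped (group size < %d)\n",
              nrow(x$results), length(x$skipped_genes), x$min_group))
  top <- x$results[order(x$results$p_value), ]
  cat("  top genes by nominal p:\n")
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}

#' Summarize a dependency screen
#'
#' @param object a \code{coamp_screen}.
#' @param alpha nominal p-value threshold for the hit count (default 0.05).
#' @param ... unused.
#' @return data frame of tested genes sorted by p-value, with attributes
#'   \code{n_significant} (genes with \eqn{p < \alpha}) and \code{alpha}.
#' @method summary coamp_screen
#' @export
summary.coamp_screen <- function(object, alpha = 0.05, ...) {
  res <- object$results[order(object$results$p_value), ]
  rownames(res) <- NULL
  structure(res, n_significant = sum(res$p_value < alpha), alpha = alpha)
}

#' Volcano plot of a dependency screen
#'
#' Median dependency difference (coamplified minus oncogene-only) on the
#' x-axis against \eqn{-\log_{10}} nominal p on the y-axis; genes below
#' \code{alpha} with a negative shift (candidate collateral dependencies)
#' are highlighted.
#'
#' @param x a \code{coamp_screen}.
#' @param alpha highlight threshold on nominal p (default 0.05).
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{x}.
#' @method plot coamp_screen
#' @export
plot.coamp_screen <- function(x, alpha = 0.05, ...) {
  res <- x$results
  hit <- res$p_value < alpha & res$median_diff < 0
  graphics::plot(res$median_diff, -log10(res$p_value),
                 xlab = "median dependency difference (coamp - oncogene-only)",
                 ylab = expression(-log[10] ~ "nominal p"),
                 pch = 19, col = ifelse(hit, "red3", "grey50"), ...)
  graphics::abline(h = -log10(alpha), lty = 2, col = "grey30")
  if (any(hit))
    graphics::text(res$median_diff[hit], -log10(res$p_value[hit]),
                   res$gene[hit], pos = 4, cex = 0.7)
  invisible(x)
}

#' @method as.data.frame coamp_screen
#' @export
as.data.frame.coamp_screen <- function(x, ...) x$results

#' Screen many oncogene-passenger pairs
#'
#' Runs \code{\link{classify_cell_lines}} and \code{\link{coamp_screen}} for
#' every supplied pair (duplicates removed). Pairs whose stratification is
#' too small to test any gene are reported as untestable rather than failing
#' the run, mirroring screens restricted to oncogenes with sufficient
#' dependency information.
#'
#' @param cn copy-number matrix (lines x genes).
#' @param dep dependency matrix (lines x genes).
#' @param pairs data frame with columns \code{oncogene} and \code{passenger},
#'   or a list of length-2 character vectors.
#' @param cn_threshold,min_group see \code{\link{classify_cell_lines}} and
#'   \code{\link{coamp_screen}}.
#' @param alpha nominal significance threshold used for the per-pair hit
#'   count (default 0.05).
#' @return a \code{screen_set} list: \code{screens} (named
#'   \code{coamp_screen} list), \code{untestable} (named reasons),
#'   \code{n_significant_pairs} (pairs with at least one gene at
#'   \eqn{p < \alpha}) and \code{alpha}.
#' @export
screen_all_oncogenes <- function(cn, dep, pairs, cn_threshold = 2,
                                 min_group = 3L, alpha = 0.05) {
  if (is.data.frame(pairs)) {
    pairs <- Map(c, as.character(pairs$oncogene), as.character(pairs$passenger))
  }
  keys <- vapply(pairs, paste, character(1), collapse = ":")
  pairs <- pairs[!duplicated(keys)]
  names(pairs) <- keys[!duplicated(keys)]

  screens <- list(); untestable <- character()
  for (key in names(pairs)) {
    pr <- pairs[[key]]
    out <- tryCatch({
      grp <- classify_cell_lines(cn, pr[1L], pr[2L], cn_threshold)
      coamp_screen(dep, grp, min_group)
    }, error = function(e) conditionMessage(e))
    if (is.character(out)) untestable[key] <- out else screens[[key]] <- out
  }
  n_sig <- sum(vapply(screens, function(s) any(s$results$p_value < alpha),
                      logical(1)))
  structure(list(screens = screens, untestable = untestable,
                 n_significant_pairs = n_sig, alpha = alpha),
            class = "screen_set")
}

#' @export
print.screen_set <- function(x, ...) {
  cat(sprintf(
    "screen_set: %d pair(s) tested, %d untestable; %d pair(s) with >= 1 gene at p < %g\n",
    length(x$screens), length(x$untestable), x$n_significant_pairs, x$alpha))
  if (length(x$untestable))
    cat("  untestable: ", paste(names(x$untestable), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
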