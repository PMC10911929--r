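# Gene-set analyses for candidate collateral targets: one-sided
# hypergeometric over-representation and preranked permutation enrichment
# (weighted Kolmogorov-Smirnov running sum with a gene-label null).

#' Hypergeometric over-representation analysis
#'
#' One-sided (over-representation) hypergeometric test of the overlap
#' between a hit list and each gene set within a finite universe:
#' \eqn{p = \sum_{k \ge x} C(K,k) C(N-K, n-k) / C(N,n)} with
#' \eqn{N = |universe|}, \eqn{K = |set|}, \eqn{n = |hits|},
#' \eqn{x = |overlap|}. Hits and sets are restricted to the universe;
#' q-values are Benjamini-Hochberg across the collection.
#'
#' @param hits character vector of hit genes.
#' @param gene_sets named list of character vectors (a single unnamed
#'   character vector is treated as a one-set collection).
#' @param universe character vector, the background gene universe.
#' @return data frame with one row per set: \code{set}, \code{set_size},
#'   \code{n_hits}, \code{overlap}, \code{p_value}, \code{q_value}.
#' @examples
#' ora_hypergeometric(c("a", "b", "c"), list(S = c("a", "b", "c", "d", "e")),
#'                    letters[1:10])  # p = choose(5,3)/choose(10,3)
#' @export
ora_hypergeometric <- function(hits, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  hits <- intersect(unique(hits), universe)
  N <- length(universe); n <- length(hits)
  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    gs <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(gs); x <- length(intersect(hits, gs))
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, n_hits = n, overlap = x,
               p_value = p, stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res
}

# running-sum enrichment score for hit positions in a ranking of length N
# with scores s (sorted descending); weight exponent 1
gsea_es <- function(s, hit_idx) {
  N <- length(s)
  inhit <- logical(N); inhit[hit_idx] <- TRUE
  Nh <- sum(inhit); Nm <- N - Nh
  if (Nm == 0L) return(1)  # set spans the whole ranking (degenerate)
  w <- abs(s[inhit])
  if (sum(w) == 0) w <- rep(1, Nh)  # all-zero scores: fall back to uniform
  steps <- numeric(N)
  steps[inhit] <- w / sum(w)
  steps[!inhit] <- -1 / Nm
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Preranked permutation enrichment
#'
#' Weighted Kolmogorov-Smirnov enrichment of each gene set in a ranked list:
#' the running sum increments proportionally to \eqn{|score|} at set members
#' (weight exponent 1) and decrements uniformly at non-members; the
#' enrichment score ES is the maximum deviation. The null distribution comes
#' from \code{n_perm} random gene-label sets of equal size;
#' \eqn{NES = ES / mean(|null ES|)} over null scores of matching sign, and
#' the p-value is the fraction of same-sign null scores at least as extreme
#' (with add-one smoothing so that \eqn{p > 0}). Ties in the ranking are
#' broken by gene symbol, lexicographically, for determinism.
#'
#' @param scores named numeric vector of ranking scores (larger = higher in
#'   the list); finite.
#' @param gene_sets named list of character vectors (or one character
#'   vector). Each set must share at least one gene with the ranking.
#' @param n_perm number of label permutations (default 1000; below 100
#'   raises a warning).
#' @param seed optional integer seed for the permutation null.
#' @return data frame with one row per set: \code{set}, \code{size}
#'   (members present in the ranking), \code{ES}, \code{NES},
#'   \code{p_value}, \code{q_value}, \code{n_perm}.
#' @export
preranked_enrichment <- function(scores, gene_sets, n_perm = 1000L,
                                 seed = NULL) {
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (n_perm < 100L) warning("n_perm < 100: p-values will be coarse",
                             call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  ord <- order(-scores, names(scores))
  s <- unname(scores[ord]); genes <- names(scores)[ord]
  N <- length(s)

  res <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    hit_idx <- which(genes %in% gene_sets[[nm]])
    if (length(hit_idx) == 0L)
      stop(sprintf("gene set '%s' is disjoint from the ranking", nm),
           call. = FALSE)
    k <- length(hit_idx)
    es <- gsea_es(s, hit_idx)
    null_es <- vapply(seq_len(n_perm),
                      function(i) gsea_es(s, sample.int(N, k)), numeric(1))
    same <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    data.frame(set = nm, size = k, ES = es, NES = nes, p_value = p,
               n_perm = n_perm, stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res[, c("set", "size", "ES", "NES", "p_value", "q_value", "n_perm")]
}
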