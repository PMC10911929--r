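# Nomination of a candidate intrinsically disordered region from
# per-residue disorder-score tracks (e.g. PONDR and IUPred2A outputs):
# normalize and average the tracks, smooth with a least-squares polynomial,
# and report the longest contiguous run of residues whose fitted score
# clears a threshold.

#' Consensus of disorder-score tracks
#'
#' Min-max normalizes every track to [0, 1] and averages them per residue.
#' A constant track is degenerate under min-max normalization and maps to
#' all zeros.
#'
#' @param tracks a list of equal-length numeric vectors (one per predictor),
#'   or a single numeric vector.
#' @return numeric vector of consensus scores in [0, 1].
#' @export
consensus_track <- function(tracks) {
  if (!is.list(tracks)) tracks <- list(tracks)
  if (length(tracks) == 0L) stop("need at least one track", call. = FALSE)
  L <- length(tracks[[1L]])
  if (any(lengths(tracks) != L))
    stop("tracks differ in length", call. = FALSE)
  norm <- lapply(tracks, function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) rep(0, L) else (x - r[1L]) / (r[2L] - r[1L])
  })
  Reduce(`+`, norm) / length(norm)
}

#' Nominate a disordered region by polynomial modeling
#'
#' Fits a least-squares polynomial of the given degree to the per-residue
#' consensus scores and nominates the longest contiguous run of residues
#' (optionally restricted to a search window) whose fitted value is at or
#' above the threshold. Returns \code{NULL} when no residue qualifies.
#'
#' @param track numeric vector of per-residue scores (1-based residue
#'   index); length must exceed \code{degree + 1}.
#' @param degree polynomial degree (default 9, non-negative).
#' @param threshold fitted-score cutoff (default 0.5).
#' @param search_window optional integer pair \code{c(start, end)}
#'   restricting the nominated run (1-based, inclusive).
#' @return a \code{nominated_region} list with \code{start_aa},
#'   \code{end_aa}, \code{peak} (maximum fitted score inside the region),
#'   or \code{NULL}.
#' @export
nominate_region <- function(track, degree = 9L, threshold = 0.5,
                            search_window = NULL) {
  if (degree < 0) stop("degree must be non-negative", call. = FALSE)
  L <- length(track)
  if (L <= degree + 1L)
    stop("track shorter than degree + 2 residues", call. = FALSE)
  idx <- seq_len(L)
  fit <- if (degree == 0L) stats::lm(track ~ 1)
         else stats::lm(track ~ stats::poly(idx, degree))
  fitted_vals <- unname(stats::fitted(fit))

  ok <- fitted_vals >= threshold
  if (!is.null(search_window))
    ok <- ok & idx >= search_window[1L] & idx <= search_window[2L]
  if (!any(ok)) return(NULL)

  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  best <- cand[which.max(runs$lengths[cand])]  # longest run; first on ties
  region <- starts[best]:ends[best]
  structure(list(start_aa = starts[best], end_aa = ends[best],
                 peak = max(fitted_vals[region])),
            class = "nominated_region")
}

#' @export
print.nominated_region <- function(x, ...) {
  cat(sprintf("nominated region: residues %d-%d (peak fitted score %.3f)\n",
              x$start_aa, x$end_aa, x$peak))
  invisible(x)
}
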