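# Cohort-level coamplification statistics: how often an oncogene is
# amplified, how many passenger genes ride on its amplicon, and which
# passenger combinations co-occur (upset-style counts).

amplified_samples_for <- function(compositions, oncogene) {
  has_onc <- vapply(compositions$oncogene_members,
                    function(m) oncogene %in% m, logical(1))
  unique(compositions$sample[has_onc])
}

# per amplified sample, the passenger genes coamplified with `oncogene`:
# union over its oncogene-bearing intervals, by default restricted to
# passengers whose own gene-level status is amplified
passenger_sets_for <- function(compositions, oncogene,
                               require_amplified_status = TRUE) {
  amp_samples <- amplified_samples_for(compositions, oncogene)
  calls <- attr(compositions, "calls")
  out <- lapply(amp_samples, function(smp) {
    sel <- compositions$sample == smp &
      vapply(compositions$oncogene_members, function(m) oncogene %in% m,
             logical(1))
    pas <- unique(unlist(compositions$passenger_members[sel]))
    if (require_amplified_status && length(pas)) {
      ok <- calls$status[calls$sample == smp][match(
        pas, calls$gene[calls$sample == smp])] == "amplified"
      pas <- pas[ok]
    }
    pas
  })
  names(out) <- amp_samples
  out
}

#' Summarize coamplification for one oncogene across a cohort
#'
#' Computes the oncogene's amplification frequency, the mean number of
#' passenger genes coamplified per amplified sample, the coamplification
#' incidence (fraction of amplified samples carrying at least one passenger),
#' and the per-passenger coamplification fraction among amplified samples.
#' A sample counts as amplified iff some non-orphan amplicon interval
#' contains the oncogene; a sample with several such intervals contributes
#' the union of its passengers once.
#'
#' @param compositions an \code{amplicon_composition} from
#'   \code{\link{classify_passengers}}.
#' @param oncogene oncogene symbol (must be in the annotation).
#' @param require_amplified_status if \code{TRUE} (default), a passenger
#'   counts as coamplified only when its own gene-level status is amplified;
#'   if \code{FALSE}, any fragment overlap with the amplicon counts.
#' @return an \code{oncogene_coamp_summary} list with fields
#'   \code{n_samples}, \code{n_amplified}, \code{amplification_frequency},
#'   \code{mean_passenger_count}, \code{coamp_incidence} and
#'   \code{passenger_fraction} (named vector).
#' @export
summarize_cohort <- function(compositions, oncogene,
                             require_amplified_status = TRUE) {
  ann <- attr(compositions, "annotation")
  if (!oncogene %in% ann$gene)
    stop(sprintf("oncogene '%s' not in annotation", oncogene), call. = FALSE)
  samples <- attr(compositions, "samples")
  psets <- passenger_sets_for(compositions, oncogene,
                              require_amplified_status)
  n_amp <- length(psets)
  counts <- lengths(psets)
  pf <- if (n_amp > 0) sort(table(unlist(psets)) / n_amp, decreasing = TRUE)
        else table(character())
  structure(list(
    oncogene = oncogene,
    n_samples = length(samples),
    n_amplified = n_amp,
    amplification_frequency = if (length(samples)) n_amp / length(samples) else 0,
    mean_passenger_count = if (n_amp > 0) mean(counts) else 0,
    coamp_incidence = if (n_amp > 0) mean(counts > 0) else 0,
    passenger_fraction = stats::setNames(as.numeric(pf), names(pf))
  ), class = "oncogene_coamp_summary")
}

#' @export
print.oncogene_coamp_summary <- function(x, ...) {
  cat(sprintf("coamplification summary for %s\n", x$oncogene))
  cat(sprintf("  amplified: %d / %d samples (frequency %.3f)\n",
              x$n_amplified, x$n_samples, x$amplification_frequency))
  if (x$n_amplified == 0) {
    cat("  no amplified samples; passenger statistics reported as 0\n")
    return(invisible(x))
  }
  cat(sprintf("  mean passenger count: %.3f; coamp incidence: %.3f\n",
              x$mean_passenger_count, x$coamp_incidence))
  if (length(x$passenger_fraction)) {
    top <- utils::head(x$passenger_fraction, 10)
    cat("  top passenger fractions among amplified samples:\n")
    cat(sprintf("    %-12s %.3f\n", names(top), top), sep = "")
  }
  invisible(x)
}

#' Passenger-combination (upset) counts
#'
#' Assigns every sample amplified for the oncogene to exactly one subset of
#' the chosen passenger list -- the passengers it actually carries -- and
#' counts samples per subset, including empty subsets, so the counts
#' partition the amplified samples (as in an upset plot).
#'
#' @inheritParams summarize_cohort
#' @param passengers non-empty ordered character vector of passenger symbols.
#' @return a \code{combination_counts} data frame with one logical column per
#'   passenger and a \code{count} column; all \eqn{2^k} subsets are listed.
#'   The number of amplified samples is kept in the \code{n_amplified}
#'   attribute.
#' @export
combination_counts <- function(compositions, oncogene, passengers,
                               require_amplified_status = TRUE) {
  if (length(passengers) == 0L)
    stop("passengers must be non-empty", call. = FALSE)
  ann <- attr(compositions, "annotation")
  absent <- setdiff(passengers, ann$gene)
  if (length(absent))
    stop("passenger symbol(s) not in annotation: ",
         paste(absent, collapse = ", "), call. = FALSE)
  psets <- passenger_sets_for(compositions, oncogene,
                              require_amplified_status)
  k <- length(passengers)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- passengers
  keys <- apply(grid, 1L, function(r) paste(passengers[as.logical(r)],
                                            collapse = "+"))
  observed <- vapply(psets, function(p)
    paste(passengers[passengers %in% p], collapse = "+"), character(1))
  grid$count <- as.integer(table(factor(observed, levels = keys)))
  structure(grid, class = c("combination_counts", "data.frame"),
            n_amplified = length(psets), oncogene = oncogene)
}

#' @export
print.combination_counts <- function(x, ...) {
  cat(sprintf("passenger combination counts for %s (%d amplified samples)\n",
              attr(x, "oncogene"), attr(x, "n_amplified")))
  NextMethod()
}
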