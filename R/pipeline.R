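# End-to-end pipeline driver: executes the requested stages in dependency
# order (call -> summarize -> screen -> correlate), writes TSV outputs with
# "#"-prefixed metadata lines, and records a JSON run manifest (tool
# version, parameters, seed, input digests) from which every output is
# reproducible.

pkg_version <- function() as.character(utils::packageVersion("coamplikon"))

file_digests <- function(paths) {
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        logical(1))]
  if (!length(paths)) return(list())
  as.list(tools::md5sum(unlist(paths)))
}

#' Run the coamplification pipeline
#'
#' Executes the requested stages in dependency order and writes their
#' outputs to \code{out_dir}. \code{"call"} needs \code{seg}, \code{genes},
#' \code{oncogenes} and \code{platforms} in \code{config};
#' \code{"summarize"} needs \code{"call"} plus \code{oncogene} (and
#' optionally \code{passengers} for combination counts); \code{"screen"}
#' needs \code{cn}, \code{dep}, \code{oncogene} and \code{passenger}.
#' Inputs may be file paths or in-memory objects. Every output carries
#' metadata comment lines, and a JSON manifest with the tool version, full
#' parameter set, seed and input file digests is written alongside.
#'
#' @param config named list of inputs and parameters; recognised elements:
#'   \code{seg}, \code{genes}, \code{oncogenes} (character vector or file of
#'   symbols), \code{platforms} (named vector or two-column TSV),
#'   \code{gap} (bp, default 10000), \code{oncogene}, \code{passenger},
#'   \code{passengers}, \code{cn}, \code{dep}, \code{cn_threshold}
#'   (default 2), \code{min_group} (default 3).
#' @param stages character subset of \code{c("call", "summarize", "screen")}.
#' @param out_dir output directory.
#' @param seed integer recorded in the manifest and used for any stochastic
#'   stage.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, stages = c("call", "summarize", "screen"),
                         out_dir, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)

  meta <- c(sprintf("coamplikon %s", pkg_version()),
            sprintf("seed=%s", seed),
            sprintf("stages=%s", paste(stages, collapse = ",")))
  results <- list()

  load_or <- function(x, loader) if (is.character(x) && length(x) == 1L &&
                                       file.exists(x)) loader(x) else x

  if ("call" %in% stages) {
    need <- setdiff(c("seg", "genes", "oncogenes"), names(config))
    if (length(need))
      stop("stage 'call' is missing input(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    platforms <- config$platforms %||% character()
    if (is.character(platforms) && length(platforms) == 1L &&
        file.exists(platforms)) {
      tab <- utils::read.delim(platforms, stringsAsFactors = FALSE)
      platforms <- stats::setNames(tab[[2L]], tab[[1L]])
    }
    oncogenes <- config$oncogenes
    if (is.character(oncogenes) && length(oncogenes) == 1L &&
        file.exists(oncogenes))
      oncogenes <- readLines(oncogenes)
    segments <- load_or(config$seg, function(p) read_segments(p, platforms))
    annotation <- load_or(config$genes,
                          function(p) read_gene_annotation(p, oncogenes))
    calls <- gene_level_calls(segments, annotation,
                              config$cutoffs %||% platform_cutoffs())
    calls <- merge_amplified_intervals(calls, config$gap %||% 10000L)
    results$calls <- calls
    results$composition <- classify_passengers(calls)
    write_tsv_with_meta(calls$calls, file.path(out_dir, "calls.tsv"),
                        c(meta, sprintf("gap_tolerance=%s",
                                        config$gap %||% 10000L)))
    iv <- calls$intervals
    iv$members <- vapply(iv$members, paste, character(1), collapse = ",")
    write_tsv_with_meta(iv, file.path(out_dir, "amplicons.tsv"), meta)
  }

  if ("summarize" %in% stages) {
    if (is.null(results$composition))
      stop("stage 'summarize' requires stage 'call' outputs; run 'call' first",
           call. = FALSE)
    if (is.null(config$oncogene))
      stop("stage 'summarize' needs 'oncogene'", call. = FALSE)
    sm <- summarize_cohort(results$composition, config$oncogene)
    results$summary <- sm
    write_tsv_with_meta(
      data.frame(oncogene = sm$oncogene, n_samples = sm$n_samples,
                 n_amplified = sm$n_amplified,
                 amplification_frequency = sm$amplification_frequency,
                 mean_passenger_count = sm$mean_passenger_count,
                 coamp_incidence = sm$coamp_incidence),
      file.path(out_dir, "summary.tsv"), meta)
    if (!is.null(config$passengers)) {
      cc <- combination_counts(results$composition, config$oncogene,
                               config$passengers)
      results$combinations <- cc
      write_tsv_with_meta(as.data.frame(cc),
                          file.path(out_dir, "upset.tsv"),
                          c(meta, sprintf("n_amplified=%d",
                                          attr(cc, "n_amplified"))))
    }
  }

  if ("screen" %in% stages) {
    need <- setdiff(c("cn", "dep", "oncogene", "passenger"), names(config))
    if (length(need))
      stop("stage 'screen' is missing input(s): ",
           paste(need, collapse = ", "), call. = FALSE)
    cn <- load_or(config$cn, function(p) read_matrix(p, "linear_cn"))
    dep <- load_or(config$dep, function(p) read_matrix(p, "dependency_score"))
    groups <- classify_cell_lines(cn, config$oncogene, config$passenger,
                                  config$cn_threshold %||% 2)
    scr <- coamp_screen(dep, groups, config$min_group %||% 3L)
    results$groups <- groups
    results$screen <- scr
    write_tsv_with_meta(
      scr$results[order(scr$results$p_value), ],
      file.path(out_dir, "screen.tsv"),
      c(meta, sprintf("pair=%s:%s", config$oncogene, config$passenger),
        sprintf("cn_threshold=%s", config$cn_threshold %||% 2),
        sprintf("min_group=%s", config$min_group %||% 3L)))
  }

  manifest <- list(
    tool = "coamplikon", version = pkg_version(),
    stages = stages, seed = seed,
    parameters = config[vapply(config, function(x)
      is.atomic(x) && length(x) <= 100L, logical(1))],
    input_digests = file_digests(config[c("seg", "genes", "platforms",
                                          "cn", "dep")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
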