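#' Run the full clustering + aggregation pipeline
#'
#' Executes the complete two-step algorithm: read/validate the matrix,
#' build the entry distribution and the refined delta-quantile grids,
#' score all element pairs, form generator-based clusters, keep affine
#' clusters (scores strictly above `threshold`), fuse equal-score
#' overlapping clusters, aggregate them into the colored graph, and
#' rank the key aggregates. Deterministic: identical input yields
#' byte-identical outputs.
#'
#' As an optimization, the affinity threshold is applied to pair scores
#' before cluster construction; this is equivalent to building all
#' clusters and filtering afterwards because a cluster's common score
#' equals each of its pairs' scores.
#'
#' @param input a `clag_matrix`, or a path passed to [read_matrix()].
#' @param delta quantile width in (0, 1), conventionally a multiple of
#'   0.05. Controls how permissive "closeness" is.
#' @param threshold affinity cutoff in `[-1, 1)` for cluster scores
#'   (default 0: affine clusters).
#' @param symmetric `"auto"` enables symmetric mode exactly when the
#'   matrix is square with matching labels; `"on"`/`"off"` override
#'   (`"on"` errors on a non-square matrix).
#' @param transpose,force_square passed to [read_matrix()] when `input`
#'   is a path.
#' @param out_dir if non-NULL, output files are written there (see
#'   [write_outputs()]).
#' @param dump_scores keep the full pair-score table in the result (and
#'   write `pair_scores.tsv` when `out_dir` is set).
#' @param refine apply grid heterogeneity refinement (default TRUE).
#' @param verbose print run statistics.
#' @return a `clag_run` list: `matrix`, `grids`, `clusters` (ranked
#'   affine), `fused`, `graph`, `aggregates` (ranked), `symmetric_mode`,
#'   `counts` (clustered elements, clusters, key aggregates), and
#'   `scores` when `dump_scores = TRUE`.
#' @export
clag_run <- function(input, delta, threshold = 0,
                     symmetric = c("auto", "on", "off"),
                     transpose = FALSE, force_square = FALSE,
                     out_dir = NULL, dump_scores = FALSE,
                     refine = TRUE, verbose = FALSE) {
  symmetric <- match.arg(symmetric)
  stopifnot(delta > 0, delta < 1)
  if (threshold < -1 || threshold >= 1)
    stop("score threshold must lie in [-1, 1)")
  mat <- if (inherits(input, "clag_matrix")) input
         else read_matrix(input, transpose = transpose,
                          force_square = force_square)
  sym <- switch(symmetric,
                auto = mat$is_square,
                on = TRUE,
                off = FALSE)
  if (sym && !mat$is_square)
    stop("symmetric mode requires a square matrix with matching labels")

  dist <- extract_distribution(mat, symmetric_mode = sym)
  grids <- build_grids(dist, delta, refine = refine)
  scores <- score_all_pairs(mat, grids, symmetric_mode = sym)

  keep <- scores$s_env > threshold
  if (sym) keep <- keep & !is.na(scores$s_sym) & scores$s_sym > threshold
  affine_pairs <- scores[keep]
  data.table::setattr(affine_pairs, "M", attr(scores, "M"))
  data.table::setattr(affine_pairs, "G", attr(scores, "G"))

  clusters <- build_clusters(affine_pairs, mat, symmetric_mode = sym)
  clusters <- affine_filter(clusters, threshold, symmetric_mode = sym)
  clusters <- rank_clusters(clusters, symmetric_mode = sym)
  fused <- fuse_equal_score(clusters, symmetric_mode = sym)
  graph <- aggregate_clusters(fused)
  aggregates <- rank_aggregates(graph)

  counts <- list(
    clustered_elements = length(unique(unlist(clusters$members))),
    clusters = nrow(clusters),
    key_aggregates = nrow(aggregates))
  if (verbose) {
    message(sprintf(
      "clag: %d x %d matrix%s, delta=%g, threshold=%g", nrow(mat$values),
      ncol(mat$values), if (sym) " (symmetric)" else "", delta, threshold))
    message(sprintf(
      "clag: 0-grid %d intervals%s, 1-grid %d intervals%s",
      length(grids$grid0$starts),
      if (grids$grid0$refined) " (refined)" else "",
      length(grids$grid1$starts),
      if (grids$grid1$refined) " (refined)" else ""))
    message(sprintf(
      "clag: %d clustered elements, %d affine clusters, %d key aggregates",
      counts$clustered_elements, counts$clusters, counts$key_aggregates))
  }
  run <- structure(list(matrix = mat, grids = grids, clusters = clusters,
                        fused = fused, graph = graph,
                        aggregates = aggregates, symmetric_mode = sym,
                        delta = delta, threshold = threshold,
                        counts = counts,
                        scores = if (dump_scores) scores else NULL),
                   class = "clag_run")
  if (!is.null(out_dir)) {
    write_outputs(clusters, aggregates, graph, out_dir, matrix = mat)
    if (dump_scores) write_pair_scores(scores, mat, out_dir)
  }
  run
}

write_pair_scores <- function(scores, mat, out_dir) {
  path <- file.path(out_dir, "pair_scores.tsv")
  labels <- mat$element_labels
  writeLines(c("v\tz\tK\ts_env\ts_sym",
               paste(labels[scores$v], labels[scores$z], scores$k_close,
                     format_num(scores$s_env), format_num(scores$s_sym),
                     sep = "\t")), path)
  invisible(path)
}

#' Parameter sweep over delta and threshold
#'
#' Runs the pipeline for every (delta, threshold) combination and
#' tabulates how many elements cluster and how many key aggregates
#' form. A plateau in these counts across consecutive delta values is
#' the usual criterion for choosing delta.
#'
#' @param input matrix or path, as in [clag_run()].
#' @param deltas non-empty numeric vector of delta values.
#' @param thresholds numeric vector of score thresholds (default 0).
#' @param ... further arguments passed to [clag_run()].
#' @return a `data.table` with columns `delta`, `threshold`,
#'   `clustered_elements`, `clusters`, `key_aggregates`.
#' @export
clag_sweep <- function(input, deltas, thresholds = 0, ...) {
  if (length(deltas) == 0L) stop("empty delta list")
  mat <- if (inherits(input, "clag_matrix")) input else read_matrix(input)
  grid <- expand.grid(threshold = thresholds, delta = deltas)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run <- clag_run(mat, delta = grid$delta[i],
                    threshold = grid$threshold[i], ...)
    data.table::data.table(delta = grid$delta[i],
                           threshold = grid$threshold[i],
                           clustered_elements = run$counts$clustered_elements,
                           clusters = run$counts$clusters,
                           key_aggregates = run$counts$key_aggregates)
  })
  data.table::rbindlist(rows)
}

#' @export
print.clag_run <- function(x, ...) {
  cat(sprintf(paste0(
    "clag_run: delta=%g, threshold=%g%s\n",
    "  %d clustered elements, %d affine clusters, %d key aggregates\n"),
    x$delta, x$threshold,
    if (x$symmetric_mode) ", symmetric mode" else "",
    x$counts$clustered_elements, x$counts$clusters,
    x$counts$key_aggregates))
  invisible(x)
}
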