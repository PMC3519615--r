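#' Generate a Gaussian-cluster benchmark dataset
#'
#' Emulates the multidimensional Gaussian benchmark: `n_points` vectors
#' in `dim` dimensions organized in `n_clusters` isotropic Gaussian
#' clusters. Cluster centers are drawn uniformly in a box of side
#' `3 * separation` per coordinate and accepted by rejection so that all
#' pairwise center distances are at least `separation`; points are
#' assigned to clusters in equal-sized blocks (remainder to the last)
#' and drawn N(center, sd^2 I). The default `separation = 10 * sd`
#' mirrors the well-separated regime. Fully reproducible from `seed`
#' (the caller's RNG state is untouched).
#'
#' The returned matrix has dimensions as characters (rows) and points
#' as elements (columns), ready for [clag_run()].
#'
#' @param n_points number of points (default 1024).
#' @param n_clusters number of clusters (default 16).
#' @param dim dimensionality (default 32).
#' @param sd within-cluster standard deviation per coordinate.
#' @param separation minimum Euclidean distance between centers.
#' @param seed integer RNG seed.
#' @return a `clag_synth` list: `matrix` (a `clag_matrix`),
#'   `true_labels` (named integer vector, one per element), `centers`,
#'   `params`.
#' @export
generate_gaussian <- function(n_points = 1024L, n_clusters = 16L,
                              dim = 32L, sd = 1, separation = 10 * sd,
                              seed = 1L) {
  stopifnot(n_points >= n_clusters, n_clusters >= 1L,
            sd > 0, separation > 0)
  # seed the generation locally; the caller's RNG state is untouched
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  centers <- base::matrix(NA_real_, n_clusters, dim)
  placed <- 0L
  tries <- 0L
  while (placed < n_clusters) {
    if (tries > 1000L * n_clusters)
      stop("could not place ", n_clusters, " centers at separation ",
           separation, "; box too crowded")
    cand <- stats::runif(dim, 0, 3 * separation)
    ok <- placed == 0L ||
      all(sqrt(rowSums((centers[seq_len(placed), , drop = FALSE] -
                          rep(cand, each = placed))^2)) >= separation)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    tries <- tries + 1L
  }
  block <- n_points %/% n_clusters
  labels <- rep(seq_len(n_clusters), times = c(
    rep(block, n_clusters - 1L), n_points - block * (n_clusters - 1L)))
  pts <- centers[labels, , drop = FALSE] +
    base::matrix(stats::rnorm(n_points * dim, 0, sd), n_points, dim)
  values <- t(pts)  # dim x n_points: characters are dimensions
  elem <- sprintf("p%0*d", nchar(n_points), seq_len(n_points))
  chars <- sprintf("d%0*d", nchar(dim), seq_len(dim))
  dimnames(values) <- list(chars, elem)
  names(labels) <- elem
  structure(list(matrix = as_clag_matrix(values),
                 true_labels = labels, centers = centers,
                 params = list(n_points = n_points,
                               n_clusters = n_clusters, dim = dim,
                               sd = sd, separation = separation,
                               seed = seed)),
            class = "clag_synth")
}

#' Write a synthetic dataset as TSV
#'
#' Emits the matrix (same dialect as [read_matrix()] expects) and a
#' two-column labels table.
#'
#' @param synth a `clag_synth` from [generate_gaussian()].
#' @param out_dir output directory.
#' @return invisibly, the files written.
#' @export
write_synth <- function(synth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  m <- synth$matrix$values
  mat_path <- file.path(out_dir, "synthetic_matrix.tsv")
  writeLines(c(paste(c("", colnames(m)), collapse = "\t"),
               paste(rownames(m),
                     apply(m, 1L, function(r)
                       paste(format_num(r), collapse = "\t")),
                     sep = "\t")), mat_path)
  lab_path <- file.path(out_dir, "synthetic_labels.tsv")
  writeLines(c("element\tcluster",
               paste(names(synth$true_labels), synth$true_labels,
                     sep = "\t")), lab_path)
  invisible(c(mat_path, lab_path))
}

#' Score cluster recovery against ground truth
#'
#' Maps each key aggregate to its majority true cluster and counts
#' errors as unclustered points plus points whose aggregate's majority
#' label differs from their own (the misclassified + unclassified
#' convention). The mapping is invariant to label permutation.
#'
#' @param aggregates ranked key-aggregate table ([rank_aggregates()]).
#' @param truth a `clag_synth`, or a named integer vector of true labels.
#' @return list: `errors`, `n_aggregates`, `n_unclustered`,
#'   `n_misclassified`.
#' @export
recovery_errors <- function(aggregates, truth) {
  labels <- if (inherits(truth, "clag_synth")) truth$true_labels
            else truth
  clustered <- unlist(aggregates$members)
  mis <- 0L
  for (mem in aggregates$members) {
    lab <- labels[mem]
    maj <- names(which.max(table(lab)))
    mis <- mis + sum(lab != as.integer(maj))
  }
  uncl <- length(labels) - length(clustered)
  list(errors = mis + uncl, n_aggregates = nrow(aggregates),
       n_unclustered = uncl, n_misclassified = mis)
}
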