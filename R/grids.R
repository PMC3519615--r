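#' Extract the sorted entry distribution of a data matrix
#'
#' Pools all matrix entries into a sorted multiset, the basis for the
#' delta-quantile grids. In symmetric (square) mode the diagonal entries
#' are excluded: self-scores are not pairwise signals and would distort
#' the quantiles. Ties are ordered by original matrix position
#' (row-major), so duplicated values keep a stable, deterministic rank.
#'
#' Each matrix cell is assigned a rank in the distribution. Excluded
#' diagonal cells receive a clamped insertion rank (the number of
#' distribution entries less than or equal to the value, at least 1) so
#' that they can still be located on the grids when a pair comparison
#' touches them.
#'
#' @param matrix a `clag_matrix` (see [read_matrix()]).
#' @param symmetric_mode logical; exclude the diagonal (square mode).
#' @return a `clag_distribution`: list with `sorted_entries`, `T` (entry
#'   count), and `rank_matrix` (integer matrix of per-cell ranks).
#' @export
extract_distribution <- function(matrix, symmetric_mode = FALSE) {
  stopifnot(inherits(matrix, "clag_matrix"))
  v <- matrix$values
  M <- nrow(v); N <- ncol(v)
  include <- base::matrix(TRUE, M, N)
  if (symmetric_mode) {
    if (!matrix$is_square)
      stop("symmetric mode requires a square matrix with matching labels")
    diag(include) <- FALSE
  }
  idx <- which(include)
  if (length(idx) < 2L)
    stop("distribution needs at least 2 entries")
  rows <- ((idx - 1L) %% M) + 1L
  cols <- ((idx - 1L) %/% M) + 1L
  rowmajor <- (rows - 1L) * N + cols
  o <- order(v[idx], rowmajor, method = "radix")
  sorted <- v[idx][o]
  rank_matrix <- base::matrix(NA_integer_, M, N,
                              dimnames = dimnames(v))
  rank_matrix[idx[o]] <- seq_along(o)
  if (symmetric_mode) {
    dg <- diag(v)
    r <- findInterval(dg, sorted)
    rank_matrix[cbind(seq_len(M), seq_len(N))] <- pmin.int(
      pmax.int(r, 1L), length(sorted))
  }
  structure(list(sorted_entries = sorted, T = length(sorted),
                 rank_matrix = rank_matrix),
            class = "clag_distribution")
}

#' Delta-quantile starting at a given rank
#'
#' The delta-quantile starting at entry rank `start_rank` covers
#' `ceiling(delta * T)` consecutive ranks, truncated at the tail of the
#' distribution ("largest set" semantics at the boundary).
#'
#' @param start_rank integer rank in `1..T`.
#' @param dist a `clag_distribution`.
#' @param delta quantile width in (0, 1).
#' @return integer vector `c(first_rank, last_rank)`.
#' @export
delta_quantile <- function(start_rank, dist, delta) {
  Tn <- dist$T
  stopifnot(start_rank >= 1L, start_rank <= Tn, delta > 0, delta < 1)
  q <- ceiling(delta * Tn)
  c(start_rank, min(Tn, start_rank + q - 1L))
}

# interval sizes for a grid: offset 0 segments the distribution in
# delta-quantiles from rank 1; offset 1 starts with a (delta/2)-quantile,
# so its first and last intervals are half-width.  The final interval
# absorbs the remainder.
grid_sizes <- function(Tn, delta, offset) {
  q <- ceiling(delta * Tn)
  stopifnot(q >= 1L, q <= Tn)
  sizes <- integer(0)
  rem <- Tn
  if (offset == 1L) {
    h <- min(ceiling((delta / 2) * Tn), Tn)
    sizes <- h
    rem <- Tn - h
  }
  while (rem > q) {
    sizes <- c(sizes, q)
    rem <- rem - q
  }
  if (rem > 0L) sizes <- c(sizes, rem)
  sizes
}

grid_from_sizes <- function(dist, sizes, offset, refined = FALSE) {
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lo <- dist$sorted_entries[starts]
  hi <- dist$sorted_entries[ends]
  len <- hi - lo
  mu <- mean(len)
  sigma <- sqrt(mean((len - mu)^2))
  structure(list(offset = offset, starts = starts, ends = ends,
                 lo = lo, hi = hi, lengths = len,
                 mu = mu, sigma = sigma, refined = refined,
                 interval_of = rep.int(seq_along(sizes), sizes)),
            class = "clag_grid")
}

#' Build a 0-grid or 1-grid over the entry distribution
#'
#' Partitions the sorted distribution into delta-quantile intervals. The
#' 0-grid starts at the minimal entry; the 1-grid is shifted by a
#' (delta/2)-quantile so its first and last intervals are half-width.
#' Interval bounds are the min/max entry values inside each quantile.
#'
#' @param dist a `clag_distribution`.
#' @param delta quantile width in (0, 1).
#' @param offset 0 or 1.
#' @return a `clag_grid` with interval bounds, lengths, their mean `mu`
#'   and (population) standard deviation `sigma`, and a rank-to-interval
#'   lookup.
#' @export
build_grid <- function(dist, delta, offset = 0L) {
  stopifnot(inherits(dist, "clag_distribution"), offset %in% c(0L, 1L))
  grid_from_sizes(dist, grid_sizes(dist$T, delta, offset), as.integer(offset))
}

#' Is a grid heterogeneous?
#'
#' A distribution is heterogeneous in a grid when some interval's
#' value-length exceeds `mu + sigma` of that grid's interval lengths
#' (strictly greater). Such grids are refined by [refine_grid()].
#'
#' @param grid a `clag_grid`.
#' @return logical flag.
#' @export
is_heterogeneous <- function(grid) {
  any(grid$lengths > grid$mu + grid$sigma)
}

#' Refine a heterogeneous grid
#'
#' Every interval whose length exceeds `mu + sigma` (frozen from the
#' unrefined grid) is cut in half at its value midpoint `(lo + hi) / 2`;
#' entries with value less than or equal to the midpoint go to the left
#' half. A single pass; not iterated. Because the interval bounds are
#' attained member values, both halves are non-empty whenever the length
#' is positive (an empty half would be dropped with a message).
#'
#' @param grid a `clag_grid`.
#' @param dist the `clag_distribution` the grid was built from.
#' @return a `clag_grid` with `refined = TRUE` (unchanged if homogeneous).
#' @export
refine_grid <- function(grid, dist) {
  thr <- grid$mu + grid$sigma
  if (!any(grid$lengths > thr)) return(grid)
  sorted <- dist$sorted_entries
  sizes <- integer(0)
  for (i in seq_along(grid$starts)) {
    s <- grid$starts[i]; e <- grid$ends[i]
    if (grid$lengths[i] > thr) {
      mid <- (grid$lo[i] + grid$hi[i]) / 2
      nleft <- findInterval(mid, sorted[s:e])
      nright <- (e - s + 1L) - nleft
      if (nleft == 0L || nright == 0L) {
        message("refine_grid: degenerate split left an empty half; interval kept whole")
        sizes <- c(sizes, e - s + 1L)
      } else {
        sizes <- c(sizes, nleft, nright)
      }
    } else {
      sizes <- c(sizes, e - s + 1L)
    }
  }
  grid_from_sizes(dist, sizes, grid$offset, refined = TRUE)
}

#' Build the refined 0-grid/1-grid pair
#'
#' Convenience wrapper: builds both grids at the given delta and applies
#' one refinement pass to each. Emits a warning when delta is not a
#' multiple of 0.05 (the conventional step).
#'
#' @param dist a `clag_distribution`.
#' @param delta quantile width in (0, 1).
#' @param refine apply heterogeneity refinement (default TRUE).
#' @return a `clag_grids` pair: list with `grid0`, `grid1`, `delta`,
#'   `q` (delta-quantile size in ranks) and the distribution.
#' @export
build_grids <- function(dist, delta, refine = TRUE) {
  stopifnot(delta > 0, delta < 1)
  if (abs(delta / 0.05 - round(delta / 0.05)) > 1e-9)
    warning("delta = ", delta, " is not a multiple of 0.05")
  g0 <- build_grid(dist, delta, 0L)
  g1 <- build_grid(dist, delta, 1L)
  if (refine) {
    g0 <- refine_grid(g0, dist)
    g1 <- refine_grid(g1, dist)
  }
  structure(list(grid0 = g0, grid1 = g1, delta = delta,
                 q = ceiling(delta * dist$T), distribution = dist),
            class = "clag_grids")
}

# vectorized closeness on rank pairs; r_lo/r_hi must be ordered
# (rank order coincides with value order under the stable tie rule).
# Entries with equal values are close by definition: tie ranks can
# straddle an interval boundary, but the entries coincide in value
# space, which is what closeness measures.
close_ranks <- function(r_lo, r_hi, grids) {
  sorted <- grids$distribution$sorted_entries
  i0l <- grids$grid0$interval_of[r_lo]
  i0h <- grids$grid0$interval_of[r_hi]
  i1l <- grids$grid1$interval_of[r_lo]
  i1h <- grids$grid1$interval_of[r_hi]
  quant <- r_hi <= r_lo + grids$q - 1L
  (sorted[r_lo] == sorted[r_hi]) |
    (i0l == i0h) | (i1l == i1h) |
    (((i0h - i0l == 1L) | (i1h - i1l == 1L)) & quant)
}

#' Closeness of two entries
#'
#' Two entries are close when they share an interval in the 0-grid or the
#' 1-grid, or when they lie in consecutive intervals of either grid and
#' the larger entry falls in the delta-quantile starting at the smaller.
#' Entries with equal values are always close, even when their tie
#' ranks straddle an interval boundary.
#' Entries are identified by their rank in the distribution (see
#' [extract_distribution()]); argument order does not matter.
#'
#' @param rank1,rank2 integer ranks in `1..T` (vectorized).
#' @param grids a `clag_grids` pair.
#' @return logical vector.
#' @export
are_close <- function(rank1, rank2, grids) {
  stopifnot(inherits(grids, "clag_grids"))
  Tn <- grids$distribution$T
  stopifnot(all(rank1 >= 1L & rank1 <= Tn), all(rank2 >= 1L & rank2 <= Tn))
  close_ranks(pmin.int(rank1, rank2), pmax.int(rank1, rank2), grids)
}
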