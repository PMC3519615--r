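# Diff sets are grouped, not enumerated, for most of the pipeline, so
# they are encoded compactly: the M-bit membership mask is packed into
# 40-bit chunks carried exactly by doubles, then printed as a "/"-joined
# key string.  Encoding is vectorized across pairs via crossprod.
diff_chunk_bits <- 40L

diff_weights <- function(M) {
  nchunk <- ceiling(M / diff_chunk_bits)
  W <- base::matrix(0, M, nchunk)
  pos <- seq_len(M) - 1L
  W[cbind(seq_len(M), pos %/% diff_chunk_bits + 1L)] <-
    2^(pos %% diff_chunk_bits)
  W
}

encode_diff <- function(notclose_mat, W) {
  km <- crossprod(W, notclose_mat)  # nchunk x npairs
  keys <- sprintf("%.0f", km[1L, ])
  if (nrow(km) > 1L)
    for (c in 2L:nrow(km))
      keys <- paste(keys, sprintf("%.0f", km[c, ]), sep = "/")
  keys
}

decode_diff <- function(key, M) {
  chunks <- as.numeric(strsplit(key, "/", fixed = TRUE)[[1L]])
  idx <- integer(0)
  for (c in seq_along(chunks)) {
    x <- chunks[c]
    base <- (c - 1L) * diff_chunk_bits
    b <- 0L
    while (x > 0) {
      if (x %% 2 >= 1) idx <- c(idx, base + b + 1L)
      x <- x %/% 2
      b <- b + 1L
    }
  }
  idx[idx <= M]
}

#' Environmental score of an element pair
#'
#' Counts the characters X for which the entries `A[V, X]` and `A[Z, X]`
#' are close on the grids (K of them); the raw score K/M is normalized
#' to `[-1, 1]` as `2 K / M - 1`. The characters that are not close form
#' the Diff set. For binary matrices, closeness is plain equality of the
#' two entries.
#'
#' @param v,z element labels (or column indices).
#' @param matrix a `clag_matrix`.
#' @param grids a `clag_grids` pair built on this matrix's distribution.
#' @return list with `v`, `z`, `k_close`, `s_env_raw` (K/M), `s_env`,
#'   `diff_set` (character labels).
#' @export
environmental_score <- function(v, z, matrix, grids) {
  iv <- resolve_element(v, matrix); iz <- resolve_element(z, matrix)
  M <- nrow(matrix$values)
  if (matrix$is_binary) {
    close <- matrix$values[, iv] == matrix$values[, iz]
  } else {
    R <- grids$distribution$rank_matrix
    close <- are_close(R[, iv], R[, iz], grids)
  }
  K <- sum(close)
  list(v = matrix$element_labels[iv], z = matrix$element_labels[iz],
       k_close = K, s_env_raw = K / M, s_env = 2 * K / M - 1,
       diff_set = matrix$character_labels[!close])
}

resolve_element <- function(x, matrix) {
  if (is.numeric(x)) return(as.integer(x))
  i <- match(x, matrix$element_labels)
  if (is.na(i)) stop("unknown element label: ", x)
  i
}

# raw symmetric score indices for every element pair of a square matrix,
# vectorized over the full N x N rank matrix; NA where undefined
symmetric_raw_matrix <- function(matrix, grids) {
  R <- grids$distribution$rank_matrix
  tR <- t(R)
  L <- pmin(R, tR); H <- pmax(R, tR)
  i0 <- grids$grid0$interval_of; i1 <- grids$grid1$interval_of
  lo0 <- grids$grid0$lo; lo1 <- grids$grid1$lo
  i0l <- i0[L]; i0h <- i0[H]; i1l <- i1[L]; i1h <- i1[H]
  raw <- rep.int(NA_integer_, length(L))
  if (matrix$is_binary) {
    eq <- as.vector(matrix$values == t(matrix$values))
    raw[eq] <- 2L * (i0l[eq] - 1L)
  } else {
    quant <- as.vector(H <= L + grids$q - 1L)
    # equal values count as sharing the lower rank's 0-grid interval
    eq <- as.vector(matrix$values == t(matrix$values))
    case1 <- eq | (i0l == i0h)
    case2 <- !case1 & (i1l == i1h)
    cons0 <- (i0h - i0l == 1L) & quant
    cons1 <- (i1h - i1l == 1L) & quant
    rest <- !case1 & !case2
    case3 <- rest & cons0 & cons1
    case4a <- rest & cons0 & !cons1
    case4b <- rest & !cons0 & cons1
    raw[case1] <- 2L * (i0l[case1] - 1L)
    raw[case2] <- 2L * (i1l[case2] - 1L) + 1L
    # consecutive in both grids: pick by which interval starts first
    # (ties take the 0-grid branch)
    g1first <- lo1[i1l[case3]] <= lo0[i0l[case3]]
    raw[case3] <- ifelse(g1first, 2L * (i0l[case3] - 1L),
                         2L * (i1l[case3] - 1L) + 1L)
    raw[case4a] <- 2L * (i0l[case4a] - 1L)
    raw[case4b] <- 2L * (i1l[case4b] - 1L) + 1L
  }
  base::matrix(raw, nrow(R), ncol(R))
}

normalize_sym <- function(raw, grids) {
  G <- length(grids$grid0$starts)
  2 * raw / (2 * G - 1) - 1
}

#' Symmetric score of an element pair (square mode)
#'
#' For a square matrix, locates the entry pair `(A[V, Z], A[Z, V])` on
#' the grids. Defined only when the two entries are close; the raw index
#' encodes the position of the shared (or straddled) interval: `2n` for
#' the n-th 0-grid interval, `2n + 1` for the n-th 1-grid interval
#' (0-based), with the straddling cases resolved toward whichever
#' interval starts first. Normalized to about `[-1, 1]` by
#' `2 raw / (2 G - 1) - 1`, G the number of 0-grid intervals.
#'
#' @inheritParams environmental_score
#' @return list with `v`, `z`, `s_sym_raw` (integer or NA) and `s_sym`
#'   (numeric or NA).
#' @export
symmetric_score <- function(v, z, matrix, grids) {
  if (!matrix$is_square)
    stop("symmetric score requires a square matrix")
  iv <- resolve_element(v, matrix); iz <- resolve_element(z, matrix)
  raw <- symmetric_raw_matrix(matrix, grids)[iv, iz]
  list(v = matrix$element_labels[iv], z = matrix$element_labels[iz],
       s_sym_raw = raw,
       s_sym = if (is.na(raw)) NA_real_ else normalize_sym(raw, grids))
}

#' Score all element pairs
#'
#' Computes one record per unordered element pair: the closeness count
#' K, the normalized environmental score, the encoded Diff set, and (in
#' symmetric mode) the symmetric score. Runs in O(N^2 M).
#'
#' @param matrix a `clag_matrix`.
#' @param grids a `clag_grids` pair built on this matrix's distribution.
#' @param symmetric_mode logical; also compute symmetric scores
#'   (requires a square matrix whose distribution excluded the
#'   diagonal).
#' @return a `data.table` with columns `v`, `z` (element indices,
#'   v < z), `k_close`, `s_env`, `diff_key` (encoded Diff set; decode
#'   with the `diff_set` column of [build_clusters()] output),
#'   `s_sym_raw`, `s_sym`; attribute `M` carries the environment size.
#' @export
score_all_pairs <- function(matrix, grids, symmetric_mode = FALSE) {
  M <- nrow(matrix$values); N <- ncol(matrix$values)
  if (N < 2L) stop("need at least two elements")
  R <- grids$distribution$rank_matrix
  W <- diff_weights(M)
  i0 <- grids$grid0$interval_of; i1 <- grids$grid1$interval_of
  q <- grids$q
  out <- vector("list", N - 1L)
  for (v in seq_len(N - 1L)) {
    zs <- (v + 1L):N
    k <- length(zs)
    if (matrix$is_binary) {
      close <- matrix$values[, zs, drop = FALSE] == matrix$values[, v]
    } else {
      rv <- R[, v]
      rz <- R[, zs, drop = FALSE]
      lo <- pmin(rv, rz); hi <- pmax(rv, rz)
      i0l <- i0[lo]; i0h <- i0[hi]; i1l <- i1[lo]; i1h <- i1[hi]
      quant <- as.vector(hi <= lo + q - 1L)
      eq <- as.vector(matrix$values[, zs, drop = FALSE] ==
                        matrix$values[, v])
      close <- base::matrix(
        eq | (i0l == i0h) | (i1l == i1h) |
          (((i0h - i0l == 1L) | (i1h - i1l == 1L)) & quant),
        nrow = M)
    }
    K <- as.integer(.colSums(close, M, k))
    out[[v]] <- data.table::data.table(
      v = v, z = zs, k_close = K,
      diff_key = encode_diff(!close, W))
  }
  scores <- data.table::rbindlist(out)
  scores[, "s_env" := 2 * scores$k_close / M - 1]
  if (symmetric_mode) {
    raw <- symmetric_raw_matrix(matrix, grids)
    sraw <- raw[cbind(scores$v, scores$z)]
    scores[, "s_sym_raw" := sraw]
    scores[, "s_sym" := normalize_sym(sraw, grids)]
  } else {
    scores[, "s_sym_raw" := NA_integer_]
    scores[, "s_sym" := NA_real_]
  }
  data.table::setattr(scores, "M", M)
  data.table::setattr(scores, "G", length(grids$grid0$starts))
  scores[]
}
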