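# Brute-force oracles, written from first principles with plain loops.
# They re-derive grid intervals, closeness, scores and clusters
# independently of the package's vectorized implementation.

# intervals as a list of contiguous rank vectors over the sorted entries
oracle_intervals <- function(sorted, delta, offset) {
  Tn <- length(sorted)
  q <- ceiling(delta * Tn)
  ivs <- list()
  pos <- 1L
  if (offset == 1L) {
    h <- ceiling((delta / 2) * Tn)
    ivs[[1L]] <- seq_len(h)
    pos <- h + 1L
  }
  while (pos <= Tn) {
    if (Tn - pos + 1L > q) {
      ivs[[length(ivs) + 1L]] <- pos:(pos + q - 1L)
      pos <- pos + q
    } else {
      ivs[[length(ivs) + 1L]] <- pos:Tn
      pos <- Tn + 1L
    }
  }
  ivs
}

oracle_refine <- function(ivs, sorted) {
  len <- sapply(ivs, function(r) sorted[max(r)] - sorted[min(r)])
  mu <- mean(len)
  sigma <- sqrt(mean((len - mu)^2))
  out <- list()
  for (i in seq_along(ivs)) {
    r <- ivs[[i]]
    if (len[i] > mu + sigma) {
      mid <- (sorted[min(r)] + sorted[max(r)]) / 2
      left <- r[sorted[r] <= mid]
      right <- r[sorted[r] > mid]
      if (length(left) > 0L) out[[length(out) + 1L]] <- left
      if (length(right) > 0L) out[[length(out) + 1L]] <- right
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  out
}

oracle_grids <- function(sorted, delta, refine = TRUE) {
  i0 <- oracle_intervals(sorted, delta, 0L)
  i1 <- oracle_intervals(sorted, delta, 1L)
  if (refine) {
    i0 <- oracle_refine(i0, sorted)
    i1 <- oracle_refine(i1, sorted)
  }
  list(i0 = i0, i1 = i1, q = ceiling(delta * length(sorted)),
       sorted = sorted)
}

oracle_which_interval <- function(rank, ivs) {
  for (i in seq_along(ivs)) if (rank %in% ivs[[i]]) return(i)
  stop("rank not in any interval")
}

oracle_close <- function(r1, r2, og) {
  rlo <- min(r1, r2); rhi <- max(r1, r2)
  if (og$sorted[rlo] == og$sorted[rhi]) return(TRUE)
  for (ivs in list(og$i0, og$i1)) {
    a <- oracle_which_interval(rlo, ivs)
    b <- oracle_which_interval(rhi, ivs)
    if (a == b) return(TRUE)
    if (b == a + 1L && rhi <= rlo + og$q - 1L) return(TRUE)
  }
  FALSE
}

oracle_symraw <- function(r1, r2, og) {
  if (!oracle_close(r1, r2, og)) return(NA_integer_)
  rlo <- min(r1, r2); rhi <- max(r1, r2)
  i0l <- oracle_which_interval(rlo, og$i0)
  i0h <- oracle_which_interval(rhi, og$i0)
  i1l <- oracle_which_interval(rlo, og$i1)
  i1h <- oracle_which_interval(rhi, og$i1)
  if (og$sorted[rlo] == og$sorted[rhi]) return(2L * (i0l - 1L))
  if (i0l == i0h) return(2L * (i0l - 1L))
  if (i1l == i1h) return(2L * (i1l - 1L) + 1L)
  quant <- rhi <= rlo + og$q - 1L
  c0 <- (i0h == i0l + 1L) && quant
  c1 <- (i1h == i1l + 1L) && quant
  start0 <- og$sorted[min(og$i0[[i0l]])]
  start1 <- og$sorted[min(og$i1[[i1l]])]
  if (c0 && c1) {
    if (start1 <= start0) 2L * (i0l - 1L) else 2L * (i1l - 1L) + 1L
  } else if (c0) {
    2L * (i0l - 1L)
  } else if (c1) {
    2L * (i1l - 1L) + 1L
  } else {
    stop("close pair matched no symmetric-score case")
  }
}

# naive pair scores for a whole matrix: env K and Diff via oracle_close,
# symmetric raw index via oracle_symraw
oracle_pair_scores <- function(mat, delta, symmetric = FALSE,
                               refine = TRUE) {
  dist <- extract_distribution(mat, symmetric_mode = symmetric)
  og <- oracle_grids(dist$sorted_entries, delta, refine = refine)
  R <- dist$rank_matrix
  N <- ncol(mat$values); M <- nrow(mat$values)
  recs <- list()
  for (v in seq_len(N - 1L)) for (z in (v + 1L):N) {
    if (mat$is_binary) {
      close <- mat$values[, v] == mat$values[, z]
    } else {
      close <- logical(M)
      for (x in seq_len(M))
        close[x] <- oracle_close(R[x, v], R[x, z], og)
    }
    sraw <- if (!symmetric) {
      NA_integer_
    } else if (mat$is_binary) {
      # binary rule: defined iff the two entries are equal; index from
      # the containing 0-grid interval
      if (mat$values[v, z] == mat$values[z, v])
        2L * (oracle_which_interval(min(R[v, z], R[z, v]), og$i0) - 1L)
      else NA_integer_
    } else {
      oracle_symraw(R[v, z], R[z, v], og)
    }
    recs[[length(recs) + 1L]] <- list(
      v = v, z = z, K = sum(close),
      diff = mat$character_labels[!close], sraw = sraw)
  }
  recs
}

# naive generator-based clustering with dedup of identical member sets
oracle_clusters <- function(mat, recs, symmetric = FALSE) {
  N <- ncol(mat$values)
  labels <- mat$element_labels
  lookup <- list()
  for (r in recs) {
    lookup[[paste(r$v, r$z)]] <- r
    lookup[[paste(r$z, r$v)]] <- r
  }
  out <- list()
  for (v in seq_len(N)) {
    keys <- character(0); groups <- list()
    for (z in seq_len(N)) {
      if (z == v) next
      r <- lookup[[paste(v, z)]]
      if (symmetric && is.na(r$sraw)) next
      key <- paste(r$K, paste(sort(r$diff), collapse = ","), r$sraw)
      if (key %in% keys) {
        groups[[key]]$z <- c(groups[[key]]$z, z)
      } else {
        keys <- c(keys, key)
        groups[[key]] <- list(z = z, K = r$K, diff = sort(r$diff),
                              sraw = r$sraw)
      }
    }
    for (g in groups) {
      mem <- sort(labels[c(v, g$z)], method = "radix")
      out[[length(out) + 1L]] <- list(
        generator = labels[v], members = mem, K = g$K,
        diff = g$diff, sraw = g$sraw)
    }
  }
  sig <- sapply(out, function(cl)
    paste(paste(cl$members, collapse = ","), cl$K,
          paste(cl$diff, collapse = ","), cl$sraw, sep = ";"))
  gens <- sapply(out, function(cl) cl$generator)
  keepers <- tapply(seq_along(out), sig, function(ix)
    ix[order(gens[ix], method = "radix")[1L]])
  out[sort(as.integer(keepers))]
}

# canonical string signature for comparing cluster tables
cluster_signatures <- function(clusters) {
  sort(vapply(seq_len(nrow(clusters)), function(i)
    paste(paste(sort(clusters$members[[i]], method = "radix"),
                collapse = ","),
          clusters$k_close[i],
          paste(sort(clusters$diff_set[[i]], method = "radix"),
                collapse = ","),
          clusters$s_sym_raw[i], sep = ";"),
    character(1)))
}

oracle_signatures <- function(ocl) {
  sort(vapply(ocl, function(cl)
    paste(paste(cl$members, collapse = ","), cl$K,
          paste(cl$diff, collapse = ","), cl$sraw, sep = ";"),
    character(1)))
}

random_clag_matrix <- function(M, N, square = FALSE, binary = FALSE) {
  if (square) {
    v <- matrix(runif(N * N), N, N)
    labs <- paste0("e", seq_len(N))
    dimnames(v) <- list(labs, labs)
  } else {
    v <- matrix(runif(M * N), M, N,
                dimnames = list(paste0("r", seq_len(M)),
                                paste0("c", seq_len(N))))
  }
  if (binary) v[] <- as.numeric(v > 0.5)
  as_clag_matrix(v)
}
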