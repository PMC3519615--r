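#' Fuse overlapping equal-score clusters
#'
#' Within each group of clusters sharing the same environmental score
#' (and symmetric score, when present), clusters that share an element
#' are unioned transitively until no more can be fused; the fused
#' cluster keeps the group score. The result is re-ranked. Fused
#' clusters no longer have a single generator or Diff set.
#'
#' @param clusters ranked affine cluster table ([rank_clusters()]).
#' @param symmetric_mode logical; include the symmetric score in the
#'   equal-score grouping and in the re-ranking.
#' @return a ranked `data.table` with `members` (list), `k_close`,
#'   `s_env`, `s_sym_raw`, `s_sym`.
#' @export
fuse_equal_score <- function(clusters, symmetric_mode = FALSE) {
  if (nrow(clusters) == 0L)
    return(data.table::data.table(members = list(), k_close = integer(0),
                                  s_env = numeric(0),
                                  s_sym_raw = integer(0),
                                  s_sym = numeric(0)))
  gkey <- paste(clusters$k_close, clusters$s_sym_raw)
  pieces <- lapply(split(seq_len(nrow(clusters)), gkey), function(ix) {
    mem <- clusters$members[ix]
    comp <- overlap_components(mem)
    fused <- lapply(split(seq_along(mem), comp), function(j)
      sort(unique(unlist(mem[j])), method = "radix"))
    data.table::data.table(
      members = unname(fused),
      k_close = clusters$k_close[ix[1L]],
      s_env = clusters$s_env[ix[1L]],
      s_sym_raw = clusters$s_sym_raw[ix[1L]],
      s_sym = clusters$s_sym[ix[1L]])
  })
  res <- data.table::rbindlist(pieces)
  rank_clusters(res, symmetric_mode)
}

# connected components of the "shares a member" relation over sets
overlap_components <- function(member_sets) {
  n <- length(member_sets)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (el in member_sets[[i]]) {
      j <- seen[[el]]
      if (is.null(j)) {
        assign(el, i, envir = seen)
      } else {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Aggregate ranked clusters into a colored graph
#'
#' Processes the fused, ranked cluster list top-down. A cluster disjoint
#' from all existing aggregates becomes a new clique with a fresh color.
#' A cluster that overlaps existing aggregates contributes its new nodes
#' and all its clique edges; the new nodes take the shared color when
#' all shared nodes carry one color, and a fresh color when the shared
#' nodes span several colors. Node colors are never repainted. Colors
#' are allocated in processing order (0, 1, 2, ...), so the coloring is
#' deterministic. Key aggregates are the monochromatic node sets; the
#' score of the first and last cluster entering each color is recorded.
#'
#' @param clusters ranked fused cluster table ([fuse_equal_score()]).
#' @return a `clag_aggregation`: list with `node_colors` (named integer
#'   vector), `edges` (2-column character matrix, each row sorted),
#'   `color_scores` (per-color first/last entering scores), and
#'   `components` (connected components of the whole graph).
#' @export
aggregate_clusters <- function(clusters) {
  color <- new.env(hash = TRUE, parent = emptyenv())
  node_order <- character(0)
  edges <- new.env(hash = TRUE, parent = emptyenv())
  edge_list <- list()
  next_color <- 0L
  first_env <- last_env <- numeric(0)
  first_sym <- last_sym <- numeric(0)
  for (i in seq_len(nrow(clusters))) {
    mem <- clusters$members[[i]]
    se <- clusters$s_env[i]; ss <- clusters$s_sym[i]
    colored <- !vapply(mem, function(m) is.null(color[[m]]), logical(1))
    shared_cols <- unique(vapply(mem[colored], function(m) color[[m]],
                                 integer(1)))
    newn <- mem[!colored]
    if (length(newn) > 0L) {
      if (length(shared_cols) == 1L) {
        cid <- shared_cols
        last_env[cid + 1L] <- se; last_sym[cid + 1L] <- ss
      } else {
        cid <- next_color
        next_color <- next_color + 1L
        first_env[cid + 1L] <- last_env[cid + 1L] <- se
        first_sym[cid + 1L] <- last_sym[cid + 1L] <- ss
      }
      for (m in newn) assign(m, cid, envir = color)
      node_order <- c(node_order, newn)
    }
    # clique edges over the cluster's members
    if (length(mem) >= 2L) {
      pr <- utils::combn(sort(mem, method = "radix"), 2L)
      keys <- paste(pr[1L, ], pr[2L, ], sep = "\t")
      fresh <- vapply(keys, function(k) is.null(edges[[k]]), logical(1))
      if (any(fresh)) {
        for (k in keys[fresh]) assign(k, TRUE, envir = edges)
        edge_list[[length(edge_list) + 1L]] <-
          cbind(pr[1L, fresh], pr[2L, fresh])
      }
    }
  }
  node_colors <- vapply(node_order, function(m) color[[m]], integer(1))
  edges_mat <- if (length(edge_list) > 0L) do.call(rbind, edge_list)
               else base::matrix(character(0), 0L, 2L)
  comp <- if (length(node_order) > 0L)
    graph_components(node_order, edges_mat) else list()
  structure(list(node_colors = node_colors, edges = edges_mat,
                 color_scores = data.table::data.table(
                   color = seq_len(next_color) - 1L,
                   s_env_first = first_env, s_env_last = last_env,
                   s_sym_first = first_sym, s_sym_last = last_sym),
                 components = comp),
            class = "clag_aggregation")
}

graph_components <- function(nodes, edges) {
  idx <- seq_along(nodes)
  names(idx) <- nodes
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges) > 0L)
    for (r in seq_len(nrow(edges))) {
      ri <- find(idx[[edges[r, 1L]]]); rj <- find(idx[[edges[r, 2L]]])
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(idx, find, integer(1))
  unname(lapply(split(nodes, roots), sort, method = "radix"))
}

#' Rank key aggregates
#'
#' Key aggregates (monochromatic node sets of the aggregation graph) are
#' sorted descending by the score of their first entering cluster
#' (symmetric score first when defined, then environmental), then by the
#' last entering scores; remaining ties break on the lexicographic
#' member list.
#'
#' @param graph a `clag_aggregation` from [aggregate_clusters()].
#' @return a `data.table`: `color`, `members` (list), `s_env_first`,
#'   `s_env_last`, `s_sym_first`, `s_sym_last`.
#' @export
rank_aggregates <- function(graph) {
  cs <- graph$color_scores
  if (nrow(cs) == 0L)
    return(data.table::data.table(color = integer(0), members = list(),
                                  s_env_first = numeric(0),
                                  s_env_last = numeric(0),
                                  s_sym_first = numeric(0),
                                  s_sym_last = numeric(0)))
  members <- lapply(split(names(graph$node_colors), graph$node_colors),
                    sort, method = "radix")
  members <- members[as.character(cs$color)]
  mkey <- vapply(members, paste, character(1), collapse = ",")
  sym_def <- !all(is.na(cs$s_sym_first))
  if (sym_def) {
    o <- order(-cs$s_sym_first, -cs$s_env_first, -cs$s_sym_last,
               -cs$s_env_last, mkey, method = "radix")
  } else {
    o <- order(-cs$s_env_first, -cs$s_env_last, mkey, method = "radix")
  }
  data.table::data.table(
    color = cs$color[o], members = unname(members[o]),
    s_env_first = cs$s_env_first[o], s_env_last = cs$s_env_last[o],
    s_sym_first = cs$s_sym_first[o], s_sym_last = cs$s_sym_last[o])
}

#' @export
print.clag_aggregation <- function(x, ...) {
  cat(sprintf("clag_aggregation: %d nodes, %d edges, %d key aggregates\n",
              length(x$node_colors), nrow(x$edges),
              length(unique(x$node_colors))))
  invisible(x)
}
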