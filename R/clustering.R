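#' Build clusters from pair scores
#'
#' Every element acts as a cluster generator V: its partners Z are
#' grouped by identical environmental score and identical Diff set
#' (plus identical symmetric score in symmetric mode, where partners
#' with an undefined symmetric score are skipped). Each group, together
#' with V, is a cluster; a lone qualifying partner still forms a
#' two-element cluster. Clusters generated from different generators
#' with the same member set and scores collapse to one record keeping
#' the lexicographically smallest generator (the aggregation step would
#' fuse them anyway).
#'
#' @param scores pair-score table from [score_all_pairs()].
#' @param matrix the `clag_matrix` the scores were computed on.
#' @param symmetric_mode logical; use the three-condition (symmetric)
#'   cluster definition.
#' @return a `data.table` of clusters: `generator`, `members` (list of
#'   element labels), `k_close`, `s_env`, `s_sym_raw`, `s_sym`,
#'   `diff_key`, `diff_set` (list of character labels).
#' @export
build_clusters <- function(scores, matrix, symmetric_mode = FALSE) {
  M <- attr(scores, "M")
  labels <- matrix$element_labels
  # both orientations: every element is tried as generator
  gen <- c(scores$v, scores$z)
  partner <- c(scores$z, scores$v)
  dt <- data.table::data.table(
    gen = gen, partner = partner,
    k_close = rep(scores$k_close, 2L),
    diff_key = rep(scores$diff_key, 2L),
    s_sym_raw = rep(scores$s_sym_raw, 2L))
  if (symmetric_mode) dt <- dt[!is.na(dt$s_sym_raw)]
  if (nrow(dt) == 0L) return(empty_clusters())
  grp_cols <- c("gen", "k_close", "diff_key",
                if (symmetric_mode) "s_sym_raw")
  partner <- NULL  # NSE note
  cl <- dt[, list(members = list(sort(labels[c(.BY$gen, partner)],
                                      method = "radix"))),
           by = grp_cols]
  if (!symmetric_mode) cl[, "s_sym_raw" := NA_integer_]
  # deduplicate identical member sets with identical scores
  mkey <- paste(vapply(cl$members, paste, character(1), collapse = ","),
                cl$k_close, cl$diff_key, cl$s_sym_raw, sep = ";")
  o <- order(mkey, labels[cl$gen], method = "radix")
  cl <- cl[o][!duplicated(mkey[o])]
  G <- attr(scores, "G")
  res <- data.table::data.table(
    generator = labels[cl$gen],
    members = cl$members,
    k_close = cl$k_close,
    s_env = 2 * cl$k_close / M - 1,
    s_sym_raw = cl$s_sym_raw,
    s_sym = if (symmetric_mode) 2 * cl$s_sym_raw / (2 * G - 1) - 1
            else NA_real_,
    diff_key = cl$diff_key,
    diff_set = lapply(cl$diff_key, function(k)
      matrix$character_labels[decode_diff(k, M)]))
  res[]
}

empty_clusters <- function() {
  data.table::data.table(
    generator = character(0), members = list(),
    k_close = integer(0), s_env = numeric(0),
    s_sym_raw = integer(0), s_sym = numeric(0),
    diff_key = character(0), diff_set = list())
}

#' Keep affine clusters
#'
#' An affine cluster has a strictly positive common environmental score
#' (and symmetric score, in symmetric mode); more generally the cutoff
#' is a hyperparameter delta in `[-1, 1)`, compared strictly.
#'
#' @param clusters cluster table from [build_clusters()].
#' @param delta_aff affinity threshold (default 0).
#' @param symmetric_mode logical; also require `s_sym > delta_aff`.
#' @return the filtered cluster table.
#' @export
affine_filter <- function(clusters, delta_aff = 0, symmetric_mode = FALSE) {
  if (delta_aff < -1 || delta_aff >= 1)
    stop("affinity threshold must lie in [-1, 1)")
  keep <- clusters$s_env > delta_aff
  if (symmetric_mode)
    keep <- keep & !is.na(clusters$s_sym) & clusters$s_sym > delta_aff
  clusters[keep]
}

#' Rank clusters by score
#'
#' Descending by symmetric score (symmetric mode), then environmental
#' score; ties broken by the lexicographic member label list so the
#' order is deterministic regardless of input order.
#'
#' @inheritParams affine_filter
#' @return the reordered cluster table.
#' @export
rank_clusters <- function(clusters, symmetric_mode = FALSE) {
  if (nrow(clusters) == 0L) return(clusters)
  mkey <- vapply(clusters$members, paste, character(1), collapse = ",")
  # diff_key joins the tie-break so equal-score, equal-member clusters
  # with different Diff sets still order deterministically
  dkey <- if ("diff_key" %in% names(clusters)) clusters$diff_key
          else character(nrow(clusters))
  if (symmetric_mode) {
    o <- order(-clusters$s_sym, -clusters$s_env, mkey, dkey,
               method = "radix")
  } else {
    o <- order(-clusters$s_env, mkey, dkey, method = "radix")
  }
  clusters[o]
}
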