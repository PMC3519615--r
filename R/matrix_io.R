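#' Construct a clag_matrix from a numeric matrix
#'
#' Validates labels, renormalizes entries to `[0, 1]` when needed (the
#' original range is kept in `norm_record`), and detects binary and
#' square modes. Binary mode is detected on the raw values, before
#' renormalization. A square matrix (identical row and column label
#' sets) has its rows reordered to the column order so that `A[V, Z]`
#' addresses element pair (V, Z) directly.
#'
#' @param values numeric matrix, M characters (rows) x N elements
#'   (columns), with dimnames or explicit labels.
#' @param character_labels,element_labels optional label vectors
#'   (default: dimnames).
#' @param force_square treat as square even if labels differ (requires
#'   M == N; column labels are imposed on rows).
#' @return a `clag_matrix`: list with `values` (in `[0, 1]`),
#'   `element_labels`, `character_labels`, `is_binary`, `is_square`,
#'   `norm_record`.
#' @export
as_clag_matrix <- function(values, character_labels = rownames(values),
                           element_labels = colnames(values),
                           force_square = FALSE) {
  values <- as.matrix(values)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty matrix")
  if (is.null(character_labels))
    character_labels <- paste0("r", seq_len(nrow(values)))
  if (is.null(element_labels))
    element_labels <- paste0("c", seq_len(ncol(values)))
  character_labels <- as.character(character_labels)
  element_labels <- as.character(element_labels)
  if (anyDuplicated(element_labels))
    stop("duplicate element (column) labels")
  if (anyDuplicated(character_labels))
    stop("duplicate character (row) labels")
  if (!is.numeric(values) || anyNA(values))
    stop("matrix body must be numeric with no missing values")
  is_binary <- all(values %in% c(0, 1))
  labels_match <- nrow(values) == ncol(values) &&
    setequal(character_labels, element_labels)
  if (force_square && nrow(values) != ncol(values))
    stop("force_square requires a square matrix")
  is_square <- force_square || labels_match
  if (labels_match && !identical(character_labels, element_labels)) {
    perm <- match(element_labels, character_labels)
    values <- values[perm, , drop = FALSE]
    character_labels <- character_labels[perm]
  }
  if (is_square) character_labels <- element_labels
  rng <- range(values)
  norm_record <- NULL
  if (rng[1] < 0 || rng[2] > 1) {
    norm_record <- rng
    values <- normalize_matrix(values)
  }
  dimnames(values) <- list(character_labels, element_labels)
  structure(list(values = values,
                 element_labels = element_labels,
                 character_labels = character_labels,
                 is_binary = is_binary,
                 is_square = is_square,
                 norm_record = norm_record),
            class = "clag_matrix")
}

#' Min-max renormalization to [0, 1]
#'
#' Maps `x` to `(x - min) / (max - min)`. A constant matrix maps to 0.5
#' everywhere: the degenerate case stays deterministic and clustering
#' then places every pair in a single interval.
#'
#' @param values numeric matrix or vector.
#' @return object of the same shape with entries in `[0, 1]`.
#' @export
normalize_matrix <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) {
    values[] <- 0.5
    return(values)
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Read a data matrix from TSV/CSV
#'
#' Expects a header row of element labels and a leading column of
#' character labels; the body must be numeric. Rows are characters (the
#' environment E), columns are the elements being clustered; use
#' `transpose = TRUE` for the opposite layout. Entries outside `[0, 1]`
#' are min-max renormalized (recorded in `norm_record`).
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.csv` means comma, anything else tab) unless `sep` is given.
#' @param transpose logical; input has elements as rows.
#' @param force_square treat as square (see [as_clag_matrix()]).
#' @param sep field separator override.
#' @return a `clag_matrix`.
#' @export
read_matrix <- function(path, transpose = FALSE, force_square = FALSE,
                        sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          row.names = 1L, check.names = FALSE,
                          colClasses = "character",
                          comment.char = "", quote = "\"")
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty matrix in ", path)
  suppressWarnings(num <- vapply(df, as.numeric, numeric(nrow(df))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", rownames(df)[bad[1L]],
         "', column '", colnames(df)[bad[2L]], "' in ", path)
  }
  values <- base::matrix(num, nrow = nrow(df),
                         dimnames = list(rownames(df), colnames(df)))
  if (transpose) values <- t(values)
  as_clag_matrix(values, force_square = force_square)
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

members_string <- function(members) {
  vapply(members, function(m) paste(sort(m, method = "radix"),
                                    collapse = ","), character(1))
}

#' Write clustering and aggregation outputs
#'
#' Writes up to four files into `out_dir`: `clusters.tsv` (one ranked
#' affine cluster per row), `key_aggregates.tsv` (ranked key aggregates
#' with first/last entering scores), `aggregation_graph.dot` (Graphviz
#' DOT, undirected, node `color`/`aggregate` attributes per key
#' aggregate) and, when `matrix` is supplied, `reordered_matrix.tsv`
#' (columns permuted so key-aggregate members are contiguous in ranked
#' order, unclustered elements last). With no clusters, `clusters.tsv`
#' holds only the header and no graph file is written.
#'
#' @param clusters ranked cluster table (see [rank_clusters()]).
#' @param aggregates ranked key-aggregate table ([rank_aggregates()]).
#' @param graph a `clag_aggregation` ([aggregate_clusters()]), or NULL.
#' @param out_dir output directory (created if missing).
#' @param matrix optional `clag_matrix` for the reordered matrix output.
#' @return invisibly, the vector of files written.
#' @export
write_outputs <- function(clusters, aggregates, graph, out_dir,
                          matrix = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  written <- character(0)

  cl_path <- file.path(out_dir, "clusters.tsv")
  header <- c("rank", "generator", "members", "n_members", "K",
              "s_env", "s_sym", "diff")
  lines <- paste(header, collapse = "\t")
  if (nrow(clusters) > 0L) {
    diff_str <- vapply(clusters$diff_set, function(d)
      paste(sort(d, method = "radix"), collapse = ","), character(1))
    lines <- c(lines, paste(seq_len(nrow(clusters)), clusters$generator,
                            members_string(clusters$members),
                            lengths(clusters$members), clusters$k_close,
                            format_num(clusters$s_env),
                            format_num(clusters$s_sym),
                            diff_str, sep = "\t"))
  }
  writeLines(lines, cl_path)
  written <- c(written, cl_path)

  ka_path <- file.path(out_dir, "key_aggregates.tsv")
  header <- c("rank", "color", "members", "n_members",
              "s_env_first", "s_env_last", "s_sym_first", "s_sym_last")
  lines <- paste(header, collapse = "\t")
  if (!is.null(aggregates) && nrow(aggregates) > 0L) {
    lines <- c(lines, paste(seq_len(nrow(aggregates)), aggregates$color,
                            members_string(aggregates$members),
                            lengths(aggregates$members),
                            format_num(aggregates$s_env_first),
                            format_num(aggregates$s_env_last),
                            format_num(aggregates$s_sym_first),
                            format_num(aggregates$s_sym_last),
                            sep = "\t"))
  }
  writeLines(lines, ka_path)
  written <- c(written, ka_path)

  if (!is.null(graph) && nrow(clusters) > 0L) {
    dot_path <- file.path(out_dir, "aggregation_graph.dot")
    writeLines(render_dot(graph), dot_path)
    written <- c(written, dot_path)
  }

  if (!is.null(matrix)) {
    rm_path <- file.path(out_dir, "reordered_matrix.tsv")
    ordered <- character(0)
    if (!is.null(aggregates) && nrow(aggregates) > 0L)
      ordered <- unlist(lapply(aggregates$members,
                               sort, method = "radix"))
    rest <- setdiff(matrix$element_labels, ordered)
    vals <- matrix$values[, c(ordered, rest), drop = FALSE]
    lines <- c(paste(c("", colnames(vals)), collapse = "\t"),
               paste(rownames(vals),
                     apply(vals, 1L, function(r)
                       paste(format_num(r), collapse = "\t")),
                     sep = "\t"))
    writeLines(lines, rm_path)
    written <- c(written, rm_path)
  }
  invisible(written)
}

# fixed palette for DOT node fill; aggregate ids beyond it cycle
dot_palette <- c("red", "blue", "green3", "orange", "purple", "cyan3",
                 "magenta", "gold", "brown", "pink", "olivedrab",
                 "steelblue", "darkgreen", "salmon", "navy", "turquoise",
                 "violet", "khaki", "gray50", "tomato")

render_dot <- function(graph) {
  cols <- graph$node_colors
  nodes <- names(cols)
  pal <- dot_palette[(cols %% length(dot_palette)) + 1L]
  out <- c("graph aggregation {", "  node [style=filled];",
           sprintf("  \"%s\" [color=\"%s\", aggregate=\"%d\"];",
                   nodes, pal, cols))
  if (nrow(graph$edges) > 0L)
    out <- c(out, sprintf("  \"%s\" -- \"%s\";",
                          graph$edges[, 1L], graph$edges[, 2L]))
  c(out, "}")
}

#' @export
print.clag_matrix <- function(x, ...) {
  cat(sprintf("clag_matrix: %d characters x %d elements%s%s%s\n",
              nrow(x$values), ncol(x$values),
              if (x$is_binary) ", binary" else "",
              if (x$is_square) ", square" else "",
              if (!is.null(x$norm_record))
                sprintf(", renormalized from [%g, %g]",
                        x$norm_record[1], x$norm_record[2]) else ""))
  invisible(x)
}
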