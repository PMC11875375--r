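#' Read a scored protein-interaction edge list
#'
#' Parses a tab-separated interaction file into one record per row. Two
#' dialects are built in: `"hippie"` (columns ID-A, alt-ID-A, ID-B, alt-ID-B,
#' score, evidence; IDs taken from columns 1 and 3, score from column 5) and
#' `"generic"` (protein_a, protein_b, confidence). Column positions can also
#' be given explicitly, so any tabular dialect with one pair + score per row
#' can be consumed.
#'
#' @param path Path to a UTF-8 tab-separated file.
#' @param dialect `"generic"` (default) or `"hippie"`.
#' @param id_cols Integer vector of length 2: column indices of the two
#'   protein IDs. Overrides `dialect`.
#' @param score_col Integer: column index of the confidence score. Overrides
#'   `dialect`.
#' @param header Does the file carry a header row? Default `TRUE`.
#'
#' @return A tibble with columns `protein_a`, `protein_b`, `confidence`
#'   (one row per parsed input row; duplicates are *not* collapsed here, see
#'   [build_network()]).
#' @seealso [build_network()], [largest_connected_component()]
#' @export
read_interactions <- function(path, dialect = c("generic", "hippie"),
                              id_cols = NULL, score_col = NULL, header = TRUE) {
  if (!file.exists(path)) {
    stop("interaction file not found: ", path, call. = FALSE)
  }
  dialect <- match.arg(dialect)
  if (is.null(id_cols)) {
    id_cols <- if (dialect == "hippie") c(1L, 3L) else c(1L, 2L)
  }
  if (is.null(score_col)) {
    score_col <- if (dialect == "hippie") 5L else 3L
  }
  raw <- readr::read_tsv(path, col_names = header,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          confidence = double()))
  }
  needed <- max(id_cols, score_col)
  if (ncol(raw) < needed) {
    stop("interaction file has ", ncol(raw), " columns but the dialect needs ",
         needed, " (is the score column missing?)", call. = FALSE)
  }
  out <- tibble::tibble(
    protein_a  = as.character(raw[[id_cols[1]]]),
    protein_b  = as.character(raw[[id_cols[2]]]),
    confidence = suppressWarnings(as.numeric(raw[[score_col]]))
  )
  bad <- which(is.na(out$confidence) | !nzchar(out$protein_a) | !nzchar(out$protein_b))
  if (length(bad) > 0) {
    lines <- bad + as.integer(header)
    stop("unparseable interaction rows (file line",
         if (length(bad) > 1) "s" else "", " ",
         paste(utils::head(lines, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "",
         "): score not numeric or empty identifier", call. = FALSE)
  }
  if (any(out$confidence < 0 | out$confidence > 1)) {
    stop("confidence scores must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Build a simple undirected network from interaction records
#'
#' Applies the confidence filter (inclusive, `confidence >= min_confidence`),
#' drops self-interactions, and collapses duplicate edges in either
#' orientation. Edge endpoints are stored lexicographically sorted, so the
#' edge set is canonical.
#'
#' @param records Data frame with columns `protein_a`, `protein_b` and
#'   (unless `min_confidence = 0` and no filtering is wanted) `confidence`.
#' @param min_confidence Keep interactions with score at least this value
#'   (default 0.71, the high-confidence cutoff used for the human
#'   interactome).
#'
#' @return A tibble of unique undirected edges, columns `protein_a`
#'   (lexicographically smaller endpoint), `protein_b`, `confidence` (the
#'   maximum score observed among collapsed duplicates).
#' @examples
#' recs <- tibble::tibble(protein_a = c("A", "B", "C", "A"),
#'                        protein_b = c("B", "A", "C", "C"),
#'                        confidence = c(0.9, 0.9, 1, 0.5))
#' build_network(recs, min_confidence = 0.71) # single A-B edge
#' @export
build_network <- function(records, min_confidence = 0.71) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b") %in% names(records)))
  if (!("confidence" %in% names(records))) {
    records$confidence <- 1
  }
  stopifnot(min_confidence >= 0, min_confidence <= 1)
  records |>
    dplyr::filter(.data$confidence >= min_confidence,
                  .data$protein_a != .data$protein_b) |>
    dplyr::mutate(.a = pmin(.data$protein_a, .data$protein_b),
                  .b = pmax(.data$protein_a, .data$protein_b)) |>
    dplyr::group_by(.data$.a, .data$.b) |>
    dplyr::summarise(confidence = max(.data$confidence), .groups = "drop") |>
    dplyr::rename(protein_a = ".a", protein_b = ".b") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Internal: igraph object from an edge tibble
#' @noRd
edges_to_igraph <- function(edges) {
  igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE
  )
}

#' Node identifiers of an edge table
#'
#' @param edges Edge tibble as returned by [build_network()].
#' @return Sorted character vector of distinct node IDs.
#' @export
network_nodes <- function(edges) {
  sort(unique(c(edges$protein_a, edges$protein_b)))
}

#' Largest connected component of a network
#'
#' Keeps the edges of the component with the most nodes. Ties between
#' equal-sized components are broken deterministically in favour of the
#' component whose sorted node-ID tuple is lexicographically smallest.
#'
#' @param edges Edge tibble as returned by [build_network()].
#' @return Edge tibble restricted to the winning component (empty input
#'   passes through unchanged).
#' @export
largest_connected_component <- function(edges) {
  if (nrow(edges) == 0) {
    return(edges)
  }
  g <- edges_to_igraph(edges)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    keys <- vapply(best, function(k) {
      paste(sort(names(comp$membership)[comp$membership == k]), collapse = "\x01")
    }, character(1))
    best <- best[order(keys)][1]
  }
  keep <- names(comp$membership)[comp$membership == best]
  edges |>
    dplyr::filter(.data$protein_a %in% keep & .data$protein_b %in% keep)
}

#' Write / read a node table (coordinates + centralities)
#'
#' Plain UTF-8 tab-separated table with one row per node and columns
#' `id`, `r`, `theta`, `DC`, `BC`, `CC`, `EC` (the layout of a node
#' annotation table: hyperbolic coordinates and the four centralities).
#' Values round-trip to full double precision.
#'
#' @param table Node tibble with the columns above.
#' @param path File path.
#' @param w Angular span used to validate `theta` on read (default `2*pi`).
#' @return `write_node_table()` returns `path` invisibly;
#'   `read_node_table()` returns the node tibble.
#' @export
write_node_table <- function(table, path) {
  check_node_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path, w = 2 * pi) {
  if (!file.exists(path)) {
    stop("node table not found: ", path, call. = FALSE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_node_table(tab, w = w)
  tab
}

node_table_cols <- c("id", "r", "theta", "DC", "BC", "CC", "EC")

check_node_table <- function(table, w = NULL) {
  missing <- setdiff(node_table_cols, names(table))
  if (length(missing) > 0) {
    stop("node table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table$id)) {
    stop("node table has duplicated node identifiers", call. = FALSE)
  }
  if (any(table$r < 0)) {
    stop("node table has negative radii", call. = FALSE)
  }
  if (!is.null(w) && nrow(table) > 0 &&
      (any(table$theta < 0) || any(table$theta >= w))) {
    stop("node table theta outside [0, w) for w = ", format(w), call. = FALSE)
  }
  invisible(table)
}

#' Write / read an edge feature table
#'
#' Tab-separated table of per-edge geometry: columns `protein_a`,
#' `protein_b`, `hyp_dist` (hyperbolic distance), `r_abs_diff` (absolute
#' radial difference).
#'
#' @param table Edge feature tibble.
#' @param path File path.
#' @export
write_edge_table <- function(table, path) {
  stopifnot(all(c("protein_a", "protein_b") %in% names(table)))
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_edge_table
#' @export
read_edge_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
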