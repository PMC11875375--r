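#' Score every network edge in both directions
#'
#' Each undirected edge yields exactly two prediction records — one per
#' orientation, the first protein playing effector and the second target —
#' so a network with `|E|` edges produces `2 |E|` rows. Scoring streams in
#' chunks so proteome-scale tables need not hold all tree votes at once.
#'
#' @param model A `ptm_rf` model.
#' @param edges Edge tibble.
#' @param node_table Node tibble (`id`, `r`, `theta`, `DC`, `BC`, `CC`,
#'   `EC`) covering every node.
#' @param threshold Classification threshold for `predicted_class`
#'   (default 0.5).
#' @param w Angular span.
#' @param chunk_size Rows scored per chunk (default 50000).
#' @return Tibble `p1` (tested as effector), `p2` (tested as target),
#'   `score`, `predicted_class`, sorted by (`p1`, `p2`).
#' @export
score_all_edges <- function(model, edges, node_table, threshold = 0.5,
                            w = 2 * pi, chunk_size = 50000) {
  pairs <- tibble::tibble(
    effector = c(edges$protein_a, edges$protein_b),
    target = c(edges$protein_b, edges$protein_a)
  ) |>
    dplyr::arrange(.data$effector, .data$target)
  n <- nrow(pairs)
  scores <- numeric(n)
  for (start in seq(1, max(n, 1), by = chunk_size)) {
    if (n == 0) break
    idx <- start:min(start + chunk_size - 1, n)
    feats <- assemble_features(pairs[idx, ], node_table, w = w)
    scores[idx] <- stats::predict(model, feats)
  }
  tibble::tibble(p1 = pairs$effector, p2 = pairs$target, score = scores,
                 predicted_class = scores >= threshold)
}

#' Count predictions at or above score thresholds
#'
#' @param records Prediction tibble from [score_all_edges()].
#' @param thresholds Numeric thresholds (default `c(0.5, 0.9)`).
#' @return Tibble `threshold`, `n` (count of records with
#'   `score >= threshold`; non-increasing in the threshold).
#' @export
threshold_counts <- function(records, thresholds = c(0.5, 0.9)) {
  tibble::tibble(
    threshold = thresholds,
    n = vapply(thresholds, function(t) sum(records$score >= t), integer(1))
  )
}

#' Best predictions for one protein as effector or target
#'
#' @param records Prediction tibble from [score_all_edges()].
#' @param protein Protein identifier.
#' @param role Which role the protein plays: `"effector"` (rows where it is
#'   `p1`) or `"target"` (`p2`).
#' @param min_score Keep records scoring at least this (default 0).
#' @return Prediction rows for the protein in the requested role, sorted by
#'   descending score. Unknown proteins return an empty tibble with a
#'   warning.
#' @export
query_protein <- function(records, protein, role = c("effector", "target"),
                          min_score = 0) {
  role <- match.arg(role)
  col <- if (role == "effector") "p1" else "p2"
  out <- records[records[[col]] == protein & records$score >= min_score, ]
  if (nrow(out) == 0 && !(protein %in% c(records$p1, records$p2))) {
    warning("protein ", protein, " does not occur in the prediction table",
            call. = FALSE)
  }
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' Write / read a prediction table
#'
#' Tab-separated table with columns `p1`, `p2`, `score`,
#' `predicted_class`.
#'
#' @param records Prediction tibble.
#' @param path File path.
#' @export
write_prediction_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
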