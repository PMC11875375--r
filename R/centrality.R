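#' Node centralities of a connected network
#'
#' Computes the four per-node importance measures used as classifier
#' features:
#' \describe{
#'   \item{DC}{degree centrality: the raw number of neighbours.}
#'   \item{BC}{shortest-path betweenness, normalised by `(n-1)(n-2)/2` so it
#'     lies in `[0, 1]`.}
#'   \item{CC}{closeness, `(n-1) / sum of shortest-path distances`, in
#'     `(0, 1]`.}
#'   \item{EC}{eigenvector centrality: the principal adjacency eigenvector
#'     scaled so its maximum entry is exactly 1.}
#' }
#' Closeness is only well defined on a connected graph, so disconnected
#' input is rejected; run [largest_connected_component()] first.
#'
#' @param edges Edge tibble ([build_network()] output).
#' @return A tibble with columns `id`, `DC`, `BC`, `CC`, `EC`, one row per
#'   node, sorted by `id`.
#' @export
compute_centralities <- function(edges) {
  g <- edges_to_igraph(edges)
  if (igraph::vcount(g) == 0) {
    return(tibble::tibble(id = character(), DC = double(), BC = double(),
                          CC = double(), EC = double()))
  }
  if (!igraph::is_connected(g)) {
    stop("network is disconnected: closeness centrality is undefined; ",
         "apply largest_connected_component() first", call. = FALSE)
  }
  n <- igraph::vcount(g)
  dc <- igraph::degree(g)
  bc <- if (n > 2) {
    igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  } else {
    stats::setNames(rep(0, n), igraph::V(g)$name)
  }
  cc <- igraph::closeness(g, normalized = TRUE)
  # eigen_centrality scales to max = 1 (its only behaviour since igraph 2.1)
  ec <- igraph::eigen_centrality(g, options = list(maxiter = 10000,
                                                   tol = 1e-12))$vector
  tibble::tibble(id = igraph::V(g)$name, DC = as.numeric(dc),
                 BC = as.numeric(bc), CC = as.numeric(cc),
                 EC = as.numeric(ec)) |>
    dplyr::arrange(.data$id)
}
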