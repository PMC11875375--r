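#' Radial coordinates from degree rank
#'
#' Under the popularity-similarity model the radius of a node encodes its
#' seniority: high-degree hubs joined early and sit near the disc centre.
#' Nodes are ranked by decreasing degree (ties broken by lexicographic node
#' ID) and the k-th node receives
#' `r_k = 2 beta ln k + 2 (1 - beta) ln N`, `beta = 1/(gamma - 1)`.
#'
#' @param edges Edge tibble ([build_network()] output).
#' @param gamma Degree exponent (> 2).
#' @return Tibble `id`, `r`, `rank` sorted by rank (decreasing degree).
#' @export
assign_radial_coords <- function(edges, gamma = 2.97) {
  if (gamma <= 2) stop("gamma must exceed 2", call. = FALSE)
  beta <- 1 / (gamma - 1)
  g <- edges_to_igraph(edges)
  deg <- igraph::degree(g)
  ids <- names(deg)
  ord <- order(-deg, ids)
  N <- length(ids)
  tibble::tibble(
    id = ids[ord],
    r = 2 * beta * log(seq_len(N)) + 2 * (1 - beta) * log(N),
    rank = seq_len(N)
  )
}

#' Angular coordinates by Laplacian eigenmaps (LaBNE)
#'
#' Solves the generalized eigenproblem `L v = lambda D v` for the graph
#' Laplacian `L = D - A` (equivalently the symmetric normalized Laplacian),
#' takes the eigenvectors of the 2nd and 3rd smallest eigenvalues as planar
#' coordinates, and reads the angle `atan2(y, x)` mapped into `[0, w)`.
#' The eigenvector gauge (sign, rotation, reflection) is arbitrary; all
#' consumers must compare angles gauge-invariantly (see
#' [circular_correlation()]).
#'
#' A dense symmetric eigensolver is used up to `dense_limit` nodes; larger
#' networks use igraph's ARPACK interface on the normalized adjacency.
#'
#' @param edges Edge tibble of a *connected* network.
#' @param w Angular span (default `2*pi`).
#' @param dense_limit Node count up to which the dense solver is used
#'   (default 2000).
#' @return Tibble `id`, `theta` (angles in `[0, w)`), sorted by `id`.
#' @export
labne_angles <- function(edges, w = 2 * pi, dense_limit = 2000) {
  g <- edges_to_igraph(edges)
  n <- igraph::vcount(g)
  if (n < 3) stop("need at least 3 nodes to infer angles", call. = FALSE)
  if (!igraph::is_connected(g)) {
    stop("network is disconnected; apply largest_connected_component() first",
         call. = FALSE)
  }
  deg <- igraph::degree(g)
  dhalf <- 1 / sqrt(deg)
  if (n <= dense_limit) {
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    M <- A * tcrossprod(dhalf)          # D^{-1/2} A D^{-1/2}
    es <- eigen(M, symmetric = TRUE)
    # smallest eigenvalues of L_norm = largest of M; want 2nd and 3rd smallest
    u <- es$vectors[, c(2, 3)]
  } else {
    A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
    mv <- function(x, extra = NULL) dhalf * as.numeric(A %*% (dhalf * x))
    ar <- igraph::arpack(mv, sym = TRUE,
                         options = list(n = n, nev = 3, ncv = 12,
                                        which = "LA", maxiter = 5000))
    ord <- order(ar$values, decreasing = TRUE)
    u <- ar$vectors[, ord[c(2, 3)]]
  }
  v <- u * dhalf                         # back to generalized eigenvectors
  theta <- atan2(v[, 2], v[, 1]) %% (2 * pi)
  theta <- theta * (w / (2 * pi))
  tibble::tibble(id = igraph::V(g)$name, theta = as.numeric(theta)) |>
    dplyr::arrange(.data$id)
}

# Fermi-Dirac log-likelihood terms for one node against a set of others.
# Returns sum over `nbr` of log p(d) plus sum over `non` of log(1 - p(d)).
node_loglik <- function(r0, th0, r, th, is_edge, R, Tt, w) {
  d <- hyperbolic_distance(r0, th0, r, th, w)
  z <- (d - R) / (2 * Tt)
  # log p = -log(1 + e^z); log(1-p) = z - log(1 + e^z), computed stably
  lse <- ifelse(z > 30, z, log1p(exp(z)))
  sum(ifelse(is_edge, -lse, z - lse))
}

#' Likelihood refinement of angular coordinates (HyperMap-style)
#'
#' Visits nodes in decreasing-degree order and replaces each node's angle
#' by the best of `n_candidates` equally spaced candidates in
#' `[theta - window, theta + window]` (the incumbent is always a candidate,
#' so the model likelihood never decreases). The local objective is the
#' Fermi-Dirac log-likelihood
#' `sum(edges) log p(d) + sum(non-edges) log(1 - p(d))` with
#' `p(d) = 1/(1 + exp((d - R)/(2 T)))` and `R` the largest radius.
#'
#' For tractability on large networks the non-edge sum can be subsampled
#' (`nonedge_cap` seeded non-neighbours per node); exact mode
#' (`nonedge_cap = Inf`) evaluates every pair and is the default up to
#' 2000 nodes.
#'
#' @param edges Edge tibble of a connected network.
#' @param radii Tibble `id`, `r` (from [assign_radial_coords()]).
#' @param init_angles Tibble `id`, `theta` (from [labne_angles()]).
#' @param temperature PS temperature (must be >= 0.01; the likelihood is
#'   degenerate at `T = 0`).
#' @param w Angular span.
#' @param window Half-width of the candidate interval (radians).
#' @param n_candidates Number of equally spaced candidates per node.
#' @param passes Number of full sweeps over the nodes.
#' @param nonedge_cap Maximum number of non-neighbours entering each node's
#'   local likelihood (`Inf` = exact; the default uses exact mode for
#'   networks up to 2000 nodes and a cap of 2000 beyond).
#' @param seed Seed for the non-edge subsample.
#' @return Tibble `id`, `theta` of refined angles, sorted by `id`.
#' @export
hypermap_refine <- function(edges, radii, init_angles, temperature = 0.83,
                            w = 2 * pi, window = pi / 6, n_candidates = 60,
                            passes = 1, nonedge_cap = NULL, seed = 1L) {
  if (temperature < 0.01) {
    stop("temperature below 0.01 makes the likelihood degenerate; ",
         "use T >= 0.01", call. = FALSE)
  }
  g <- edges_to_igraph(edges)
  ids <- igraph::V(g)$name
  n <- length(ids)
  if (is.null(nonedge_cap)) {
    nonedge_cap <- if (n <= 2000) Inf else 2000
  }
  r <- radii$r[match(ids, radii$id)]
  th <- (init_angles$theta[match(ids, init_angles$id)]) %% w
  if (anyNA(r) || anyNA(th)) {
    stop("radii / init_angles do not cover every network node", call. = FALSE)
  }
  R <- max(r)
  deg <- igraph::degree(g)
  visit <- order(-deg, ids)
  adj <- igraph::as_adj_list(g)
  set.seed(seed)

  for (p in seq_len(passes)) {
    for (v in visit) {
      nbr <- as.integer(adj[[v]])
      non <- setdiff(seq_len(n)[-v], nbr)
      if (is.finite(nonedge_cap) && length(non) > nonedge_cap) {
        non <- sort(sample(non, nonedge_cap))
      }
      others <- c(nbr, non)
      is_edge <- c(rep(TRUE, length(nbr)), rep(FALSE, length(non)))
      cands <- unique(c(th[v],
                        seq(th[v] - window, th[v] + window,
                            length.out = max(n_candidates, 1)) %% w))
      ll <- vapply(cands, function(cand) {
        node_loglik(r[v], cand, r[others], th[others], is_edge, R,
                    temperature, w)
      }, numeric(1))
      th[v] <- cands[which.max(ll)]
    }
  }
  tibble::tibble(id = ids, theta = th %% w) |> dplyr::arrange(.data$id)
}

#' Total Fermi-Dirac log-likelihood of an embedding
#'
#' Sum over all node pairs of `log p(d)` for edges and `log(1 - p(d))` for
#' non-edges, with `p(d) = 1/(1 + exp((d - R)/(2 T)))`, `R = max(r)`.
#' Quadratic in the node count; intended for diagnostics and testing on
#' small and medium networks.
#'
#' @param edges Edge tibble.
#' @param coords Tibble `id`, `r`, `theta`.
#' @param temperature PS temperature (> 0).
#' @param w Angular span.
#' @return A single number (the log-likelihood).
#' @export
embedding_loglik <- function(edges, coords, temperature = 0.83, w = 2 * pi) {
  ids <- coords$id
  n <- length(ids)
  r <- coords$r
  th <- coords$theta
  R <- max(r)
  key <- paste(pmin(edges$protein_a, edges$protein_b),
               pmax(edges$protein_a, edges$protein_b), sep = "\x01")
  total <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- hyperbolic_distance(r[i], th[i], r[j], th[j], w)
    z <- (d - R) / (2 * temperature)
    lse <- ifelse(z > 30, z, log1p(exp(z)))
    pk <- paste(pmin(ids[i], ids[j]), pmax(ids[i], ids[j]), sep = "\x01")
    is_edge <- pk %in% key
    total <- total + sum(ifelse(is_edge, -lse, z - lse))
  }
  total
}

#' Embed a network in the hyperbolic plane (LaBNE + HM)
#'
#' Composition of [assign_radial_coords()], [labne_angles()] and (optionally)
#' [hypermap_refine()]: radii from degree rank, angles from Laplacian
#' eigenmaps, refined by likelihood maximisation. Deterministic given its
#' inputs and settings.
#'
#' @param edges Edge tibble of a connected network.
#' @param gamma Degree exponent (default 2.97).
#' @param temperature PS temperature (default 0.83).
#' @param w Angular span (default `2*pi`).
#' @param refine Run the likelihood refinement? Default `TRUE`.
#' @param ... Further arguments passed to [hypermap_refine()] (`window`,
#'   `n_candidates`, `passes`, `nonedge_cap`, `seed`).
#' @return An `embedded_network`: list with `edges`, `coords` (tibble `id`,
#'   `r`, `theta`, `rank`) and `params`.
#' @export
embed_network <- function(edges, gamma = 2.97, temperature = 0.83,
                          w = 2 * pi, refine = TRUE, ...) {
  rad <- assign_radial_coords(edges, gamma = gamma)
  ang <- labne_angles(edges, w = w)
  if (refine) {
    ang <- hypermap_refine(edges, rad, ang, temperature = max(temperature, 0.01),
                           w = w, ...)
  }
  coords <- dplyr::inner_join(rad, ang, by = "id") |>
    dplyr::select("id", "r", "theta", "rank") |>
    dplyr::arrange(.data$id)
  structure(list(edges = edges, coords = coords,
                 params = list(gamma = gamma, temperature = temperature,
                               w = w, refined = refine)),
            class = "embedded_network")
}

#' @export
print.embedded_network <- function(x, ...) {
  cat("Hyperbolic embedding:", nrow(x$coords), "nodes,", nrow(x$edges),
      "edges (gamma =", x$params$gamma, ", T =", x$params$temperature,
      if (isTRUE(x$params$refined)) ", refined)" else ", LaBNE only)", "\n")
  invisible(x)
}

#' Gauge-invariant circular correlation between two angle sets
#'
#' Fisher-Lee circular correlation, reported as an absolute value so it is
#' invariant to rotation and reflection of either embedding — the natural
#' gauge freedom of Laplacian eigenmaps.
#'
#' @param theta1,theta2 Numeric angle vectors of equal length (radians).
#' @return Absolute circular correlation in `[0, 1]`.
#' @export
circular_correlation <- function(theta1, theta2) {
  stopifnot(length(theta1) == length(theta2))
  n <- length(theta1)
  ij <- utils::combn(n, 2)
  s1 <- sin(theta1[ij[1, ]] - theta1[ij[2, ]])
  s2 <- sin(theta2[ij[1, ]] - theta2[ij[2, ]])
  abs(sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2)))
}
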