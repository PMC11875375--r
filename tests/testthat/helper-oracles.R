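# Independent brute-force oracles, deliberately written against plain R
# structures (no igraph) so they cross-check the package implementations.

# adjacency list (integer indices) from an edge tibble
oracle_adjacency <- function(edges) {
  ids <- sort(unique(c(edges$protein_a, edges$protein_b)))
  n <- length(ids)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$protein_a[k], ids)
    j <- match(edges$protein_b[k], ids)
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  list(ids = ids, adj = lapply(adj, unique))
}

oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) {
        if (is.infinite(dist[u])) {
          dist[u] <- dist[v] + 1
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# number of distinct shortest paths between all pairs, by dynamic
# programming over the BFS level structure
oracle_path_counts <- function(adj, dist_from) {
  n <- length(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dist_from[s, ]
    sigma[s, s] <- 1
    for (lev in sort(unique(d[d > 0 & is.finite(d)]))) {
      for (t in which(d == lev)) {
        sigma[s, t] <- sum(sigma[s, adj[[t]][d[adj[[t]]] == lev - 1]])
      }
    }
  }
  sigma
}

# DC raw degree; BC normalised by (n-1)(n-2)/2; CC = (n-1)/sum d;
# EC principal adjacency eigenvector (power iteration), max entry = 1
oracle_centralities <- function(edges) {
  g <- oracle_adjacency(edges)
  adj <- g$adj
  n <- length(adj)
  dist_from <- t(vapply(seq_len(n), function(s) oracle_bfs(adj, s),
                        numeric(n)))
  sigma <- oracle_path_counts(adj, dist_from)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s < t && s != v && t != v && sigma[s, t] > 0 &&
            dist_from[s, v] + dist_from[v, t] == dist_from[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    bc[v] <- tot
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  A <- matrix(0, n, n)
  for (v in seq_len(n)) A[v, adj[[v]]] <- 1
  x <- rep(1 / sqrt(n), n)
  for (it in seq_len(10000)) {
    x_new <- A %*% x
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < 1e-12) break
    x <- as.numeric(x_new)
  }
  tibble::tibble(
    id = g$ids,
    DC = vapply(adj, length, integer(1)),
    BC = bc,
    CC = (n - 1) / rowSums(dist_from),
    EC = as.numeric(x) / max(x)
  )
}

# Mann-Whitney concordance probability: ties count one half
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# random connected graph: spanning tree + extra random edges
random_connected_graph <- function(n, extra = n, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  from <- to <- character(0)
  for (i in 2:n) {
    j <- sample(i - 1, 1)
    from <- c(from, ids[i]); to <- c(to, ids[j])
  }
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    from <- c(from, ids[ij[1]]); to <- c(to, ids[ij[2]])
  }
  build_network(tibble::tibble(protein_a = from, protein_b = to,
                               confidence = 1), min_confidence = 0)
}

# labeled feature table where only the two theta columns carry signal
theta_signal_data <- function(n = 400, seed = 1) {
  set.seed(seed)
  feats <- ptm_feature_names()
  dat <- tibble::as_tibble(stats::setNames(
    lapply(feats, function(f) stats::runif(n)), feats))
  dat$theta_eff <- stats::runif(n, 0, 2 * pi)
  dat$theta_tgt <- stats::runif(n, 0, 2 * pi)
  signal <- angular_separation(dat$theta_eff, 1.8) < pi / 2 &
    angular_separation(dat$theta_tgt, 4.5) < pi / 2
  prob <- ifelse(signal, 0.9, 0.1)
  dat$label <- ifelse(stats::runif(n) < prob, "positive", "negative")
  dat$effector <- sprintf("e%03d", seq_len(n))
  dat$target <- sprintf("t%03d", seq_len(n))
  dat
}

# small PS network + LaBNE fixture shared across tests (built once)
ps500_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- generate_ps_network(
        ps_params(N = 500, m = 4, gamma = 2.5, temperature = 0.1), seed = 3)
      rad <- assign_radial_coords(net$edges, gamma = 2.5)
      ang <- labne_angles(net$edges)
      cache <<- list(net = net, radii = rad, labne = ang)
    }
    cache
  }
})
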