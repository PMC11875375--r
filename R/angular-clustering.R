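#' Circular gaps between consecutive sorted angles
#'
#' Sorts the angles increasingly and returns the `n` gaps of the circular
#' sequence: the `n - 1` consecutive differences plus the wrap-around gap
#' `w - (max - min)`. The gaps always sum to `w`.
#'
#' @param thetas Numeric vector of angles in `[0, w)` (at least 2).
#' @param w Angular span (default `2*pi`).
#' @return Tibble with columns `gap` (width) and `after` (index into the
#'   sorted angle order after which the gap opens; the wrap gap follows the
#'   last sorted angle).
#' @export
circular_gaps <- function(thetas, w = 2 * pi) {
  if (length(thetas) < 2) {
    stop("need at least 2 angles to compute gaps", call. = FALSE)
  }
  if (any(thetas < 0) || any(thetas >= w)) {
    stop("angles must lie in [0, w)", call. = FALSE)
  }
  s <- sort(thetas)
  tibble::tibble(
    gap = c(diff(s), w - (max(s) - min(s))),
    after = seq_along(s)
  )
}

#' Cluster nodes by cutting large angular gaps
#'
#' Cuts the circle at every gap strictly greater than `g`; each remaining
#' arc of consecutive angles forms one cluster. If any resulting cluster
#' holds fewer than `min_size` nodes the call fails with a constraint error
#' (choose `g` with [select_gap_size()]). If no gap exceeds `g`, all nodes
#' fall into a single cluster.
#'
#' @param nodes Data frame with columns `id` and `theta` (angles in
#'   `[0, w)`).
#' @param g Gap threshold (> 0); the published defaults are 0.0077 for
#'   top-level clustering (minimum 3 members) and 0.0042 for subclustering
#'   the first sector (minimum 5).
#' @param min_size Minimum cluster membership.
#' @param w Angular span.
#' @return Tibble `id`, `theta`, `cluster` (integer labels, 1 = cluster
#'   whose first member has the smallest angle after the largest cut),
#'   sorted by angle. Attribute `"gap_size"` records `g`.
#' @export
cluster_by_gap <- function(nodes, g, min_size = 3, w = 2 * pi) {
  stopifnot(g > 0, min_size >= 1,
            all(c("id", "theta") %in% names(nodes)))
  memb <- gap_cut(nodes, g, w, circular = TRUE)
  sizes <- table(memb$cluster)
  if (any(sizes < min_size)) {
    stop("gap size g = ", format(g), " produces ", sum(sizes < min_size),
         " cluster(s) below the minimum size ", min_size,
         "; pick g with select_gap_size()", call. = FALSE)
  }
  attr(memb, "gap_size") <- g
  memb
}

# Shared cutter. circular = TRUE considers the wrap gap; FALSE treats the
# input as an arc (subclustering).
gap_cut <- function(nodes, g, w, circular) {
  ord <- order(nodes$theta, nodes$id)
  out <- nodes[ord, c("id", "theta")]
  n <- nrow(out)
  if (n == 1) {
    out$cluster <- 1L
    return(tibble::as_tibble(out))
  }
  gaps <- diff(out$theta)
  cut_after <- which(gaps > g)            # strict: gaps equal to g stay inside
  if (!circular) {
    lab <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% cut_after)))
    out$cluster <- lab
    return(tibble::as_tibble(out))
  }
  wrap <- w - (out$theta[n] - out$theta[1])
  if (length(cut_after) == 0 && wrap <= g) {
    out$cluster <- 1L
    return(tibble::as_tibble(out))
  }
  lab <- cumsum(c(1L, as.integer(seq_len(n - 1) %in% cut_after)))
  if (wrap <= g) {
    # circle not cut at the wrap point: first and last arcs are one cluster
    lab[lab == max(lab)] <- 1L
    # relabel in order of first appearance around the circle
    lab <- match(lab, unique(lab))
  }
  out$cluster <- lab
  tibble::as_tibble(out)
}

#' Smallest gap threshold satisfying the minimum-size constraint
#'
#' Scans the observed circular gap values as candidate thresholds and
#' returns the smallest `g` whose induced clustering (see
#' [cluster_by_gap()]) has every cluster at least `min_size` strong — the
#' smallest valid `g` yields the most clusters.
#'
#' @inheritParams cluster_by_gap
#' @return The selected gap size (a single number). The largest gap is
#'   always a valid fallback when `n >= min_size`.
#' @export
select_gap_size <- function(nodes, min_size = 3, w = 2 * pi) {
  stopifnot(nrow(nodes) >= min_size)
  cand <- sort(unique(circular_gaps(nodes$theta, w)$gap))
  for (g in cand) {
    memb <- gap_cut(nodes, g, w, circular = TRUE)
    if (all(table(memb$cluster) >= min_size)) {
      return(g)
    }
  }
  cand[length(cand)]
}

#' Subcluster one angularly contiguous cluster
#'
#' Applies the gap-cutting algorithm inside a single arc: only the
#' consecutive gaps within the arc are candidates for cutting (no
#' wrap-around gap exists inside an arc).
#'
#' @param nodes Data frame `id`, `theta` restricted to one contiguous
#'   cluster.
#' @param g2 Gap threshold for the subclustering (published default 0.0042;
#'   an alternative reading of the same analysis used 0.042).
#' @param min_size2 Minimum subcluster membership (published default 5).
#' @param w Angular span.
#' @return Tibble `id`, `theta`, `cluster` (subcluster labels along the
#'   arc).
#' @export
subcluster <- function(nodes, g2, min_size2 = 5, w = 2 * pi) {
  stopifnot(g2 > 0)
  memb <- gap_cut(nodes, g2, w, circular = FALSE)
  sizes <- table(memb$cluster)
  if (any(sizes < min_size2)) {
    stop("subcluster gap g = ", format(g2), " produces cluster(s) below ",
         "the minimum size ", min_size2, call. = FALSE)
  }
  attr(memb, "gap_size") <- g2
  memb
}
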