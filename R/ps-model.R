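#' Parameters of the popularity-similarity growth model
#'
#' Bundles the parameters of the popularity-similarity (PS) model under
#' which networks grow in the hyperbolic disc: new nodes appear at radius
#' `2 ln i`, existing nodes drift outward (popularity fading with exponent
#' `beta = 1/(gamma - 1)`), and each newcomer links to the `m` hyperbolically
#' closest nodes (temperature `T = 0`) or samples targets with the Fermi-Dirac
#' connection probability `p(d) = 1 / (1 + exp((d - R_i)/(2 T)))` (`T > 0`).
#'
#' @param N Number of nodes (>= m + 1).
#' @param m Links added per new node.
#' @param gamma Target degree-distribution exponent (> 2).
#' @param temperature PS temperature in `[0, 1)`; lower values give stronger
#'   clustering.
#' @param w Angular span of the similarity dimension (default `2*pi`).
#'
#' @return A list of class `ps_params`.
#' @export
ps_params <- function(N, m, gamma = 2.97, temperature = 0.83, w = 2 * pi) {
  if (gamma <= 2) stop("gamma must exceed 2", call. = FALSE)
  if (temperature < 0 || temperature >= 1) {
    stop("temperature must lie in [0, 1)", call. = FALSE)
  }
  if (N < m + 1) stop("N must be at least m + 1", call. = FALSE)
  if (m < 1) stop("m must be a positive integer", call. = FALSE)
  structure(list(N = as.integer(N), m = as.integer(m), gamma = gamma,
                 beta = 1 / (gamma - 1), temperature = temperature, w = w),
            class = "ps_params")
}

#' @export
print.ps_params <- function(x, ...) {
  cat("PS model parameters: N =", x$N, " m =", x$m, " gamma =", x$gamma,
      "(beta =", round(x$beta, 4), ") T =", x$temperature,
      " w =", format(x$w), "\n")
  invisible(x)
}

# Disc radius R_i calibrated so the expected number of links made by node i
# is m under the Fermi-Dirac connection probability (standard PS-model form).
ps_disc_radius <- function(i, params) {
  Tt <- params$temperature
  beta <- params$beta
  m <- params$m
  r_i <- 2 * log(i)
  r_i - 2 * log((2 * Tt / sin(pi * Tt)) *
                  (1 - exp(-(1 - beta) * log(i))) / (m * (1 - beta)))
}

#' Grow a popularity-similarity network with ground-truth coordinates
#'
#' Simulates the PS growth process: node `i` is born at radius `2 ln i` with
#' a uniform angle; before each arrival every existing node `j` fades to
#' `r_j(i) = beta * 2 ln j + (1 - beta) * 2 ln i`; the newcomer connects to
#' `min(i - 1, m)` distinct existing nodes — the hyperbolically closest ones
#' at `T = 0`, or sampled by repeated Bernoulli sweeps with the Fermi-Dirac
#' probability at `T > 0` (capped at 50 sweeps, then topped up with the
#' closest remaining nodes so the link count is always exactly
#' `min(i - 1, m)`). Reported coordinates are the final (fully faded) ones.
#'
#' @param params A [ps_params()] object.
#' @param seed Integer seed; the run is fully reproducible.
#'
#' @return A list of class `ps_network` with elements
#'   \item{edges}{tibble `protein_a`, `protein_b`, `confidence` (all 1);
#'     endpoints lexicographically sorted, node IDs zero-padded `n0001` ...}
#'   \item{coords}{tibble `id`, `r`, `theta` of ground-truth final
#'     coordinates, plus `birth` (arrival rank).}
#'   \item{params}{the `ps_params` used.}
#' @export
generate_ps_network <- function(params, seed = 1L) {
  stopifnot(inherits(params, "ps_params"))
  N <- params$N
  m <- params$m
  beta <- params$beta
  Tt <- params$temperature
  w <- params$w
  set.seed(seed)

  theta <- stats::runif(N, 0, w)
  id <- sprintf("n%0*d", nchar(as.character(N)), seq_len(N))
  from <- integer(0)
  to <- integer(0)

  for (i in 2:N) {
    ex <- seq_len(i - 1)
    # radii of existing nodes after fading toward node i's arrival time
    r_ex <- beta * 2 * log(ex) + (1 - beta) * 2 * log(i)
    r_new <- 2 * log(i)
    d <- hyperbolic_distance(r_new, theta[i], r_ex, theta[ex], w)
    k <- min(i - 1, m)
    if (Tt == 0 || k == i - 1) {
      sel <- ex[order(d, ex)][seq_len(k)]
    } else {
      Ri <- ps_disc_radius(i, params)
      p <- 1 / (1 + exp((d - Ri) / (2 * Tt)))
      chosen <- logical(i - 1)
      sweeps <- 0L
      while (sum(chosen) < k && sweeps < 50L) {
        sweeps <- sweeps + 1L
        cand <- which(!chosen)
        hit <- cand[stats::runif(length(cand)) < p[cand]]
        if (length(hit) > k - sum(chosen)) {
          hit <- sample(hit, k - sum(chosen))
        }
        chosen[hit] <- TRUE
      }
      if (sum(chosen) < k) {
        rest <- which(!chosen)
        fill <- rest[order(d[rest], rest)][seq_len(k - sum(chosen))]
        chosen[fill] <- TRUE
      }
      sel <- ex[chosen]
    }
    from <- c(from, rep.int(i, length(sel)))
    to <- c(to, sel)
  }

  r_final <- beta * 2 * log(seq_len(N)) + (1 - beta) * 2 * log(N)
  edges <- tibble::tibble(
    protein_a = pmin(id[from], id[to]),
    protein_b = pmax(id[from], id[to]),
    confidence = 1
  ) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
  coords <- tibble::tibble(id = id, r = r_final, theta = theta,
                           birth = seq_len(N))
  structure(list(edges = edges, coords = coords, params = params),
            class = "ps_network")
}

#' @export
print.ps_network <- function(x, ...) {
  cat("PS network:", nrow(x$coords), "nodes,", nrow(x$edges), "edges",
      "(gamma =", x$params$gamma, ", T =", x$params$temperature, ")\n")
  invisible(x)
}

#' Plant kinase / phosphatase annotations in an embedded network
#'
#' Draws effector sets concentrated in angular sectors, emulating the
#' empirical observation that phosphorylation effectors crowd a narrow
#' region of the similarity dimension. Kinases are drawn preferentially
#' from within `spread` of `kinase_center`; phosphatases from within
#' `spread` of `phosphatase_center` (two-sector mode, the default) or
#' uniformly (`mode = "uniform"`). If a sector holds fewer nodes than
#' requested it is topped up with the angularly closest outsiders (a
#' warning is raised).
#'
#' @param coords Node coordinate tibble (`id`, `r`, `theta`).
#' @param kinase_fraction,phosphatase_fraction Fractions of nodes to label
#'   as each effector type.
#' @param kinase_center,phosphatase_center Sector centres in radians.
#' @param spread Angular half-width of each sector.
#' @param mode `"two-sector"` (default) or `"uniform"`.
#' @param w Angular span (default `2*pi`).
#' @param seed Integer seed.
#'
#' @return A list of class `ptm_annotation` with character vectors
#'   `kinases` and `phosphatases` (disjoint) and an empty `positive_pairs`
#'   tibble to be filled by [plant_positive_pairs()].
#' @export
plant_effectors <- function(coords, kinase_fraction = 0.05,
                            phosphatase_fraction = 0.02,
                            kinase_center = 1.8, phosphatase_center = 4.5,
                            spread = 0.3, mode = c("two-sector", "uniform"),
                            w = 2 * pi, seed = 1L) {
  stopifnot(kinase_fraction > 0, kinase_fraction < 1,
            phosphatase_fraction > 0, phosphatase_fraction < 1)
  mode <- match.arg(mode)
  set.seed(seed)
  n <- nrow(coords)
  n_kin <- max(1L, round(kinase_fraction * n))
  n_pho <- max(1L, round(phosphatase_fraction * n))

  draw_sector <- function(center, k, exclude) {
    pool <- coords$id[!(coords$id %in% exclude)]
    sep <- angular_separation(coords$theta[match(pool, coords$id)], center, w)
    if (mode == "uniform" || spread >= w / 2) {
      return(sample(pool, k))
    }
    inside <- pool[sep < spread]
    if (length(inside) >= k) {
      return(sample(inside, k))
    }
    warning("angular sector around ", format(center), " holds only ",
            length(inside), " nodes; filling with nearest-by-angle nodes",
            call. = FALSE)
    pool[order(sep)][seq_len(k)]
  }

  kin <- draw_sector(kinase_center, n_kin, exclude = character(0))
  pho <- draw_sector(phosphatase_center, n_pho, exclude = kin)
  structure(list(kinases = sort(kin), phosphatases = sort(pho),
                 positive_pairs = empty_pair_table()),
            class = "ptm_annotation")
}

empty_pair_table <- function() {
  tibble::tibble(effector = character(), target = character(),
                 effector_type = character())
}

#' Plant directed positive pairs on effector-incident edges
#'
#' Samples `n_pos` edges having exactly one effector endpoint, orients them
#' effector to target, and weights the sampling by `exp(-d / lambda)` in the
#' hyperbolic distance `d`, so planted positives sit at shorter distances
#' than background edges (mirroring the empirical signal).
#'
#' @param net A `ps_network` (or any list with `edges` and `coords`).
#' @param annotation A `ptm_annotation` from [plant_effectors()].
#' @param n_pos Number of positive pairs to plant.
#' @param lambda Distance scale of the sampling weight (default 2).
#' @param seed Integer seed.
#'
#' @return The annotation with `positive_pairs` filled: a tibble with
#'   columns `effector`, `target`, `effector_type`.
#' @export
plant_positive_pairs <- function(net, annotation, n_pos, lambda = 2,
                                 seed = 1L) {
  stopifnot(inherits(annotation, "ptm_annotation"), n_pos >= 0)
  set.seed(seed)
  eff <- c(annotation$kinases, annotation$phosphatases)
  edges <- net$edges
  a_eff <- edges$protein_a %in% eff
  b_eff <- edges$protein_b %in% eff
  cand <- edges[xor(a_eff, b_eff), ]
  if (n_pos > nrow(cand)) {
    stop("requested ", n_pos, " positives but only ", nrow(cand),
         " edges have exactly one effector endpoint", call. = FALSE)
  }
  if (n_pos == 0) {
    annotation$positive_pairs <- empty_pair_table()
    return(annotation)
  }
  co <- net$coords
  ia <- match(cand$protein_a, co$id)
  ib <- match(cand$protein_b, co$id)
  d <- hyperbolic_distance(co$r[ia], co$theta[ia], co$r[ib], co$theta[ib],
                           net$params$w)
  pick <- sample(nrow(cand), n_pos, prob = exp(-d / lambda))
  sel <- cand[pick, ]
  src_is_a <- sel$protein_a %in% eff
  effector <- ifelse(src_is_a, sel$protein_a, sel$protein_b)
  target <- ifelse(src_is_a, sel$protein_b, sel$protein_a)
  annotation$positive_pairs <- tibble::tibble(
    effector = effector,
    target = target,
    effector_type = ifelse(effector %in% annotation$kinases,
                           "kinase", "phosphatase")
  )
  annotation
}
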