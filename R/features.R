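#' Names of the fourteen classifier features, in canonical order
#'
#' Effector block (`r`, `theta`, `DC`, `BC`, `CC`, `EC`), target block
#' (same six), then the two edge features: hyperbolic distance and absolute
#' radial difference.
#'
#' @return Character vector of length 14.
#' @export
ptm_feature_names <- function() {
  c("r_eff", "theta_eff", "DC_eff", "BC_eff", "CC_eff", "EC_eff",
    "r_tgt", "theta_tgt", "DC_tgt", "BC_tgt", "CC_tgt", "EC_tgt",
    "hyp_dist", "r_abs_diff")
}

#' Assemble the 14 feature columns for directed pairs
#'
#' Looks up both proteins of every directed pair in a node table
#' (hyperbolic coordinates + centralities) and builds the feature matrix:
#' six node properties for the effector, six for the target, then the two
#' edge properties (hyperbolic distance and `|r_eff - r_tgt|`), which are
#' symmetric under swapping the pair's orientation.
#'
#' @param pairs Data frame with columns `effector` and `target` (and
#'   optionally `label`, carried through).
#' @param node_table Node tibble with columns `id`, `r`, `theta`, `DC`,
#'   `BC`, `CC`, `EC`.
#' @param w Angular span (default `2*pi`).
#' @return A tibble: `effector`, `target`, any carried columns, then the 14
#'   features of [ptm_feature_names()].
#' @export
assemble_features <- function(pairs, node_table, w = 2 * pi) {
  check_node_table(node_table)
  ie <- match(pairs$effector, node_table$id)
  it <- match(pairs$target, node_table$id)
  if (anyNA(ie) || anyNA(it)) {
    missing <- unique(c(pairs$effector[is.na(ie)], pairs$target[is.na(it)]))
    stop("node table lacks feature rows for: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ..." else "", call. = FALSE)
  }
  eff <- node_table[ie, c("r", "theta", "DC", "BC", "CC", "EC")]
  tgt <- node_table[it, c("r", "theta", "DC", "BC", "CC", "EC")]
  names(eff) <- paste0(names(eff), "_eff")
  names(tgt) <- paste0(names(tgt), "_tgt")
  out <- dplyr::bind_cols(
    tibble::as_tibble(pairs),
    eff, tgt,
    tibble::tibble(
      hyp_dist = hyperbolic_distance(eff$r_eff, eff$theta_eff,
                                     tgt$r_tgt, tgt$theta_tgt, w),
      r_abs_diff = radial_difference(eff$r_eff, tgt$r_tgt)
    )
  )
  out
}
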