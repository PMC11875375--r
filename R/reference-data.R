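#' Locate locally provided reference data
#'
#' Reproducing the published interactome numbers (node/edge counts of the
#' filtered human interaction network, the 24 angular clusters, the
#' classifier metrics) requires the published supplementary tables and/or
#' the pinned interactome release, which are too large to ship with the
#' package. Place them in a directory and point the option
#' `hyperptm.reference_dir` at it (default `data-raw/reference` below the
#' working directory). Expected files:
#' \describe{
#'   \item{`node_table.tsv`}{published node coordinates and centralities
#'     (columns `id`, `r`, `theta`, `DC`, `BC`, `CC`, `EC`).}
#'   \item{`hippie_v2.3.tsv`}{raw scored interactome edge list (HIPPIE
#'     dialect).}
#'   \item{`training_pairs.tsv`}{curated directed pairs (`p1`,
#'     `effector_type`, `p2`).}
#' }
#'
#' @param file Optional file name to append.
#' @return The directory (or file) path; it is not required to exist —
#'   callers check availability themselves.
#' @export
ptm_reference_path <- function(file = NULL) {
  dir <- getOption("hyperptm.reference_dir", file.path("data-raw", "reference"))
  if (is.null(file)) dir else file.path(dir, file)
}
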