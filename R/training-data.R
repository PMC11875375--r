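#' Read effector catalogs (kinases, phosphatases)
#'
#' Each catalog file lists one protein identifier per line (blank lines and
#' lines starting with `#` are ignored). A protein present in both catalogs
#' is of ambiguous effector type; [build_directed_positives()] treats such
#' proteins conservatively.
#'
#' @param kinase_path,phosphatase_path Paths to the catalog files.
#' @return A list of class `effector_catalog` with character vectors
#'   `kinases` and `phosphatases`.
#' @export
read_effector_catalog <- function(kinase_path, phosphatase_path) {
  read_ids <- function(p) {
    if (!file.exists(p)) stop("catalog file not found: ", p, call. = FALSE)
    x <- trimws(readLines(p, warn = FALSE))
    sort(unique(x[nzchar(x) & !startsWith(x, "#")]))
  }
  effector_catalog(read_ids(kinase_path), read_ids(phosphatase_path))
}

#' Construct an effector catalog from ID vectors
#'
#' @param kinases,phosphatases Character vectors of protein identifiers.
#' @return A list of class `effector_catalog`.
#' @export
effector_catalog <- function(kinases, phosphatases) {
  structure(list(kinases = sort(unique(as.character(kinases))),
                 phosphatases = sort(unique(as.character(phosphatases)))),
            class = "effector_catalog")
}

#' @export
print.effector_catalog <- function(x, ...) {
  both <- intersect(x$kinases, x$phosphatases)
  cat("Effector catalog:", length(x$kinases), "kinases,",
      length(x$phosphatases), "phosphatases",
      if (length(both)) paste0("(", length(both), " ambiguous)") else "", "\n")
  invisible(x)
}

#' Load phosphorylation / dephosphorylation PPI annotations
#'
#' Reads a tab-separated file with columns `idA`, `idB`, `code` (PSI-MI
#' interaction-type code) and keeps pairs whose code belongs to `codes` —
#' by default MI:0217 ("phosphorylation reaction") and MI:0203
#' ("dephosphorylation reaction"). Rows with other codes are skipped with a
#' warning; duplicate pairs (either orientation) collapse.
#'
#' @param path Path to the annotation TSV (header row expected).
#' @param codes Character vector of accepted PSI-MI codes.
#' @return Tibble of unordered pairs, columns `protein_a`, `protein_b`
#'   (lexicographically sorted endpoints).
#' @export
load_ptm_annotations <- function(path, codes = c("MI:0217", "MI:0203")) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 3) {
    stop("annotation file needs columns idA, idB, code", call. = FALSE)
  }
  names(raw)[1:3] <- c("idA", "idB", "code")
  drop <- !(raw$code %in% codes)
  if (any(drop)) {
    warning(sum(drop), " row(s) with interaction-type codes outside {",
            paste(codes, collapse = ", "), "} skipped", call. = FALSE)
  }
  kept <- raw[!drop, ]
  tibble::tibble(
    protein_a = pmin(kept$idA, kept$idB),
    protein_b = pmax(kept$idA, kept$idB)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Orient PTM-annotated pairs into directed positives
#'
#' Applies the direction-assignment rules for phosphorylation /
#' dephosphorylation pairs:
#' * exactly one endpoint is an effector (kinase or phosphatase) — one
#'   positive oriented effector to target;
#' * one endpoint is a kinase and the other a phosphatase — two positives,
#'   each protein acting on the other;
#' * neither endpoint is an effector, or both are the same effector type —
#'   discarded (direction undecidable);
#' * a protein listed in both catalogs is of ambiguous type; pairs whose
#'   direction would depend on resolving the ambiguity are discarded.
#'
#' Pairs are optionally restricted to the edges of a network; annotated
#' pairs missing from the network are dropped and counted.
#'
#' @param ptm_pairs Tibble of unordered pairs (`protein_a`, `protein_b`).
#' @param catalog An [effector_catalog()].
#' @param edges Optional edge tibble; when given, positives are restricted
#'   to network edges.
#' @return Tibble of class `ptm_positives`: columns `effector`, `target`,
#'   `effector_type` (`"kinase"` / `"phosphatase"`), `label` (`"positive"`),
#'   with attributes `n_discarded` (pairs failing the direction rules) and
#'   `n_missing_edges` (annotated pairs absent from the network).
#' @export
build_directed_positives <- function(ptm_pairs, catalog, edges = NULL) {
  stopifnot(inherits(catalog, "effector_catalog"))
  ambiguous <- intersect(catalog$kinases, catalog$phosphatases)
  kin <- setdiff(catalog$kinases, ambiguous)
  pho <- setdiff(catalog$phosphatases, ambiguous)

  n_missing <- 0L
  if (!is.null(edges)) {
    key <- paste(edges$protein_a, edges$protein_b, sep = "\x01")
    pk <- paste(pmin(ptm_pairs$protein_a, ptm_pairs$protein_b),
                pmax(ptm_pairs$protein_a, ptm_pairs$protein_b), sep = "\x01")
    present <- pk %in% key
    n_missing <- sum(!present)
    ptm_pairs <- ptm_pairs[present, ]
  }

  type_of <- function(id) {
    dplyr::case_when(
      id %in% ambiguous ~ "ambiguous",
      id %in% kin ~ "kinase",
      id %in% pho ~ "phosphatase",
      TRUE ~ "none"
    )
  }
  ta <- type_of(ptm_pairs$protein_a)
  tb <- type_of(ptm_pairs$protein_b)

  rows <- purrr::pmap(
    list(ptm_pairs$protein_a, ptm_pairs$protein_b, ta, tb),
    function(a, b, typa, typb) {
      one_eff <- (typa %in% c("kinase", "phosphatase")) && typb == "none"
      one_eff_rev <- (typb %in% c("kinase", "phosphatase")) && typa == "none"
      mixed <- (typa == "kinase" && typb == "phosphatase") ||
        (typa == "phosphatase" && typb == "kinase")
      if (one_eff) {
        tibble::tibble(effector = a, target = b, effector_type = typa)
      } else if (one_eff_rev) {
        tibble::tibble(effector = b, target = a, effector_type = typb)
      } else if (mixed) {
        tibble::tibble(effector = c(a, b), target = c(b, a),
                       effector_type = c(typa, typb))
      } else {
        NULL   # neither / same type / ambiguous: direction undecidable
      }
    }
  )
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(effector = character(), target = character(),
                          effector_type = character())
  }
  out$label <- "positive"
  out <- dplyr::arrange(out, .data$effector, .data$target)
  attr(out, "n_discarded") <- nrow(ptm_pairs) - length(unique(
    paste(pmin(out$effector, out$target), pmax(out$effector, out$target))))
  attr(out, "n_missing_edges") <- n_missing
  class(out) <- c("ptm_positives", class(out))
  out
}

#' Build the negative pool of directed pairs
#'
#' The candidate pool is every directed orientation of every network edge,
#' minus the positive pairs. By default the *reverse* orientation of each
#' positive is also excluded (its true label is unknown — the classifier is
#' known to struggle with pure direction); set
#' `include_reverse_positives = TRUE` for the literal "everything else is
#' negative" reading.
#'
#' @param edges Edge tibble.
#' @param positives Tibble with `effector`, `target` columns.
#' @param n Number of negatives to draw (`Inf` or `NULL` returns the full
#'   pool).
#' @param include_reverse_positives Keep reverse orientations of positives
#'   in the pool? Default `FALSE`.
#' @param seed Integer seed for the subsample.
#' @return Tibble `effector`, `target`, `effector_type` (`"unknown"`),
#'   `label` (`"negative"`).
#' @export
build_negatives <- function(edges, positives, n = NULL,
                            include_reverse_positives = FALSE, seed = 1L) {
  pool <- tibble::tibble(
    effector = c(edges$protein_a, edges$protein_b),
    target = c(edges$protein_b, edges$protein_a)
  )
  poskey <- paste(positives$effector, positives$target, sep = "\x01")
  if (!include_reverse_positives) {
    poskey <- c(poskey, paste(positives$target, positives$effector, sep = "\x01"))
  }
  pool <- pool[!(paste(pool$effector, pool$target, sep = "\x01") %in% poskey), ]
  pool <- dplyr::arrange(pool, .data$effector, .data$target)
  if (!is.null(n) && is.finite(n)) {
    if (n > nrow(pool)) {
      stop("requested ", n, " negatives but the pool holds only ",
           nrow(pool), call. = FALSE)
    }
    set.seed(seed)
    pool <- pool[sort(sample(nrow(pool), n)), ]
  }
  pool$effector_type <- "unknown"
  pool$label <- "negative"
  pool
}

#' Write / read a directed training table
#'
#' Tab-separated table with columns `p1` (effector), `effector_type`, `p2`
#' (target) — the layout of a curated directed-pair training table.
#'
#' @param positives Tibble with `effector`, `target`, `effector_type`.
#' @param path File path.
#' @export
write_training_table <- function(positives, path) {
  readr::write_tsv(tibble::tibble(p1 = positives$effector,
                                  effector_type = positives$effector_type,
                                  p2 = positives$target), path)
  invisible(path)
}

#' @rdname write_training_table
#' @return `read_training_table()` returns a tibble `effector`, `target`,
#'   `effector_type`, `label = "positive"`.
#' @export
read_training_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("p1", "effector_type", "p2") %in% names(tab)))
  tibble::tibble(effector = as.character(tab$p1),
                 target = as.character(tab$p2),
                 effector_type = as.character(tab$effector_type),
                 label = "positive")
}
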