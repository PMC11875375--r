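#' Pipeline configuration with published defaults
#'
#' Collects every tunable of the end-to-end pipeline, defaulting to the
#' published analysis configuration: confidence cutoff 0.71, embedding
#' parameters `gamma = 2.97`, `T = 0.83`, `w = 2*pi`, angular-gap sizes
#' 0.0077 (minimum cluster size 3) and 0.0042 (subclusters, minimum 5),
#' and the random-forest protocol (500 trees, `mtry = 14`, 5-fold
#' cross-validation repeated 10 times, under-sampling, 70/30 split,
#' decision threshold 0.5).
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `ptm_config`.
#' @export
ptm_config <- function(...) {
  cfg <- list(
    min_confidence = 0.71,
    gamma = 2.97,
    temperature = 0.83,
    w = 2 * pi,
    gap_size = 0.0077,
    min_cluster_size = 3,
    subgap_size = 0.0042,
    min_subcluster_size = 5,
    ntrees = 500,
    mtry = 14,
    folds = 5,
    repeats = 10,
    train_fraction = 0.7,
    threshold = 0.5,
    refine = TRUE,
    refine_window = pi / 6,
    refine_candidates = 60,
    refine_passes = 1,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "ptm_config")
}

#' @export
print.ptm_config <- function(x, ...) {
  cat("PTM-PPI pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Run the full pipeline on in-memory inputs
#'
#' Orchestrates filter, largest connected component, hyperbolic embedding,
#' centralities, angular clustering, training-set construction, training,
#' evaluation, and proteome-wide bidirectional scoring. Byte-identical
#' outputs under identical inputs, configuration and seed.
#'
#' @param interactions Interaction records tibble (`protein_a`,
#'   `protein_b`, `confidence`), e.g. from [read_interactions()].
#' @param positives Directed positive pairs (`effector`, `target`,
#'   `effector_type`), e.g. from [build_directed_positives()] or
#'   [read_training_table()].
#' @param config A [ptm_config()].
#' @param coords Optional precomputed node coordinates (`id`, `r`,
#'   `theta`); when given, embedding is skipped and these are used (e.g. a
#'   published coordinate table).
#' @param n_negatives Negatives drawn for training (default: equal to the
#'   number of positives; `Inf` takes the whole pool).
#' @param output_dir Optional directory; when given, the node, cluster,
#'   training and prediction tables are written there as TSV and the
#'   resolved configuration as `config.txt`.
#' @param quiet Suppress stage messages? Default `FALSE`.
#' @return A list of class `ptm_run`: `edges`, `node_table`, `clusters`,
#'   `training` (feature tibble), `split`, `model` (`ptm_rf`), `evaluation`
#'   (`ptm_eval`), `predictions`, `threshold_counts`, `config`.
#' @export
run_ptm_pipeline <- function(interactions, positives, config = ptm_config(),
                             coords = NULL, n_negatives = NULL,
                             output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ptm_config"))
  say <- function(...) if (!quiet) message(...)

  net <- build_network(interactions, min_confidence = config$min_confidence)
  say("filtered network: ", length(network_nodes(net)), " nodes, ",
      nrow(net), " edges")
  net <- largest_connected_component(net)
  say("largest connected component: ", length(network_nodes(net)),
      " nodes, ", nrow(net), " edges")

  if (is.null(coords)) {
    emb <- embed_network(net, gamma = config$gamma,
                         temperature = config$temperature, w = config$w,
                         refine = config$refine,
                         window = config$refine_window,
                         n_candidates = config$refine_candidates,
                         passes = config$refine_passes,
                         seed = config$seed)
    coords <- emb$coords
    say("embedded network in the hyperbolic plane")
  }
  cent <- compute_centralities(net)
  node_table <- dplyr::inner_join(coords[, c("id", "r", "theta")], cent,
                                  by = "id")
  say("computed centralities for ", nrow(node_table), " nodes")

  g_used <- config$gap_size
  clusters <- tryCatch(
    cluster_by_gap(node_table, g = g_used,
                   min_size = config$min_cluster_size, w = config$w),
    error = function(e) {
      g2 <- select_gap_size(node_table, min_size = config$min_cluster_size,
                            w = config$w)
      say("gap size ", format(g_used), " violates the minimum cluster size; ",
          "using selected g = ", format(g2))
      g_used <<- g2
      cluster_by_gap(node_table, g = g2,
                     min_size = config$min_cluster_size, w = config$w)
    })
  say("angular clustering: ", max(clusters$cluster), " clusters (g = ",
      format(g_used), ")")

  positives$label <- "positive"
  pos_in_net <- positives[
    paste(pmin(positives$effector, positives$target),
          pmax(positives$effector, positives$target), sep = "\x01") %in%
      paste(net$protein_a, net$protein_b, sep = "\x01"), ]
  if (is.null(n_negatives)) n_negatives <- nrow(pos_in_net)
  negatives <- build_negatives(net, pos_in_net, n = n_negatives,
                               seed = config$seed)
  labeled <- dplyr::bind_rows(pos_in_net, negatives)
  training <- assemble_features(labeled, node_table, w = config$w)
  say("training set: ", nrow(pos_in_net), " positives, ",
      nrow(negatives), " negatives")

  split <- split_train_test(training, train_fraction = config$train_fraction,
                            seed = config$seed)
  model <- train_rf(split$train, ntrees = config$ntrees, mtry = config$mtry,
                    folds = config$folds, repeats = config$repeats,
                    seed = config$seed)
  evaluation <- evaluate_model(model, split$test,
                               threshold = config$threshold)
  say(sprintf("model: cv accuracy %.3f | test accuracy %.3f | AUC %.3f",
              model$cv_accuracy, evaluation$accuracy, evaluation$auc))

  predictions <- score_all_edges(model, net, node_table,
                                 threshold = config$threshold, w = config$w)
  tc <- threshold_counts(predictions, c(0.5, 0.9))
  say("scored ", nrow(predictions), " directed pairs; ",
      tc$n[1], " at score >= 0.5, ", tc$n[2], " at score >= 0.9")

  run <- structure(list(edges = net, node_table = node_table,
                        clusters = clusters, training = training,
                        split = split, model = model,
                        evaluation = evaluation, predictions = predictions,
                        threshold_counts = tc, config = config),
                   class = "ptm_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_node_table(node_table, file.path(output_dir, "node_table.tsv"))
    readr::write_tsv(clusters, file.path(output_dir, "clusters.tsv"))
    write_training_table(pos_in_net, file.path(output_dir, "training_pairs.tsv"))
    write_prediction_table(predictions, file.path(output_dir, "predictions.tsv"))
    writeLines(c(paste0("seed: ", config$seed),
                 utils::capture.output(print(config))),
               file.path(output_dir, "config.txt"))
  }
  run
}

#' @export
print.ptm_run <- function(x, ...) {
  cat("PTM-PPI pipeline run\n")
  cat("  network:", length(network_nodes(x$edges)), "nodes,",
      nrow(x$edges), "edges\n")
  cat("  clusters:", max(x$clusters$cluster), "\n")
  cat(sprintf("  cv accuracy %.3f | test accuracy %.3f | AUC %.3f\n",
              x$model$cv_accuracy, x$evaluation$accuracy, x$evaluation$auc))
  cat("  predictions:", nrow(x$predictions), "directed pairs\n")
  invisible(x)
}

#' Run the pipeline on a purely synthetic demonstration network
#'
#' Generates a popularity-similarity network with planted effectors and
#' positive pairs (the synthetic analogue of the curated phosphorylation /
#' dephosphorylation training pairs) and runs the full pipeline on it using
#' the ground-truth coordinates. A one-call smoke test of every stage.
#'
#' @param N Nodes in the synthetic network (default 1000).
#' @param m Links per new node (default 4).
#' @param gamma,temperature PS parameters of the synthetic network
#'   (defaults 2.5 and 0.3 — see the vignette for the rationale).
#' @param n_pos Planted positive pairs (default 150).
#' @param config A [ptm_config()]; the embedding parameters inside it are
#'   used for inference, not generation.
#' @param use_true_coords Use the generator's ground-truth coordinates
#'   (default) instead of re-embedding (slower but exercises the embedding
#'   stage).
#' @param ... Passed to [run_ptm_pipeline()].
#' @param seed Integer seed.
#' @return A `ptm_run` (see [run_ptm_pipeline()]) plus elements
#'   `synthetic_truth` (the generated network) and `annotation`.
#' @export
run_synthetic_demo <- function(N = 1000, m = 4, gamma = 2.5,
                               temperature = 0.3, n_pos = 150,
                               config = ptm_config(seed = seed),
                               use_true_coords = TRUE, ..., seed = 1L) {
  net <- generate_ps_network(ps_params(N = N, m = m, gamma = gamma,
                                       temperature = temperature),
                             seed = seed)
  ann <- plant_effectors(net$coords, seed = seed + 1L)
  ann <- plant_positive_pairs(net, ann, n_pos = n_pos, seed = seed + 2L)
  run <- run_ptm_pipeline(net$edges, ann$positive_pairs, config = config,
                          coords = if (use_true_coords) net$coords else NULL,
                          ...)
  run$synthetic_truth <- net
  run$annotation <- ann
  run
}
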