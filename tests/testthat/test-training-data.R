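catalog <- effector_catalog(kinases = c("K1", "K2", "KB"),
                            phosphatases = c("P1", "KB"))

test_that("PTM annotation loading filters PSI-MI codes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("idA\tidB\tcode",
               "A\tB\tMI:0217",
               "B\tA\tMI:0217",       # duplicate, reversed
               "C\tD\tMI:0190",       # not a PTM reaction code
               "E\tF\tMI:0203"), path)
  expect_warning(pairs <- load_ptm_annotations(path), "skipped")
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$protein_a <= pairs$protein_b))
  expect_true("E" %in% pairs$protein_a)   # dephosphorylation rows retained
})

test_that("direction assignment follows the effector rules", {
  pairs <- tibble::tibble(protein_a = c("K1", "K1", "K1", "X", "K1", "KB"),
                          protein_b = c("X", "K2", "P1", "Y", "KB", "Z"))
  pos <- build_directed_positives(pairs, catalog)
  # K1-X: one effector -> one oriented pair
  expect_true(any(pos$effector == "K1" & pos$target == "X"))
  # K1-K2: both kinases -> discarded
  expect_false(any(pos$target == "K2" | pos$effector == "K2"))
  # K1-P1: kinase vs phosphatase -> both orientations
  expect_true(any(pos$effector == "K1" & pos$target == "P1"))
  expect_true(any(pos$effector == "P1" & pos$target == "K1"))
  expect_equal(pos$effector_type[pos$effector == "P1"], "phosphatase")
  # X-Y: no effector -> discarded; KB ambiguous -> discarded
  expect_false(any(c("X", "Y") %in% pos$effector))
  expect_false(any(pos$effector == "KB" | pos$target == "KB"))
  expect_equal(nrow(pos), 3)   # K1->X plus the two K1/P1 orientations
  expect_true(all(pos$label == "positive"))
})

test_that("every endpoint-type combination is covered by exactly one rule", {
  types <- c("none", "kinase", "phosphatase", "ambiguous")
  proto <- list(none = "X", kinase = "K1", phosphatase = "P1",
                ambiguous = "KB")
  for (ta in types) {
    for (tb in types) {
      a <- proto[[ta]]; b <- paste0(proto[[tb]], "'")
      cat2 <- effector_catalog(
        kinases = c("K1", "K1'", "KB", "KB'"),
        phosphatases = c("P1", "P1'", "KB", "KB'"))
      pos <- build_directed_positives(
        tibble::tibble(protein_a = a, protein_b = b), cat2)
      expected <- if ((ta == "kinase" && tb == "phosphatase") ||
                      (ta == "phosphatase" && tb == "kinase")) {
        2L
      } else if ((ta %in% c("kinase", "phosphatase") && tb == "none") ||
                 (tb %in% c("kinase", "phosphatase") && ta == "none")) {
        1L
      } else {
        0L
      }
      expect_equal(nrow(pos), expected, info = paste(ta, tb))
    }
  }
})

test_that("positives are restricted to network edges with a count", {
  edges <- build_network(tibble::tibble(protein_a = c("K1", "K1"),
                                        protein_b = c("X", "Y"),
                                        confidence = 1), 0)
  pairs <- tibble::tibble(protein_a = c("K1", "K1", "K1"),
                          protein_b = c("X", "Y", "Z"))
  pos <- build_directed_positives(pairs, catalog, edges = edges)
  expect_equal(nrow(pos), 2)
  expect_equal(attr(pos, "n_missing_edges"), 1L)
})

test_that("negative pool is the directed complement of the positives", {
  edges <- build_network(tibble::tibble(protein_a = c("A", "B"),
                                        protein_b = c("B", "C"),
                                        confidence = 1), 0)
  positives <- tibble::tibble(effector = "A", target = "B")
  # literal reading: all 4 orientations minus the positive
  lit <- build_negatives(edges, positives, include_reverse_positives = TRUE)
  expect_equal(nrow(lit), 3)
  # default also shields the unknown-label reverse orientation
  def <- build_negatives(edges, positives)
  expect_equal(nrow(def), 2)
  expect_false(any(def$effector == "A" & def$target == "B"))
  expect_false(any(def$effector == "B" & def$target == "A"))
  # no positives: the pool is every orientation
  expect_equal(nrow(build_negatives(edges, positives[0, ])), 4)
  expect_error(build_negatives(edges, positives, n = 10), "pool")
  sub <- build_negatives(edges, positives, n = 1, seed = 5)
  expect_equal(nrow(sub), 1)
  expect_true(all(sub$label == "negative"))
})

test_that("training tables round-trip through the TSV layout", {
  pos <- tibble::tibble(effector = c("K1", "P1"), target = c("X", "Y"),
                        effector_type = c("kinase", "phosphatase"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_table(pos, path)
  back <- read_training_table(path)
  expect_equal(back$effector, pos$effector)
  expect_equal(back$target, pos$target)
  expect_equal(back$effector_type, pos$effector_type)
  expect_true(all(back$label == "positive"))
})
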