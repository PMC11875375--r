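toy_tsv <- function(lines, header = "protein_a\tprotein_b\tconfidence") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

test_that("read_interactions parses generic and HIPPIE dialects", {
  p <- toy_tsv(c("A\tB\t0.9", "B\tC\t0.5", "A\tC\t0.71"))
  recs <- read_interactions(p)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$confidence, c(0.9, 0.5, 0.71))

  hp <- toy_tsv("P1\t111\tP2\t222\t0.85\texp",
                header = "id_a\talt_a\tid_b\talt_b\tscore\tevidence")
  rh <- read_interactions(hp, dialect = "hippie")
  expect_equal(rh$protein_a, "P1")
  expect_equal(rh$protein_b, "P2")
  expect_equal(rh$confidence, 0.85)
})

test_that("read_interactions flags empty files and malformed rows", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("protein_a\tprotein_b\tconfidence", empty)
  expect_equal(nrow(read_interactions(empty)), 0)

  bad <- toy_tsv(c("A\tB\t0.9", "C\tD\tNA"))
  expect_error(read_interactions(bad), "line.*3")
  expect_error(read_interactions(tempfile()), "not found")
  short <- toy_tsv("A\tB", header = "protein_a\tprotein_b")
  expect_error(read_interactions(short), "score column")
})

test_that("build_network filters, deduplicates and drops self-loops", {
  recs <- tibble::tibble(protein_a = c("A", "B", "C", "A"),
                         protein_b = c("B", "A", "C", "C"),
                         confidence = c(0.9, 0.9, 1.0, 0.5))
  net <- build_network(recs, min_confidence = 0.71)
  expect_equal(nrow(net), 1)
  expect_equal(net$protein_a, "A")
  expect_equal(net$protein_b, "B")

  clean <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"),
                          confidence = c(0.2, 0.3))
  expect_equal(nrow(build_network(clean, min_confidence = 0)), 2)
})

test_that("build_network is idempotent and uses an inclusive cutoff", {
  recs <- tibble::tibble(protein_a = c("A", "B", "C"),
                         protein_b = c("B", "C", "A"),
                         confidence = c(0.71, 0.709999, 0.8))
  net <- build_network(recs)
  expect_equal(nrow(net), 2)  # 0.71 kept (inclusive), 0.709999 dropped
  again <- build_network(dplyr::mutate(net, confidence = 1), 0)
  expect_equal(again[, 1:2], net[, 1:2])
})

test_that("largest component wins by size, ties by lexicographic node set", {
  edges <- build_network(tibble::tibble(
    protein_a = c("a", "b", "c", "x"), protein_b = c("b", "c", "d", "y"),
    confidence = 1), 0)
  lcc <- largest_connected_component(edges)
  expect_setequal(network_nodes(lcc), c("a", "b", "c", "d"))

  # path x-y-z (3 nodes) vs triangle a-b-c (3 nodes): tie broken toward abc
  tie <- build_network(tibble::tibble(
    protein_a = c("x", "y", "a", "b", "a"),
    protein_b = c("y", "z", "b", "c", "c"), confidence = 1), 0)
  expect_setequal(network_nodes(largest_connected_component(tie)),
                  c("a", "b", "c"))

  # connected input passes through; edge count never grows
  expect_equal(largest_connected_component(edges |> head(3)),
               edges |> head(3))
  expect_lte(nrow(lcc), nrow(edges))
  empty <- edges[0, ]
  expect_equal(nrow(largest_connected_component(empty)), 0)
})

test_that("node tables round-trip at full precision and check invariants", {
  tab <- tibble::tibble(id = sprintf("n%d", 1:5),
                        r = c(0, pi, exp(1), 1 / 3, 9.123456789012),
                        theta = runif(5, 0, 2 * pi),
                        DC = 1:5, BC = runif(5), CC = runif(5),
                        EC = runif(5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_node_table(tab, path)
  back <- read_node_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  bad <- dplyr::mutate(tab, theta = theta + 2 * pi)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(read_node_table(path2), "theta outside")
  expect_error(write_node_table(tab[, -2], path), "missing column")
})
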