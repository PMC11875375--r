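test_that("parameter validation rejects degenerate settings", {
  expect_error(ps_params(N = 10, m = 2, gamma = 2), "gamma")
  expect_error(ps_params(N = 10, m = 2, temperature = 1), "temperature")
  expect_error(ps_params(N = 2, m = 2), "N must be")
})

test_that("the first m+1 nodes form a complete graph", {
  net <- generate_ps_network(ps_params(N = 3, m = 2, temperature = 0.5),
                             seed = 1)
  expect_equal(nrow(net$edges), 3)  # K3
  expect_setequal(net$coords$id, c("n1", "n2", "n3"))
})

test_that("edge count at T = 0 matches the closed form sum min(i-1, m)", {
  net <- generate_ps_network(ps_params(N = 500, m = 2, gamma = 2.5,
                                       temperature = 0), seed = 1)
  expect_equal(nrow(net$edges), 1 + 2 * 498)
  # and link count is exact at T > 0 too (Bernoulli sweeps are topped up)
  net2 <- generate_ps_network(ps_params(N = 200, m = 3, gamma = 2.5,
                                        temperature = 0.6), seed = 2)
  expect_equal(nrow(net2$edges), 2 + 1 + 3 * 197)
})

test_that("radii follow the fading law and angles stay in [0, w)", {
  par <- ps_params(N = 100, m = 2, gamma = 3, temperature = 0.2)
  net <- generate_ps_network(par, seed = 5)
  beta <- 1 / (3 - 1)
  expect_equal(net$coords$r,
               beta * 2 * log(1:100) + (1 - beta) * 2 * log(100))
  expect_true(all(net$coords$theta >= 0 & net$coords$theta < 2 * pi))
})

test_that("generation is deterministic under a fixed seed", {
  par <- ps_params(N = 150, m = 3, gamma = 2.7, temperature = 0.4)
  a <- generate_ps_network(par, seed = 11)
  b <- generate_ps_network(par, seed = 11)
  expect_identical(a$edges, b$edges)
  expect_identical(a$coords, b$coords)
  c <- generate_ps_network(par, seed = 12)
  expect_false(identical(a$edges, c$edges))
})

test_that("clustering coefficient decreases with temperature", {
  mean_cc <- sapply(c(0, 0.5, 0.9), function(Tt) {
    mean(sapply(1:5, function(s) {
      net <- generate_ps_network(ps_params(N = 1000, m = 2, gamma = 2.5,
                                           temperature = Tt), seed = s)
      igraph::transitivity(igraph::graph_from_data_frame(net$edges[, 1:2],
                                                         directed = FALSE))
    }))
  })
  expect_true(all(diff(mean_cc) < 0))
})

test_that("planted effectors concentrate around their sector centres", {
  net <- generate_ps_network(ps_params(N = 1000, m = 2, gamma = 2.5,
                                       temperature = 0.3), seed = 4)
  ann <- plant_effectors(net$coords, kinase_fraction = 0.05,
                         kinase_center = 1.8, spread = 0.3, seed = 2)
  th <- net$coords$theta
  is_kin <- net$coords$id %in% ann$kinases
  sep <- angular_separation(th, 1.8)
  expect_lt(mean(sep[is_kin]), mean(sep[!is_kin]))
  expect_true(all(sep[is_kin] < 0.3))
  # kinases and phosphatases never overlap
  expect_length(intersect(ann$kinases, ann$phosphatases), 0)
  # uniform mode covers the whole circle
  annu <- plant_effectors(net$coords, kinase_fraction = 0.2,
                          spread = pi, mode = "uniform", seed = 2)
  expect_gt(max(angular_separation(
    th[net$coords$id %in% annu$kinases], 1.8)), 0.5)
  # reproducible
  expect_identical(ann$kinases,
                   plant_effectors(net$coords, kinase_fraction = 0.05,
                                   kinase_center = 1.8, spread = 0.3,
                                   seed = 2)$kinases)
})

test_that("planted positives are effector-incident, short-distance edges", {
  net <- generate_ps_network(ps_params(N = 1000, m = 2, gamma = 2.5,
                                       temperature = 0.3), seed = 4)
  ann <- plant_effectors(net$coords, seed = 2)
  ann <- plant_positive_pairs(net, ann, n_pos = 100, lambda = 2, seed = 3)
  pos <- ann$positive_pairs
  expect_equal(nrow(pos), 100)
  eff <- c(ann$kinases, ann$phosphatases)
  expect_true(all(pos$effector %in% eff))
  expect_true(all(!(pos$target %in% eff)))
  # every positive is a network edge
  key <- paste(net$edges$protein_a, net$edges$protein_b)
  expect_true(all(paste(pmin(pos$effector, pos$target),
                        pmax(pos$effector, pos$target)) %in% key))
  # positives sit at shorter hyperbolic distances than background
  co <- net$coords
  dist_of <- function(a, b) {
    ia <- match(a, co$id); ib <- match(b, co$id)
    hyperbolic_distance(co$r[ia], co$theta[ia], co$r[ib], co$theta[ib])
  }
  expect_lt(mean(dist_of(pos$effector, pos$target)),
            mean(dist_of(net$edges$protein_a, net$edges$protein_b)))

  expect_equal(nrow(plant_positive_pairs(net, ann, 0)$positive_pairs), 0)
  expect_error(plant_positive_pairs(net, ann, 1e6), "only")
})
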