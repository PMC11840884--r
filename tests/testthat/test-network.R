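fox <- animal_profile(4.5, "mammal")
elephant <- animal_profile(4000, "mammal")
dmax_fox <- max_dispersal_distance(fox)$d_max

test_that("link weights encode relative energy remaining with clamping", {
  # coincident patches: zero cost, full weight; a patch at Dmax/2: half
  L <- landscape(data.frame(patch_id = 1:3,
                            x = c(0, 0, dmax_fox / 2), y = c(0, 0, 0)),
                 extent = dmax_fox)
  net <- build_network(fox, L)
  expect_equal(net$weights[1, 2], 1)
  expect_equal(net$weights[1, 3], 0.5, tolerance = 1e-12)
  expect_equal(net$weights[2, 3], 0.5, tolerance = 1e-12)
  expect_identical(diag(net$weights), c(`1` = 0, `2` = 0, `3` = 0))
  # separation of exactly Dmax fully depletes the available energy
  L2 <- landscape(data.frame(patch_id = 1:2, x = c(0, dmax_fox), y = c(0, 0)),
                  extent = dmax_fox)
  expect_lt(abs(build_network(fox, L2)$weights[1, 2]), 1e-12)
  # and beyond Dmax the link is absent, not negative
  L3 <- landscape(data.frame(patch_id = 1:2, x = c(0, 2 * dmax_fox),
                             y = c(0, 0)), extent = 2 * dmax_fox)
  net3 <- build_network(fox, L3)
  expect_identical(net3$weights[1, 2], 0)
  expect_identical(connectance(net3), 0)
  expect_identical(weighted_connectance(net3), 0)
})

test_that("a four-patch square with side Dmax/2 gives the hand-derived
           weights", {
  s <- dmax_fox / 2
  L <- landscape(data.frame(patch_id = 1:4, x = c(0, s, 0, s),
                            y = c(0, 0, s, s)), extent = s)
  W <- build_network(fox, L)$weights
  sides <- rbind(c(1, 2), c(1, 3), c(2, 4), c(3, 4))
  diags <- rbind(c(1, 4), c(2, 3))
  expect_equal(unname(W[sides]), rep(0.5, 4), tolerance = 1e-9)
  expect_equal(unname(W[diags]), rep(1 - sqrt(2) / 2, 2), tolerance = 1e-9)
})

test_that("connectance metrics follow their hand-count definitions", {
  # three patches with pair weights {1, 0.5, 0}
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 0.5
  fake <- structure(list(weights = W), class = "dispersal_network")
  expect_equal(connectance(fake), 2 / 3)
  expect_equal(weighted_connectance(fake), 0.5)
})

test_that("a slow-depleting giant saturates any landscape it spans", {
  # landscape diameter far below Dmax(4000 kg running mammal)
  L <- generate_random_landscape(30, extent = 2e5, seed = 17)
  net <- build_network(elephant, L)
  expect_identical(connectance(net), 1)
  expect_true(all(net$weights[upper.tri(net$weights)] > 0))
})

test_that("weights are symmetric, bounded, and vanish exactly beyond
           Dmax", {
  L <- generate_clustered_landscape(40, 5, spread = 2e4, extent = 5e5,
                                    seed = 3)
  net <- build_network(fox, L)
  W <- net$weights
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
  ut <- upper.tri(W)
  expect_identical(unname(W[ut] == 0), unname(net$distances[ut] >= net$d_max))
  expect_lte(weighted_connectance(net), connectance(net))
  expect_lte(connectance(net), 1)
})

test_that("larger Dmax never lowers connectance on a fixed landscape", {
  for (seed in c(101, 202)) {
    for (L in list(generate_random_landscape(35, extent = 1e6, seed = seed),
                   generate_clustered_landscape(35, 4, spread = 5e4,
                                                extent = 1e6, seed = seed))) {
      small <- build_network(fox, L)
      large <- build_network(elephant, L)
      expect_gte(connectance(large), connectance(small))
      expect_gte(weighted_connectance(large), weighted_connectance(small))
    }
  }
})

test_that("scaling coordinates and Dmax together leaves connectance
           invariant", {
  L <- generate_random_landscape(25, extent = 3e5, seed = 12)
  net1 <- build_network(fox, L)
  s <- 7.5
  Ls <- landscape(transform(L$patches, x = x * s, y = y * s),
                  extent = L$extent * s)
  # Dmax is linear in the storage coefficient a2, so scaling a2 scales Dmax
  net2 <- build_network(fox, Ls, params = dispersal_params(a2 = 2e6 * s))
  expect_equal(net2$d_max, net1$d_max * s, tolerance = 1e-12)
  expect_identical(connectance(net2), connectance(net1))
  expect_equal(weighted_connectance(net2), weighted_connectance(net1),
               tolerance = 1e-12)
})

test_that("connectance agrees with an independent graph-library density
           computation", {
    skip_if_not_installed("igraph")
    L <- generate_clustered_landscape(30, 3, spread = 3e4, extent = 4e5,
                                      seed = 8)
    net <- build_network(fox, L)
    g <- igraph::graph_from_adjacency_matrix(net$weights > 0,
                                             mode = "undirected")
    expect_equal(connectance(net), igraph::edge_density(g))
})

test_that("network exports round-trip edges and record the metrics", {
  L <- generate_random_landscape(10, extent = 3e5, seed = 44)
  net <- build_network(fox, L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, f)
  edges <- utils::read.csv(f, comment.char = "#")
  expect_identical(nrow(edges), 45L)
  expect_identical(names(edges), c("source", "target", "distance_m",
                                   "weight"))
  expect_equal(sort(edges$weight), sort(network_edges(net)$weight))
  metrics <- grep("^# connectance", readLines(f), value = TRUE)
  expect_length(metrics, 1)
  expect_equal(as.numeric(sub(".*connectance=([0-9.]+),.*", "\\1", metrics)),
               connectance(net), tolerance = 1e-6)
  g <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, g)
  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(g)
  expect_identical(xml2::xml_name(doc), "graphml")
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  expect_length(nodes, 10)
})
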