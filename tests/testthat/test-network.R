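test_that("Sorensen weight matches hand values and the classic identity", {
  expect_equal(sorensen_weight(c("a", "b"), c("a", "b")), 1)
  expect_equal(sorensen_weight(c("a"), c("b")), 0)
  expect_equal(sorensen_weight(c("a", "b", "c"), c("a", "b", "d", "e")),
               2 / 3.5)
  expect_error(sorensen_weight(character(0), "a"), "empty")
  # symmetry and algebraic identity with 2|A^B| / (|A| + |B|)
  set.seed(29)
  pool <- letters
  for (i in 1:20) {
    a <- sample(pool, sample(1:10, 1))
    b <- sample(pool, sample(1:10, 1))
    w <- sorensen_weight(a, b)
    expect_equal(w, sorensen_weight(b, a))
    expect_equal(w, 2 * length(intersect(unique(a), unique(b))) /
                   (length(unique(a)) + length(unique(b))))
    expect_gte(w, 0); expect_lte(w, 1)
  }
})

test_that("network construction finds planted ties, components and isolates", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = c("z"), D = c("q"))
  regs <- c(A = "West", B = "West", C = "East", D = "East")
  cl <- classified_from_sets(sets, regs)
  net <- build_class_network(assemblage_profiles(cl))
  # chain A-B-C is one component; D is an isolate
  ci <- components_and_isolates(net)
  expect_equal(ci$n_components, 2)
  expect_equal(ci$isolates, "D")
  expect_setequal(ci$components[[1]], c("A", "B", "C"))
  expect_equal(network_density(net), 2 / 6)
  # pairwise disjoint profiles: all isolates, zero density
  sets0 <- list(A = "x", B = "y", C = "z")
  net0 <- build_class_network(
    assemblage_profiles(classified_from_sets(sets0, c(A = "W", B = "W", C = "E"))))
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(components_and_isolates(net0)$n_isolates, 3)
  expect_equal(network_density(net0), 0)
})

test_that("density conventions agree between edge list and adjacency views", {
  sets <- list(A = c("x", "y"), B = c("y", "z"), C = c("x", "z", "w"),
               D = c("w"))
  regs <- c(A = "W", B = "W", C = "E", D = "E")
  net <- build_class_network(assemblage_profiles(classified_from_sets(sets, regs)))
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  nv <- nrow(adj)
  expect_equal(network_density(net), sum(adj) / (nv * (nv - 1)))
  wadj <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  expect_equal(network_density(net, "weighted"), sum(wadj) / (nv * (nv - 1)))
  # complete 4-node network has density 1
  setsK <- list(A = "x", B = "x", C = "x", D = "x")
  netK <- build_class_network(
    assemblage_profiles(classified_from_sets(setsK, c(A = "W", B = "W", C = "E", D = "E"))))
  expect_equal(network_density(netK), 1)
})

test_that("cross-region sharing counts the intersection of regional unions", {
  sets <- list(A = c("x", "y", "s1"), B = c("s2"), C = c("s1", "s2", "z"))
  regs <- c(A = "West", B = "West", C = "East")
  cl <- classified_from_sets(sets, regs)
  expect_equal(cross_region_shared_classes(cl), 2)  # s1 and s2
  regs1 <- c(A = "West", B = "West", C = "West")
  expect_equal(
    cross_region_shared_classes(classified_from_sets(sets, regs1)), 0)
})

test_that("edge list writer round-trips weights", {
  sets <- list(A = c("x", "y"), B = c("y", "z"))
  net <- build_class_network(
    assemblage_profiles(classified_from_sets(sets, c(A = "W", B = "E"))))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_edge_list(net, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 1)
  expect_equal(d$shared_count, 1)
  expect_equal(d$sorensen_weight, 0.5)
})
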