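# Network traits: centralities, density, selectivity, differentiation,
# neighbour stability, within-group SDs

test_that("star centralities match closed forms", {
  star <- adj_from_edges(rbind(c("hub", "l1"), c("hub", "l2"),
                               c("hub", "l3")))
  cent <- node_centralities(star)
  expect_equal(cent$degree[cent$node == "hub"], 3L)
  expect_equal(cent$degree[cent$node != "hub"], rep(1L, 3))
  expect_equal(cent$strength[cent$node == "hub"], 3)
  expect_equal(cent$eigenvector[cent$node == "hub"], 1)
  expect_equal(cent$eigenvector[cent$node != "hub"], rep(1 / sqrt(3), 3))
})

test_that("empty and asymmetric inputs are handled explicitly", {
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  cent <- node_centralities(z)
  expect_true(all(cent$degree == 0 & cent$strength == 0 &
                    cent$eigenvector == 0))
  expect_match(attr(cent, "flags"), "empty")
  bad <- z; bad[1, 2] <- 1
  expect_error(node_centralities(bad), "asymmetric")
})

test_that("centralities agree with igraph on random weighted graphs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    w <- matrix(0, n, n)
    ij <- which(upper.tri(w))
    on <- sample(ij, max(1, rbinom(1, length(ij), 0.4)))
    w[on] <- runif(length(on))
    w <- w + t(w)
    dimnames(w) <- list(letters[1:n], letters[1:n])
    cent <- node_centralities(w)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(cent$degree, unname(igraph::degree(g)))
    expect_equal(cent$strength, unname(igraph::strength(g)))
    ev_ig <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
    # compare up to the dominant component (igraph scales max to 1 too)
    expect_equal(cent$eigenvector, unname(ev_ig), tolerance = 1e-6)
  }
})

test_that("edge density counts ties over potential connections", {
  tri <- adj_from_edges(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  expect_equal(edge_density(tri), 1)
  empty4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(edge_density(empty4), 0)
  two_of_six <- adj_from_edges(rbind(c("a", "b"), c("c", "d")),
                               nodes = letters[1:4])
  expect_equal(edge_density(two_of_six), 1 / 3)
  expect_true(is.na(edge_density(tri, subset = "a")))
})

test_that("individual selectivity is the sample CV over group-mate weights", {
  g <- c("A", "B", "C")
  m <- adj_from_edges(rbind(c("A", "B"), c("A", "C")), w = c(0.1, 0.3))
  expect_equal(selectivity_cv(m, "A", g), sqrt(2) / 2, tolerance = 1e-12)
  m2 <- adj_from_edges(rbind(c("A", "B")), nodes = c("A", "B", "C", "D"),
                       w = 0.2)
  expect_equal(selectivity_cv(m2, "A", c("A", "B", "C", "D")), sqrt(3),
               tolerance = 1e-12)
  meq <- adj_from_edges(rbind(c("A", "B"), c("A", "C")), w = c(0.4, 0.4))
  expect_equal(selectivity_cv(meq, "A", g), 0)
  expect_true(is.na(selectivity_cv(m, "A", c("A", "B"))))   # group too small
})

test_that("social differentiation is the CV over within-group dyads", {
  m <- adj_from_edges(rbind(c("a", "b"), c("a", "c"), c("b", "c")),
                      w = c(0.2, 0.2, 0.8))
  expect_equal(social_differentiation(m, c("a", "b", "c")),
               0.34641016 / 0.4, tolerance = 1e-6)
  # one positive dyad among six -> sample CV sqrt(6)
  m2 <- adj_from_edges(rbind(c("a", "b")), nodes = letters[1:4], w = 0.5)
  expect_equal(social_differentiation(m2, letters[1:4]), sqrt(6),
               tolerance = 1e-12)
  meq <- adj_from_edges(t(combn(letters[1:3], 2)), w = 0.3)
  expect_equal(social_differentiation(meq, letters[1:3]), 0)
})

test_that("neighbour stability is the Jaccard of binarized neighbour sets", {
  n1 <- adj_from_edges(rbind(c("x", "A"), c("x", "B")),
                       nodes = c("x", "A", "B", "C"))
  n2 <- adj_from_edges(rbind(c("x", "B"), c("x", "C")),
                       nodes = c("x", "A", "B", "C"))
  expect_equal(neighbour_stability(n1, n2, "x"), 1 / 3)
  expect_equal(neighbour_stability(n1, n1, "x"), 1)
  n0 <- adj_from_edges(rbind(c("A", "B")), nodes = c("x", "A", "B", "C"))
  expect_equal(neighbour_stability(n0, n1, "x"), 0)
  expect_true(is.na(neighbour_stability(n0, n0, "x")))
})

test_that("group SD follows the sample convention and flags degenerate input", {
  expect_equal(group_sd(c(2, 2, 2)), 0)
  expect_equal(group_sd(c(1, 3)), sqrt(2))
  expect_true(is.na(group_sd(5)))
  expect_equal(group_sd(c(1, NA, 3)), sqrt(2))
})

test_that("the tidy trait table covers all periods, nodes and groups", {
  fd <- fixture_data()
  nets <- period_networks(fd$events, fd$pcfg, fd$roster, "active")
  tt <- trait_table(nets, fd$groups)
  expect_setequal(unique(tt$period), names(nets))
  expect_setequal(unique(tt$trait[tt$unit == "node"]),
                  c("degree", "strength", "eigenvector", "selectivity"))
  expect_true(all(c("density", "differentiation", "sd_strength") %in%
                    tt$trait[tt$unit == "group"]))
  expect_equal(tt$defined, !is.na(tt$value))
  # spot check one period against direct recomputation
  m <- nets[["3"]]
  cent <- node_centralities(m)
  sub <- tt[tt$period == "3" & tt$trait == "strength" & tt$unit == "node", ]
  expect_equal(sub$value[match(cent$node, sub$id)], cent$strength)
})
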