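test_that("trivial topologies come out exactly", {
  # two haplotypes one step apart: a single 1-step edge
  hs <- toy_hapset(matrix(c(2L, 1L), 1, 2,
                          dimnames = list("P1", c("H1", "H2"))),
                   c("AAAA", "AAAT"))
  net <- median_joining_network(hs)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$steps, 1)
  expect_false(any(net$is_median))

  # chain A - B - C with no shortcut: a path, no medians
  hs2 <- toy_hapset(matrix(c(1L, 1L, 1L), 1, 3,
                           dimnames = list("P1", c("H1", "H2", "H3"))),
                    c("AAAA", "AAAT", "AATT"))
  net2 <- median_joining_network(hs2)
  expect_equal(nrow(net2$edges), 2)
  expect_equal(sum(net2$edges$steps), 2)
  expect_false(any(net2$is_median))
  expect_false(any(c("H1", "H3") %in%
                     c(net2$edges$from, net2$edges$to)[
                       duplicated(c(net2$edges$from, net2$edges$to))]))
})

test_that("the classic 3-haplotype star adds exactly one median", {
  # pairwise distances all 2; consensus AAA is absent. Exhaustive check:
  # triangle over observed nodes costs 6 (or any spanning pair-set 4);
  # the star through AAA costs 3, the optimum over all candidate networks.
  hs <- toy_hapset(matrix(c(3L, 2L, 1L), 1, 3,
                          dimnames = list("P1", c("H1", "H2", "H3"))),
                   c("AAT", "ATA", "TAA"))
  net <- median_joining_network(hs)
  expect_equal(sum(net$is_median), 1)
  med <- rownames(net$seq)[net$is_median]
  expect_equal(paste(net$seq[med, ], collapse = ""), "AAA")
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$edges$steps), 3)
  expect_equal(unname(net$freq[med]), 0L)
  # every observed haplotype is a node, each one step from the median
  expect_true(all(c("H1", "H2", "H3") %in% rownames(net$seq)))
  expect_true(all(net$edges$steps == 1))
})

test_that("homoplasy-free simulations collapse to trees tracking S", {
  for (r in 1:10) {
    sim <- simulate_coalescent(n = 12, theta = 4, seed = 12000 + r)
    if (sim$truth$S < 2) next
    hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
    if (nrow(hs$seq) < 2) next
    net <- median_joining_network(hs)
    # infinite-sites data: tree with (#nodes - 1) edges, steps sum to S
    expect_equal(nrow(net$edges), nrow(net$seq) - 1)
    expect_equal(sum(net$edges$steps), sim$truth$S)
    g <- network_to_igraph(net)
    expect_true(igraph::is_connected(g))
  }
})

test_that("the epsilon = 0 network contains a minimum spanning tree", {
  for (r in 1:5) {
    sim <- simulate_coalescent(n = 10, theta = 6, seed = 13000 + r)
    hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
    if (nrow(hs$seq) < 3) next
    net <- median_joining_network(hs)
    # the network spans all nodes and its total cost is <= the MST cost of
    # the observed haplotypes alone (medians only ever lower the cost)
    d_obs <- hamming_matrix(hs)
    g_full <- igraph::graph_from_adjacency_matrix(d_obs, mode = "undirected",
                                                  weighted = TRUE)
    mst_cost <- sum(igraph::E(igraph::mst(g_full))$weight)
    expect_lte(sum(net$edges$steps), mst_cost)
  }
})

test_that("no median vector in the final network is obsolete", {
  hs <- toy_hapset(matrix(c(1L, 1L, 1L, 1L), 1, 4,
                          dimnames = list("P1", paste0("H", 1:4))),
                   c("TAAAA", "ATAAA", "AATTA", "AATAT"))
  net <- median_joining_network(hs)
  eps <- net$epsilon
  d_full <- notophylo:::seq_dist(net$seq)
  cost <- notophylo:::msn_cost(d_full, eps)
  for (v in which(net$is_median)) {
    keep <- setdiff(seq_len(nrow(net$seq)), v)
    cost_wo <- notophylo:::msn_cost(d_full[keep, keep], eps)
    expect_gt(cost_wo, cost)
  }
})

test_that("network export writes edge CSV and GraphML", {
  hs <- toy_hapset(matrix(c(2L, 1L), 1, 2,
                          dimnames = list("P1", c("H1", "H2"))),
                   c("AAAA", "AATT"))
  net <- median_joining_network(hs)
  csvf <- tempfile(fileext = ".csv"); gml <- tempfile(fileext = ".graphml")
  write_network(net, csvf, gml)
  ed <- utils::read.csv(csvf)
  expect_equal(names(ed), c("from", "to", "steps", "sites"))
  expect_equal(ed$steps, 2)
  expect_equal(ed$sites, "3;4")
  expect_true(file.exists(gml))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 2)
})

test_that("strict-clock surrogate dating scales exactly with the rate", {
  fix <- make_structured_fixture("two_clades", seed = 321)
  hs <- collapse_haplotypes(filter_sites(fix$alignment), fix$popmap)
  dt <- strict_clock_ages(hs, "A", "B", mu = c(1e-9, 3e-9), n_boot = 50,
                          seed = 1)
  expect_equal(dt$ages$T_years[2], dt$ages$T_years[1] / 3)
  expect_equal(dt$ages$T_lower[2], dt$ages$T_lower[1] / 3)

  # identical groups -> zero net divergence and age
  hs1 <- toy_hapset(rbind(P1 = c(2L, 2L), P2 = c(2L, 2L)),
                    c("AAAA", "TTAA"), species = c("A", "B"))
  colnames(hs1$counts) <- c("H1", "H2")
  rownames(hs1$seq) <- c("H1", "H2")
  dt1 <- strict_clock_ages(hs1, "A", "B", n_boot = 10, seed = 1)
  expect_equal(dt1$d_net, 0)
  expect_equal(dt1$ages$T_years, c(0, 0))

  expect_error(strict_clock_ages(hs, "A", "nope"), "empty group")
})

test_that("known split times fall inside the site-bootstrap CI", {
  # two clades split at T_s (coalescent units); per-site rate per unit time
  # is theta/(2L), so the truth is recoverable on the simulator's own scale
  hit <- 0; n_rep <- 25
  T_s <- 6; theta <- 3; L <- 2000
  for (r in 1:n_rep) {
    sim <- simulate_coalescent(n = c(10, 10), demes = 2, migration = 0,
                               theta = theta, split_time = T_s, L = L,
                               seed = 14000 + r)
    sim$popmap$species <- c("A", "B")[as.integer(
      sub("P", "", sim$popmap$population))]
    hs <- collapse_haplotypes(filter_sites(sim$alignment), sim$popmap)
    mu_unit <- theta / (2 * sim$truth$L)
    dt <- strict_clock_ages(hs, "A", "B", mu = mu_unit, n_boot = 200,
                            seed = r)
    if (dt$ages$T_lower[1] <= T_s && T_s <= dt$ages$T_upper[1]) hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.8)
})
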