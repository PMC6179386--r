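test_that("weighted distances sum per-class traversal costs", {
  # chain: s -0.4- m1 -0.4- m2 -1- t
  net <- coab_network(tibble::tibble(
    from = c("s", "m1", "m2"), to = c("m1", "m2", "t"),
    class = c("coabundance", "coabundance", "ppi"),
    evidence = NA_character_, condition = NA_character_,
    weight = c(0.4, 0.4, 1)))
  d <- weighted_shortest_distances(net, "s", "t")
  expect_equal(unname(d[1, 1]), 1.8)

  # parallel routes: 3 ppi hops (3.0) vs 5 co-abundance hops (2.0)
  ids_p <- c("s", "p1", "p2", "t")
  ids_c <- c("s", "c1", "c2", "c3", "c4", "t")
  par <- coab_network(tibble::tibble(
    from = c(ids_p[-4], ids_c[-6]), to = c(ids_p[-1], ids_c[-1]),
    class = c(rep("ppi", 3), rep("coabundance", 5)),
    evidence = NA_character_, condition = NA_character_,
    weight = c(rep(1, 3), rep(0.4, 5))))
  expect_equal(unname(weighted_shortest_distances(par, "s", "t")[1, 1]), 2.0)

  # equal weights reduce to hop counts
  rg <- random_test_net(30, 0.15, rng_seed = 4)
  expect_equal(weighted_shortest_distances(rg),
               weighted_shortest_distances(rg, unweighted = TRUE))
})

test_that("proximity scores follow PS(c) = sum I(s)/(d+1)", {
  pg <- path_net(3)  # n01 - n02 - n03
  seeds <- tibble::tibble(protein = "n01", weight = 1)
  rk <- proximity_score(pg, seeds)
  expect_equal(rk$score[rk$protein == "n03"], 1 / 3)
  expect_equal(rk$score[rk$protein == "n01"], 1)  # the seed itself, d = 0

  star <- toy_net(rep("hub", 3), c("s1", "s2", "s3"))
  rk2 <- proximity_score(star, tibble::tibble(protein = c("s1", "s2", "s3"),
                                              weight = 1))
  expect_equal(rk2$score[rk2$protein == "hub"], 1.5)
  expect_equal(rk2$rank[rk2$protein == "hub"], 4)  # seeds score 1 + 2/3 each

  # rank/percentile bijection: rank 1 -> 100, rank n -> 0
  expect_equal(rk2$percentile, 100 * (4 - rk2$rank) / 3)
})

test_that("kernel distance damps far seeds exponentially", {
  pg <- path_net(4)
  rk <- kernel_score(pg, tibble::tibble(protein = "n01", weight = 1))
  expect_equal(rk$score[rk$protein == "n03"], 3)  # single seed: dk = d + 1
  d_all <- rk$score[order(rk$protein)]
  expect_equal(d_all, 1:4)

  two <- kernel_score(path_net(5),
                      tibble::tibble(protein = c("n02", "n04"), weight = 1))
  # n03 sits at d = 1 and d = 1; n01 at d = 1 and d = 3
  expect_equal(two$score[two$protein == "n03"], 2)
  expect_equal(two$score[two$protein == "n01"],
               -log((exp(-2) + exp(-4)) / 2), tolerance = 1e-12)
  expect_equal(round(two$score[two$protein == "n01"], 3), 2.566)
  expect_equal(two$rank[1], 1L)  # ascending: smallest dk ranks first
})

test_that("proximity and kernel agree with exhaustive oracles", {
  # unweighted graphs vs a hand-rolled BFS
  for (s in 1:6) {
    net <- random_test_net(40, 0.08, rng_seed = s)
    adj <- adj_list(net)
    nodes <- network_nodes(net)
    seeds <- tibble::tibble(protein = sample(nodes, 4), weight = 1)
    d_or <- t(vapply(seeds$protein, function(x) bfs_oracle(adj, x)[nodes],
                     numeric(length(nodes))))
    ps_or <- colSums(1 / (d_or + 1))
    dk_or <- -log(colSums(exp(-(d_or + 1))) / 4)
    rk <- proximity_score(net, seeds)
    expect_equal(rk$score[match(nodes, rk$protein)], unname(ps_or))
    kk <- kernel_score(net, seeds)
    expect_equal(kk$score[match(nodes, kk$protein)], unname(dk_or))
  }

  # weighted graphs vs exhaustive simple-path enumeration
  for (s in 1:4) {
    net <- random_test_net(9, 0.3, rng_seed = 100 + s,
                           weights = c(0.4, 1, 2))
    nodes <- network_nodes(net)
    seeds <- tibble::tibble(protein = nodes[1:2], weight = 1)
    d_or <- outer(seeds$protein, nodes,
                  Vectorize(function(a, b) enum_shortest(net, a, b)))
    ps_or <- colSums(1 / (d_or + 1))
    rk <- proximity_score(net, seeds)
    expect_equal(rk$score[match(nodes, rk$protein)], unname(ps_or),
                 tolerance = 1e-12)
  }
})

test_that("proximity is monotone under edge addition", {
  set.seed(8)
  for (i in 1:5) {
    net <- random_test_net(25, 0.12, rng_seed = 200 + i)
    nodes <- network_nodes(net)
    seeds <- tibble::tibble(protein = sample(nodes, 3), weight = 1)
    before <- proximity_score(net, seeds)
    pair <- sample(nodes, 2)
    aug <- coab_network(dplyr::bind_rows(
      tibble::as_tibble(net),
      tibble::tibble(from = pair[1], to = pair[2], class = "coabundance",
                     evidence = NA_character_, condition = NA_character_,
                     weight = 0.4)))
    after <- proximity_score(aug, seeds)
    common <- intersect(before$protein, after$protein)
    expect_true(all(after$score[match(common, after$protein)] >=
                      before$score[match(common, before$protein)] - 1e-12))
  }
})

test_that("random walk with restart solves the stationary system", {
  two <- toy_net("a", "b")
  p <- rwr_score(two, tibble::tibble(protein = "a", weight = 1),
                 restart = 0.5)
  expect_equal(p$score[p$protein == "a"], 2 / 3, tolerance = 1e-5)
  expect_equal(p$score[p$protein == "b"], 1 / 3, tolerance = 1e-5)

  net <- random_test_net(30, 0.15, rng_seed = 2)
  seeds <- tibble::tibble(protein = network_nodes(net)[1:3], weight = 1)
  rk <- rwr_score(net, seeds, restart = 0.75)
  expect_equal(sum(rk$score), 1, tolerance = 1e-4)

  # restart -> 1: probability concentrates on the seeds
  hi <- rwr_score(net, seeds, restart = 0.999)
  expect_equal(sort(hi$score, decreasing = TRUE)[1:3], rep(1 / 3, 3),
               tolerance = 1e-2)
})

test_that("degree-aware correction flattens on regular graphs, penalizes hubs", {
  ring_ids <- sprintf("r%02d", 1:8)
  ring <- toy_net(ring_ids, ring_ids[c(2:8, 1)])
  seeds <- tibble::tibble(protein = ring_ids[1:2], weight = 1)
  rw <- rwr_score(ring, seeds)
  da <- dada_score(ring, seeds)
  expect_identical(da$protein, rw$protein)  # same ordering on regular graph

  # hub and low-degree node "a" sit at the same distance from the seed;
  # the hub outranks "a" under RWR purely through its leaf degree, and the
  # degree correction reverses that
  star <- coab_network(tibble::tibble(
    from = c("x2", "x1", "x1", rep("hub", 8)),
    to = c("x1", "a", "hub", sprintf("l%d", 1:8)),
    class = "ppi", evidence = NA_character_,
    condition = NA_character_, weight = 1))
  seeds2 <- tibble::tibble(protein = "x2", weight = 1)
  rw2 <- rwr_score(star, seeds2)
  da2 <- dada_score(star, seeds2)
  expect_lt(rw2$rank[rw2$protein == "hub"], rw2$rank[rw2$protein == "a"])
  expect_gt(da2$rank[da2$protein == "hub"], rw2$rank[rw2$protein == "hub"])
  expect_lt(da2$rank[da2$protein == "a"], da2$rank[da2$protein == "hub"])

  # seeding every node makes the ratio exactly flat
  all_seeds <- tibble::tibble(protein = network_nodes(ring), weight = 1)
  flat <- dada_score(ring, all_seeds)
  expect_equal(flat$score, rep(1, 8), tolerance = 1e-6)
})

test_that("weight-ratio scan maximizes cross-validated AUROC with smallest-tie rule", {
  sc <- simulate_scenario(n_nodes = 300, mean_degree = 6, n_seeds = 30,
                          module_sizes = c(15, 15), rng_seed = 5)
  ppi <- extract_lcc(sc$network)
  corr <- permutation_significance(sc$abundance$MIFNg, n_perm = 100,
                                   rng_seed = 6)
  coa <- build_coabundance_network(corr, 0.9, 0.05)

  single <- optimize_weight_ratio(ppi, coa, sc$seeds, ratio_grid = 1,
                                  k = 5, rng_seed = 2)
  expect_equal(single$best_ratio, 1)

  # empty co-abundance set: every ratio gives the same AUROC -> smallest
  flat <- optimize_weight_ratio(ppi, coa[0, ], sc$seeds,
                                ratio_grid = c(0.5, 1, 2), k = 5,
                                rng_seed = 2)
  expect_equal(flat$best_ratio, 0.5)
  expect_equal(length(unique(flat$table$mean_auroc)), 1)

  expect_warning(
    dropped <- optimize_weight_ratio(ppi, coa, sc$seeds,
                                     ratio_grid = c(0, 1), k = 5,
                                     rng_seed = 2),
    "non-positive")
  expect_equal(dropped$table$ratio, 1)
})

test_that("seed-linked co-abundance puts the ratio optimum at or below parity", {
  # planted modules are correlation cliques, so their shortcut benefit is
  # already realized at w_C/w_P = 1; the scan should find an interior
  # maximum at or below parity, never in the up-weighted tail
  hits <- 0
  for (s in 1:10) {
    sc <- simulate_scenario(n_nodes = 400, mean_degree = 8, n_seeds = 40,
                            module_sizes = c(20, 20),
                            module_overlap_with_seeds = 0.6,
                            rng_seed = 300 + s)
    ppi <- extract_lcc(sc$network)
    corr <- permutation_significance(sc$abundance$MIFNg, n_perm = 100,
                                     rng_seed = s)
    coa <- build_coabundance_network(corr, 0.9, 0.05)
    scan <- optimize_weight_ratio(ppi, coa, sc$seeds,
                                  ratio_grid = c(0.2, 0.5, 1, 2, 5),
                                  k = 5, rng_seed = s)
    if (scan$best_ratio <= 1) hits <- hits + 1
    expect_equal(max(scan$table$mean_auroc),
                 scan$table$mean_auroc[scan$table$ratio == scan$best_ratio])
  }
  expect_gte(hits, 8)
})
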