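test_that("generated PPI networks are simple, connected and heavy-tailed", {
  net <- generate_ppi_network(10, 2, "preferential-attachment", rng_seed = 1)
  expect_equal(length(network_nodes(net)), 10)
  expect_gte(nrow(net), 9)
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))

  net2 <- generate_ppi_network(10, 2, "preferential-attachment", rng_seed = 1)
  expect_identical(tibble::as_tibble(net), tibble::as_tibble(net2))

  big <- generate_ppi_network(2000, 12, rng_seed = 7)
  deg <- igraph::degree(as_igraph(big))
  expect_gt(max(deg), 5 * mean(deg))

  dd <- generate_ppi_network(200, 6, "duplication-divergence", rng_seed = 3)
  expect_true(igraph::is_connected(as_igraph(dd)))
  expect_true(igraph::is_simple(as_igraph(dd)))

  expect_error(generate_ppi_network(10, 9, rng_seed = 1), "mean_degree")
})

test_that("seed planting respects locality from uniform to BFS neighborhoods", {
  net <- generate_ppi_network(100, 4, rng_seed = 5)
  s <- plant_seed_targets(net, 5, locality = 0, rng_seed = 3)
  expect_equal(nrow(s), 5)
  expect_equal(anyDuplicated(s$protein), 0)
  expect_true(all(s$weight == 1))

  pg <- path_net(20)
  s1 <- plant_seed_targets(pg, 5, locality = 1, rng_seed = 3)
  sub <- as_igraph(pg)
  sub <- igraph::induced_subgraph(sub, s1$protein)
  expect_true(igraph::is_connected(sub))

  # intermediate locality pulls targets closer together than uniform draws
  big <- generate_ppi_network(800, 8, rng_seed = 9)
  g <- as_igraph(big)
  mean_pairwise <- function(ids) {
    d <- igraph::distances(g, v = ids, to = ids, weights = NA)
    mean(d[upper.tri(d)])
  }
  s_loc <- plant_seed_targets(big, 60, locality = 0.5, rng_seed = 9)
  obs <- mean_pairwise(s_loc$protein)
  set.seed(1)
  unif <- replicate(100, mean_pairwise(sample(network_nodes(big), 60)))
  expect_lt(obs, mean(unif))
})

test_that("abundance time-courses anchor t0 at 1 and plant correlated modules", {
  net <- generate_ppi_network(50, 4, rng_seed = 2)
  ab <- generate_abundance_timecourse(net, module_sizes = 4, noise_sd = 0,
                                      rng_seed = 4, n_background = 5)
  m <- abundance_values(ab)
  expect_true(all(m[, "t0"] == 1))
  mods <- attr(ab, "modules")
  prof <- m[mods$module1, ]
  expect_true(all(apply(prof, 2, function(x) diff(range(x)) == 0)))
  expect_equal(min(stats::cor(t(prof))), 1)

  # no modules, huge noise: profiles are uncorrelated
  ab2 <- generate_abundance_timecourse(net, module_sizes = integer(0),
                                       noise_sd = 10, rng_seed = 6,
                                       n_background = 30)
  r <- stats::cor(t(abundance_values(ab2)))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.6)

  expect_error(generate_abundance_timecourse(net, noise_sd = -1), "noise_sd")
})

test_that("module seed overlap draws members from the seed set", {
  net <- generate_ppi_network(200, 4, rng_seed = 2)
  seeds <- plant_seed_targets(net, 40, locality = 0, rng_seed = 1)
  ab <- generate_abundance_timecourse(net, module_sizes = c(20, 20),
                                      module_overlap_with_seeds = 0.5,
                                      seeds = seeds, rng_seed = 3,
                                      n_background = 10)
  mods <- attr(ab, "modules")
  for (m in mods) {
    expect_equal(sum(m %in% seeds$protein), 10)
    expect_equal(length(m), 20)
  }
  expect_equal(anyDuplicated(unlist(mods)), 0)
})

test_that("synthetic PSM tables round-trip through aggregation", {
  net <- generate_ppi_network(30, 4, rng_seed = 2)
  ab <- generate_abundance_timecourse(net, module_sizes = 3, noise_sd = 0.2,
                                      rng_seed = 5, n_background = 7)
  psms <- generate_psm_table(ab, psm_count_range = c(1, 1), cv = 0,
                             rng_seed = 1)
  expect_equal(nrow(psms), nrow(ab))

  psms2 <- generate_psm_table(ab, psm_count_range = c(3, 9), cv = 0,
                              rng_seed = 1)
  agg <- aggregate_psms(psms2)
  expect_equal(abundance_values(agg)[agg$protein, ],
               abundance_values(ab)[agg$protein, ], tolerance = 1e-12)

  psms3 <- generate_psm_table(ab, psm_count_range = c(5, 40), cv = 0.1,
                              rng_seed = 2)
  agg3 <- aggregate_psms(psms3)
  ref <- abundance_values(ab)
  for (p in agg3$protein) {
    expect_gt(stats::cor(abundance_values(agg3)[p, ], ref[p, ]), 0.95)
  }
  expect_error(generate_psm_table(ab, cv = -0.1), "cv")
})

test_that("expression tables put planted regulators in the top decile", {
  net <- generate_ppi_network(300, 4, rng_seed = 2)
  regs <- list(stim = sample(network_nodes(net), 10))
  ep <- generate_expression_and_pathways(net, regs, n_pathways = 10,
                                         rng_seed = 4)
  fc <- ep$expression[ep$expression$condition == "stim", ]
  thr <- stats::quantile(fc$fold_change, 0.9)
  expect_true(all(fc$fold_change[fc$protein %in% regs$stim] >= thr))
  expect_true(all(regs$stim %in% ep$pathways[[ep$true_pathway]]))

  tmp <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ep$pathways, tmp)
  expect_identical(read_gmt(tmp), ep$pathways)
})

test_that("scenarios regenerate bit-identically from the same master seed", {
  a <- simulate_scenario(n_nodes = 150, mean_degree = 6, n_seeds = 20,
                         module_sizes = c(10, 10), n_pathways = 5,
                         rng_seed = 11)
  b <- simulate_scenario(n_nodes = 150, mean_degree = 6, n_seeds = 20,
                         module_sizes = c(10, 10), n_pathways = 5,
                         rng_seed = 11)
  expect_identical(tibble::as_tibble(a$network), tibble::as_tibble(b$network))
  expect_identical(a$seeds, b$seeds)
  for (cond in names(a$abundance)) {
    expect_identical(abundance_values(a$abundance[[cond]]),
                     abundance_values(b$abundance[[cond]]))
  }
  expect_identical(a$expression, b$expression)
  expect_identical(a$pathways, b$pathways)
  expect_identical(a$truth, b$truth)

  # every profiled/annotated protein is a network node
  nodes <- network_nodes(a$network)
  expect_true(all(a$abundance[[1]]$protein %in% nodes))
  expect_true(all(unlist(a$pathways) %in% nodes))
  expect_true(all(unlist(a$truth$regulators) %in% nodes))
})

test_that("seed participation dose controls the downstream AUROC gain", {
  # monotone dose response of the planted signal, at reduced scale
  overlaps <- c(0, 0.25, 0.5, 0.75, 1)
  gains <- purrr::map_dfr(overlaps, function(ov) {
    reps <- vapply(1:4, function(r) {
      sc <- simulate_scenario(n_nodes = 300, mean_degree = 6, n_seeds = 30,
                              module_sizes = c(15, 15),
                              module_overlap_with_seeds = ov,
                              conditions = c("M0", "MIFNg"),
                              rng_seed = 600 + r)
      corr <- permutation_significance(sc$abundance$MIFNg, n_perm = 80,
                                       rng_seed = r)
      coa <- build_coabundance_network(corr, 0.9, 0.05)
      ppi <- extract_lcc(sc$network)
      ev <- compare_networks_cv(ppi, combine_networks(ppi, coa, 1, 0.4),
                                sc$seeds, k = 5, rng_seed = r)
      ev$mean_auroc[["ppi_plus_coa"]] - ev$mean_auroc[["ppi"]]
    }, numeric(1))
    tibble::tibble(overlap = ov, gain = reps)
  })
  rho <- stats::cor(gains$overlap, gains$gain, method = "spearman")
  expect_gt(rho, 0)
  # and the end points separate cleanly
  expect_gt(mean(gains$gain[gains$overlap == 1]),
            mean(gains$gain[gains$overlap == 0]))
})
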