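test_that("pearson correlations recover affine relations and flag degeneracy", {
  m <- rbind(a = 1:6, b = c(2, 4, 6, 8, 10, 12), c = 6:1,
             flat = rep(2, 6))
  corr <- correlation_matrix(abundance_from_matrix(m))
  expect_equal(corr$r["a", "b"], 1)
  expect_equal(corr$r["a", "c"], -1)
  expect_true(corr$mask["a", "flat"])
  expect_equal(corr$r["a", "flat"], 0)
  expect_equal(corr$r, t(corr$r))
  expect_equal(unname(diag(corr$r)), rep(1, 4))
})

test_that("biweight midcorrelation matches pearson on clean data", {
  m <- rbind(a = 1:6, b = c(2, 4, 6, 8, 10, 12), c = 6:1)
  bc <- correlation_matrix(abundance_from_matrix(m), method = "bicor")
  expect_equal(bc$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(bc$r["a", "c"], -1, tolerance = 1e-12)

  # correlated Gaussian toys of length 6: typical agreement with pearson
  # is tight, but single weight-truncated points occasionally deviate (a
  # known small-sample property of the median/MAD standardization), so the
  # 0.15 band is asserted distributionally over a fixed-seed batch
  set.seed(42)
  devs <- replicate(100, {
    latent <- rnorm(6, sd = 1.5)
    x <- rbind(p = latent + rnorm(6, sd = 0.1),
               q = latent + rnorm(6, sd = 0.1))
    pe <- correlation_matrix(abundance_from_matrix(x))$r["p", "q"]
    bi <- correlation_matrix(abundance_from_matrix(x),
                             method = "bicor")$r["p", "q"]
    abs(pe - bi)
  })
  expect_lt(stats::median(devs), 0.01)
  expect_gte(mean(devs < 0.15), 0.9)
})

test_that("partial correlation follows the first-order closed form", {
  expect_equal(first_order_partial(0.9, 0.7, 0.7), 0.41 / 0.51,
               tolerance = 1e-12)

  # matrix implementation agrees with the closed form computed from the
  # pairwise correlations it controls for
  set.seed(7)
  X <- matrix(rnorm(18), 6, 3)
  B <- matrix(rnorm(18), 6, 3)
  colnames(X) <- colnames(B) <- c("a", "b", "c")
  pc <- coabnet:::partial_cor_matrix(X, B)
  z <- (B[, "a"] + B[, "b"]) / 2
  expect_equal(pc["a", "b"],
               first_order_partial(stats::cor(X[, "a"], X[, "b"]),
                                   stats::cor(X[, "a"], z),
                                   stats::cor(X[, "b"], z)),
               tolerance = 1e-10)

  ab <- abundance_from_matrix(rbind(a = X[, 1], b = X[, 2], c = X[, 3]))
  ctl <- abundance_from_matrix(rbind(a = B[, 1], b = B[, 2], c = B[, 3]))
  full <- correlation_matrix(ab, method = "partial", control = ctl)
  expect_equal(full$r["a", "b"], pc["a", "b"], tolerance = 1e-10)
  expect_error(correlation_matrix(ab, method = "partial"), "control")
})

test_that("permutation P* is r_>/N with strict exceedance and BH q-values", {
  set.seed(3)
  m <- matrix(rnorm(60), 10, 6)
  rownames(m) <- sprintf("p%02d", 1:10)
  corr <- permutation_significance(abundance_from_matrix(m), n_perm = 50,
                                   rng_seed = 9)
  ut <- upper.tri(corr$p)
  # P* lives on the permutation grid {0, 1/N, ..., 1}
  expect_true(all(abs(corr$p[ut] * 50 - round(corr$p[ut] * 50)) < 1e-12))
  # Q* is the BH step-up of the upper-triangle P*, hence never smaller
  expect_equal(corr$q[ut], bh_oracle(corr$p[ut]))
  expect_true(all(corr$q[ut] >= corr$p[ut] - 1e-12))

  # a perfectly correlated pair can never be strictly exceeded: P* = 0
  lin <- rbind(a = 1:6, b = 2 * (1:6))
  pl <- permutation_significance(abundance_from_matrix(lin), n_perm = 100,
                                 rng_seed = 1)
  expect_equal(pl$p["a", "b"], 0)

  # determinism under the seed
  corr2 <- permutation_significance(abundance_from_matrix(m), n_perm = 50,
                                    rng_seed = 9)
  expect_identical(corr$p, corr2$p)

  # conservative pseudo-count mode shifts the grid
  pc <- permutation_significance(abundance_from_matrix(lin), n_perm = 99,
                                 rng_seed = 1, pseudo_count = TRUE)
  expect_equal(pc$p["a", "b"], 1 / 100)
})

test_that("null profiles give calibrated empirical p-values", {
  set.seed(11)
  m <- matrix(rnorm(64 * 6), 64, 6)
  rownames(m) <- sprintf("p%03d", 1:64)
  corr <- permutation_significance(abundance_from_matrix(m), n_perm = 300,
                                   rng_seed = 21)
  frac <- mean(corr$p[upper.tri(corr$p)] <= 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("density scan counts thresholded edges and keeps the density plateau", {
  m <- rbind(a = 1:6, b = 2 * (1:6), c = 3 * (1:6), d = 1:6 + 10)
  corr <- permutation_significance(abundance_from_matrix(m), n_perm = 50,
                                   rng_seed = 2)
  scan <- density_sensitivity_scan(corr, r_grid = c(0.5, 0.7, 0.9, 0.95))
  expect_equal(scan$table$density, rep(1, 4))
  expect_equal(scan$selected, 0.95)

  # hand-set mixed case: 3 of 6 pairs pass the threshold
  corr$r[] <- -1; diag(corr$r) <- 1
  corr$r["a", "b"] <- corr$r["b", "a"] <- 0.95
  corr$r["a", "c"] <- corr$r["c", "a"] <- 0.95
  corr$r["a", "d"] <- corr$r["d", "a"] <- 0.95
  corr$q[] <- 0
  scan2 <- density_sensitivity_scan(corr, r_grid = 0.9)
  expect_equal(scan2$table$density, 0.5)
  expect_error(density_sensitivity_scan(corr, numeric(0)), "empty")
})

test_that("co-abundance networks recover planted cliques and respect thresholds", {
  net <- generate_ppi_network(60, 4, rng_seed = 8)
  ab <- generate_abundance_timecourse(net, module_sizes = 4, noise_sd = 0,
                                      rng_seed = 3, n_background = 0)
  corr <- permutation_significance(ab, n_perm = 200, rng_seed = 5)
  coa <- build_coabundance_network(corr, 0.90, 0.01, condition = "stim")
  mod <- attr(ab, "modules")$module1
  expect_equal(nrow(coa), 6)  # complete K4 over the zero-noise module
  expect_setequal(network_nodes(coa), mod)
  expect_true(all(coa$condition == "stim"))

  expect_message(empty <- build_coabundance_network(corr, 1.01, 0.01),
                 "empty")
  expect_equal(nrow(empty), 0)

  # monotonicity: raising the threshold can only drop edges
  lo <- build_coabundance_network(corr, 0.80, 0.05)
  hi <- build_coabundance_network(corr, 0.95, 0.05)
  expect_true(all(paste(hi$from, hi$to) %in% paste(lo$from, lo$to)))
})

test_that("planted modules are recovered with few cross-module edges", {
  net <- generate_ppi_network(300, 6, rng_seed = 14)
  ab <- generate_abundance_timecourse(net, module_sizes = 20,
                                      noise_sd = 0.02, rng_seed = 14,
                                      n_background = 60)
  corr <- permutation_significance(ab, n_perm = 300, rng_seed = 15)
  coa <- build_coabundance_network(corr, 0.90, 0.01)
  mod <- attr(ab, "modules")$module1
  keys <- paste(coa$from, coa$to)
  pairs <- utils::combn(sort(mod), 2)
  within <- paste(pairs[1, ], pairs[2, ])
  expect_gte(mean(within %in% keys), 0.9)
  n_cross <- sum(!(keys %in% within))
  n_cross_possible <- choose(80, 2) - choose(20, 2)
  expect_lte(n_cross / n_cross_possible, 0.01)

  # edge stats TSV export mirrors the thresholded pairs
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_coabundance_tsv(coa, tmp)
  back <- readr::read_tsv(tmp, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(coa))
  expect_true(all(back$r >= 0.9))
})
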