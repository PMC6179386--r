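#' Minimum-cost network distances
#'
#' Shortest-path distances where the cost of a path is the sum of the
#' traversal weights of its edges (w_C per co-abundance link, w_P per PPI
#' link, as set by [combine_networks()]). With all weights equal to w the
#' distances reduce to w times the unweighted hop count. Unreachable pairs
#' are `Inf`.
#'
#' @param net a `coab_network`.
#' @param sources,targets node identifier vectors (default: all nodes).
#' @param unweighted ignore traversal weights and count hops.
#' @return a numeric matrix, sources in rows, targets in columns.
#' @export
weighted_shortest_distances <- function(net, sources = NULL, targets = NULL,
                                        unweighted = FALSE) {
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  if (is.null(sources)) sources <- nodes
  if (is.null(targets)) targets <- nodes
  stopifnot(all(sources %in% nodes), all(targets %in% nodes))
  w <- if (unweighted) NA else igraph::E(g)$weight
  igraph::distances(g, v = sources, to = targets, weights = w)
}

new_ranking <- function(scores, method, higher_better = TRUE,
                        params = list()) {
  ord <- order(if (higher_better) -scores else scores, names(scores))
  n <- length(scores)
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  out <- tibble::tibble(
    protein = names(scores), score = unname(scores), rank = rank,
    percentile = if (n > 1) 100 * (n - rank) / (n - 1) else 100
  ) |> dplyr::arrange(.data$rank)
  structure(out, method = method, higher_better = higher_better,
            params = params,
            class = c("coab_ranking", class(tibble::tibble())))
}

#' @rdname proximity_score
#' @param ranking a `coab_ranking`.
#' @export
ranking_method <- function(ranking) attr(ranking, "method")

map_seeds <- function(net, seeds) {
  nodes <- network_nodes(net)
  seeds <- tibble::as_tibble(seeds)
  if (!"weight" %in% names(seeds)) seeds$weight <- 1.0
  seeds <- seeds[seeds$protein %in% nodes, , drop = FALSE]
  if (nrow(seeds) == 0) stop("no seeds map onto the network")
  stopifnot(all(seeds$weight > 0))
  seeds
}

#' Proximity score ranking
#'
#' Scores every node c of the network by PS(c) = sum over seeds s of
#' I(s) / (d_cs + 1), where d_cs is the minimum-cost network distance and
#' I(s) the seed importance weight (default 1). Seeds unreachable from a
#' candidate contribute 0; higher scores rank better. Ties are broken by
#' protein identifier.
#'
#' @param net a `coab_network` (typically from [combine_networks()]).
#' @param seeds seed-set tibble with `protein` and optional `weight`.
#' @return a `coab_ranking` tibble (`protein`, `score`, `rank`,
#'   `percentile`, rank 1 = best, percentile 100 = best).
#' @export
proximity_score <- function(net, seeds) {
  seeds <- map_seeds(net, seeds)
  d <- weighted_shortest_distances(net, sources = seeds$protein)
  ps <- colSums(seeds$weight / (d + 1))
  new_ranking(ps, "proximity", higher_better = TRUE,
              params = list(n_seeds = nrow(seeds)))
}

#' Kernel distance ranking
#'
#' dk(c) = -ln( sum over seeds of exp(-(d_cs + 1)) / |S| ); long paths are
#' exponentially damped and lower dk ranks better. Unreachable seeds
#' contribute exp(-Inf) = 0; a candidate unreachable from every seed gets
#' dk = Inf.
#'
#' @inheritParams proximity_score
#' @return a `coab_ranking` (ascending: rank 1 = smallest dk).
#' @export
kernel_score <- function(net, seeds) {
  seeds <- map_seeds(net, seeds)
  d <- weighted_shortest_distances(net, sources = seeds$protein)
  dk <- -log(colSums(exp(-(d + 1))) / nrow(seeds))
  new_ranking(dk, "kernel", higher_better = FALSE,
              params = list(n_seeds = nrow(seeds)))
}

rwr_stationary <- function(net, restart_vec, restart = 0.75, tol = 1e-6,
                           max_iter = 10000L) {
  g <- as_igraph(net)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  cs <- Matrix::colSums(A)
  W <- A %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
  e <- restart_vec[igraph::V(g)$name]
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - restart) * (W %*% p) + restart * e)
    names(p_new) <- names(e)
    if (sum(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("random walk with restart did not converge")
}

#' Random walk with restart ranking
#'
#' Stationary distribution of p <- (1 - restart) W p + restart e, with W
#' the column-normalized unweighted adjacency matrix and e uniform over the
#' seed set. Higher stationary probability ranks better.
#'
#' @inheritParams proximity_score
#' @param restart restart probability in (0, 1).
#' @param tol L1 convergence tolerance.
#' @return a `coab_ranking`.
#' @export
rwr_score <- function(net, seeds, restart = 0.75, tol = 1e-6) {
  stopifnot(restart > 0, restart < 1)
  seeds <- map_seeds(net, seeds)
  nodes <- network_nodes(net)
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds$protein] <- seeds$weight / sum(seeds$weight)
  p <- rwr_stationary(net, e, restart, tol)
  new_ranking(p, "rwr", higher_better = TRUE,
              params = list(restart = restart, n_seeds = nrow(seeds)))
}

#' Degree-aware random walk ranking (DADA-style)
#'
#' Divides each node's seeded RWR stationary probability by its stationary
#' probability under a uniform restart vector over all nodes. The uniform
#' walk captures pure degree attraction, so the ratio corrects the hub
#' bias of plain RWR: on a regular graph the reference is flat and the
#' ordering equals RWR's. Nodes with a zero reference score are excluded
#' with a message.
#'
#' @inheritParams rwr_score
#' @return a `coab_ranking` (descending ratio).
#' @export
dada_score <- function(net, seeds, restart = 0.75, tol = 1e-6) {
  stopifnot(restart > 0, restart < 1)
  seeds <- map_seeds(net, seeds)
  nodes <- network_nodes(net)
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds$protein] <- seeds$weight / sum(seeds$weight)
  p_seed <- rwr_stationary(net, e, restart, tol)
  u <- stats::setNames(rep(1 / length(nodes), length(nodes)), nodes)
  p_ref <- rwr_stationary(net, u, restart, tol)
  keep <- p_ref > 0
  if (any(!keep)) message(sum(!keep), " node(s) with zero reference score excluded")
  new_ranking(p_seed[keep] / p_ref[keep], "dada", higher_better = TRUE,
              params = list(restart = restart, n_seeds = nrow(seeds)))
}

#' Scan the co-abundance/PPI weight ratio for the best cross-validated AUROC
#'
#' For each ratio w_C / w_P (w_P fixed at 1) the PPI and co-abundance
#' networks are combined with those traversal weights and the seed set is
#' k-fold cross-validated: each fold's training seeds generate a proximity
#' ranking and the held-out seeds are the positives. Returns the ratio
#' maximizing the mean AUROC across folds; ties go to the smallest ratio.
#' Non-positive grid points would make co-abundance paths free and are
#' dropped with a warning.
#'
#' @param ppi,coa `coab_network` objects.
#' @param seeds seed-set tibble (at least k rows after mapping).
#' @param ratio_grid candidate ratios in (0, 10].
#' @param k number of folds.
#' @param rng_seed integer seed for the fold split.
#' @param method ranking method used inside the scan.
#' @return a list of class `coab_ratio_scan` with `best_ratio`, `table`
#'   (ratio, mean_auroc) and `fold_aurocs` (ratio x fold matrix).
#' @export
optimize_weight_ratio <- function(ppi, coa, seeds,
                                  ratio_grid = c(0.1, 0.2, 0.4, 0.7, 1, 2,
                                                 4, 7, 10),
                                  k = 7, rng_seed = 1L,
                                  method = "proximity") {
  if (any(ratio_grid <= 0)) {
    warning("dropping non-positive weight ratios from the grid")
    ratio_grid <- ratio_grid[ratio_grid > 0]
  }
  if (length(ratio_grid) == 0) stop("ratio grid is empty")
  ratio_grid <- sort(ratio_grid)
  seeds <- map_seeds(ppi, seeds)
  folds <- kfold_split(seeds, k = k, rng_seed = rng_seed)
  fold_auc <- matrix(NA_real_, length(ratio_grid), k,
                     dimnames = list(as.character(ratio_grid), NULL))
  for (i in seq_along(ratio_grid)) {
    net <- combine_networks(ppi, coa, w_ppi = 1, w_coa = ratio_grid[i])
    fold_auc[i, ] <- cv_fold_aurocs(net, seeds, folds, method = method)
  }
  mean_auc <- rowMeans(fold_auc)
  best <- ratio_grid[which.max(mean_auc)]  # which.max takes the first tie
  structure(list(
    best_ratio = best,
    table = tibble::tibble(ratio = ratio_grid, mean_auroc = unname(mean_auc)),
    fold_aurocs = fold_auc
  ), class = "coab_ratio_scan")
}
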