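#' Youden-style optimal rank cutoff from ROC points
#'
#' Picks the ROC point maximizing sensitivity + specificity
#' (equivalently TPR - FPR, Youden's J); its `cutoff` is the number of
#' top-ranked candidates kept. Ties go to the smallest cutoff.
#'
#' @param roc tibble of ROC points with columns `cutoff`, `tpr`, `fpr`
#'   (from [roc_curve()] or a `coab_evaluation`).
#' @return the optimal rank cutoff (integer count).
#' @export
optimal_rank_cutoff <- function(roc) {
  if (nrow(roc) < 2) stop("degenerate ROC: need at least two points")
  j <- roc$tpr - roc$fpr
  best <- which(j >= max(j) - 1e-9)
  roc$cutoff[best[which.min(roc$cutoff[best])]]
}

top_k_set <- function(scores, k, id, value) {
  # top-k identifiers by descending value, ties kept deterministically
  ord <- order(-scores[[value]], scores[[id]])
  scores[[id]][ord][seq_len(min(k, nrow(scores)))]
}

#' Triple evidence filter for candidate selection
#'
#' Intersects (i) the top `N` proteins of the network prioritization, (ii)
#' the proteins within the top `top_k` by baseline-relative abundance
#' (by default a protein qualifies if it is top-`top_k` at any single time
#' point; `abun_mode = "total"` uses the summed profile difference), and
#' (iii) the top `top_k` genes by expression fold change. Known seed
#' targets are removed from the result.
#'
#' @param ranking a `coab_ranking` from the network prioritization.
#' @param N network-rank cutoff (e.g. from [optimal_rank_cutoff()]).
#' @param abun_scores output of [relative_abundance()].
#' @param expr_scores tibble with `protein` and `fold_change`.
#' @param top_k size of the abundance and expression top lists.
#' @param seeds seed identifiers (tibble or character) removed from the
#'   candidates.
#' @param abun_mode `"per_timepoint"` or `"total"`.
#' @return tibble of candidates with their network rank, ordered by it;
#'   empty (with a warning) if the intersection is empty.
#' @export
filter_candidates <- function(ranking, N, abun_scores, expr_scores,
                              top_k = 500, seeds = NULL,
                              abun_mode = c("per_timepoint", "total")) {
  abun_mode <- match.arg(abun_mode)
  top_net <- ranking$protein[ranking$rank <= N]
  if (abun_mode == "per_timepoint") {
    dcols <- grep("^d_t", names(abun_scores), value = TRUE)
    top_ab <- unique(unlist(lapply(dcols, function(cl) {
      top_k_set(abun_scores, top_k, "protein", cl)
    })))
  } else {
    top_ab <- top_k_set(abun_scores, top_k, "protein", "total")
  }
  top_ex <- top_k_set(expr_scores, top_k, "protein", "fold_change")
  seed_ids <- if (is.null(seeds)) character(0)
              else if (is.character(seeds)) seeds else seeds$protein
  cand <- setdiff(Reduce(intersect, list(top_net, top_ab, top_ex)), seed_ids)
  if (length(cand) == 0) warning("candidate intersection is empty")
  out <- ranking[ranking$protein %in% cand, c("protein", "rank")]
  names(out) <- c("protein", "network_rank")
  dplyr::arrange(out, .data$network_rank)
}

within_set_rank <- function(proteins, value, decreasing = TRUE) {
  ord <- order(if (decreasing) -value else value, proteins)
  rk <- integer(length(proteins))
  rk[ord] <- seq_along(proteins)
  rk
}

#' Combined ranking of the filtered candidates
#'
#' Each candidate is re-ranked within the filtered set on the network
#' prioritization, the total baseline-relative abundance and the
#' expression fold change (1 = best for each); the combination score is
#' R_comb = (N_prior + N_abun + N_expr) / 3 and the final order is
#' ascending in R_comb with ties broken by N_prior then identifier.
#'
#' @param candidates character vector or tibble with a `protein` column.
#' @param ranking a `coab_ranking`.
#' @param abun_scores output of [relative_abundance()] (uses `total`).
#' @param expr_scores tibble with `protein` and `fold_change`.
#' @return tibble of class `coab_combined_ranking` with columns `protein`,
#'   `n_prior`, `n_abun`, `n_expr`, `r_comb`, `final_rank`.
#' @export
combined_rank <- function(candidates, ranking, abun_scores, expr_scores) {
  ids <- if (is.character(candidates)) candidates else candidates$protein
  stopifnot(all(ids %in% ranking$protein),
            all(ids %in% abun_scores$protein),
            all(ids %in% expr_scores$protein))
  net_rank <- ranking$rank[match(ids, ranking$protein)]
  ab <- abun_scores$total[match(ids, abun_scores$protein)]
  ex <- expr_scores$fold_change[match(ids, expr_scores$protein)]
  out <- tibble::tibble(
    protein = ids,
    n_prior = within_set_rank(ids, net_rank, decreasing = FALSE),
    n_abun = within_set_rank(ids, ab, decreasing = TRUE),
    n_expr = within_set_rank(ids, ex, decreasing = TRUE)
  )
  out$r_comb <- (out$n_prior + out$n_abun + out$n_expr) / 3
  out <- dplyr::arrange(out, .data$r_comb, .data$n_prior, .data$protein)
  out$final_rank <- seq_len(nrow(out))
  structure(out, class = c("coab_combined_ranking",
                           class(tibble::tibble())))
}

#' Candidate-to-target distance with a degree-matched node null
#'
#' D is the mean over candidates of each candidate's mean unweighted
#' shortest distance to all reachable targets. The null replaces the
#' candidate set by degree-bin-matched random nodes (logarithmic degree
#' bins, sampled uniformly within each candidate's bin) for `n_real`
#' realizations; z = (D - mean(D_r)) / sd(D_r) and
#' p_emp = P(D_r < D), so small p means candidates sit closer to the
#' targets than degree-matched chance. Observed and mean null path-length
#' histograms over all candidate-target pairs are returned.
#'
#' @param net a `coab_network`.
#' @param candidates,targets node identifier vectors.
#' @param n_real number of null realizations.
#' @param log_base base of the logarithmic degree binning.
#' @param rng_seed integer seed.
#' @return a list of class `coab_proximity` with `D`, `d_c` (per-candidate
#'   tibble), `null_D`, `z`, `p_emp`, `hist_obs` and `hist_null`.
#' @export
candidate_target_proximity <- function(net, candidates, targets,
                                       n_real = 1000, log_base = 2,
                                       rng_seed = 1L) {
  stopifnot(n_real >= 1)
  nodes <- network_nodes(net)
  candidates <- intersect(candidates, nodes)
  targets <- intersect(targets, nodes)
  stopifnot(length(candidates) > 0, length(targets) > 0)
  set.seed(rng_seed)
  g <- as_igraph(net)
  # distances from every target to every node: one matrix serves the
  # observed set and all null draws
  dist_all <- igraph::distances(g, v = targets, to = nodes, weights = NA)
  colnames(dist_all) <- nodes

  mean_to_targets <- function(set) {
    d <- dist_all[, set, drop = FALSE]
    dc <- apply(d, 2, function(x) mean(x[is.finite(x)]))
    dc[is.finite(dc)]
  }
  hist_of <- function(set, lengths) {
    d <- dist_all[, set, drop = FALSE]
    d <- d[is.finite(d)]
    vapply(lengths, function(l) sum(d == l), numeric(1))
  }

  dc <- mean_to_targets(candidates)
  if (length(dc) < length(candidates)) {
    message(length(candidates) - length(dc),
            " candidate(s) with no reachable target excluded")
  }
  D <- mean(dc)

  deg <- igraph::degree(g)
  bin_of <- floor(log(pmax(deg, 1), base = log_base))
  bins <- split(names(deg), bin_of)
  cand_bins <- as.character(bin_of[candidates])

  obs_lengths <- dist_all[, names(dc), drop = FALSE]
  max_len <- max(obs_lengths[is.finite(obs_lengths)])
  null_D <- numeric(n_real)
  null_hist <- matrix(0, n_real, max_len + 1)
  for (r in seq_len(n_real)) {
    draw <- vapply(cand_bins, function(b) {
      pool <- bins[[b]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    null_D[r] <- mean(mean_to_targets(draw))
    h <- hist_of(draw, 0:max_len)
    null_hist[r, ] <- h
  }
  structure(list(
    D = D,
    d_c = tibble::tibble(protein = names(dc), mean_dist = unname(dc)),
    null_D = null_D,
    z = (D - mean(null_D)) / stats::sd(null_D),
    p_emp = mean(null_D < D),
    hist_obs = tibble::tibble(length = 0:max_len,
                              count = hist_of(names(dc), 0:max_len)),
    hist_null = tibble::tibble(length = 0:max_len,
                               mean_count = colMeans(null_hist),
                               sd_count = apply(null_hist, 2, stats::sd))
  ), class = "coab_proximity")
}

#' @export
tidy.coab_proximity <- function(x, ...) x$d_c

#' @export
glance.coab_proximity <- function(x, ...) {
  tibble::tibble(D = x$D, null_mean = mean(x$null_D),
                 null_sd = stats::sd(x$null_D), z = x$z, p_emp = x$p_emp,
                 n_real = length(x$null_D))
}
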