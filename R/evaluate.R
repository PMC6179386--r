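#' Split a seed set into k cross-validation folds
#'
#' Disjoint near-equal test folds covering all seeds: `n %% k` folds get
#' one extra member. The same partition object must be reused for every
#' network variant being compared, so fold AUROCs are paired.
#'
#' @param seeds seed-set tibble (or character vector of identifiers).
#' @param k number of folds (>= 2, <= number of seeds).
#' @param rng_seed integer seed.
#' @return a list of k lists with elements `train` and `test`.
#' @export
kfold_split <- function(seeds, k = 7, rng_seed = 1L) {
  ids <- if (is.character(seeds)) seeds else tibble::as_tibble(seeds)$protein
  if (k < 2) stop("k must be at least 2")
  if (length(ids) < k) stop("need at least k seeds")
  set.seed(rng_seed)
  shuffled <- sample(ids)
  sizes <- rep(length(ids) %/% k, k)
  extra <- length(ids) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  idx <- split(shuffled, rep(seq_len(k), sizes))
  lapply(idx, function(test) list(train = setdiff(ids, test), test = test))
}

#' Area under the ROC curve by rank-sum
#'
#' AUROC = probability that a random positive outranks a random negative,
#' with tied scores counted 1/2 (midrank formulation). Negatives are all
#' ranked nodes that are not positives, after removing `exclude` (e.g.
#' training seeds).
#'
#' @param ranking a `coab_ranking`.
#' @param positives node identifiers; must intersect the ranking.
#' @param exclude nodes removed from the evaluation entirely.
#' @return the AUROC in \[0, 1\].
#' @export
auroc <- function(ranking, positives, exclude = NULL) {
  tbl <- ranking[!(ranking$protein %in% exclude), , drop = FALSE]
  is_pos <- tbl$protein %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) stop("need both positives and negatives")
  hb <- isTRUE(attr(ranking, "higher_better"))
  s <- if (hb) tbl$score else -tbl$score
  rk <- rank(s)  # midranks handle ties as 1/2
  (sum(rk[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

roc_points_from <- function(ord_is_pos) {
  n_pos <- sum(ord_is_pos)
  n_neg <- sum(!ord_is_pos)
  tibble::tibble(
    cutoff = 0:length(ord_is_pos),
    tpr = c(0, cumsum(ord_is_pos)) / n_pos,
    fpr = c(0, cumsum(!ord_is_pos)) / n_neg
  )
}

#' ROC and precision-recall point lists
#'
#' Points are generated by sweeping the rank cutoff from 0 to the number of
#' ranked nodes (deterministic tie-broken order), so `cutoff` is the number
#' of top-ranked nodes called positive.
#'
#' @inheritParams auroc
#' @return `roc_curve()`: tibble (cutoff, tpr, fpr); `pr_curve()`: tibble
#'   (cutoff, recall, precision).
#' @export
roc_curve <- function(ranking, positives, exclude = NULL) {
  tbl <- ranking[!(ranking$protein %in% exclude), , drop = FALSE]
  tbl <- tbl[order(tbl$rank), , drop = FALSE]
  roc_points_from(tbl$protein %in% positives)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(ranking, positives, exclude = NULL) {
  tbl <- ranking[!(ranking$protein %in% exclude), , drop = FALSE]
  tbl <- tbl[order(tbl$rank), , drop = FALSE]
  is_pos <- tbl$protein %in% positives
  i <- seq_along(is_pos)
  tibble::tibble(
    cutoff = i,
    recall = cumsum(is_pos) / sum(is_pos),
    precision = cumsum(is_pos) / i
  )
}

score_fun_for <- function(method) {
  switch(method,
         proximity = proximity_score,
         kernel = kernel_score,
         rwr = rwr_score,
         dada = dada_score,
         stop("unknown ranking method: ", method))
}

# midrank AUROC on raw scores (higher is better after sign flip)
auroc_from_scores <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  rk <- rank(scores)
  (sum(rk[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# per-fold AUROCs: train seeds score the network, held-out seeds are the
# positives, and training seeds are excluded from the negative pool.
# proximity and kernel share one all-seed distance matrix across folds,
# which makes repeated evaluation (ratio scans, random-edge nulls) cheap;
# the result is identical to scoring each fold from scratch.
cv_fold_aurocs <- function(net, seeds, folds, method = "proximity") {
  cv_eval(net, seeds, folds, method, pooled = FALSE)$aurocs
}

# shared engine: per-fold AUROCs and (optionally) pooled percentile/label
# pairs across folds for ROC/PR curves
cv_eval <- function(net, seeds, folds, method = "proximity",
                    pooled = FALSE) {
  pooled_rows <- list()
  if (method %in% c("proximity", "kernel")) {
    g <- as_igraph(net)
    nodes <- igraph::V(g)$name
    seeds <- seeds[seeds$protein %in% nodes, , drop = FALSE]
    d <- igraph::distances(g, v = seeds$protein, to = nodes,
                           weights = igraph::E(g)$weight)
    aurocs <- vapply(seq_along(folds), function(i) {
      f <- folds[[i]]
      tr <- seeds$protein %in% f$train
      s <- if (method == "proximity") {
        colSums(seeds$weight[tr] / (d[tr, , drop = FALSE] + 1))
      } else {
        log(colSums(exp(-(d[tr, , drop = FALSE] + 1))) / sum(tr))
      }
      keep <- !(nodes %in% f$train)
      if (pooled) {
        # percentile over the full node ranking, as a fold-comparable score
        ord <- order(-s, nodes)
        rk <- integer(length(s))
        rk[ord] <- seq_along(s)
        pooled_rows[[i]] <<- tibble::tibble(
          score = (100 * (length(s) - rk) / (length(s) - 1))[keep],
          is_pos = nodes[keep] %in% f$test)
      }
      auroc_from_scores(s[keep], nodes[keep] %in% f$test)
    }, numeric(1))
  } else {
    fun <- score_fun_for(method)
    aurocs <- vapply(seq_along(folds), function(i) {
      f <- folds[[i]]
      rk <- fun(net, seeds[seeds$protein %in% f$train, , drop = FALSE])
      sub <- rk[!(rk$protein %in% f$train), , drop = FALSE]
      if (pooled) {
        pooled_rows[[i]] <<- tibble::tibble(
          score = sub$percentile, is_pos = sub$protein %in% f$test)
      }
      auroc(rk, positives = f$test, exclude = f$train)
    }, numeric(1))
  }
  list(aurocs = aurocs,
       pooled = if (pooled) dplyr::bind_rows(pooled_rows) else NULL)
}

#' Two-tailed paired t-test on matched fold AUROCs
#'
#' The fold partition is shared between the two variants, so per-fold
#' AUROCs are paired; df = k - 1. All-zero differences make the p-value
#' undefined (flagged), not 0.
#'
#' @param a,b fold AUROC vectors of equal length (same fold order).
#' @return list with `t_stat`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_fold_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  diffs <- a - b
  if (stats::sd(diffs) == 0) {
    return(list(t_stat = NA_real_, df = length(a) - 1, p_value = NA_real_,
                mean_diff = mean(diffs), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t_stat = unname(tt$statistic), df = length(a) - 1,
       p_value = tt$p.value, mean_diff = mean(diffs), degenerate = FALSE)
}

#' Cross-validated comparison of two network variants
#'
#' Runs the same k-fold partition on both networks (so fold AUROCs are
#' paired), scores each fold's training seeds, evaluates on the held-out
#' seeds with training seeds removed from the negatives, and compares the
#' paired fold AUROCs with a two-tailed paired t-test (df = k - 1). If all
#' fold differences are zero the p-value is undefined and flagged rather
#' than reported as 0.
#'
#' @param ppi,ppi_plus_coa the two `coab_network` variants.
#' @param seeds seed-set tibble.
#' @param k folds.
#' @param rng_seed integer seed for the shared fold split.
#' @param method ranking method.
#' @return a list of class `coab_evaluation`: `fold_aurocs` tibble,
#'   `mean_auroc` (named), `t_stat`, `df`, `p_value`, `degenerate`,
#'   `roc` (per-variant pooled ROC points), `pr` (pooled PR points).
#' @export
compare_networks_cv <- function(ppi, ppi_plus_coa, seeds, k = 7,
                                rng_seed = 1L, method = "proximity") {
  seeds <- map_seeds(ppi, seeds)
  folds <- kfold_split(seeds, k = k, rng_seed = rng_seed)
  variants <- list(ppi = ppi, ppi_plus_coa = ppi_plus_coa)
  ev <- lapply(variants, cv_eval, seeds = seeds, folds = folds,
               method = method, pooled = TRUE)
  auc <- lapply(ev, `[[`, "aurocs")
  pt <- paired_fold_test(auc$ppi_plus_coa, auc$ppi)
  degenerate <- pt$degenerate
  t_stat <- pt$t_stat
  p_value <- pt$p_value
  roc <- lapply(ev, function(e) {
    roc_points_from(e$pooled$is_pos[order(-e$pooled$score)])
  })
  pr <- lapply(ev, function(e) {
    is_pos <- e$pooled$is_pos[order(-e$pooled$score)]
    i <- seq_along(is_pos)
    tibble::tibble(cutoff = i, recall = cumsum(is_pos) / sum(is_pos),
                   precision = cumsum(is_pos) / i)
  })
  structure(list(
    folds = folds,
    fold_aurocs = tibble::tibble(
      fold = rep(seq_len(k), 2),
      variant = rep(c("ppi", "ppi_plus_coa"), each = k),
      auroc = c(auc$ppi, auc$ppi_plus_coa)
    ),
    mean_auroc = vapply(auc, mean, numeric(1)),
    t_stat = t_stat, df = k - 1, p_value = p_value,
    degenerate = degenerate, roc = roc, pr = pr,
    method = method
  ), class = "coab_evaluation")
}

#' @export
tidy.coab_evaluation <- function(x, ...) x$fold_aurocs

#' @export
glance.coab_evaluation <- function(x, ...) {
  tibble::tibble(
    mean_auroc_ppi = x$mean_auroc[["ppi"]],
    mean_auroc_ppi_plus_coa = x$mean_auroc[["ppi_plus_coa"]],
    auroc_gain = x$mean_auroc[["ppi_plus_coa"]] - x$mean_auroc[["ppi"]],
    t_stat = x$t_stat, df = x$df, p_value = x$p_value,
    degenerate = x$degenerate
  )
}

#' Degree-preserving random-edge control for the co-abundance gain
#'
#' Repeatedly replaces the co-abundance edges by the same number of
#' degree-preserving random edges and recomputes the cross-validated mean
#' AUROC; the empirical p-value is the fraction of realizations whose
#' random AUROC is at least the co-abundance AUROC.
#'
#' @param ppi backbone network.
#' @param coa co-abundance network (template for edge counts/degrees).
#' @param seeds seed-set tibble.
#' @param n_real number of random realizations.
#' @param rng_seed integer seed (folds and realizations derive from it).
#' @param k folds.
#' @param w_coa traversal weight given to co-abundance and random edges.
#' @param method ranking method.
#' @return a list of class `coab_random_control`: `auroc_coa`,
#'   `auroc_random` (length `n_real`), `p_emp`, `auroc_ppi`.
#' @export
random_edge_control <- function(ppi, coa, seeds, n_real = 20, rng_seed = 1L,
                                k = 7, w_coa = 1.0, method = "proximity") {
  stopifnot(n_real >= 1)
  seeds <- map_seeds(ppi, seeds)
  folds <- kfold_split(seeds, k = k, rng_seed = rng_seed)
  combined <- combine_networks(ppi, coa, w_ppi = 1, w_coa = w_coa)
  auroc_coa <- mean(cv_fold_aurocs(combined, seeds, folds, method))
  auroc_ppi <- mean(cv_fold_aurocs(ppi, seeds, folds, method))
  auroc_random <- vapply(seq_len(n_real), function(r) {
    net_r <- degree_preserving_random_edges(
      ppi, template = coa, weight_new = w_coa,
      rng_seed = derive_seed(rng_seed, 1000L + r))
    mean(cv_fold_aurocs(net_r, seeds, folds, method))
  }, numeric(1))
  structure(list(
    auroc_coa = auroc_coa, auroc_ppi = auroc_ppi,
    auroc_random = auroc_random,
    p_emp = mean(auroc_random >= auroc_coa)
  ), class = "coab_random_control")
}

#' @export
glance.coab_random_control <- function(x, ...) {
  tibble::tibble(
    auroc_coa = x$auroc_coa, auroc_ppi = x$auroc_ppi,
    mean_auroc_random = mean(x$auroc_random),
    sd_auroc_random = stats::sd(x$auroc_random),
    p_emp = x$p_emp, n_real = length(x$auroc_random)
  )
}

#' Navigability: per-node average hop distance to a target set
#'
#' For each network variant, every node of `node_set` gets the mean
#' unweighted shortest distance to all reachable targets (nodes reaching
#' no target are excluded with a message). Variant distributions are
#' compared pairwise with a two-sided Mann-Whitney U test, Bonferroni
#' corrected over the number of pairwise tests.
#'
#' @param net_variants named list of `coab_network` objects.
#' @param node_set nodes whose navigability is measured.
#' @param targets target node set.
#' @return a list with `values` (tibble variant, protein, mean_dist) and
#'   `tests` (tibble variant_a, variant_b, p_raw, p_bonf).
#' @export
navigability <- function(net_variants, node_set, targets) {
  stopifnot(length(names(net_variants)) == length(net_variants))
  values <- purrr::imap_dfr(net_variants, function(net, nm) {
    nodes <- network_nodes(net)
    ns <- intersect(node_set, nodes)
    tg <- intersect(targets, nodes)
    d <- weighted_shortest_distances(net, sources = ns, targets = tg,
                                     unweighted = TRUE)
    md <- apply(d, 1, function(x) mean(x[is.finite(x)]))
    drop <- !is.finite(md)
    if (any(drop)) message(sum(drop), " node(s) with no reachable target excluded")
    tibble::tibble(variant = nm, protein = ns[!drop],
                   mean_dist = unname(md[!drop]))
  })
  combos <- utils::combn(names(net_variants), 2)
  n_tests <- ncol(combos)
  tests <- purrr::map_dfr(seq_len(n_tests), function(i) {
    a <- values$mean_dist[values$variant == combos[1, i]]
    b <- values$mean_dist[values$variant == combos[2, i]]
    # exact enumeration for small samples, normal approximation with tie
    # correction otherwise (ties force the approximation in either case);
    # fully tied samples are a p = 1 degenerate case
    p <- suppressWarnings(stats::wilcox.test(
      a, b, exact = length(a) <= 20 && length(b) <= 20)$p.value)
    if (!is.finite(p)) {
      p <- if (identical(sort(a), sort(b))) 1 else NA_real_
    }
    tibble::tibble(variant_a = combos[1, i], variant_b = combos[2, i],
                   p_raw = p, p_bonf = min(1, p * n_tests))
  })
  list(values = values, tests = tests)
}

#' Percentile ranks of a gene set within a ranking
#'
#' @inheritParams auroc
#' @param gene_set node identifiers.
#' @return numeric vector of percentiles (100 = top-ranked), one per
#'   member of `gene_set` found in the ranking.
#' @export
percentile_ranks <- function(ranking, gene_set) {
  hit <- ranking$protein %in% gene_set
  if (!any(hit)) stop("gene set does not intersect the ranking")
  ranking$percentile[hit]
}
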