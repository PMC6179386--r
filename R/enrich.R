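#' Read / write gene sets in GMT format
#'
#' Each line: set name, description, then tab-separated members. The
#' writer uses the set name as description.
#'
#' @param path file path.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(length(names(sets)) == length(sets), !anyDuplicated(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Edge overlap between a co-abundance network and a reference network
#'
#' Both networks are pruned to their shared proteins; the universe is all
#' unordered shared-protein pairs. From the 2x2 table (a = edge in both,
#' b = co-abundance only, c = reference only, d = neither) the sample odds
#' ratio ad/bc is reported with a Woolf 95% CI
#' (log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)); a zero cell triggers a
#' flagged Haldane 0.5 correction for the OR and CI only. The two-sided
#' p-value is the exact conditional (Fisher) test under the
#' minimum-likelihood rule.
#'
#' @param coa,reference `coab_network` objects.
#' @return one-row tibble with the table cells, `odds_ratio`, `ci_lo`,
#'   `ci_hi`, `p_value`, `haldane`.
#' @export
edge_overlap_enrichment <- function(coa, reference) {
  shared <- intersect(network_nodes(coa), network_nodes(reference))
  if (length(shared) < 2) stop("need at least 2 shared proteins")
  keys <- function(net) {
    e <- net[net$from %in% shared & net$to %in% shared, ]
    paste(e$from, e$to, sep = "\r")
  }
  ka <- keys(coa)
  kb <- keys(reference)
  n_univ <- length(shared) * (length(shared) - 1) / 2
  a <- length(intersect(ka, kb))
  b <- length(ka) - a
  c_ <- length(kb) - a
  d <- n_univ - a - b - c_
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  haldane <- any(c(a, b, c_, d) == 0)
  h <- if (haldane) 0.5 else 0
  or <- (a + h) * (d + h) / ((b + h) * (c_ + h))
  se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (c_ + h) + 1 / (d + h))
  tibble::tibble(
    a = a, b = b, c = c_, d = d,
    odds_ratio = or,
    ci_lo = exp(log(or) - 1.96 * se),
    ci_hi = exp(log(or) + 1.96 * se),
    p_value = p,
    haldane = haldane
  )
}

#' Rank cutoff for the "top prioritized" set by rank-wise permutation
#'
#' Null rankings are generated from degree-bin-matched random seed sets of
#' the same size as the real one; for each rank position r the empirical
#' p-value is the fraction of realizations whose score at position r is at
#' least as good as the observed score at position r. The cutoff is the
#' largest r such that every position up to r has p < `alpha`; the
#' observed top-r proteins are returned.
#'
#' @param ranking the observed `coab_ranking`.
#' @param net the network that produced it.
#' @param seeds the real seed set.
#' @param n_real number of random seed-set realizations.
#' @param alpha per-rank empirical p threshold (`alpha >= 1` returns the
#'   full ranking).
#' @param log_base base of the logarithmic degree binning.
#' @param rng_seed integer seed.
#' @param method ranking method (must match the observed ranking's).
#' @return list with `top` (character vector, possibly empty), `cutoff`
#'   and `p_by_rank` tibble.
#' @export
top_prioritized_cutoff <- function(ranking, net, seeds, n_real = 10000,
                                   alpha = 0.01, log_base = 2,
                                   rng_seed = 1L, method = "proximity") {
  seeds <- map_seeds(net, seeds)
  set.seed(rng_seed)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  bin_of <- floor(log(pmax(deg, 1), base = log_base))
  bins <- split(names(deg), bin_of)
  seed_bins <- as.character(bin_of[seeds$protein])
  hb <- isTRUE(attr(ranking, "higher_better"))
  obs <- ranking$score[order(ranking$rank)]
  exceed <- numeric(length(obs))
  fast <- method %in% c("proximity", "kernel")
  nodes <- igraph::V(g)$name
  fun <- if (fast) NULL else score_fun_for(method)
  bin_levels <- as.integer(names(bins))
  # same-SIZE null seed sets: sample without replacement within each
  # degree bin (borrowing from neighboring bins only if a bin is smaller
  # than its seed count), so null scores are not deflated by duplicates
  draw_null_set <- function() {
    unlist(lapply(unique(seed_bins), function(b) {
      need <- sum(seed_bins == b)
      pool <- bins[[b]]
      widen <- 0L
      while (length(pool) < need) {
        widen <- widen + 1L
        lv <- bin_levels[abs(bin_levels - as.integer(b)) <= widen]
        pool <- unique(unlist(bins[as.character(lv)], use.names = FALSE))
      }
      sample(pool, need)
    }), use.names = FALSE)
  }
  for (r in seq_len(n_real)) {
    draw <- draw_null_set()
    null_sorted <- if (fast) {
      # reuse the cached graph: a null ranking is just a distance matrix
      d <- igraph::distances(g, v = draw, to = nodes,
                             weights = igraph::E(g)$weight)
      s <- if (method == "proximity") colSums(1 / (d + 1))
           else -log(colSums(exp(-(d + 1))) / length(draw))
      sort(s, decreasing = hb)
    } else {
      rk <- fun(net, tibble::tibble(protein = draw, weight = 1))
      rk$score[order(rk$rank)]
    }
    # rankings may differ in length by a few excluded nodes; pad with worst
    n <- length(obs)
    ns <- null_sorted[seq_len(min(n, length(null_sorted)))]
    length(ns) <- n
    ns[is.na(ns)] <- if (hb) -Inf else Inf
    exceed <- exceed + if (hb) (ns >= obs) else (ns <= obs)
  }
  p_by_rank <- exceed / n_real
  ok <- if (alpha >= 1) rep(TRUE, length(obs)) else p_by_rank < alpha
  cutoff <- if (ok[1]) {
    bad <- which(!ok)
    if (length(bad) == 0) length(obs) else bad[1] - 1L
  } else 0L
  list(
    top = if (cutoff > 0) ranking$protein[order(ranking$rank)][seq_len(cutoff)]
          else character(0),
    cutoff = cutoff,
    p_by_rank = tibble::tibble(rank = seq_along(obs), p_emp = p_by_rank)
  )
}

#' Hypergeometric gene-set enrichment with BH adjustment
#'
#' Upper-tail hypergeometric p-value per set (probability of an overlap at
#' least as large as observed given the universe), BH-adjusted across all
#' tested sets; rows with q at or below `q_max` are flagged significant.
#'
#' @param query node set (e.g. top prioritized proteins); restricted to the
#'   universe.
#' @param sets named list of gene sets; each is intersected with the
#'   universe, empty intersections are skipped.
#' @param universe background identifiers; defaults to the union of all
#'   set members.
#' @param q_max significance ceiling on the BH q-value.
#' @return tibble with `set`, `set_size`, `overlap`, `p`, `q`,
#'   `significant`, `members` (semicolon-joined overlap).
#' @export
hypergeometric_enrichment <- function(query, sets, universe = NULL,
                                      q_max = 0.05) {
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0) stop("empty universe")
  query <- intersect(query, universe)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0]
  rows <- purrr::imap_dfr(sets, function(members, nm) {
    ov <- intersect(query, members)
    tibble::tibble(
      set = nm, set_size = length(members), overlap = length(ov),
      p = stats::phyper(length(ov) - 1, length(members),
                        length(universe) - length(members), length(query),
                        lower.tail = FALSE),
      members = paste(sort(ov), collapse = ";")
    )
  })
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$significant <- rows$q <= q_max
  dplyr::arrange(rows[, c("set", "set_size", "overlap", "p", "q",
                          "significant", "members")], .data$p, .data$set)
}

#' Jaccard pathway network over the top prioritized proteins
#'
#' Nodes are the significantly enriched sets, sized by -log10(q); edges
#' connect set pairs whose Jaccard index over their top-prioritized
#' members, J = |A n B| / |A u B|, is at least `j_min`.
#'
#' @param rows significant rows of [hypergeometric_enrichment()].
#' @param top_proteins the top prioritized proteins defining memberships.
#' @param sets the full gene-set collection (named list).
#' @param j_min minimum Jaccard index for an edge.
#' @return list of class `coab_pathway_network` with `nodes` (set,
#'   neglog_q) and `edges` (set_a, set_b, jaccard).
#' @export
pathway_network <- function(rows, top_proteins, sets, j_min = 0.1) {
  rows <- rows[rows$significant, , drop = FALSE]
  members <- lapply(sets[rows$set], intersect, top_proteins)
  nodes <- tibble::tibble(set = rows$set, neglog_q = -log10(rows$q))
  edges <- tibble::tibble(set_a = character(0), set_b = character(0),
                          jaccard = numeric(0))
  if (nrow(rows) >= 2) {
    combos <- utils::combn(rows$set, 2)
    j <- vapply(seq_len(ncol(combos)), function(i) {
      a <- members[[combos[1, i]]]
      b <- members[[combos[2, i]]]
      u <- length(union(a, b))
      if (u == 0) 0 else length(intersect(a, b)) / u
    }, numeric(1))
    keep <- j >= j_min & j > 0
    edges <- tibble::tibble(set_a = combos[1, keep],
                            set_b = combos[2, keep], jaccard = j[keep])
  }
  structure(list(nodes = nodes, edges = edges),
            class = "coab_pathway_network")
}
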