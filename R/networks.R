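#' Interaction networks as tidy edge tables
#'
#' A `coab_network` is a tibble of undirected edges with one row per protein
#' pair and columns `from`, `to`, `class` (`"ppi"`, `"coabundance"` or
#' `"both"`), `evidence` (semicolon-separated experimental evidence flags,
#' may be `NA`), `condition` (stimulation condition tag for co-abundance
#' edges, `NA` otherwise) and `weight` (positive traversal cost used by the
#' shortest-path machinery). Edges are stored canonically with
#' `from < to`; self-loops are rejected and parallel edges merged (classes
#' unioned to `"both"`, evidence unioned, the smaller weight kept).
#'
#' @param edges data frame with at least `from` and `to` columns; optional
#'   `class`, `evidence`, `condition`, `weight` columns are filled with
#'   defaults (`"ppi"`, `NA`, `NA`, `1`).
#' @return a tibble of class `coab_network`.
#' @export
#' @examples
#' net <- coab_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' network_nodes(net)
coab_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (!"class" %in% names(edges)) edges$class <- "ppi"
  if (!"evidence" %in% names(edges)) edges$evidence <- NA_character_
  if (!"condition" %in% names(edges)) edges$condition <- NA_character_
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- dplyr::mutate(
    edges,
    from = as.character(.data$from),
    to = as.character(.data$to),
    weight = as.numeric(.data$weight)
  )
  if (any(edges$from == edges$to)) {
    stop("self-loops are not allowed in a coab_network")
  }
  if (any(!is.na(edges$weight) & edges$weight <= 0)) {
    stop("edge traversal weights must be positive")
  }
  edges <- edges[, c("from", "to", "class", "evidence", "condition",
                     "weight")]
  if (nrow(edges) == 0) {
    return(structure(edges, class = c("coab_network",
                                      class(tibble::tibble()))))
  }
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  # merge parallel edges: classes union to "both", evidence unioned, min weight
  edges <- edges |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      class = merge_classes(.data$class),
      evidence = merge_evidence(.data$evidence),
      condition = merge_conditions(.data$condition),
      weight = min(.data$weight),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$from, .data$to)
  structure(edges, class = c("coab_network", class(tibble::tibble())))
}

merge_classes <- function(x) {
  u <- unique(unlist(strsplit(x, ";", fixed = TRUE)))
  u <- u[!is.na(u)]
  if (length(u) == 1) u else "both"
}

merge_evidence <- function(x) {
  u <- sort(unique(unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE))))
  if (length(u) == 0) NA_character_ else paste(u, collapse = ";")
}

merge_conditions <- function(x) {
  u <- sort(unique(x[!is.na(x)]))
  if (length(u) == 0) NA_character_ else paste(u, collapse = ";")
}

#' @rdname coab_network
#' @param net a `coab_network`.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$from, net$to)))
}

#' Convert a coab_network to an igraph graph
#'
#' The `weight` column becomes the igraph `weight` edge attribute, so
#' igraph's shortest-path routines interpret it as a traversal cost.
#'
#' @param net a `coab_network`.
#' @return an undirected [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net[, c("from", "to", "class", "condition", "weight")]),
    directed = FALSE
  )
}

#' Read / write networks as edge-list TSV
#'
#' Columns: `from`, `to`, `class`, `evidence`, `condition`, `weight`.
#' Missing optional columns are defaulted on read.
#'
#' @param path file path.
#' @return `read_network_tsv()` returns a `coab_network`;
#'   `write_network_tsv()` returns `path` invisibly.
#' @export
read_network_tsv <- function(path) {
  coab_network(readr::read_tsv(path, show_col_types = FALSE,
                               progress = FALSE))
}

#' @rdname read_network_tsv
#' @param net a `coab_network`.
#' @export
write_network_tsv <- function(net, path) {
  readr::write_tsv(tibble::as_tibble(net), path, progress = FALSE)
  invisible(path)
}

#' Remove edges supported only by discardable evidence
#'
#' Literature interactomes mix direct physical evidence with indirect
#' co-complex associations and single low-throughput reports that carry
#' investigation bias. An edge is removed iff its evidence set is non-empty
#' and entirely contained in `remove`; any retained evidence type keeps the
#' edge. Nodes left without edges drop out of the node set.
#'
#' @param net a `coab_network`.
#' @param remove character vector of evidence flags to discard.
#' @return the de-noised `coab_network`.
#' @export
denoise_ppi <- function(net, remove = c("low-throughput", "co-complex")) {
  ev <- strsplit(ifelse(is.na(net$evidence), "", net$evidence), ";",
                 fixed = TRUE)
  drop <- vapply(ev, function(e) length(e) > 0 && all(e %in% remove),
                 logical(1))
  coab_network(net[!drop, , drop = FALSE])
}

#' Extract the largest connected component
#'
#' Ties in component size are broken by the component containing the
#' lexicographically smallest node, making the result deterministic.
#'
#' @param net a `coab_network`.
#' @return the `coab_network` restricted to the LCC.
#' @export
extract_lcc <- function(net) {
  if (nrow(net) == 0) stop("cannot extract the LCC of an empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # pick the tied component holding the smallest node id
    first_member <- vapply(best, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, character(1))
    best <- best[order(first_member)[1]]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  coab_network(net[net$from %in% keep & net$to %in% keep, , drop = FALSE])
}

#' Superimpose a co-abundance network on a PPI network
#'
#' Takes the union of nodes and edges. Traversal weights: `w_ppi` for
#' PPI-only edges, `w_coa` for co-abundance-only edges, and
#' `min(w_ppi, w_coa)` for edges present in both networks, so that under
#' `w_coa < w_ppi` the condition-specific evidence dominates path costs.
#' Condition tags of co-abundance edges are preserved.
#'
#' @param ppi,coa `coab_network` objects.
#' @param w_ppi,w_coa positive traversal weights for the two edge classes.
#' @return the combined `coab_network`.
#' @export
combine_networks <- function(ppi, coa, w_ppi = 1.0, w_coa = 1.0) {
  stopifnot(w_ppi > 0, w_coa > 0)
  p <- tibble::as_tibble(ppi)[, c("from", "to", "evidence", "condition")]
  p$class <- "ppi"
  if (nrow(coa) == 0) {
    p$weight <- w_ppi
    return(coab_network(p))
  }
  c_ <- tibble::as_tibble(coa)[, c("from", "to", "evidence", "condition")]
  c_$class <- "coabundance"
  key_p <- paste(p$from, p$to, sep = "\r")
  key_c <- paste(c_$from, c_$to, sep = "\r")
  p$weight <- ifelse(key_p %in% key_c, min(w_ppi, w_coa), w_ppi)
  c_$weight <- ifelse(key_c %in% key_p, min(w_ppi, w_coa), w_coa)
  coab_network(dplyr::bind_rows(p, c_))
}

#' Prune PPI edges between strongly anti-correlated proteins
#'
#' A filtering variant of network integration: in addition to adding
#' positively correlated edges, PPI edges whose endpoint profiles are
#' strongly negatively correlated (at controlled FDR) are removed as likely
#' context-inactive. Co-abundance-class edges are never touched.
#'
#' @param combined a `coab_network` (typically from [combine_networks()]).
#' @param corr a [correlation_matrix()] result covering the edge endpoints.
#' @param r_neg_threshold correlation at or below which an edge is dropped.
#' @param q_max FDR ceiling for the negative correlation.
#' @return the filtered `coab_network`.
#' @export
remove_negative_edges <- function(combined, corr, r_neg_threshold = -0.90,
                                  q_max = 0.01) {
  if (is.null(corr$q_neg)) stop("corr must carry lower-tail Q* values; run permutation_significance()")
  idx_from <- match(combined$from, corr$proteins)
  idx_to <- match(combined$to, corr$proteins)
  covered <- !is.na(idx_from) & !is.na(idx_to)
  r <- rep(NA_real_, nrow(combined))
  q <- rep(NA_real_, nrow(combined))
  r[covered] <- corr$r[cbind(idx_from[covered], idx_to[covered])]
  q[covered] <- corr$q_neg[cbind(idx_from[covered], idx_to[covered])]
  drop <- combined$class == "ppi" & !is.na(r) & r <= r_neg_threshold &
    !is.na(q) & q <= q_max
  coab_network(combined[!drop, , drop = FALSE])
}

log_degree_bins <- function(degrees, log_base = 2) {
  # floor(log_base(degree)); degree-0 nodes are not eligible
  degrees <- degrees[degrees >= 1]
  floor(log(degrees, base = log_base))
}

#' Add degree-preserving random edges
#'
#' Null model for the contribution of co-abundance edges: for every edge of
#' `template`, a new edge is placed between endpoints drawn uniformly from
#' the logarithmic degree bins (bin id `floor(log_base(degree))` in `ppi`)
#' of the template endpoints. Duplicate and self-loop draws are rejected and
#' redrawn; after `max_attempts` failures the candidate bins are widened one
#' level at a time (up to the full node set) with a warning.
#'
#' @param ppi the backbone `coab_network` whose degrees define the bins.
#' @param template a `coab_network` whose edge count and endpoint degrees
#'   are matched.
#' @param log_base base of the logarithmic degree binning.
#' @param weight_new traversal weight given to the added edges (use the
#'   co-abundance weight when the template is a co-abundance network).
#' @param rng_seed integer seed.
#' @param max_attempts redraw budget per edge before bin widening.
#' @return a `coab_network` with exactly `nrow(ppi) + nrow(template)` edges;
#'   the added edges carry class `"coabundance"` and condition `"random"`,
#'   and are also attached as attribute `"added_edges"`.
#' @export
degree_preserving_random_edges <- function(ppi, template, log_base = 2,
                                           weight_new = 1.0, rng_seed = 1L,
                                           max_attempts = 1000L) {
  stopifnot(nrow(template) >= 1)
  set.seed(rng_seed)
  g <- as_igraph(ppi)
  deg <- igraph::degree(g)
  nodes <- names(deg)
  bin_of <- floor(log(pmax(deg, 1), base = log_base))
  bins <- split(nodes, bin_of)
  bin_levels <- as.integer(names(bins))

  node_bin <- function(v) {
    d <- deg[v]
    miss <- is.na(d)
    if (any(miss)) {
      # endpoints absent from the backbone fall back to template degrees
      d[miss] <- vapply(v[miss], function(x) {
        sum(template$from == x) + sum(template$to == x)
      }, numeric(1))
    }
    unname(floor(log(pmax(d, 1), base = log_base)))
  }
  pool_for <- function(b, widen) {
    lv <- bin_levels[abs(bin_levels - b) <= widen]
    if (length(lv) == 0) lv <- bin_levels
    unlist(bins[as.character(lv)], use.names = FALSE)
  }

  bu <- node_bin(template$from)
  bv <- node_bin(template$to)
  taken <- paste(ppi$from, ppi$to, sep = "\r")
  n_e <- nrow(template)
  ends_a <- ends_b <- character(n_e)
  pending <- seq_len(n_e)
  widen <- 0L
  rounds <- 0L
  max_widen <- diff(range(bin_levels)) + 1L
  while (length(pending)) {
    # draw all still-unplaced endpoints at once, grouped by bin level
    for (side in 1:2) {
      b_side <- if (side == 1) bu else bv
      for (lv in unique(b_side[pending])) {
        idx <- pending[b_side[pending] == lv]
        pool <- pool_for(lv, widen)
        draw <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
        if (side == 1) ends_a[idx] <- draw else ends_b[idx] <- draw
      }
    }
    key <- paste(pmin(ends_a[pending], ends_b[pending]),
                 pmax(ends_a[pending], ends_b[pending]), sep = "\r")
    ok <- ends_a[pending] != ends_b[pending] & !(key %in% taken) &
      !duplicated(key)
    taken <- c(taken, key[ok])
    pending <- pending[!ok]
    rounds <- rounds + 1L
    if (rounds %% max_attempts == 0 && length(pending)) {
      if (widen >= max_widen) {
        stop("could not place a random edge even over the full node set")
      }
      widen <- widen + 1L
      warning(sprintf("widening degree bins to +/-%d levels for %d edge(s)",
                      widen, length(pending)))
    }
  }
  add_tbl <- tibble::tibble(
    from = pmin(ends_a, ends_b),
    to = pmax(ends_a, ends_b),
    class = "coabundance",
    evidence = NA_character_,
    condition = "random",
    weight = weight_new
  )
  # inputs are canonical and the key check guarantees uniqueness, so the
  # parallel-edge merge pass can be skipped
  out <- dplyr::arrange(dplyr::bind_rows(tibble::as_tibble(ppi), add_tbl),
                        .data$from, .data$to)
  out <- structure(out, class = c("coab_network", class(tibble::tibble())))
  attr(out, "added_edges") <- add_tbl
  out
}

#' Topological summary of a network
#'
#' Standard unweighted statistics computed on the largest connected
#' component: node and edge counts, density as a percentage of possible
#' pairs, average degree, average local clustering coefficient (isolated
#' and degree-1 nodes count as zero), diameter and average shortest path
#' length.
#'
#' @param net a `coab_network`.
#' @return a one-row tibble.
#' @export
network_summary <- function(net) {
  lcc <- extract_lcc(net)
  g <- as_igraph(lcc)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    density_pct = 100 * m / (n * (n - 1) / 2),
    mean_degree = 2 * m / n,
    clustering = mean(igraph::transitivity(g, type = "local",
                                           isolates = "zero")),
    diameter = igraph::diameter(g, weights = NA),
    aspl = igraph::mean_distance(g, weights = NA)
  )
}
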