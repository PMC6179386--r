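# Independent oracles and tiny fixture builders used across the suite.

# build a coab_network from a plain edge list given as a two-column matrix
# or data frame of identifiers, with optional weights
toy_net <- function(from, to, weight = 1, class = "ppi",
                    evidence = NA_character_, condition = NA_character_) {
  coab_network(tibble::tibble(from = from, to = to, class = class,
                              evidence = evidence, condition = condition,
                              weight = weight))
}

path_net <- function(n, prefix = "n") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  toy_net(ids[-n], ids[-1])
}

# hand-rolled breadth-first search: hop distances from one source over an
# adjacency list; independent of igraph
bfs_oracle <- function(adj, start) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (!is.finite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist
}

adj_list <- function(net) {
  nodes <- network_nodes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(net))) {
    adj[[net$from[i]]] <- c(adj[[net$from[i]]], net$to[i])
    adj[[net$to[i]]] <- c(adj[[net$to[i]]], net$from[i])
  }
  adj
}

# exhaustive simple-path enumeration for weighted shortest distances on
# small graphs; independent of igraph's dijkstra
enum_shortest <- function(net, from, to) {
  if (from == to) return(0)
  edges <- rbind(
    data.frame(a = net$from, b = net$to, w = net$weight),
    data.frame(a = net$to, b = net$from, w = net$weight)
  )
  best <- Inf
  recurse <- function(v, visited, cost) {
    if (cost >= best) return()
    if (v == to) {
      best <<- cost
      return()
    }
    nxt <- edges[edges$a == v & !(edges$b %in% visited), , drop = FALSE]
    for (i in seq_len(nrow(nxt))) {
      recurse(nxt$b[i], c(visited, nxt$b[i]), cost + nxt$w[i])
    }
  }
  recurse(from, from, 0)
  best
}

# concordant-pair AUROC oracle: P(pos > neg) + 0.5 P(pos == neg) over all
# positive-negative score pairs
auroc_oracle <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up, written out longhand
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# two-sided Fisher p by full enumeration under the minimum-likelihood rule
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b
  n <- c_ + d
  k <- a + c_
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random connected-ish test graph with unique node names
random_test_net <- function(n, p_edge, rng_seed, weights = NULL) {
  set.seed(rng_seed)
  g <- igraph::sample_gnp(n, p_edge)
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) {
    el <- matrix(c(1, 2), ncol = 2)
  }
  ids <- sprintf("v%03d", seq_len(n))
  w <- if (is.null(weights)) 1 else sample(weights, nrow(el), replace = TRUE)
  toy_net(ids[el[, 1]], ids[el[, 2]], weight = w)
}

# small abundance matrix straight from a numeric matrix (rows = proteins)
abundance_from_matrix <- function(m, time_points = NULL,
                                  condition = "cond") {
  if (is.null(time_points)) time_points <- c(0, 8, 12, 24, 48, 72)[seq_len(ncol(m))]
  colnames(m) <- paste0("t", time_points)
  abundance_matrix(
    dplyr::bind_cols(tibble::tibble(protein = rownames(m)),
                     tibble::as_tibble(m, .name_repair = "minimal")),
    condition = condition, time_points = time_points)
}
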