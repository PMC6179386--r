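#' Pairwise correlation of abundance profiles
#'
#' Computes the symmetric correlation matrix between the time-course
#' profiles of all profiled proteins. Methods: `"pearson"` (product-moment
#' on the time-point vectors), `"bicor"` (biweight midcorrelation with the
#' standard (1-u^2)^2 outlier down-weighting, u = (x - median)/(9 mad)),
#' and `"partial"` (first-order partial correlation of each pair
#' controlling for the pairwise mean of the two proteins' baseline
#' profiles, r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))).
#' Zero-variance profiles yield an undefined correlation, recorded as 0
#' with a raised mask flag so they never become edges.
#'
#' @param abundance an `abundance_matrix` with >= 3 time points.
#' @param method correlation flavor.
#' @param control baseline `abundance_matrix` (required for `"partial"`;
#'   must share proteins and time points).
#' @return a list of class `coab_correlation` with elements `proteins`,
#'   `r` (symmetric matrix), `mask` (logical matrix of undefined entries),
#'   `method`, and `condition`; [permutation_significance()] adds `p`, `q`
#'   and `n_perm`.
#' @export
correlation_matrix <- function(abundance,
                               method = c("pearson", "bicor", "partial"),
                               control = NULL) {
  method <- match.arg(method)
  X <- t(abundance_values(abundance))  # time x proteins
  if (nrow(X) < 3) stop("need at least 3 time points")
  proteins <- colnames(X)
  if (method == "partial") {
    if (is.null(control)) stop("partial correlation requires a control matrix")
    common <- intersect(proteins, control$protein)
    if (!setequal(common, proteins)) {
      X <- X[, proteins %in% common, drop = FALSE]
      proteins <- colnames(X)
    }
    B <- t(abundance_values(control))[, proteins, drop = FALSE]
    rmat <- partial_cor_matrix(X, B)
  } else {
    S <- cor_transform(X, method)
    rmat <- crossprod(S)
  }
  mask <- !is.finite(rmat)
  rmat[mask] <- 0
  diag(rmat) <- 1
  diag(mask) <- FALSE
  dimnames(rmat) <- dimnames(mask) <- list(proteins, proteins)
  structure(list(proteins = proteins, r = rmat, mask = mask,
                 method = method, n_perm = NULL, p = NULL, q = NULL,
                 condition = abundance_condition(abundance),
                 control_condition = if (!is.null(control))
                   abundance_condition(control) else NULL),
            class = "coab_correlation")
}

# columns standardized so that crossprod() gives the correlation:
# pearson -> centered unit-norm columns; bicor -> biweight-transformed
# unit-norm columns. Degenerate columns become NaN and are masked upstream.
cor_transform <- function(X, method) {
  if (method == "pearson") {
    S <- sweep(X, 2, colMeans(X))
  } else {
    S <- apply(X, 2, function(x) {
      med <- stats::median(x)
      madv <- stats::median(abs(x - med))
      if (madv == 0) return(rep(NaN, length(x)))
      u <- (x - med) / (9 * madv)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      (x - med) * w
    })
  }
  nrm <- sqrt(colSums(S^2))
  sweep(S, 2, nrm, "/")
}

# first-order partial correlation controlling, for each pair (i, j), for
# z_ij = (b_i + b_j)/2 where b is the baseline profile; fully vectorized
# through cross-covariance matrices.
partial_cor_matrix <- function(X, B) {
  cxx <- stats::cov(X)
  cbb <- stats::cov(B)
  cxb <- stats::cov(X, B)
  vx <- diag(cxx)
  vb <- diag(cbb)
  # cov(x_i, z_ij) = (cov(x_i,b_i) + cov(x_i,b_j)) / 2
  m1 <- (diag(cxb) + cxb) / 2
  vz <- (outer(vb, vb, "+") + 2 * cbb) / 4
  rxy <- cxx / sqrt(outer(vx, vx))
  rxz <- m1 / sqrt(outer(vx, rep(1, ncol(X))) * vz)
  ryz <- t(rxz)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# all orderings of 1..n, one per row
all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_orderings(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' First-order partial correlation from pairwise correlations
#'
#' @param r_xy,r_xz,r_yz pairwise correlations.
#' @return r_xy.z, the correlation of x and y with z partialled out.
#' @export
first_order_partial <- function(r_xy, r_xz, r_yz) {
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Permutation empirical p-values and BH q-values for a correlation matrix
#'
#' For each of `n_perm` realizations, every protein's profile is shuffled
#' over the time-point order and the pairwise correlations recomputed; the
#' empirical p-value is P* = r_> / N, the fraction of permutations whose
#' permuted correlation strictly exceeds the observed one. P* values on the
#' upper triangle are then Benjamini-Hochberg adjusted to Q*. By default
#' only one member of each pair is shuffled per realization (equivalent
#' under exchangeability); `shuffle = "both"` shuffles both. With six time
#' points there are only 720 distinct orders, so permutations are sampled
#' with replacement (Monte-Carlo).
#'
#' @inheritParams correlation_matrix
#' @param n_perm number of permutations N.
#' @param rng_seed integer seed.
#' @param shuffle shuffle one pair member per realization, or both. The
#'   partial method always recomputes the full matrix from shuffled
#'   profiles (both members).
#' @param pseudo_count use the conservative (r_> + 1)/(N + 1) estimator
#'   instead of the plain r_> / N.
#' @return a `coab_correlation` with `p`, `q`, their lower-tail twins
#'   `p_neg`/`q_neg` (significance of strongly negative correlations) and
#'   `n_perm` filled in.
#' @export
permutation_significance <- function(abundance,
                                     method = c("pearson", "bicor", "partial"),
                                     control = NULL, n_perm = 300,
                                     rng_seed = 1L,
                                     shuffle = c("one", "both"),
                                     pseudo_count = FALSE) {
  method <- match.arg(method)
  shuffle <- match.arg(shuffle)
  stopifnot(n_perm >= 1)
  obs <- correlation_matrix(abundance, method, control)
  X <- t(abundance_values(abundance))
  X <- X[, obs$proteins, drop = FALSE]
  set.seed(rng_seed)
  exceed <- matrix(0L, ncol(X), ncol(X))
  below <- matrix(0L, ncol(X), ncol(X))
  if (method == "partial") {
    B <- t(abundance_values(control))[, obs$proteins, drop = FALSE]
    for (b in seq_len(n_perm)) {
      Xp <- apply(X, 2, sample)
      rp <- partial_cor_matrix(Xp, B)
      exceed <- exceed + (!is.na(rp) & rp > obs$r)
      below <- below + (!is.na(rp) & rp < obs$r)
    }
  } else {
    S <- cor_transform(X, method)
    S[!is.finite(S)] <- 0
    nt <- nrow(S)
    np <- ncol(S)
    # with few time points, draw whole column shuffles from the table of
    # all nt! orderings in one indexing step per realization
    perms <- if (factorial(nt) <= 5040) all_orderings(nt) else NULL
    col_off <- (seq_len(np) - 1L) * nt
    for (b in seq_len(n_perm)) {
      if (is.null(perms)) {
        Sp <- apply(S, 2, sample)
      } else {
        pick <- perms[sample.int(nrow(perms), np, replace = TRUE), ,
                      drop = FALSE]
        Sp <- matrix(S[as.vector(t(pick)) + rep(col_off, each = nt)],
                     nt, np)
      }
      rp <- if (shuffle == "one") crossprod(Sp, S) else crossprod(Sp)
      exceed <- exceed + (rp > obs$r)
      below <- below + (rp < obs$r)
    }
  }
  mc_p <- function(count) {
    p <- if (pseudo_count) (count + 1) / (n_perm + 1) else count / n_perm
    diag(p) <- 0
    ut <- upper.tri(p)
    q <- matrix(NA_real_, nrow(p), ncol(p))
    q[ut] <- stats::p.adjust(p[ut], method = "BH")
    q[lower.tri(q)] <- t(q)[lower.tri(q)]
    diag(q) <- 0
    dimnames(p) <- dimnames(q) <- dimnames(obs$r)
    list(p = p, q = q)
  }
  up <- mc_p(exceed)
  lo <- mc_p(below)
  obs$p <- up$p
  obs$q <- up$q
  # lower-tail twin (permuted r below observed): significance of strong
  # NEGATIVE correlations, consumed by remove_negative_edges()
  obs$p_neg <- lo$p
  obs$q_neg <- lo$q
  obs$n_perm <- n_perm
  obs
}

#' @export
tidy.coab_correlation <- function(x, ...) {
  ut <- which(upper.tri(x$r), arr.ind = TRUE)
  out <- tibble::tibble(
    protein_a = x$proteins[ut[, 1]],
    protein_b = x$proteins[ut[, 2]],
    r = x$r[ut],
    masked = x$mask[ut]
  )
  if (!is.null(x$p)) {
    out$p <- x$p[ut]
    out$q <- x$q[ut]
  }
  out
}

#' Network density as a function of the correlation threshold
#'
#' For each threshold in `r_grid`, counts the protein pairs with
#' correlation at or above the threshold and Q* at or below `q_max`, and
#' reports the resulting network density. The selected threshold is the
#' largest grid value whose density stays within a relative tolerance of
#' the density at the preceding grid value, i.e. the highest correlation
#' that still "maintains" the density.
#'
#' @param corr a `coab_correlation` with q-values.
#' @param r_grid ascending thresholds.
#' @param q_max FDR ceiling.
#' @param rel_tol relative density-change tolerance defining "maintained".
#' @return a list of class `coab_density_scan` with `table` (threshold,
#'   n_edges, density) and `selected`.
#' @export
density_sensitivity_scan <- function(corr, r_grid, q_max = 0.01,
                                     rel_tol = 0.05) {
  if (length(r_grid) == 0) stop("r_grid must be non-empty")
  stopifnot(!is.unsorted(r_grid))
  if (is.null(corr$q)) stop("corr must carry Q* values")
  ut <- upper.tri(corr$r)
  ok <- ut & !corr$mask & corr$q <= q_max
  n <- length(corr$proteins)
  npairs <- n * (n - 1) / 2
  n_edges <- vapply(r_grid, function(t) sum(ok & corr$r >= t), numeric(1))
  density <- n_edges / npairs
  sel_idx <- 1L
  if (length(r_grid) > 1) {
    maintained <- c(FALSE, abs(diff(density)) <=
                      rel_tol * pmax(density[-length(density)], 0))
    # treat a flat zero-to-zero step as maintained
    maintained[c(FALSE, density[-length(density)] == 0 &
                   density[-1] == 0)] <- TRUE
    if (any(maintained)) sel_idx <- max(which(maintained))
  }
  structure(list(
    table = tibble::tibble(threshold = r_grid, n_edges = n_edges,
                           density = density),
    selected = r_grid[sel_idx]
  ), class = "coab_density_scan")
}

#' Build a co-abundance network from a significance-annotated correlation
#'
#' Edges connect protein pairs with correlation at or above `r_threshold`
#' (ties included) and Q* at or below `q_max`. Isolated proteins are not
#' part of the node set. The per-edge statistics (r, P*, Q*) are attached
#' as attribute `"edge_stats"` and written by [write_coabundance_tsv()].
#'
#' @param corr a `coab_correlation` with q-values.
#' @param r_threshold correlation cutoff.
#' @param q_max FDR ceiling.
#' @param condition condition tag stamped on the edges; defaults to the
#'   correlation's condition.
#' @return a `coab_network` of class-`"coabundance"` edges (possibly empty).
#' @export
build_coabundance_network <- function(corr, r_threshold = 0.90,
                                      q_max = 0.01, condition = NULL) {
  if (is.null(corr$q)) stop("corr must carry Q* values; run permutation_significance()")
  if (is.null(condition)) condition <- corr$condition
  ut <- which(upper.tri(corr$r) & !corr$mask & corr$r >= r_threshold &
                corr$q <= q_max, arr.ind = TRUE)
  stats_tbl <- tibble::tibble(
    from = corr$proteins[ut[, 1]],
    to = corr$proteins[ut[, 2]],
    r = corr$r[ut],
    p = corr$p[ut],
    q = corr$q[ut],
    condition = if (is.null(condition)) NA_character_ else condition
  )
  if (nrow(stats_tbl) == 0) {
    message("co-abundance network is empty at r >= ", r_threshold)
  }
  net <- coab_network(tibble::tibble(
    from = stats_tbl$from, to = stats_tbl$to, class = "coabundance",
    evidence = NA_character_, condition = stats_tbl$condition, weight = 1
  )[seq_len(nrow(stats_tbl)), ])
  attr(net, "edge_stats") <- stats_tbl
  net
}

#' @rdname build_coabundance_network
#' @param net a co-abundance `coab_network` from
#'   [build_coabundance_network()].
#' @param path output TSV path (columns protein_a, protein_b, r, P*, Q*,
#'   condition).
#' @export
write_coabundance_tsv <- function(net, path) {
  st <- attr(net, "edge_stats")
  if (is.null(st)) stop("network carries no edge statistics")
  names(st) <- c("protein_a", "protein_b", "r", "P*", "Q*", "condition")
  readr::write_tsv(st, path, progress = FALSE)
  invisible(path)
}
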