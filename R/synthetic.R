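#' Generate a synthetic protein-protein interaction network
#'
#' Emulates the heavy-tailed degree structure of literature interactomes
#' with either linear preferential attachment or a duplication-divergence
#' growth process. The result is a simple, undirected, connected graph whose
#' edges carry class `"ppi"` and a single evidence flag drawn at random with
#' configurable proportions.
#'
#' @param n_nodes number of proteins (>= 10).
#' @param mean_degree target average degree (>= 2, < n_nodes - 1).
#' @param model `"preferential-attachment"` or `"duplication-divergence"`.
#' @param rng_seed integer seed; the same seed reproduces the same network.
#' @param evidence_props named numeric proportions for the evidence flags.
#' @return a `coab_network` with node names `P0001`, `P0002`, ...
#' @export
generate_ppi_network <- function(n_nodes, mean_degree,
                                 model = c("preferential-attachment",
                                           "duplication-divergence"),
                                 rng_seed = 1L,
                                 evidence_props = c("binary-HT" = 0.5,
                                                    "low-throughput" = 0.3,
                                                    "co-complex" = 0.2)) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 10, mean_degree >= 2)
  if (mean_degree >= n_nodes - 1) stop("mean_degree must be < n_nodes - 1")
  set.seed(rng_seed)
  ids <- sprintf("P%04d", seq_len(n_nodes))
  if (model == "preferential-attachment") {
    m <- max(1L, round(mean_degree / 2))
    g <- igraph::sample_pa(n_nodes, m = m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
  } else {
    # duplication-divergence: each new node copies a parent's edges with
    # retention probability q and always links to the parent, so the graph
    # stays connected; stationary mean degree is 2/(1 - 2q).
    q <- max(0, (mean_degree - 2) / (2 * mean_degree))
    adj <- vector("list", n_nodes)
    adj[[1]] <- 2L; adj[[2]] <- 1L
    for (v in 3:n_nodes) {
      parent <- sample.int(v - 1L, 1L)
      inherit <- adj[[parent]][stats::runif(length(adj[[parent]])) < q]
      nbrs <- unique(c(parent, inherit))
      adj[[v]] <- nbrs
      for (u in nbrs) adj[[u]] <- c(adj[[u]], v)
    }
    el <- do.call(rbind, lapply(seq_len(n_nodes), function(v) {
      nb <- adj[[v]]; nb <- nb[nb > v]
      if (length(nb)) cbind(v, nb) else NULL
    }))
  }
  el <- unique(t(apply(el, 1, sort)))
  ev <- sample(names(evidence_props), nrow(el), replace = TRUE,
               prob = evidence_props)
  coab_network(tibble::tibble(
    from = ids[el[, 1]], to = ids[el[, 2]],
    class = "ppi", evidence = ev,
    condition = NA_character_, weight = 1
  ))
}

#' Plant a seed target set on a network
#'
#' `locality = 0` samples targets uniformly without replacement;
#' `locality = 1` grows the whole set by breadth-first expansion from a
#' random anchor; intermediate values grow `round(locality * n_targets)`
#' targets by BFS and sample the remainder uniformly. All targets receive
#' importance weight 1.
#'
#' @param network a `coab_network`.
#' @param n_targets number of targets (< node count).
#' @param locality real in `[0, 1]` controlling clustering of the targets.
#' @param rng_seed integer seed.
#' @return a tibble with columns `protein` and `weight` (a seed set).
#' @export
plant_seed_targets <- function(network, n_targets, locality = 0,
                               rng_seed = 1L) {
  stopifnot(locality >= 0, locality <= 1)
  nodes <- network_nodes(network)
  if (n_targets >= length(nodes)) stop("n_targets must be < node count")
  set.seed(rng_seed)
  n_local <- round(locality * n_targets)
  picked <- character(0)
  if (n_local > 0) {
    g <- as_igraph(network)
    anchor <- sample(nodes, 1L)
    ord <- igraph::bfs(g, root = anchor, order = TRUE)$order
    picked <- igraph::V(g)$name[ord][seq_len(n_local)]
  }
  remaining <- setdiff(nodes, picked)
  picked <- c(picked, sample(remaining, n_targets - n_local))
  tibble::tibble(protein = sort(picked), weight = 1.0)
}

#' Generate a time-course abundance matrix with planted co-abundance modules
#'
#' Proteins belonging to one module share a smooth latent trajectory (a
#' cumulative sum of Gaussian steps with a mild induction drift) plus
#' i.i.d. Gaussian noise, so module pairs are strongly correlated; all
#' other profiled proteins receive independent noise-only trajectories.
#' Profiles are exponentiated, baseline-anchored ratios: the column at
#' `t = 0` is identically 1. A configurable fraction of each module's
#' members is drawn from the seed target set itself, which controls
#' whether the resulting co-abundance edges shorten paths to the seeds:
#' drug targets that respond to the stimulation participate in the
#' co-regulated program, and only that participation lets co-abundance
#' edges bring the remaining seeds closer.
#'
#' @param network a `coab_network` supplying the node universe.
#' @param module_sizes integer vector; sizes of planted modules (sum <=
#'   node count).
#' @param module_overlap_with_seeds fraction in `[0, 1]` of module members
#'   drawn from the seed set (requires `seeds`).
#' @param noise_sd standard deviation (log scale) of the i.i.d. noise.
#' @param time_points hours, starting at 0.
#' @param rng_seed integer seed.
#' @param seeds seed-set tibble from [plant_seed_targets()]; only needed
#'   when `module_overlap_with_seeds > 0`.
#' @param n_background number of non-module proteins profiled; default
#'   fills the panel to 40% of the node set.
#' @param condition condition label attached to the matrix.
#' @param latent_step_sd step size of the latent module trajectories.
#' @param latent_step_mean induction drift of the latent steps (stimulated
#'   programs are predominantly up-regulated).
#' @param modules optional named list of member vectors, overriding module
#'   sampling (used by [simulate_scenario()] to keep one common proteome
#'   across conditions).
#' @param background optional explicit vector of non-module profiled
#'   proteins, overriding background sampling.
#' @return an `abundance_matrix`; planted module membership is attached as
#'   attribute `"modules"` (list of character vectors).
#' @export
generate_abundance_timecourse <- function(network, module_sizes = integer(0),
                                          module_overlap_with_seeds = 0,
                                          noise_sd = 0.1,
                                          time_points = c(0, 8, 12, 24, 48, 72),
                                          rng_seed = 1L, seeds = NULL,
                                          n_background = NULL,
                                          condition = NA_character_,
                                          latent_step_sd = 0.5,
                                          latent_step_mean = 0.2,
                                          modules = NULL,
                                          background = NULL) {
  stopifnot(time_points[1] == 0, all(diff(time_points) > 0))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  nodes <- network_nodes(network)
  if (sum(module_sizes) > length(nodes)) stop("module sizes exceed node count")
  set.seed(rng_seed)
  nt <- length(time_points)

  seed_ids <- if (is.null(seeds)) character(0) else seeds$protein

  if (is.null(modules)) {
    modules <- sample_modules(nodes, module_sizes,
                              module_overlap_with_seeds, seed_ids)
  }
  taken <- unlist(modules, use.names = FALSE)

  if (is.null(background)) {
    if (is.null(n_background)) {
      n_background <- max(0L, round(0.4 * length(nodes)) - length(taken))
    }
    background <- sample(setdiff(nodes, taken),
                         min(n_background, length(nodes) - length(taken)))
  } else {
    background <- setdiff(background, taken)
  }
  proteins <- c(taken, background)

  prof <- matrix(0, nrow = length(proteins), ncol = nt,
                 dimnames = list(proteins, paste0("t", time_points)))
  for (i in seq_along(module_sizes)) {
    latent <- cumsum(c(0, stats::rnorm(nt - 1, mean = latent_step_mean,
                                       sd = latent_step_sd)))
    for (p in modules[[i]]) {
      eps <- stats::rnorm(nt, sd = noise_sd)
      prof[p, ] <- exp(latent + eps - (latent[1] + eps[1]))
    }
  }
  for (p in background) {
    eps <- stats::rnorm(nt, sd = max(noise_sd, 1e-8))
    prof[p, ] <- exp(eps - eps[1])
  }
  out <- abundance_matrix(
    dplyr::bind_cols(tibble::tibble(protein = proteins),
                     tibble::as_tibble(prof, .name_repair = "minimal")),
    condition = condition, time_points = time_points)
  attr(out, "modules") <- modules
  out
}

# disjoint modules: a fraction of members drawn from the seed set, the
# rest from non-seed nodes
sample_modules <- function(nodes, module_sizes, overlap, seed_ids) {
  taken <- character(0)
  modules <- vector("list", length(module_sizes))
  for (i in seq_along(module_sizes)) {
    sz <- module_sizes[i]
    n_seed <- round(overlap * sz)
    pool_seed <- setdiff(seed_ids, taken)
    seed_members <- sample(pool_seed, min(n_seed, length(pool_seed)))
    pool_rest <- setdiff(nodes, c(taken, seed_members, seed_ids))
    rest <- sample(pool_rest, sz - length(seed_members))
    modules[[i]] <- sort(c(seed_members, rest))
    taken <- c(taken, modules[[i]])
  }
  names(modules) <- paste0("module", seq_along(modules), recycle0 = TRUE)
  modules
}

#' Expand an abundance matrix into a synthetic PSM table
#'
#' Each protein receives a uniformly random number of PSMs in
#' `psm_count_range`; each PSM's channel intensities are the protein
#' profile scaled by a per-PSM base intensity and multiplicative log-normal
#' noise with coefficient of variation `cv`. With `cv = 0` the median of
#' the PSM ratios reproduces the input profile exactly.
#'
#' @param abundance an `abundance_matrix`.
#' @param psm_count_range integer `(min, max)` PSMs per protein, min >= 1.
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param rng_seed integer seed.
#' @return a tibble with `psm_id`, `protein` and intensity columns.
#' @export
generate_psm_table <- function(abundance, psm_count_range = c(5, 40),
                               cv = 0.1, rng_seed = 1L) {
  stopifnot(psm_count_range[1] >= 1)
  if (cv < 0) stop("cv must be non-negative")
  set.seed(rng_seed)
  m <- abundance_values(abundance)
  sdlog <- sqrt(log(1 + cv^2))
  counts <- sample(psm_count_range[1]:psm_count_range[2], nrow(m),
                   replace = TRUE)
  rows <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    base <- stats::rlnorm(counts[i], meanlog = log(1e4), sdlog = 0.5)
    noise <- if (cv == 0) {
      matrix(1, counts[i], ncol(m))
    } else {
      matrix(stats::rlnorm(counts[i] * ncol(m), 0, sdlog), counts[i], ncol(m))
    }
    intens <- (base %o% m[i, ]) * noise
    colnames(intens) <- colnames(m)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(protein = rownames(m)[i]),
      tibble::as_tibble(intens, .name_repair = "minimal"))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble::tibble(psm_id = sprintf("psm%06d", seq_len(nrow(out)))),
                   out)
}

#' Synthetic fold-change table and pathway collection
#'
#' Planted regulators receive fold changes strictly above every other gene
#' in their condition (hence in the top decile); pathways are random node
#' sets of configurable sizes, with one designated "true" pathway that
#' contains all planted regulators.
#'
#' @param network node universe.
#' @param regulators named list: condition -> character vector of planted
#'   regulator identifiers.
#' @param n_pathways number of gene sets.
#' @param pathway_size_range integer `(min, max)` set sizes.
#' @param rng_seed integer seed.
#' @return a list with `expression` (tibble `protein`, `condition`,
#'   `fold_change`), `pathways` (named list of character vectors) and
#'   `true_pathway` (its name).
#' @export
generate_expression_and_pathways <- function(network, regulators,
                                             n_pathways = 50,
                                             pathway_size_range = c(20, 80),
                                             rng_seed = 1L) {
  set.seed(rng_seed)
  nodes <- network_nodes(network)
  expr <- purrr::imap_dfr(regulators, function(regs, cond) {
    fc <- stats::rnorm(length(nodes))
    names(fc) <- nodes
    if (length(regs)) {
      fc[regs] <- max(fc[setdiff(nodes, regs)]) +
        stats::runif(length(regs), 0.1, 1)
    }
    tibble::tibble(protein = nodes, condition = cond, fold_change = unname(fc))
  })
  sizes <- sample(pathway_size_range[1]:pathway_size_range[2], n_pathways,
                  replace = TRUE)
  pathways <- lapply(sizes, function(s) sort(sample(nodes, s)))
  names(pathways) <- sprintf("pathway%03d", seq_len(n_pathways))
  all_regs <- sort(unique(unlist(regulators)))
  true_size <- max(length(all_regs) + 10, pathway_size_range[1])
  pathways[["pathway_true"]] <- sort(c(
    all_regs, sample(setdiff(nodes, all_regs), true_size - length(all_regs))))
  list(expression = expr, pathways = pathways, true_pathway = "pathway_true")
}

#' Generate a complete synthetic study
#'
#' Bundles a scale-free PPI network, a seed target set, per-condition
#' six-time-point abundance matrices with planted correlated modules placed
#' near the seeds, optional PSM tables, a fold-change table and a pathway
#' collection, together with the ground truth needed to score recovery.
#' Identical `rng_seed` reproduces the scenario bit-identically.
#'
#' @param n_nodes,mean_degree,model network parameters
#'   (see [generate_ppi_network()]).
#' @param n_seeds,seed_locality seed-set parameters.
#' @param conditions condition labels; the first is the unstimulated
#'   baseline.
#' @param module_sizes module sizes planted per condition.
#' @param module_overlap_with_seeds fraction of module members adjacent to
#'   seeds.
#' @param noise_sd,time_points abundance noise and time grid (hours).
#' @param n_regulators planted regulators per stimulated condition (chosen
#'   among that condition's module members).
#' @param with_psms also generate PSM-level tables.
#' @param psm_count_range,psm_cv PSM simulation parameters.
#' @param n_pathways,pathway_size_range pathway collection parameters.
#' @param rng_seed master seed.
#' @return a list of class `coab_scenario` with elements `network`,
#'   `seeds`, `abundance`, `psm_tables`, `expression`, `pathways`,
#'   `true_pathway` and `truth`.
#' @export
simulate_scenario <- function(n_nodes = 2000, mean_degree = 12,
                              model = "preferential-attachment",
                              n_seeds = 150, seed_locality = 0.5,
                              conditions = c("M0", "MIFNg", "MIL4"),
                              module_sizes = c(50, 50, 50),
                              module_overlap_with_seeds = 0.6,
                              noise_sd = 0.05,
                              time_points = c(0, 8, 12, 24, 48, 72),
                              n_regulators = 20,
                              with_psms = FALSE,
                              psm_count_range = c(5, 40), psm_cv = 0.1,
                              n_pathways = 50, pathway_size_range = c(20, 80),
                              rng_seed = 1L) {
  stopifnot(length(conditions) >= 2)
  net <- generate_ppi_network(n_nodes, mean_degree, model,
                              rng_seed = rng_seed)
  seeds <- plant_seed_targets(net, n_seeds, seed_locality,
                              rng_seed = rng_seed + 1L)
  # one common proteome across conditions: the measured panel covers every
  # condition's module members plus a shared background, mirroring a
  # multiplexed time-course experiment quantifying the same proteins under
  # each stimulation
  nodes <- network_nodes(net)
  modules_by_cond <- list()
  for (i in seq_along(conditions)) {
    set.seed(rng_seed + 10L * i)
    modules_by_cond[[conditions[i]]] <- sample_modules(
      nodes, module_sizes, module_overlap_with_seeds, seeds$protein)
  }
  all_members <- unique(unlist(modules_by_cond, use.names = FALSE))
  set.seed(rng_seed + 2L)
  shared_background <- sample(
    setdiff(nodes, all_members),
    max(0L, round(0.4 * length(nodes)) - length(all_members)))

  abundance <- list()
  psm_tables <- list()
  modules <- list()
  regulators <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    ab <- generate_abundance_timecourse(
      net, module_sizes = module_sizes,
      module_overlap_with_seeds = module_overlap_with_seeds,
      noise_sd = noise_sd, time_points = time_points,
      rng_seed = rng_seed + 10L * i, seeds = seeds, condition = cond,
      modules = modules_by_cond[[cond]],
      background = c(all_members, shared_background))
    abundance[[cond]] <- ab
    modules[[cond]] <- attr(ab, "modules")
    if (i > 1) {
      # regulators: non-seed module members (candidate drug targets)
      members <- setdiff(unlist(attr(ab, "modules"), use.names = FALSE),
                         seeds$protein)
      set.seed(rng_seed + 10L * i + 5L)
      regulators[[cond]] <- sort(sample(members,
                                        min(n_regulators, length(members))))
    }
    if (with_psms) {
      psm_tables[[cond]] <- generate_psm_table(
        ab, psm_count_range = psm_count_range, cv = psm_cv,
        rng_seed = rng_seed + 10L * i + 7L)
    }
  }
  ep <- generate_expression_and_pathways(
    net, regulators, n_pathways = n_pathways,
    pathway_size_range = pathway_size_range, rng_seed = rng_seed + 99L)
  structure(list(
    network = net, seeds = seeds, abundance = abundance,
    psm_tables = if (with_psms) psm_tables else NULL,
    expression = ep$expression, pathways = ep$pathways,
    true_pathway = ep$true_pathway,
    truth = list(modules = modules, regulators = regulators,
                 rng_seed = rng_seed)
  ), class = "coab_scenario")
}

#' Write every scenario input to plain-text files
#'
#' Edge-list TSV, one abundance TSV per condition, seed list TXT,
#' fold-change TSV, pathway GMT and a truth JSON.
#'
#' @param scenario a `coab_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_tsv(scenario$network, file.path(dir, "ppi.tsv"))
  for (cond in names(scenario$abundance)) {
    write_abundance_tsv(scenario$abundance[[cond]],
                        file.path(dir, paste0("abundance_", cond, ".tsv")))
  }
  writeLines(scenario$seeds$protein, file.path(dir, "seeds.txt"))
  readr::write_tsv(scenario$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  write_gmt(scenario$pathways, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
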