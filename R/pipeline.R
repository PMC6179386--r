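#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' `n_perm = 300` correlation permutations, edge threshold
#' `r_threshold = 0.90` at `q_max = 0.01` FDR, PSM filter `psm_min = 10`
#' (strictly greater than), `k_folds = 7`, weight-ratio grid over (0, 10],
#' `n_random_edges = 20` edge-randomization realizations,
#' `n_random_nodes = 1000` node-null realizations, `n_rank_perm = 10000`
#' rank permutations at `alpha_rank = 0.01`, `top_k = 500` evidence
#' filters, `jaccard_min = 0.1`, `enrich_q = 0.05`, and a master
#' `rng_seed` from which every stage seed is derived.
#'
#' @param ... overrides for any default, including `scenario` (a list of
#'   [simulate_scenario()] arguments) and `w_coa` (used when
#'   `optimize = FALSE`).
#' @return a list of class `coab_config`.
#' @export
coab_config <- function(...) {
  cfg <- list(
    scenario = list(),
    n_perm = 300, r_threshold = 0.90, q_max = 0.01,
    psm_min = 10, k_folds = 7,
    ratio_grid = c(0.1, 0.2, 0.4, 0.7, 1, 2, 4, 7, 10),
    optimize = TRUE, w_coa = 0.4,
    denoise = FALSE,
    n_random_edges = 20, n_random_nodes = 1000,
    n_rank_perm = 10000, alpha_rank = 0.01,
    top_k = 500, jaccard_min = 0.1, enrich_q = 0.05,
    method = "proximity",
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "coab_config")
}

read_seed_txt <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    protein = vapply(parts, `[`, character(1), 1L),
    weight = vapply(parts, function(x) {
      if (length(x) > 1) as.numeric(x[2]) else 1.0
    }, numeric(1))
  )
}

load_inputs <- function(inputs) {
  need <- c("ppi", "abundance", "seeds")
  for (f in need) {
    if (is.null(inputs[[f]])) stop("missing input: ", f)
  }
  paths <- c(inputs$ppi, unlist(inputs$abundance), inputs$seeds,
             inputs$expression, inputs$gene_sets)
  for (p in paths) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  abundance <- purrr::imap(inputs$abundance, function(p, cond) {
    read_abundance_tsv(p, condition = cond)
  })
  list(
    network = read_network_tsv(inputs$ppi),
    abundance = abundance,
    seeds = read_seed_txt(inputs$seeds),
    expression = if (!is.null(inputs$expression))
      readr::read_tsv(inputs$expression, show_col_types = FALSE,
                      progress = FALSE) else NULL,
    pathways = if (!is.null(inputs$gene_sets)) read_gmt(inputs$gene_sets)
               else NULL,
    psm_tables = NULL, truth = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes abundance processing, co-abundance network construction,
#' network integration, prioritization (with optional weight-ratio
#' optimization), cross-validated evaluation against random-edge nulls,
#' candidate selection with combined ranking and proximity statistics, and
#' pathway enrichment, writing each stage's tables to `out_dir` together
#' with a provenance manifest (configuration, derived stage seeds, row
#' counts and file checksums). The same configuration and master seed
#' produce byte-identical outputs.
#'
#' @param config a [coab_config()].
#' @param out_dir output directory (created).
#' @param simulate generate inputs with [simulate_scenario()] using
#'   `config$scenario`; otherwise `inputs` must name existing files.
#' @param inputs list of paths: `ppi`, `abundance` (named list,
#'   condition -> TSV; the first is the baseline), `seeds`, optional
#'   `expression`, `gene_sets`.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = coab_config(), out_dir,
                         simulate = TRUE, inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed_of <- function(i) derive_seed(config$rng_seed, i)
  manifest <- list(config = unclass(config),
                   stage_seeds = list(), counts = list(), stages = character(0))
  note <- function(stage, ...) {
    manifest$stages <<- c(manifest$stages, stage)
    manifest$counts[[stage]] <<- list(...)
  }

  # stage 1: inputs
  if (simulate) {
    sc_args <- config$scenario
    sc_args$rng_seed <- seed_of(1)
    scenario <- do.call(simulate_scenario, sc_args)
    write_scenario(scenario, file.path(out_dir, "inputs"))
  } else {
    scenario <- load_inputs(inputs)
  }
  manifest$stage_seeds$simulate <- seed_of(1)
  conditions <- names(scenario$abundance)
  baseline <- conditions[1]
  stim <- conditions[-1]
  note("inputs", n_nodes = length(network_nodes(scenario$network)),
       n_edges = nrow(scenario$network), n_seeds = nrow(scenario$seeds),
       conditions = conditions)

  # stage 2: abundance (PSM aggregation if PSM tables are supplied)
  abundance <- scenario$abundance
  if (!is.null(scenario$psm_tables)) {
    abundance <- purrr::imap(scenario$psm_tables, function(psms, cond) {
      aggregate_psms(filter_by_psm_count(psms, config$psm_min),
                     condition = cond)
    })
  }
  rel_abun <- purrr::map(stim, function(cond) {
    relative_abundance(abundance[[cond]], abundance[[baseline]])
  })
  names(rel_abun) <- stim
  for (cond in stim) {
    readr::write_tsv(rel_abun[[cond]],
                     file.path(out_dir, paste0("relative_abundance_", cond,
                                               ".tsv")), progress = FALSE)
  }
  note("abundance", proteins = vapply(abundance, nrow, numeric(1)))

  # stage 3: co-abundance networks
  coa <- list()
  for (i in seq_along(stim)) {
    cond <- stim[i]
    corr <- permutation_significance(abundance[[cond]],
                                     n_perm = config$n_perm,
                                     rng_seed = seed_of(30 + i))
    coa[[cond]] <- build_coabundance_network(corr,
                                             r_threshold = config$r_threshold,
                                             q_max = config$q_max,
                                             condition = cond)
    write_coabundance_tsv(coa[[cond]],
                          file.path(out_dir, paste0("coabundance_", cond,
                                                    ".tsv")))
  }
  manifest$stage_seeds$coabundance <- vapply(seq_along(stim),
                                             function(i) seed_of(30 + i),
                                             numeric(1))
  note("coabundance", edges = vapply(coa, nrow, numeric(1)))

  # stage 4: network integration
  ppi <- scenario$network
  if (config$denoise) ppi <- denoise_ppi(ppi)
  ppi <- extract_lcc(ppi)
  readr::write_tsv(network_summary(ppi),
                   file.path(out_dir, "ppi_summary.tsv"), progress = FALSE)
  note("integrate", ppi_nodes = length(network_nodes(ppi)),
       ppi_edges = nrow(ppi))

  # stage 5: prioritization (weight-ratio optimization, final rankings)
  w_coa <- list()
  rankings <- list()
  combined <- list()
  scans <- list()
  for (i in seq_along(stim)) {
    cond <- stim[i]
    if (config$optimize) {
      scans[[cond]] <- optimize_weight_ratio(
        ppi, coa[[cond]], scenario$seeds, ratio_grid = config$ratio_grid,
        k = config$k_folds, rng_seed = seed_of(50 + i),
        method = config$method)
      w_coa[[cond]] <- scans[[cond]]$best_ratio
      readr::write_tsv(scans[[cond]]$table,
                       file.path(out_dir, paste0("ratio_scan_", cond, ".tsv")),
                       progress = FALSE)
    } else {
      w_coa[[cond]] <- config$w_coa
    }
    combined[[cond]] <- combine_networks(ppi, coa[[cond]], w_ppi = 1,
                                         w_coa = w_coa[[cond]])
    rankings[[cond]] <- score_fun_for(config$method)(combined[[cond]],
                                                     scenario$seeds)
    readr::write_tsv(tibble::as_tibble(rankings[[cond]]),
                     file.path(out_dir, paste0("ranking_", cond, ".tsv")),
                     progress = FALSE)
  }
  manifest$stage_seeds$prioritize <- vapply(seq_along(stim),
                                            function(i) seed_of(50 + i),
                                            numeric(1))
  note("prioritize", w_coa = unlist(w_coa))

  # stage 6: evaluation against nulls
  evaluations <- list()
  controls <- list()
  for (i in seq_along(stim)) {
    cond <- stim[i]
    evaluations[[cond]] <- compare_networks_cv(
      ppi, combined[[cond]], scenario$seeds, k = config$k_folds,
      rng_seed = seed_of(60 + i), method = config$method)
    controls[[cond]] <- random_edge_control(
      ppi, coa[[cond]], scenario$seeds, n_real = config$n_random_edges,
      rng_seed = seed_of(70 + i), k = config$k_folds,
      w_coa = w_coa[[cond]], method = config$method)
    readr::write_tsv(glance(evaluations[[cond]]),
                     file.path(out_dir, paste0("evaluation_", cond, ".tsv")),
                     progress = FALSE)
    readr::write_tsv(glance(controls[[cond]]),
                     file.path(out_dir, paste0("random_control_", cond,
                                               ".tsv")), progress = FALSE)
    readr::write_tsv(evaluations[[cond]]$roc$ppi_plus_coa,
                     file.path(out_dir, paste0("roc_", cond, ".tsv")),
                     progress = FALSE)
  }
  manifest$stage_seeds$evaluate <- vapply(seq_along(stim),
                                          function(i) seed_of(60 + i),
                                          numeric(1))
  note("evaluate",
       auroc_gain = vapply(evaluations, function(e)
         unname(e$mean_auroc["ppi_plus_coa"] - e$mean_auroc["ppi"]),
         numeric(1)),
       p_emp = vapply(controls, function(x) x$p_emp, numeric(1)))

  # stage 7: candidate selection, combined ranking, proximity statistics
  selections <- list()
  if (!is.null(scenario$expression)) {
    for (i in seq_along(stim)) {
      cond <- stim[i]
      expr_cond <- scenario$expression[scenario$expression$condition == cond,
                                       c("protein", "fold_change")]
      roc <- evaluations[[cond]]$roc$ppi_plus_coa
      # the pooled CV ROC counts fold-stacked rows; convert the Youden
      # point to a rank cutoff over the node set via its cutoff fraction
      n_cut <- max(1, round(optimal_rank_cutoff(roc) / max(roc$cutoff) *
                              nrow(rankings[[cond]])))
      cand <- filter_candidates(rankings[[cond]], N = n_cut,
                                abun_scores = rel_abun[[cond]],
                                expr_scores = expr_cond,
                                top_k = config$top_k,
                                seeds = scenario$seeds)
      comb <- if (nrow(cand) > 0) {
        combined_rank(cand, rankings[[cond]], rel_abun[[cond]], expr_cond)
      } else NULL
      prox <- if (nrow(cand) > 0) {
        candidate_target_proximity(
          combined[[cond]], cand$protein, scenario$seeds$protein,
          n_real = config$n_random_nodes, rng_seed = seed_of(80 + i))
      } else NULL
      if (!is.null(comb)) {
        readr::write_tsv(tibble::as_tibble(comb),
                         file.path(out_dir, paste0("candidates_", cond,
                                                   ".tsv")), progress = FALSE)
      }
      if (!is.null(prox)) {
        jsonlite::write_json(unclass(glance(prox)),
                             file.path(out_dir, paste0("proximity_", cond,
                                                       ".json")),
                             auto_unbox = TRUE, digits = NA)
        readr::write_tsv(dplyr::left_join(prox$hist_obs, prox$hist_null,
                                          by = "length"),
                         file.path(out_dir, paste0("path_lengths_", cond,
                                                   ".tsv")), progress = FALSE)
      }
      selections[[cond]] <- list(n_cut = n_cut, candidates = cand,
                                 combined = comb, proximity = prox)
    }
    manifest$stage_seeds$select <- vapply(seq_along(stim),
                                          function(i) seed_of(80 + i),
                                          numeric(1))
    note("select", n_candidates = vapply(selections, function(s)
      nrow(s$candidates), numeric(1)))
  }

  # stage 8: enrichment
  enrichments <- list()
  if (!is.null(scenario$pathways)) {
    for (i in seq_along(stim)) {
      cond <- stim[i]
      overlap <- edge_overlap_enrichment(coa[[cond]], ppi)
      top <- top_prioritized_cutoff(
        rankings[[cond]], combined[[cond]], scenario$seeds,
        n_real = config$n_rank_perm, alpha = config$alpha_rank,
        rng_seed = seed_of(90 + i), method = config$method)
      enr <- hypergeometric_enrichment(top$top, scenario$pathways,
                                       q_max = config$enrich_q)
      pnet <- pathway_network(enr, top$top, scenario$pathways,
                              j_min = config$jaccard_min)
      readr::write_tsv(overlap,
                       file.path(out_dir, paste0("edge_overlap_", cond,
                                                 ".tsv")), progress = FALSE)
      readr::write_tsv(enr, file.path(out_dir, paste0("enrichment_", cond,
                                                      ".tsv")),
                       progress = FALSE)
      readr::write_tsv(pnet$edges,
                       file.path(out_dir, paste0("pathway_network_", cond,
                                                 ".tsv")), progress = FALSE)
      enrichments[[cond]] <- list(overlap = overlap, top = top,
                                  enrichment = enr, pathway_network = pnet)
    }
    manifest$stage_seeds$enrich <- vapply(seq_along(stim),
                                          function(i) seed_of(90 + i),
                                          numeric(1))
    note("enrich", n_top = vapply(enrichments, function(e)
      length(e$top$top), numeric(1)))
  }

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(out_dir, files))), files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    scenario = scenario, abundance = abundance, rel_abun = rel_abun,
    coa = coa, ppi = ppi, combined = combined, rankings = rankings,
    scans = scans, evaluations = evaluations, controls = controls,
    selections = selections, enrichments = enrichments,
    manifest = manifest
  ))
}
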