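#' Abundance matrices
#'
#' An `abundance_matrix` is a tibble with a `protein` column and one numeric
#' column per time point (named `t0`, `t8`, ..., hours). Values are abundance
#' ratios relative to the time-zero channel, so the `t0` column equals 1 for
#' matrices produced by [aggregate_psms()]. The stimulation condition label
#' and the numeric time grid travel as attributes.
#'
#' @param tbl data frame with `protein` plus time-point columns.
#' @param condition condition label (e.g. `"M(IFNg)"`).
#' @param time_points strictly increasing numeric vector of hours starting
#'   at 0; defaults to parsing the `t<hours>` column names.
#' @return a tibble of class `abundance_matrix`.
#' @export
abundance_matrix <- function(tbl, condition = NA_character_,
                             time_points = NULL) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot("protein" %in% names(tbl))
  tcols <- setdiff(names(tbl), "protein")
  if (is.null(time_points)) {
    time_points <- as.numeric(sub("^t", "", tcols))
  }
  stopifnot(!anyNA(time_points), all(diff(time_points) > 0),
            time_points[1] == 0, length(tcols) == length(time_points))
  if (anyNA(tbl[tcols])) stop("abundance matrices may not contain missing cells")
  tbl <- tbl[, c("protein", tcols)]
  structure(tbl, condition = condition, time_points = time_points,
            class = c("abundance_matrix", class(tibble::tibble())))
}

#' @rdname abundance_matrix
#' @param x an `abundance_matrix`.
#' @export
abundance_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "protein")])
  rownames(m) <- x$protein
  m
}

#' @rdname abundance_matrix
#' @export
abundance_condition <- function(x) attr(x, "condition")

#' @rdname abundance_matrix
#' @export
abundance_time_points <- function(x) attr(x, "time_points")

#' Read / write abundance TSV (row = protein, columns t0, t8, ...)
#' @param path file path.
#' @param condition condition label to attach on read.
#' @return an `abundance_matrix` / the path, invisibly.
#' @export
read_abundance_tsv <- function(path, condition = NA_character_) {
  abundance_matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE),
                   condition = condition)
}

#' @rdname read_abundance_tsv
#' @param x an `abundance_matrix`.
#' @export
write_abundance_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' Aggregate peptide-spectrum matches into protein abundance ratios
#'
#' Each PSM's channel intensities are first normalized to its own time-zero
#' channel; the protein-level ratio at each time point is then the median
#' over that protein's PSM ratios (standard midpoint median for even
#' counts). PSMs with a non-positive time-zero intensity are rejected with a
#' warning; proteins left without PSMs are dropped.
#'
#' @param psms a tibble with columns `psm_id`, `protein` and one intensity
#'   column per time point (`t0`, `t8`, ...).
#' @param condition condition label for the resulting matrix.
#' @return an `abundance_matrix` with `t0` identically 1.
#' @export
aggregate_psms <- function(psms, condition = NA_character_) {
  psms <- tibble::as_tibble(psms)
  tcols <- grep("^t[0-9.]+$", names(psms), value = TRUE)
  stopifnot(length(tcols) >= 2, "t0" %in% tcols, "protein" %in% names(psms))
  bad <- !is.finite(psms$t0) | psms$t0 <= 0
  if (any(bad)) {
    warning(sprintf("rejecting %d PSM(s) with non-positive t0 intensity",
                    sum(bad)))
    psms <- psms[!bad, , drop = FALSE]
  }
  if (nrow(psms) == 0) stop("no PSMs survive the t0 check")
  ratios <- psms[tcols] / psms$t0
  ratios$protein <- psms$protein
  prof <- ratios |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(tcols), stats::median),
                     .groups = "drop") |>
    dplyr::arrange(.data$protein)
  abundance_matrix(prof, condition = condition)
}

#' Keep proteins identified by strictly more than `min_psms` PSMs
#'
#' High-confidence filter applied before network construction: only
#' proteins with more than `min_psms` peptide-spectrum matches (default
#' strictly greater than 10) are retained.
#'
#' @param psms PSM tibble as in [aggregate_psms()].
#' @param min_psms count; a protein with exactly `min_psms` PSMs is dropped.
#' @return the filtered PSM tibble.
#' @export
filter_by_psm_count <- function(psms, min_psms = 10) {
  stopifnot(min_psms >= 0)
  counts <- table(psms$protein)
  keep <- names(counts)[counts > min_psms]
  psms[psms$protein %in% keep, , drop = FALSE]
}

#' Baseline-relative abundance profiles and total scores
#'
#' For each protein present in both matrices, the per-time-point difference
#' (condition minus baseline) and a total score summing those differences
#' over all time points between and including 0 and the last measured time.
#' The total is signed by default (induction-oriented); set
#' `absolute = TRUE` to sum absolute differences instead.
#'
#' @param condition,baseline `abundance_matrix` objects sharing time points.
#' @param absolute sum `|difference|` instead of the signed difference.
#' @return a tibble with `protein`, one `d_t*` column per time point, and
#'   `total`.
#' @export
relative_abundance <- function(condition, baseline, absolute = FALSE) {
  stopifnot(identical(abundance_time_points(condition),
                      abundance_time_points(baseline)))
  common <- intersect(condition$protein, baseline$protein)
  if (length(common) == 0) stop("no proteins shared between condition and baseline")
  mc <- abundance_values(condition)[common, , drop = FALSE]
  mb <- abundance_values(baseline)[common, , drop = FALSE]
  d <- mc - mb
  total <- if (absolute) rowSums(abs(d)) else rowSums(d)
  out <- tibble::as_tibble(d, .name_repair = "minimal")
  names(out) <- paste0("d_", colnames(mc))
  dplyr::bind_cols(tibble::tibble(protein = common), out,
                   tibble::tibble(total = unname(total)))
}
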