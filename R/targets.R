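#' Cis-acting lncRNA target genes by genomic window
#'
#' Pairs a lncRNA with a gene when both lie on the same chromosome and the
#' boundary-to-boundary gap between their intervals is at most
#' `cis_window_bp` (100 kb by default, covering both the upstream and the
#' downstream side; overlapping intervals have gap 0). Strand is ignored:
#' the window is symmetric. Coordinates are the internal 0-based half-open
#' convention of [read_annotation()].
#'
#' @param lnc_annotation,gene_annotation Annotation tibbles (`feature`,
#'   `chrom`, `start`, `end`, `strand`).
#' @param config A [pipeline_config()].
#' @param lnc_ids,gene_ids Optional id subsets (e.g. DE-passed features);
#'   ids missing from the annotation are skipped with one warning giving the
#'   count.
#' @return Tibble: `lncrna`, `gene`, `mode = "cis"`, `distance_bp`.
#' @export
cis_targets <- function(lnc_annotation, gene_annotation,
                        config = pipeline_config(),
                        lnc_ids = NULL, gene_ids = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  lnc <- subset_annotation(lnc_annotation, lnc_ids, "lncRNA")
  gene <- subset_annotation(gene_annotation, gene_ids, "gene")
  pairs <- dplyr::inner_join(
    lnc[, c("feature", "chrom", "start", "end")],
    gene[, c("feature", "chrom", "start", "end")],
    by = "chrom", suffix = c("_l", "_g"), relationship = "many-to-many"
  )
  pairs |>
    dplyr::mutate(distance_bp = pmax(
      0, pmax(.data$start_l, .data$start_g) - pmin(.data$end_l, .data$end_g)
    )) |>
    dplyr::filter(.data$distance_bp <= config$cis_window_bp,
                  .data$feature_l != .data$feature_g) |>
    dplyr::transmute(lncrna = .data$feature_l, gene = .data$feature_g,
                     mode = "cis", distance_bp = .data$distance_bp) |>
    dplyr::arrange(.data$lncrna, .data$gene)
}

subset_annotation <- function(ann, ids, what) {
  if (is.null(ids)) return(ann)
  missing <- setdiff(ids, ann$feature)
  if (length(missing) > 0) {
    rlang::warn(sprintf("%d %s id(s) without annotation were skipped",
                        length(missing), what))
  }
  ann[ann$feature %in% ids, , drop = FALSE]
}

#' Trans-acting lncRNA target genes by co-expression
#'
#' Pairs a lncRNA with a gene when the Pearson correlation of their
#' expression profiles exceeds `trans_r_min` (signed `r > 0.95` by default;
#' set `trans_use_abs` in the config to use |r|). Correlations are computed
#' on the configured sample scope and transform. Constant profiles have
#' undefined correlation and are excluded (one warning gives the count).
#'
#' @param lnc_expr,gene_expr Wide expression tibbles sharing the exact same
#'   sample set.
#' @param groups Sample/group tibble.
#' @param config A [pipeline_config()].
#' @param lnc_ids,gene_ids Optional id subsets (e.g. DE-passed lncRNAs).
#' @return Tibble: `lncrna`, `gene`, `mode = "trans"`, `pearson_r`.
#' @export
trans_targets <- function(lnc_expr, gene_expr, groups,
                          config = pipeline_config(),
                          lnc_ids = NULL, gene_ids = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_expression(lnc_expr)
  validate_expression(gene_expr)
  if (!setequal(expr_sample_ids(lnc_expr), expr_sample_ids(gene_expr))) {
    rlang::abort("lncRNA and gene matrices must share the same sample set",
                 class = "cernet_input_error")
  }
  validate_expression(lnc_expr, groups)
  validate_expression(gene_expr, groups)
  if (!is.null(lnc_ids)) lnc_expr <- lnc_expr[lnc_expr$feature %in% lnc_ids, ]
  if (!is.null(gene_ids)) {
    gene_expr <- gene_expr[gene_expr$feature %in% gene_ids, ]
  }
  samples <- scope_samples(groups, config$correlation_scope)
  lv <- transform_fpkm(expr_values(lnc_expr, samples),
                       config$correlation_transform)
  gv <- transform_fpkm(expr_values(gene_expr, samples),
                       config$correlation_transform)
  const_l <- apply(lv, 1, stats::sd) == 0
  const_g <- apply(gv, 1, stats::sd) == 0
  n_const <- sum(const_l) + sum(const_g)
  if (n_const > 0) {
    rlang::warn(sprintf(
      "%d constant profile(s) excluded (undefined correlation)", n_const))
  }
  lv <- lv[!const_l, , drop = FALSE]
  gv <- gv[!const_g, , drop = FALSE]
  if (nrow(lv) == 0 || nrow(gv) == 0) {
    return(tibble::tibble(lncrna = character(), gene = character(),
                          mode = character(), pearson_r = numeric()))
  }
  r <- stats::cor(t(lv), t(gv))
  hits <- if (config$trans_use_abs) abs(r) > config$trans_r_min else {
    r > config$trans_r_min
  }
  idx <- which(hits, arr.ind = TRUE)
  tibble::tibble(
    lncrna = rownames(r)[idx[, 1]],
    gene = colnames(r)[idx[, 2]],
    mode = "trans",
    pearson_r = r[idx]
  ) |>
    dplyr::filter(.data$lncrna != .data$gene) |>
    dplyr::arrange(.data$lncrna, .data$gene)
}

#' Qualify miRNA-target edges by multi-source agreement
#'
#' Collapses a per-source evidence table to one row per (miRNA, target) pair
#' and keeps pairs supported by at least `mrna_sources_required` distinct
#' sources (mRNA targets) or `lncrna_sources_required` (lncRNA targets).
#' Duplicate (mirna, target, source) rows count once. The default
#' requirement of 1 takes the union of sources; raise it for intersection.
#'
#' @param evidence Evidence tibble (`mirna`, `target`, `target_class`,
#'   `source`).
#' @param config A [pipeline_config()].
#' @return Tibble: `mirna`, `target`, `target_class`, `n_sources`,
#'   `sources` (comma-joined, sorted).
#' @export
qualify_mirna_edges <- function(evidence, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (nrow(evidence) == 0) {
    rlang::abort("evidence table is empty", class = "cernet_input_error")
  }
  bad <- setdiff(unique(evidence$target_class), c("mRNA", "lncRNA"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown target_class value(s): ",
                        paste(bad, collapse = ", ")),
                 class = "cernet_validation_error")
  }
  incons <- evidence |>
    dplyr::distinct(.data$target, .data$target_class) |>
    dplyr::count(.data$target) |>
    dplyr::filter(.data$n > 1)
  if (nrow(incons) > 0) {
    rlang::abort(paste0("inconsistent target_class for target(s): ",
                        paste(incons$target, collapse = ", ")),
                 class = "cernet_validation_error")
  }
  evidence |>
    dplyr::distinct(.data$mirna, .data$target, .data$target_class,
                    .data$source) |>
    dplyr::group_by(.data$mirna, .data$target, .data$target_class) |>
    dplyr::summarise(
      n_sources = dplyr::n_distinct(.data$source),
      sources = paste(sort(unique(.data$source)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sources >= ifelse(.data$target_class == "mRNA",
                                            config$mrna_sources_required,
                                            config$lncrna_sources_required)) |>
    dplyr::arrange(.data$mirna, .data$target)
}
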