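#' Two-group Mann-Whitney U test
#'
#' The rank-sum test used for per-feature differential expression. `u` is
#' the classic U statistic of the case group (0 when every case value lies
#' below every control value). The two-sided p-value comes from exact
#' enumeration of rank assignments when both groups have at most 8
#' observations and there are no ties (feasible at the 8-vs-8 study size);
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param case,control Numeric vectors, each with at least 2 observations.
#' @param exact `"auto"` (exact when feasible, the default) or `"never"`.
#' @return A one-row tibble: `u`, `p`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
mann_whitney <- function(case, control, exact = c("auto", "never")) {
  exact <- rlang::arg_match(exact)
  if (length(case) < 2 || length(control) < 2) {
    rlang::abort("each group needs at least 2 observations",
                 class = "cernet_input_error")
  }
  if (anyNA(case) || anyNA(control)) {
    rlang::abort("missing values in test input",
                 class = "cernet_input_error")
  }
  ties <- anyDuplicated(c(case, control)) > 0
  use_exact <- exact == "auto" && !ties &&
    length(case) <= 8 && length(control) <= 8
  ht <- suppressWarnings(
    stats::wilcox.test(case, control, exact = use_exact,
                       correct = !use_exact)
  )
  tibble::tibble(
    u = unname(ht$statistic),
    p = ht$p.value,
    method = if (use_exact) "exact" else "normal"
  )
}

#' Per-feature differential expression with abundance and fold-change filters
#'
#' Runs the Mann-Whitney test on every feature of an expression table and
#' applies the three screening filters with strict comparators: abundance
#' (group-mean FPKM must exceed `fpkm_min`), significance (raw
#' `p < p_max`) and effect size (fold change above `fc_min` or below
#' `1/fc_min`). Fold change is `(mean_case + pseudocount) /
#' (mean_control + pseudocount)` on group means. A Benjamini-Hochberg
#' `bh_q` column is reported for information but plays no part in the
#' filter, which uses the raw p-value. Direction is case-relative: `"up"`
#' means higher in the case group; features that fail any filter are
#' `"ns"`.
#'
#' @param expr Wide expression tibble (see [validate_expression()]).
#' @param groups Sample/group tibble (`"case"`/`"control"`).
#' @param rna_class Label recorded in the output (`"mrna"`, `"lncrna"`,
#'   `"mirna"` or any string).
#' @param config A [pipeline_config()].
#' @param verbose If `TRUE`, report stage counts (tested/passed/up/down).
#' @return A tibble ordered by feature id with columns `feature`, `class`,
#'   `mean_case`, `mean_control`, `fc`, `log2fc`, `u`, `p`, `bh_q`,
#'   `direction`, `passed`.
#' @export
run_de <- function(expr, groups, rna_class = "mrna",
                   config = pipeline_config(), verbose = FALSE) {
  validate_expression(expr, groups)
  stopifnot(inherits(config, "pipeline_config"))
  if (length(unique(groups$group)) < 2) {
    rlang::abort("both case and control samples are required",
                 class = "cernet_input_error")
  }
  vals <- expr_values(expr)
  case_s <- intersect(colnames(vals), groups$sample[groups$group == "case"])
  ctrl_s <- intersect(colnames(vals), groups$sample[groups$group == "control"])
  if (length(case_s) < 2 || length(ctrl_s) < 2) {
    rlang::abort("each group needs at least 2 samples",
                 class = "cernet_input_error")
  }
  mean_case <- rowMeans(vals[, case_s, drop = FALSE])
  mean_ctrl <- rowMeans(vals[, ctrl_s, drop = FALSE])
  tests <- purrr::map(seq_len(nrow(vals)), function(i) {
    mann_whitney(vals[i, case_s], vals[i, ctrl_s],
                 exact = config$exact_test)
  })
  fc <- (mean_case + config$pseudocount) / (mean_ctrl + config$pseudocount)
  p <- purrr::map_dbl(tests, "p")
  abundant <- switch(config$abundance_rule,
    max_group_mean = pmax(mean_case, mean_ctrl) > config$fpkm_min,
    both_group_means = pmin(mean_case, mean_ctrl) > config$fpkm_min,
    overall_mean = rowMeans(vals) > config$fpkm_min
  )
  effect <- fc > config$fc_min | fc < 1 / config$fc_min
  passed <- abundant & (p < config$p_max) & effect
  out <- tibble::tibble(
    feature = expr$feature,
    class = rna_class,
    mean_case = unname(mean_case),
    mean_control = unname(mean_ctrl),
    fc = unname(fc),
    log2fc = log2(unname(fc)),
    u = purrr::map_dbl(tests, "u"),
    p = p,
    bh_q = stats::p.adjust(p, method = "BH"),
    direction = dplyr::case_when(!passed ~ "ns", fc > 1 ~ "up",
                                 .default = "down"),
    passed = passed
  ) |>
    dplyr::arrange(.data$feature)
  if (verbose) {
    s <- de_summary(out)
    rlang::inform(sprintf(
      "DE [%s]: %d tested, %d passed (%d up, %d down)",
      rna_class, s$total, s$passed, s$up, s$down))
  }
  out
}

#' Summarise a DE table as stage counts
#'
#' @param de A table from [run_de()].
#' @return One-row tibble: `total`, `passed`, `up`, `down`.
#' @export
de_summary <- function(de) {
  tibble::tibble(
    total = nrow(de),
    passed = sum(de$passed),
    up = sum(de$direction == "up"),
    down = sum(de$direction == "down")
  )
}

#' Features dysregulated in both of two comparisons
#'
#' Intersects two DE tables of the same RNA class and reports every feature
#' that passes in both, flagging whether the direction is concordant
#' (shared dysregulation) or discordant.
#'
#' @param de_a,de_b DE tables from [run_de()] for the same `rna_class`.
#' @return Tibble with `feature`, `class`, `direction_a`, `direction_b`,
#'   `concordant`; concordant rows form the shared dysregulated set.
#' @export
shared_de <- function(de_a, de_b) {
  if (!identical(unique(de_a$class), unique(de_b$class))) {
    rlang::abort("DE tables compare different RNA classes",
                 class = "cernet_input_error")
  }
  dplyr::inner_join(
    dplyr::filter(de_a, .data$passed)[, c("feature", "class", "direction")],
    dplyr::filter(de_b, .data$passed)[, c("feature", "direction")],
    by = "feature", suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(concordant = .data$direction_a == .data$direction_b) |>
    dplyr::arrange(.data$feature)
}
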