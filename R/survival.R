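#' Kaplan-Meier log-rank screen for one expression profile
#'
#' Dichotomizes subjects at the median of the expression values (ties go to
#' the low group), then compares the two survival curves with the two-sample
#' log-rank test: the observed-minus-expected event count in the high group
#' with its hypergeometric variance, referred to chi-square on 1 df.
#' `hazard_direction` is `"high-risk"` when the high-expression group has
#' more events than expected. A degenerate split (all values equal, or fewer
#' than 2 subjects on a side) yields a non-evaluable result rather than an
#' error.
#'
#' @param surv Survival tibble (`sample`, `time` > 0, `event` in 0/1).
#' @param values Named numeric vector of expression values; names are sample
#'   ids matching `surv$sample`.
#' @return One-row tibble: `n_high`, `n_low`, `logrank_chi2`, `p_value`,
#'   `hazard_direction`, `evaluable`.
#' @export
km_logrank <- function(surv, values) {
  validate_survival(surv)
  if (is.null(names(values))) {
    rlang::abort("`values` must be named by sample id",
                 class = "cernet_input_error")
  }
  common <- intersect(surv$sample, names(values))
  surv <- surv[surv$sample %in% common, ]
  v <- values[surv$sample]
  high <- v > stats::median(v)
  non_eval <- tibble::tibble(
    n_high = sum(high), n_low = sum(!high),
    logrank_chi2 = NA_real_, p_value = NA_real_,
    hazard_direction = NA_character_, evaluable = FALSE
  )
  if (sum(high) < 2 || sum(!high) < 2 || sum(surv$event) == 0) {
    return(non_eval)
  }
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sd_fit <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ grp)
  chi2 <- unname(sd_fit$chisq)
  oe_high <- sd_fit$obs[2] - sd_fit$exp[2]
  tibble::tibble(
    n_high = sum(high), n_low = sum(!high),
    logrank_chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    hazard_direction = ifelse(oe_high > 0, "high-risk", "low-risk"),
    evaluable = TRUE
  )
}

#' Screen every miRNA of an expression table for prognostic value
#'
#' Runs [km_logrank()] per miRNA against one survival table (typically an
#' independent cohort). `significant` applies the configured raw p-value
#' threshold with no multiplicity correction, matching the screening style
#' in which each network miRNA is queried separately.
#'
#' @param surv Survival tibble (`sample`, `time`, `event`).
#' @param expr Wide miRNA expression tibble over the same subjects.
#' @param config A [pipeline_config()].
#' @return Tibble, one row per miRNA: `mirna`, `n_high`, `n_low`,
#'   `logrank_chi2`, `p_value`, `hazard_direction`, `evaluable`,
#'   `significant`.
#' @export
km_screen <- function(surv, expr, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_expression(expr)
  vals <- expr_values(expr)
  purrr::map_dfr(rownames(vals), function(f) {
    dplyr::bind_cols(tibble::tibble(mirna = f),
                     km_logrank(surv, vals[f, ]))
  }) |>
    dplyr::mutate(significant = !is.na(.data$p_value) &
                    .data$p_value < config$p_max) |>
    dplyr::arrange(.data$mirna)
}

#' Survival-related ceRNA axes of a network
#'
#' For every network miRNA that screened significant, emits one axis
#' aggregating all of its lncRNA partners and all of its mRNA partners from
#' the network — the multi-partner row shape in which survival-related
#' lncRNA/miRNA/mRNA regulations are reported. `km` may be a [km_screen()]
#' result or any precomputed adapter table with columns `mirna` and `p`
#' (plus optional `direction`), so externally screened p-values drop in
#' unchanged.
#'
#' @param network A `cerna_network` from [build_network()].
#' @param km Per-miRNA screen results (`mirna`, `p_value` or `p`; optional
#'   `significant`).
#' @param config A [pipeline_config()].
#' @return Tibble, one row per significant network miRNA, ordered by id:
#'   `mirna`, `lncrnas`, `mrnas` (comma-joined sorted partner lists),
#'   `n_lncrna`, `n_mrna`, `p_value`.
#' @export
screen_axes <- function(network, km, config = pipeline_config()) {
  stopifnot(inherits(network, "cerna_network"),
            inherits(config, "pipeline_config"))
  if (!"p_value" %in% names(km) && "p" %in% names(km)) {
    km$p_value <- km$p
  }
  if (!all(c("mirna", "p_value") %in% names(km))) {
    rlang::abort("`km` needs columns mirna and p_value (or p)",
                 class = "cernet_input_error")
  }
  if (!"significant" %in% names(km)) {
    km$significant <- !is.na(km$p_value) & km$p_value < config$p_max
  }
  net_mirnas <- network$nodes$id[network$nodes$type == "miRNA"]
  sig <- km[km$significant & km$mirna %in% net_mirnas, c("mirna", "p_value")]
  if (nrow(sig) == 0) {
    return(tibble::tibble(mirna = character(), lncrnas = character(),
                          mrnas = character(), n_lncrna = integer(),
                          n_mrna = integer(), p_value = numeric()))
  }
  partners <- function(mi, kind) {
    sort(unique(network$edges$to[network$edges$from == mi &
                                   network$edges$kind == kind]))
  }
  sig |>
    dplyr::distinct(.data$mirna, .keep_all = TRUE) |>
    dplyr::mutate(
      lnc = purrr::map(.data$mirna, partners, kind = "miRNA-lncRNA"),
      mr = purrr::map(.data$mirna, partners, kind = "miRNA-mRNA"),
      lncrnas = purrr::map_chr(.data$lnc, paste, collapse = ","),
      mrnas = purrr::map_chr(.data$mr, paste, collapse = ","),
      n_lncrna = lengths(.data$lnc),
      n_mrna = lengths(.data$mr)
    ) |>
    dplyr::select("mirna", "lncrnas", "mrnas", "n_lncrna", "n_mrna",
                  "p_value") |>
    dplyr::arrange(.data$mirna)
}

#' Count distinct miRNA-keyed survival axes
#'
#' @param axes Axis tibble from [screen_axes()] or [read_axes()].
#' @return Number of distinct miRNAs keying an axis.
#' @export
count_axes <- function(axes) {
  dplyr::n_distinct(axes$mirna)
}
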