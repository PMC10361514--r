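#' @importFrom rlang .data
NULL

# Internal helpers shared by the DE, target and network stages. An expression
# table is a wide tibble: a `feature` character column followed by one numeric
# column per sample, values on the FPKM scale. Group membership travels in a
# separate two-column tibble (sample, group), group in {case, control}.

expr_sample_ids <- function(expr) setdiff(names(expr), "feature")

expr_values <- function(expr, samples = NULL) {
  m <- as.matrix(expr[, expr_sample_ids(expr), drop = FALSE])
  rownames(m) <- expr$feature
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  m
}

#' Validate an expression table
#'
#' Checks the invariants every pipeline stage relies on: a `feature` column
#' with unique ids, unique sample columns, a dense non-negative numeric value
#' table, and (when `groups` is supplied) a case/control label for every
#' sample. Errors name the offending feature, sample or value.
#'
#' @param expr Wide expression tibble (`feature` column plus one numeric
#'   column per sample, FPKM scale).
#' @param groups Optional tibble with columns `sample` and `group`
#'   (`"case"`/`"control"`).
#' @return `expr`, invisibly, if all checks pass.
#' @export
validate_expression <- function(expr, groups = NULL) {
  if (!is.data.frame(expr) || !"feature" %in% names(expr)) {
    rlang::abort("expression table must have a `feature` column",
                 class = "cernet_format_error")
  }
  dup <- expr$feature[duplicated(expr$feature)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicated feature id(s): ",
                        paste(unique(dup), collapse = ", ")),
                 class = "cernet_format_error")
  }
  samples <- expr_sample_ids(expr)
  if (length(samples) == 0) {
    rlang::abort("expression table has no sample columns",
                 class = "cernet_format_error")
  }
  if (anyDuplicated(samples)) {
    rlang::abort("duplicated sample id(s) in header",
                 class = "cernet_format_error")
  }
  vals <- expr_values(expr)
  if (!is.numeric(vals)) {
    rlang::abort("sample columns must be numeric",
                 class = "cernet_validation_error")
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    rlang::abort(paste0("missing value at feature ", rownames(vals)[bad[1]],
                        ", sample ", colnames(vals)[bad[2]]),
                 class = "cernet_validation_error")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    rlang::abort(paste0("negative FPKM value at feature ",
                        rownames(vals)[bad[1]], ", sample ",
                        colnames(vals)[bad[2]]),
                 class = "cernet_validation_error")
  }
  if (!is.null(groups)) {
    check_groups(groups)
    missing <- setdiff(samples, groups$sample)
    if (length(missing) > 0) {
      rlang::abort(paste0("sample(s) without a group label: ",
                          paste(missing, collapse = ", ")),
                   class = "cernet_validation_error")
    }
  }
  invisible(expr)
}

check_groups <- function(groups) {
  if (!is.data.frame(groups) ||
      !all(c("sample", "group") %in% names(groups))) {
    rlang::abort("groups must be a tibble with columns `sample` and `group`",
                 class = "cernet_format_error")
  }
  bad <- setdiff(unique(groups$group), c("case", "control"))
  if (length(bad) > 0) {
    rlang::abort(paste0("group labels must be 'case'/'control'; found: ",
                        paste(bad, collapse = ", ")),
                 class = "cernet_validation_error")
  }
  if (anyDuplicated(groups$sample)) {
    rlang::abort("duplicated sample id(s) in group map",
                 class = "cernet_format_error")
  }
  invisible(groups)
}

# Samples used for correlations under a config scope.
scope_samples <- function(groups, scope) {
  switch(scope,
    pooled  = groups$sample,
    case    = groups$sample[groups$group == "case"],
    control = groups$sample[groups$group == "control"]
  )
}

# FPKM -> correlation scale.
transform_fpkm <- function(m, transform) {
  switch(transform, log2p1 = log2(m + 1), fpkm = m)
}
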