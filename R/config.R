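#' Pipeline configuration
#'
#' Collects every tunable threshold of the ceRNA pipeline in one object.
#' The defaults reproduce the screening settings used throughout the
#' tissue-exosome workflow: features are called differentially expressed when
#' FPKM > 5, raw Mann-Whitney P < 0.05 and fold change > 1.5; trans-acting
#' lncRNA targets require Pearson r > 0.95; ceRNA couplings require a negative
#' miRNA-partner correlation with |r| > 0.5; cis targets must lie within
#' 100 kb; hubs have network degree > 5. All comparators are strict, so
#' boundary values (FPKM = 5, FC = 1.5, p = 0.05, r = 0.5, r = 0.95,
#' gap = 100,001 bp) fail their filters.
#'
#' @param fpkm_min Abundance threshold on the FPKM scale (strict: FPKM must
#'   exceed this value). Default 5.
#' @param fc_min Fold-change threshold, applied symmetrically: a feature
#'   passes when FC > `fc_min` or FC < 1/`fc_min`. Default 1.5.
#' @param p_max Raw P-value threshold (strict `p < p_max`); also used by the
#'   survival screen. Default 0.05.
#' @param trans_r_min Pearson correlation threshold for trans-acting lncRNA
#'   target assignment (strict, signed by default). Default 0.95.
#' @param cerna_abs_r_min Correlation-magnitude threshold for ceRNA couplings
#'   (strict, applied to |r| with the sign constraint r < 0 for
#'   miRNA-partner pairs). Default 0.5.
#' @param cis_window_bp Maximum boundary-to-boundary gap (bp) for a cis
#'   lncRNA-gene pair; a gap of exactly `cis_window_bp` passes. Default
#'   100,000.
#' @param hub_min_degree Minimum degree for a hub node; the default 6
#'   implements the strict "degree > 5" rule.
#' @param mrna_sources_required,lncrna_sources_required Number of distinct
#'   prediction sources an evidence edge needs to qualify, per target class.
#'   Default 1 (union of sources); set higher for source intersection.
#' @param correlation_scope Which samples correlations use: `"pooled"`
#'   (case + control of the comparison, the default), `"case"` or
#'   `"control"`.
#' @param correlation_transform Scale on which Pearson correlations are
#'   computed: `"log2p1"` (log2(FPKM + 1), default) or `"fpkm"` (raw).
#' @param abundance_rule How "FPKM > fpkm_min" is interpreted:
#'   `"max_group_mean"` (default; the larger of the two group means must
#'   exceed the threshold, keeping features expressed in only one condition),
#'   `"both_group_means"` or `"overall_mean"`.
#' @param pseudocount Offset added to both group means before forming the
#'   fold change, so features absent from one group do not divide by zero.
#'   Default 0.01 FPKM.
#' @param exact_test `"auto"` (default): exact Mann-Whitney enumeration when
#'   both groups have at most 8 observations and there are no ties, otherwise
#'   the tie-corrected normal approximation with continuity correction;
#'   `"never"`: always the normal approximation.
#' @param trans_use_abs If `TRUE`, the trans-target filter uses |r| instead of
#'   signed r. Default `FALSE` (signed, as the threshold is conventionally
#'   stated).
#' @param lnc_mrna_check If `TRUE`, triples additionally require a positive
#'   lncRNA-mRNA correlation with r > `cerna_abs_r_min`. Off by default: the
#'   canonical assembly rules constrain only the two miRNA-partner
#'   correlations, though the ceRNA hypothesis predicts the positive pair.
#'
#' @return A `pipeline_config` object (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$fpkm_min
#' stricter <- pipeline_config(mrna_sources_required = 2)
#' @export
pipeline_config <- function(fpkm_min = 5,
                            fc_min = 1.5,
                            p_max = 0.05,
                            trans_r_min = 0.95,
                            cerna_abs_r_min = 0.5,
                            cis_window_bp = 100000,
                            hub_min_degree = 6L,
                            mrna_sources_required = 1L,
                            lncrna_sources_required = 1L,
                            correlation_scope = c("pooled", "case", "control"),
                            correlation_transform = c("log2p1", "fpkm"),
                            abundance_rule = c("max_group_mean",
                                               "both_group_means",
                                               "overall_mean"),
                            pseudocount = 0.01,
                            exact_test = c("auto", "never"),
                            trans_use_abs = FALSE,
                            lnc_mrna_check = FALSE) {
  cfg <- list(
    fpkm_min = as.numeric(fpkm_min),
    fc_min = as.numeric(fc_min),
    p_max = as.numeric(p_max),
    trans_r_min = as.numeric(trans_r_min),
    cerna_abs_r_min = as.numeric(cerna_abs_r_min),
    cis_window_bp = as.numeric(cis_window_bp),
    hub_min_degree = as.integer(hub_min_degree),
    mrna_sources_required = as.integer(mrna_sources_required),
    lncrna_sources_required = as.integer(lncrna_sources_required),
    correlation_scope = rlang::arg_match(correlation_scope),
    correlation_transform = rlang::arg_match(correlation_transform),
    abundance_rule = rlang::arg_match(abundance_rule),
    pseudocount = as.numeric(pseudocount),
    exact_test = rlang::arg_match(exact_test),
    trans_use_abs = isTRUE(trans_use_abs),
    lnc_mrna_check = isTRUE(lnc_mrna_check)
  )
  for (fld in c("fpkm_min", "fc_min", "p_max", "trans_r_min",
                "cerna_abs_r_min", "cis_window_bp", "pseudocount")) {
    if (!is.finite(cfg[[fld]]) || cfg[[fld]] <= 0) {
      rlang::abort(paste0("`", fld, "` must be a positive number"),
                   class = "cernet_validation_error")
    }
  }
  if (is.na(cfg$hub_min_degree) || cfg$hub_min_degree < 1L) {
    rlang::abort("`hub_min_degree` must be an integer >= 1",
                 class = "cernet_validation_error")
  }
  if (cfg$mrna_sources_required < 1L || cfg$lncrna_sources_required < 1L) {
    rlang::abort("source-agreement requirements must be >= 1",
                 class = "cernet_validation_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys in the file override [pipeline_config()] defaults; arguments passed
#' through `...` override the file in turn, mirroring the usual
#' config-file-plus-flag precedence.
#'
#' @param path Path to a YAML file whose keys are `pipeline_config()`
#'   argument names.
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path, ...) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) {
    rlang::abort("config file must contain a YAML mapping",
                 class = "cernet_format_error")
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "cernet_format_error")
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
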