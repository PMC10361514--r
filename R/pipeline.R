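#' Run the full ceRNA pipeline for one comparison
#'
#' Chains the stages for one case-vs-control comparison: per-class
#' differential expression, evidence qualification, correlation-constrained
#' triple assembly, network construction, hub detection and (when a survival
#' cohort is supplied) the Kaplan-Meier screen with axis extraction.
#'
#' @param expr Named list of wide expression tibbles (`mrna`, `lncrna`,
#'   `mirna`).
#' @param groups Sample/group tibble for the comparison.
#' @param evidence Evidence tibble (`mirna`, `target`, `target_class`,
#'   `source`).
#' @param survival Optional list with `survival` (sample/time/event tibble)
#'   and `expression` (cohort miRNA tibble), e.g. the `survival` element of
#'   [simulate_study()].
#' @param config A [pipeline_config()].
#' @param verbose Report stage counts as messages.
#' @return A `cerna_result` list: `de` (named list of DE tables),
#'   `qualified_edges`, `triples`, `network`, `hubs`, `km` (or `NULL`),
#'   `axes` (or `NULL`), `config`.
#' @examples
#' sim <- simulate_study(simulation_design(n_mrna = 80, n_lncrna = 40,
#'                                         n_mirna = 25, n_de_per_class = 8,
#'                                         n_triples = 4, seed = 11))
#' res <- run_cerna_pipeline(sim$expression, sim$groups, sim$evidence,
#'                           survival = sim$survival)
#' glance(res$network)
#' @export
run_cerna_pipeline <- function(expr, groups, evidence, survival = NULL,
                               config = pipeline_config(),
                               verbose = FALSE) {
  de <- list(
    mrna = run_de(expr$mrna, groups, "mrna", config, verbose),
    lncrna = run_de(expr$lncrna, groups, "lncrna", config, verbose),
    mirna = run_de(expr$mirna, groups, "mirna", config, verbose)
  )
  edges <- qualify_mirna_edges(evidence, config)
  triples <- assemble_triples(edges, de, expr, groups, config)
  network <- build_network(triples)
  hubs <- find_hubs(network, config)
  km <- NULL
  axes <- NULL
  if (!is.null(survival)) {
    net_mirnas <- network$nodes$id[network$nodes$type == "miRNA"]
    cohort <- survival$expression
    cohort <- cohort[cohort$feature %in% net_mirnas, , drop = FALSE]
    if (nrow(cohort) > 0) {
      km <- km_screen(survival$survival, cohort, config)
      axes <- screen_axes(network, km, config)
    } else {
      axes <- screen_axes(network,
                          tibble::tibble(mirna = character(),
                                         p_value = numeric()), config)
    }
  }
  if (verbose) {
    rlang::inform(sprintf(
      "network: %d nodes, %d edges from %d triples; %d hub(s)%s",
      nrow(network$nodes), nrow(network$edges), nrow(triples), nrow(hubs),
      if (is.null(axes)) "" else sprintf("; %d survival axis/axes",
                                         count_axes(axes))))
  }
  structure(list(de = de, qualified_edges = edges, triples = triples,
                 network = network, hubs = hubs, km = km, axes = axes,
                 config = config),
            class = "cerna_result")
}

#' Score emitted triples against planted truth
#'
#' Precision and recall of an emitted triple set against the planted triples
#' of a synthetic study, matching on the ordered (lncrna, mirna, mrna) key.
#'
#' @param triples Emitted triples from [assemble_triples()].
#' @param truth_triples Planted triples (`lncrna`, `mirna`, `mrna`), e.g.
#'   `sim$truth$triples`.
#' @return One-row tibble: `n_emitted`, `n_true`, `tp`, `precision`,
#'   `recall`.
#' @export
score_triples <- function(triples, truth_triples) {
  key <- function(x) paste(x$lncrna, x$mirna, x$mrna)
  emitted <- unique(key(triples))
  truth <- unique(key(truth_triples))
  tp <- length(intersect(emitted, truth))
  tibble::tibble(
    n_emitted = length(emitted),
    n_true = length(truth),
    tp = tp,
    precision = if (length(emitted) == 0) NA_real_ else tp / length(emitted),
    recall = if (length(truth) == 0) NA_real_ else tp / length(truth)
  )
}

#' @export
print.cerna_result <- function(x, ...) {
  cat("<cerna_result>\n")
  for (cls in names(x$de)) {
    s <- de_summary(x$de[[cls]])
    cat(sprintf("  DE %-7s %d/%d passed (%d up, %d down)\n",
                paste0(cls, ":"), s$passed, s$total, s$up, s$down))
  }
  s <- glance(x$network)
  cat(sprintf("  network: %d nodes, %d edges, %d triples; %d hub(s)\n",
              s$n_nodes, s$n_edges, s$n_triples, nrow(x$hubs)))
  if (!is.null(x$axes)) {
    cat(sprintf("  survival axes: %d\n", count_axes(x$axes)))
  }
  invisible(x)
}
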