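pair_cor <- function(a_vals, b_vals, a_ids, b_ids) {
  # correlation for specific (a, b) id pairs; rows of *_vals are features
  purrr::map2_dbl(a_ids, b_ids, function(a, b) {
    x <- a_vals[a, ]
    y <- b_vals[b, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  })
}

#' Assemble correlation-constrained ceRNA triples
#'
#' Builds candidate lncRNA/miRNA/mRNA triples from qualified miRNA-target
#' edges restricted to DE-passed features of one comparison, then applies
#' the two integration rules: (1) negative expression correlation between
#' the miRNA and each partner, (2) correlation magnitude above
#' `cerna_abs_r_min` (strictly, so r = -0.5 fails). The lncRNA-mRNA
#' correlation is always reported and, when `lnc_mrna_check` is enabled in
#' the config, additionally required to exceed `+cerna_abs_r_min`.
#' Correlations use the configured sample scope (case + control pooled by
#' default) and transform. Qualified-edge members with no expression profile
#' are skipped with one warning giving the count.
#'
#' @param edges Qualified edge tibble from [qualify_mirna_edges()].
#' @param de Named list of DE tables (`mrna`, `lncrna`, `mirna`) from
#'   [run_de()], all from the same comparison.
#' @param expr Named list of wide expression tibbles (`mrna`, `lncrna`,
#'   `mirna`).
#' @param groups Sample/group tibble of the comparison.
#' @param config A [pipeline_config()].
#' @return Tibble ordered by (lncrna, mirna, mrna): ids, the three
#'   correlations `r_mi_lnc`, `r_mi_m`, `r_lnc_m`, evidence source lists and
#'   the DE direction of each member.
#' @export
assemble_triples <- function(edges, de, expr, groups,
                             config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stopifnot(all(c("mrna", "lncrna", "mirna") %in% names(de)),
            all(c("mrna", "lncrna", "mirna") %in% names(expr)))
  passed <- purrr::map(de, ~ .x$feature[.x$passed])
  dirs <- purrr::map(de, ~ stats::setNames(.x$direction, .x$feature))

  samples <- scope_samples(groups, config$correlation_scope)
  vals <- purrr::map(expr, function(e) {
    transform_fpkm(expr_values(e, samples), config$correlation_transform)
  })

  empty <- tibble::tibble(
    lncrna = character(), mirna = character(), mrna = character(),
    r_mi_lnc = numeric(), r_mi_m = numeric(), r_lnc_m = numeric(),
    mrna_sources = character(), lncrna_sources = character(),
    lncrna_dir = character(), mirna_dir = character(),
    mrna_dir = character()
  )
  if (nrow(edges) == 0) return(empty)

  mi_m <- edges |>
    dplyr::filter(.data$target_class == "mRNA",
                  .data$mirna %in% passed$mirna,
                  .data$target %in% passed$mrna)
  mi_l <- edges |>
    dplyr::filter(.data$target_class == "lncRNA",
                  .data$mirna %in% passed$mirna,
                  .data$target %in% passed$lncrna)

  n_noexpr <- sum(!mi_m$target %in% rownames(vals$mrna)) +
    sum(!mi_l$target %in% rownames(vals$lncrna)) +
    sum(!unique(c(mi_m$mirna, mi_l$mirna)) %in% rownames(vals$mirna))
  if (n_noexpr > 0) {
    rlang::warn(sprintf(
      "%d qualified-edge member(s) without expression were skipped",
      n_noexpr))
  }
  mi_m <- mi_m |>
    dplyr::filter(.data$mirna %in% rownames(vals$mirna),
                  .data$target %in% rownames(vals$mrna))
  mi_l <- mi_l |>
    dplyr::filter(.data$mirna %in% rownames(vals$mirna),
                  .data$target %in% rownames(vals$lncrna))
  if (nrow(mi_m) == 0 || nrow(mi_l) == 0) return(empty)

  mi_m$r <- pair_cor(vals$mirna, vals$mrna, mi_m$mirna, mi_m$target)
  mi_l$r <- pair_cor(vals$mirna, vals$lncrna, mi_l$mirna, mi_l$target)
  keep <- function(r) !is.na(r) & r < 0 & abs(r) > config$cerna_abs_r_min
  mi_m <- mi_m[keep(mi_m$r), ]
  mi_l <- mi_l[keep(mi_l$r), ]
  if (nrow(mi_m) == 0 || nrow(mi_l) == 0) return(empty)

  triples <- dplyr::inner_join(
    dplyr::transmute(mi_l, mirna = .data$mirna, lncrna = .data$target,
                     r_mi_lnc = .data$r, lncrna_sources = .data$sources),
    dplyr::transmute(mi_m, mirna = .data$mirna, mrna = .data$target,
                     r_mi_m = .data$r, mrna_sources = .data$sources),
    by = "mirna", relationship = "many-to-many"
  )
  if (nrow(triples) == 0) return(empty)
  triples$r_lnc_m <- pair_cor(vals$lncrna, vals$mrna,
                              triples$lncrna, triples$mrna)
  if (config$lnc_mrna_check) {
    triples <- triples[!is.na(triples$r_lnc_m) &
                         triples$r_lnc_m > config$cerna_abs_r_min, ]
  }
  triples |>
    dplyr::mutate(
      lncrna_dir = unname(dirs$lncrna[.data$lncrna]),
      mirna_dir = unname(dirs$mirna[.data$mirna]),
      mrna_dir = unname(dirs$mrna[.data$mrna])
    ) |>
    dplyr::select("lncrna", "mirna", "mrna", "r_mi_lnc", "r_mi_m",
                  "r_lnc_m", "mrna_sources", "lncrna_sources",
                  "lncrna_dir", "mirna_dir", "mrna_dir") |>
    dplyr::arrange(.data$lncrna, .data$mirna, .data$mrna)
}

network_from_parts <- function(nodes, edges, triples = NULL) {
  edges <- dplyr::distinct(edges[, c("from", "to", "kind")]) |>
    dplyr::arrange(.data$from, .data$to)
  deg <- dplyr::count(
    tibble::tibble(id = c(edges$from, edges$to)), .data$id, name = "degree")
  nodes <- dplyr::distinct(nodes[, c("id", "type", "direction")]) |>
    dplyr::left_join(deg, by = "id") |>
    dplyr::mutate(degree = dplyr::coalesce(.data$degree, 0L)) |>
    dplyr::arrange(.data$type, .data$id)
  structure(list(nodes = nodes, edges = edges, triples = triples),
            class = "cerna_network")
}

#' Build the tripartite ceRNA network from a triple table
#'
#' Nodes are the union of triple members (typed lncRNA/miRNA/mRNA with their
#' DE direction); undirected edges are the miRNA-lncRNA and miRNA-mRNA
#' couplings of the triples, de-duplicated so an edge shared by many triples
#' counts once. Degree is the number of distinct incident edges. The network
#' is bipartite by construction: no lncRNA-mRNA or within-class edges exist.
#'
#' @param triples Tibble from [assemble_triples()] (direction columns
#'   optional).
#' @return A `cerna_network`: list with `nodes` (id, type, direction,
#'   degree), `edges` (from = miRNA, to = partner, kind) and the originating
#'   `triples`.
#' @export
build_network <- function(triples) {
  get_dir <- function(col) {
    if (col %in% names(triples)) triples[[col]] else {
      rep(NA_character_, nrow(triples))
    }
  }
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = triples$lncrna, type = "lncRNA",
                   direction = get_dir("lncrna_dir")),
    tibble::tibble(id = triples$mirna, type = "miRNA",
                   direction = get_dir("mirna_dir")),
    tibble::tibble(id = triples$mrna, type = "mRNA",
                   direction = get_dir("mrna_dir"))
  )
  edges <- dplyr::bind_rows(
    tibble::tibble(from = triples$mirna, to = triples$lncrna,
                   kind = "miRNA-lncRNA"),
    tibble::tibble(from = triples$mirna, to = triples$mrna,
                   kind = "miRNA-mRNA")
  )
  network_from_parts(nodes, edges, triples = triples)
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- glance(x)
  cat(sprintf(
    "<cerna_network> %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
    s$n_nodes, s$n_lncrna, s$n_mirna, s$n_mrna, s$n_edges))
  invisible(x)
}

#' @describeIn build_network Node table with degrees, one row per node.
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @method tidy cerna_network
#' @export
tidy.cerna_network <- function(x, ...) x$nodes

#' @describeIn build_network One-row summary: node counts by type, edge
#'   count, triple count and triple-membership count (each triple contributes
#'   two memberships; reported alongside the de-duplicated edge count because
#'   an "interaction" total can be read either way).
#' @method glance cerna_network
#' @export
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_lncrna = sum(x$nodes$type == "lncRNA"),
    n_mirna = sum(x$nodes$type == "miRNA"),
    n_mrna = sum(x$nodes$type == "mRNA"),
    n_edges = nrow(x$edges),
    n_triples = if (is.null(x$triples)) NA_integer_ else nrow(x$triples),
    triple_memberships = if (is.null(x$triples)) NA_integer_ else {
      2L * nrow(x$triples)
    }
  )
}

#' Hub nodes of a ceRNA network
#'
#' Nodes whose degree is at least `hub_min_degree` (default 6, implementing
#' the strict "degree > 5" rule: a degree-6 star is a hub, a degree-5 star
#' is not), sorted by degree descending then id.
#'
#' @param network A `cerna_network`.
#' @param config A [pipeline_config()].
#' @return Tibble: `hub`, `type`, `degree`, `direction`.
#' @export
find_hubs <- function(network, config = pipeline_config()) {
  stopifnot(inherits(network, "cerna_network"),
            inherits(config, "pipeline_config"))
  network$nodes |>
    dplyr::filter(.data$degree >= config$hub_min_degree) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id) |>
    dplyr::transmute(hub = .data$id, type = .data$type,
                     degree = .data$degree, direction = .data$direction)
}

#' Intersect two ceRNA networks
#'
#' Reports the nodes shared by two subtype networks (matched by id and type,
#' with each network's DE direction and a concordance flag), the shared
#' edges, and the induced shared subnetwork. Commutative and idempotent on
#' node/edge sets. `normalize_ids` strips transcript suffixes (`-NNN`)
#' before matching, for gene-level comparison of id styles that mix
#' transcript-level and gene-level symbols.
#'
#' @param net_a,net_b `cerna_network` objects.
#' @param normalize_ids Strip `-<digits>` id suffixes before matching.
#' @return A `cerna_intersection`: list with `nodes` (id, type,
#'   direction_a, direction_b, concordant), `edges` (from, to, kind) and
#'   `network` (the induced shared subnetwork).
#' @export
intersect_networks <- function(net_a, net_b, normalize_ids = FALSE) {
  stopifnot(inherits(net_a, "cerna_network"),
            inherits(net_b, "cerna_network"))
  norm <- function(x) if (normalize_ids) sub("-\\d+$", "", x) else x
  prep <- function(net) {
    nodes <- net$nodes |>
      dplyr::mutate(id = norm(.data$id)) |>
      dplyr::distinct(.data$id, .data$type, .keep_all = TRUE)
    edges <- net$edges |>
      dplyr::mutate(from = norm(.data$from), to = norm(.data$to)) |>
      dplyr::distinct()
    list(nodes = nodes, edges = edges)
  }
  a <- prep(net_a)
  b <- prep(net_b)
  nodes <- dplyr::inner_join(
    a$nodes[, c("id", "type", "direction")],
    b$nodes[, c("id", "type", "direction")],
    by = c("id", "type"), suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(concordant = .data$direction_a == .data$direction_b) |>
    dplyr::arrange(.data$type, .data$id)
  edges <- dplyr::inner_join(a$edges, b$edges,
                             by = c("from", "to", "kind")) |>
    dplyr::arrange(.data$from, .data$to)
  sub_nodes <- nodes |>
    dplyr::filter(.data$id %in% c(edges$from, edges$to)) |>
    dplyr::transmute(id = .data$id, type = .data$type,
                     direction = ifelse(.data$concordant,
                                        .data$direction_a, NA_character_))
  structure(list(nodes = nodes, edges = edges,
                 network = network_from_parts(sub_nodes, edges)),
            class = "cerna_intersection")
}

#' @export
print.cerna_intersection <- function(x, ...) {
  cat(sprintf("<cerna_intersection> %d shared nodes, %d shared edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
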