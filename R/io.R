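#' Read an FPKM expression table with its group map
#'
#' Reads a tab-separated matrix (first column feature ids, header row of
#' sample ids, FPKM values) together with a two-column group map
#' (sample, group). Input is validated, not coerced: duplicate ids, negative
#' or missing values, and samples without a group label are errors naming the
#' offender.
#'
#' @param path Expression TSV.
#' @param group_map_path Two-column TSV (`sample`, `group`) labelling every
#'   sample as `"case"` or `"control"`.
#' @return A list with `expression` (wide tibble) and `groups`.
#' @export
read_expression <- function(path, group_map_path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  names(expr)[1] <- "feature"
  expr$feature <- as.character(expr$feature)
  groups <- readr::read_tsv(group_map_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  names(groups)[1:2] <- c("sample", "group")
  validate_expression(expr, groups)
  list(expression = tibble::as_tibble(expr), groups = tibble::as_tibble(groups))
}

#' Write an expression table and group map as TSV
#'
#' @param expr Wide expression tibble.
#' @param groups Sample/group tibble.
#' @param path Expression TSV path.
#' @param group_map_path Group-map TSV path (default `<path>.groups.tsv`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, groups, path,
                             group_map_path = paste0(path, ".groups.tsv")) {
  validate_expression(expr, groups)
  readr::write_tsv(expr, path)
  readr::write_tsv(groups, group_map_path)
  invisible(path)
}

grange_to_ann <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- if (!is.null(gr$Name)) {
    as.character(gr$Name)
  } else if (!is.null(gr$name)) {
    as.character(gr$name)
  } else if (!is.null(gr$ID)) {
    as.character(gr$ID)
  } else {
    rlang::abort("annotation records carry no feature name",
                 class = "cernet_format_error")
  }
  tibble::tibble(
    feature = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = strand
  )
}

#' Read genomic feature annotation (BED or GFF3)
#'
#' BED is 0-based half-open and is stored verbatim; GFF3 is 1-based closed
#' and is converted at the boundary (`start - 1`, `end`). The dialect is
#' chosen by the file extension (`.bed` vs `.gff3`/`.gff`). Intervals that
#' are empty after conversion are rejected.
#'
#' @param path Annotation file ending in `.bed`, `.gff3` or `.gff`.
#' @return Annotation tibble: `feature`, `chrom`, `start`, `end` (0-based
#'   half-open, `start < end`), `strand` (`+`, `-` or `.`).
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("bed", "gff3", "gff")) {
    rlang::abort("annotation path must end in .bed, .gff3 or .gff",
                 class = "cernet_format_error")
  }
  gr <- rtracklayer::import(path)
  ann <- grange_to_ann(gr)
  bad <- ann$feature[ann$start >= ann$end]
  if (length(bad) > 0) {
    rlang::abort(paste0("empty interval (start >= end) for feature(s): ",
                        paste(bad, collapse = ", ")),
                 class = "cernet_validation_error")
  }
  if (any(!nzchar(ann$chrom))) {
    rlang::abort("empty chromosome name in annotation",
                 class = "cernet_validation_error")
  }
  ann
}

#' Write genomic feature annotation (BED or GFF3)
#'
#' The inverse of [read_annotation()]: internal 0-based half-open intervals
#' are emitted verbatim as BED or converted to 1-based closed GFF3, so
#' read-back is an identity map.
#'
#' @param ann Annotation tibble (`feature`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output path ending in `.bed`, `.gff3` or `.gff`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("bed", "gff3", "gff")) {
    rlang::abort("annotation path must end in .bed, .gff3 or .gff",
                 class = "cernet_format_error")
  }
  if (any(ann$start >= ann$end)) {
    rlang::abort("annotation contains empty intervals (start >= end)",
                 class = "cernet_validation_error")
  }
  strand <- ifelse(ann$strand %in% c("+", "-"), ann$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = strand
  )
  if (ext == "bed") {
    gr$name <- ann$feature
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$source <- "cernet"
    gr$type <- "gene"
    gr$ID <- ann$feature
    gr$Name <- ann$feature
    rtracklayer::export(gr, path, format = "GFF3")
  }
  invisible(path)
}

#' Read a survival table
#'
#' @param path TSV with columns `sample`, `time` (positive), `event` (0/1).
#' @return Validated survival tibble.
#' @export
read_survival <- function(path) {
  surv <- readr::read_tsv(path, show_col_types = FALSE)
  names(surv)[1:3] <- c("sample", "time", "event")
  validate_survival(surv)
  tibble::as_tibble(surv)
}

validate_survival <- function(surv) {
  if (!is.data.frame(surv) ||
      !all(c("sample", "time", "event") %in% names(surv))) {
    rlang::abort("survival table needs columns sample, time, event",
                 class = "cernet_format_error")
  }
  if (anyDuplicated(surv$sample)) {
    rlang::abort("duplicated sample id(s) in survival table",
                 class = "cernet_format_error")
  }
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    bad <- surv$sample[!is.finite(surv$time) | surv$time <= 0][1]
    rlang::abort(paste0("non-positive survival time for sample ", bad),
                 class = "cernet_validation_error")
  }
  if (!all(surv$event %in% c(0, 1))) {
    bad <- surv$sample[!surv$event %in% c(0, 1)][1]
    rlang::abort(paste0("event indicator must be 0/1; offending sample: ", bad),
                 class = "cernet_validation_error")
  }
  invisible(surv)
}

#' Read a miRNA-target evidence table
#'
#' @param path TSV with columns `mirna`, `target`, `target_class`
#'   (`"mRNA"`/`"lncRNA"`), `source`.
#' @return Evidence tibble.
#' @export
read_evidence <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  names(ev)[1:4] <- c("mirna", "target", "target_class", "source")
  bad <- setdiff(unique(ev$target_class), c("mRNA", "lncRNA"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown target_class value(s): ",
                        paste(bad, collapse = ", ")),
                 class = "cernet_validation_error")
  }
  tibble::as_tibble(ev)
}

#' Write a ceRNA network to disk
#'
#' Supported formats: `"edgelist"` (TSV with from/to/kind plus a node-table
#' TSV alongside), `"sif"` (simple interaction format, one line per edge with
#' the edge kind as the interaction type), and `"graphml"` (via igraph, with
#' node `type` and edge `kind` attributes). All three round-trip through
#' [read_network()] with identical node and edge sets.
#'
#' @param network A `cerna_network` from [build_network()].
#' @param path Output path.
#' @param format One of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path,
                          format = c("edgelist", "sif", "graphml")) {
  stopifnot(inherits(network, "cerna_network"))
  format <- rlang::arg_match(format)
  nodes <- network$nodes
  edges <- network$edges
  if (format == "edgelist") {
    readr::write_tsv(edges, path)
    readr::write_tsv(nodes[, c("id", "type", "direction")],
                     paste0(path, ".nodes.tsv"))
  } else if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$from, edges$kind, edges$to)
    isolated <- setdiff(nodes$id, c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("from", "to", "kind")], directed = FALSE,
      vertices = data.frame(name = nodes$id, type = nodes$type,
                            direction = ifelse(is.na(nodes$direction), "",
                                               nodes$direction))
    )
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network written by [write_network()]
#'
#' @param path Network file.
#' @param format One of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return A `cerna_network`.
#' @export
read_network <- function(path, format = c("edgelist", "sif", "graphml")) {
  format <- rlang::arg_match(format)
  if (format == "edgelist") {
    edges <- readr::read_tsv(path, show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  } else if (format == "sif") {
    raw <- readLines(path)
    parts <- strsplit(raw, "\t")
    is_edge <- lengths(parts) == 3
    edges <- tibble::tibble(
      from = purrr::map_chr(parts[is_edge], 1),
      kind = purrr::map_chr(parts[is_edge], 2),
      to = purrr::map_chr(parts[is_edge], 3)
    )[, c("from", "to", "kind")]
    # node types are implied by the typed edge kinds: the `from` end of a
    # miRNA-* edge is the miRNA, the `to` end carries the partner class
    typed <- dplyr::bind_rows(
      tibble::tibble(id = edges$from, type = "miRNA"),
      tibble::tibble(id = edges$to,
                     type = sub("^miRNA-", "", edges$kind))
    )
    extra <- setdiff(purrr::map_chr(parts[!is_edge], 1),
                     c(edges$from, edges$to))
    nodes <- dplyr::bind_rows(
      dplyr::distinct(typed),
      tibble::tibble(id = extra, type = NA_character_)
    )
    nodes$direction <- NA_character_
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- character(0)
    attr_or_na <- function(a) {
      if (is.null(a)) rep(NA_character_, length(nm)) else as.character(a)
    }
    nodes <- tibble::tibble(
      id = nm,
      type = attr_or_na(igraph::V(g)$type),
      direction = dplyr::na_if(attr_or_na(igraph::V(g)$direction), "")
    )
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(from = el$from, to = el$to, kind = el$kind)
    # the graph is undirected: restore the miRNA -> partner orientation
    flip <- nodes$type[match(edges$to, nodes$id)] %in% "miRNA"
    tmp <- edges$from[flip]
    edges$from[flip] <- edges$to[flip]
    edges$to[flip] <- tmp
  }
  network_from_parts(nodes, edges)
}

#' Read a survival-axis table
#'
#' Parses the tabular form in which survival-related ceRNA axes are reported:
#' one row per miRNA with comma-separated lncRNA and mRNA partner lists
#' (columns `lncRNA`, `miRNA`, `mRNA` in any order).
#'
#' @param path Axis TSV.
#' @return Tibble with `mirna`, `lncrnas`, `mrnas` (comma-joined partner
#'   lists) and list-columns `lncrna_ids`, `mrna_ids`.
#' @export
read_axes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  nm <- tolower(names(tab))
  need <- c("lncrna", "mirna", "mrna")
  if (!all(need %in% nm)) {
    rlang::abort("axis table needs columns lncRNA, miRNA, mRNA",
                 class = "cernet_format_error")
  }
  names(tab) <- nm
  split_ids <- function(x) {
    purrr::map(x, ~ sort(unique(trimws(strsplit(.x, ",")[[1]]))))
  }
  tibble::tibble(
    mirna = tab$mirna,
    lncrna_ids = split_ids(tab$lncrna),
    mrna_ids = split_ids(tab$mrna)
  ) |>
    dplyr::mutate(
      lncrnas = purrr::map_chr(.data$lncrna_ids, paste, collapse = ","),
      mrnas = purrr::map_chr(.data$mrna_ids, paste, collapse = ",")
    )
}
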