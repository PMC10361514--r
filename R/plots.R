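#' Volcano plot of a differential-expression table
#'
#' log2 fold change against -log10 raw p, with the strict screening
#' thresholds drawn as dashed guides and passing features coloured by
#' direction.
#'
#' @param de DE tibble from [run_de()].
#' @param config A [pipeline_config()] (for the guide lines).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, config = pipeline_config()) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(config$p_max),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-log2(config$fc_min),
                                       log2(config$fc_min)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 raw p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn build_network Force-directed sketch of the tripartite
#'   network, nodes coloured by RNA class and sized by degree.
#' @param object A `cerna_network`.
#' @method autoplot cerna_network
#' @export
autoplot.cerna_network <- function(object, ...) {
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = object$nodes$id)
  # fixed layout stream; leaves the caller's RNG state untouched
  xy <- with_stream(1L, 0L, igraph::layout_with_fr(g))
  pos <- tibble::tibble(id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2]) |>
    dplyr::left_join(object$nodes, by = "id")
  seg <- object$edges |>
    dplyr::left_join(pos[, c("id", "x", "y")], by = c("from" = "id")) |>
    dplyr::left_join(pos[, c("id", "x", "y")], by = c("to" = "id"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type,
                   size = .data$degree)) +
    ggplot2::scale_size_continuous(range = c(1.5, 6)) +
    ggplot2::labs(colour = NULL, size = "degree") +
    ggplot2::theme_void()
}

#' Kaplan-Meier curves for a median-dichotomized expression profile
#'
#' The visual companion of [km_logrank()]: step curves for the high- and
#' low-expression groups defined by the median split.
#'
#' @param surv Survival tibble (`sample`, `time`, `event`).
#' @param values Named expression vector (names are sample ids).
#' @return A ggplot object.
#' @export
plot_km <- function(surv, values) {
  validate_survival(surv)
  common <- intersect(surv$sample, names(values))
  surv <- surv[surv$sample %in% common, ]
  v <- values[surv$sample]
  grp <- factor(ifelse(v > stats::median(v), "high", "low"),
                levels = c("low", "high"))
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ grp)
  strata <- rep(names(fit$strata), fit$strata)
  steps <- tibble::tibble(
    time = fit$time, surv = fit$surv,
    group = sub("^grp=", "", strata)
  ) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(steps, ggplot2::aes(x = .data$time, y = .data$surv,
                                      colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "expression") +
    ggplot2::theme_minimal()
}
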