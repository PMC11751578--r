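# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.lddt_result <- function(x, ...) x$per_residue

#' @export
glance.lddt_result <- function(x, ...) {
  tibble::tibble(lddt_global = x$global, n_pairs = x$n_pairs,
                 n_residues = nrow(x$per_residue))
}

#' @export
tidy.struct_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.struct_eval <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.probe_report <- function(x, ...) {
  id <- c("target", "perturbation", "stage", "status", "message")
  tidyr::pivot_longer(tibble::as_tibble(x), -dplyr::all_of(id),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.probe_report <- function(x, ...) summarize_experiment(x)

#' Per-residue lDDT profile plot
#'
#' @param object an `lddt_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lddt_result <- function(object, ...) {
  df <- object$per_residue
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_idx, y = .data$lddt)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = object$global, linetype = "dashed") +
    ggplot2::facet_wrap(~chain, scales = "free_x") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "residue index", y = "per-residue lDDT",
                  title = sprintf("lDDT profile (global %.3f)", object$global)) +
    ggplot2::theme_minimal()
}

#' Experiment report overview plot
#'
#' Mean and standard deviation of the headline metrics per perturbation
#' and stage.
#'
#' @param object a `probe_report`.
#' @param metrics metric columns to show.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.probe_report <- function(object,
                                  metrics = c("tm", "lddt_global",
                                              "alpha_rmsd"), ...) {
  agg <- summarize_experiment(object)
  agg <- agg[agg$metric %in% metrics, , drop = FALSE]
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$perturbation, y = .data$mean,
                                    color = .data$stage)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean +/- sd") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
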