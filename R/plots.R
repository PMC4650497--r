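# ggplot2 views of the main result types.

#' @describeIn fit_pca Score plot of the first two components, coloured by
#'   time of measurement when available.
#' @param object A fitted object.
#' @export
autoplot.latent_model <- function(object, ...) {
  sc <- object$scores
  if (!all(c("comp1", "comp2") %in% names(sc))) {
    abort("At least two components are needed for a score plot.")
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$comp1, y = .data$comp2))
  if ("time" %in% names(sc)) {
    p <- p + ggplot2::aes(colour = factor(.data$time)) +
      ggplot2::labs(colour = "time (h)")
  }
  p + ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = "component 1", y = "component 2",
      title = sprintf("%s scores", object$method)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn hac_ward Mean kinetic profile per cluster (each gene
#'   translated to 0 at baseline), with one grey line per gene.
#' @param object A fitted object.
#' @export
autoplot.kinetic_clustering <- function(object, ...) {
  genes <- as_tibble(object$gene_profiles) %>%
    mutate(gene = object$assignments$gene,
           cluster = object$assignments$cluster) %>%
    tidyr::pivot_longer(cols = -c("gene", "cluster"),
                        names_to = "time", values_to = "value") %>%
    mutate(time = as.numeric(.data$time))
  ggplot2::ggplot(genes, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(
      data = object$profiles,
      ggplot2::aes(y = .data$mean), colour = "red", linewidth = 1
    ) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time after injection (h)",
                  y = "log2 expression (0 at baseline)") +
    ggplot2::theme_minimal()
}

#' Mean kinetics of the clinical variables
#'
#' Mean +/- SEM trajectory per variable over the time course.
#'
#' @param data Long clinical tibble (`animal`, `time`, `variable`, `value`).
#' @return A ggplot object, one facet per variable (free y scales).
#' @export
plot_bio_kinetics <- function(data) {
  summ <- data %>%
    group_by(.data$variable, .data$time) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sem = sd(.data$value, na.rm = TRUE) /
                sqrt(sum(!is.na(.data$value))),
              .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             size = 0.2) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time after injection (h)", y = "mean +/- SEM") +
    ggplot2::theme_minimal()
}
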