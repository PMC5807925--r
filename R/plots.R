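# ggplot2 displays for sweep results and partitions.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col facet_wrap labs scale_x_log10 theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a resolution sweep
#'
#' Three panels against gamma: partition stability (mean `1 - nVI` between
#' runs), mean modularity of the real network versus degree-matched random
#' graphs (ribbon = +/- 1 sd), and the mean community count.
#'
#' @param object A `gamma_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_sweep <- function(object, ...) {
  d <- bind_rows(
    tibble(gamma = object$gamma, panel = "stability (1 - nVI)",
           series = "real", mean = object$stability_mean,
           sd = object$stability_sd),
    tibble(gamma = object$gamma, panel = "modularity", series = "real",
           mean = object$q_real_mean, sd = object$q_real_sd),
    tibble(gamma = object$gamma, panel = "modularity", series = "random",
           mean = object$q_random_mean, sd = object$q_random_sd),
    tibble(gamma = object$gamma, panel = "communities", series = "real",
           mean = object$n_communities_mean, sd = 0))
  ggplot(d, aes(x = .data$gamma, y = .data$mean, colour = .data$series,
                fill = .data$series)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd),
                alpha = 0.25, colour = NA) +
    geom_line() +
    facet_wrap(~ .data$panel, scales = "free_y", ncol = 1) +
    labs(x = "resolution (gamma)", y = NULL, colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot a p-value threshold sweep
#'
#' Scale-free fit (R^2 and slope), edge count, and mean degree of the
#' intersection network across the p-value ladder.
#'
#' @param object A `threshold_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  d <- bind_rows(
    tibble(threshold = object$threshold, panel = "scale-free R^2",
           value = object$r_squared),
    tibble(threshold = object$threshold, panel = "scale-free slope",
           value = object$slope),
    tibble(threshold = object$threshold, panel = "edges",
           value = as.numeric(object$n_edges)),
    tibble(threshold = object$threshold, panel = "mean degree",
           value = object$mean_degree))
  ggplot(d, aes(x = .data$threshold, y = .data$value)) +
    geom_line() + geom_point() +
    scale_x_log10() +
    facet_wrap(~ .data$panel, scales = "free_y", ncol = 1) +
    labs(x = "edge p-value threshold", y = NULL) +
    theme_minimal()
}

#' Plot community sizes of a partition
#'
#' @param object A `coocc_partition`.
#' @param ... Unused.
#' @return A ggplot of community sizes, largest first.
#' @export
autoplot.coocc_partition <- function(object, ...) {
  d <- count(as_tibble(object), .data$community_id, name = "size")
  ggplot(d, aes(x = factor(.data$community_id), y = .data$size)) +
    geom_col() +
    labs(x = "community", y = "OTUs") +
    theme_minimal()
}
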