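#' Plot the permutation null of a cluster test
#'
#' Histogram of the maximal-cluster-mass null distribution with the observed
#' cluster masses overlaid as vertical lines.
#'
#' @param result a `cluster_test`.
#' @return A ggplot object.
#' @export
plot_cluster_null <- function(result) {
  df <- data.frame(null_max_mass = result$null_max_mass)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$null_max_mass)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "maximal cluster mass under the null", y = "shuffles") +
    ggplot2::theme_minimal()
  if (length(result$clusters) > 0) {
    obs <- data.frame(mass = vapply(result$clusters, `[[`, numeric(1), "mass"))
    p <- p + ggplot2::geom_vline(data = obs,
                                 ggplot2::aes(xintercept = .data$mass),
                                 colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot the seed-by-network connectivity profile
#'
#' Cell means with standard-error bars, split by network and network
#' hemisphere, coloured by seed hemisphere — the bar-plot rendering of the
#' connectivity spider plot.
#'
#' @param table a profile table from [build_profile_table()].
#' @return A ggplot object.
#' @export
plot_connectivity_profile <- function(table) {
  tab <- as.data.frame(table)
  agg <- stats::aggregate(mean_connectivity ~ seed_hemisphere + network +
                            network_hemisphere, data = tab,
                          FUN = function(v) c(mean = mean(v),
                                              sem = stats::sd(v) / sqrt(length(v))))
  agg <- cbind(agg[, 1:3], as.data.frame(agg$mean_connectivity))
  ggplot2::ggplot(agg, ggplot2::aes(x = interaction(.data$network,
                                                    .data$network_hemisphere),
                                    y = .data$mean, fill = .data$seed_hemisphere)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.2) +
    ggplot2::labs(x = "network x network hemisphere",
                  y = "mean connectivity (Pearson r)", fill = "seed") +
    ggplot2::theme_minimal()
}
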