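#' Plot a haplotype frequency profile
#'
#' Bars show the averaged frequency of each retained haplotype; points show
#' the individual subsample replicates; the dashed line marks the retention
#' threshold.
#'
#' @param object A `haplotype_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.haplotype_profile <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$haplotype_id)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_frequency),
                      data = dplyr::distinct(td, .data$haplotype_id,
                                             .data$mean_frequency),
                      fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$frequency), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "haplotype", y = "frequency",
                  title = object$sample_id,
                  subtitle = sprintf("%d subsamples; background %.4f",
                                     object$n_subsamples,
                                     object$background_mean)) +
    ggplot2::theme_minimal()
}

#' Plot within/between group mean p-distances
#'
#' @param object A `distance_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.distance_summary <- function(object, ...) {
  td <- tidy(object)
  td <- td[!is.na(td$mean_p), , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$comparison, y = .data$mean_p)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "mean p-distance") +
    ggplot2::theme_minimal()
}
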