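#' Plot a read-length distribution
#'
#' Bar chart of the abundance-weighted size distribution; the bimodal
#' 21/24-nt structure of plant sRNA populations shows as twin peaks.
#'
#' @param dist Output of [srna_size_distribution()] (with or without
#'   `by_library`).
#' @return A ggplot object.
#' @export
plot_size_distribution <- function(dist) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = factor(length), y = pct))
  if ("library" %in% names(dist)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = library),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "grey30")
  }
  p + ggplot2::labs(x = "read length (nt)", y = "% of reads") +
    ggplot2::theme_minimal()
}

#' Plot a positional decile profile
#'
#' @param profile Output of [decile_profile()] or [te_decile_profiles()];
#'   multiple elements are faceted.
#' @return A ggplot object.
#' @export
plot_decile_profile <- function(profile) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = factor(bin), y = total)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "element fraction (5' to 3')",
                  y = "sRNA counts") +
    ggplot2::theme_minimal()
  if (length(unique(profile$element_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(~element_id, scales = "free_y")
  }
  p
}

#' Plot per-superfamily sRNA counts or densities
#'
#' Box plots of per-element totals (or densities) by TE superfamily.
#'
#' @param profiles Output of [profile_features()] (TE rows are kept).
#' @param y Column to plot: `"total_count"` or `"density"`.
#' @return A ggplot object.
#' @export
plot_superfamily_counts <- function(profiles, y = c("total_count",
                                                    "density")) {
  y <- match.arg(y)
  dat <- profiles[!is.na(profiles$superfamily), , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = superfamily, y = .data[[y]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL,
                  y = if (y == "density") "sRNA counts / bp"
                      else "sRNA counts") +
    ggplot2::theme_minimal()
}
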