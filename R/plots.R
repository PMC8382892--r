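#' Plot observed isolation by distance
#'
#' FST against distance per pair class with OLS lines, mirroring the
#' standard mine/coast IBD figure.
#'
#' @param ibd Output of [observed_ibd()] (or a tibble with columns
#'   `km` (or `distance`), `fst`, `class`).
#' @return A ggplot.
#' @export
plot_ibd <- function(ibd) {
  pairs <- if (is.list(ibd) && !is.data.frame(ibd)) ibd$pairs else ibd
  xcol <- if ("km" %in% names(pairs)) "km" else "distance"
  ggplot2::ggplot(pairs,
                  ggplot2::aes(.data[[xcol]], .data$fst,
                               colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c("mine-mine" = "darkorange",
                                            "coast-coast" = "steelblue",
                                            "mine-coast" = "darkgreen")) +
    ggplot2::labs(x = if (xcol == "km") "distance (km)" else "distance",
                  y = expression(F[ST]), colour = "pair class")
}

#' @export
autoplot.scenario_contrast <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fits,
                              cols = dplyr::starts_with("slope_"),
                              names_to = "class", names_prefix = "slope_",
                              values_to = "slope")
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$slope,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_fill_manual(values = c("mine-mine" = "darkorange",
                                          "coast-coast" = "steelblue")) +
    ggplot2::labs(x = NULL, y = "IBD slope per replicate",
                  title = paste(object$scenario, collapse = "/")) +
    ggplot2::guides(fill = "none")
}

#' @export
autoplot.quartet_tests <- function(object, tested_only = FALSE, ...) {
  df <- as_tibble(object)
  if (tested_only) df <- df[df$tested, ]
  thr <- attr(object, "z_threshold")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$type), abs(.data$z))) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = thr, colour = "red") +
    ggplot2::labs(x = "quartet type", y = "|z|",
                  subtitle = sprintf("Dunn-Bonferroni threshold %.2f",
                                     thr))
}

#' Upset-style intersection bars for an outlier scan
#'
#' Exclusive (upset) counts per comparison subset, shaded by the exact
#' multi-set intersection p-value for subsets of size >= 2.
#'
#' @param scan An [scan_all_pairs()] result.
#' @param level `"scaffold"` or `"snp"`.
#' @return A ggplot.
#' @export
plot_intersections <- function(scan, level = c("scaffold", "snp")) {
  level <- match.arg(level)
  tab <- tidy(scan, level = level)
  tab$subset <- factor(tab$subset,
                       levels = tab$subset[order(-tab$degree,
                                                 -tab$exclusive)])
  ggplot2::ggplot(tab, ggplot2::aes(.data$subset, .data$exclusive,
                                    fill = log10(pmax(.data$p, 1e-300)))) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_viridis_c(name = "log10 p", direction = -1) +
    ggplot2::labs(x = NULL, y = "exclusive intersection size") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
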