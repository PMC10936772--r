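#' Plot standardized effect sizes of the external-filtering test
#'
#' One panel per trait, stages side by side: solid points are the
#' per-population SES values (starred when either one-sided test is
#' significant), the crossed circle and segment are the mean and sd of
#' the SES values, and the shaded box is the null envelope (the
#' alpha and 1-alpha null quantiles expressed on the SES scale).
#'
#' @param object A `tstat_results` from [run_tstats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tstat_results <- function(object, ...) {
  ts <- object$tstats
  ms <- object$mean_ses
  ts$ses_env_low <- (ts$null_q_low - ts$null_mean) / ts$null_sd
  ts$ses_env_high <- (ts$null_q_high - ts$null_mean) / ts$null_sd
  ts$label <- ifelse(ts$significant_low | ts$significant_high, "*", "")
  env <- dplyr::summarise(
    dplyr::group_by(ts, .data$acronym, .data$stage),
    lo = min(.data$ses_env_low), hi = max(.data$ses_env_high),
    .groups = "drop")
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$stage, y = .data$ses)) +
    ggplot2::geom_rect(data = env,
                       ggplot2::aes(x = NULL, y = NULL,
                                    xmin = as.numeric(factor(.data$stage)) - 0.35,
                                    xmax = as.numeric(factor(.data$stage)) + 0.35,
                                    ymin = .data$lo, ymax = .data$hi),
                       fill = "grey85", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$population), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label,
                                    colour = .data$population),
                       nudge_x = 0.12, size = 5, show.legend = FALSE) +
    ggplot2::geom_pointrange(
      data = ms,
      ggplot2::aes(y = .data$mean_ses,
                   ymin = .data$mean_ses - .data$sd_ses,
                   ymax = .data$mean_ses + .data$sd_ses),
      shape = 13, size = 0.4) +
    ggplot2::facet_wrap(~acronym) +
    ggplot2::labs(x = "ontogenetic stage",
                  y = "standardized effect size of T_IP.IR",
                  colour = "population") +
    ggplot2::theme_minimal()
}

#' PCA biplot
#'
#' Scores of the first two components with loading arrows overlaid,
#' optionally coloured by a grouping vector (e.g. population).
#'
#' @param object A `trait_pca` from [run_pca()].
#' @param groups Optional grouping vector aligned with the score rows.
#' @param arrow_scale Multiplier for the loading arrows (default: scaled
#'   to the score range).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trait_pca <- function(object, groups = NULL, arrow_scale = NULL,
                               ...) {
  if (object$n_components < 2) {
    stop("biplot needs at least 2 components", call. = FALSE)
  }
  sc <- tibble::as_tibble(object$scores[, 1:2, drop = FALSE])
  names(sc) <- c("PC1", "PC2")
  if (!is.null(groups)) sc$group <- groups
  ld <- tibble::as_tibble(object$loadings[, 1:2, drop = FALSE],
                          rownames = "variable")
  names(ld) <- c("variable", "PC1", "PC2")
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(as.matrix(sc[, c("PC1", "PC2")]))) /
      max(abs(as.matrix(ld[, c("PC1", "PC2")])))
  }
  lab <- sprintf("PC%d (%.1f%%)", 1:2, 100 * object$explained[1:2])
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group,
                                         shape = .data$group), alpha = 0.8)
  }
  p +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.02, "npc")),
      colour = "grey30") +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.08,
                   y = .data$PC2 * arrow_scale * 1.08,
                   label = .data$variable),
      colour = "grey20", size = 3.2) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
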