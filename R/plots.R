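treatment_fill <- function() {
  ggplot2::scale_fill_manual(
    values = c(`TRUE` = "#5B9BD5", `FALSE` = "#ED9B5B"),
    labels = c(`TRUE` = "delegation", `FALSE` = "no-delegation"),
    name = NULL
  )
}

#' Box plots of final public accounts per treatment
#'
#' Public-account distributions by number of choices and delegation
#' condition, one panel per game, with the collective threshold as a dashed
#' reference line and cell means marked with a cross.
#'
#' @param gm Output of [group_metrics()].
#' @param threshold Collective target to mark.
#' @return A ggplot object.
#' @export
plot_public_accounts <- function(gm, threshold = 80) {
  ggplot2::ggplot(gm, ggplot2::aes(
    x = factor(.data$treatment_choices),
    y = .data$final_public_account,
    fill = .data$treatment_delegation
  )) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::stat_summary(
      fun = mean, geom = "point", shape = 4, size = 3, colour = "white",
      position = ggplot2::position_dodge(0.8)
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~game, labeller = ggplot2::label_both) +
    treatment_fill() +
    ggplot2::labs(x = "number of choices", y = "public account (ECoins)") +
    ggplot2::theme_minimal()
}

#' Group success rates per treatment
#'
#' @inheritParams plot_public_accounts
#' @return A ggplot object.
#' @export
plot_success_rates <- function(gm) {
  rates <- gm |>
    dplyr::group_by(.data$game, .data$treatment_choices,
                    .data$treatment_delegation) |>
    dplyr::summarise(success_rate = mean(.data$success), .groups = "drop")
  ggplot2::ggplot(rates, ggplot2::aes(
    x = factor(.data$treatment_choices), y = .data$success_rate,
    fill = .data$treatment_delegation
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::facet_wrap(~game, labeller = ggplot2::label_both) +
    treatment_fill() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "number of choices", y = "fraction of successful groups") +
    ggplot2::theme_minimal()
}

#' Within-group private-account variance per treatment
#'
#' The in-group inequality measure: box plots of the variance of members'
#' final private accounts, per treatment cell and game.
#'
#' @inheritParams plot_public_accounts
#' @return A ggplot object.
#' @export
plot_private_variance <- function(gm) {
  ggplot2::ggplot(gm, ggplot2::aes(
    x = factor(.data$treatment_choices),
    y = .data$private_account_variance,
    fill = .data$treatment_delegation
  )) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(0.8)) +
    ggplot2::facet_wrap(~game, labeller = ggplot2::label_both) +
    treatment_fill() +
    ggplot2::labs(
      x = "number of choices",
      y = "within-group variance of private accounts"
    ) +
    ggplot2::theme_minimal()
}

#' Centroid trajectories of a behavior clustering
#'
#' Average contribution per round for each behavioral cluster, the
#' round-by-round view of the identified profiles.
#'
#' @param object A [cluster_actions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.crd_clusters <- function(object, ...) {
  centers <- as.data.frame(object$centers)
  names(centers) <- seq_len(ncol(centers))
  centers$behavior <- object$labels
  long <- tidyr::pivot_longer(centers, -"behavior",
                              names_to = "round", values_to = "mean_action")
  long$round <- as.integer(long$round)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$round, y = .data$mean_action,
    colour = .data$behavior, group = .data$behavior
  )) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 2, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "round", y = "average contribution (ECoins)",
                  colour = "profile") +
    ggplot2::theme_minimal()
}
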