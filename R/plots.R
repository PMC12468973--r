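# ggplot2 displays for training traces and selection results.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col labs
#'   facet_wrap theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Training curves of a policy
#'
#' Cumulative reward and episode accuracy per training episode, the
#' standard view of an episodic agent's learning progress.
#'
#' @param object A `dqn_policy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dqn_policy <- function(object, ...) {
  df <- object$episode_log |>
    tidyr::pivot_longer(c("reward", "accuracy"), names_to = "quantity")
  ggplot(df, aes(x = .data$episode, y = .data$value)) +
    geom_line(colour = "#2c7fb8") +
    facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    labs(x = "episode", y = NULL,
         title = paste("Training progress:", object$config$variant)) +
    theme_minimal()
}

#' Optimizer convergence curves
#'
#' Best-so-far wrapper fitness per iteration for each metaheuristic in a
#' selection report; nonincreasing by elitism.
#'
#' @param report A `selection_report` from [select_features()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(report) {
  df <- purrr::imap_dfr(report$traces, function(tr, alg) {
    tibble(algorithm = alg, iteration = seq_along(tr), fitness = tr)
  })
  ggplot(df, aes(x = .data$iteration, y = .data$fitness,
                 colour = .data$algorithm)) +
    geom_line() +
    labs(x = "iteration", y = "1 - CV accuracy",
         title = "Metaheuristic convergence") +
    theme_minimal()
}

#' Shapley importance bar plot
#'
#' @param report A `selection_report`.
#' @param top_n Number of top-ranked features to show. Default 20.
#' @return A ggplot object.
#' @export
plot_importances <- function(report, top_n = 20) {
  df <- report$importances |>
    arrange(.data$rank) |>
    head(top_n) |>
    mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot(df, aes(x = .data$importance, y = .data$feature)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = "mean |Shapley value|", y = NULL,
         title = "Top feature importances") +
    theme_minimal()
}
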