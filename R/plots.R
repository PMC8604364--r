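# Figure panels mirroring the standard RM-ASCA+ presentation: scree,
# per-component score trajectories by group, loading bars — each with
# optional bootstrap whiskers — and augmented-score spaghetti plots.

#' Scree plot of explained variance fractions
#' @param dec an `sca_decomposition`.
#' @return A ggplot object.
#' @export
plot_scree <- function(dec) {
  df <- tibble::tibble(component = names(dec$explained_fraction),
                       explained = 100 * dec$explained_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "explained variance (%)") +
    ggplot2::theme_minimal()
}

#' Score trajectories by group over time
#'
#' One panel per component; cell scores connected over time within group,
#' with bootstrap percentile whiskers when a [bootstrap_rm_asca()] result
#' is supplied.
#'
#' @param dec an `sca_decomposition`.
#' @param boot optional `bootstrap_result` for CI whiskers.
#' @return A ggplot object.
#' @export
plot_scores <- function(dec, boot = NULL) {
  cells <- scores_by_cell(dec)
  comp <- colnames(dec$loadings)
  long <- do.call(rbind, lapply(comp, function(a) {
    tibble::tibble(time = cells$time, group = cells$group,
                   component = a, score = cells[[a]])
  }))
  long$time <- factor(long$time, levels = levels(dec$time))
  if (!is.null(boot)) {
    key <- paste(long$time, long$group, long$component)
    bkey <- paste(boot$score_ci$time, boot$score_ci$group,
                  boot$score_ci$component)
    idx <- match(key, bkey)
    long$lower <- boot$score_ci$lower[idx]
    long$upper <- boot$score_ci$upper[idx]
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$score,
                                          colour = .data$group,
                                          group = .data$group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~component) +
    ggplot2::labs(x = "time", y = "score") +
    ggplot2::theme_minimal()
  if (!is.null(boot)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.1)
  }
  p
}

#' Loading bars per component
#' @param dec an `sca_decomposition`.
#' @param boot optional `bootstrap_result` for CI whiskers.
#' @return A ggplot object.
#' @export
plot_loadings <- function(dec, boot = NULL) {
  long <- loadings_table(dec)
  if (!is.null(boot)) {
    key <- paste(long$variable, long$component)
    bkey <- paste(boot$loading_ci$variable, boot$loading_ci$component)
    idx <- match(key, bkey)
    long$lower <- boot$loading_ci$lower[idx]
    long$upper <- boot$loading_ci$upper[idx]
  }
  long$variable <- factor(long$variable, levels = rownames(dec$loadings))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$variable,
                                          y = .data$loading)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~component) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = "loading") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  if (!is.null(boot)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper), width = 0.3)
  }
  p
}

#' Augmented-score spaghetti plot
#'
#' Per-subject trajectories of augmented scores (fitted effects plus
#' random intercepts, optionally plus residuals) on one component,
#' overlaid on the cell-score trajectories, to judge effect size against
#' between-subject and residual variation.
#'
#' @param dec an `sca_decomposition`.
#' @param fm the `rm_fit` behind it.
#' @param component component name (default `"PC1"`).
#' @param with_residuals also show residual variation (dashed lines).
#' @param max_subjects optional cap on plotted subjects (complete-data
#'   subjects are preferred), to keep the panel readable.
#' @param seed seed for the subject subsample.
#' @return A ggplot object.
#' @export
plot_augmented_scores <- function(dec, fm, component = "PC1",
                                  with_residuals = TRUE,
                                  max_subjects = 30, seed = 1) {
  m <- construct_effect_matrix(fm, dec$source_families)
  m_ru <- augment_effect_matrix(m, fm, with_random = TRUE,
                                with_residuals = FALSE)
  t_ru <- project_augmented(dec, m_ru)
  t_ru$kind <- "fitted + random effects"
  long <- t_ru
  if (with_residuals) {
    m_re <- augment_effect_matrix(m, fm, with_random = TRUE,
                                  with_residuals = TRUE)
    t_re <- project_augmented(dec, m_re)
    t_re$kind <- "+ residuals"
    long <- rbind(t_ru, t_re)
  }
  nrows <- table(long$subject[long$kind == long$kind[1]])
  complete <- names(nrows)[nrows == nlevels(dec$time)]
  pool <- if (length(complete) > 0) complete else unique(long$subject)
  if (length(pool) > max_subjects) {
    set.seed(seed)
    pool <- sample(pool, max_subjects)
  }
  long <- long[long$subject %in% pool, ]
  long$time <- factor(long$time, levels = levels(dec$time))

  cells <- scores_by_cell(dec)
  cells$time <- factor(cells$time, levels = levels(dec$time))

  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data[[component]],
                                     group = interaction(.data$subject,
                                                         .data$kind),
                                     colour = .data$group,
                                     linetype = .data$kind)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_line(data = cells,
                       ggplot2::aes(x = .data$time, y = .data[[component]],
                                    group = .data$group,
                                    colour = .data$group),
                       linewidth = 1.3, inherit.aes = FALSE) +
    ggplot2::labs(x = "time", y = paste(component, "score")) +
    ggplot2::theme_minimal()
}
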