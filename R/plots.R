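#' Abacus plot of visit timings
#'
#' Draws one horizontal line per subject with a marker at every visit time —
#' the standard first look at a longitudinal visit process. A random subset
#' of subjects (default 20) is shown so the plot stays readable; the
#' sampling is seeded and reproducible.
#'
#' @param cohort a [visit_cohort()].
#' @param n_subjects number of subjects to display (capped at the cohort
#'   size; default 20).
#' @param seed integer seed for the subject sampling.
#' @param file optional path; when given the plot is also written there
#'   (format from the extension, e.g. `.png`, `.pdf`).
#' @return the ggplot object, invisibly when `file` is given.
#' @export
abacus_plot <- function(cohort, n_subjects = 20, seed = NULL, file = NULL) {
  stopifnot(inherits(cohort, "visit_cohort"))
  if (nrow(cohort$visits) == 0) stop("cohort has no visits to plot", call. = FALSE)
  ids <- cohort$subjects$id
  n_subjects <- min(n_subjects, length(ids))
  if (!is.null(seed)) set.seed(seed)
  shown <- sort(sample(ids, n_subjects))
  df <- cohort$visits[cohort$visits$id %in% shown, , drop = FALSE]
  df$id <- factor(df$id, levels = rev(shown))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$id), colour = "grey70") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::labs(x = paste0("Time (", cohort$time_unit, ")"), y = "Subject",
                  title = paste0("Visit timings for ", n_subjects,
                                 " randomly sampled subjects")) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Plot mean proportions against bin width
#'
#' Plots the three summary curves of a bin-width sweep — the mean proportions
#' of individuals with 0, 1, and more than 1 visit per bin — against bin
#' width. The curves are drawn from the very numbers held in the sweep table
#' (the same ones [write_table()] exports); nothing is recomputed.
#'
#' @param sweep a `sweep_result`.
#' @param file optional output path, as in [abacus_plot()].
#' @return the ggplot object, invisibly when `file` is given.
#' @export
proportions_plot <- function(sweep, file = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- as.data.frame(unclass(sweep))
  long <- data.frame(
    bin_width = rep(df$bin_width, 3),
    proportion = c(df$mean_p0, df$mean_p1, df$mean_p2plus),
    visits = factor(rep(c("0 visits", "1 visit", "> 1 visits"),
                        each = nrow(df)),
                    levels = c("0 visits", "1 visit", "> 1 visits")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_width,
                                          y = .data$proportion,
                                          colour = .data$visits)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Bin width", y = "Mean proportion of individuals",
                  colour = NULL,
                  title = "Mean proportions of individuals with 0, 1, > 1 visits per bin") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
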