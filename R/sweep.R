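#' Sweep anchored bin widths over a grid of gap fractions
#'
#' Recomputes the mean 0/1/>1-visit proportions while widening the right side
#' of every schedule-anchored bin across a grid of gap fractions, holding the
#' left side fixed (the asymmetric construction used when protocol visits
#' cannot occur early). The default grid runs from 1% to 95% of the gap in 1%
#' steps.
#'
#' @param cohort a [visit_cohort()].
#' @param schedule a [visit_schedule()].
#' @param left_frac fixed left gap fraction (default 0.05).
#' @param right_fracs grid of right gap fractions.
#' @param weight across-bin averaging, see [bin_proportions()].
#' @return A `sweep_result`: data frame with columns `right_frac`,
#'   `bin_width` (mean bin width across the anchored bins), `mean_p0`,
#'   `mean_p1`, `mean_p2plus`, sorted by bin width; attribute `mode =
#'   "schedule"`.
#' @export
sweep_schedule <- function(cohort, schedule, left_frac = 0.05,
                           right_fracs = seq(0.01, 0.95, by = 0.01),
                           weight = c("none", "at_risk")) {
  weight <- match.arg(weight)
  stopifnot(inherits(cohort, "visit_cohort"), inherits(schedule, "visit_schedule"))
  rows <- lapply(right_fracs, function(rf) {
    bins <- tryCatch(schedule_bins(schedule, left_frac, rf),
                     error = function(e) stop("right_frac = ", rf, ": ",
                                              conditionMessage(e), call. = FALSE))
    m <- mean_proportions(bin_proportions(cohort, bins, weight = weight))
    data.frame(right_frac = rf, bin_width = mean(bins$right - bins$left),
               mean_p0 = m["p0"], mean_p1 = m["p1"], mean_p2plus = m["p2plus"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$bin_width), , drop = FALSE]
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "mode") <- "schedule"
  attr(out, "left_frac") <- left_frac
  out
}

#' Sweep uniform bin widths over a grid of bin counts
#'
#' Recomputes the mean 0/1/>1-visit proportions for equal-width bins tiling
#' [0, tau) as the number of bins varies (more bins = narrower bins). The
#' default grid runs from 2 bins up to `max(50, ceiling(tau / g))` where `g`
#' is the cohort's median inter-visit gap, so that bin widths span from half
#' the window down to around a typical visit spacing.
#'
#' @param cohort a [visit_cohort()].
#' @param tau study horizon.
#' @param n_bins_list integer grid of bin counts (all >= 1).
#' @param weight across-bin averaging, see [bin_proportions()].
#' @return A `sweep_result` with columns `n_bins`, `bin_width` (= tau /
#'   n_bins), `mean_p0`, `mean_p1`, `mean_p2plus`, sorted by bin width
#'   ascending; attribute `mode = "uniform"`.
#' @export
sweep_uniform <- function(cohort, tau, n_bins_list = NULL,
                          weight = c("none", "at_risk")) {
  weight <- match.arg(weight)
  stopifnot(inherits(cohort, "visit_cohort"))
  if (is.null(n_bins_list)) {
    gaps <- unlist(tapply(cohort$visits$time, cohort$visits$id, diff,
                          simplify = FALSE), use.names = FALSE)
    g <- if (length(gaps)) stats::median(gaps) else tau
    n_bins_list <- 2:max(50, ceiling(tau / max(g, tau / 200)))
  }
  rows <- lapply(n_bins_list, function(nb) {
    m <- mean_proportions(bin_proportions(cohort, uniform_bins(tau, nb),
                                          weight = weight))
    data.frame(n_bins = nb, bin_width = tau / nb,
               mean_p0 = m["p0"], mean_p1 = m["p1"], mean_p2plus = m["p2plus"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$bin_width), , drop = FALSE]
  class(out) <- c("sweep_result", "data.frame")
  attr(out, "mode") <- "uniform"
  attr(out, "tau") <- tau
  out
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Bin-width sweep (", attr(x, "mode"), " mode), ", nrow(x), " widths\n",
      sep = "")
  print.data.frame(round_df(utils::head(as.data.frame(unclass(x)), 10), 4),
                   row.names = FALSE)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Classify a visit pattern from a bin-width sweep
#'
#' Applies the two-step decision rule: find the bin width maximising the mean
#' proportion of individuals with exactly 1 visit per bin (ties broken toward
#' the smallest width), then inspect the other two proportions there. A
#' nonzero proportion with >1 visit indicates irregularity; if that is
#' (near) zero but the 0-visit proportion is not, the data look like repeated
#' measures subject to missingness; if both are (near) zero the data look
#' like repeated measures. "Near zero" means below `epsilon`, since sample
#' proportions are rarely exactly 0. As supporting evidence the largest width
#' at which the >1-visit proportion stays below `epsilon` is reported with
#' its proportions.
#'
#' @param sweep a `sweep_result` from [sweep_schedule()] or [sweep_uniform()].
#' @param epsilon tolerance below which a proportion counts as zero
#'   (default 0.01).
#' @return An object of class `visit_classification`: a list with `label`
#'   (one of `"repeated_measures"`, `"repeated_with_missingness"`,
#'   `"irregular"`), `width_star` and the proportions there, `width_zero`
#'   (NA when no width keeps the >1 proportion below `epsilon`) and the
#'   proportions there, and `epsilon`.
#' @export
classify_visits <- function(sweep, epsilon = 0.01) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (nrow(sweep) < 1) stop("empty sweep", call. = FALSE)
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)", call. = FALSE)
  ord <- order(sweep$bin_width)
  s <- sweep[ord, , drop = FALSE]

  star <- which(s$mean_p1 == max(s$mean_p1))[1]   # ties -> smallest width
  p0 <- s$mean_p0[star]; p2 <- s$mean_p2plus[star]
  label <- if (p2 > epsilon) "irregular"
           else if (p0 > epsilon) "repeated_with_missingness"
           else "repeated_measures"

  zero_ok <- which(s$mean_p2plus <= epsilon)
  zero <- if (length(zero_ok)) zero_ok[length(zero_ok)] else NA_integer_

  structure(list(
    label = label,
    width_star = s$bin_width[star],
    at_width_star = c(p0 = s$mean_p0[star], p1 = s$mean_p1[star],
                      p2plus = s$mean_p2plus[star]),
    width_zero = if (is.na(zero)) NA_real_ else s$bin_width[zero],
    at_width_zero = if (is.na(zero)) c(p0 = NA_real_, p1 = NA_real_,
                                       p2plus = NA_real_)
                    else c(p0 = s$mean_p0[zero], p1 = s$mean_p1[zero],
                           p2plus = s$mean_p2plus[zero]),
    epsilon = epsilon), class = "visit_classification")
}

#' @export
print.visit_classification <- function(x, ...) {
  cat("Visit-pattern classification: ", x$label, "\n", sep = "")
  cat(sprintf("  max mean p1 at width %.4g: p0 = %.3f, p1 = %.3f, p2plus = %.3f\n",
              x$width_star, x$at_width_star[1], x$at_width_star[2],
              x$at_width_star[3]))
  if (!is.na(x$width_zero)) {
    cat(sprintf("  largest width with p2plus <= %g: %.4g (p0 = %.3f, p1 = %.3f)\n",
                x$epsilon, x$width_zero, x$at_width_zero[1], x$at_width_zero[2]))
  } else {
    cat("  no width keeps p2plus <= ", x$epsilon, "\n", sep = "")
  }
  invisible(x)
}

#' Area-under-the-curve irregularity score
#'
#' Summarises a bin-width sweep into a single irregularity number: the
#' trapezoidal area under the curve traced by the points (mean proportion
#' with 0 visits, mean proportion with >1 visit) as bin width varies. Points
#' are sorted by their x-coordinate and y-values at duplicate x are averaged
#' first, so the score does not depend on row order. For perfect repeated
#' measures every point sits at the origin and the score is 0; larger scores
#' indicate greater irregularity, up to 1 for a curve pinned at the top of
#' the unit square.
#'
#' @param sweep a `sweep_result` with at least two rows.
#' @return a single number in [0, 1].
#' @export
auc_irregularity <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  if (nrow(sweep) < 2) {
    stop("need at least two sweep rows to trace a curve", call. = FALSE)
  }
  x <- sweep$mean_p0; y <- sweep$mean_p2plus
  ybar <- tapply(y, factor(x), mean)
  xs <- as.numeric(names(ybar))
  o <- order(xs)
  xs <- xs[o]; ys <- as.numeric(ybar)[o]
  if (length(xs) < 2) return(0)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}
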