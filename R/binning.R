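#' Pre-specified visit schedule
#'
#' Represents the protocol's pre-specified visit times T_1 < ... < T_k inside
#' the study window (0, tau). Bins anchored on these times are built with
#' [schedule_bins()].
#'
#' @param times strictly increasing numeric vector of scheduled visit times,
#'   all in (0, tau).
#' @param tau study horizon; must exceed the last scheduled time.
#' @return An object of class `visit_schedule`.
#' @examples
#' visit_schedule(c(2, 4, 6, 8, 10), tau = 12)
#' @export
visit_schedule <- function(times, tau) {
  times <- as.numeric(times)
  if (length(times) < 1) stop("schedule needs at least one time", call. = FALSE)
  if (any(diff(times) <= 0)) stop("schedule times must be strictly increasing", call. = FALSE)
  if (times[1] <= 0) stop("schedule times must be > 0", call. = FALSE)
  if (tau <= times[length(times)]) {
    stop("tau must exceed the last scheduled time", call. = FALSE)
  }
  structure(list(times = times, tau = as.numeric(tau)), class = "visit_schedule")
}

#' @export
print.visit_schedule <- function(x, ...) {
  cat("Visit schedule: ", paste(x$times, collapse = ", "),
      " on (0, ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Ordered set of counting bins
#'
#' Low-level constructor for an ordered, non-overlapping set of half-open
#' intervals [L_j, R_j). Bins may be anchored (one schedule time inside each
#' bin) or free; they need not tile the axis and may have unequal widths.
#' The closure convention is fixed package-wide: a visit exactly at L belongs
#' to the bin, a visit exactly at R does not, so touching bins partition
#' their union.
#'
#' @param left,right numeric vectors of bin boundaries, `left < right`
#'   elementwise and `right[j] <= left[j+1]`.
#' @param anchors optional vector of anchor times, one per bin, each strictly
#'   inside its bin.
#' @return An object of class `bin_set`: a data frame with columns `left`,
#'   `right` and optionally `anchor`.
#' @export
bin_set <- function(left, right, anchors = NULL) {
  left <- as.numeric(left); right <- as.numeric(right)
  if (length(left) != length(right) || length(left) < 1) {
    stop("left and right must be equal-length, non-empty", call. = FALSE)
  }
  if (any(left >= right)) {
    j <- which(left >= right)[1]
    stop("bin ", j, " has left >= right (", left[j], " >= ", right[j], ")",
         call. = FALSE)
  }
  if (length(left) > 1 && any(right[-length(right)] > left[-1] + 1e-12)) {
    j <- which(right[-length(right)] > left[-1] + 1e-12)[1]
    stop("bins ", j, " and ", j + 1, " overlap: R_", j, " = ", right[j],
         " > L_", j + 1, " = ", left[j + 1], call. = FALSE)
  }
  df <- data.frame(left = left, right = right)
  if (!is.null(anchors)) {
    anchors <- as.numeric(anchors)
    if (length(anchors) != length(left)) {
      stop("anchors must have one entry per bin", call. = FALSE)
    }
    if (any(anchors <= left | anchors >= right)) {
      stop("every anchor must lie strictly inside its bin", call. = FALSE)
    }
    df$anchor <- anchors
  }
  class(df) <- c("bin_set", "data.frame")
  df
}

#' @export
print.bin_set <- function(x, ...) {
  cat("Bin set with ", nrow(x), " half-open bins [L, R)",
      if ("anchor" %in% names(x)) ", anchored" else "", "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Bins anchored on pre-specified visit times
#'
#' Builds one bin around each scheduled time T_j using the gap-fraction rule:
#' the left cut-point sits `left_frac` of the way back toward the previous
#' scheduled time and the right cut-point `right_frac` of the way toward the
#' next, i.e. L_j = T_j - left_frac (T_j - T_{j-1}) and
#' R_j = T_j + right_frac (T_{j+1} - T_j). The study origin stands in for
#' T_0 and the horizon tau for T_{k+1}, so the first and last bins use the
#' gaps to the window edges. Fractions may differ between sides (e.g. a
#' narrow left side when protocol visits cannot occur early).
#'
#' @param schedule a [visit_schedule()].
#' @param left_frac,right_frac gap fractions in (0, 1). Fractions of 0.5 make
#'   touching bins that tile the midpoints; larger values that would make
#'   neighbouring bins overlap are an error.
#' @return An anchored [bin_set()].
#' @examples
#' s <- visit_schedule(c(2, 4, 6, 8, 10), tau = 12)
#' schedule_bins(s, 0.1, 0.1)  # bin around 4 is [3.8, 4.2)
#' @export
schedule_bins <- function(schedule, left_frac, right_frac = left_frac) {
  stopifnot(inherits(schedule, "visit_schedule"))
  if (left_frac <= 0 || left_frac >= 1 || right_frac <= 0 || right_frac >= 1) {
    stop("gap fractions must lie in (0, 1)", call. = FALSE)
  }
  tt <- schedule$times
  ext <- c(0, tt, schedule$tau)        # T_0 = origin, T_{k+1} = tau
  k <- length(tt)
  left <- tt - left_frac * (tt - ext[seq_len(k)])
  right <- tt + right_frac * (ext[seq_len(k) + 2L] - tt)
  if (k > 1 && any(right[-k] > left[-1] + 1e-12)) {
    j <- which(right[-k] > left[-1] + 1e-12)[1]
    stop("bins around T_", j, " = ", tt[j], " and T_", j + 1, " = ", tt[j + 1],
         " overlap (R = ", right[j], " > L = ", left[j + 1],
         "); reduce the gap fractions", call. = FALSE)
  }
  bin_set(left, right, anchors = tt)
}

#' Equal-width bins tiling the study window
#'
#' Splits [0, tau) into `n_bins` adjacent half-open bins of width
#' `tau / n_bins`, the construction used when the protocol has no
#' pre-specified visit times.
#'
#' @param tau study horizon (> 0).
#' @param n_bins number of bins (>= 1).
#' @return An unanchored [bin_set()].
#' @examples
#' uniform_bins(12, 4)  # [0,3) [3,6) [6,9) [9,12)
#' @export
uniform_bins <- function(tau, n_bins) {
  if (!is.numeric(n_bins) || n_bins < 1 || n_bins != round(n_bins)) {
    stop("n_bins must be a positive integer", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  edges <- seq(0, tau, length.out = n_bins + 1)
  bin_set(edges[-(n_bins + 1)], edges[-1])
}

#' Count visits per subject per bin with at-risk indicators
#'
#' For every subject i and bin j, counts the visit times falling in
#' [L_j, R_j) and marks the subject at risk for the bin when they were under
#' follow-up for all times in it: `entry_i <= L_j` and `end_i >= R_j`. A
#' subject's `end` is their administrative closure time, so individuals lost
#' to follow-up remain at risk beyond their last visit until the dataset
#' closed. Visits falling between anchored bins are counted nowhere but
#' tallied in the `uncovered` diagnostic.
#'
#' @param cohort a [visit_cohort()].
#' @param bins a [bin_set()].
#' @return An object of class `bin_counts`: a list with integer matrix
#'   `counts` (subjects x bins), logical matrix `at_risk`, per-subject
#'   `uncovered` visit tallies, and the `bins` and subject `ids` used.
#' @export
count_visits <- function(cohort, bins) {
  stopifnot(inherits(cohort, "visit_cohort"), inherits(bins, "bin_set"))
  ids <- cohort$subjects$id
  n <- length(ids)
  J <- nrow(bins)

  # interleave boundaries; odd findInterval index <=> inside a bin.
  # duplicate edges (touching bins) resolve to the right bin, matching [L, R).
  breaks <- as.vector(rbind(bins$left, bins$right))
  idx <- findInterval(cohort$visits$time, breaks)
  inside <- idx %% 2L == 1L
  bin_of <- (idx + 1L) %/% 2L

  fid <- factor(cohort$visits$id, levels = ids)
  counts <- matrix(0L, n, J, dimnames = list(ids, NULL))
  if (any(inside)) {
    tab <- table(fid[inside], factor(bin_of[inside], levels = seq_len(J)))
    counts[] <- as.integer(tab)
  }
  uncovered <- as.integer(table(fid[!inside]))

  at_risk <- outer(cohort$subjects$entry, bins$left, `<=`) &
    outer(cohort$subjects$end, bins$right, `>=`)
  dimnames(at_risk) <- list(ids, NULL)

  structure(list(counts = counts, at_risk = at_risk,
                 uncovered = stats::setNames(uncovered, ids),
                 bins = bins, ids = ids),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("Bin counts: ", length(x$ids), " subjects x ", nrow(x$bins), " bins; ",
      sum(x$counts), " visits counted, ", sum(x$uncovered),
      " outside all bins\n", sep = "")
  invisible(x)
}

#' Proportions of individuals with 0, 1 and >1 visits per bin
#'
#' For each bin, computes among the at-risk subjects the proportions with
#' exactly 0, exactly 1, and more than 1 visit, then averages these across
#' bins. Bins with no at-risk subject contribute nothing to the means and are
#' reported in the `excluded_bins` attribute. The default mean is unweighted
#' across bins; `weight = "at_risk"` weights each bin by its at-risk count.
#'
#' @param counts a `bin_counts` object from [count_visits()], or a
#'   [visit_cohort()] (in which case `bins` must be given and counting is
#'   done first).
#' @param bins a [bin_set()], only when `counts` is a cohort.
#' @param weight `"none"` (unweighted mean across bins, default) or
#'   `"at_risk"`.
#' @return An object of class `proportion_summary`: a data frame with one row
#'   per bin (`bin`, `left`, `right`, `n_at_risk`, `p0`, `p1`, `p2plus`) and
#'   attributes `mean_p0`, `mean_p1`, `mean_p2plus`, `excluded_bins`.
#' @examples
#' coh <- simulate_perfect(10, visit_schedule(c(2, 4, 6), tau = 8))
#' bin_proportions(coh, schedule_bins(visit_schedule(c(2, 4, 6), 8), 0.1))
#' @export
bin_proportions <- function(counts, bins = NULL, weight = c("none", "at_risk")) {
  weight <- match.arg(weight)
  if (inherits(counts, "visit_cohort")) {
    if (is.null(bins)) stop("supply `bins` when passing a cohort", call. = FALSE)
    counts <- count_visits(counts, bins)
  }
  stopifnot(inherits(counts, "bin_counts"))
  C <- counts$counts; A <- counts$at_risk
  J <- ncol(C)
  n_at_risk <- colSums(A)
  p0 <- p1 <- p2 <- rep(NA_real_, J)
  for (j in seq_len(J)) {
    if (n_at_risk[j] >= 1) {
      cj <- C[A[, j], j]
      p0[j] <- mean(cj == 0)
      p1[j] <- mean(cj == 1)
      p2[j] <- mean(cj > 1)
    }
  }
  keep <- n_at_risk >= 1
  if (!any(keep)) {
    stop("no bin has any at-risk subject; cannot compute proportions", call. = FALSE)
  }
  w <- if (weight == "none") rep(1, sum(keep)) else n_at_risk[keep]
  out <- data.frame(bin = seq_len(J), left = counts$bins$left,
                    right = counts$bins$right, n_at_risk = n_at_risk,
                    p0 = p0, p1 = p1, p2plus = p2)
  class(out) <- c("proportion_summary", "data.frame")
  attr(out, "mean_p0") <- stats::weighted.mean(p0[keep], w)
  attr(out, "mean_p1") <- stats::weighted.mean(p1[keep], w)
  attr(out, "mean_p2plus") <- stats::weighted.mean(p2[keep], w)
  attr(out, "excluded_bins") <- which(!keep)
  attr(out, "weight") <- weight
  out
}

#' Mean proportions from a proportion summary
#' @param x a `proportion_summary`.
#' @return named numeric vector `c(p0, p1, p2plus)` of across-bin means.
#' @export
mean_proportions <- function(x) {
  stopifnot(inherits(x, "proportion_summary"))
  c(p0 = attr(x, "mean_p0"), p1 = attr(x, "mean_p1"),
    p2plus = attr(x, "mean_p2plus"))
}

#' @export
print.proportion_summary <- function(x, ...) {
  m <- mean_proportions(x)
  cat("Per-bin proportions of subjects with 0 / 1 / >1 visits",
      " (at-risk denominators)\n", sep = "")
  print.data.frame(round_df(as.data.frame(unclass(x)), 4), row.names = FALSE)
  cat(sprintf("Mean across bins: p0 = %.4f, p1 = %.4f, p2plus = %.4f\n",
              m[1], m[2], m[3]))
  ex <- attr(x, "excluded_bins")
  if (length(ex)) cat("Bins with no at-risk subjects (excluded): ",
                      paste(ex, collapse = ", "), "\n", sep = "")
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
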