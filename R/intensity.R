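#' Expand a cohort into counting-process (start, stop, event) form
#'
#' Builds the recurrent-event data layout used by the Andersen-Gill model:
#' per subject, one row per inter-visit interval `(t_m, t_{m+1}]` with
#' `event = 1` at its endpoint, followed by a censored row from the last
#' visit to the end of follow-up (`event = 0`), emitted only when follow-up
#' extends beyond the last visit. Subjects with no visits contribute a single
#' censored row covering their whole window.
#'
#' Time-varying covariates are lagged by whole visits: the row ending at
#' visit m carries the value observed at visit `m - lag`, so the default
#' `lag = 1` uses the value from the previous visit — the intensity at any
#' time then depends only on the history already observed, never on the
#' outcome recorded at the visit being predicted. Intervals reaching back
#' before the first observed value (and the interval before the first visit)
#' use the subject's baseline value, taken from the same-named column of the
#' cohort's subject table. With `lag = 0` each row carries the value from the
#' visit that closes it (last observation carried forward without shift).
#'
#' @param cohort a [visit_cohort()].
#' @param covariates character vector of per-visit covariate names to carry
#'   (must exist in `cohort$visits`; baseline values are looked up in
#'   `cohort$subjects` under the same names).
#' @param lag non-negative integer number of visits to lag by (default 1).
#' @param timescale `"absolute"` keeps times on the cohort scale (e.g. age);
#'   `"followup"` shifts each subject so their entry time is 0.
#' @return An object of class `counting_process` (a data frame with columns
#'   `id`, `start`, `stop`, `event`, then the covariates), with attributes
#'   `timescale` and `lag`.
#' @export
to_counting_process <- function(cohort, covariates = NULL, lag = 1,
                                timescale = c("absolute", "followup")) {
  timescale <- match.arg(timescale)
  stopifnot(inherits(cohort, "visit_cohort"), lag >= 0, lag == round(lag))
  covariates <- covariates %||% character(0)
  miss <- setdiff(covariates, names(cohort$visits))
  if (length(miss)) {
    stop("per-visit covariate(s) not found in cohort: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss_base <- setdiff(covariates, names(cohort$subjects))
  if (length(miss_base)) {
    stop("baseline value(s) missing from subject table for covariate(s): ",
         paste(miss_base, collapse = ", "), call. = FALSE)
  }
  subj <- cohort$subjects
  vis_by_id <- split(cohort$visits, factor(cohort$visits$id, levels = subj$id))
  out <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    v <- vis_by_id[[i]]
    entry <- subj$entry[i]; end <- subj$end[i]
    tt <- v$time
    M <- length(tt)
    bounds <- c(entry, tt, if (M == 0 || end > tt[M]) end)
    nr <- length(bounds) - 1
    if (nr < 1) next  # end == entry and no visits: nothing to contribute
    rows <- data.frame(id = subj$id[i],
                       start = bounds[-length(bounds)],
                       stop = bounds[-1],
                       event = as.integer(seq_len(nr) <= M),
                       stringsAsFactors = FALSE)
    for (cv in covariates) {
      # value index for row r: visit r - lag; 0 -> baseline; clamp at M
      idx <- pmin(pmax(seq_len(nr) - lag, 0L), M)
      vals <- c(subj[[cv]][i], v[[cv]])[idx + 1L]
      rows[[cv]] <- vals
    }
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (timescale == "followup") {
    off <- stats::setNames(subj$entry, subj$id)
    res$start <- res$start - off[res$id]
    res$stop <- res$stop - off[res$id]
  }
  structure(res, class = c("counting_process", "data.frame"),
            timescale = timescale, lag = lag, covariates = covariates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit an Andersen-Gill visit-intensity model
#'
#' Fits the Andersen-Gill extension of the Cox proportional-hazards model to
#' counting-process visit data, characterising the instantaneous visit rate
#' as `lambda0(t) * exp(X(t)' beta)`. The partial likelihood is maximised
#' with the Efron approximation for tied event times. Hazard ratios with
#' Wald 95% confidence intervals and p-values are reported per coefficient.
#' Robust (sandwich) standard errors clustered by subject, the usual guard
#' against within-subject correlation in recurrent-event fits, are available
#' via `robust = TRUE`.
#'
#' @param table a `counting_process` from [to_counting_process()].
#' @param covariates names of covariate columns to include.
#' @param robust cluster-robust standard errors by subject (default FALSE).
#' @return An object of class `intensity_model`: list with `coefficients`
#'   (data frame: term, coef, se, hazard_ratio, ci_low, ci_high, p_value),
#'   `fit` (the underlying `coxph` object), `n`, `n_events`, `ties`,
#'   `timescale`, `covariates`, `dropped` (for selection, see
#'   [backward_select()]).
#' @export
fit_andersen_gill <- function(table, covariates, robust = FALSE) {
  stopifnot(inherits(table, "counting_process"))
  miss <- setdiff(covariates, names(table))
  if (length(miss)) {
    stop("covariate(s) not in counting-process table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (sum(table$event) < 1) stop("no events in table", call. = FALSE)
  for (cv in covariates) {
    if (is.numeric(table[[cv]]) && stats::var(table[[cv]]) == 0) {
      stop("covariate '", cv, "' is constant", call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    "Surv(start, stop, event) ~",
    paste(covariates, collapse = " + "),
    if (robust) "+ cluster(id)" else ""),
    env = environment())
  dat <- as.data.frame(table)
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(is.na(stats::coef(fit)))) {
    stop("Andersen-Gill fit failed (singular or separated covariates)",
         call. = FALSE)
  }
  if (!is.null(fit$info) && "convergence" %in% names(fit$info) &&
      fit$info[["convergence"]] != 0) {
    stop("Andersen-Gill fit did not converge after ", fit$iter,
         " iterations", call. = FALSE)
  }
  sm <- summary(fit)
  se_col <- if (robust) "robust se" else "se(coef)"
  cf <- sm$coefficients
  se <- cf[, se_col]
  beta <- cf[, "coef"]
  z <- beta / se
  tab <- data.frame(term = rownames(cf), coef = beta, se = se,
                    hazard_ratio = exp(beta),
                    ci_low = exp(beta - stats::qnorm(0.975) * se),
                    ci_high = exp(beta + stats::qnorm(0.975) * se),
                    p_value = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, fit = fit,
                 n = nrow(dat), n_events = sum(dat$event),
                 ties = "efron", robust = robust,
                 timescale = attr(table, "timescale"),
                 covariates = covariates, dropped = character(0)),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Andersen-Gill visit-intensity model (", x$n_events, " events / ",
      x$n, " intervals; Efron ties", if (x$robust) "; robust SE" else "",
      ")\n", sep = "")
  if (nrow(x$coefficients) == 0) {
    cat("  null model (no covariates retained)\n")
  } else {
    tab <- x$coefficients
    tab$p_value <- format.pval(tab$p_value, digits = 3, eps = 1e-4)
    print.data.frame(round_df(tab, 3), row.names = FALSE)
  }
  if (length(x$dropped)) {
    cat("Dropped by selection: ", paste(x$dropped, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Single-step backward selection on the visit-intensity model
#'
#' Fits the full Andersen-Gill model on all candidate covariates, then
#' retains those with p-values below `alpha` and refits once on the retained
#' set. A covariate expanding to several coefficients (factors) is retained
#' if any of its coefficients passes. `iterative = TRUE` instead removes the
#' single worst covariate and refits repeatedly until all remaining p-values
#' are below `alpha`. If nothing survives, a null model is returned with a
#' warning.
#'
#' @param table a `counting_process`.
#' @param covariates candidate covariate names.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @param iterative drop one covariate at a time instead of one pass.
#' @param robust see [fit_andersen_gill()].
#' @return An `intensity_model` whose `dropped` element logs the removed
#'   covariates; a null model (empty coefficient table) if none survive.
#' @export
backward_select <- function(table, covariates, alpha = 0.05,
                            iterative = FALSE, robust = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  cov_p <- function(model, covs) {
    # min p over the coefficients a covariate expands to
    vapply(covs, function(cv) {
      hit <- grepl(paste0("^", cv), model$coefficients$term)
      min(model$coefficients$p_value[hit])
    }, numeric(1))
  }
  dropped <- character(0)
  current <- covariates
  model <- fit_andersen_gill(table, current, robust = robust)
  repeat {
    p <- cov_p(model, current)
    if (iterative) {
      if (all(p < alpha)) break
      worst <- current[which.max(p)]
      dropped <- c(dropped, worst)
      current <- setdiff(current, worst)
    } else {
      dropped <- current[p >= alpha]
      current <- current[p < alpha]
    }
    if (!length(current)) {
      warning("no covariate retained at alpha = ", alpha,
              "; returning null model", call. = FALSE)
      model <- null_intensity_model(table)
      model$dropped <- dropped
      return(model)
    }
    model <- fit_andersen_gill(table, current, robust = robust)
    if (!iterative) break
  }
  model$dropped <- dropped
  model
}

null_intensity_model <- function(table) {
  structure(list(coefficients = data.frame(term = character(0),
                                           coef = numeric(0), se = numeric(0),
                                           hazard_ratio = numeric(0),
                                           ci_low = numeric(0),
                                           ci_high = numeric(0),
                                           p_value = numeric(0)),
                 fit = NULL, n = nrow(table), n_events = sum(table$event),
                 ties = "efron", robust = FALSE,
                 timescale = attr(table, "timescale"),
                 covariates = character(0), dropped = character(0)),
            class = "intensity_model")
}

#' Inverse-intensity weights for observed visits
#'
#' Computes, for every observed visit (event row of the counting-process
#' table), a weight proportional to the reciprocal of its estimated visit
#' intensity. In the stabilized form (default) the baseline intensity
#' cancels and the weight is `exp(-(X - x_bar)' beta_hat)`, exactly 1 for a
#' subject at the covariate mean. The unstabilized form divides additionally
#' by the Breslow baseline-intensity increment at the visit time. These
#' weights are the input to inverse-intensity-weighted outcome analyses
#' (e.g. weighted GEE); this package exports them and does not fit the
#' outcome model.
#'
#' @param model an `intensity_model` fitted on compatible covariates.
#' @param table the `counting_process` to weight (typically the one the model
#'   was fitted on).
#' @param stabilize drop the baseline intensity factor (default TRUE).
#' @return data frame with one row per observed visit: `id`, `visit_time`,
#'   `weight`; all weights positive and finite.
#' @export
inverse_intensity_weights <- function(model, table, stabilize = TRUE) {
  stopifnot(inherits(model, "intensity_model"), inherits(table, "counting_process"))
  ev <- as.data.frame(table)[table$event == 1, , drop = FALSE]
  if (is.null(model$fit)) {  # null model: unit stabilized weights
    lp <- rep(0, nrow(ev))
  } else {
    miss <- setdiff(model$covariates, names(ev))
    if (length(miss)) {
      stop("table lacks covariate(s) the model uses: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    lp <- unname(stats::predict(model$fit, newdata = ev, type = "lp",
                                reference = "sample"))
  }
  w <- exp(-lp)
  if (!stabilize) {
    if (is.null(model$fit)) {
      stop("unstabilized weights need a fitted model", call. = FALSE)
    }
    bh <- survival::basehaz(model$fit, centered = FALSE)
    inc <- diff(c(0, bh$hazard))
    jump <- stats::setNames(inc, format(bh$time, digits = 15))
    key <- format(ev$stop, digits = 15)
    lam0 <- jump[key]
    if (anyNA(lam0) || any(lam0 <= 0)) {
      stop("could not recover a positive baseline-intensity increment at ",
           "every event time", call. = FALSE)
    }
    w <- w / as.numeric(lam0)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("non-finite or non-positive weight produced", call. = FALSE)
  }
  data.frame(id = ev$id, visit_time = ev$stop, weight = unname(w),
             stringsAsFactors = FALSE)
}
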