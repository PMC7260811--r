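# Independent oracles and random-input generators shared across tests.

# Brute-force visit counter: iterates every (subject, bin, visit) triple.
# Deliberately naive; the package's vectorized counter must match it exactly.
brute_force_counts <- function(cohort, bins) {
  ids <- cohort$subjects$id
  n <- length(ids)
  J <- nrow(bins)
  counts <- matrix(0L, n, J, dimnames = list(ids, NULL))
  at_risk <- matrix(FALSE, n, J, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    tt <- cohort$visits$time[cohort$visits$id == ids[i]]
    for (j in seq_len(J)) {
      cnt <- 0L
      for (t in tt) {
        if (t >= bins$left[j] && t < bins$right[j]) cnt <- cnt + 1L
      }
      counts[i, j] <- cnt
      at_risk[i, j] <- cohort$subjects$entry[i] <= bins$left[j] &&
        cohort$subjects$end[i] >= bins$right[j]
    }
  }
  list(counts = counts, at_risk = at_risk)
}

# Random small cohort with staggered entry and closure.
random_cohort <- function(n = 10, tau = 12, max_visits = 8) {
  ids <- sprintf("R%02d", seq_len(n))
  kk <- sample(0:max_visits, n, replace = TRUE)
  if (all(kk == 0)) kk[1] <- 1
  vis <- lapply(seq_len(n), function(i) {
    if (kk[i] == 0) return(NULL)
    data.frame(id = ids[i], time = sort(runif(kk[i], 0, tau)))
  })
  visits <- do.call(rbind, vis)
  first <- tapply(visits$time, factor(visits$id, levels = ids), min)
  last <- tapply(visits$time, factor(visits$id, levels = ids), max)
  entry <- ifelse(is.na(first), runif(n, 0, tau / 2), runif(n) * first)
  end <- ifelse(is.na(last), entry + runif(n, 0, tau),
                last + runif(n) * pmax(tau - last, 0))
  # a share of subjects observed over the whole window, as in a real cohort
  full <- runif(n) < 0.5
  entry[full] <- 0
  end[full] <- pmax(end[full], tau)
  subjects <- data.frame(id = ids, entry = entry, end = end,
                         lost_to_followup = runif(n) < 0.2)
  suppressWarnings(visit_cohort(visits, subjects))
}

# Random non-overlapping bin set inside (0, tau), possibly with gaps.
random_bins <- function(tau = 12, max_bins = 15) {
  J <- sample(1:max_bins, 1)
  cuts <- sort(runif(2 * J, 0, tau))
  bin_set(cuts[seq(1, 2 * J, by = 2)], cuts[seq(2, 2 * J, by = 2)])
}

# Hand-coded Efron partial log-likelihood for (start, stop] counting-process
# data. Independent of survival::coxph; maximized numerically in tests.
efron_loglik <- function(beta, start, stop, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (t in sort(unique(stop[event == 1]))) {
    D <- which(event == 1 & stop == t)
    R <- which(start < t & stop >= t)
    d <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - (l / d) * sumD)
    }
  }
  ll
}

maximize_efron <- function(start, stop, event, X) {
  X <- as.matrix(X)
  if (ncol(X) == 1) {
    opt <- stats::optimize(function(b) efron_loglik(b, start, stop, event, X),
                           interval = c(-10, 10), maximum = TRUE,
                           tol = 1e-10)
    opt$maximum
  } else {
    opt <- stats::optim(rep(0, ncol(X)),
                        function(b) -efron_loglik(b, start, stop, event, X),
                        method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    opt$par
  }
}

# Counting-process table with the package's class, built by hand.
as_cp <- function(df, covariates = character(0)) {
  structure(df, class = c("counting_process", "data.frame"),
            timescale = "absolute", lag = 1, covariates = covariates)
}

# Bare sweep_result for AUC geometry tests.
as_sweep <- function(p0, p2plus, width = seq_along(p0)) {
  structure(data.frame(bin_width = width, mean_p0 = p0,
                       mean_p1 = 1 - p0 - p2plus, mean_p2plus = p2plus),
            class = c("sweep_result", "data.frame"), mode = "uniform")
}

schedule_2_10 <- function() visit_schedule(c(2, 4, 6, 8, 10), tau = 12)
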