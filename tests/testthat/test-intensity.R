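make_cohort_xy <- function() {
  visit_cohort(
    data.frame(id = "A", time = c(1, 2), x = c(5, 7)),
    data.frame(id = "A", entry = 0, end = 3, x = 9))
}

test_that("counting-process expansion applies the 1-visit lag rule", {
  cp <- to_counting_process(make_cohort_xy(), covariates = "x", lag = 1)
  expect_equal(cp$start, c(0, 1, 2))
  expect_equal(cp$stop, c(1, 2, 3))
  expect_equal(cp$event, c(1L, 1L, 0L))
  # row ending at the first visit uses the baseline value, then each row
  # carries the value observed at the previous visit
  expect_equal(cp$x, c(9, 5, 7))
})

test_that("lag 0 carries the value observed at the visit closing each row", {
  cp <- to_counting_process(make_cohort_xy(), covariates = "x", lag = 0)
  expect_equal(cp$x, c(5, 7, 7))  # final censored row carries forward
})

test_that("expansion emits visits + 1 rows, censored tails, empty subjects", {
  set.seed(71)
  coh <- random_cohort(n = 12, tau = 12)
  # push end times strictly beyond the last visit so every subject has a tail
  coh$subjects$end <- coh$subjects$end + 0.5
  cp <- to_counting_process(coh)
  nvis <- table(factor(coh$visits$id, levels = coh$subjects$id))
  nrows <- table(factor(cp$id, levels = coh$subjects$id))
  expect_equal(as.numeric(nrows), as.numeric(nvis) + 1)
  # per subject: contiguous, non-overlapping, events exactly at visit times
  for (id in coh$subjects$id) {
    rows <- cp[cp$id == id, ]
    expect_true(all(rows$start < rows$stop))
    expect_equal(rows$start[-1], rows$stop[-nrow(rows)])
    expect_equal(rows$stop[rows$event == 1],
                 coh$visits$time[coh$visits$id == id])
    expect_equal(rows$event[nrow(rows)], 0L)
  }

  # a subject with no visits contributes one censored row over their window
  solo <- suppressWarnings(visit_cohort(
    data.frame(id = "A", time = 1),
    data.frame(id = c("A", "B"), entry = c(0, 2), end = c(3, 10))))
  cpe <- to_counting_process(solo)
  b <- cpe[cpe$id == "B", ]
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$stop, b$event), c(2, 10, 0))

  expect_error(to_counting_process(solo, covariates = "w"), "not found")
})

test_that("the follow-up timescale shifts each subject's entry to zero", {
  coh <- visit_cohort(data.frame(id = c("A", "B"), time = c(3, 5)),
                      data.frame(id = c("A", "B"), entry = c(2, 4),
                                 end = c(6, 7)))
  cp <- to_counting_process(coh, timescale = "followup")
  expect_equal(cp$start, c(0, 1, 0, 1))
  expect_equal(cp$stop, c(1, 4, 1, 3))
})

test_that("the fit maximizes the Efron partial likelihood", {
  # tiny fixed table, including tied event times
  tab <- as_cp(data.frame(
    id = rep(c("A", "B", "C"), times = c(3, 2, 2)),
    start = c(0, 1, 2, 0, 2, 0, 1),
    stop = c(1, 2, 4, 2, 3, 1, 3),
    event = c(1, 1, 0, 1, 1, 1, 0),
    x = c(0.5, -1, 0.2, 1.5, -0.3, -0.7, 0.9)), covariates = "x")
  fit <- fit_andersen_gill(tab, "x")
  beta_hat <- fit$coefficients$coef
  beta_oracle <- maximize_efron(tab$start, tab$stop, tab$event, tab$x)
  expect_equal(beta_hat, beta_oracle, tolerance = 1e-6)
  # the oracle's likelihood is maximal at the fit, not nearby
  ll <- function(b) efron_loglik(b, tab$start, tab$stop, tab$event,
                                 as.matrix(tab$x))
  expect_gt(ll(beta_hat), ll(beta_hat + 0.01))
  expect_gt(ll(beta_hat), ll(beta_hat - 0.01))

  # randomized small tables with <= 8 events
  set.seed(83)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(1:2, 1)
      tt <- sort(sample(seq(0.5, 6, by = 0.5), k + 1))
      data.frame(id = paste0("S", i), start = tt[-length(tt)], stop = tt[-1],
                 event = c(rep(1, k - 1), rbinom(1, 1, 0.7), 0)[seq_len(k)],
                 x = round(rnorm(k), 2))
    })
    tab <- as_cp(do.call(rbind, rows), covariates = "x")
    if (sum(tab$event) < 2 || var(tab$x[tab$event == 1]) == 0) next
    fit <- try(suppressWarnings(fit_andersen_gill(tab, "x")), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (abs(fit$coefficients$coef) > 5) next  # near-separation, oracle boundary
    beta_oracle <- maximize_efron(tab$start, tab$stop, tab$event, tab$x)
    expect_equal(fit$coefficients$coef, beta_oracle, tolerance = 1e-6)
  }

  # two covariates against the vector oracle
  set.seed(97)
  cp <- to_counting_process(
    simulate_irregular(15, 6, 0.8, beta = 0.4, scenario = "VAR", seed = 31),
    covariates = "y")
  cp$z <- round(rnorm(nrow(cp)), 2)
  attr(cp, "covariates") <- c("y", "z")
  fit2 <- fit_andersen_gill(cp, c("y", "z"))
  oracle2 <- maximize_efron(cp$start, cp$stop, cp$event, cbind(cp$y, cp$z))
  expect_equal(fit2$coefficients$coef, oracle2, tolerance = 1e-5)
})

test_that("hazard ratios, confidence bounds and p-values are mutually consistent", {
  cp <- to_counting_process(
    simulate_irregular(80, 12, 0.5, beta = 0.5, scenario = "VAR", seed = 41),
    covariates = "y")
  fit <- fit_andersen_gill(cp, "y")
  co <- fit$coefficients
  expect_equal(co$hazard_ratio, exp(co$coef), tolerance = 1e-10)
  expect_equal(co$ci_low, exp(co$coef - qnorm(0.975) * co$se), tolerance = 1e-10)
  expect_equal(co$ci_high, exp(co$coef + qnorm(0.975) * co$se), tolerance = 1e-10)
  expect_true(co$ci_low < co$hazard_ratio && co$hazard_ratio < co$ci_high)
  expect_true(co$p_value >= 0 && co$p_value <= 1)
  # robust (clustered) errors are available and change only the SE column
  rob <- fit_andersen_gill(cp, "y", robust = TRUE)
  expect_equal(rob$coefficients$coef, co$coef)
})

test_that("the fitted intensity recovers the generating coefficient", {
  coh <- simulate_irregular(400, 12, 0.5, beta = log(1.5), scenario = "VAR",
                            seed = 59)
  fit <- fit_andersen_gill(to_counting_process(coh, covariates = "y"), "y")
  co <- fit$coefficients
  expect_lt(abs(co$coef - log(1.5)), 3 * co$se)
})

test_that("guard rails: empty events, constant covariates, missing columns", {
  tab <- as_cp(data.frame(id = "A", start = 0, stop = 1, event = 0, x = 1),
               covariates = "x")
  expect_error(fit_andersen_gill(tab, "x"), "no events")
  tab2 <- as_cp(data.frame(id = c("A", "B"), start = 0, stop = c(1, 2),
                           event = 1, x = 3), covariates = "x")
  expect_error(fit_andersen_gill(tab2, "x"), "constant")
  expect_error(fit_andersen_gill(tab2, "q"), "not in counting-process")
})

test_that("single-step selection retains exactly the strong predictors", {
  # y drives the intensity; a pure-noise covariate rides along
  coh <- simulate_irregular(250, 12, 0.5, beta = 0.6, scenario = "VAR",
                            seed = 61)
  cp <- to_counting_process(coh, covariates = "y")
  set.seed(62)
  cp$noise <- rnorm(nrow(cp))
  attr(cp, "covariates") <- c("y", "noise")
  sel <- backward_select(cp, c("y", "noise"), alpha = 0.05)
  expect_equal(sel$coefficients$term, "y")
  expect_equal(sel$dropped, "noise")

  # alpha = 1 keeps everything: identical to the full fit
  full <- fit_andersen_gill(cp, c("y", "noise"))
  keep_all <- backward_select(cp, c("y", "noise"), alpha = 1)
  expect_equal(keep_all$coefficients, full$coefficients)

  # nothing true: null model with a warning (single seeded draw)
  cpn <- cp
  expect_warning(nullm <- backward_select(cpn, "noise", alpha = 1e-6),
                 "null model")
  expect_equal(nrow(nullm$coefficients), 0)
  w <- inverse_intensity_weights(nullm, cpn)
  expect_true(all(w$weight == 1))

  # iterative elimination drops one at a time and logs the order
  it <- backward_select(cp, c("y", "noise"), alpha = 0.05, iterative = TRUE)
  expect_equal(it$coefficients$term, "y")
})

test_that("inverse-intensity weights follow the fitted linear predictor", {
  coh <- simulate_irregular(120, 12, 0.5, beta = 0.5, scenario = "VAR",
                            seed = 67)
  cp <- to_counting_process(coh, covariates = "y")
  fit <- fit_andersen_gill(cp, "y")
  w <- inverse_intensity_weights(fit, cp)
  ev <- as.data.frame(cp)[cp$event == 1, ]
  beta <- fit$coefficients$coef
  xbar <- fit$fit$means
  expect_equal(w$weight, exp(-(ev$y - xbar) * beta), tolerance = 1e-10)
  expect_equal(nrow(w), sum(cp$event))
  # at the covariate mean the stabilized weight is exactly 1
  probe <- cp[1, ]
  probe$y <- unname(xbar)
  probe$event <- 1L
  attr(probe, "covariates") <- "y"
  expect_equal(inverse_intensity_weights(fit, probe)$weight, 1)
  # a unit covariate at coefficient log(2) halves the intensity reciprocal
  probe$y <- unname(xbar) + 1
  expect_equal(inverse_intensity_weights(fit, probe)$weight,
               exp(-beta), tolerance = 1e-10)

  # unstabilized weights include the Breslow baseline and stay positive/finite
  wu <- inverse_intensity_weights(fit, cp, stabilize = FALSE)
  expect_true(all(is.finite(wu$weight) & wu$weight > 0))
  expect_true(all(is.finite(w$weight) & w$weight > 0))
})

test_that("weights are positive and finite across the simulation ladder", {
  s <- schedule_2_10()
  cohorts <- list(
    simulate_jitter(60, s, 0.5, seed = 3),
    simulate_irregular(60, 12, 0.5, beta = 0, scenario = "VCAR", seed = 4),
    simulate_irregular(60, 12, 0.5, beta = 0.7, scenario = "VAR", seed = 5),
    simulate_irregular(60, 12, 0.5, beta = 0.7, scenario = "VNAR", seed = 6))
  for (coh in cohorts) {
    if (!"y" %in% names(coh$visits)) coh$visits$y <- rnorm(nrow(coh$visits))
    if (!"y" %in% names(coh$subjects)) coh$subjects$y <- rnorm(n_subjects(coh))
    cp <- to_counting_process(coh, covariates = "y")
    fit <- fit_andersen_gill(cp, "y")
    w <- inverse_intensity_weights(fit, cp)
    expect_true(all(is.finite(w$weight) & w$weight > 0))
  }
})
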