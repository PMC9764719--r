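test_that("the stabilized weight product matches hand arithmetic", {
  sw <- stabilized_weight_product(a = c(1, 0), p_num = c(0.5, 0.5),
                                  p_den = c(0.8, 0.4), id = c(1, 1),
                                  t = c(1, 2))
  expect_equal(sw, c(0.625, 0.625 * (0.5 / 0.6)), tolerance = 1e-12)
  expect_equal(round(sw[2], 4), 0.5208)

  # rows arrive unsorted and must come back aligned
  sw2 <- stabilized_weight_product(a = c(0, 1), p_num = c(0.5, 0.5),
                                   p_den = c(0.4, 0.8), id = c(1, 1),
                                   t = c(2, 1))
  expect_equal(sw2, c(0.625 * (0.5 / 0.6), 0.625), tolerance = 1e-12)

  expect_warning(
    stabilized_weight_product(1, p_num = 0.5, p_den = 1 - 1e-12,
                              id = 1, t = 1),
    "positivity")
})

test_that("identical numerator and denominator models stabilize to weight one", {
  pd <- cohort_persondays(tiny_sim(seed = 7))$persondays
  m <- fit_exposure_models(pd, numerator = default_numerator_formula(),
                           denominator = default_numerator_formula())
  ws <- compute_stabilized_weights(m, pd)
  expect_lt(max(abs(ws$sw - 1)), 1e-10)
})

test_that("a saturated exposure model reproduces empirical frequencies", {
  # one stay-day per patient, a single binary hospital-day confounder
  set.seed(33)
  n <- 400
  l <- rbinom(n, 1, 0.5)
  a <- rbinom(n, 1, ifelse(l == 1, 0.7, 0.3))
  pd <- data.table::data.table(patient_id = 1:n, t = 1L, A = a, A_lag = 0L,
                               cumA_lag = 0L, turnover = l)
  m <- fit_exposure_models(pd, numerator = A ~ 1,
                           denominator = A ~ factor(turnover))
  p_den <- predict(m$denominator, newdata = pd, type = "response")
  emp <- tapply(a, l, mean)
  expect_lt(max(abs(p_den - emp[as.character(l)])), 1e-6)
  p_num <- predict(m$numerator, newdata = pd, type = "response")
  expect_lt(max(abs(p_num - mean(a))), 1e-6)
})

test_that("degenerate exposure raises an estimation error", {
  pd <- cohort_persondays(tiny_sim(seed = 7))$persondays
  pd$A <- 0L
  expect_error(fit_exposure_models(pd), class = "occmsm_estimation_error")
})

test_that("without confounding the two exposure models nearly coincide", {
  # exposure depends only on its own history; confounders are pure noise
  set.seed(17)
  n <- 4000
  pd <- data.table::rbindlist(lapply(1:n, function(i) {
    a <- integer(3)
    for (s in 1:3) a[s] <- rbinom(1, 1, plogis(-1.2 + 0.8 * (s > 1 && a[s - 1])))
    data.table::data.table(patient_id = i, t = 1:3, A = a,
                           A_lag = c(0L, a[1], a[2]),
                           cumA_lag = c(0L, cumsum(a)[1:2]),
                           turnover = rnorm(3, 50, 10),
                           mean_pccl = rnorm(3, 1, 0.2))
  }))
  m <- fit_exposure_models(pd, numerator = A ~ A_lag + cumA_lag + factor(t),
                           denominator = A ~ A_lag + cumA_lag + factor(t) +
                             turnover + mean_pccl)
  cf <- summary(m$denominator)$coefficients
  for (term in c("turnover", "mean_pccl"))
    expect_lt(abs(cf[term, "Estimate"] / cf[term, "Std. Error"]), 2)
  p_num <- predict(m$numerator, newdata = pd, type = "response")
  p_den <- predict(m$denominator, newdata = pd, type = "response")
  expect_lt(max(abs(p_num - p_den)), 0.02)
})

test_that("truncation winsorizes at interpolated percentile bounds", {
  ws <- data.table::data.table(patient_id = 1:100, t = 1L,
                               p_num = 0.5, p_den = 0.5, sw = as.numeric(1:100))
  data.table::setattr(ws, "class", c("weight_set", class(ws)))
  tr <- truncate_weights(ws, 1, 99)
  expect_equal(unname(attr(tr, "bounds")), c(1.99, 99.01))
  expect_identical(attr(tr, "n_modified"), 2L)
  expect_equal(sort(unique(tr$sw))[1], 1.99)
  expect_equal(max(tr$sw), 99.01)
  expect_lte(stats::var(tr$sw), stats::var(ws$sw))

  same <- data.table::copy(ws); same$sw <- 1
  tr2 <- truncate_weights(same, 1, 99)
  expect_identical(attr(tr2, "n_modified"), 0L)
  expect_true(all(tr2$sw == 1))

  # full-range bounds are the identity transform
  tr3 <- truncate_weights(ws, 0, 100)
  expect_equal(tr3$sw, ws$sw)

  expect_error(truncate_weights(ws, 99, 1), class = "occmsm_config_error")
})

test_that("weight diagnostics report the five distribution summaries", {
  d <- weight_diagnostics(c(1, 1, 1, 1))
  expect_equal(d$mean, 1); expect_equal(d$median, 1)
  expect_equal(d$q25, 1); expect_equal(d$q75, 1)
  expect_equal(d$min, 1); expect_equal(d$max, 1)
  expect_false(d$misspecification_flag)

  d2 <- weight_diagnostics(c(0.5, 1, 1.5, 2))
  expect_equal(d2$mean, 1.25)
  expect_equal(d2$median, 1.25)
  expect_equal(d2$min, 0.5); expect_equal(d2$max, 2)
  expect_true(d2$misspecification_flag)
  expect_true(all(c("mean", "median", "q25", "q75", "min", "max") %in%
                    names(d2)))
  p <- plot_weight_density(c(0.5, 1, 1.5, 2))
  expect_s3_class(p, "ggplot")
})

test_that("the product formula matches exhaustive sequence-probability tabulation", {
  # fully discrete two-day system: binary confounder each day, binary exposure
  set.seed(91)
  n <- 3000
  l1 <- rbinom(n, 1, 0.5)
  a1 <- rbinom(n, 1, plogis(-0.4 + 0.9 * l1))
  l2 <- rbinom(n, 1, plogis(-0.2 + 0.8 * a1))
  a2 <- rbinom(n, 1, plogis(-0.5 + 0.7 * l2 + 0.6 * a1))
  pd <- data.table::data.table(
    patient_id = rep(1:n, each = 2),
    t = rep(1:2, n),
    A = as.integer(rbind(a1, a2)),
    A_lag = as.integer(rbind(0L, a1)),
    turnover = as.integer(rbind(l1, l2)))
  m <- fit_exposure_models(
    pd,
    numerator = A ~ factor(t) * factor(A_lag),
    denominator = A ~ factor(t) * factor(A_lag) * factor(turnover))
  ws <- compute_stabilized_weights(m, pd)

  # oracle: empirical conditional sequence probabilities by exhaustive tabulation
  key1 <- l1; key2 <- paste(a1, l2)
  p1_den <- tapply(a1, key1, mean)[as.character(key1)]
  p2_den <- tapply(a2, key2, mean)[as.character(key2)]
  p1_num <- mean(a1)
  p2_num <- tapply(a2, a1, mean)[as.character(a1)]
  obs <- function(p, a) ifelse(a == 1, p, 1 - p)
  sw1 <- obs(p1_num, a1) / obs(p1_den, a1)
  sw2 <- sw1 * obs(p2_num, a2) / obs(p2_den, a2)
  expect_lt(max(abs(ws[t == 1, sw] - sw1)), 1e-6)
  expect_lt(max(abs(ws[t == 2, sw] - sw2)), 1e-6)
})

test_that("weighting balances the time-varying confounders across exposure", {
  parts <- cohort_persondays(sim_config(seed = 5))
  pd <- parts$persondays
  m <- fit_exposure_models(pd)
  ws <- compute_stabilized_weights(m, pd)
  pd$.w <- ws$sw
  # exposure and the confounders live at the hospital-day level
  agg <- pd[, .(A = A[1], turnover = turnover[1], mean_pccl = mean_pccl[1],
                w = mean(.w)), by = .(hospital_id, day)]
  zstat <- function(weighted) {
    f <- if (weighted)
      glm(A ~ turnover + mean_pccl, family = quasibinomial(), data = agg,
          weights = w)
    else glm(A ~ turnover + mean_pccl, family = binomial(), data = agg)
    cf <- coef(f)[-1]
    cf / sqrt(diag(sandwich::vcovHC(f, type = "HC0")))[-1]
  }
  z_raw <- zstat(FALSE)
  z_w <- zstat(TRUE)
  # raw data show a strong turnover-exposure association; weighting removes it
  expect_gt(max(abs(z_raw)), 2)
  expect_lt(max(abs(z_w)), 2)
})
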