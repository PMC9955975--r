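test_that("product-limit estimator matches hand computation", {
  # 4 patients, events at months 3 and 6, the other two followed past 6
  km <- km_estimate(c(3, 6, 8, 8), c(1, 1, 0, 0))
  expect_equal(km_survival_at(km, 3), 0.75)
  expect_equal(km_survival_at(km, 6), 0.5)
  expect_equal(km_survival_at(km, 2), 1.0)

  # all censored: the curve never drops
  km0 <- km_estimate(c(5, 7, 12), c(0, 0, 0))
  expect_equal(km_survival_at(km0, 12), 1.0)

  # 36 patients, 14 events within 12 months, 22 followed to 12 months
  times <- c(rep(c(3, 6, 9), length.out = 14), rep(12, 22))
  events <- c(rep(1, 14), rep(0, 22))
  km36 <- km_estimate(times, events)
  expect_equal(km_survival_at(km36, 12), 22 / 36, tolerance = 1e-12)
  expect_equal(round(100 * km_survival_at(km36, 12), 1), 61.1)

  expect_error(km_estimate(c(-1, 2), c(1, 0)), "nonnegative")
  expect_error(km_estimate(numeric(0), integer(0)), "no survival")
})

test_that("KM curve properties: monotone, order-invariant, ECDF link", {
  set.seed(5)
  time <- round(rexp(40, 0.1), 2)
  event <- rbinom(40, 1, 0.7)
  km <- km_estimate(time, event)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(diff(km$n_risk) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))

  # invariance to record order
  perm <- sample(40)
  km_p <- km_estimate(time[perm], event[perm])
  expect_equal(km, km_p)

  # with no censoring, S(t) = 1 - ECDF(t) at every observed time
  km_all <- km_estimate(time, rep(1, 40))
  for (t in unique(time)) {
    expect_equal(km_survival_at(km_all, t), 1 - ecdf(time)(t),
                 tolerance = 1e-12)
  }
  # and matches the hand product-limit oracle with censoring present
  for (t in c(2, 5, 10, 20)) {
    expect_equal(km_survival_at(km, t), brute_force_km(time, event, t),
                 tolerance = 1e-12)
  }
})

test_that("log-rank statistic matches a hand-worked table", {
  # group a events at {1,2}, group b at {3,4}, two per group, no censoring:
  # O_a - E_a = 2 - (1/2 + 1/3), V = 1/4 + 2/9 -> chi-square = 2.882353
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(lr$chi_square, 2.882353, tolerance = 1e-6)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(2.882353, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  # identical event times in both groups: observed = expected
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("a", "b"), 3))
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "event")
})

test_that("strongly separated hazards are detected in nearly every cohort", {
  # hazard ratio 8 between groups at the study's group sizes
  set.seed(97)
  hits <- 0
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    t_short <- pmin(rexp(36, 0.04), 12)
    t_long <- pmin(rexp(27, 0.32), 12)
    time <- c(t_short, t_long)
    event <- as.integer(time < 12)
    group <- rep(c("short", "long"), c(36, 27))
    p <- logrank_test(time, event, group)$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("log-rank p-values are uniform under the null", {
  set.seed(131)
  n <- 60
  time <- pmin(rexp(n, 0.15), 12)
  event <- as.integer(time < 12)
  p <- replicate(500, {
    g <- sample(rep(c("a", "b"), each = n / 2))
    logrank_test(time, event, g)$p_value
  })
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox fit recovers null and strong protective effects", {
  set.seed(211)
  # pure-noise covariate: HR near 1, inside its own CI
  n <- 800
  d <- data.frame(time_months = rexp(n, 0.2), event = rep(1L, n),
                  x = rnorm(n))
  fit <- cox_fit(d, "x", mode = "univariate")
  expect_true(fit$ci_low <= 1 && 1 <= fit$ci_high)
  expect_equal(fit$hr, 1, tolerance = 0.15)

  # binary covariate with true hazard ratio 0.12, no censoring
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  d2 <- data.frame(time_months = rexp(n, 0.3 * 0.12^x), event = rep(1L, n),
                   x = x)
  fit2 <- cox_fit(d2, "x", mode = "univariate")
  expect_lt(abs(log(fit2$hr) - log(0.12)), 0.1)
  expect_true(fit2$converged)
})

test_that("Cox score test equals the log-rank chi-square without ties", {
  set.seed(307)
  n <- 30
  time <- rexp(n, 0.1) + seq_len(n) * 1e-6   # break ties
  event <- rep(1L, n)
  grp <- rep(c(0, 1), length.out = n)
  d <- data.frame(time_months = time, event = event, g = grp)
  score <- survival::coxph(survival::Surv(time_months, event) ~ g, data = d,
                           ties = "efron")$score
  lr <- logrank_test(time, event, ifelse(grp == 1, "b", "a"))
  expect_equal(unname(score), lr$chi_square, tolerance = 1e-8)
})

test_that("Cox estimates are unbiased with near-nominal CI coverage", {
  set.seed(401)
  for (true_beta in c(-2, -1, 0, 1)) {
    cover <- 0
    betas <- numeric(0)
    n_sim <- 200
    for (i in seq_len(n_sim)) {
      n <- 500
      x <- rbinom(n, 1, 0.5)
      d <- data.frame(time_months = rexp(n, 0.2 * exp(true_beta * x)),
                      event = rep(1L, n), x = x)
      fit <- cox_fit(d, "x", mode = "univariate")
      betas <- c(betas, log(fit$hr))
      if (log(fit$ci_low) <= true_beta && true_beta <= log(fit$ci_high)) {
        cover <- cover + 1
      }
    }
    expect_gte(cover / n_sim, 0.90)
    expect_lte(cover / n_sim, 0.99)
    expect_lt(abs(mean(betas) - true_beta), 0.05)
  }
})

test_that("multivariate Cox respects the univariate entry rule", {
  set.seed(503)
  n <- 300
  x1 <- rbinom(n, 1, 0.5)            # real effect
  x2 <- rnorm(n)                     # noise
  d <- data.frame(time_months = rexp(n, 0.2 * exp(-1.2 * x1)),
                  event = rep(1L, n), x1 = x1, x2 = x2)
  fit <- cox_fit(d, c("x1", "x2"), mode = "both")
  uni <- fit[fit$analysis == "univariate", ]
  multi <- fit[fit$analysis == "multivariate", ]
  expect_equal(nrow(uni), 2)
  expect_true("x1" %in% multi$term)
  selected <- uni$term[uni$p_value < 0.05]
  expect_setequal(multi$term, selected)

  expect_error(cox_fit(d, "missing_col"), "missing_col")
  d$const <- 1
  expect_error(cox_fit(d, "const"), "constant")
})

test_that("p-values format with the <0.001 floor", {
  expect_identical(format_p(c(0.0004, 0.049, 0.5)),
                   c("<0.001", "0.049", "0.500"))
})
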