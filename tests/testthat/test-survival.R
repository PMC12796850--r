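test_that("product-limit estimate matches the worked five-subject example", {
  d <- data.frame(time = c(5, 10, 15, 20, 25), event = c(0, 1, 1, 0, 1))
  km <- km_fit(d)[[1]]
  expect_equal(km_surv_at(km, 10), 0.75)
  expect_equal(km_surv_at(km, 15), 0.50)
  expect_equal(median_survival(km), 15)
  expect_equal(km_surv_at(km, 25), 0)

  # all censored: S stays at 1, median undefined
  km2 <- km_fit(data.frame(time = 1:4, event = 0))[[1]]
  expect_equal(km_surv_at(km2, 100), 1)
  expect_true(is.na(median_survival(km2)))

  # single subject with an event: S drops to 0
  km3 <- km_fit(data.frame(time = 1, event = 1))[[1]]
  expect_equal(km3$surv, 0)
  expect_equal(median_survival(km3), 1)

  # S hitting exactly 0.5 defines the median (boundary rule)
  km4 <- km_fit(data.frame(time = c(1, 2), event = c(1, 0)))[[1]]
  expect_equal(km4$surv, 0.5)
  expect_equal(median_survival(km4), 1)
})

test_that("product-limit agrees with the brute-force oracle on all small datasets", {
  # exhaustive over (time, status) in {1,2,3} x {0,1} for n <= 4,
  # then randomized tied datasets for n in 5..8
  grid <- expand.grid(time = 1:3, status = 0:1)
  for (n in 1:4) {
    idx <- do.call(expand.grid, rep(list(seq_len(nrow(grid))), n))
    for (r in seq_len(nrow(idx))) {
      d <- grid[as.integer(idx[r, ]), ]
      km <- km_fit(data.frame(time = d$time, event = d$status))[[1]]
      at <- c(0.5, 1, 1.5, 2, 2.5, 3, 4)
      expect_equal(km_surv_at(km, at), km_oracle(d$time, d$status, at))
    }
  }
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    tm <- sample(1:5, n, replace = TRUE)
    st <- rbinom(n, 1, 0.6)
    km <- km_fit(data.frame(time = tm, event = st))[[1]]
    at <- seq(0, 6, by = 0.5)
    expect_equal(km_surv_at(km, at), km_oracle(tm, st, at))
  }
})

test_that("survival estimate and Greenwood SE match the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(7)
  tm <- round(rexp(40, 0.1), 0) + 1
  st <- rbinom(40, 1, 0.7)
  km <- km_fit(data.frame(time = tm, event = st))[[1]]
  sf <- survival::survfit(survival::Surv(tm, st) ~ 1)
  i <- match(km$time, sf$time)
  expect_equal(km$surv, sf$surv[i], tolerance = 1e-10)
  expect_equal(km$se, sf$std.err[i] * sf$surv[i], tolerance = 1e-8)
})

test_that("KM on exponential data tracks the true survival curve", {
  set.seed(12)
  lam <- 0.1; n <- 3000
  tm <- rexp(n, lam)
  cens <- pmin(tm, 20)
  st <- as.integer(tm <= 20)
  km <- km_fit(data.frame(time = cens, event = st))[[1]]
  at <- c(2, 5, 10, 15)
  mc_se <- sqrt(exp(-lam * at) * (1 - exp(-lam * at)) / n)
  expect_true(all(abs(km_surv_at(km, at) - exp(-lam * at)) < 4 * mc_se))
})

test_that("fixed-effects Cox fit matches the analytic three-subject solution", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0),
                  unit = c("a", "b", "a"), seal_id = 1:3)
  f <- cox_fixed(d, reference_level = "b")
  expect_equal(unname(coef(f)), -log(2) / 2, tolerance = 1e-6)
  # the score vanishes and the observed information is positive at the MLE
  X <- matrix(c(1, 0, 1), ncol = 1)
  ev <- hauloutnet:::cox_eval(d$time, d$event, X, coef(f))
  expect_lt(abs(ev$score), 1e-6)
  expect_gt(ev$info[1, 1], 0)
})

test_that("degenerate covariates are rejected", {
  d <- data.frame(time = 1:4, event = c(1, 1, 0, 1), unit = "a",
                  seal_id = 1:4, weight_kg = 60)
  expect_error(cox_fixed(d), "zero variance|no covariates")
  d$weight_kg <- c(60, 61, 59, 62)
  expect_silent(cox_fixed(d))  # weight alone still identifies a model
})

test_that("a monotone partial likelihood raises a divergence error", {
  # the covariate level 'b' has no events at all: its MLE is -infinity
  d <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = c(1, 1, 1, 0, 0, 0),
                  unit = rep(c("a", "b"), each = 3), seal_id = 1:6)
  expect_error(cox_fixed(d, reference_level = "a"), "monotone")
})

test_that("Cox fit recovers a known hazard ratio on large simulated data", {
  set.seed(21)
  n <- 1500
  x <- rep(0:1, each = n / 2)
  tm <- rexp(n, 0.05 * 2^x)
  st <- as.integer(tm <= 40); tm <- pmin(tm, 40)
  d <- data.frame(time = tm, event = st, unit = ifelse(x == 1, "hi", "lo"),
                  seal_id = seq_len(n))
  f <- cox_fixed(d, reference_level = "lo")
  expect_equal(unname(coef(f)["unithi"]), log(2), tolerance = 0.12)
})

test_that("fixed-effects fit matches survival::coxph with Efron ties", {
  skip_if_not_installed("survival")
  set.seed(31)
  n <- 60
  unit <- sample(c("U1", "U2", "U3"), n, replace = TRUE)
  w <- rnorm(n, 65, 20)
  tm <- ceiling(rexp(n, 0.08 * ifelse(unit == "U1", 2, 1)))  # integer ties
  st <- rbinom(n, 1, 0.8)
  st[which.max(tm)] <- 0  # keep the largest time censored for stability
  d <- data.frame(time = tm, event = st, unit = unit, weight_kg = w,
                  seal_id = seq_len(n))
  f <- cox_fixed(d, reference_level = "U1")
  cp <- survival::coxph(
    survival::Surv(time, event) ~ stats::relevel(factor(unit), "U1") + weight_kg,
    data = d, ties = "efron")
  expect_equal(unname(coef(f)), unname(coef(cp)), tolerance = 1e-4)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(cp)))), tolerance = 1e-4)
})

test_that("the default reference level is the unit with the highest crossing rate", {
  d <- data.frame(time = c(1, 3, 4, 10, 2, 9), event = c(1, 0, 1, 0, 1, 0),
                  unit = rep(c("fast", "slow", "mid"), each = 2),
                  seal_id = 1:6)
  f <- cox_fixed(d)
  expect_equal(f$reference, "fast")
  expect_false("unitfast" %in% names(coef(f)))
})

test_that("frailty fit collapses to the fixed fit when heterogeneity is absent", {
  co <- simulate_cohort(recovery_config(n_seals = 30, sigma_b = 0, seed = 17))
  ri <- risk_intervals_from_cohort(co)
  fx <- cox_fixed(ri, reference_level = "U1")
  fr <- cox_frailty(ri, reference_level = "U1")
  expect_lt(max(abs(coef(fr) - coef(fx))), 0.05)
  expect_lt(fr$sigma2_b, 0.05)
})

test_that("frailty fit detects strong individual heterogeneity", {
  co <- simulate_cohort(recovery_config(n_seals = 60, sigma_b = 1, seed = 23))
  ri <- risk_intervals_from_cohort(co)
  fr <- cox_frailty(ri, reference_level = "U1")
  expect_gt(fr$sigma2_b, 0.2)
  expect_equal(length(ranef(fr)), length(unique(ri$seal_id)))
  # frailty modes correlate with the generator's true per-seal effects
  b_true <- co$seals$b[match(names(ranef(fr)), co$seals$seal_id)]
  expect_gt(cor(ranef(fr), b_true), 0.5)
})

test_that("median survival reads off the fitted curve", {
  d <- data.frame(time = c(5, 10, 15, 20, 25), event = c(0, 1, 1, 0, 1))
  expect_equal(median_survival(km_fit(d)[[1]]), 15)
  d2 <- data.frame(time = c(10, 20, 30), event = c(1, 0, 0))
  expect_true(is.na(median_survival(km_fit(d2)[[1]])))  # S stays at 2/3
})
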