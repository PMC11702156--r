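# Synthetic-data generation and the simulation-study drivers.

test_that("draw_design has the Toeplitz AR(1) correlation structure", {
  x0 <- draw_design(4000, 6, rho = 0, seed = 1)
  off <- cor(x0)[upper.tri(diag(6))]
  expect_lt(max(abs(off)), 4 / sqrt(4000))
  expect_lt(abs(mean(x0)), 0.05)
  expect_lt(abs(sd(as.vector(x0)) - 1), 0.05)

  x5 <- draw_design(4000, 6, rho = 0.5, seed = 2)
  c_mat <- cor(x5)
  lag1 <- mean(c_mat[cbind(1:5, 2:6)])
  lag2 <- mean(c_mat[cbind(1:4, 3:6)])
  expect_lt(abs(lag1 - 0.5), 3 / sqrt(4000) * 3)
  expect_lt(abs(lag2 - 0.25), 3 / sqrt(4000) * 3)
  # marginal variance stays 1 under the recursion
  expect_lt(max(abs(apply(x5, 2, sd) - 1)), 0.06)

  expect_identical(draw_design(10, 3, 0.5, seed = 7),
                   draw_design(10, 3, 0.5, seed = 7))
  expect_error(draw_design(10, 3, rho = 1), "rho")
})

test_that("empirical_snr follows its definition and scaling identities", {
  set.seed(21)
  x <- draw_design(300, 8)
  beta <- c(1, -0.5, rep(0, 6))
  expect_equal(empirical_snr(x, numeric(8)), 0)
  # linear: variance of the conditional means over noise variance 1
  expect_equal(empirical_snr(x, beta), var(as.vector(x %*% beta)))
  # exact quadratic scaling in the linear family
  for (k in c(0.3, 2, 7)) {
    expect_equal(empirical_snr(x, k * beta),
                 k^2 * empirical_snr(x, beta), tolerance = 1e-12)
  }
  # logistic: var(mu) / mean(mu (1 - mu))
  mu <- plogis(0.2 + as.vector(x %*% beta))
  expect_equal(empirical_snr(x, beta, 0.2, "logistic"),
               var(mu) / mean(mu * (1 - mu)))
})

test_that("linear SNR calibration is exact and fixed at k = 1 when on target", {
  set.seed(22)
  x <- draw_design(200, 10)
  raw <- numeric(10); raw[c(2, 5, 9)] <- c(0.4, -0.9, 0.3)
  for (target in c(0.005, 1, 10)) {
    cal <- calibrate_coefficients(x, raw, target, "linear")
    expect_equal(empirical_snr(x, cal$beta), target, tolerance = 1e-10)
    expect_equal(cal$intercept, 0)
  }
  current <- empirical_snr(x, raw)
  cal_fix <- calibrate_coefficients(x, raw, current, "linear")
  expect_equal(cal_fix$k, 1, tolerance = 1e-12)
  expect_error(calibrate_coefficients(x, numeric(10), 1), "no signal")
})

test_that("logistic SNR calibration solves the two-equation system", {
  set.seed(23)
  x <- draw_design(500, 20)
  raw <- numeric(20)
  act <- sample(20, 10)
  raw[act] <- runif(10, 0.25, 1) * sample(c(-1, 1), 10, TRUE)
  for (target in c(0.05, 0.5, 5)) {
    cal <- calibrate_coefficients(x, raw, target, "logistic")
    achieved <- empirical_snr(x, cal$beta, cal$intercept, "logistic")
    expect_lt(abs(achieved - target) / target, 1e-6)
    mu <- plogis(cal$intercept + as.vector(x %*% cal$beta))
    expect_lt(abs(mean(mu) - 0.5), 1e-6)
  }
})

test_that("draw_outcome matches the generating model", {
  set.seed(24)
  x <- draw_design(5000, 3)
  y0 <- draw_outcome(x, numeric(3), 0, "logistic", seed = 5)
  expect_lt(abs(mean(y0) - 0.5), 3 * 0.5 / sqrt(5000))
  yl <- draw_outcome(x, numeric(3), 0, "linear", seed = 5)
  expect_gt(shapiro.test(yl[1:4999])$p.value, 1e-4)
  expect_lt(abs(sd(yl) - 1), 0.05)
  expect_identical(draw_outcome(x, c(1, 0, 0), 0, "linear", seed = 9),
                   draw_outcome(x, c(1, 0, 0), 0, "linear", seed = 9))
})

test_that("selection_metrics counts errors and recoveries", {
  active <- paste0("X", 1:10)
  m <- selection_metrics(active, active, 10)
  expect_false(m$fp_event); expect_equal(m$fdp, 0); expect_equal(m$sensitivity, 1)
  m0 <- selection_metrics(character(), active, 10)
  expect_false(m0$fp_event); expect_equal(m0$fdp, 0); expect_equal(m0$sensitivity, 0)
  m1 <- selection_metrics(c(active, "X99"), active, 10)
  expect_true(m1$fp_event)
  expect_equal(m1$fdp, 1 / 11)
  expect_equal(m1$sensitivity, 1)
})

test_that("null study FWER tracks the analytic asymptotic value", {
  res <- run_null_study("linear", n = 1000, p = 100, rho = 0, alpha = 0.05,
                        reps = 400, seed = 10)
  se <- sqrt(res$fwer_asymptotic * (1 - res$fwer_asymptotic) / res$reps)
  expect_lt(abs(res$fwer - res$fwer_asymptotic), 3 * max(se, res$fwer_se))
  expect_equal(res$reps, 400)
  # reproducible under the master seed
  res2 <- run_null_study("linear", n = 1000, p = 100, rho = 0, alpha = 0.05,
                         reps = 400, seed = 10)
  expect_equal(res$fwer, res2$fwer)
})

test_that("null study at the simplest-form level has FWER near alpha0", {
  a0 <- alpha_null_cancel()
  res <- run_null_study("linear", n = 500, p = 500, rho = 0, alpha = a0,
                        reps = 200, seed = 12)
  analytic <- asymptotic_fwer(500, critical_bound(500, a0))
  expect_lt(abs(res$fwer - analytic), 3 * sqrt(analytic * (1 - analytic) / 200))
})

test_that("full study is deterministic and ranks methods by conservativeness", {
  methods <- list(criterion("AIC"), criterion("BIC"),
                  criterion("EAIC", alpha = 0.5),
                  criterion("EAIC", alpha = 0.05))
  res <- run_full_study("linear", n = 400, p = 50, rho = 0, snr = 1,
                        n_active = 10, reps = 40, seed = 20,
                        methods = methods)
  expect_equal(nrow(res), 5) # four criteria + oracle
  fw <- setNames(res$fwer, res$method)
  noise <- 3 * sqrt(0.25 / 40)
  expect_gte(fw["AIC"], fw["BIC"] - noise)
  expect_gte(fw["BIC"], fw["EAIC(alpha=0.5)"] - noise)
  expect_gte(fw["EAIC(alpha=0.5)"], fw["EAIC(alpha=0.05)"] - noise)
  expect_true(all(res$fwer >= res$fdr - 1e-12 | res$fdr <= 1))
  expect_true(all(res$sensitivity >= 0 & res$sensitivity <= 1))
  res2 <- run_full_study("linear", n = 400, p = 50, rho = 0, snr = 1,
                         n_active = 10, reps = 40, seed = 20,
                         methods = methods)
  expect_equal(res$fwer, res2$fwer)
  expect_equal(res$mean_tp, res2$mean_tp)
})

test_that("oracle recovers all active variables in favorable settings", {
  res <- run_full_study("linear", n = 1000, p = 100, rho = 0, snr = 5,
                        n_active = 10, reps = 40, seed = 30,
                        methods = list(criterion("EAIC", alpha = 0.05)))
  orc <- res[res$method == "oracle", ]
  expect_gte(orc$sensitivity, 0.95)
  expect_lte(orc$fwer, 0.1)
})

test_that("sensitivity is nondecreasing in SNR for the EAIC", {
  sens <- vapply(c(0.1, 1, 5), function(s) {
    res <- run_full_study("linear", n = 300, p = 40, rho = 0, snr = s,
                          n_active = 10, reps = 25, seed = 40,
                          methods = list(criterion("EAIC", alpha = 0.05)),
                          include_oracle = FALSE)
    res$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) > -0.1)) # monotone up to Monte-Carlo noise
})

test_that("study results plot and bind into panels", {
  res <- dplyr::bind_rows(lapply(c(0.5, 2), function(s) {
    run_full_study("linear", n = 200, p = 20, rho = 0, snr = s,
                   n_active = 5, reps = 5, seed = 50,
                   methods = list(criterion("AIC")))
  }))
  class(res) <- c("eaic_study", class(res))
  expect_s3_class(autoplot(res, "fwer"), "ggplot")
  expect_s3_class(autoplot(res, "sensitivity"), "ggplot")
})
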