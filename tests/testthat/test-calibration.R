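test_that("observable mapping picks the free species and interpolates", {
  traj <- integrate_network(tube_network(), tube_initial(),
                            times = seq(0, 5000, by = 50))
  obs <- predict_observables(traj, times = 0)
  expect_equal(unname(obs[1, ]), c(20, 0, 0, 5))
  # long-time limit: all substrate converted to propyl acetate, precursor
  # fully consumed
  obs_end <- predict_observables(traj, times = 5000)
  expect_equal(unname(obs_end[1, ]), c(0, 0, 20, 0), tolerance = 0.02)
  # interpolation lands between grid values
  mid <- predict_observables(traj, times = 25)
  expect_true(mid[1, "propargyl"] < 20 && mid[1, "propargyl"] > 0)
  expect_error(predict_observables(traj, times = 6000), "span")
  # an all-zero trajectory maps to all-zero observables
  net0 <- build_network(c(k1 = 0))
  traj0 <- integrate_network(net0, phip_state(), c(0, 10))
  expect_true(all(predict_observables(traj0) == 0))
})

test_that("noiseless parameter recovery is accurate to <1%", {
  ds <- generate_tube_timeseries(noise_sd = 0, seed = 1)
  fit <- fit_rate_constants(ds)
  truth <- calibrated_rate_constants()[1:5]
  expect_lt(max(abs(fit$estimates - truth) / truth), 0.01)
  # each estimate lies inside its own confidence interval
  expect_true(all(fit$ci$lower <= fit$ci$estimate &
                    fit$ci$estimate <= fit$ci$upper))
  # covariance symmetric positive semidefinite
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  # objective at the estimate does not exceed the objective at the guess
  guess <- rep(0.01, 5)
  pred_g <- phipflow:::.predict_dataset(stats::setNames(guess, paste0("k", 1:5)), ds)
  wrss_guess <- sum(((pred_g - ds$observables) / ds$sigma)^2)
  expect_lte(fit$wrss, wrss_guess)
})

test_that("starting at the truth is a fixed point of the fit", {
  ds <- generate_tube_timeseries(noise_sd = 0, seed = 1)
  fit <- fit_rate_constants(ds, initial_guess = calibrated_rate_constants()[1:5])
  expect_lt(fit$wrss, 1e-6)
  expect_lte(fit$niter, 2)
})

test_that("fit validates its inputs", {
  ds <- generate_tube_timeseries(noise_sd = 0, seed = 1)
  short <- phip_dataset(ds$times[1:3], ds$observables[1:3, ], 0.3)
  expect_error(fit_rate_constants(short), "5 time points")
  zero <- phip_dataset(ds$times, 0 * ds$observables, 0.3)
  expect_error(fit_rate_constants(zero), "singular")
  expect_error(fit_rate_constants(ds, initial_guess = rep(20, 5)), "bounds")
})

test_that("confidence intervals follow the normal-quantile arithmetic", {
  fake <- structure(
    list(estimates = c(k1 = 0.0015), se = c(k1 = 5e-4),
         covariance = matrix(25e-8, 1, 1), degenerate = FALSE),
    class = "phip_fit")
  ci <- confidence_intervals(fake, 0.95)
  expect_equal(ci$lower, 0.0015 - qnorm(0.975) * 5e-4)
  expect_equal(ci$upper, 0.0015 + qnorm(0.975) * 5e-4)
  expect_equal(ci$upper, 0.0025, tolerance = 0.02)
  expect_equal(ci$lower, 0.0005, tolerance = 0.1)
  # width monotone in level
  w <- vapply(c(0.5, 0.8, 0.95, 0.99),
              function(l) diff(unlist(confidence_intervals(fake, l)[, c("lower", "upper")])),
              0)
  expect_true(all(diff(w) > 0))
  # zero covariance: zero width, flagged
  degen <- structure(
    list(estimates = c(k1 = 0.0015), se = c(k1 = 0),
         covariance = matrix(0, 1, 1), degenerate = FALSE),
    class = "phip_fit")
  cid <- confidence_intervals(degen)
  expect_equal(cid$lower, cid$upper)
  expect_true(attr(cid, "degenerate"))
})

test_that("dataset CSV round-trips and fitting is order invariant", {
  ds <- generate_tube_timeseries(noise_sd = 0.5, seed = 7)
  f <- tempfile(fileext = ".csv")
  write_dataset_csv(ds, f)
  back <- read_dataset_csv(f)
  expect_equal(back$observables, ds$observables)
  expect_equal(back$sigma, ds$sigma)
  # shuffle the CSV rows: the reconstructed dataset and fit are unchanged
  df <- utils::read.csv(f)
  set.seed(3)
  utils::write.csv(df[sample(nrow(df)), ], f, row.names = FALSE)
  shuffled <- read_dataset_csv(f)
  expect_equal(shuffled$observables, ds$observables)
  fit1 <- fit_rate_constants(back)
  fit2 <- fit_rate_constants(shuffled)
  expect_identical(fit1$estimates, fit2$estimates)
  unlink(f)
})

test_that("fit JSON export carries estimates, intervals and covariance", {
  ds <- generate_tube_timeseries(noise_sd = 0, seed = 1)
  fit <- fit_rate_constants(ds, initial_guess = calibrated_rate_constants()[1:5])
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(unlist(obj$estimates), fit$estimates)
  expect_equal(dim(obj$covariance), c(5L, 5L))
  unlink(f)
})
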