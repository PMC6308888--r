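test_that("occupancy NLL matches hand-evaluated site terms", {
  spec <- model_spec(~1, ~1, "occupancy")

  # certain event: history [1,1] with psi = p = 1 (logit +40)
  d <- make_binary_data(matrix(c(1, 1), 1, 2))
  expect_equal(occu_negloglik(c(40, 40), d, spec), 0, tolerance = 1e-9)

  # zero-inflation: history [0,0] with psi = 0 gives likelihood 1
  d0 <- make_binary_data(matrix(c(0, 0), 1, 2))
  expect_equal(occu_negloglik(c(-40, 0), d0, spec), 0, tolerance = 1e-9)

  # two sites, psi = p = 0.5: -(ln 0.125 + ln 0.625)
  d2 <- make_binary_data(rbind(c(1, 0), c(0, 0)))
  expect_equal(occu_negloglik(c(0, 0), d2, spec),
               -(log(0.125) + log(0.625)), tolerance = 1e-10)

  # general agreement with the direct double-loop oracle, incl. missing visits
  set.seed(31)
  for (rep in 1:20) {
    y <- matrix(rbinom(24, 1, 0.4), 6, 4)
    y[sample(24, 3)] <- NA
    psi <- runif(1, 0.05, 0.95); p <- runif(1, 0.05, 0.95)
    expect_equal(
      occu_negloglik(c(qlogis(psi), qlogis(p)), make_binary_data(y), spec),
      occu_nll_direct(y, psi, p), tolerance = 1e-10)
  }
})

test_that("all-detection data makes the NLL monotone decreasing in psi and p", {
  d <- make_binary_data(matrix(1, 5, 3))
  spec <- model_spec(~1, ~1, "occupancy")
  grid <- qlogis(seq(0.1, 0.9, by = 0.1))
  for (b_p in grid) {
    vals <- vapply(grid, function(b) occu_negloglik(c(b, b_p), d, spec),
                   numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  for (b_psi in grid) {
    vals <- vapply(grid, function(b) occu_negloglik(c(b_psi, b), d, spec),
                   numeric(1))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("likelihood is invariant to site order and visit permutation", {
  covs <- simulate_covariates(15, 4, seed = 3)
  sim <- simulate_occupancy_data(c(`(Intercept)` = 0.3, MST = 0.5),
                                 c(`(Intercept)` = -0.4), covs, seed = 4)
  d <- sim$dataset
  spec <- model_spec(~MST, ~1, "occupancy")
  par <- c(0.2, 0.5, -0.4)
  base <- occu_negloglik(par, d, spec)

  ord <- sample(15)
  d_s <- survey_data(d$y[ord, ], site_covs = d$site_covs[ord, , drop = FALSE],
                     visit_covs = lapply(d$visit_covs, function(m) m[ord, ]),
                     mode = "binary", site_ids = d$site_ids[ord])
  expect_equal(occu_negloglik(par, d_s, spec), base, tolerance = 1e-12)

  # visit permutation with visit-constant detection covariates
  vp <- c(4, 2, 1, 3)
  d_v <- survey_data(d$y[, vp], site_covs = d$site_covs,
                     visit_covs = lapply(d$visit_covs, function(m) m[, vp]),
                     mode = "binary", site_ids = d$site_ids)
  expect_equal(occu_negloglik(par, d_v, spec), base, tolerance = 1e-12)
})

test_that("intercept-only MLE matches a two-stage brute-force grid search", {
  set.seed(1)
  y <- matrix(rbinom(40, 1, 0.5), 10, 4)
  y[1:3, ] <- 0           # all-zero histories keep the optimum interior
  d <- make_binary_data(y)
  fit <- fit_occupancy(d, model_spec(~1, ~1, "occupancy"), seed = 5)
  oracle <- grid_minimize(function(q) occu_nll_direct(y, q$psi, q$p),
                          axes = list(psi = c(0.01, 0.99), p = c(0.01, 0.99)),
                          points = 25L, stages = 4L)
  expect_equal(plogis(unname(coef(fit)[1])), unname(oracle$par["psi"]),
               tolerance = 1e-3)
  expect_equal(plogis(unname(coef(fit)[2])), unname(oracle$par["p"]),
               tolerance = 1e-3)
  expect_equal(-fit$loglik, oracle$value, tolerance = 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$K)
  expect_equal(fit$aicc, fit$aic + 2 * 2 * 3 / (10 - 2 - 1))
})

test_that("with no all-zero histories and psi at 1, the p MLE is the raw frequency", {
  set.seed(12)
  y <- matrix(rbinom(60, 1, 0.5), 15, 4)
  y[rowSums(y) == 0, 1] <- 1
  phat <- mean(y)
  d <- make_binary_data(y)
  spec <- model_spec(~1, ~1, "occupancy")
  at <- function(p) occu_negloglik(c(40, qlogis(p)), d, spec)
  expect_lt(at(phat), at(phat + 0.01))
  expect_lt(at(phat), at(phat - 0.01))
})

test_that("saturated detection data is boundary-flagged", {
  d <- make_binary_data(matrix(1, 8, 3))
  fit <- suppressWarnings(fit_occupancy(d, seed = 2))
  expect_true(fit$boundary)
  expect_gt(plogis(coef(fit)[1]), 0.95)
  expect_gt(plogis(coef(fit)[2]), 0.95)
})

test_that("predictions back-transform the linear predictor with delta-method CIs", {
  d <- make_binary_data(matrix(c(0, 1), 1, 2),
                        site_covs = data.frame(MST = 0))
  fit <- manual_occu_fit(c(psi_int = 0, psi_MST = 1), c(p_int = 0), d,
                         vcov = diag(3),
                         spec = model_spec(~MST, ~1, "occupancy"))
  pr <- predict(fit, grid = data.frame(MST = 1))
  z <- qnorm(0.975)
  expect_equal(pr$estimate, plogis(1), tolerance = 1e-12)
  expect_equal(pr$se_link, sqrt(2), tolerance = 1e-12)
  expect_equal(pr$lower, plogis(1 - z * sqrt(2)), tolerance = 1e-12)
  expect_equal(pr$upper, plogis(1 + z * sqrt(2)), tolerance = 1e-12)

  # grid at the training mean (standardized 0) recovers the intercept
  pr0 <- predict(fit, grid = data.frame(MST = 0))
  expect_equal(pr0$estimate, plogis(0))

  # zero coefficient -> flat curve
  fit2 <- manual_occu_fit(c(psi_int = 0.4, psi_MST = 0), c(p_int = 0), d,
                          vcov = diag(3),
                          spec = model_spec(~MST, ~1, "occupancy"))
  pr2 <- predict(fit2, grid = data.frame(MST = seq(-2, 2, by = 0.5)))
  expect_true(all(abs(pr2$estimate - plogis(0.4)) < 1e-12))

  # monotone in a covariate with positive coefficient
  pr3 <- predict(fit, grid = data.frame(MST = seq(-2, 2, by = 0.5)))
  expect_true(all(diff(pr3$estimate) > 0))

  # extraneous grid covariate errors
  expect_error(predict(fit, grid = data.frame(ELV = 1)), "absent")

  # raw-scale grid goes through the standardization record
  rec <- structure(data.frame(covariate = "MST", mean = 14, sd = 3),
                   class = c("standardization_record", "data.frame"))
  pr4 <- predict(fit, grid = data.frame(MST = 17), record = rec)
  expect_equal(pr4$estimate, plogis(1), tolerance = 1e-12)
})

test_that("fit serializes to JSON with the full inference record", {
  set.seed(8)
  d <- make_binary_data(matrix(rbinom(40, 1, 0.5), 10, 4))
  fit <- fit_occupancy(d, seed = 2)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$loglik, fit$loglik)
  expect_equal(js$aicc, fit$aicc)
  expect_equal(unlist(js$estimates), unlist(fit$estimates),
               tolerance = 1e-12)
  expect_true(is.matrix(js$vcov))
})
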