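# Minimal hand-built fits with controlled criterion values and coefficients,
# so weights and averaged effects can be checked against hand arithmetic.
fake_fit <- function(aicc, beta = NULL, se = NULL, n_sites = 40,
                     formula = ~1, loglik = -10) {
  est <- c(`psi_(Intercept)` = 0)
  vc <- matrix(0.1, 1, 1, dimnames = list(names(est), names(est)))
  if (!is.null(beta)) {
    est <- c(est, psi_X = beta)
    vc <- diag(c(0.1, se^2))
    dimnames(vc) <- list(names(est), names(est))
  }
  structure(list(spec = model_spec(formula, ~1, "occupancy"),
                 estimates = est, vcov = vc, loglik = loglik,
                 K = length(est), n_sites = n_sites,
                 aic = aicc, aicc = aicc, converged = TRUE,
                 boundary = FALSE, n_state = length(est) - 0, n_det = 0),
            class = c("occu_fit", "salocc_fit"))
}

test_that("Akaike weights follow the exponential-delta formula, stably", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))

  set.seed(2)
  for (rep in 1:20) {
    v <- runif(sample(2:10, 1), 0, 5000)
    w <- akaike_weights(v)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # invariant to adding a constant
    expect_equal(akaike_weights(v + 123.4), w, tolerance = 1e-12)
  }
  # numerically stable for huge deltas
  expect_equal(akaike_weights(c(0, 4000)), c(1, 0))
  expect_error(akaike_weights(c(1, NaN)), "finite")
})

test_that("rank table orders by criterion with stable ties", {
  fits <- list(a = fake_fit(12), b = fake_fit(10), c = fake_fit(20))
  tab <- rank_table(model_set(fits))
  expect_equal(tab$model, c("b", "a", "c"))
  expect_equal(tab$delta, c(0, 2, 10))
  expect_equal(tab$weight, akaike_weights(c(10, 12, 20))[order(c(10, 12, 20))],
               tolerance = 1e-12)
  expect_equal(tab$cum_weight[3], 1, tolerance = 1e-12)

  one <- rank_table(model_set(list(only = fake_fit(5))))
  expect_equal(one$delta, 0)
  expect_equal(one$weight, 1)

  tie <- rank_table(model_set(list(first = fake_fit(7), second = fake_fit(7))))
  expect_equal(tie$model, c("first", "second"))
  expect_equal(tie$weight, c(0.5, 0.5))
})

test_that("cumulative weights partition the set", {
  fits <- list(m1 = fake_fit(10), m2 = fake_fit(10), m3 = fake_fit(10))
  set <- model_set(fits)
  expect_equal(cumulative_weight(set, function(f) TRUE), 1)
  expect_equal(cumulative_weight(set, function(f) FALSE), 0)
  expect_equal(cumulative_weight(set, c("m1", "m3")), 2 / 3, tolerance = 1e-12)
  pred <- function(f) f$K > 1
  expect_equal(cumulative_weight(set, pred) +
                 cumulative_weight(set, Negate(pred)), 1, tolerance = 1e-12)
})

test_that("model-averaged beta reproduces the revised-estimator arithmetic", {
  # weights 0.6 / 0.4 via aicc gap 2*log(1.5)
  fits <- list(m1 = fake_fit(100, beta = 1.0, se = 0.5, formula = ~X),
               m2 = fake_fit(100 + 2 * log(1.5), beta = 2.0, se = 0.5,
                             formula = ~X))
  set <- model_set(fits)
  expect_equal(unname(set$weights), c(0.6, 0.4), tolerance = 1e-12)
  eff <- model_average_beta(set, "X")
  expect_equal(eff$beta_bar, 1.4, tolerance = 1e-12)
  expect_equal(eff$se, 0.70, tolerance = 1e-12)
  expect_equal(eff$ci50, 1.4 + c(-1, 1) * 0.674 * 0.7, tolerance = 1e-12)
  expect_equal(eff$ci95, 1.4 + c(-1, 1) * 1.96 * 0.7, tolerance = 1e-12)
  expect_true(eff$important)   # CI95 = (0.028, 2.772) excludes 0
  # 50% CI nested in 95% CI
  expect_true(eff$ci50[1] > eff$ci95[1] && eff$ci50[2] < eff$ci95[2])

  # single containing model: beta and conditional SE pass through
  single <- model_set(list(m = fake_fit(10, beta = 0.8, se = 0.3,
                                        formula = ~X)))
  e1 <- model_average_beta(single, "X")
  expect_equal(e1$beta_bar, 0.8)
  expect_equal(e1$se, 0.3, tolerance = 1e-12)

  # identical betas and SEs across models: averaging changes nothing
  same <- model_set(list(a = fake_fit(10, 1.2, 0.4, formula = ~X),
                         b = fake_fit(11, 1.2, 0.4, formula = ~X)))
  e2 <- model_average_beta(same, "X")
  expect_equal(e2$beta_bar, 1.2, tolerance = 1e-12)
  expect_equal(e2$se, 0.4, tolerance = 1e-12)

  # shrinkage scope zeroes the absent models
  mixed <- model_set(list(with = fake_fit(10, 1.0, 0.5, formula = ~X),
                          without = fake_fit(10)))
  e3 <- model_average_beta(mixed, "X", scope = "all_models_shrinkage")
  expect_equal(e3$beta_bar, 0.5, tolerance = 1e-12)
  e4 <- model_average_beta(mixed, "X", scope = "containing_models")
  expect_equal(e4$beta_bar, 1.0, tolerance = 1e-12)

  expect_error(model_average_beta(set, "NOPE"), "no model")
})

test_that("model-averaged predictions stay in the link-scale convex hull", {
  set.seed(3)
  covs <- simulate_covariates(80, 4, seed = 3)
  sim <- simulate_occupancy_data(c(`(Intercept)` = 0.4, MST = 0.7),
                                 c(`(Intercept)` = -0.3), covs, seed = 4)
  std <- standardize_covariates(sim$dataset)
  f1 <- fit_occupancy(std$data, model_spec(~1, ~1, "occupancy"), seed = 5)
  f2 <- fit_occupancy(std$data, model_spec(~MST, ~1, "occupancy"), seed = 5)
  set2 <- model_set(list(null = f1, mst = f2))
  grid <- data.frame(MST = seq(-1.5, 1.5, length.out = 7))
  avg <- model_average_predictions(set2, grid, type = "state")
  p1 <- predict(f1, grid = NULL)
  p2 <- predict(f2, grid = grid)
  eta1 <- qlogis(p1$estimate); eta2 <- qlogis(p2$estimate)
  eta_avg <- qlogis(avg$estimate)
  expect_true(all(eta_avg >= pmin(eta1, eta2) - 1e-9))
  expect_true(all(eta_avg <= pmax(eta1, eta2) + 1e-9))
  # unconditional SE at least the weighted within-model floor
  expect_true(all(avg$se_link^2 + 1e-12 >=
                    set2$weights[1] * p1$se_link^2 +
                    set2$weights[2] * p2$se_link^2))
  expect_true(all(avg$lower <= avg$estimate & avg$estimate <= avg$upper))

  # single-model set: identical to the model's own prediction
  solo <- model_average_predictions(model_set(list(m = f2)), grid)
  expect_equal(solo$estimate, p2$estimate, tolerance = 1e-12)
  expect_equal(solo$se_link, p2$se_link, tolerance = 1e-12)
})

test_that("averaging two intercept-only fits reports link-scale and response means", {
  mk <- function(psi) {
    est <- c(`psi_(Intercept)` = qlogis(psi))
    structure(list(spec = model_spec(~1, ~1, "occupancy"), estimates = est,
                   vcov = matrix(0.04, 1, 1,
                                 dimnames = list(names(est), names(est))),
                   loglik = -5, K = 1, n_sites = 40, aic = 100, aicc = 100,
                   converged = TRUE, boundary = FALSE, n_state = 1,
                   n_det = 0),
              class = c("occu_fit", "salocc_fit"))
  }
  set2 <- model_set(list(a = mk(0.6), b = mk(0.8)))
  avg <- model_average_predictions(set2, response_scale_average = TRUE)
  expect_equal(avg$estimate, plogis((qlogis(0.6) + qlogis(0.8)) / 2),
               tolerance = 1e-12)
  expect_equal(avg$estimate_response_avg, 0.7, tolerance = 1e-12)
  # identical predictions -> no between-model variance added
  same <- model_set(list(a = mk(0.6), b = mk(0.6)))
  avg2 <- model_average_predictions(same)
  expect_equal(avg2$se_link, 0.2, tolerance = 1e-12)
})

test_that("effect plot returns the plotted table", {
  fits <- list(m1 = fake_fit(100, 1.0, 0.5, formula = ~X),
               m2 = fake_fit(101, 2.0, 0.5, formula = ~X))
  eff <- model_average_beta(model_set(fits), "X")
  png_file <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_file)
  df <- plot_averaged_effects(list(eff))
  grDevices::dev.off()
  expect_equal(df$beta, eff$beta_bar)
  expect_true(file.exists(png_file))
})
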