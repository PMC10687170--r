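# Fitting the behavioral model: weights, predictions, grid search,
# baseline comparison, and fit metrics.

test_that("least-squares weights reproduce fitted values and intercepts", {
  set.seed(3)
  n <- 60
  X <- cbind(const = 1, a = rnorm(n), b = rnorm(n))
  w_true <- c(1, 2, -0.5)
  y <- as.vector(X %*% w_true)
  f <- fit_weights(X, y)
  expect_equal(f$fitted, y, tolerance = 1e-8)
  expect_equal(f$noise_var, 0, tolerance = 1e-12)

  # constant response: intercept picks it up exactly
  f2 <- fit_weights(matrix(1, 20, 1, dimnames = list(NULL, "const")),
                    rep(3.5, 20))
  expect_equal(unname(f2$weights), 3.5, ignore_attr = TRUE)

  # full-rank noisy case agrees with the normal-equations oracle
  y2 <- y + rnorm(n, 0, 0.3)
  f3 <- fit_weights(X, y2)
  oracle <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(unname(f3$weights), as.vector(oracle), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-deficient one-hot designs get minimum-norm weights", {
  set.seed(4)
  n <- 50
  g <- sample(c("u", "v"), n, replace = TRUE)
  X <- cbind(const = 1, u = (g == "u") * 1, v = (g == "v") * 1)
  y <- ifelse(g == "u", 1, 3) + rnorm(n, 0, 0.1)
  f <- fit_weights(X, y)
  # fitted values match the cell means regardless of the coding freedom
  expect_equal(f$fitted, ave(y, g), tolerance = 1e-8)
  # minimum-norm solution matches the pseudo-inverse oracle
  expect_equal(unname(f$weights), as.vector(MASS::ginv(X) %*% y),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("point predictions evaluate the two linear equations", {
  fit <- list(
    rt_weights = c(const = 0.1, x_se = 0.5, x_p = -0.2,
                   speed_fast = 0.3, speed_slow = -0.3,
                   dir_down = 0.05, dir_right = 0, dir_up = -0.05,
                   dir_left = 0.1),
    se_weights = c(const = -0.02, x_se = 0.1, x_p = 0.05, rt = 0.2,
                   fast.unperturbed = 0.01, fast.towards = 0.02,
                   fast.away = 0.03, slow.unperturbed = -0.01,
                   slow.towards = -0.02, slow.away = -0.03))
  tr <- trial_table("s", "fast", "up", "towards", 0.5, 0.1,
                    perturb_force = 5, perturb_angle = 0)
  p <- predict_behavior(tr[1, ], x_se_z = 1.5, x_p_z = -0.5, fit)
  rt_expect <- 0.1 + 0.5 * 1.5 + (-0.2) * (-0.5) + 0.3 + (-0.05)
  expect_equal(p$rt_z, rt_expect, tolerance = 1e-12)
  expect_equal(p$se, -0.02 + 0.1 * 1.5 + 0.05 * (-0.5) + 0.2 * rt_expect +
                 0.02, tolerance = 1e-12)

  # all-zero weights -> null prediction; constant-only -> the constant
  fit0 <- lapply(fit, function(w) w * 0)
  p0 <- predict_behavior(tr[1, ], 1, 1, fit0)
  expect_equal(unlist(p0), c(rt_z = 0, se = 0))
  fitc <- fit0
  fitc$rt_weights["const"] <- 1
  expect_equal(predict_behavior(tr[1, ], 2, -3, fitc)$rt_z, 1)
})

test_that("grid search spans 99 x 99 decay values and recovers noiseless truth", {
  sp <- generator_spec(n_trials = 120, seed = 11,
                       noise_sd_rt = 0, noise_sd_se = 0)
  sim <- simulate_session(sp)
  fit <- grid_search_fit(sim$trials)
  expect_length(fit$grid$alphas, 99)
  expect_equal(range(fit$grid$alphas), c(0.01, 0.99))
  expect_equal(fit$params$alpha_se, 0.30)
  expect_equal(fit$params$alpha_p, 0.70)
  expect_equal(fit$metrics$pearson_rt, 1, tolerance = 1e-6)
  expect_equal(fit$metrics$pearson_se, 1, tolerance = 1e-6)
})

test_that("both selection criteria agree on clean data", {
  sp <- generator_spec(n_trials = 150, seed = 12)
  sim <- simulate_session(sp)
  f_r <- grid_search_fit(sim$trials, criterion = "rmse")
  f_p <- grid_search_fit(sim$trials, criterion = "pearson")
  expect_lte(abs(f_r$params$alpha_se - f_p$params$alpha_se), 0.15)
  expect_s3_class(f_p, "behavior_fit")
})

test_that("perturbation-free sessions fit without NaN propagation", {
  sp <- generator_spec(n_trials = 80, p_perturb = 0, seed = 5)
  sim <- simulate_session(sp)
  fit <- grid_search_fit(sim$trials)
  expect_equal(fit$states$x_p_raw, rep(0, sum(sim$trials$completed)))
  expect_false(any(is.na(unlist(fit$rt_weights))))
  expect_false(any(is.na(fit$rt_estimate)))
  # the perturbed-state column is flagged non-identifiable
  expect_false(attr(fit$rt_weights, "identifiable")[["x_p"]])
})

test_that("fit metrics match an independent formula oracle", {
  sp <- generator_spec(n_trials = 100, seed = 21)
  sim <- simulate_session(sp)
  fit <- grid_search_fit(sim$trials)
  comp <- sim$trials[sim$trials$completed, ]
  rt_z <- (comp$rt_seconds - fit$rt_center) / fit$rt_scale
  r2_oracle <- 1 - sum((rt_z - fit$rt_estimate)^2) /
    sum((rt_z - mean(rt_z))^2)
  expect_equal(fit$metrics$r2_rt, r2_oracle, tolerance = 1e-10)
  expect_equal(fit$metrics$deviance_rt, sum((rt_z - fit$rt_estimate)^2),
               tolerance = 1e-10)
  expect_equal(fit$metrics$pearson_rt, cor(rt_z, fit$rt_estimate),
               tolerance = 1e-10)
  # perfect fit: R2 = 1, deviance = 0
  sp0 <- generator_spec(n_trials = 60, seed = 2,
                        noise_sd_rt = 0, noise_sd_se = 0)
  f0 <- grid_search_fit(simulate_session(sp0)$trials)
  expect_equal(f0$metrics$r2_rt, 1, tolerance = 1e-6)
  expect_equal(f0$metrics$deviance_rt, 0, tolerance = 1e-6)
})

test_that("baseline model equals the full model when states are inert", {
  # states all zero (no perturbations, constant SE) -> identical fits
  tt <- trial_table("s", rep(c("fast", "slow"), 20),
                    rep(c("down", "right", "up", "left"), 10),
                    rep("unperturbed", 40),
                    rt_seconds = 0.8 + 0.1 * sin(1:40),
                    speed_error = 0)
  full <- statereach:::finalize_fit(tt, state_params(0.5, 0.5))
  base <- fit_baseline(tt)
  expect_equal(full$rt_estimate, base$rt_estimate, tolerance = 1e-8)
})

test_that("reference-coded refit yields confidence intervals", {
  sp <- generator_spec(n_trials = 120, seed = 9)
  sim <- simulate_session(sp)
  fit <- grid_search_fit(sim$trials)
  rf <- reference_fit(fit, sim$trials)
  expect_true(all(c("x_se", "x_p") %in% rownames(rf$rt$ci)))
  expect_true(all(rf$rt$ci[, 1] <= rf$rt$ci[, 2]))
})

test_that("grid search demands enough completed trials", {
  tt <- tiny_trials(12)
  expect_error(grid_search_fit(tt), ">= 20")
})
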