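test_that("dataset validation enforces the tidy schema", {
  syn <- make_clean_synthetic(duration_h = 24)
  df <- as.data.frame(syn$dataset)
  expect_s3_class(timecourse_dataset(df), "ferrodyn_dataset")
  expect_error(timecourse_dataset(df[, -3]), class = "ferrodyn_schema_error")
  bad <- df; bad$observable[1] <- "mystery_signal"
  expect_error(timecourse_dataset(bad), class = "ferrodyn_schema_error")
  bad <- df; bad$time_h[1] <- -2
  expect_error(timecourse_dataset(bad), class = "ferrodyn_schema_error")
  bad <- df; bad$value[bad$observable == "confluence_pct"][1] <- 150
  expect_error(timecourse_dataset(bad), class = "ferrodyn_schema_error")
})

test_that("fit specification rejects invalid and unidentifiable setups", {
  expect_error(fit_spec(free = "gamma"), class = "ferrodyn_invalid_input")
  expect_error(fit_spec(free = c("a", "ros_scale")),
               class = "ferrodyn_invalid_input")  # confounded product
  expect_error(fit_spec(condition_specific = "r0", free = c("alpha", "K")),
               class = "ferrodyn_invalid_input")
  expect_error(fit_spec(multistart = 0), class = "ferrodyn_invalid_input")
  expect_error(fit_spec(bounds = list(alpha = c(1, 0.1))),
               class = "ferrodyn_invalid_input")
  s <- fit_spec(free = c("a"), fixed = list(ros_scale = 0.5))
  expect_s3_class(s, "ferrodyn_fit_spec")
})

test_that("residuals vanish on self-generated data and scale linearly in weights", {
  syn <- make_clean_synthetic(duration_h = 36)
  p <- syn$true_params[[1]]
  obs <- syn$obs
  w1 <- c(confluence_pct = 1, lipid_ros_ratio = 1, dead_per_confluence = 1)
  r1 <- wls_residuals(p, obs, syn$dataset, weights = w1)
  expect_length(r1, nrow(syn$dataset))
  expect_lt(max(abs(r1)), 1e-7)
  ## linearity in the weights on perturbed parameters
  p2 <- update_params(p, alpha = p$alpha * 1.2)
  ra <- wls_residuals(p2, obs, syn$dataset, weights = w1)
  rb <- wls_residuals(p2, obs, syn$dataset, weights = 2 * w1)
  expect_equal(rb, 2 * ra)
  ## RSS equals a brute-force record loop
  w <- make_weights(syn$dataset)
  r <- wls_residuals(p2, obs, syn$dataset, weights = w)
  pred <- predict_observables(p2, obs,
                              model_state(0.22, 0),
                              sort(unique(syn$dataset$time_h)))
  rss_naive <- 0
  for (i in seq_len(nrow(syn$dataset))) {
    row <- syn$dataset[i, ]
    pv <- pred[[row$observable]][pred$time_h == row$time_h]
    rss_naive <- rss_naive + (w[i] * (row$value - pv))^2
  }
  expect_equal(sum(r^2), rss_naive, tolerance = 1e-10)
  expect_error(wls_residuals(p, obs, syn$dataset,
                             weights = c(confluence_pct = 1)),
               class = "ferrodyn_invalid_input")
})

test_that("inverse-variance weights are finite and per-observable", {
  scn <- scenario("MD", "MD", n0 = 0.22, replicates = 3, seed = 7)
  syn <- generate_dataset(scn)
  w <- make_weights(syn$dataset)
  expect_length(w, nrow(syn$dataset))
  expect_true(all(is.finite(w) & w > 0))
  ## one weight per observable under the pooled scheme
  expect_equal(length(unique(round(tapply(w, syn$dataset$observable, unique), 12))), 3L)
  expect_error(make_weights(syn$dataset, "magic"),
               class = "ferrodyn_invalid_input")
})

test_that("noiseless generate-and-refit recovers the free parameters", {
  syn <- make_clean_synthetic(seed = 11)
  truth <- c(alpha = 0.05, K = 1, beta = 0.045, r0 = 0.48)
  fit <- fit_timecourses(syn$dataset,
                         fit_spec(free = names(truth), multistart = 2, seed = 1))
  expect_s3_class(fit, "ferrodyn_fit")
  expect_true(fit$convergence)
  expect_true(all(rel_err(fit$estimates[names(truth)], truth) < 0.05))
  ## optimizer-reported RSS equals recomputed RSS
  w <- make_weights(syn$dataset)
  r <- wls_residuals(lapply(fit$per_condition, `[[`, "params"),
                     lapply(fit$per_condition, `[[`, "obs"),
                     syn$dataset, weights = w)
  expect_equal(fit$rss, sum(r^2), tolerance = 1e-10)
})

test_that("refitting with an identical seed reproduces the estimates exactly", {
  syn <- generate_dataset(scenario("LD_RSL3", "LD", n0 = 0.10,
                                   r0_multiplier = 0.4, duration_h = 48,
                                   replicates = 2, seed = 5))
  spec <- fit_spec(free = c("alpha", "beta"), multistart = 3, seed = 21)
  f1 <- fit_timecourses(syn$dataset, spec)
  f2 <- fit_timecourses(syn$dataset, spec)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rss, f2$rss)
})

test_that("condition-specific parameters are estimated per condition", {
  scns <- list(
    control = scenario("control", "LD", n0 = 0.10, duration_h = 48,
                       replicates = 1, noise = no_noise(), seed = 2),
    RSL3 = scenario("RSL3", "LD", n0 = 0.10, r0_multiplier = 0.4,
                    duration_h = 48, replicates = 1, noise = no_noise(),
                    seed = 3))
  syn <- generate_dataset(scns)
  fit <- fit_timecourses(syn$dataset,
                         fit_spec(free = c("beta", "r0"),
                                  condition_specific = "r0",
                                  multistart = 2, seed = 1))
  est <- fit$estimates
  expect_true(all(c("r0.control", "r0.RSL3", "beta") %in% names(est)))
  expect_lt(est[["r0.RSL3"]], est[["r0.control"]])
  expect_equal(est[["r0.control"]], 1.2, tolerance = 0.05)
  expect_equal(est[["r0.RSL3"]], 0.48, tolerance = 0.05)
})

test_that("prediction maps the trajectory onto the observation channels", {
  p <- canonical()
  obs <- observation_model()
  pred <- predict_observables(p, obs, model_state(0.22, 0), seq(0, 24, by = 2))
  expect_equal(pred$confluence_pct[1], 22)   # 100 * n0 at t = 0
  expect_equal(pred$lipid_ros_ratio[1], obs$ros_baseline)
  expect_equal(pred$dead_per_confluence[1], 0)
  ## no death term: the dead channel stays identically zero
  p0 <- model_params(beta = 0)
  pr0 <- predict_observables(p0, obs, model_state(0.22, 0), seq(0, 24, by = 2))
  expect_true(all(abs(pr0$dead_per_confluence) < 1e-12))
  ## no ROS production: ratio pinned at the baseline
  pa <- model_params(a = 0, c = 0)
  pra <- predict_observables(pa, obs, model_state(0.22, 0), seq(0, 24, by = 2))
  expect_true(all(abs(pra$lipid_ros_ratio - obs$ros_baseline) < 1e-12))
})
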