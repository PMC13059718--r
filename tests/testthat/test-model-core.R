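test_that("parameter construction validates the physical constraints", {
  p <- canonical()
  expect_s3_class(p, "ferrodyn_params")
  expect_equal(p$r0, 1.2)
  expect_error(model_params(b = 0.02, c = 0.03), class = "ferrodyn_invalid_input")
  expect_error(model_params(b = 0.02, c = 0.02), class = "ferrodyn_invalid_input")
  expect_error(model_params(h = 0.5), class = "ferrodyn_invalid_input")
  expect_error(model_params(alpha = -1), class = "ferrodyn_invalid_input")
  expect_error(model_params(K = 0), class = "ferrodyn_invalid_input")
  expect_error(model_params(alpha = NA_real_), class = "ferrodyn_invalid_input")
  p2 <- update_params(p, r0 = 0.48)
  expect_equal(p2$r0, 0.48)
  expect_equal(p2$alpha, p$alpha)
  expect_error(update_params(p, c = 1), class = "ferrodyn_invalid_input")
})

test_that("model state validates non-negativity and finiteness", {
  s <- model_state(0.1, 2)
  expect_equal(unname(s[["n"]]), 0.1)
  expect_error(model_state(-0.1, 0), class = "ferrodyn_invalid_input")
  expect_error(model_state(0.1, Inf), class = "ferrodyn_invalid_input")
  expect_error(model_rhs("x", canonical()), class = "ferrodyn_invalid_input")
})

test_that("death switch has the Hill-midpoint and limit values", {
  p <- canonical()
  expect_equal(death_switch(0, p), 0)
  expect_equal(death_switch(p$r0, p), 0.5)
  expect_equal(death_switch(2 * p$r0, p), 16 / 17)  # h = 4
  r <- seq(0, 6, length.out = 200)
  expect_true(all(diff(death_switch(r, p)) >= 0))   # monotone non-decreasing
  expect_true(all(death_switch(r, p) >= 0 & death_switch(r, p) <= 1))
  expect_error(death_switch(-1, p), class = "ferrodyn_invalid_input")

  ps <- update_params(p, switch_form = "step")
  expect_equal(death_switch(c(0.5, 1.2, 2), ps), c(0, 0.5, 1))
})

test_that("right-hand side matches hand-evaluated values", {
  p <- canonical()
  ## equilibrium by construction: logistic term and switch both vanish
  expect_equal(unname(model_rhs(model_state(p$K, 0), p)), c(0, 0))
  ## extinction line is invariant in n
  expect_equal(model_rhs(model_state(0, 1.7), p)[["dn"]], 0)
  ## hand evaluation at (n = 0.5, r = 0):
  ## dn = 0.05*0.5*0.5 = 0.0125, dr = 0.5*0.05*0.5 = 0.0125
  expect_equal(unname(model_rhs(model_state(0.5, 0), p)),
               c(0.0125, 0.0125), tolerance = 1e-12)
})

test_that("analytic Jacobian matches finite differences on random states", {
  p <- canonical()
  set.seed(42)
  fd_jac <- function(st, eps = 1e-6) {
    f0n <- model_rhs(model_state(st[1] + eps, st[2]), p)
    f1n <- model_rhs(model_state(max(st[1] - eps, 0), st[2]), p)
    f0r <- model_rhs(model_state(st[1], st[2] + eps), p)
    f1r <- model_rhs(model_state(st[1], max(st[2] - eps, 0)), p)
    cbind((f0n - f1n) / (2 * eps), (f0r - f1r) / (2 * eps))
  }
  for (i in 1:100) {
    st <- c(runif(1, 0.01, 1.2), runif(1, 0.01, 5))
    J <- model_jacobian(model_state(st[1], st[2]), p)
    expect_equal(unname(J), unname(fd_jac(st)), tolerance = 1e-5)
  }
})

test_that("decoupled linearization has eigenvalues -alpha and -b", {
  p <- model_params(beta = 0, a = 0, c = 0)
  ev <- sort(Re(eigen(model_jacobian(model_state(p$K, 0), p),
                      only.values = TRUE)$values))
  expect_equal(ev, sort(c(-p$alpha, -p$b)), tolerance = 1e-12)
})

test_that("simulation reproduces the closed-form logistic limit", {
  p <- model_params(beta = 0, a = 0, c = 0)
  n0 <- 0.05
  times <- seq(0, 120, by = 2)
  tr <- simulate_model(p, model_state(n0, 0), times)
  expected <- p$K * n0 * exp(p$alpha * times) /
    (p$K + n0 * (exp(p$alpha * times) - 1))
  expect_lt(max(abs(tr$n - expected) / expected), 1e-6)
})

test_that("simulation reproduces the closed-form ROS decay limit", {
  p <- model_params(a = 0, c = 0)
  r_init <- 3
  times <- seq(0, 100, by = 1)
  tr <- simulate_model(p, model_state(0.2, r_init), times)
  expected <- r_init * exp(-p$b * times)
  expect_lt(max(abs(tr$r - expected) / expected), 1e-6)
})

test_that("trajectories stay non-negative with a cumulative dead channel", {
  p <- canonical()
  tr <- simulate_model(p, model_state(0.10, 3), seq(0, 500, by = 2))
  expect_true(all(tr$n >= 0))
  expect_true(all(tr$r >= 0))
  expect_true(all(diff(tr$dead) >= -1e-10))  # dead count accrues
  expect_s3_class(tr, "ferrodyn_trajectory")
  ## deterministic for fixed inputs
  tr2 <- simulate_model(p, model_state(0.10, 3), seq(0, 500, by = 2))
  expect_identical(tr, tr2)
})

test_that("simulation rejects invalid time grids", {
  p <- canonical()
  expect_error(simulate_model(p, model_state(0.1, 0), c(0, 0, 1)),
               class = "ferrodyn_invalid_input")
  expect_error(simulate_model(p, model_state(0.1, 0), c(-1, 1)),
               class = "ferrodyn_invalid_input")
  expect_error(simulate_model(p, model_state(0.1, 0), 5),
               class = "ferrodyn_invalid_input")
})

test_that("fixed-point enumeration finds the canonical equilibria", {
  p <- canonical()
  fp <- find_fixed_points(p)
  ## equilibrium residual contract
  for (i in seq_len(nrow(fp))) {
    res <- model_rhs(model_state(fp$n[i], fp$r[i]), p)
    expect_lt(sqrt(sum(res^2)), 1e-8)
  }
  ## pairwise deduplication
  if (nrow(fp) > 1) {
    d <- as.matrix(dist(fp[, c("n", "r")]))
    expect_true(all(d[upper.tri(d)] > 1e-5))
  }
  ## extinction-line point (0, a*alpha/(b - c)) is present
  r_ext <- p$a * p$alpha / (p$b - p$c)
  expect_equal(r_ext, 2.5)
  expect_true(any(fp$n < 1e-8 & abs(fp$r - r_ext) < 1e-6))
  ## resistant state at full confluence, zero ROS
  expect_true(any(abs(fp$n - p$K) < 1e-8 & fp$r < 1e-8 &
                    fp$classification == "stable"))
  ## second stable state at low n, high r
  stab <- fp[fp$classification == "stable", ]
  expect_equal(nrow(stab), 2L)
  low <- stab[which.min(stab$n), ]
  expect_equal(low$n, 0.2060805, tolerance = 1e-4)
  expect_equal(low$r, 1.984799, tolerance = 1e-4)
})

test_that("with strong death and no ROS production only the boundary equilibria remain", {
  p <- model_params(beta = 0.5, a = 0, c = 0)
  fp <- find_fixed_points(p, search_box = c(r_max = 5, n_max = 1.2))
  pts <- fp[, c("n", "r")]
  expect_equal(nrow(pts), 2L)
  expect_true(any(abs(pts$n - p$K) < 1e-8 & pts$r < 1e-8))
  expect_true(any(pts$n < 1e-8 & pts$r < 1e-8))
})

test_that("fixed-point search rejects a non-positive search box", {
  expect_error(find_fixed_points(canonical(), c(r_max = -1, n_max = 1)),
               class = "ferrodyn_invalid_input")
})
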