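make_recovery_problem <- function(free = c("b", "u", "r"), sigma = 0,
                                  seed = NULL, equal = list()) {
  p0 <- demo_system()
  design <- synthetic_design(p0, "recovery_after_depletion",
                             times = seq(1, 40, by = 3), sigma = sigma,
                             seed = seed)
  obs <- generate_synthetic(design)$observed
  fit_problem(obs, p0, free = free, equal = equal,
              init = function(p) depleted_state(p, 0.5))
}

test_that("the cost is zero at the generator and positive elsewhere", {
  prob <- make_recovery_problem()
  truth <- c(b = 0.1, u = 0.2, r = 1)
  expect_lt(ssr_cost(truth, prob), 1e-6)
  expect_gt(ssr_cost(c(b = 0.1, u = 0.22, r = 1), prob), 1)
  # truth beats random nearby perturbations
  set.seed(3)
  for (i in 1:8) {
    pert <- truth * exp(stats::rnorm(3, 0, 0.1))
    expect_gt(ssr_cost(pert, prob), ssr_cost(truth, prob))
  }
})

test_that("infeasible or failing parameter sets cost infinity", {
  prob <- make_recovery_problem()
  expect_identical(ssr_cost(c(b = -1, u = 0.2, r = 1), prob), Inf)
  # no positive equilibrium => the depletion init cannot be built
  expect_identical(ssr_cost(c(b = 0.1, u = 0.2, r = 0.4), prob), Inf)
})

test_that("zero-temperature annealing is a downhill search", {
  prob <- make_recovery_problem(free = c("b", "u"))
  fit <- anneal_fit(prob, init = c(b = 0.15, u = 0.3), t0 = 0, alpha = 1,
                    max_iter = 300, polish = 0, seed = 4)
  cost_on_accept <- fit$trace$cost[fit$trace$accepted]
  expect_true(all(diff(cost_on_accept) <= 1e-12))
  expect_lte(fit$cost, ssr_cost(c(b = 0.15, u = 0.3), prob))
})

test_that("equality-constrained parameters move in lockstep", {
  p <- system_params(100, list(demo_clone(), demo_clone()))
  design <- synthetic_design(p, "competition_timecourse",
                             times = seq(1, 20, by = 2),
                             fractions = c(0.7, 0.3))
  obs <- generate_synthetic(design)$observed
  prob <- fit_problem(obs, p, free = c("b", "u"),
                      equal = list(c("b", "b[2]"), c("u", "u[2]")),
                      init = function(pp) equilibrium_state(pp, c(0.7, 0.3)))
  # the constrained pair tracks the free value exactly
  vals <- apply_equality(c(b = 0.07, u = 0.33), prob$equal)
  expect_identical(vals[["b[2]"]], vals[["b"]])
  expect_identical(vals[["u[2]"]], vals[["u"]])
  expect_lt(ssr_cost(c(b = 0.1, u = 0.2), prob), 1e-6)
  fit <- anneal_fit(prob, init = c(b = 0.12, u = 0.25), max_iter = 150,
                    polish = 50, seed = 9)
  expect_true(is.finite(fit$cost))
})

test_that("short annealing runs improve the fit and are seed-reproducible", {
  prob <- make_recovery_problem(free = c("b", "u"))
  f1 <- anneal_fit(prob, init = c(b = 0.15, u = 0.3), max_iter = 400,
                   polish = 100, seed = 21)
  f2 <- anneal_fit(prob, init = c(b = 0.15, u = 0.3), max_iter = 400,
                   polish = 100, seed = 21)
  expect_identical(f1$par, f2$par)
  expect_lt(f1$cost, ssr_cost(c(b = 0.15, u = 0.3), prob))
  expect_lte(f1$cost, min(f1$trace$cost))
})

test_that("stats::optim SANN agrees as an independent minimiser", {
  prob <- make_recovery_problem(free = c("b", "u"))
  start <- c(b = 0.13, u = 0.26)
  set.seed(5)
  ref <- stats::optim(log(start),
                      function(lp) ssr_cost(setNames(exp(lp), names(start)),
                                            prob),
                      method = "SANN",
                      control = list(maxit = 400, temp = 1))
  ours <- anneal_fit(prob, init = start, max_iter = 400, polish = 100,
                     seed = 6)
  expect_lte(ours$cost, ref$value * 1.5 + 1e-6)
})

test_that("tidy and glance expose the fit in broom style", {
  prob <- make_recovery_problem(free = c("b", "u"))
  fit <- anneal_fit(prob, init = c(b = 0.12, u = 0.25), max_iter = 100,
                    polish = 0, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("b", "u"))
  gl <- glance(fit)
  expect_named(gl, c("cost", "iterations", "accept_rate", "seed",
                     "fitness", "E_star"))
  expect_identical(gl$seed, 2)
  expect_equal(gl$cost, fit$cost)
})

test_that("fit problems validate their inputs", {
  p0 <- demo_system()
  obs <- tibble::tibble(time = 1, clone = 1, compartment = "N", count = 50)
  expect_error(fit_problem(obs, p0, free = "q"), "unknown free")
  bad <- obs; bad$compartment <- "X"
  expect_error(fit_problem(bad, p0, free = "b"), "compartment")
  prob <- fit_problem(obs, p0, free = "b")
  expect_error(anneal_fit(prob, init = c(u = 1)), "every free")
  expect_error(anneal_fit(prob, init = c(b = 0.1), max_iter = 0), "max_iter")
})
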