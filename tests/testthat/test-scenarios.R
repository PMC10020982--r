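test_that("doubling attachment: unbound cells dip, then settle higher", {
  p0 <- demo_system()
  traj <- run_schedule(p0, "equilibrium",
                       niche_events(event_scale(1, "b", 2)), c(0, 400),
                       output_times = c(seq(0, 5, 0.05), seq(6, 400)))
  tb <- tibble::as_tibble(traj)
  unbound <- tb$A + tb$I
  base <- unbound[tb$time == 0]
  expect_lt(min(unbound), base * 0.95)          # transient dip
  expect_gt(dplyr::last(unbound), base * 1.05)  # durable rise
  expect_gt(dplyr::last(tb$N), 70)              # more niche-bound cells
})

test_that("doubling differentiation of inactive cells: flux overshoots then drops below baseline", {
  p0 <- demo_system()
  traj <- run_schedule(p0, "equilibrium",
                       niche_events(event_scale(10, "d_I", 2)), c(0, 400),
                       output_times = c(seq(0, 12, 0.05), seq(13, 400)))
  tb <- tibble::as_tibble(traj)
  base <- tb$flux[tb$time == 0]
  expect_gt(max(tb$flux), base * 1.2)           # transient overshoot
  expect_lt(dplyr::last(tb$flux), base)         # reduced homeostatic output
  expect_lt(dplyr::last(tb$A), 28 / 3)          # fewer unbound cells
  expect_lt(dplyr::last(tb$I), 14 / 3)
})

test_that("null events leave the trajectory unchanged", {
  p0 <- demo_system()
  grid <- seq(0, 50, 0.5)
  plain <- simulate_niche(p0, "equilibrium", c(0, 50), output_times = grid)
  nulled <- run_schedule(p0, "equilibrium",
                         niche_events(event_scale(10, "u", 1),
                                      event_add(20, 0),
                                      event_kill(30, 0)),
                         c(0, 50), output_times = grid)
  expect_equal(tibble::as_tibble(nulled), tibble::as_tibble(plain),
               tolerance = 1e-10)
})

test_that("schedules are reproducible bit-for-bit", {
  p0 <- demo_system()
  ev <- niche_events(event_scale(1, "u", 2), event_kill(5, 0.3))
  t1 <- run_schedule(p0, "equilibrium", ev, c(0, 100))
  t2 <- run_schedule(p0, "equilibrium", ev, c(0, 100))
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
})

test_that("event validation catches unknown targets and clones", {
  p0 <- demo_system()
  expect_error(run_schedule(p0, "equilibrium",
                            niche_events(event_scale(1, "zz", 2)), c(0, 10)),
               "zz")
  expect_error(run_schedule(p0, "equilibrium",
                            niche_events(event_scale(1, "u", 2, clone = 3)),
                            c(0, 10)),
               "unknown clone")
  expect_error(run_schedule(p0, "equilibrium",
                            niche_events(event_scale(99, "u", 2)), c(0, 10)),
               "t_span")
})

test_that("splitting the graft raises chimerism in unpreconditioned hosts", {
  host <- demo_system()
  donor <- demo_clone()
  single <- transplant_protocol(host, donor, total_dose = 20, n_doses = 1)
  multi <- transplant_protocol(host, donor, total_dose = 20, n_doses = 4,
                               dose_interval = 1)
  expect_gt(multi$chimerism, single$chimerism + 1e-3)

  # the advantage hinges on host detachment: with u = 0 it disappears
  host0 <- demo_system(u = 0)
  s0 <- transplant_protocol(host0, donor, total_dose = 20, n_doses = 1)
  m0 <- transplant_protocol(host0, donor, total_dose = 20, n_doses = 4,
                            dose_interval = 1)
  expect_lt(abs(m0$chimerism - s0$chimerism), 1e-3)
})

test_that("the multi-dose advantage does not grow with preconditioning", {
  host <- demo_system()
  donor <- demo_clone()
  gap <- vapply(c(0, 0.5, 0.9), function(pc) {
    multi <- transplant_protocol(host, donor, 20, 4, 1,
                                 preconditioning_fraction = pc)
    single <- transplant_protocol(host, donor, 20, 1,
                                  preconditioning_fraction = pc)
    multi$chimerism - single$chimerism
  }, numeric(1))
  expect_true(all(diff(gap) <= 1e-6))
})

test_that("transplant protocol rejects malformed dosing", {
  host <- demo_system()
  expect_error(transplant_protocol(host, demo_clone(), 20, n_doses = 0),
               "n_doses")
  expect_error(transplant_protocol(host, demo_clone(), 20, n_doses = 2,
                                   dose_interval = 0),
               "dose_interval")
})

test_that("brief mobilization before HSCT yields a small CSC reduction", {
  csc_host <- demo_system(r = 1.2)
  donor <- demo_clone()
  res <- mobilization_hsct(csc_host, donor, mobilization_days = 1,
                           u_multiplier = 3, transplant_dose = 50)
  expect_gt(res$relative_reduction, 0)
  expect_lt(res$relative_reduction, 0.10)
})

test_that("multi-day mobilization alone expands the malignant population", {
  csc_host <- demo_system(r = 1.2)
  donor <- demo_clone()
  res <- mobilization_hsct(csc_host, donor, mobilization_days = 5,
                           u_multiplier = 3, transplant_dose = 0,
                           endpoint = 5, burden = "total")
  expect_gt(res$burden_with, res$burden_without * 1.05)
})

test_that("a unit mobilization multiplier is a null intervention", {
  csc_host <- demo_system(r = 1.2)
  res <- mobilization_hsct(csc_host, demo_clone(), mobilization_days = 3,
                           u_multiplier = 1, transplant_dose = 20)
  expect_equal(res$burden_with, res$burden_without, tolerance = 1e-9)
  expect_equal(res$relative_reduction, 0, tolerance = 1e-9)
})
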