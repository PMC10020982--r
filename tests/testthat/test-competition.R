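test_that("the fitter clone is predicted to win; equal fitness is neutral", {
  c1 <- demo_clone()
  c2 <- demo_clone(r = 1.2)
  out <- predict_outcome(list(c1, c2))
  expect_identical(out$winner, 2L)
  expect_equal(out$fitness$fitness, c(1 / 30, 0.1 * 0.7 / 1.7))
  expect_equal(out$final_E, 1.7 / 0.07)

  # co-doubled b and d_I, or a changed u alone, leave fitness equal
  expect_identical(predict_outcome(list(c1, demo_clone(b = 0.2, d_I = 2)))$winner,
                   "neutral")
  expect_identical(predict_outcome(list(c1, demo_clone(u = 0.6)))$winner,
                   "neutral")
  # no persistent clone at all
  expect_identical(predict_outcome(list(demo_clone(r = 0.1),
                                        demo_clone(r = 0.2)))$winner,
                   "extinction")
})

test_that("neutral pairs preserve their niche fractions", {
  p <- system_params(100, list(demo_clone(label = "wt"),
                               demo_clone(label = "mut")))
  res <- simulate_competition(p, c(0.9, 0.1), c(0, 2000))
  ab <- abundance_metrics(res$trajectory)
  mut <- ab$niche_fraction[ab$clone == "mut"]
  expect_equal(max(abs(mut - 0.1)), 0, tolerance = 1e-6)
  expect_true(all(is.na(res$exclusion_times)))
})

test_that("a 20% division-rate advantage drives the healthy clone out", {
  p <- system_params(100, list(demo_clone(label = "healthy"),
                               demo_clone(r = 1.2, label = "mutated")))
  res <- simulate_competition(p, c(0.9, 0.1), c(0, 3000))
  ab <- abundance_metrics(res$trajectory)
  healthy <- ab$niche_fraction[ab$clone == "healthy"]
  expect_lt(dplyr::last(healthy), 1e-6)
  expect_false(is.na(res$exclusion_times[["healthy"]]))
  # loser fraction eventually decreases monotonically
  tail_part <- healthy[seq(floor(length(healthy) / 3), length(healthy))]
  expect_true(all(diff(tail_part) <= 1e-10))
  # final empty-niche count approaches the winner's 1/F
  tb <- tibble::as_tibble(res$trajectory)
  occ <- sum(tb$N[tb$time == max(tb$time)])
  expect_equal(100 - occ, res$outcome$final_E, tolerance = 1e-4)
})

test_that("tripling the winner's detachment speeds up exclusion", {
  base <- system_params(100, list(demo_clone(label = "healthy"),
                                  demo_clone(r = 1.2, label = "mutated")))
  fast <- system_params(100, list(demo_clone(label = "healthy"),
                                  demo_clone(r = 1.2, u = 0.6,
                                             label = "mutated")))
  t1 <- simulate_competition(base, c(0.9, 0.1), c(0, 3000))$exclusion_times
  t2 <- simulate_competition(fast, c(0.9, 0.1), c(0, 3000))$exclusion_times
  expect_lt(t2[["healthy"]], t1[["healthy"]])
})

test_that("simulated winners agree with the fitness ordering", {
  set.seed(23)
  for (i in 1:12) {
    c1 <- random_viable_clone()
    # competitor differing by >= 25% in one fitness-relevant rate
    c2 <- c1
    pick <- sample(c("b", "r", "d_I"), 1)
    c2[[pick]] <- c1[[pick]] * sample(c(0.75, 1.25), 1)
    if (!is_persistent(structure(c2, class = "clone_params"))) next
    p <- system_params(100, list(c1, c2))
    pred <- predict_outcome(p$clones)
    res <- simulate_competition(p, c(0.5, 0.5), c(0, 30000),
                                threshold = 1e-3, rtol = 1e-8, atol = 1e-10)
    ab <- abundance_metrics(res$trajectory)
    last <- ab[ab$time == max(ab$time), ]
    sim_winner <- last$clone[which.max(last$niche_fraction)]
    expect_identical(sim_winner, paste0("clone", pred$winner))
  }
})

test_that("niche share and progenitor-output share can diverge (tripled u)", {
  # neutral pair at the murine-like reference rates; clone 2 holds 10% of
  # the niche, then its detachment rate is tripled at t = 1
  cl <- clone_params(0.5, 0.001, 0.03, 0.01, 0.05, label = "c1")
  cl2 <- cl; cl2$label <- "c2"
  p <- system_params(100, list(cl, cl2))
  traj <- run_schedule(p, equilibrium_state(p, c(0.9, 0.1)),
                       niche_events(event_scale(1, "u", 3, clone = 2)),
                       c(0, 50000))
  ab <- abundance_metrics(traj)
  c2 <- ab[ab$clone == "c2", ]
  # niche share barely moves
  expect_lt(max(abs(c2$niche_fraction - 0.1)), 0.01)
  # progenitor share rises from 10% toward 3 n2 / (n1 + 3 n2)
  n2 <- dplyr::last(c2$niche_fraction)
  expect_equal(dplyr::last(c2$progenitor_fraction), 3 * n2 / (1 - n2 + 3 * n2),
               tolerance = 1e-3)
  expect_gt(dplyr::last(c2$progenitor_fraction), 0.2)
})

test_that("a single clone holds both abundance shares at one", {
  p0 <- demo_system()
  traj <- simulate_niche(p0, "equilibrium", c(0, 10))
  ab <- abundance_metrics(traj)
  expect_true(all(ab$niche_fraction == 1))
  expect_true(all(ab$progenitor_fraction == 1))
})

test_that("abundance fractions are undefined when the niche is empty", {
  p <- system_params(100, list(demo_clone(), demo_clone()))
  traj <- simulate_niche(p, make_state(p, N = 0, A = c(1, 1), I = 0),
                         c(0, 1), output_times = c(0, 1))
  ab <- abundance_metrics(traj)
  expect_true(all(is.na(ab$niche_fraction[ab$time == 0])))
})
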