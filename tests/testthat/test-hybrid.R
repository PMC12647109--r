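test_that("acceleration coefficients swap 2.5/0.5 linearly with constant sum", {
  expect_equal(unname(accel_coefficients(0, 100)), c(2.5, 0.5))
  expect_equal(unname(accel_coefficients(100, 100)), c(0.5, 2.5))
  sums <- vapply(0:100, function(t) sum(accel_coefficients(t, 100)),
                 numeric(1L))
  expect_equal(sums, rep(3, 101))
  expect_error(accel_coefficients(0, 0), "T must be")
})

test_that("Levy steps use the Mantegna scale and are symmetric with heavy tails", {
  expect_equal(mantegna_sigma(1.5), 0.6965745026, tolerance = 1e-9)
  expect_error(levy_step(3, beta = 2.5), "beta")
  set.seed(1)
  x <- levy_step(1e5)
  expect_lt(abs(mean(x)), 3 * sd(x) / sqrt(length(x)))
  exkurt <- mean((x - mean(x))^4) / sd(x)^4 - 3
  expect_gt(exkurt, 10)
})

test_that("opposition initialization mirrors coordinates and improves the start", {
  sf <- small_fixture()
  D <- nrow(sf$tab)
  x <- c(1, 1, 1)
  opp <- (D + 1) - x
  expect_equal(opp, c(12, 12, 12))
  expect_equal((D + 1) - opp, x)   # involution

  # paired trials: best of 2*pop opposition candidates vs pop plain draws
  obl <- plain <- numeric(100)
  for (s in seq_len(100)) {
    set.seed(1000 + s)
    obl[s] <- max(opposition_init(sf$tab, 3, 10)$score)
    set.seed(1000 + s)
    pos <- matrix(runif(10 * 3, 1, D), 10, 3)
    plain[s] <- max(apply(pos, 1L, function(p)
      selection_fitness(repair_selection(p, D), sf$tab)$raw_fitness))
  }
  expect_gte(mean(obl), mean(plain))
})

test_that("hybrid velocity update has the gbest fixed point and pure attraction", {
  x <- c(3, 4); v <- c(0, 0)
  upd <- hybrid_velocity_update(x, v, x, x, w = 0.7, c1 = 2, c2 = 2)
  expect_equal(upd$position, x)
  expect_equal(upd$velocity, c(0, 0))
  # w = 0, c2 = 0, r1 forced to 1, c1 = 1: jump exactly onto the leader
  lead <- c(9, 1)
  upd2 <- hybrid_velocity_update(x, c(5, 5), lead, x, w = 0, c1 = 1,
                                 c2 = 0, r1 = c(1, 1), r2 = c(1, 1))
  expect_equal(upd2$position, lead)
})

test_that("velocities stay bounded under contraction with bounded attractors", {
  lead <- c(10, 2, 7); gb <- c(4, 4, 4)
  worst <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- runif(3, 0, 12); v <- rep(0, 3)
    for (t in 1:1000) {
      upd <- hybrid_velocity_update(x, v, lead, gb, w = 0.7,
                                    c1 = 1.5, c2 = 1.5)
      x <- upd$position; v <- upd$velocity
      worst <- max(worst, max(abs(v)))
    }
  }
  expect_lt(worst, 1e4)
})

test_that("hybrid runs are bit-identical per seed with monotone curves", {
  sf <- small_fixture()
  r1 <- hybrid_run(sf$tab, 3, pop = 10, iters = 60, seed = 9)
  r2 <- hybrid_run(sf$tab, 3, pop = 10, iters = 60, seed = 9)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$curve))
  expect_true(is_feasible(r1$selection, nrow(sf$tab), 3))
  expect_lte(r1$fitness, sf$bf$fitness + 1e-12)
})

test_that("all three phase branches execute and stagnant particles restart", {
  sf <- small_fixture()
  r <- hybrid_run(sf$tab, 3, pop = 10, iters = 100, seed = 4)
  expect_true(all(r$branch_counts >= 1))
  expect_gt(r$n_restarts, 0)
  expect_gt(r$n_levy_events, 0)
  # phase budget: late = 30, balanced = 30, early = 40 iterations x pop
  expect_equal(unname(r$branch_counts),
               c(30, 30, 40) * 10)
})

test_that("evaluation counts scale exactly linearly in iterations and population", {
  sf <- small_fixture()
  base <- hybrid_run(sf$tab, 3, pop = 10, iters = 40, seed = 2)
  dblT <- hybrid_run(sf$tab, 3, pop = 10, iters = 80, seed = 2)
  dblN <- hybrid_run(sf$tab, 3, pop = 20, iters = 40, seed = 2)
  expect_equal(base$evals$loop, 40 * 10)
  expect_equal(dblT$evals$loop, 2 * base$evals$loop)
  expect_equal(dblN$evals$loop, 2 * base$evals$loop)
  expect_equal(dblN$evals$init, 2 * base$evals$init)
})

test_that("hybrid recovers the planted optimum and the schedule is validated", {
  sf <- small_fixture()
  r <- hybrid_run(sf$tab, 3, pop = 20, iters = 200, seed = 1)
  expect_equal(sort(r$selection), sf$bf$selection)
  expect_error(hybrid_schedule(mid_phase_frac = 0.8, late_phase_frac = 0.7),
               "mid_phase_frac")
})

test_that("the drug_select front end wraps runs with working methods", {
  sf <- small_fixture()
  fit <- drug_select(sf$tab, 3, algorithm = "hybrid", pop = 10,
                     iters = 60, seed = 3)
  expect_s3_class(fit, "drug_select")
  expect_equal(unname(coef(fit)), c(0.5, 0.3, 0.2))
  expect_equal(fit$fitness$penalized_fitness, fit$run$fitness)
  expect_equal(nrow(fit$drugs), 3)
  expect_output(print(fit), "Best fitness")
  expect_output(summary(fit), "Criterion breakdown")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
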