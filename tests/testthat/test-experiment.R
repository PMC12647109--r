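test_that("run summaries compute mean, sample std, max and the composite score", {
  s <- summarize_runs(c(0.6, 0.8))
  expect_equal(s[["mean"]], 0.7)
  expect_equal(s[["std"]], sd(c(0.6, 0.8)))
  expect_equal(s[["std"]], 0.1414214, tolerance = 1e-6)
  expect_equal(s[["max"]], 0.8)
  expect_equal(s[["weighted_score"]],
               0.5 * 0.7 + 0.3 * 0.8 + 0.2 * (1 - s[["std"]]))
  d <- summarize_runs(c(0.42, 0.42, 0.42))
  expect_equal(d[["std"]], 0)
  expect_equal(d[["mean"]], d[["max"]])
})

test_that("benchmark ranks algorithms by weighted score with valid rank permutation", {
  sf <- small_fixture()
  bench <- run_benchmark(sf$tab, 3, algorithms = c("pso", "hybrid"),
                         n_runs = 3, iters = 40, pop = 8, base_seed = 11)
  expect_s3_class(bench, "benchmark_summary")
  expect_setequal(bench$rank, 1:2)
  expect_equal(bench$rank[order(-bench$weighted_score)], 1:2)
  runs <- attr(bench, "runs")
  expect_equal(dim(runs), c(3L, 2L))
  expect_true(all(bench$mean <= bench$max))
  expect_error(run_benchmark(sf$tab, 3, algorithms = "simulated_annealing",
                             n_runs = 2, iters = 5, pop = 5),
               "valid names")
})

test_that("a one-way sweep at the base value reproduces the benchmark hybrid row", {
  sf <- small_fixture()
  bench <- run_benchmark(sf$tab, 3, algorithms = "hybrid", n_runs = 3,
                         iters = 40, pop = 8, base_seed = 5)
  sweep <- one_way_sweep(sf$tab, 3, "alpha", values = 0.5, n_runs = 3,
                         iters = 40, pop = 8, base_seed = 5)
  expect_equal(sweep$mean, bench$mean)
  expect_equal(sweep$std, bench$std)
  grid11 <- one_way_sweep(sf$tab, 3, "gamma", values = seq(0, 1, 0.1),
                          n_runs = 2, iters = 10, pop = 5)
  expect_equal(nrow(grid11), 11)
})

test_that("dropping the review criterion cannot raise the optimizer score", {
  sf <- small_fixture()
  with_g <- vapply(1:3, function(s)
    hybrid_run(sf$tab, 3, criterion_weights(0.5, 0.3, 0.2),
               pop = 20, iters = 200, seed = s)$fitness, numeric(1L))
  no_g <- vapply(1:3, function(s)
    hybrid_run(sf$tab, 3, criterion_weights(0.5, 0.3, 0),
               pop = 20, iters = 200, seed = s)$fitness, numeric(1L))
  expect_true(all(no_g <= with_g + 1e-12))
})

test_that("the simplex grid enumerates exact unit-sum weight triples", {
  g <- simplex_grid(0.1)
  expect_equal(nrow(g), 66)
  expect_true(all(abs(rowSums(g) - 1) < 1e-12))
  expect_false(any(duplicated(g)))
  g5 <- simplex_grid(0.5)
  expect_equal(nrow(g5), 6)
  expect_error(simplex_grid(0.3), "divide 1")
})

test_that("Sobol indices recover analytic variance shares of additive functions", {
  f <- function(w) 2 * w[1] + w[2]
  s <- sobol_indices(f, n_base = 4096, seed = 1)
  expect_lt(max(abs(s$first_order - c(0.8, 0.2, 0))), 0.05)
  expect_lt(max(abs(s$total - c(0.8, 0.2, 0))), 0.05)
  # constant objective: guarded zero-variance path
  s0 <- sobol_indices(function(w) 1, n_base = 256, seed = 1)
  expect_equal(s0$first_order, rep(0, 3))
  # a function of alpha only leaves beta/gamma totals at 0 exactly
  sa <- sobol_indices(function(w) w[1]^2, n_base = 512, seed = 2)
  expect_equal(sa$total[2:3], c(0, 0))
  expect_gt(sa$first_order[1], 0.9)
})

test_that("Kruskal-Wallis H matches hand ranks and the reference implementation", {
  groups <- list(c(1, 2, 3), c(4, 5, 6))
  got <- kruskal_wallis(groups)
  expect_equal(got$H, 27 / 7, tolerance = 1e-12)   # rank sums 6 and 15
  ref <- stats::kruskal.test(unlist(groups),
                             factor(rep(1:2, each = 3)))
  expect_equal(got$H, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)

  # ties engage the correction factor identically to the reference
  tied <- list(c(1, 2, 2, 3), c(2, 3, 4, 4), c(5, 5, 1, 2))
  gt <- kruskal_wallis(tied)
  rt <- stats::kruskal.test(unlist(tied),
                            factor(rep(1:3, each = 4)))
  expect_equal(gt$H, unname(rt$statistic), tolerance = 1e-9)
  expect_equal(gt$p, rt$p.value, tolerance = 1e-9)

  # identical observations: H = 0, p = 1
  same <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)

  # rank invariance under within-group permutation
  perm <- kruskal_wallis(list(c(3, 1, 2), c(6, 4, 5)))
  expect_equal(perm$H, got$H)
})

test_that("selection frequencies and top-set overlap behave as fractions", {
  sels <- list(c(1, 2, 3), c(1, 2, 4), c(1, 5, 6))
  f <- selection_frequency(sels, 10)
  expect_equal(f[1], 1)
  expect_equal(f[2], 2 / 3)
  expect_equal(sum(f), 9 / 3)
  expect_equal(top_overlap(f, f, n = 3), 1)
})

test_that("artifact export writes deterministic convergence, box-plot and summary tables", {
  sf <- small_fixture()
  bench <- run_benchmark(sf$tab, 3, algorithms = c("pso", "hybrid"),
                         n_runs = 3, iters = 30, pop = 8, base_seed = 1)
  out1 <- file.path(tempfile(), "a")
  paths <- export_run_artifacts(bench, out1)
  expect_true(all(file.exists(paths)))
  box <- read.csv(file.path(out1, "fitness_distributions.csv"))
  expect_equal(dim(box), c(3L, 2L))
  summ <- readLines(file.path(out1, "summary.csv"))
  for (lbl in c("Mean", "Std. Dev", "Max Fitness", "Weighted Score",
                "Final Rank"))
    expect_true(any(startsWith(summ, lbl)))
  conv <- read.delim(file.path(out1, "pso_convergence.tsv"))
  expect_equal(names(conv), c("iteration", "best_score"))
  expect_equal(nrow(conv), 30)
  # byte-identical re-export
  out2 <- file.path(tempfile(), "b")
  export_run_artifacts(bench, out2)
  for (fn in list.files(out1))
    expect_identical(readLines(file.path(out1, fn)),
                     readLines(file.path(out2, fn)))
})
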