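algorithm_registry <- function() {
  list(pso = pso_run, eavoa = eavoa_run, hybrid = hybrid_run)
}

#' Summary statistics for a set of independent runs
#'
#' Computes mean, sample (n-1) standard deviation and max of the final
#' fitness values, plus the weighted composite score
#' `w_mean * mean + w_max * max + w_stability * (1 - std)` used for
#' ranking (score weights default to 0.5 / 0.3 / 0.2; the composite
#' formula is a package convention, configurable via `score_weights`).
#'
#' @param runs numeric vector of per-run final best fitness values.
#' @param score_weights named numeric `c(mean, max, stability)`.
#' @return Named numeric `c(mean, std, max, weighted_score)`.
#' @export
summarize_runs <- function(runs,
                           score_weights = c(mean = 0.5, max = 0.3,
                                             stability = 0.2)) {
  stopifnot(length(runs) >= 2L)
  m <- mean(runs); s <- stats::sd(runs); mx <- max(runs)
  c(mean = m, std = s, max = mx,
    weighted_score = score_weights[["mean"]] * m +
      score_weights[["max"]] * mx +
      score_weights[["stability"]] * (1 - s))
}

#' Multi-run benchmark of the optimizers
#'
#' Runs each named algorithm over `n_runs` seeds (`base_seed` to
#' `base_seed + n_runs - 1`, common across algorithms so comparisons are
#' paired), collects final best fitness per run and ranks algorithms by
#' the weighted composite score of [summarize_runs()] (descending; ties
#' break by algorithm name).
#'
#' @param table a normalized `drug_table`.
#' @param k subset size.
#' @param algorithms subset of `c("pso", "eavoa", "hybrid")`.
#' @param n_runs number of independent runs per algorithm (>= 2).
#' @param iters,pop optimizer settings shared by all algorithms.
#' @param base_seed first seed.
#' @param weights a [criterion_weights()].
#' @param score_weights see [summarize_runs()].
#' @return A data frame of class `benchmark_summary` (one row per
#'   algorithm: mean, std, max, weighted_score, rank) with attributes
#'   `runs` (n_runs x algorithms matrix of final fitness) and `curves`
#'   (list of per-algorithm convergence-curve matrices).
#' @export
run_benchmark <- function(table, k,
                          algorithms = c("pso", "eavoa", "hybrid"),
                          n_runs = 10, iters = 500, pop = 30,
                          base_seed = 1, weights = criterion_weights(),
                          score_weights = c(mean = 0.5, max = 0.3,
                                            stability = 0.2)) {
  registry <- algorithm_registry()
  unknown <- setdiff(algorithms, names(registry))
  if (length(unknown))
    stop("unknown algorithm(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(registry), collapse = ", "))
  if (n_runs < 2) stop("n_runs must be >= 2")
  seeds <- base_seed + seq_len(n_runs) - 1L
  finals <- matrix(NA_real_, n_runs, length(algorithms),
                   dimnames = list(paste0("run", seq_len(n_runs)),
                                   algorithms))
  curves <- stats::setNames(vector("list", length(algorithms)), algorithms)
  for (a in algorithms) {
    cm <- matrix(NA_real_, iters, n_runs)
    for (r in seq_len(n_runs)) {
      res <- registry[[a]](table, k, weights, pop, iters, seeds[r])
      finals[r, a] <- res$fitness
      cm[, r] <- res$curve
    }
    curves[[a]] <- cm
  }
  stats_mat <- t(apply(finals, 2L, summarize_runs,
                       score_weights = score_weights))
  out <- data.frame(algorithm = algorithms, stats_mat,
                    stringsAsFactors = FALSE)
  ord <- order(-out$weighted_score, out$algorithm)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  rownames(out) <- NULL
  structure(out, runs = finals, curves = curves, seeds = seeds,
            class = c("benchmark_summary", "data.frame"))
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("Benchmark over %d runs (seeds %d..%d):\n",
              nrow(attr(x, "runs")), attr(x, "seeds")[1L],
              utils::tail(attr(x, "seeds"), 1L)))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}

#' One-way sensitivity sweep of a criterion weight
#'
#' Varies one of the weights alpha, beta, gamma over `values` while the
#' other two stay at the base configuration (0.5, 0.3, 0.2 by default),
#' and reports mean and sample std of the hybrid optimizer's final fitness
#' over `n_runs` seeded runs per value (seeds shared across values, so
#' comparisons are paired).
#'
#' @param table a normalized `drug_table`.
#' @param k subset size.
#' @param coefficient `"alpha"`, `"beta"` or `"gamma"`.
#' @param values numeric grid within \[0, 1\].
#' @param n_runs runs per grid value.
#' @param iters,pop,base_seed optimizer settings.
#' @param base named numeric base weights.
#' @return Data frame with columns `value`, `mean`, `std`.
#' @export
one_way_sweep <- function(table, k,
                          coefficient = c("alpha", "beta", "gamma"),
                          values = seq(0, 1, 0.1), n_runs = 5,
                          iters = 200, pop = 20, base_seed = 1,
                          base = c(alpha = 0.5, beta = 0.3, gamma = 0.2)) {
  coefficient <- match.arg(coefficient)
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  rows <- lapply(values, function(v) {
    w <- base; w[coefficient] <- v
    wts <- criterion_weights(w[["alpha"]], w[["beta"]], w[["gamma"]])
    finals <- vapply(base_seed + seq_len(n_runs) - 1L, function(s)
      hybrid_run(table, k, wts, pop, iters, s)$fitness, numeric(1L))
    data.frame(value = v, mean = mean(finals), std = stats::sd(finals))
  })
  do.call(rbind, rows)
}

#' Simplex grid of weight triples
#'
#' All non-negative triples (alpha, beta, gamma) on the `step` lattice
#' summing to 1; at step 0.1 there are exactly 66.
#'
#' @param step lattice step; `1/step` must be an integer.
#' @return Data frame with columns `alpha`, `beta`, `gamma`.
#' @export
simplex_grid <- function(step = 0.1) {
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9)
    stop("step must divide 1 exactly (got ", step, ")")
  g <- expand.grid(i = 0:n, j = 0:n)
  g <- g[g$i + g$j <= n, ]
  out <- data.frame(alpha = g$i * step, beta = g$j * step,
                    gamma = (n - g$i - g$j) * step)
  rownames(out) <- NULL
  out
}

#' Fitness landscape over the weight simplex
#'
#' Evaluates mean hybrid final fitness at every [simplex_grid()] triple.
#'
#' @inheritParams one_way_sweep
#' @param step simplex lattice step.
#' @return The grid with a `mean_fitness` column, plus the argmax row as
#'   attribute `best`.
#' @export
grid_sensitivity <- function(table, k, step = 0.1, n_runs = 3,
                             iters = 200, pop = 20, base_seed = 1) {
  g <- simplex_grid(step)
  g$mean_fitness <- vapply(seq_len(nrow(g)), function(r) {
    wts <- criterion_weights(g$alpha[r], g$beta[r], g$gamma[r])
    mean(vapply(base_seed + seq_len(n_runs) - 1L, function(s)
      hybrid_run(table, k, wts, pop, iters, s)$fitness, numeric(1L)))
  }, numeric(1L))
  attr(g, "best") <- g[which.max(g$mean_fitness), ]
  g
}

#' Sobol first-order and total sensitivity indices
#'
#' Saltelli-style estimator over the unit cube of (alpha, beta, gamma):
#' two independent sample matrices A and B of size `n_base` plus the three
#' hybrids AB_i give `S_i = mean(f(B) (f(AB_i) - f(A))) / Var` and
#' `ST_i = mean((f(A) - f(AB_i))^2) / (2 Var)`. A constant objective
#' (zero variance) returns all-zero indices.
#'
#' @param objective_fn function taking a numeric triple
#'   `(alpha, beta, gamma)` and returning a scalar.
#' @param n_base base sample size (>= 64; powers of two recommended).
#' @param seed RNG seed for the sample matrices.
#' @return Data frame with columns `coefficient`, `first_order`, `total`.
#' @export
sobol_indices <- function(objective_fn, n_base = 4096, seed = 1) {
  if (n_base < 64) stop("n_base must be >= 64")
  set.seed(seed)
  A <- matrix(stats::runif(n_base * 3), n_base, 3)
  B <- matrix(stats::runif(n_base * 3), n_base, 3)
  fA <- apply(A, 1L, objective_fn)
  fB <- apply(B, 1L, objective_fn)
  v <- stats::var(c(fA, fB))
  coefs <- c("alpha", "beta", "gamma")
  if (v == 0)
    return(data.frame(coefficient = coefs, first_order = 0, total = 0))
  first <- numeric(3); total <- numeric(3)
  for (i in 1:3) {
    ABi <- A; ABi[, i] <- B[, i]
    fABi <- apply(ABi, 1L, objective_fn)
    first[i] <- mean(fB * (fABi - fA)) / v
    total[i] <- 0.5 * mean((fA - fABi)^2) / v
  }
  data.frame(coefficient = coefs, first_order = first, total = total)
}

#' Hybrid-fitness objective for Sobol decomposition
#'
#' Wraps the hybrid optimizer as a deterministic function of the weight
#' triple for [sobol_indices()]: each sample point runs the optimizer at a
#' fixed seed (optimizer noise folded into the function); `n_rep > 1`
#' averages over consecutive seeds instead.
#'
#' @inheritParams one_way_sweep
#' @param seed fixed per-point seed.
#' @param n_rep replicates averaged per point.
#' @return A function `(triple) -> mean final fitness`.
#' @export
hybrid_objective_fn <- function(table, k, iters = 100, pop = 20,
                                seed = 1, n_rep = 1) {
  function(w) {
    wts <- criterion_weights(w[1L], w[2L], w[3L])
    mean(vapply(seed + seq_len(n_rep) - 1L, function(s)
      hybrid_run(table, k, wts, pop, iters, s)$fitness, numeric(1L)))
  }
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction and the chi-squared
#' approximation on `n_groups - 1` degrees of freedom. When every
#' observation is identical the statistic is 0 and p = 1.
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 1
#'   observation).
#' @return List with `H`, `p` and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(lengths(groups) < 1L)) stop("each group needs >= 1 observation")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(x)
  C <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (C <= 0) {
    H <- 0
  } else {
    H <- H / C
  }
  df <- length(groups) - 1L
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Selection frequency of each drug across runs
#'
#' @param selections list of integer selection vectors (one per run).
#' @param D total number of drugs.
#' @return Numeric vector of length D: fraction of runs selecting each
#'   drug.
#' @export
selection_frequency <- function(selections, D) {
  tabulate(unlist(selections), nbins = D) / length(selections)
}

#' Overlap of the top-n drugs between two configurations
#'
#' Ranks drugs by selection frequency under each configuration and returns
#' `|top_n(a) intersect top_n(b)| / n`.
#'
#' @param freq_a,freq_b frequency vectors from [selection_frequency()].
#' @param n size of the head compared (default 10).
#' @return A fraction in \[0, 1\].
#' @export
top_overlap <- function(freq_a, freq_b, n = 10) {
  ta <- order(-freq_a)[seq_len(min(n, length(freq_a)))]
  tb <- order(-freq_b)[seq_len(min(n, length(freq_b)))]
  length(intersect(ta, tb)) / n
}

#' Export benchmark artifacts as plain-text tables
#'
#' Writes, deterministically: one convergence TSV per algorithm
#' (`<algo>_convergence.tsv`, columns iteration and mean best score across
#' runs), a box-plot data CSV (`fitness_distributions.csv`, one column per
#' algorithm, one row per run) and a summary CSV (`summary.csv`) with the
#' per-run fitness values and footer rows Mean, Std. Dev, Max Fitness,
#' Weighted Score and Final Rank.
#'
#' @param summary a `benchmark_summary` from [run_benchmark()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_run_artifacts <- function(summary, outdir) {
  stopifnot(inherits(summary, "benchmark_summary"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  runs <- attr(summary, "runs")
  curves <- attr(summary, "curves")
  paths <- character(0)
  for (a in names(curves)) {
    p <- file.path(outdir, paste0(a, "_convergence.tsv"))
    utils::write.table(
      data.frame(iteration = seq_len(nrow(curves[[a]])),
                 best_score = rowMeans(curves[[a]])),
      p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p_box <- file.path(outdir, "fitness_distributions.csv")
  utils::write.csv(as.data.frame(runs), p_box, row.names = FALSE)
  df <- as.data.frame(summary)
  footer <- rbind(
    c("Mean", formatC(df$mean, format = "f", digits = 5)),
    c("Std. Dev", formatC(df$std, format = "f", digits = 5)),
    c("Max Fitness", formatC(df$max, format = "f", digits = 5)),
    c("Weighted Score", formatC(df$weighted_score, format = "f",
                                digits = 5)),
    c("Final Rank", as.character(df$rank)))
  body <- cbind(rownames(runs), formatC(runs, format = "f", digits = 5))
  tab <- rbind(c("Run", colnames(runs)), body, footer)
  p_sum <- file.path(outdir, "summary.csv")
  utils::write.table(tab, p_sum, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(paths, p_box, p_sum))
}
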