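#' Select an optimal drug subset by metaheuristic search
#'
#' Front end to the three optimizers. Finds a feasible subset of `k`
#' distinct drugs maximizing the weighted-sum fitness
#' `alpha * mean(rating_norm) - beta * mean(severity_norm) +
#' gamma * mean(reviews_norm)` over the normalized table.
#'
#' @param table a normalized `drug_table` (see [prepare_drug_table()]).
#' @param k subset size.
#' @param algorithm `"hybrid"` (default), `"pso"` or `"eavoa"`.
#' @param weights a [criterion_weights()].
#' @param pop swarm size (default 30).
#' @param iters iterations (default 500).
#' @param seed integer seed; runs are exactly reproducible.
#' @param ... further arguments passed to [hybrid_run()], [pso_run()] or
#'   [eavoa_run()].
#' @return An object of class `drug_select` with the selection, its
#'   [selection_fitness()] breakdown, the convergence curve and run
#'   metadata; supports `print`, `summary`, `coef` and `plot`.
#' @examples
#' \donttest{
#' gen <- generate_drug_table(synthetic_spec(D = 12, k = 3, seed = 1))
#' tab <- prepare_drug_table(gen$table)
#' fit <- drug_select(tab, k = 3, iters = 100, pop = 20, seed = 7)
#' print(fit)
#' }
#' @export
drug_select <- function(table, k,
                        algorithm = c("hybrid", "pso", "eavoa"),
                        weights = criterion_weights(), pop = 30,
                        iters = 500, seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  run <- switch(algorithm,
    hybrid = hybrid_run(table, k, weights, pop, iters, seed, ...),
    pso = pso_run(table, k, weights, pop, iters, seed, ...),
    eavoa = eavoa_run(table, k, weights, pop, iters, seed, ...))
  fit <- selection_fitness(run$selection, table, weights, k = k)
  cols <- intersect(c("drug_name", "condition", "rating_raw",
                      "review_count", "severity", "rating_norm",
                      "severity_norm", "reviews_norm"), names(table))
  structure(list(selection = run$selection,
                 drugs = as.data.frame(table)[run$selection, cols],
                 fitness = fit, curve = run$curve, run = run,
                 algorithm = algorithm, weights = weights, k = k,
                 seed = seed, table_size = nrow(table)),
            class = "drug_select")
}

#' @export
print.drug_select <- function(x, ...) {
  cat(sprintf("Drug subset selection (%s, k = %d of D = %d, seed %d)\n",
              toupper(x$algorithm), x$k, x$table_size, x$seed))
  cat(sprintf("Best fitness: %.5f\n", x$fitness$penalized_fitness))
  cat("Selected drugs:\n")
  print.data.frame(x$drugs[, intersect(c("drug_name", "condition",
                                         "rating_raw", "review_count",
                                         "severity"), names(x$drugs))],
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.drug_select <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCriterion breakdown (normalized means over the selection):\n")
  cat(sprintf("  rating  %.4f  (weight alpha = %.2f)\n",
              x$fitness$mean_rating, x$weights$alpha))
  cat(sprintf("  side-effect severity  %.4f  (weight beta = %.2f)\n",
              x$fitness$mean_side_effect, x$weights$beta))
  cat(sprintf("  reviews  %.4f  (weight gamma = %.2f)\n",
              x$fitness$mean_reviews, x$weights$gamma))
  cat(sprintf("\nConvergence: %.5f (iter 1) -> %.5f (iter %d), %d evals\n",
              x$curve[1L], x$curve[length(x$curve)], length(x$curve),
              x$run$evals$total))
  invisible(x)
}

#' @export
coef.drug_select <- function(object, ...) {
  unlist(object$weights)
}

#' Plot the convergence curve of a selection run
#'
#' @param x a `drug_select` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drug_select <- function(x, ...) {
  graphics::plot(seq_along(x$curve), x$curve, type = "l",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("%s convergence (seed %d)",
                                toupper(x$algorithm), x$seed), ...)
  invisible(x)
}
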