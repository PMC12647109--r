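# Shared optimizer plumbing. All optimizers work on continuous positions in
# [1, D]^k; decoding = round/clamp/repair to a feasible k-subset. A single
# seeded session RNG drives every stochastic draw of a run, so a run is a
# pure function of (table, settings, seed).

make_ctx <- function(table, weights, k) {
  stopifnot(inherits(table, "drug_table"))
  if (!is_normalized(table))
    stop("table must be normalized; see prepare_drug_table()")
  D <- nrow(table)
  if (k < 1 || k > D) stop("k must be in [1, D]")
  list(score = drug_scores(table, weights), D = D, k = k)
}

# Decode a position and evaluate the penalized fitness. Repair guarantees
# feasibility, so penalized = raw here; the feasibility contract is
# asserted on every evaluation.
decode_eval <- function(pos, ctx, counter = NULL) {
  sel <- repair_selection(pos, ctx$D, ctx$k)
  if (!is_feasible(sel, ctx$D, ctx$k))
    stop("internal error: repaired selection infeasible")
  if (!is.null(counter)) counter$n <- counter$n + 1L
  list(sel = sel, score = mean(ctx$score[sel]))
}

new_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' Linearly decaying inertia weight
#'
#' `w = wmax - (wmax - wmin) * t / T`, from `wmax` at t = 0 down to `wmin`
#' at t = T.
#'
#' @param t current iteration (0 <= t <= T).
#' @param T maximum iteration (>= 1).
#' @param wmax,wmin schedule endpoints (defaults 0.9 and 0.4).
#' @return The inertia weight at iteration `t`.
#' @export
inertia_weight <- function(t, T, wmax = 0.9, wmin = 0.4) {
  if (T < 1) stop("T must be >= 1")
  if (any(t < 0) || any(t > T)) stop("t must be within [0, T]")
  wmax - (wmax - wmin) * t / T
}

swarm_result <- function(algorithm, ctx, table, gbest, curve, counters,
                         seed, pop, iters, extras = list()) {
  structure(c(list(algorithm = algorithm, selection = gbest$sel,
                   fitness = gbest$score, position = gbest$pos,
                   curve = curve, evals = counters, seed = seed, pop = pop,
                   iters = iters, k = ctx$k, D = ctx$D,
                   drug_names = table$drug_name[gbest$sel]),
              extras),
            class = "swarm_run")
}

#' @export
print.swarm_run <- function(x, ...) {
  cat(sprintf("%s run (pop %d, %d iterations, seed %d)\n",
              toupper(x$algorithm), x$pop, x$iters, x$seed))
  cat(sprintf("  best fitness %.5f, selection {%s}\n", x$fitness,
              paste(x$selection, collapse = ", ")))
  cat(sprintf("  drugs: %s\n", paste(x$drug_names, collapse = ", ")))
  cat(sprintf("  fitness evaluations: %d (init %d, loop %d)\n",
              x$evals$total, x$evals$init, x$evals$loop))
  invisible(x)
}
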