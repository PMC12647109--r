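#' Criterion weights
#'
#' Weights of the three selection criteria in the weighted-sum fitness:
#' `alpha` scales mean normalized rating (maximized), `beta` mean
#' normalized side-effect severity (minimized), `gamma` mean normalized
#' review count (maximized). Defaults are the base configuration
#' alpha = 0.5, beta = 0.3, gamma = 0.2.
#'
#' @param alpha,beta,gamma non-negative finite weights.
#' @return An object of class `criterion_weights`.
#' @export
criterion_weights <- function(alpha = 0.5, beta = 0.3, gamma = 0.2) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative")
  structure(as.list(w), class = "criterion_weights")
}

#' Check feasibility of a selection vector
#'
#' A selection is feasible iff it has exactly `k` indices, all within
#' \[1, D\], all distinct.
#'
#' @param sel integer vector of selected (1-based) drug indices.
#' @param D total number of drugs.
#' @param k target subset size.
#' @return Logical scalar.
#' @export
is_feasible <- function(sel, D, k) {
  length(sel) == k && all(sel >= 1L & sel <= D) &&
    !anyDuplicated(sel) && all(sel == round(sel))
}

#' Weighted-sum fitness of a drug selection, with constraint penalties
#'
#' Computes the raw fitness
#' `alpha * mean(rating_norm) - beta * mean(severity_norm) +
#' gamma * mean(reviews_norm)` over the selected records, plus violation
#' counts and the penalized fitness
#' `raw - lambda1 * P_equality - lambda2 * P_uniqueness`. Out-of-bounds
#' indices never crash: they are clamped for the component means and
#' counted as equality violations; `P_equality` also counts any deviation
#' of the selection length from `k`, and `P_uniqueness` counts duplicates.
#' Feasible selections have zero penalties, so penalized = raw.
#'
#' @param sel integer vector of selected indices (1-based).
#' @param table a normalized `drug_table`.
#' @param weights a [criterion_weights()].
#' @param k target subset size (defaults to `length(sel)`).
#' @param lambda1,lambda2 non-negative penalty coefficients for the
#'   equality (size/bounds) and uniqueness constraints; with criteria
#'   normalized to \[0, 1\], the unit defaults make any violation dominate
#'   any criterion gain.
#' @return An object of class `fitness_result`: a list with components
#'   `mean_rating`, `mean_side_effect`, `mean_reviews`, `raw_fitness`,
#'   `p_equality`, `p_uniqueness`, `penalized_fitness`.
#' @export
selection_fitness <- function(sel, table, weights = criterion_weights(),
                              k = length(sel), lambda1 = 1, lambda2 = 1) {
  stopifnot(inherits(table, "drug_table"))
  if (!is_normalized(table))
    stop("table must be normalized; see normalize_features()")
  if (lambda1 < 0 || lambda2 < 0) stop("penalty coefficients must be >= 0")
  D <- nrow(table)
  sel <- round(as.numeric(sel))
  oob <- sum(sel < 1 | sel > D)
  cl <- as.integer(clamp(sel, 1, D))
  mr <- mean(table$rating_norm[cl])
  ms <- mean(table$severity_norm[cl])
  mv <- mean(table$reviews_norm[cl])
  raw <- weights$alpha * mr - weights$beta * ms + weights$gamma * mv
  p_eq <- abs(length(sel) - k) + oob
  p_un <- length(sel) - length(unique(sel))
  structure(list(mean_rating = mr, mean_side_effect = ms, mean_reviews = mv,
                 raw_fitness = raw, p_equality = p_eq, p_uniqueness = p_un,
                 penalized_fitness = raw - lambda1 * p_eq - lambda2 * p_un),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(paste0("Fitness: raw %.5f, penalized %.5f ",
                     "(equality violations %d, duplicates %d)\n"),
              x$raw_fitness, x$penalized_fitness, x$p_equality,
              x$p_uniqueness))
  cat(sprintf("  mean rating %.4f | mean side-effect %.4f | mean reviews %.4f\n",
              x$mean_rating, x$mean_side_effect, x$mean_reviews))
  invisible(x)
}

#' Decode a continuous position into a feasible selection
#'
#' Rounds each coordinate to the nearest integer, clamps to \[1, D\] and
#' replaces duplicates, in left-to-right scan order, with uniformly random
#' unused indices. The result is always feasible; already-feasible integer
#' positions pass through unchanged. Draws come from the session RNG, so a
#' seeded run replays exactly.
#'
#' @param pos numeric vector of length `k` (a particle position).
#' @param D total number of drugs; must satisfy `D >= k`.
#' @param k subset size (defaults to `length(pos)`).
#' @return Integer vector of `k` unique indices in \[1, D\].
#' @export
repair_selection <- function(pos, D, k = length(pos)) {
  if (D < k) stop("infeasible: cannot draw ", k, " unique indices from ", D)
  if (length(pos) != k) stop("position length must equal k")
  idx <- as.integer(clamp(round(pos), 1, D))
  seen <- logical(D)
  dup <- integer(0)
  for (i in seq_len(k)) {
    if (seen[idx[i]]) dup <- c(dup, i) else seen[idx[i]] <- TRUE
  }
  if (length(dup)) {
    unused <- which(!seen)
    repl <- if (length(unused) == 1L) unused else
      sample(unused, length(dup))
    idx[dup] <- repl
  }
  idx
}

#' Exhaustive optimum by subset enumeration
#'
#' Enumerates all k-subsets of the table (lexicographic order) and returns
#' the one maximizing raw fitness; ties break to the lexicographically
#' smallest index vector. Serves as the ground-truth oracle for the
#' optimizers on small instances; refuses when `choose(D, k)` exceeds
#' `max_subsets`.
#'
#' @inheritParams selection_fitness
#' @param k subset size.
#' @param max_subsets enumeration budget (default 1e6).
#' @return A list with `selection` (integer vector), `fitness` (raw
#'   fitness) and `n_evaluated` (number of subsets enumerated).
#' @export
brute_force_optimum <- function(table, k, weights = criterion_weights(),
                                max_subsets = 1e6) {
  stopifnot(inherits(table, "drug_table"), is_normalized(table))
  D <- nrow(table)
  if (choose(D, k) > max_subsets)
    stop("combinatorial budget exceeded: choose(", D, ", ", k, ") > ",
         format(max_subsets, scientific = FALSE))
  score <- drug_scores(table, weights)
  subsets <- utils::combn(D, k)
  vals <- colMeans(matrix(score[subsets], nrow = k))
  best <- which.max(vals)  # first max = lexicographically smallest
  list(selection = as.integer(subsets[, best]), fitness = vals[best],
       n_evaluated = ncol(subsets))
}

# Per-drug composite score; the raw fitness of a selection is the mean of
# these over its members (means are linear in the per-drug contributions).
drug_scores <- function(table, weights) {
  weights$alpha * table$rating_norm - weights$beta * table$severity_norm +
    weights$gamma * table$reviews_norm
}
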