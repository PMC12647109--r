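#' Standard particle swarm optimization over drug subsets
#'
#' Canonical PSO with linearly decaying inertia ([inertia_weight()]) and
#' constant acceleration coefficients, operating on continuous positions
#' decoded to feasible k-subsets by [repair_selection()]. Velocity update
#' per particle, per dimension, with fresh uniform r1, r2:
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`; `x <- x + v`.
#'
#' @param table a normalized `drug_table`.
#' @param k subset size.
#' @param weights a [criterion_weights()].
#' @param pop swarm size (default 30).
#' @param iters number of iterations (default 500).
#' @param seed integer seed; the whole trajectory is a pure function of
#'   (table, settings, seed).
#' @param c1,c2 acceleration constants (default 2.0 each).
#' @param wmax,wmin inertia schedule endpoints.
#' @return A `swarm_run`: best selection, fitness, per-iteration
#'   convergence curve (non-decreasing), and evaluation counters.
#' @export
pso_run <- function(table, k, weights = criterion_weights(), pop = 30,
                    iters = 500, seed = 1, c1 = 2, c2 = 2,
                    wmax = 0.9, wmin = 0.4) {
  ctx <- make_ctx(table, weights, k)
  set.seed(seed)
  cnt_init <- new_counter(); cnt_loop <- new_counter()

  pos <- matrix(stats::runif(pop * k, 1, ctx$D), pop, k)
  vel <- matrix(0, pop, k)
  de <- apply(pos, 1L, decode_eval, ctx = ctx, counter = cnt_init)
  cur_sel <- lapply(de, `[[`, "sel")
  pbest_pos <- pos
  pbest_score <- vapply(de, `[[`, numeric(1L), "score")
  pbest_sel <- cur_sel
  gb <- which.max(pbest_score)
  gbest <- list(pos = pbest_pos[gb, ], score = pbest_score[gb],
                sel = pbest_sel[[gb]])

  curve <- numeric(iters)
  for (t in seq_len(iters)) {
    w <- inertia_weight(t, iters, wmax, wmin)
    for (i in seq_len(pop)) {
      r1 <- stats::runif(k); r2 <- stats::runif(k)
      vel[i, ] <- w * vel[i, ] + c1 * r1 * (pbest_pos[i, ] - pos[i, ]) +
        c2 * r2 * (gbest$pos - pos[i, ])
      pos[i, ] <- pos[i, ] + vel[i, ]
      d <- decode_eval(pos[i, ], ctx, cnt_loop)
      if (d$score > pbest_score[i]) {
        pbest_score[i] <- d$score
        pbest_pos[i, ] <- pos[i, ]
        pbest_sel[[i]] <- d$sel
      }
      if (d$score > gbest$score)
        gbest <- list(pos = pos[i, ], score = d$score, sel = d$sel)
    }
    curve[t] <- gbest$score
  }
  swarm_result("pso", ctx, table, gbest, curve,
               list(init = cnt_init$n, loop = cnt_loop$n,
                    total = cnt_init$n + cnt_loop$n),
               seed, pop, iters)
}
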