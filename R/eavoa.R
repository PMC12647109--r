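#' Starvation-rate trend term
#'
#' The deterministic trend `dt = h * (sin(pi t / 2T) + cos(pi t / 2T) - 1)`
#' of the starvation rate; exactly 0 at t = 0 and t = T.
#'
#' @param t current iteration (0 <= t <= T).
#' @param T maximum iteration.
#' @param h disturbance amplitude (default 0.5).
#' @return Numeric trend value.
#' @export
starvation_dt <- function(t, T, h = 0.5) {
  if (any(t < 0) || any(t > T)) stop("t must be within [0, T]")
  # sinpi/cospi keep the endpoints exact: dt(0) = dt(T) = 0
  h * (sinpi(t / (2 * T)) + cospi(t / (2 * T)) - 1)
}

#' Vulture starvation rate
#'
#' `F = (2 rand + 1) * z * (1 - t/T) + dt` with rand ~ U(0,1) and
#' z ~ U(-1,1) resampled per call, plus the trend [starvation_dt()].
#' Large |F| drives exploration, small |F| exploitation; at t = T the
#' stochastic part vanishes and F = 0 exactly.
#'
#' @inheritParams starvation_dt
#' @return A single stochastic starvation value.
#' @export
starvation_rate <- function(t, T, h = 0.5) {
  (2 * stats::runif(1) + 1) * stats::runif(1, -1, 1) * (1 - t / T) +
    starvation_dt(t, T, h)
}

#' Leader-selection probabilities over the best three vultures
#'
#' Converts the fitness values of the three ranked leaders into selection
#' shares (w1, w2) for [select_leader()]. The default `"proportional"`
#' weighting assigns fitness-proportional shares after shifting the three
#' values to be non-negative, so better leaders are picked more often
#' (equal fitness gives 1/3 each). `"inverse"` uses the inverse-fitness
#' transcription (z1 from the second best, z2 from the best).
#'
#' @param fit numeric vector of length 3: fitness of the best, second and
#'   third leader (maximization scale).
#' @param weighting `"proportional"` or `"inverse"`.
#' @return Numeric `c(w1, w2)` with w1, w2 >= 0 and w1 + w2 <= 1.
#' @export
leader_weights <- function(fit, weighting = c("proportional", "inverse")) {
  weighting <- match.arg(weighting)
  stopifnot(length(fit) == 3L)
  fs <- fit - min(fit)
  if (sum(fs) == 0) return(c(w1 = 1 / 3, w2 = 1 / 3))
  if (weighting == "proportional") {
    w <- fs / sum(fs)
    c(w1 = w[1L], w2 = w[2L])
  } else {
    g <- fs + max(fs) * 1e-6 + 1e-12
    inv <- 1 / g
    c(w1 = inv[2L] / sum(inv), w2 = inv[1L] / sum(inv))
  }
}

#' Representative vulture (leader) selection
#'
#' Draws p = rand * |F| and returns the best leader if p < w1, the second
#' best if w1 <= p < w1 + w2, and otherwise a uniformly random population
#' member. With fewer than three ranked leaders the best available
#' position is returned.
#'
#' @param best_pos matrix whose rows are the ranked best positions
#'   (best first).
#' @param best_fit fitness values of those positions.
#' @param F current starvation rate.
#' @param population matrix of all current positions (for the random
#'   fallback).
#' @param weighting passed to [leader_weights()].
#' @param probs optional explicit `c(w1, w2)` overriding the computed
#'   weights.
#' @return A position vector.
#' @export
select_leader <- function(best_pos, best_fit, F, population,
                          weighting = "proportional", probs = NULL) {
  best_pos <- as.matrix(best_pos)
  if (nrow(best_pos) < 3L) return(best_pos[1L, ])
  w <- probs %||% leader_weights(best_fit[1:3], weighting)
  p <- stats::runif(1) * abs(F)
  if (p < w[1L]) best_pos[1L, ]
  else if (p < w[1L] + w[2L]) best_pos[2L, ]
  else population[sample(nrow(population), 1L), ]
}

#' Rotating flight (spiral exploitation) move
#'
#' Generates two spiral candidates around the leader,
#' `B1 = R +/- S1` and `B2 = R +/- S2` with
#' `S1 = rand * (R - P) * F * cos(theta)` and
#' `S2 = rand * (R - P) * F * sin(theta)` elementwise, and greedily keeps
#' the candidate with better evaluated fitness. The trig argument is the
#' elementwise product `2 * P * R` clipped to +/- 10 pi
#' (`trig = "product"`), or `2 pi u` with fresh uniform u per dimension
#' (`trig = "uniform"`). The +/- sign is drawn uniformly per candidate.
#' With F = 0 or P = R both candidates collapse onto R.
#'
#' @param R leader position.
#' @param P current position.
#' @param F starvation rate.
#' @param eval_fn function(position) -> fitness, used for the greedy pick.
#' @param trig `"product"` (default) or `"uniform"`.
#' @return A list with `position` and its `score`.
#' @export
rotating_flight <- function(R, P, F, eval_fn,
                            trig = c("product", "uniform")) {
  trig <- match.arg(trig)
  k <- length(R)
  stopifnot(length(P) == k)
  ang <- if (trig == "product") clamp(2 * P * R, -10 * pi, 10 * pi)
         else 2 * pi * stats::runif(k)
  S1 <- stats::runif(k) * ((R - P) * F * cos(ang))
  S2 <- stats::runif(k) * ((R - P) * F * sin(ang))
  B1 <- R + sample(c(-1, 1), 1L) * S1
  B2 <- R + sample(c(-1, 1), 1L) * S2
  f1 <- eval_fn(B1); f2 <- eval_fn(B2)
  if (f1 >= f2) list(position = B1, score = f1)
  else list(position = B2, score = f2)
}

#' Accumulation (aggregation) move around the elite vultures
#'
#' Builds elite-anchored points `C_m = BV_m - (BV_m * x) /
#' ((BV_m - x)^2 + eps) * F` elementwise (m = 1..3, x the current
#' position), averages them into `C4 = (C1 + C2)/2` and
#' `C5 = (C1 + C3)/2`, and greedily returns the fitter. Coordinates with
#' exactly zero displacement contribute no correction, so a fully
#' converged swarm (all elites = x) is a fixed point; `eps` guards
#' near-zero denominators. `sam_form = "literal"` reproduces the printed
#' asymmetric transcription instead.
#'
#' @param best3 3-row matrix of the ranked best positions.
#' @param R leader position (used by the literal form).
#' @param P current position.
#' @param F starvation rate.
#' @param eval_fn function(position) -> fitness.
#' @param sam_form `"symmetrized"` (default) or `"literal"`.
#' @param eps denominator guard (default 1e-12).
#' @return A list with `position` and its `score`.
#' @export
accumulation_move <- function(best3, R, P, F, eval_fn,
                              sam_form = c("symmetrized", "literal"),
                              eps = 1e-12) {
  sam_form <- match.arg(sam_form)
  best3 <- as.matrix(best3)
  stopifnot(nrow(best3) == 3L)
  corr <- function(BV, x) {
    d2 <- (BV - x)^2
    term <- (BV * x) / (d2 + eps) * F
    term[d2 == 0] <- 0
    term
  }
  if (sam_form == "symmetrized") {
    C1 <- best3[1L, ] - corr(best3[1L, ], P)
    C2 <- best3[2L, ] - corr(best3[2L, ], P)
    C3 <- best3[3L, ] - corr(best3[3L, ], P)
  } else {
    C1 <- best3[1L, ] - corr(best3[1L, ], R)
    d2 <- (best3[2L, ] - R)^2
    lit <- function(BV) {
      term <- (best3[2L, ] * P) / (d2 + eps) * F
      term[d2 == 0] <- 0
      BV - term
    }
    C2 <- lit(best3[2L, ])
    C3 <- lit(best3[3L, ])
  }
  C4 <- (C1 + C2) / 2
  C5 <- (C1 + C3) / 2
  f4 <- eval_fn(C4); f5 <- eval_fn(C5)
  if (f4 >= f5) list(position = C4, score = f4)
  else list(position = C5, score = f5)
}

#' Enhanced African vulture optimization over drug subsets
#'
#' EAVOA baseline with the three enhancement mechanisms: representative
#' leader selection ([select_leader()]), rotating flight
#' ([rotating_flight()]) and the accumulation mechanism
#' ([accumulation_move()]), phase-switched by the starvation rate:
#' |F| >= 1 triggers the exploration move (towards the leader with a
#' stochastic jump, or a uniform random point, each with probability 0.5),
#' 0.5 <= |F| < 1 the accumulation move, |F| < 0.5 the rotating flight.
#'
#' @inheritParams pso_run
#' @param h starvation disturbance amplitude (default 0.5).
#' @param weighting leader weighting, see [leader_weights()].
#' @param sam_form see [accumulation_move()].
#' @param trig see [rotating_flight()].
#' @return A `swarm_run` (best selection, fitness, non-decreasing
#'   convergence curve, evaluation counters).
#' @export
eavoa_run <- function(table, k, weights = criterion_weights(), pop = 30,
                      iters = 500, seed = 1, h = 0.5,
                      weighting = "proportional",
                      sam_form = "symmetrized", trig = "product") {
  ctx <- make_ctx(table, weights, k)
  if (pop < 3) stop("pop must be >= 3")
  set.seed(seed)
  cnt_init <- new_counter(); cnt_loop <- new_counter()

  pos <- matrix(stats::runif(pop * k, 1, ctx$D), pop, k)
  de <- apply(pos, 1L, decode_eval, ctx = ctx, counter = cnt_init)
  cur_sel <- lapply(de, `[[`, "sel")
  cur_score <- vapply(de, `[[`, numeric(1L), "score")
  gb <- which.max(cur_score)
  gbest <- list(pos = pos[gb, ], score = cur_score[gb],
                sel = cur_sel[[gb]])

  curve <- numeric(iters)
  for (t in seq_len(iters)) {
    ord <- order(cur_score, decreasing = TRUE)
    best3 <- pos[ord[1:3], , drop = FALSE]
    best3_fit <- cur_score[ord[1:3]]
    for (i in seq_len(pop)) {
      Fi <- starvation_rate(t, iters, h)
      lead <- select_leader(best3, best3_fit, Fi, pos, weighting)
      cache <- list()
      eval_fn <- function(p) {
        d <- decode_eval(p, ctx, cnt_loop)
        cache[[length(cache) + 1L]] <<- list(p = p, d = d)
        d$score
      }
      if (abs(Fi) >= 1) {                      # exploration
        newpos <- if (stats::runif(1) < 0.5) {
          lead - abs(2 * stats::runif(ctx$k) * lead - pos[i, ]) * Fi
        } else {
          stats::runif(ctx$k, 1, ctx$D)
        }
        d <- decode_eval(newpos, ctx, cnt_loop)
        res <- list(position = newpos, score = d$score)
        cache <- list(list(p = newpos, d = d))
      } else if (abs(Fi) >= 0.5) {             # accumulation (SAM)
        res <- accumulation_move(best3, lead, pos[i, ], Fi, eval_fn,
                                 sam_form = sam_form)
      } else {                                 # rotating flight (RFS)
        res <- rotating_flight(lead, pos[i, ], Fi, eval_fn, trig = trig)
      }
      hit <- Find(function(e) identical(e$p, res$position), cache)
      pos[i, ] <- clamp(res$position, 1, ctx$D)
      cur_score[i] <- hit$d$score
      cur_sel[[i]] <- hit$d$sel
      if (cur_score[i] > gbest$score)
        gbest <- list(pos = pos[i, ], score = cur_score[i],
                      sel = cur_sel[[i]])
    }
    curve[t] <- gbest$score
  }
  swarm_result("eavoa", ctx, table, gbest, curve,
               list(init = cnt_init$n, loop = cnt_loop$n,
                    total = cnt_init$n + cnt_loop$n),
               seed, pop, iters)
}
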