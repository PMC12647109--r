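#' Hybrid schedule constants
#'
#' The fixed schedules and phase constants of the hybrid optimizer:
#' inertia endpoints (0.9 -> 0.4), acceleration schedules
#' (c1: 2.5 - 2 t/T, c2: 0.5 + 2 t/T), phase thresholds (early phase up to
#' 0.4 T, balanced phase up to 0.7 T, late exploitation after), the Levy
#' mutation period (every 20 iterations), stagnation restart threshold
#' (6 iterations without personal improvement), elite count (2), gene swap
#' count (2), mid-phase attraction (0.7) and perturbation ranges
#' (integers in [-3, 3] mid-phase, [-5, 5] early), and the Levy tail index
#' beta = 1.5.
#'
#' @param wmax,wmin inertia endpoints.
#' @param c1_start,c1_slope,c2_start,c2_slope acceleration schedules.
#' @param mid_phase_frac,late_phase_frac phase thresholds as fractions of T.
#' @param levy_period iterations between global Levy mutations.
#' @param restart_threshold stagnant iterations before a restart.
#' @param elite_count elites carried unmodified.
#' @param gene_swap_count genes swapped with the global best late-phase.
#' @param mid_influence attraction strength towards the global best
#'   mid-phase.
#' @param mid_perturb,early_perturb integer perturbation half-ranges.
#' @param levy_beta,levy_scale Levy tail index and step scale.
#' @param h starvation disturbance for the early-phase leader draw.
#' @return A list of class `hybrid_schedule`.
#' @export
hybrid_schedule <- function(wmax = 0.9, wmin = 0.4, c1_start = 2.5,
                            c1_slope = 2.0, c2_start = 0.5, c2_slope = 2.0,
                            mid_phase_frac = 0.4, late_phase_frac = 0.7,
                            levy_period = 20, restart_threshold = 6,
                            elite_count = 2, gene_swap_count = 2,
                            mid_influence = 0.7, mid_perturb = 3,
                            early_perturb = 5, levy_beta = 1.5,
                            levy_scale = 1, h = 0.5) {
  if (!(mid_phase_frac > 0 && mid_phase_frac < late_phase_frac &&
        late_phase_frac < 1))
    stop("need 0 < mid_phase_frac < late_phase_frac < 1")
  if (levy_period < 1) stop("levy_period must be >= 1")
  if (elite_count < 1) stop("elite_count must be >= 1")
  structure(as.list(environment()), class = "hybrid_schedule")
}

#' Time-varying acceleration coefficients
#'
#' `c1 = 2.5 - 2 t/T` (cognitive/leader attraction, decaying) and
#' `c2 = 0.5 + 2 t/T` (social attraction, growing); their sum is constant.
#'
#' @param t current iteration (0 <= t <= T).
#' @param T maximum iteration (>= 1).
#' @param c1_start,c1_slope,c2_start,c2_slope schedule constants.
#' @return Named numeric `c(c1, c2)`.
#' @export
accel_coefficients <- function(t, T, c1_start = 2.5, c1_slope = 2.0,
                               c2_start = 0.5, c2_slope = 2.0) {
  if (T < 1) stop("T must be >= 1")
  if (any(t < 0) || any(t > T)) stop("t must be within [0, T]")
  c(c1 = c1_start - c1_slope * t / T, c2 = c2_start + c2_slope * t / T)
}

#' Mantegna scale constant for Levy steps
#'
#' `sigma_u = [Gamma(1+beta) sin(pi beta/2) /
#' (Gamma((1+beta)/2) beta 2^((beta-1)/2))]^(1/beta)`; about 0.6966 at
#' beta = 1.5.
#'
#' @param beta tail index, 1 < beta <= 2.
#' @return The numerator scale sigma_u.
#' @export
mantegna_sigma <- function(beta) {
  if (beta <= 1 || beta > 2) stop("beta must be in (1, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Heavy-tailed Levy flight step (Mantegna construction)
#'
#' `step_i = u_i / |v_i|^(1/beta)` with u ~ N(0, sigma_u^2), v ~ N(0, 1);
#' symmetric around zero with power-law tails enabling occasional long
#' jumps.
#'
#' @param dim number of dimensions.
#' @param beta tail index (default 1.5).
#' @param scale multiplicative step size (default 1).
#' @return Numeric vector of `dim` steps.
#' @export
levy_step <- function(dim, beta = 1.5, scale = 1) {
  sigma <- mantegna_sigma(beta)
  u <- stats::rnorm(dim, 0, sigma)
  v <- stats::rnorm(dim)
  scale * u / abs(v)^(1 / beta)
}

#' Hybrid velocity update towards a vulture leader
#'
#' The hybrid's PSO-style update with the personal best replaced by a
#' vulture leader: `v <- w v + c1 r1 (best_vulture - x) +
#' c2 r2 (gbest - x)`; `x <- x + v`, with fresh uniform r1, r2 per
#' dimension (injectable for deterministic checks).
#'
#' @param x,v current position and velocity.
#' @param best_vulture leader position drawn by [select_leader()].
#' @param gbest global best position.
#' @param w inertia weight.
#' @param c1,c2 acceleration coefficients.
#' @param r1,r2 optional fixed random vectors (default fresh U(0,1)).
#' @return List with updated `position` and `velocity`.
#' @export
hybrid_velocity_update <- function(x, v, best_vulture, gbest, w, c1, c2,
                                   r1 = NULL, r2 = NULL) {
  k <- length(x)
  r1 <- r1 %||% stats::runif(k)
  r2 <- r2 %||% stats::runif(k)
  v <- w * v + c1 * r1 * (best_vulture - x) + c2 * r2 * (gbest - x)
  list(position = x + v, velocity = v)
}

#' Opposition-based swarm initialization
#'
#' Draws `pop` uniform positions in \[1, D\]^k, mirrors each coordinate to
#' its opposite `(D + 1) - x`, evaluates all `2 pop` decoded candidates
#' and keeps the best `pop` as the initial swarm (velocities zero). Uses
#' the session RNG.
#'
#' @param table a normalized `drug_table`.
#' @param k subset size.
#' @param pop swarm size.
#' @param weights a [criterion_weights()].
#' @return List with `pos`, `vel`, `sel`, `score` and the evaluation count
#'   `evals`.
#' @export
opposition_init <- function(table, k, pop, weights = criterion_weights()) {
  ctx <- make_ctx(table, weights, k)
  if (pop < 2) stop("pop must be >= 2")
  cnt <- new_counter()
  X <- matrix(stats::runif(pop * k, 1, ctx$D), pop, k)
  O <- (ctx$D + 1) - X
  allp <- rbind(X, O)
  de <- apply(allp, 1L, decode_eval, ctx = ctx, counter = cnt)
  score <- vapply(de, `[[`, numeric(1L), "score")
  keep <- order(score, decreasing = TRUE)[seq_len(pop)]
  list(pos = allp[keep, , drop = FALSE], vel = matrix(0, pop, k),
       sel = lapply(de[keep], `[[`, "sel"), score = score[keep],
       evals = cnt$n)
}

#' Hybrid PSO-EAVOA optimizer over drug subsets
#'
#' The package's core optimizer: opposition-based initialization followed
#' by phase-switched per-particle updates over T iterations.
#'
#' Per particle, exactly one branch applies each iteration:
#' \describe{
#'   \item{late (t > 0.7 T)}{with probability 0.5 replace two random genes
#'     with the corresponding global-best genes, otherwise add a Levy
#'     perturbation ([levy_step()]);}
#'   \item{balanced (0.4 T < t <= 0.7 T)}{`x <- x + 0.7 (gbest - x) +
#'     (2 - 2 t/T) * perturb` with integer perturbations in \[-3, 3\] per
#'     gene;}
#'   \item{early (t <= 0.4 T)}{with probability 0.5 the hybrid velocity
#'     update ([hybrid_velocity_update()]) towards a leader drawn from the
#'     personal-best pool by [select_leader()], otherwise integer noise in
#'     \[-5, 5\] per gene.}
#' }
#' Every 20th iteration every particle additionally receives a Levy
#' mutation; a particle stagnant for 6 iterations (against its own
#' personal best) is reinitialized uniformly at random. After the particle
#' loop the worst particle is replaced by the global best and the top-2
#' elites are re-inserted if their scores would otherwise be lost, so the
#' global best never degrades.
#'
#' @inheritParams pso_run
#' @param schedule a [hybrid_schedule()].
#' @param weighting leader weighting, see [leader_weights()].
#' @return A `swarm_run` with additional fields `branch_counts` (late /
#'   balanced / early executions), `n_restarts` and `n_levy_events`.
#' @export
hybrid_run <- function(table, k, weights = criterion_weights(), pop = 30,
                       iters = 500, seed = 1,
                       schedule = hybrid_schedule(),
                       weighting = "proportional") {
  ctx <- make_ctx(table, weights, k)
  if (pop < 3) stop("pop must be >= 3")
  s <- schedule
  set.seed(seed)
  cnt_loop <- new_counter()

  init <- opposition_init(table, k, pop, weights)
  pos <- init$pos; vel <- init$vel
  cur_sel <- init$sel; cur_score <- init$score
  pbest_pos <- pos; pbest_score <- cur_score; pbest_sel <- cur_sel
  no_improve <- integer(pop)
  gb <- which.max(pbest_score)
  gbest <- list(pos = pbest_pos[gb, ], score = pbest_score[gb],
                sel = pbest_sel[[gb]])

  n_swap <- min(k, s$gene_swap_count)
  branch_counts <- c(late = 0L, balanced = 0L, early = 0L)
  n_restarts <- 0L; n_levy_events <- 0L
  curve <- numeric(iters)

  for (t in seq_len(iters)) {
    w <- inertia_weight(t, iters, s$wmax, s$wmin)
    cc <- accel_coefficients(t, iters, s$c1_start, s$c1_slope,
                             s$c2_start, s$c2_slope)
    ordp <- order(pbest_score, decreasing = TRUE)
    best3 <- pbest_pos[ordp[seq_len(min(3L, pop))], , drop = FALSE]
    best3_fit <- pbest_score[ordp[seq_len(min(3L, pop))]]
    n_elite <- min(s$elite_count, pop)
    elite_idx <- ordp[seq_len(n_elite)]
    elite_pos <- pbest_pos[elite_idx, , drop = FALSE]
    elite_score <- pbest_score[elite_idx]
    elite_sel <- pbest_sel[elite_idx]

    for (i in seq_len(pop)) {
      if (t > s$late_phase_frac * iters) {
        branch_counts["late"] <- branch_counts["late"] + 1L
        if (stats::runif(1) < 0.5) {
          g <- sample(k, n_swap)
          pos[i, g] <- gbest$pos[g]
        } else {
          pos[i, ] <- pos[i, ] +
            levy_step(k, s$levy_beta, s$levy_scale)
        }
      } else if (t > s$mid_phase_frac * iters) {
        branch_counts["balanced"] <- branch_counts["balanced"] + 1L
        perturb <- sample(seq(-s$mid_perturb, s$mid_perturb), k,
                          replace = TRUE)
        pos[i, ] <- pos[i, ] + s$mid_influence * (gbest$pos - pos[i, ]) +
          (2 - 2 * t / iters) * perturb
      } else {
        branch_counts["early"] <- branch_counts["early"] + 1L
        if (stats::runif(1) < 0.5) {
          Fi <- starvation_rate(t, iters, s$h)
          lead <- select_leader(best3, best3_fit, Fi, pbest_pos, weighting)
          upd <- hybrid_velocity_update(pos[i, ], vel[i, ], lead,
                                        gbest$pos, w, cc["c1"], cc["c2"])
          pos[i, ] <- upd$position
          vel[i, ] <- upd$velocity
        } else {
          pos[i, ] <- pos[i, ] +
            sample(seq(-s$early_perturb, s$early_perturb), k,
                   replace = TRUE)
        }
      }
      if (t %% s$levy_period == 0) {
        pos[i, ] <- pos[i, ] + levy_step(k, s$levy_beta, s$levy_scale)
        n_levy_events <- n_levy_events + 1L
      }
      if (no_improve[i] >= s$restart_threshold) {
        pos[i, ] <- stats::runif(k, 1, ctx$D)
        vel[i, ] <- 0
        no_improve[i] <- 0L
        n_restarts <- n_restarts + 1L
      }
      pos[i, ] <- clamp(pos[i, ], 1, ctx$D)
      d <- decode_eval(pos[i, ], ctx, cnt_loop)
      cur_score[i] <- d$score
      cur_sel[[i]] <- d$sel
      if (d$score > pbest_score[i]) {
        pbest_score[i] <- d$score
        pbest_pos[i, ] <- pos[i, ]
        pbest_sel[[i]] <- d$sel
        no_improve[i] <- 0L
      } else {
        no_improve[i] <- no_improve[i] + 1L
      }
      if (d$score > gbest$score)
        gbest <- list(pos = pos[i, ], score = d$score, sel = d$sel)
    }

    # worst particle -> global best
    worst <- which.min(cur_score)
    pos[worst, ] <- gbest$pos
    vel[worst, ] <- 0
    cur_score[worst] <- gbest$score
    cur_sel[[worst]] <- gbest$sel
    if (gbest$score > pbest_score[worst]) {
      pbest_score[worst] <- gbest$score
      pbest_pos[worst, ] <- gbest$pos
      pbest_sel[[worst]] <- gbest$sel
    }

    # elite preservation: re-insert snapshots over the worst slots
    ordc <- order(cur_score)
    slots <- setdiff(ordc, worst)[seq_len(n_elite)]
    for (j in seq_len(n_elite)) {
      sl <- slots[j]
      if (elite_score[j] > cur_score[sl]) {
        pos[sl, ] <- elite_pos[j, ]
        vel[sl, ] <- 0
        cur_score[sl] <- elite_score[j]
        cur_sel[[sl]] <- elite_sel[[j]]
        if (elite_score[j] > pbest_score[sl]) {
          pbest_score[sl] <- elite_score[j]
          pbest_pos[sl, ] <- elite_pos[j, ]
          pbest_sel[[sl]] <- elite_sel[[j]]
        }
      }
    }
    curve[t] <- gbest$score
  }
  swarm_result("hybrid", ctx, table, gbest, curve,
               list(init = init$evals, loop = cnt_loop$n,
                    total = init$evals + cnt_loop$n),
               seed, pop, iters,
               extras = list(branch_counts = branch_counts,
                             n_restarts = n_restarts,
                             n_levy_events = n_levy_events))
  }
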