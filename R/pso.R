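#' Swarm configuration for ICM parameter tuning
#'
#' Fixed hyper-parameters of the global-best particle swarm: 50 particles
#' and acceleration coefficients `c1 = c2 = 2` (the conventional settings),
#' a linearly decaying inertia schedule (see [inertia()]), a per-dimension
#' velocity clamp, and the ranges the raw `[0, 1]` particle coordinates are
#' scaled into (see [scale_particle()]).
#'
#' @param population Number of particles (default 50).
#' @param c1,c2 Cognitive and social acceleration coefficients (default 2).
#' @param max_iterations Iteration ceiling (default 50; convergence is
#'   typically reached within the first few iterations and the run stops
#'   early once the fitness tolerance is met).
#' @param v_max Velocity clamp per dimension in the unit box (default 0.25).
#' @param seed RNG seed for the swarm initialisation and updates, or `NULL`
#'   to use the current RNG state.
#' @param h_low,h_high Magnitude range for the (negative) threshold
#'   amplitude `h` (default 0.1 to 10: at least 0.1 so fired thresholds keep
#'   dropping, at most 10 to keep the threshold scale commensurate with the
#'   unit stimulus).
#' @param n_max Maximum ICM iteration count (default 5).
#' @param e_init Initial ICM threshold handed to [scale_particle()]
#'   (default 5).
#' @param patience Stagnation stop: end the run after this many consecutive
#'   iterations without any global-best improvement (default 10, matching
#'   the flat convergence the method shows after its first few evaluations;
#'   `Inf` disables it).
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(population = 50, c1 = 2, c2 = 2,
                         max_iterations = 50, v_max = 0.25, seed = NULL,
                         h_low = 0.1, h_high = 10, n_max = 5, e_init = 5,
                         patience = 10) {
  stopifnot(population >= 2, c1 > 0, c2 > 0, max_iterations >= 0,
            v_max > 0, h_low > 0, h_high > h_low, n_max >= 1, patience >= 1)
  structure(list(population = as.integer(population), c1 = c1, c2 = c2,
                 max_iterations = as.integer(max_iterations), v_max = v_max,
                 seed = seed, h_low = h_low, h_high = h_high,
                 n_max = as.integer(n_max), e_init = e_init,
                 patience = patience),
            class = "swarm_config")
}

#' Linearly decaying inertia weight
#'
#' `w(t) = 0.9 - 0.5 * t / t_max`: starts at 0.9 (exploration) and ends at
#' 0.4 (exploitation).
#'
#' @param t Current iteration (0 to `t_max`).
#' @param t_max Maximum iteration count (> 0).
#' @return The inertia weight.
#' @export
inertia <- function(t, t_max) {
  if (t_max <= 0) stop("t_max must be positive")
  0.9 - 0.5 * (t / t_max)
}

#' Map a raw particle position to valid ICM parameters
#'
#' The swarm searches the unit box; each coordinate is scaled into the range
#' the network requires so every particle is a feasible parameter set:
#' `f = 0.05 + 0.94 p1` (inside (0, 1)), `g = f * (0.05 + 0.9 p2)`
#' (enforcing `g < f`), `h = -(h_low + p3 (h_high - h_low))` (negative), and
#' `n = 1 + round(p4 (n_max - 1))` (an integer iteration count in
#' `1..n_max`).
#'
#' @param position Numeric 4-vector; coordinates are clipped to `[0, 1]`.
#' @param config [swarm_config()] providing `h_low`, `h_high`, `n_max`,
#'   `e_init`.
#' @return An [icm_params()] object.
#' @export
scale_particle <- function(position, config = swarm_config()) {
  stopifnot(length(position) == 4L)
  p <- pmin(pmax(position, 0), 1)
  f <- 0.05 + 0.94 * p[1]
  g <- f * (0.05 + 0.9 * p[2])
  h <- -(config$h_low + p[3] * (config$h_high - config$h_low))
  n <- 1L + as.integer(round(p[4] * (config$n_max - 1L)))
  icm_params(f = f, g = g, h = h, n_iterations = n, e_init = config$e_init)
}

#' Particle velocity update
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, componentwise, then
#' clamped to `[-v_max, v_max]`.
#'
#' @param velocity,position,pbest,gbest Numeric vectors of equal length.
#' @param w Inertia weight.
#' @param c1,c2 Acceleration coefficients.
#' @param r1,r2 Uniform random vectors in `[0, 1]` (same length).
#' @param v_max Velocity clamp.
#' @return The updated velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest, gbest, w, c1, c2,
                            r1, r2, v_max) {
  v <- w * velocity + c1 * r1 * (pbest - position) +
    c2 * r2 * (gbest - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Particle position update
#'
#' `x' = x + v'`, clipped into the unit box.
#'
#' @param position,velocity Numeric vectors of equal length.
#' @return The updated position.
#' @export
update_position <- function(position, velocity) {
  pmin(pmax(position + velocity, 0), 1)
}

#' Global-best particle swarm minimisation in the unit box
#'
#' Generic PSO core used by [tune_icm()]: positions are initialised
#' uniformly in `[0, 1]^d`, velocities uniformly in `[-v_max, v_max]`;
#' personal and global bests are replaced only on strict improvement; the
#' run stops when the global best fitness drops to `tolerance` or below,
#' when the global best has stagnated for `config$patience` consecutive
#' iterations, or after `max_iterations` velocity/position updates.
#'
#' @param objective Function taking a position vector, returning a scalar
#'   fitness to minimise.
#' @param d Search-space dimension.
#' @param config [swarm_config()].
#' @param tolerance Early-stopping fitness tolerance (default 0: run to the
#'   iteration ceiling unless an exact optimum is found).
#' @return A list: `gbest` (best position), `gbest_fitness`,
#'   `convergence_trace` (gbest fitness after initialisation and after each
#'   iteration; non-increasing), `evaluations_used`, `iterations_used`.
#' @export
pso_minimize <- function(objective, d, config = swarm_config(),
                         tolerance = 0) {
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$population
  pos <- matrix(stats::runif(np * d), nrow = np)
  vel <- matrix(stats::runif(np * d, -config$v_max, config$v_max), nrow = np)

  fit <- apply(pos, 1L, objective)
  pbest <- pos
  pbest_fit <- fit
  gi <- which.min(fit)
  gbest <- pos[gi, ]
  gbest_fit <- fit[gi]
  evals <- np
  trace <- gbest_fit

  t_max <- max(config$max_iterations, 1L)
  iters <- 0L
  stagnant <- 0L
  patience <- if (is.null(config$patience)) Inf else config$patience
  while (iters < config$max_iterations && gbest_fit > tolerance &&
         stagnant < patience) {
    iters <- iters + 1L
    improved <- FALSE
    w <- inertia(iters, t_max)
    for (i in seq_len(np)) {
      r1 <- stats::runif(d)
      r2 <- stats::runif(d)
      vel[i, ] <- update_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                  w, config$c1, config$c2, r1, r2,
                                  config$v_max)
      pos[i, ] <- update_position(pos[i, ], vel[i, ])
      fi <- objective(pos[i, ])
      evals <- evals + 1L
      if (fi < pbest_fit[i]) {
        pbest_fit[i] <- fi
        pbest[i, ] <- pos[i, ]
      }
      if (fi < gbest_fit) {
        gbest_fit <- fi
        gbest <- pos[i, ]
        improved <- TRUE
      }
    }
    stagnant <- if (improved) 0L else stagnant + 1L
    trace <- c(trace, gbest_fit)
  }

  list(gbest = gbest, gbest_fitness = gbest_fit,
       convergence_trace = trace, evaluations_used = evals,
       iterations_used = iters)
}

#' Tune the four ICM parameters for one frame
#'
#' Runs [pso_minimize()] over the four raw coordinates mapped by
#' [scale_particle()]; each evaluation segments the LoG stimulus with
#' [run_icm()] and scores `|MI(frame, mask) - mi_target|` via
#' [mutual_information()] and [fitness_error()]. The mutual information is
#' always computed against the original grayscale frame, not the filtered
#' stimulus.
#'
#' @param image Original grayscale frame in `[0, 1]`.
#' @param s_image LoG-preprocessed stimulus of the same shape (from
#'   [apply_log()]).
#' @param swarm [swarm_config()].
#' @param fitness [fitness_config()].
#' @param mask_filter Optional function `(mask) -> mask` applied to each
#'   candidate pulse image before its mutual information is computed --
#'   [segment_frame()] passes the feature-level cleanup ([refine_mask()])
#'   here so the fitness scores the detector's actual segmentation output.
#'   `NULL` scores the raw pulse image.
#' @return A list: `best_params` ([icm_params()]), `best_fitness`,
#'   `best_mask` (0/1 matrix from the best parameters, after `mask_filter`
#'   if given), `best_mi`, `convergence_trace`, `evaluations_used`,
#'   `iterations_used`.
#' @export
tune_icm <- function(image, s_image, swarm = swarm_config(),
                     fitness = fitness_config(), mask_filter = NULL) {
  if (!all(dim(image) == dim(s_image))) {
    stop("image and stimulus must have the same shape")
  }
  bins <- fitness$intensity_bins
  xq <- quantize_intensity(image, bins)
  candidate <- function(p) {
    params <- scale_particle(p, swarm)
    mask <- run_icm(s_image, params)$mask
    if (!is.null(mask_filter)) mask <- mask_filter(mask)
    mask
  }
  objective <- function(p) {
    mi <- mutual_information(xq, candidate(p), bins = bins, quantized = TRUE)
    fitness_error(mi, fitness)
  }
  res <- pso_minimize(objective, d = 4L, config = swarm,
                      tolerance = fitness$tolerance)
  best_params <- scale_particle(res$gbest, swarm)
  best_mask <- candidate(res$gbest)
  best_mi <- mutual_information(xq, best_mask, bins = bins, quantized = TRUE)
  list(best_params = best_params, best_fitness = res$gbest_fitness,
       best_mask = best_mask, best_mi = best_mi,
       convergence_trace = res$convergence_trace,
       evaluations_used = res$evaluations_used,
       iterations_used = res$iterations_used)
}
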