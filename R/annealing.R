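#' Simulated-annealing run configuration
#'
#' Collects the tunable parameters of the multiobjective annealing loop.
#' Defaults follow the reference settings: 20 steps per temperature, rank
#' cutoff 5 (archive admits rank <= 4), minimum temperature 0.001, cooling
#' factor 0.9 and penalty weight 100. The initial temperature defaults to 1,
#' which with rank-valued energies gives a permissive early search
#' (`exp(-rank)` acceptance).
#'
#' @param initial_temperature Starting temperature (> 0), default 1.
#' @param cooling_alpha Geometric cooling factor in (0, 1), default 0.9.
#' @param temperature_min Temperature at which the run stops (> 0),
#'   default 0.001.
#' @param steps_per_temperature Iterations at each temperature, default 20.
#' @param rank_cutoff Archive admission threshold: candidates with rank
#'   strictly below this enter the archive, default 5.
#' @param penalty_lambda Default constraint penalty weight carried into
#'   problems that do not set their own, default 100.
#' @param neighbor_scale Standard deviation of the default Gaussian
#'   perturbation, as a fraction of each bound interval, default 0.1.
#' @param rng_seed Optional integer seed; when given the run is reproducible.
#' @param show_trace Print a per-temperature progress line, default `FALSE`.
#' @param hybrid_mode Run a single-objective local refinement of the best
#'   objective-sum archive member at every temperature drop, default `FALSE`.
#' @return An object of class `sa_config`.
#' @export
sa_config <- function(initial_temperature = 1,
                      cooling_alpha = 0.9,
                      temperature_min = 0.001,
                      steps_per_temperature = 20L,
                      rank_cutoff = 5L,
                      penalty_lambda = 100,
                      neighbor_scale = 0.1,
                      rng_seed = NULL,
                      show_trace = FALSE,
                      hybrid_mode = FALSE) {
  stopifnot(initial_temperature > 0,
            cooling_alpha > 0, cooling_alpha < 1,
            temperature_min > 0,
            steps_per_temperature >= 1L,
            rank_cutoff >= 1L,
            penalty_lambda >= 0,
            neighbor_scale >= 0, neighbor_scale <= 1)
  structure(list(initial_temperature = initial_temperature,
                 cooling_alpha = cooling_alpha,
                 temperature_min = temperature_min,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 rank_cutoff = as.integer(rank_cutoff),
                 penalty_lambda = penalty_lambda,
                 neighbor_scale = neighbor_scale,
                 rng_seed = rng_seed,
                 show_trace = isTRUE(show_trace),
                 hybrid_mode = isTRUE(hybrid_mode)),
            class = "sa_config")
}

#' Rank-based acceptance probability
#'
#' `exp(-rank / T)`: rank-0 (nondominated) candidates are always accepted;
#' higher-rank candidates are accepted with a probability that shrinks as
#' the temperature cools, which is what focuses the search onto the
#' trade-off surface while still allowing diversity early on.
#'
#' @param rank Non-negative Pareto rank of the candidate.
#' @param T Temperature, strictly positive.
#' @return Acceptance probability in (0, 1].
#' @export
acceptance_probability <- function(rank, T) {
  if (T <= 0) stop("temperature must be strictly positive")
  stopifnot(rank >= 0)
  exp(-rank / T)
}

#' Default neighbor: bounded Gaussian perturbation
#'
#' Adds an independent Gaussian step to each coordinate with standard
#' deviation `scale * (upper - lower)` and clips the result back into the
#' box. Coordinates with a degenerate interval (`upper == lower`) stay
#' fixed.
#'
#' @param p Current decision vector (inside the box).
#' @param lower,upper Bound vectors.
#' @param scale Perturbation scale as a fraction of each interval width.
#' @return A new decision vector inside the box.
#' @export
neighbor_default <- function(p, lower, upper, scale = 0.1) {
  step <- stats::rnorm(length(p), mean = 0, sd = scale * (upper - lower))
  clip_to_bounds(p + step, lower, upper)
}

#' Default cooling: geometric schedule
#'
#' @param T Current temperature.
#' @param alpha Cooling factor in (0, 1).
#' @return `alpha * T`.
#' @export
cooling_default <- function(T, alpha = 0.9) {
  if (alpha <= 0 || alpha >= 1) stop("cooling factor must lie in (0, 1)")
  alpha * T
}

#' Pass-through refinement (hybrid mode disabled behaviour)
#'
#' @param p Decision vector.
#' @param problem Ignored.
#' @return `p` unchanged.
#' @export
refine_passthrough <- function(p, problem) {
  p
}

#' Local single-objective refinement of the objective sum
#'
#' Hybrid mode temporarily collapses the multiobjective problem to the
#' scalar sum of its (penalized) objectives and polishes the given point
#' with a bounded derivative-free local search: `stats::optimize` on the
#' bound interval for one-dimensional problems, Nelder-Mead otherwise, with
#' proposals clipped into the box before evaluation. The result never has a
#' larger objective sum than the start; on any optimizer failure the start
#' point is returned unchanged.
#'
#' @param p Starting decision vector (inside the box).
#' @param problem A [moo_problem].
#' @param maxit Iteration budget for the simplex search, default 200.
#' @return A decision vector inside the box with objective sum `<=` that
#'   of `p`.
#' @export
refine_local <- function(p, problem, maxit = 200L) {
  fsum <- function(q) {
    val <- sum(evaluate_objectives(problem, clip_to_bounds(q, problem$lower,
                                                           problem$upper)))
    if (!is.finite(val)) val <- .Machine$double.xmax
    val
  }
  start_val <- fsum(p)
  cand <- tryCatch({
    if (problem$D == 1L) {
      opt <- stats::optimize(function(q) fsum(q), lower = problem$lower,
                             upper = problem$upper)
      opt$minimum
    } else {
      opt <- stats::optim(p, fsum, method = "Nelder-Mead",
                          control = list(maxit = maxit))
      opt$par
    }
  }, error = function(e) p)
  cand <- clip_to_bounds(cand, problem$lower, problem$upper)
  if (fsum(cand) <= start_val) cand else p
}

#' Hook set for the annealing loop
#'
#' The neighbor, cooling, acceptance and refinement functions are all
#' replaceable; the defaults implement the standard algorithm.
#'
#' @param neighbor `function(p, lower, upper, scale)` proposal generator.
#' @param cooling `function(T, alpha)` temperature update.
#' @param acceptance `function(rank, T)` acceptance probability.
#' @param refinement `function(p, problem)` hybrid-mode local refinement.
#' @return An object of class `poets_hooks`.
#' @export
poets_hooks <- function(neighbor = neighbor_default,
                        cooling = cooling_default,
                        acceptance = acceptance_probability,
                        refinement = refine_local) {
  stopifnot(is.function(neighbor), is.function(cooling),
            is.function(acceptance), is.function(refinement))
  structure(list(neighbor = neighbor, cooling = cooling,
                 acceptance = acceptance, refinement = refinement),
            class = "poets_hooks")
}

#' Run the multiobjective simulated-annealing loop
#'
#' The core algorithm: starting from `p0`, at each temperature propose
#' `steps_per_temperature` neighbors, evaluate the penalized objective
#' vector of each, Pareto-rank the candidate against the current objective
#' archive (pre-insertion), and accept it as the new working point with
#' probability `exp(-rank / T)`. Accepted candidates whose rank is strictly
#' below `rank_cutoff` are inserted into the archive, which is then
#' re-ranked and filtered so no member ever exceeds rank
#' `rank_cutoff - 1`. The temperature is cooled geometrically until it
#' falls below `temperature_min`. In hybrid mode the archive member with
#' the smallest objective sum is locally refined at every temperature drop
#' and the refined point re-injected as the working point (and archived if
#' it qualifies).
#'
#' @param problem A [moo_problem].
#' @param p0 Initial decision vector (finite; clipped into the box).
#' @param config An [sa_config]; defaults used when omitted.
#' @param hooks A [poets_hooks] set; defaults used when omitted.
#' @return An [ensemble_archive] with decision matrix `S`, objective matrix
#'   `O` and rank vector `R`.
#' @examples
#' prob <- moo_problem(function(p) c(p^2, (p - 2)^2),
#'                     lower = -10, upper = 10, K = 2)
#' arch <- run_poets(prob, p0 = 5,
#'                   config = sa_config(steps_per_temperature = 10,
#'                                      temperature_min = 0.1,
#'                                      rng_seed = 1))
#' max(arch$R) <= 4
#' @export
run_poets <- function(problem, p0, config = sa_config(),
                      hooks = poets_hooks()) {
  stopifnot(inherits(problem, "moo_problem"), inherits(config, "sa_config"))
  if (!all(is.finite(p0)) || length(p0) != problem$D) {
    stop("initial guess must be a finite vector of length ", problem$D)
  }
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  max_rank <- config$rank_cutoff - 1L

  p_cur <- clip_to_bounds(as.numeric(p0), problem$lower, problem$upper)
  o_cur <- evaluate_objectives(problem, p_cur)

  if (all(is.finite(o_cur))) {
    S <- matrix(p_cur, ncol = 1L)
    O <- matrix(o_cur, ncol = 1L)
  } else {
    S <- matrix(numeric(0), nrow = problem$D, ncol = 0L)
    O <- matrix(numeric(0), nrow = problem$K, ncol = 0L)
  }

  insert <- function(p, o) {
    arch <- filter_archive(cbind(S, p), cbind(O, o), max_rank = max_rank)
    S <<- arch$S
    O <<- arch$O
  }

  T <- config$initial_temperature
  while (T > config$temperature_min) {
    for (step in seq_len(config$steps_per_temperature)) {
      p_new <- hooks$neighbor(p_cur, problem$lower, problem$upper,
                              config$neighbor_scale)
      o_new <- evaluate_objectives(problem, p_new)
      r_new <- if (all(is.finite(o_new))) rank_candidate(o_new, O) else NA
      prob_acc <- if (is.na(r_new)) 0 else hooks$acceptance(r_new, T)
      if (stats::runif(1) <= prob_acc) {
        p_cur <- p_new
        o_cur <- o_new
        if (!is.na(r_new) && r_new < config$rank_cutoff) insert(p_new, o_new)
      }
    }
    if (config$hybrid_mode && ncol(O) > 0L) {
      best <- which.min(colSums(O))
      p_ref <- hooks$refinement(S[, best], problem)
      p_ref <- clip_to_bounds(p_ref, problem$lower, problem$upper)
      o_ref <- evaluate_objectives(problem, p_ref)
      if (all(is.finite(o_ref))) {
        p_cur <- p_ref
        o_cur <- o_ref
        if (rank_candidate(o_ref, O) < config$rank_cutoff) insert(p_ref, o_ref)
      }
    }
    if (config$show_trace) {
      mins <- if (ncol(O) > 0L) paste(signif(apply(O, 1, min), 4),
                                      collapse = " ") else "-"
      message(sprintf("T = %.5f  archive = %d  objective minima: %s",
                      T, ncol(O), mins))
    }
    T <- hooks$cooling(T, config$cooling_alpha)
  }
  filter_archive(S, O, max_rank = max_rank)
}

#' Multistart annealing with joint re-ranking
#'
#' Partitions the first coordinate's bound interval into `n_partitions`
#' equal segments, draws one uniform initial guess per segment (remaining
#' coordinates uniform over their full intervals), runs [run_poets()] from
#' each with a per-start seed derived from `config$rng_seed`, and pools the
#' per-start archives with [rerank_combined()] so the returned ranks are
#' valid for the collection.
#'
#' @param problem A [moo_problem].
#' @param n_partitions Number of starts / segments (default 10).
#' @param config An [sa_config]; `rng_seed` seeds the whole procedure.
#' @param hooks A [poets_hooks] set.
#' @return A jointly ranked [ensemble_archive].
#' @export
run_multistart <- function(problem, n_partitions = 10L,
                           config = sa_config(), hooks = poets_hooks()) {
  stopifnot(n_partitions >= 1L)
  n_partitions <- as.integer(n_partitions)
  base_seed <- config$rng_seed
  edges <- seq(problem$lower[1], problem$upper[1],
               length.out = n_partitions + 1L)
  archives <- vector("list", n_partitions)
  for (i in seq_len(n_partitions)) {
    cfg_i <- config
    cfg_i$rng_seed <- if (is.null(base_seed)) NULL else base_seed + i
    if (!is.null(cfg_i$rng_seed)) set.seed(cfg_i$rng_seed)
    p0 <- stats::runif(problem$D, problem$lower, problem$upper)
    p0[1] <- stats::runif(1, edges[i], edges[i + 1L])
    archives[[i]] <- run_poets(problem, p0, cfg_i, hooks)
  }
  rerank_combined(archives, max_rank = config$rank_cutoff - 1L)
}
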