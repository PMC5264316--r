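#' Generate conflicting synthetic training datasets
#'
#' Emulates measurements of the extracellular metabolites and cellmass on
#' several hypothetical cell types sharing one network topology but
#' differing in performance: for each dataset the mode rate constants `k`
#' are perturbed by an independent lognormal factor (coefficient of
#' variation `kinetic_cv`), the model is simulated, and multiplicative
#' lognormal measurement noise (`noise_cv`) is applied to the sampled
#' trajectory. With at least two datasets the per-dataset kinetics make
#' the objectives genuinely conflicting: no single parameter set can fit
#' every dataset exactly.
#'
#' @param true_params Generating [hcm_parameters]; defaults to
#'   `hcm_parameters()`.
#' @param n_datasets Number of datasets, default 4.
#' @param kinetic_cv Lognormal coefficient of variation of the per-dataset
#'   kinetic constants, default 0.25 (0 disables the perturbation).
#' @param noise_cv Lognormal coefficient of variation of measurement
#'   noise, default 0.05 (0 disables noise).
#' @param seed Optional integer seed for full reproducibility.
#' @param times Measurement time grid, default `seq(0, 16, 0.8)`.
#' @param modes Elementary-mode set, default canonical network modes.
#' @param x0,c0,e0 Initial conditions passed to [simulate_hcm()].
#' @param max_retries Redraws allowed when a perturbed simulation fails,
#'   default 5.
#' @return List of datasets; each is a list with `dataset_id`, `times`,
#'   `y` (times x species measurement matrix with columns `A_e`, `B_e`,
#'   `C_e`, `cellmass`) and the perturbed `params` that generated it.
#' @export
generate_synthetic_datasets <- function(true_params = hcm_parameters(),
                                        n_datasets = 4L,
                                        kinetic_cv = 0.25,
                                        noise_cv = 0.05,
                                        seed = NULL,
                                        times = seq(0, 16, 0.8),
                                        modes = NULL,
                                        x0 = c(A_e = 10, B_e = 0, C_e = 0),
                                        c0 = 0.05, e0 = 0.5,
                                        max_retries = 5L) {
  stopifnot(n_datasets >= 1L, kinetic_cv >= 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(modes)) modes <- enumerate_elementary_modes(canonical_network())
  species <- c(modes$network$external, "cellmass")
  # lognormal sigma giving the requested coefficient of variation
  sdlog <- function(cv) if (cv > 0) sqrt(log(1 + cv^2)) else 0
  sk <- sdlog(kinetic_cv)
  sn <- sdlog(noise_cv)
  datasets <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    for (attempt in seq_len(max_retries)) {
      params_d <- true_params
      if (sk > 0) {
        params_d$k <- true_params$k *
          stats::rlnorm(true_params$L, meanlog = -sk^2 / 2, sdlog = sk)
      }
      traj <- tryCatch(simulate_hcm(params_d, modes, x0 = x0, c0 = c0,
                                    e0 = e0, times = times),
                       error = function(e) NULL)
      if (!is.null(traj)) break
    }
    if (is.null(traj)) stop("dataset ", d, " failed to simulate after ",
                            max_retries, " redraws")
    y <- as.matrix(traj[, species, drop = FALSE])
    if (sn > 0) {
      noise <- matrix(stats::rlnorm(length(y), meanlog = -sn^2 / 2,
                                    sdlog = sn), nrow = nrow(y))
      y <- y * noise
    }
    datasets[[d]] <- list(dataset_id = d, times = times, y = y,
                          params = params_d)
  }
  datasets
}

#' Sum-of-squares training objective for one dataset
#'
#' Squared residuals summed over the measured species (extracellular
#' metabolites and cellmass) and measurement times; the simulation is
#' linearly interpolated onto the dataset's time grid when the grids
#' differ.
#'
#' @param sim Trajectory data.frame from [simulate_hcm()] covering the
#'   dataset's time span.
#' @param data One dataset from [generate_synthetic_datasets()].
#' @return Scalar sum of squared residuals.
#' @export
sse_objective <- function(sim, data) {
  species <- colnames(data$y)
  if (!all(species %in% names(sim))) {
    stop("simulation lacks measured species: ",
         paste(setdiff(species, names(sim)), collapse = ", "))
  }
  total <- 0
  for (sp in species) {
    xs <- if (identical(as.numeric(sim$time), as.numeric(data$times))) {
      sim[[sp]]
    } else {
      stats::approx(sim$time, sim[[sp]], xout = data$times, rule = 2)$y
    }
    total <- total + sum((xs - data$y[, sp])^2)
  }
  total
}

#' Build the multiobjective identification problem for the canonical model
#'
#' One objective per training dataset (K = number of datasets), each the
#' sum-of-squares error of a single shared simulation against that
#' dataset. The decision vector has 13 entries: the six mode rate
#' constants `k`, the six saturation constants `Ksat`, and the shared
#' enzyme-synthesis rate constant `kE`; constitutive synthesis and
#' degradation rates stay at their defaults. Simulation failures are
#' propagated as infeasible (infinite) evaluations.
#'
#' @param datasets List of datasets sharing one time grid (at least one;
#'   two or more for a genuinely multiobjective problem).
#' @param lower,upper Bounds on the 13-vector, defaults 0.01 and 5.
#' @param modes Elementary-mode set, default canonical network modes.
#' @param x0,c0,e0 Initial conditions passed to [simulate_hcm()].
#' @param base_params Template [hcm_parameters] supplying `alpha`/`beta`.
#' @return A [moo_problem] over the 13 kinetic decision variables.
#' @export
make_hcm_problem <- function(datasets,
                             lower = rep(0.01, 13),
                             upper = rep(5, 13),
                             modes = NULL,
                             x0 = c(A_e = 10, B_e = 0, C_e = 0),
                             c0 = 0.05, e0 = 0.5,
                             base_params = hcm_parameters()) {
  stopifnot(length(datasets) >= 1L, length(lower) == 13L,
            length(upper) == 13L)
  if (is.null(modes)) modes <- enumerate_elementary_modes(canonical_network())
  times <- datasets[[1]]$times
  for (d in datasets) stopifnot(identical(d$times, times))
  objective <- function(p) {
    params <- decision_to_params(p, base_params)
    sim <- simulate_hcm(params, modes, x0 = x0, c0 = c0, e0 = e0,
                        times = times)
    vapply(datasets, function(d) sse_objective(sim, d), numeric(1))
  }
  moo_problem(objective, lower = lower, upper = upper,
              K = length(datasets))
}

#' Map a 13-entry decision vector onto model parameters
#'
#' @param p Numeric 13-vector `(k_1..k_6, Ksat_1..Ksat_6, kE)`.
#' @param base_params Template supplying the fixed `alpha` and `beta`.
#' @return An [hcm_parameters].
#' @export
decision_to_params <- function(p, base_params = hcm_parameters()) {
  stopifnot(length(p) == 13L)
  hcm_parameters(k = p[1:6], Ksat = p[7:12], kE = p[13],
                 alpha = base_params$alpha, beta = base_params$beta)
}

#' Inverse of [decision_to_params()]
#'
#' @param params An [hcm_parameters] with 6 modes.
#' @return The 13-entry decision vector.
#' @export
params_to_decision <- function(params) {
  stopifnot(params$L == 6L)
  c(params$k, params$Ksat, params$kE)
}

#' Ensemble trajectory summary with a 95 percent band
#'
#' Simulates every archive member and reports, per time point and
#' observable, the ensemble mean with a band at the requested level. The
#' default band spans the ensemble percentiles (2.5/97.5 at the default
#' level), the spread statistic that brackets the training data when the
#' ensemble balances conflicting objectives. `method = "stderr"` instead
#' reports the confidence estimate of the ensemble mean
#' (`mean +/- z * sd / sqrt(A)`), which narrows towards zero width as the
#' archive grows, and `method = "sd"` the mean plus or minus one ensemble
#' standard deviation.
#'
#' @param archive An [ensemble_archive] from the identification problem
#'   (13-row decision matrix).
#' @param level Band level in (0, 1), default 0.95 (ignored for
#'   `method = "sd"`).
#' @param method `"percentile"` (default), `"stderr"` or `"sd"`.
#' @param modes,x0,c0,e0,times,base_params Simulation settings as in
#'   [make_hcm_problem()].
#' @param members Optional column subset of the archive to summarize.
#' @return A data.frame in long form: `time`, `species`, `mean`, `lower`,
#'   `upper`.
#' @export
ensemble_band <- function(archive, level = 0.95,
                          method = c("percentile", "stderr", "sd"),
                          modes = NULL,
                          x0 = c(A_e = 10, B_e = 0, C_e = 0),
                          c0 = 0.05, e0 = 0.5,
                          times = seq(0, 16, 0.8),
                          base_params = hcm_parameters(),
                          members = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(archive, "ensemble_archive"), level > 0, level < 1)
  if (ncol(archive$S) == 0L) stop("cannot summarize an empty archive")
  if (nrow(archive$S) != 13L) {
    stop("trajectory bands are defined for archives of the 13-parameter ",
         "kinetic identification problem (got D = ", nrow(archive$S), ")")
  }
  if (is.null(modes)) modes <- enumerate_elementary_modes(canonical_network())
  cols <- if (is.null(members)) seq_len(ncol(archive$S)) else members
  species <- c(modes$network$external, "cellmass")
  sims <- lapply(cols, function(j) {
    params <- decision_to_params(archive$S[, j], base_params)
    tryCatch(simulate_hcm(params, modes, x0 = x0, c0 = c0, e0 = e0,
                          times = times),
             error = function(e) NULL)
  })
  sims <- Filter(Negate(is.null), sims)
  if (length(sims) == 0L) stop("no archive member simulated successfully")
  A <- length(sims)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (sp in species) {
    vals <- vapply(sims, function(s) s[[sp]], numeric(length(times)))
    vals <- matrix(vals, nrow = length(times))
    m <- rowMeans(vals)
    sdev <- apply(vals, 1, stats::sd)
    sdev[is.na(sdev)] <- 0
    band <- switch(method,
      stderr = list(lower = m - z * sdev / sqrt(A),
                    upper = m + z * sdev / sqrt(A)),
      sd = list(lower = m - sdev, upper = m + sdev),
      percentile = {
        qs <- apply(vals, 1, stats::quantile,
                    probs = c((1 - level) / 2, 1 - (1 - level) / 2))
        list(lower = qs[1, ], upper = qs[2, ])
      })
    out[[sp]] <- data.frame(time = times, species = sp, mean = m,
                            lower = band$lower, upper = band$upper)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subsample an archive to its best members per objective
#'
#' Keeps members whose rank does not exceed `max_rank` and that fall in
#' the best `fraction` quantile of at least one objective, and identifies
#' the single best member per objective -- the selection used to ask
#' whether the ensemble contains parameter sets that describe each
#' training dataset individually.
#'
#' @param archive An [ensemble_archive].
#' @param fraction Quantile fraction in (0, 1], default 0.25.
#' @param max_rank Largest rank admitted, default 1.
#' @return An [ensemble_archive] of the selected members, with an
#'   attribute `best_per_objective` giving, per objective, the index of
#'   its best member within the returned archive.
#' @export
select_top_fraction <- function(archive, fraction = 0.25, max_rank = 1L) {
  stopifnot(inherits(archive, "ensemble_archive"),
            fraction > 0, fraction <= 1)
  A <- ncol(archive$O)
  if (A == 0L) return(archive)
  keep_rank <- archive$R <= max_rank
  K <- nrow(archive$O)
  in_top <- rep(FALSE, A)
  for (j in seq_len(K)) {
    cutoff <- stats::quantile(archive$O[j, ], probs = fraction,
                              names = FALSE, type = 1)
    in_top <- in_top | archive$O[j, ] <= cutoff
  }
  keep <- which(keep_rank & in_top)
  sel <- ensemble_archive(archive$S[, keep, drop = FALSE],
                          archive$O[, keep, drop = FALSE],
                          archive$R[keep])
  best <- if (length(keep) > 0L) {
    vapply(seq_len(K), function(j) which.min(sel$O[j, ]), integer(1))
  } else integer(0)
  attr(sel, "best_per_objective") <- best
  sel
}
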