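#' Run a named benchmark problem end to end and write the archives
#'
#' Convenience driver behind the command-line `run` subcommand: resolves a
#' built-in problem by name, runs multistart annealing, and (optionally)
#' writes the aligned archive CSVs plus a metadata echo of every effective
#' configuration value.
#'
#' @param problem A [moo_problem], or the name of a built-in benchmark
#'   (`"schaffer"`, `"binh_korn"`, `"fonseca_fleming"`).
#' @param n_partitions Multistart partitions, default 10.
#' @param config An [sa_config].
#' @param hooks A [poets_hooks] set.
#' @param output_dir Optional directory for `S.csv`/`O.csv`/`R.csv` and
#'   `run_metadata.json`.
#' @return The combined [ensemble_archive], invisibly when writing.
#' @export
poets_run <- function(problem, n_partitions = 10L, config = sa_config(),
                      hooks = poets_hooks(), output_dir = NULL) {
  problem_name <- if (is.character(problem)) problem else "custom"
  if (is.character(problem)) problem <- test_problem(problem)
  archive <- run_multistart(problem, n_partitions = n_partitions,
                            config = config, hooks = hooks)
  if (!is.null(output_dir)) {
    meta <- c(list(problem = problem_name, n_partitions = n_partitions),
              unclass(config))
    meta$rng_seed <- if (is.null(meta$rng_seed)) NA else meta$rng_seed
    save_archive(archive, output_dir, metadata = meta)
    return(invisible(archive))
  }
  archive
}

#' Scaled-down end-to-end biochemical identification demo
#'
#' Reproduces the proof-of-concept workflow at reduced scale: generates
#' four conflicting synthetic datasets from the canonical network, builds
#' the K = 4 identification problem over the 13 kinetic parameters, runs
#' multistart annealing, and summarizes the resulting ensemble
#' (trajectory mean with 95 percent band, per-objective subsample). With
#' an output directory it writes `datasets.csv`, the archive CSVs,
#' `band.csv`, `tradeoff.csv` (objective matrix plus ranks) and
#' `modes.json`.
#'
#' @param seed Integer seed driving data generation and the search.
#' @param output_dir Optional output directory.
#' @param n_partitions Multistart partitions, default 4.
#' @param config An [sa_config]; the default demo budget uses 20 steps
#'   per temperature and stops at temperature 0.01.
#' @param kinetic_cv,noise_cv Generator settings, defaults 0.25 and 0.05.
#' @param times Measurement/simulation grid, default `seq(0, 16, 0.8)`.
#' @return List with `datasets`, `problem`, `archive`, `band` and
#'   `selection` (the rank-and-quantile subsample).
#' @export
poets_demo <- function(seed = 1L, output_dir = NULL,
                       n_partitions = 4L,
                       config = sa_config(steps_per_temperature = 20L,
                                          temperature_min = 0.01,
                                          rng_seed = seed),
                       kinetic_cv = 0.25, noise_cv = 0.05,
                       times = seq(0, 16, 0.8)) {
  modes <- enumerate_elementary_modes(canonical_network())
  datasets <- generate_synthetic_datasets(n_datasets = 4L,
                                          kinetic_cv = kinetic_cv,
                                          noise_cv = noise_cv,
                                          seed = seed, times = times,
                                          modes = modes)
  problem <- make_hcm_problem(datasets, modes = modes)
  config$rng_seed <- seed + 1000L
  archive <- run_multistart(problem, n_partitions = n_partitions,
                            config = config)
  band <- ensemble_band(archive, modes = modes, times = times)
  selection <- select_top_fraction(archive, fraction = 0.25, max_rank = 1L)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_datasets(datasets, file.path(output_dir, "datasets.csv"))
    save_archive(archive, output_dir,
                 metadata = c(list(command = "demo", seed = seed,
                                   n_partitions = n_partitions,
                                   kinetic_cv = kinetic_cv,
                                   noise_cv = noise_cv),
                              unclass(config)))
    utils::write.csv(band, file.path(output_dir, "band.csv"),
                     row.names = FALSE)
    tradeoff <- as.data.frame(t(archive$O))
    names(tradeoff) <- paste0("O", seq_len(nrow(archive$O)))
    tradeoff$rank <- archive$R
    utils::write.csv(tradeoff, file.path(output_dir, "tradeoff.csv"),
                     row.names = FALSE)
    write_modes_json(modes, file.path(output_dir, "modes.json"))
  }
  list(datasets = datasets, problem = problem, archive = archive,
       band = band, selection = selection)
}
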