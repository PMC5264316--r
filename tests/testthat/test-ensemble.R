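test_that("a noiseless generator reproduces the true trajectory exactly", {
  em <- canonical_modes()
  ds <- generate_synthetic_datasets(n_datasets = 3, kinetic_cv = 0,
                                    noise_cv = 0, seed = 3, modes = em)
  truth <- simulate_hcm(hcm_parameters(), em)
  for (d in ds) {
    expect_equal(d$y[, "A_e"], truth$A_e, tolerance = 1e-10)
    expect_equal(d$y[, "cellmass"], truth$cellmass, tolerance = 1e-10)
  }
})

test_that("datasets are reproducible from the seed and carry the layout", {
  a <- generate_synthetic_datasets(n_datasets = 4, seed = 12)
  b <- generate_synthetic_datasets(n_datasets = 4, seed = 12)
  for (d in 1:4) {
    expect_identical(a[[d]]$y, b[[d]]$y)
    expect_equal(a[[d]]$dataset_id, d)
    expect_setequal(colnames(a[[d]]$y),
                    c("A_e", "B_e", "C_e", "cellmass"))
    expect_true(all(a[[d]]$y >= 0))
  }
})

test_that("kinetic variation adds spread beyond measurement noise", {
  # across-dataset spread of final cellmass, kinetic variation vs noise only
  spread <- function(cv_k) {
    ds <- generate_synthetic_datasets(n_datasets = 25, kinetic_cv = cv_k,
                                      noise_cv = 0.05, seed = 77)
    stats::sd(vapply(ds, function(d) d$y[nrow(d$y), "cellmass"],
                     numeric(1)))
  }
  expect_gt(spread(0.25), 2 * spread(0))
})

test_that("the squared-error objective has its closed-form structure", {
  em <- canonical_modes()
  ds <- generate_synthetic_datasets(n_datasets = 1, kinetic_cv = 0,
                                    noise_cv = 0, seed = 5, modes = em)[[1]]
  sim <- simulate_hcm(hcm_parameters(), em)
  expect_equal(sse_objective(sim, ds), 0, tolerance = 1e-12)

  # constant offset on one species contributes n * delta^2
  shifted <- ds
  shifted$y[, "A_e"] <- shifted$y[, "A_e"] + 0.5
  n <- length(ds$times)
  expect_equal(sse_objective(sim, shifted), n * 0.25, tolerance = 1e-10)

  # doubling all residuals quadruples the objective
  sim_y <- as.matrix(sim[, colnames(ds$y)])
  set.seed(6)
  resid <- matrix(rnorm(length(sim_y), 0, 0.2), nrow = nrow(sim_y))
  base <- ds
  base$y <- sim_y + resid
  doubled <- ds
  doubled$y <- sim_y + 2 * resid
  expect_equal(sse_objective(sim, doubled), 4 * sse_objective(sim, base),
               tolerance = 1e-8)

  bad <- ds
  colnames(bad$y)[1] <- "unknown_species"
  expect_error(sse_objective(sim, bad), "lacks measured species")
})

test_that("the identification problem scores one simulation per dataset", {
  em <- canonical_modes()
  ds <- generate_synthetic_datasets(n_datasets = 4, kinetic_cv = 0.25,
                                    noise_cv = 0, seed = 9, modes = em)
  prob <- make_hcm_problem(ds, modes = em)
  expect_equal(prob$K, 4L)
  expect_equal(prob$D, 13L)

  # the generating parameters of dataset d minimize objective d alone
  for (d in 1:2) {
    p_d <- params_to_decision(ds[[d]]$params)
    o <- evaluate_objectives(prob, p_d)
    expect_length(o, 4L)
    expect_equal(o[d], 0, tolerance = 1e-6)
    expect_true(all(o[-d] > o[d]))
  }

  # out-of-range decision vectors map to infeasible evaluations
  expect_true(all(is.finite(evaluate_objectives(prob, rep(1, 13)))))
})

test_that("decision vector round-trips through the parameter container", {
  p <- c(runif(6), runif(6, 0.1, 2), 1.4)
  expect_equal(params_to_decision(decision_to_params(p)), p)
})

test_that("ensemble bands degenerate correctly and widen with spread", {
  em <- canonical_modes()
  p_true <- params_to_decision(hcm_parameters())
  one <- ensemble_archive(matrix(p_true, ncol = 1),
                          matrix(0, nrow = 1, ncol = 1), 0L)
  band1 <- ensemble_band(one, modes = em)
  expect_equal(band1$lower, band1$mean, tolerance = 1e-12)
  expect_equal(band1$upper, band1$mean, tolerance = 1e-12)

  # identical members: still zero width
  three <- ensemble_archive(matrix(rep(p_true, 3), ncol = 3),
                            matrix(0, nrow = 1, ncol = 3), rep(0L, 3))
  band3 <- ensemble_band(three, modes = em)
  expect_equal(band3$upper - band3$lower, rep(0, nrow(band3)),
               tolerance = 1e-12)

  # wider parameter spread gives a band at least as wide, pointwise mostly
  set.seed(15)
  jitter_archive <- function(scale) {
    S <- vapply(1:8, function(i) {
      pmax(p_true * exp(rnorm(13, 0, scale)), 0.01)
    }, numeric(13))
    ensemble_archive(S, matrix(0, 1, 8), rep(0L, 8))
  }
  narrow <- ensemble_band(jitter_archive(0.02), modes = em)
  wide <- ensemble_band(jitter_archive(0.3), modes = em)
  expect_gt(mean(wide$upper - wide$lower), mean(narrow$upper - narrow$lower))
})

test_that("band level and method arguments shape the interval", {
  em <- canonical_modes()
  set.seed(16)
  S <- vapply(1:6, function(i) {
    pmax(params_to_decision(hcm_parameters()) * exp(rnorm(13, 0, 0.2)),
         0.01)
  }, numeric(13))
  arch <- ensemble_archive(S, matrix(0, 1, 6), rep(0L, 6))
  perc <- ensemble_band(arch, modes = em, method = "percentile")
  stderr_band <- ensemble_band(arch, modes = em, method = "stderr")
  sd_band <- ensemble_band(arch, modes = em, method = "sd")
  expect_true(all(perc$lower <= perc$mean + 1e-12))
  expect_true(all(perc$upper >= perc$mean - 1e-12))
  # the mean's standard error band is narrower than the sd band for A > 1
  expect_true(mean(stderr_band$upper - stderr_band$lower) <
                mean(sd_band$upper - sd_band$lower))
})

test_that("top-fraction selection keeps the documented members", {
  set.seed(17)
  O <- matrix(runif(200), nrow = 2)
  S <- matrix(runif(1300), nrow = 13)
  arch <- ensemble_archive(S, O)

  # full fraction and unlimited rank is the identity
  all_kept <- select_top_fraction(arch, fraction = 1,
                                  max_rank = max(arch$R))
  expect_equal(ncol(all_kept$O), ncol(arch$O))

  # a member minimizing every objective is always retained
  star <- ensemble_archive(cbind(arch$S, rep(0, 13)),
                           cbind(arch$O, c(-1, -1)))
  kept <- select_top_fraction(star, fraction = 0.1, max_rank = 0L)
  expect_true(any(kept$O[1, ] == -1))

  # exactly the best 25 of 100 survive a single-objective cut
  single <- ensemble_archive(matrix(runif(100), 1),
                             matrix(sample(1:100), 1),
                             rep(0L, 100))
  sel <- select_top_fraction(single, fraction = 0.25, max_rank = 0L)
  expect_equal(ncol(sel$O), 25L)
  expect_setequal(as.numeric(sel$O), 1:25)
  expect_equal(attr(sel, "best_per_objective"), which.min(sel$O[1, ]))
})
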