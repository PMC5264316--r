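test_that("the canonical network matches its blueprint", {
  net <- canonical_network()
  expect_equal(length(net$internal), 3L)
  expect_equal(ncol(net$sigma), 7L)
  expect_equal(nrow(net$sigma), 6L)
  expect_setequal(net$external, c("A_e", "B_e", "C_e"))
  # unit stoichiometry of the A -> B conversion
  expect_equal(net$sigma["A", "r2"], -1)
  expect_equal(net$sigma["B", "r2"], 1)
  # every reaction touches at least one internal species
  expect_true(all(colSums(abs(net$sigma[net$internal, ])) >= 1))
  expect_false(any(net$reversible))
})

test_that("the canonical network has exactly the six expected modes", {
  em <- canonical_modes()
  expect_equal(em$L, 6L)
  got_supports <- apply(em$Z != 0, 2, function(s) {
    paste(sort(rownames(em$Z)[s]), collapse = "+")
  })
  want <- c("r1+r2+r4", "r1+r2+r3+r6", "r1+r2+r3+r7",
            "r3+r5+r6", "r3+r5+r7", "r4+r5")
  want <- vapply(strsplit(want, "+", fixed = TRUE), function(s) {
    paste(sort(s), collapse = "+")
  }, character(1))
  expect_setequal(unname(got_supports), want)
})

test_that("every mode satisfies internal steady state and normalization", {
  em <- canonical_modes()
  net <- em$network
  balance <- net$sigma[net$internal, ] %*% em$Z
  expect_lt(max(abs(balance)), 1e-10)
  expect_true(all(em$Z >= -1e-12))

  uptake <- !is.na(em$substrate)
  expect_equal(em$z_s[uptake], rep(1, sum(uptake)))
  expect_equal(em$z_s[!uptake], rep(0, sum(!uptake)))
  # uptake modes consume exactly one unit of their substrate
  net_cons <- -net$sigma[net$external, ] %*% em$Z
  for (l in which(uptake)) {
    expect_equal(net_cons[em$substrate[l], l], 1)
  }
  # futile cycle scaled to unit maximum entry
  for (l in which(!uptake)) {
    expect_equal(max(em$Z[, l]), 1)
  }
  # growth fluxes sit on the growth-carrying modes only
  expect_equal(sum(em$z_mu > 0), 2L)
})

test_that("enumeration agrees with the exhaustive subset oracle", {
  net <- canonical_network()
  em <- enumerate_elementary_modes(net)
  oracle <- oracle_elementary_modes(net$sigma, net$internal, net$reversible)
  expect_equal(em$L, length(oracle))
  # same supports in the same deterministic order
  got <- lapply(seq_len(em$L), function(l) unname(which(em$Z[, l] != 0)))
  want <- lapply(oracle, `[[`, "support")
  expect_equal(got, want)
  # flux directions proportional to the oracle's null vectors
  for (l in seq_len(em$L)) {
    a <- em$Z[, l]
    b <- oracle[[l]]$flux
    expect_lt(max(abs(a / max(a) - b / max(b))), 1e-8)
  }

  # random small networks: mode sets coincide support-for-support
  for (seed in 1:5) {
    rnet <- random_small_network(n_internal = 2, n_reactions = 6,
                                 seed = seed)
    em_r <- enumerate_elementary_modes(rnet)
    oracle_r <- oracle_elementary_modes(rnet$sigma, rnet$internal,
                                        rnet$reversible)
    got <- lapply(seq_len(em_r$L), function(l) unname(which(em_r$Z[, l] != 0)))
    expect_equal(got, lapply(oracle_r, `[[`, "support"),
                 info = paste("random network seed", seed))
  }
})

test_that("a simple chain yields one mode and oversized networks error", {
  sigma <- matrix(c(1, -1), nrow = 1,
                  dimnames = list("A", c("rin", "rout")))
  sigma <- rbind(sigma, "X_e" = c(-1, 0), "Y_e" = c(0, 1))
  chain <- stoich_network(sigma, internal = "A")
  em <- enumerate_elementary_modes(chain)
  expect_equal(em$L, 1L)
  expect_equal(as.numeric(em$Z), c(1, 1))
  expect_equal(em$substrate, "X_e")

  big <- matrix(1, nrow = 2, ncol = 16,
                dimnames = list(c("A", "B"), paste0("r", 1:16)))
  expect_error(enumerate_elementary_modes(stoich_network(big, "A")),
               "limited to")
})

test_that("mode kinetics follow saturation behaviour", {
  em <- canonical_modes()
  params <- hcm_parameters()
  x <- c(A_e = 2, B_e = 1, C_e = 0)

  # no enzyme, no flux
  r0 <- mode_rates(rep(0, 6), params, x, em)
  expect_equal(r0$qbar, rep(0, 6))

  e <- rep(0.5, 6)
  # half-saturation: s = Ksat gives k * e / 2
  x_half <- c(A_e = params$Ksat[1], B_e = 0, C_e = 0)
  r_half <- mode_rates(e, params, x_half, em)
  a_modes <- which(em$substrate == "A_e")
  for (l in a_modes) {
    if (params$Ksat[l] == params$Ksat[1]) {
      expect_equal(r_half$qbar[l], params$k[l] * e[l] / 2)
    }
  }
  # saturation limit: huge substrate approaches k * e
  x_big <- c(A_e = 1e9, B_e = 1e9, C_e = 0)
  r_sat <- mode_rates(e, params, x_big, em)
  uptake <- !is.na(em$substrate)
  expect_equal(r_sat$qbar[uptake], (params$k * e)[uptake],
               tolerance = 1e-6)
  # the uptake-free futile cycle never carries kinetic flux
  expect_equal(r_sat$qbar[!uptake], rep(0, sum(!uptake)))
})

test_that("cybernetic controls normalize allocation and activity", {
  em <- canonical_modes()
  # one active mode takes the whole allocation
  qbar <- rep(0, 6)
  qbar[2] <- 0.7
  ctrl <- cybernetic_controls(qbar, em)
  expect_equal(ctrl$u[2], 1)
  expect_equal(ctrl$v[2], 1)
  expect_equal(sum(ctrl$u), 1)

  # two equal weights split the allocation and both run at full activity
  qbar2 <- rep(0, 6)
  qbar2[c(1, 2)] <- 1
  ctrl2 <- cybernetic_controls(qbar2, em)
  expect_equal(ctrl2$u[1:2], c(0.5, 0.5))
  expect_equal(ctrl2$v[1:2], c(1, 1))

  # guard: all-zero kinetics give zero controls
  ctrl0 <- cybernetic_controls(rep(0, 6), em)
  expect_equal(ctrl0$u, rep(0, 6))
  expect_equal(ctrl0$v, rep(0, 6))
})

test_that("growth rate is the growth-flux weighted sum of mode rates", {
  em <- canonical_modes()
  expect_equal(growth_rate(rep(0, 6), em), 0)
  q <- numeric(6)
  q[em$z_mu == 0] <- 5  # only non-growth modes active
  expect_equal(growth_rate(q, em), 0)
  q <- numeric(6)
  growth_modes <- which(em$z_mu > 0)
  q[growth_modes] <- c(0.2, 0.3)
  expect_equal(growth_rate(q, em),
               sum(em$z_mu[growth_modes] * c(0.2, 0.3)))
})

test_that("simulation respects conservation and monotonicity structure", {
  em <- canonical_modes()
  # zero kinetics freeze everything except enzyme relaxation to alpha/beta
  frozen <- simulate_hcm(hcm_parameters(k = rep(0, 6)), em,
                         times = seq(0, 50, 5))
  expect_equal(frozen$A_e, rep(10, 11), tolerance = 1e-8)
  expect_equal(frozen$cellmass, rep(0.05, 11), tolerance = 1e-8)
  # linear enzyme balance has the closed form
  # e(t) = alpha/beta + (e0 - alpha/beta) exp(-beta t)
  closed <- 0.001 / 0.05 + (0.5 - 0.001 / 0.05) * exp(-0.05 * frozen$time)
  expect_equal(frozen$e_1, closed, tolerance = 1e-5)

  # no biomass, no conversion
  sterile <- simulate_hcm(hcm_parameters(), em, c0 = 0,
                          times = seq(0, 10, 1))
  expect_equal(sterile$A_e, rep(10, 11), tolerance = 1e-8)
  expect_equal(sterile$cellmass, rep(0, 11))

  sim <- simulate_hcm(hcm_parameters(), em)
  expect_true(all(diff(sim$cellmass) >= -1e-8))
  expect_true(all(diff(sim$A_e) <= 1e-8))
  expect_true(all(as.matrix(sim[-1]) >= 0))
  expect_error(simulate_hcm(hcm_parameters(), em, times = c(1, 0)))
})

test_that("control invariants hold along a simulated trajectory", {
  em <- canonical_modes()
  params <- hcm_parameters()
  sim <- simulate_hcm(params, em)
  for (i in seq_len(nrow(sim))) {
    x <- unlist(sim[i, c("A_e", "B_e", "C_e")])
    e <- unlist(sim[i, paste0("e_", 1:6)])
    r <- mode_rates(e, params, x, em)
    if (any(r$qbar > 0)) {
      expect_equal(sum(r$u), 1, tolerance = 1e-12)
      expect_equal(max(r$v), 1, tolerance = 1e-12)
    } else {
      expect_equal(r$u, rep(0, 6))
      expect_equal(r$v, rep(0, 6))
    }
  }
})

test_that("carbon only leaves the extracellular pool through the growth sink", {
  em <- canonical_modes()
  # with growth modes disabled, A_e + B_e + C_e is conserved
  k_ng <- hcm_parameters()$k
  k_ng[em$z_mu > 0] <- 0
  sim <- simulate_hcm(hcm_parameters(k = k_ng), em, times = seq(0, 5, 0.5))
  totals <- sim$A_e + sim$B_e + sim$C_e
  expect_equal(totals, rep(totals[1], length(totals)), tolerance = 1e-5)

  # with growth on, the loss of extracellular carbon equals cellmass gain
  sim2 <- simulate_hcm(hcm_parameters(), em, times = seq(0, 5, 0.5))
  loss <- (sim2$A_e + sim2$B_e + sim2$C_e)[1] -
    (sim2$A_e + sim2$B_e + sim2$C_e)
  gain <- sim2$cellmass - sim2$cellmass[1]
  expect_equal(loss, gain, tolerance = 1e-4)
})

test_that("compiled and interpreted derivatives give the same trajectory", {
  em <- canonical_modes()
  params <- hcm_parameters(k = c(0.5, 1, 1.5, 0.3, 0.8, 0.2))
  a <- simulate_hcm(params, em, use_compiled = TRUE)
  b <- simulate_hcm(params, em, use_compiled = FALSE)
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-6)
})
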