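#' Construct a stoichiometric network
#'
#' @param sigma Stoichiometric matrix (species x reactions), positive
#'   entries produced, negative consumed.
#' @param internal Character vector of balanced (intracellular) species
#'   names; the remaining rows are dynamic extracellular species.
#' @param reversible Logical per-reaction vector; irreversible reactions
#'   carry non-negative flux.
#' @param growth_reaction Name or index of the biomass-forming reaction
#'   (optional, `NA` when absent).
#' @return An object of class `stoich_network`.
#' @export
stoich_network <- function(sigma, internal, reversible = NULL,
                           growth_reaction = NA) {
  stopifnot(is.matrix(sigma), !is.null(rownames(sigma)),
            !is.null(colnames(sigma)), all(internal %in% rownames(sigma)))
  if (is.null(reversible)) reversible <- rep(FALSE, ncol(sigma))
  stopifnot(length(reversible) == ncol(sigma))
  if (is.character(growth_reaction) && !is.na(growth_reaction)) {
    growth_reaction <- match(growth_reaction, colnames(sigma))
  }
  structure(list(sigma = sigma,
                 internal = internal,
                 external = setdiff(rownames(sigma), internal),
                 reversible = reversible,
                 growth_reaction = growth_reaction),
            class = "stoich_network")
}

#' The canonical proof-of-concept metabolic network
#'
#' Six metabolites and seven irreversible reactions: uptake of extracellular
#' substrate A_e into the cell, the intracellular chain A -> B -> C,
#' reversible exchange of B with the extracellular pool B_e (modeled as the
#' two irreversible reactions r4/r5), secretion of C as C_e, and growth
#' from C. Intracellular A, B and C are balanced (no accumulation); A_e,
#' B_e and C_e are dynamic.
#'
#' Reactions: r1 A_e -> A; r2 A -> B; r3 B -> C; r4 B -> B_e; r5 B_e -> B;
#' r6 C -> C_e; r7 C -> cellmass (growth).
#'
#' @return A [stoich_network] with 6 species rows and 7 reaction columns.
#' @export
canonical_network <- function() {
  species <- c("A", "B", "C", "A_e", "B_e", "C_e")
  reactions <- paste0("r", 1:7)
  sigma <- matrix(0, nrow = 6, ncol = 7,
                  dimnames = list(species, reactions))
  sigma["A_e", "r1"] <- -1; sigma["A", "r1"] <- 1
  sigma["A", "r2"] <- -1;   sigma["B", "r2"] <- 1
  sigma["B", "r3"] <- -1;   sigma["C", "r3"] <- 1
  sigma["B", "r4"] <- -1;   sigma["B_e", "r4"] <- 1
  sigma["B_e", "r5"] <- -1; sigma["B", "r5"] <- 1
  sigma["C", "r6"] <- -1;   sigma["C_e", "r6"] <- 1
  sigma["C", "r7"] <- -1    # growth sink: C -> cellmass
  stoich_network(sigma, internal = c("A", "B", "C"),
                 reversible = rep(FALSE, 7), growth_reaction = "r7")
}

# 1-D null vector of a matrix via SVD, or NULL if the nullity is not 1
null_vector_1d <- function(M, tol = 1e-10) {
  if (ncol(M) == 1L) {
    if (all(abs(M) < tol)) return(1)
    return(NULL)
  }
  sv <- svd(M, nu = 0, nv = ncol(M))
  nullity <- sum(sv$d < tol * max(sv$d[1], 1))
  if (nrow(M) < ncol(M)) nullity <- nullity + ncol(M) - nrow(M)
  if (nullity != 1L) return(NULL)
  sv$v[, ncol(M)]
}

#' Enumerate elementary flux modes by exhaustive support testing
#'
#' Elementary modes are the support-minimal, chemically balanced
#' steady-state flux vectors of a network: every balanced intracellular
#' species has zero net production and no mode's active-reaction set
#' strictly contains another's. For small networks they can be found
#' exactly by testing every reaction subset for a one-dimensional
#' steady-state null space with sign-consistent flux (non-negative on
#' irreversible reactions), then discarding supersets.
#'
#' Each mode column is normalized so its net substrate-uptake flux equals
#' one; modes with no net uptake (futile cycles) are scaled to a largest
#' entry of one and carry an uptake flux `z_s` of zero, which silences them
#' in the cybernetic control laws.
#'
#' @param network A [stoich_network] with at most `max_reactions` reactions.
#' @param max_reactions Guard on the exhaustive `2^R` subset scan,
#'   default 15.
#' @param tol Numerical tolerance for rank and sign tests, default 1e-10.
#' @return An object of class `elementary_modes` with fields `Z`
#'   (reactions x modes flux matrix), `z_mu` (growth flux per mode), `z_s`
#'   (substrate uptake flux per mode), `substrate` (name of each mode's
#'   uptake substrate, `NA` for uptake-free modes), `L` (mode count) and
#'   `network`.
#' @export
enumerate_elementary_modes <- function(network, max_reactions = 15L,
                                       tol = 1e-10) {
  stopifnot(inherits(network, "stoich_network"))
  R <- ncol(network$sigma)
  if (R > max_reactions) {
    stop("exhaustive enumeration is limited to ", max_reactions,
         " reactions (network has ", R, ")")
  }
  N_int <- network$sigma[network$internal, , drop = FALSE]
  supports <- list()
  fluxes <- list()
  for (code in seq_len(2^R - 1L)) {
    sub <- which(bitwAnd(code, bitwShiftL(1L, 0:(R - 1L))) != 0L)
    v <- null_vector_1d(N_int[, sub, drop = FALSE], tol = tol)
    if (is.null(v)) next
    if (any(abs(v) < tol)) next  # true support is smaller; found elsewhere
    # orient: irreversible reactions need non-negative flux
    irrev <- !network$reversible[sub]
    if (any(irrev)) {
      sgn <- sign(v[which(irrev)[1]])
      v <- v * sgn
      if (any(v[irrev] < -tol)) next
    }
    supports[[length(supports) + 1L]] <- sub
    fluxes[[length(fluxes) + 1L]] <- v
  }
  # support minimality: drop any mode whose support strictly contains another
  n <- length(supports)
  minimal <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && minimal[i] &&
          all(supports[[j]] %in% supports[[i]]) &&
          length(supports[[j]]) < length(supports[[i]])) {
        minimal[i] <- FALSE
        break
      }
    }
  }
  supports <- supports[minimal]
  fluxes <- fluxes[minimal]
  # deterministic order: lexicographic by support membership pattern
  keys <- vapply(supports, function(s) {
    paste(sprintf("%02d", s), collapse = ",")
  }, character(1))
  ord <- order(keys)
  supports <- supports[ord]
  fluxes <- fluxes[ord]

  L <- length(supports)
  Z <- matrix(0, nrow = R, ncol = L,
              dimnames = list(colnames(network$sigma),
                              if (L > 0L) paste0("em", seq_len(L))))
  for (l in seq_len(L)) Z[supports[[l]], l] <- fluxes[[l]]

  sigma_ext <- network$sigma[network$external, , drop = FALSE]
  net_uptake <- -sigma_ext %*% Z  # positive entry: net consumption
  z_s <- numeric(L)
  substrate <- rep(NA_character_, L)
  for (l in seq_len(L)) {
    cons <- net_uptake[, l]
    s <- which(cons > tol)
    if (length(s) >= 1L) {
      s <- s[which.max(cons[s])]
      Z[, l] <- Z[, l] / cons[s]
      z_s[l] <- 1
      substrate[l] <- network$external[s]
    } else {
      Z[, l] <- Z[, l] / max(abs(Z[, l]))  # futile cycle: max entry 1
      z_s[l] <- 0
    }
  }
  z_mu <- if (is.na(network$growth_reaction)) numeric(L) else
    Z[network$growth_reaction, ]
  structure(list(Z = Z, z_mu = as.numeric(z_mu), z_s = z_s,
                 substrate = substrate, L = L, network = network),
            class = "elementary_modes")
}

#' @export
print.elementary_modes <- function(x, ...) {
  cat("elementary mode set:", x$L, "modes over", nrow(x$Z), "reactions\n")
  for (l in seq_len(x$L)) {
    sup <- rownames(x$Z)[x$Z[, l] != 0]
    cat(sprintf("  em%d: {%s}  substrate = %s  growth flux = %g\n", l,
                paste(sup, collapse = ","),
                ifelse(is.na(x$substrate[l]), "-", x$substrate[l]),
                x$z_mu[l]))
  }
  invisible(x)
}

#' Default kinetic parameter set for the canonical network model
#'
#' Mode rate constants `k` (1/time), saturation constants `Ksat`
#' (concentration), a shared enzyme synthesis rate constant `kE`
#' (enzyme/time), constitutive enzyme synthesis rates `alpha` and
#' first-order enzyme degradation constants `beta` (1/time). The defaults
#' are the generating ("true") values used by the synthetic-data
#' generator.
#'
#' @param k,Ksat Numeric L-vectors (defaults for the 6-mode canonical
#'   network).
#' @param kE Scalar enzyme synthesis rate constant, default 1.
#' @param alpha,beta Scalars or L-vectors, defaults 0.001 and 0.05.
#' @param L Mode count used to recycle scalars, default `length(k)`.
#' @return An object of class `hcm_parameters`.
#' @export
hcm_parameters <- function(k = c(0.6, 1.1, 1.4, 0.4, 0.9, 0),
                           Ksat = c(0.5, 0.6, 0.4, 0.8, 0.7, 0.5),
                           kE = 1, alpha = 0.001, beta = 0.05,
                           L = length(k)) {
  stopifnot(length(k) == L, length(Ksat) == L, all(k >= 0),
            all(Ksat >= 0), kE >= 0, all(alpha >= 0), all(beta >= 0))
  structure(list(k = as.numeric(k), Ksat = as.numeric(Ksat),
                 kE = as.numeric(kE)[1],
                 alpha = rep_len(as.numeric(alpha), L),
                 beta = rep_len(as.numeric(beta), L), L = L),
            class = "hcm_parameters")
}

#' Kinetic and regulated flux rates through each elementary mode
#'
#' The unregulated ("kinetic") rate of mode `l` is saturation (Monod)
#' kinetics in the mode's uptake substrate, catalyzed by its pseudo-enzyme:
#' `qbar_l = k_l * e_l * s_l / (Ksat_l + s_l)`. Modes without an uptake
#' substrate have zero kinetic rate. The regulated rate multiplies in the
#' cybernetic activity variable: `q_l = v_l * qbar_l`.
#'
#' @param e Pseudo-enzyme level L-vector.
#' @param params An [hcm_parameters].
#' @param x Named extracellular concentration vector (negative entries are
#'   clamped to zero before evaluation).
#' @param modes An `elementary_modes` set.
#' @return List with `qbar`, `q`, and control variables `u`, `v`.
#' @export
mode_rates <- function(e, params, x, modes) {
  x <- pmax(x, 0)
  e <- pmax(e, 0)
  s <- ifelse(is.na(modes$substrate), 0, x[modes$substrate])
  qbar <- ifelse(is.na(modes$substrate), 0,
                 params$k * e * s / (params$Ksat + s))
  qbar[!is.finite(qbar)] <- 0
  ctrl <- cybernetic_controls(qbar, modes)
  list(qbar = qbar, q = ctrl$v * qbar, u = ctrl$u, v = ctrl$v)
}

#' Cybernetic control variables for enzyme synthesis and activity
#'
#' Resource-allocation control laws: with weights `w_l = z_s,l * qbar_l`,
#' the synthesis allocation is `u_l = w_l / sum(w)` (sums to one) and the
#' activity is `v_l = w_l / max(w)` (maximum one). When every weight is
#' zero -- no enzyme, or no substrate -- both vectors are zero.
#'
#' @param qbar Non-negative kinetic rate L-vector.
#' @param modes An `elementary_modes` set supplying the uptake fluxes
#'   `z_s`.
#' @return List with allocation `u` and activity `v` vectors.
#' @export
cybernetic_controls <- function(qbar, modes) {
  w <- modes$z_s * qbar
  total <- sum(w)
  if (total <= 0) {
    zero <- numeric(length(w))
    return(list(u = zero, v = zero))
  }
  list(u = w / total, v = w / max(w))
}

#' Specific growth rate from mode fluxes
#'
#' Growth-flux weighted sum of the regulated mode rates:
#' `r_G = sum(z_mu,l * q_l)`.
#'
#' @param q Regulated mode rate L-vector.
#' @param modes An `elementary_modes` set.
#' @return Scalar specific growth rate.
#' @export
growth_rate <- function(q, modes) {
  sum(modes$z_mu * q)
}

# right-hand side of the hybrid cybernetic ODE system; state layout is
# (extracellular species, pseudo-enzymes e_1..e_L, cellmass c). parms carries
# precomputed integer substrate indices and the collapsed extracellular
# stoichiometry SZ = sigma_ext %*% Z so the inner loop stays allocation-light.
hcm_rhs <- function(t, state, parms) {
  n_ext <- parms$n_ext
  L <- parms$L
  x <- pmax(state[seq_len(n_ext)], 0)
  e <- pmax(state[n_ext + seq_len(L)], 0)
  c_mass <- max(state[n_ext + L + 1L], 0)

  s <- numeric(L)
  has <- parms$has_substrate
  s[has] <- x[parms$substrate_idx[has]]
  sat <- s / (parms$Ksat + s)
  sat[!has] <- 0
  qbar <- parms$k * e * sat

  w <- parms$z_s * qbar
  total <- sum(w)
  if (total > 0) {
    u <- w / total
    v <- w / max(w)
  } else {
    u <- v <- numeric(L)
  }
  q <- v * qbar
  rG <- sum(parms$z_mu * q)

  dx <- (parms$SZ %*% q) * c_mass
  rE <- parms$kE * sat
  de <- parms$alpha + rE * u - (parms$beta + rG) * e
  list(c(dx, de, rG * c_mass))
}

#' Simulate the hybrid cybernetic model
#'
#' Integrates the coupled balances for extracellular species
#' (`dx/dt = sigma Z q c` over the extracellular rows), pseudo-enzymes
#' (`de_l/dt = alpha_l + r_E,l u_l - (beta_l + r_G) e_l` with saturating
#' regulated synthesis) and cellmass (`dc/dt = r_G c`) with a
#' stiff-capable solver (lsoda, relative tolerance 1e-6, absolute 1e-8).
#' Negative states are clamped to zero inside the rate evaluation.
#'
#' @param params An [hcm_parameters].
#' @param modes An `elementary_modes` set (defaults to the canonical
#'   network's modes).
#' @param x0 Named initial extracellular concentrations, default
#'   `c(A_e = 10, B_e = 0, C_e = 0)`.
#' @param c0 Initial cellmass, default 0.05.
#' @param e0 Initial pseudo-enzyme level (scalar or L-vector), default 0.5.
#' @param times Increasing output time grid, default `seq(0, 16, 0.8)`.
#' @param use_compiled Evaluate the derivatives in compiled code (default;
#'   falls back to the interpreted implementation for networks larger than
#'   the compiled buffer). Set `FALSE` to force the R implementation --
#'   both produce the same trajectories.
#' @return A data.frame with columns `time`, one per extracellular species,
#'   `cellmass`, and `e_1..e_L`.
#' @export
simulate_hcm <- function(params, modes = NULL,
                         x0 = c(A_e = 10, B_e = 0, C_e = 0),
                         c0 = 0.05, e0 = 0.5,
                         times = seq(0, 16, 0.8),
                         use_compiled = TRUE) {
  if (is.null(modes)) modes <- enumerate_elementary_modes(canonical_network())
  stopifnot(inherits(params, "hcm_parameters"),
            inherits(modes, "elementary_modes"),
            all(diff(times) > 0), all(x0 >= 0), c0 >= 0, all(e0 >= 0))
  network <- modes$network
  ext <- network$external
  stopifnot(setequal(names(x0), ext))
  x0 <- x0[ext]
  L <- modes$L
  state0 <- c(x0, rep_len(e0, L), c0)
  names(state0) <- c(ext, paste0("e_", seq_len(L)), "cellmass")
  SZ <- network$sigma[ext, , drop = FALSE] %*% modes$Z
  sub_idx <- match(modes$substrate, ext)
  packed_len <- 3L + 7L * L + length(ext) * L
  if (use_compiled && L <= 32L && packed_len <= 512L) {
    # compiled right-hand side; layout documented in src/hcm_rhs.c
    packed <- numeric(512L)
    packed[1:3] <- c(length(ext), L, params$kE)
    packed[3L + seq_len(7L * L)] <-
      c(params$k, params$Ksat, params$alpha, params$beta,
        modes$z_s, modes$z_mu, ifelse(is.na(sub_idx), 0, sub_idx))
    packed[3L + 7L * L + seq_len(length(ext) * L)] <- as.numeric(SZ)
    sol <- deSolve::lsoda(y = state0, times = times, func = "hcm_derivs",
                          initfunc = "hcm_initmod", dllname = "poets",
                          parms = packed, rtol = 1e-6, atol = 1e-8)
  } else {
    parms <- list(n_ext = length(ext), L = L,
                  substrate_idx = sub_idx,
                  has_substrate = !is.na(modes$substrate),
                  k = params$k, Ksat = params$Ksat, kE = params$kE,
                  alpha = params$alpha, beta = params$beta,
                  z_s = modes$z_s, z_mu = modes$z_mu, SZ = SZ)
    sol <- deSolve::lsoda(y = state0, times = times, func = hcm_rhs,
                          parms = parms, rtol = 1e-6, atol = 1e-8)
  }
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    stop("hybrid cybernetic model integration failed")
  }
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  # clamp solver noise at the non-negativity boundary
  out[-1] <- lapply(out[-1], pmax, 0)
  out
}
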