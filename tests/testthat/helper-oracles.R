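# Independent brute-force oracles, deliberately written with different
# mechanics than the package implementations they check.

# O(A^2) double-loop Fonseca-Fleming domination counter
oracle_rank <- function(O) {
  A <- ncol(O)
  r <- integer(A)
  for (i in seq_len(A)) {
    for (j in seq_len(A)) {
      if (i == j) next
      better_or_equal <- TRUE
      strictly_better <- FALSE
      for (k in seq_len(nrow(O))) {
        if (O[k, j] > O[k, i]) better_or_equal <- FALSE
        if (O[k, j] < O[k, i]) strictly_better <- TRUE
      }
      if (better_or_equal && strictly_better) r[i] <- r[i] + 1L
    }
  }
  r
}

# Exhaustive elementary-mode oracle over all reaction subsets, using a
# QR-based null space (MASS::Null) instead of the package's SVD route.
# Returns a list of modes, each a full-length flux vector scaled to unit
# maximum entry, ordered by support.
oracle_elementary_modes <- function(sigma, internal, reversible) {
  R <- ncol(sigma)
  N <- sigma[internal, , drop = FALSE]
  found <- list()
  all_subsets <- unlist(lapply(seq_len(R), function(m) {
    asplit(utils::combn(R, m), 2)
  }), recursive = FALSE)
  for (sub in all_subsets) {
    sub <- as.integer(sub)
    ns <- MASS::Null(t(N[, sub, drop = FALSE]))
    if (NCOL(ns) != 1L) next
    v <- as.numeric(ns)
    if (any(abs(v) < 1e-8)) next
    irrev <- !reversible[sub]
    if (any(irrev)) {
      v <- v * sign(v[which(irrev)[1]])
      if (any(v[irrev] < -1e-8)) next
    }
    full <- numeric(R)
    full[sub] <- v / max(abs(v))
    found[[length(found) + 1L]] <- list(support = sub, flux = full)
  }
  supports <- lapply(found, `[[`, "support")
  minimal <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      i != j && length(supports[[j]]) < length(supports[[i]]) &&
        all(supports[[j]] %in% supports[[i]])
    }, logical(1)))
  }, logical(1))
  found <- found[minimal]
  keys <- vapply(found, function(m) paste(sprintf("%02d", m$support),
                                          collapse = ","), character(1))
  found[order(keys)]
}

# random small irreversible network with a guaranteed consumed/produced
# structure: entries in {-1, 0, 1}, every internal species touched
random_small_network <- function(n_internal, n_reactions, seed) {
  set.seed(seed)
  repeat {
    sigma <- matrix(sample(c(-1L, 0L, 1L), n_internal * n_reactions,
                           replace = TRUE, prob = c(0.35, 0.3, 0.35)),
                    nrow = n_internal)
    if (all(rowSums(abs(sigma)) > 0) && all(colSums(abs(sigma)) > 0)) break
  }
  rownames(sigma) <- paste0("M", seq_len(n_internal))
  colnames(sigma) <- paste0("r", seq_len(n_reactions))
  # one extracellular feed row so the network object is well-formed
  ext <- matrix(0L, nrow = 1, ncol = n_reactions,
                dimnames = list("X_e", colnames(sigma)))
  ext[1, 1] <- -1L
  stoich_network(rbind(sigma, ext), internal = rownames(sigma))
}

# default-settings canonical fixtures shared across test files
canonical_modes <- function() {
  enumerate_elementary_modes(canonical_network())
}
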