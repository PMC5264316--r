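#' Pareto dominance between two objective vectors
#'
#' Tests whether objective vector `a` dominates objective vector `b` under
#' minimization: `a` is no worse than `b` in every component and strictly
#' better in at least one. Identical vectors never dominate each other, so
#' duplicated points in an archive all receive the same rank.
#'
#' @param a,b Numeric vectors of equal length (objective values, smaller is
#'   better). Must be finite.
#' @return `TRUE` iff `a` dominates `b`.
#' @examples
#' dominates(c(1, 1), c(2, 2)) # TRUE
#' dominates(c(1, 3), c(3, 1)) # FALSE
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop("objective vectors must have equal length (got ",
         length(a), " and ", length(b), ")")
  }
  all(a <= b) && any(a < b)
}

#' Fonseca-Fleming Pareto rank of every column of an objective archive
#'
#' The rank of a point is the number of other archive members that dominate
#' it; nondominated points have rank 0. This is the scalar "energy" used by
#' the annealing acceptance rule.
#'
#' @param O Numeric matrix, one column per archive member, one row per
#'   objective (K x A).
#' @return Integer vector of length `ncol(O)` of domination counts.
#' @export
pareto_rank <- function(O) {
  O <- as_objective_matrix(O)
  A <- ncol(O)
  if (A == 0L) return(integer(0))
  K <- nrow(O)
  r <- integer(A)
  for (i in seq_len(A)) {
    oi <- O[, i]
    # column j dominates i iff every entry of O[, j] <= oi with one strict
    le_all <- colSums(O <= oi) == K
    lt_any <- colSums(O < oi) > 0L
    r[i] <- sum(le_all & lt_any)
  }
  r
}

#' Pareto rank of a candidate point against an archive
#'
#' Counts the archive members that dominate `candidate`. The candidate is
#' ranked against the archive as it stands, before any insertion, matching
#' the annealing acceptance test.
#'
#' @param candidate Numeric K-vector of objective values.
#' @param O Numeric K x A objective matrix (may have zero columns).
#' @return Integer domination count (0 means nondominated).
#' @export
rank_candidate <- function(candidate, O) {
  O <- as_objective_matrix(O)
  if (ncol(O) == 0L) return(0L)
  if (length(candidate) != nrow(O)) {
    stop("candidate length ", length(candidate),
         " does not match archive objective count ", nrow(O))
  }
  K <- nrow(O)
  sum(colSums(O <= candidate) == K & colSums(O < candidate) > 0L)
}

#' Re-rank an archive and drop members above a rank threshold
#'
#' Recomputes all Pareto ranks of the objective archive and keeps only the
#' columns with rank at most `max_rank`; the decision matrix `S` is filtered
#' column-aligned. Applied after every archive insertion during annealing.
#' The operation is idempotent at fixed `max_rank`.
#'
#' @param S Numeric D x A decision matrix (columns aligned with `O`).
#' @param O Numeric K x A objective matrix.
#' @param max_rank Largest rank retained (default 4, i.e. a `rank_cutoff` of 5).
#' @return An [ensemble_archive] with aligned `S`, `O` and rank vector `R`.
#' @export
filter_archive <- function(S, O, max_rank = 4L) {
  S <- as_decision_matrix(S)
  O <- as_objective_matrix(O)
  if (ncol(S) != ncol(O)) {
    stop("decision and objective archives are misaligned: ",
         ncol(S), " vs ", ncol(O), " columns")
  }
  r <- pareto_rank(O)
  keep <- r <= max_rank
  ensemble_archive(S[, keep, drop = FALSE], O[, keep, drop = FALSE], r[keep])
}

#' Combine archives from independent runs under a joint ranking
#'
#' Ranks computed within one run are not valid for a pooled collection, so
#' multistart results must be concatenated and re-ranked jointly before the
#' rank filter is re-applied.
#'
#' @param archives A list of [ensemble_archive] objects sharing decision
#'   dimension D and objective count K.
#' @param max_rank Largest rank retained after joint re-ranking (default 4).
#' @return A single jointly ranked, filtered [ensemble_archive].
#' @export
rerank_combined <- function(archives, max_rank = 4L) {
  if (inherits(archives, "ensemble_archive")) archives <- list(archives)
  stopifnot(length(archives) >= 1L)
  archives <- Filter(function(a) ncol(a$O) > 0L, archives)
  if (length(archives) == 0L) {
    return(ensemble_archive(matrix(0, 0, 0), matrix(0, 0, 0), integer(0)))
  }
  K <- unique(vapply(archives, function(a) nrow(a$O), integer(1)))
  D <- unique(vapply(archives, function(a) nrow(a$S), integer(1)))
  if (length(K) != 1L || length(D) != 1L) {
    stop("archives have heterogeneous dimensions and cannot be combined")
  }
  S <- do.call(cbind, lapply(archives, `[[`, "S"))
  O <- do.call(cbind, lapply(archives, `[[`, "O"))
  filter_archive(S, O, max_rank = max_rank)
}

#' Construct an ensemble archive
#'
#' Column-aligned store of accepted decision vectors (`S`, D x A), their
#' objective vectors (`O`, K x A) and Pareto ranks (`R`, length A).
#'
#' @param S Decision matrix (D x A).
#' @param O Objective matrix (K x A).
#' @param R Integer rank vector of length A; recomputed from `O` when `NULL`.
#' @return An object of class `ensemble_archive`.
#' @export
ensemble_archive <- function(S, O, R = NULL) {
  S <- as_decision_matrix(S)
  O <- as_objective_matrix(O)
  if (ncol(S) != ncol(O)) {
    stop("S and O must have the same number of columns")
  }
  if (is.null(R)) R <- pareto_rank(O)
  R <- as.integer(R)
  if (length(R) != ncol(O)) stop("rank vector length must equal archive size")
  structure(list(S = S, O = O, R = R), class = "ensemble_archive")
}

#' @export
print.ensemble_archive <- function(x, ...) {
  A <- ncol(x$O)
  cat("ensemble archive: ", A, " member", if (A != 1L) "s", ", D = ",
      nrow(x$S), ", K = ", nrow(x$O), "\n", sep = "")
  if (A > 0L) {
    tab <- table(factor(x$R, levels = sort(unique(x$R))))
    cat("rank counts:", paste(sprintf("%s:%d", names(tab), tab),
                              collapse = " "), "\n")
    cat("objective minima:", paste(signif(apply(x$O, 1, min), 5),
                                   collapse = " "), "\n")
  }
  invisible(x)
}

# coerce vectors/matrices to a column-member matrix without guessing shape
as_objective_matrix <- function(O) {
  if (is.null(O)) return(matrix(numeric(0), 0, 0))
  if (!is.matrix(O)) O <- matrix(O, ncol = 1L)
  storage.mode(O) <- "double"
  O
}

as_decision_matrix <- function(S) {
  if (is.null(S)) return(matrix(numeric(0), 0, 0))
  if (!is.matrix(S)) S <- matrix(S, ncol = 1L)
  storage.mode(S) <- "double"
  S
}
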