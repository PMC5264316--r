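#' Define a constrained multiobjective problem
#'
#' Bundles the user objective, box bounds, inequality constraints and the
#' penalty parameter into the problem object consumed by [run_poets()]. The
#' objective takes a decision vector `p` and returns a K-vector of errors
#' (smaller is better); it is responsible for solving any model equations
#' internally. Constraints follow the `g(p) >= 0` satisfied convention and
#' are folded into the objectives by [penalize()].
#'
#' @param objective Function `p -> numeric(K)`.
#' @param lower,upper Numeric D-vectors of box bounds, `lower <= upper`.
#' @param K Number of objectives the objective function returns.
#' @param constraints Optional list of functions `p -> numeric(1)`, satisfied
#'   when `>= 0`.
#' @param penalty_lambda Non-negative penalty weight applied to the total
#'   constraint violation (default 100).
#' @return An object of class `moo_problem`.
#' @examples
#' prob <- moo_problem(function(p) c(p[1]^2, (p[1] - 2)^2),
#'                     lower = -10, upper = 10, K = 2)
#' evaluate_objectives(prob, 0) # 0 4
#' @export
moo_problem <- function(objective, lower, upper, K,
                        constraints = list(), penalty_lambda = 100) {
  stopifnot(is.function(objective), length(lower) == length(upper),
            all(lower <= upper), K >= 1L, penalty_lambda >= 0)
  if (!all(vapply(constraints, is.function, logical(1)))) {
    stop("constraints must be a list of functions p -> numeric(1)")
  }
  structure(list(objective = objective,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 D = length(lower), K = as.integer(K),
                 constraints = constraints,
                 penalty_lambda = penalty_lambda),
            class = "moo_problem")
}

#' @export
print.moo_problem <- function(x, ...) {
  cat("multiobjective problem: D =", x$D, "decision variables, K =", x$K,
      "objectives,", length(x$constraints), "constraints\n")
  invisible(x)
}

#' Evaluate the penalized objective vector of a problem
#'
#' Calls the problem objective, evaluates any inequality constraints at `p`,
#' and adds the penalty term for constraint violations to every objective
#' component. Evaluations that error or return non-finite values are treated
#' as infeasible and mapped to `+Inf` in all components, so a failed model
#' solve can never enter the archive.
#'
#' @param problem A [moo_problem].
#' @param p Decision vector of length `problem$D`.
#' @return Numeric K-vector of penalized objective values.
#' @export
evaluate_objectives <- function(problem, p) {
  stopifnot(inherits(problem, "moo_problem"))
  raw <- tryCatch(problem$objective(p), error = function(e) NULL)
  if (is.null(raw) || length(raw) != problem$K || !all(is.finite(raw))) {
    return(rep(Inf, problem$K))
  }
  if (length(problem$constraints) == 0L) return(as.numeric(raw))
  gvals <- tryCatch(
    vapply(problem$constraints, function(g) as.numeric(g(p)), numeric(1)),
    error = function(e) NA_real_)
  penalize(as.numeric(raw), gvals, problem$penalty_lambda)
}

#' Penalty transform of inequality constraint violations
#'
#' Adds `lambda * sum(max(0, -g))` -- the total violation magnitude under the
#' `g >= 0` satisfied convention -- to every objective component, so that
#' infeasible points are uniformly worse in all objectives while feasible
#' points are untouched.
#'
#' @param raw Numeric K-vector of raw objective values.
#' @param gvals Numeric C-vector of constraint values (`>= 0` means satisfied).
#' @param lambda Non-negative penalty weight.
#' @return Penalized objective vector; `+Inf` in all components when `gvals`
#'   contains non-finite values.
#' @export
penalize <- function(raw, gvals, lambda) {
  stopifnot(lambda >= 0)
  if (length(gvals) == 0L) return(raw)
  if (!all(is.finite(gvals))) return(rep(Inf, length(raw)))
  violation <- sum(pmax(0, -gvals))
  raw + lambda * violation
}

#' Clamp a decision vector into its box bounds
#'
#' Componentwise `min(upper, max(lower, p))`; idempotent, and the identity
#' for points already inside the box.
#'
#' @param p Decision vector.
#' @param lower,upper Bound vectors of matching length.
#' @return The clipped decision vector.
#' @export
clip_to_bounds <- function(p, lower, upper) {
  pmin(upper, pmax(lower, p))
}
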