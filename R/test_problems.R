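#' Schaffer bi-objective function
#'
#' One decision variable on \[-10, 10\]; objectives `x^2` and `(x - 2)^2`.
#' The Pareto-optimal set is exactly `x` in \[0, 2\], tracing the front
#' `O2 = (sqrt(O1) - 2)^2` for `O1` in \[0, 4\].
#'
#' @param x Numeric scalar.
#' @return Numeric 2-vector of objective values.
#' @export
schaffer <- function(x) {
  c(x[1]^2, (x[1] - 2)^2)
}

#' Binh and Korn constrained bi-objective function
#'
#' Two decision variables on \[0, 5\] x \[0, 3\]; objectives
#' `4x^2 + 4y^2` and `(x - 5)^2 + (y - 5)^2`, with two nonlinear
#' constraints reported in the `g >= 0` satisfied convention:
#' `g1 = 25 - ((x - 5)^2 + y^2)` (a disc the solution must stay inside)
#' and `g2 = (x - 8)^2 + (y + 3)^2 - 7.7` (a disc it must stay outside).
#'
#' @param x,y Numeric scalars.
#' @return List with `objectives` (2-vector) and `g` (2-vector of
#'   constraint values).
#' @export
binh_korn <- function(x, y) {
  list(objectives = c(4 * x^2 + 4 * y^2, (x - 5)^2 + (y - 5)^2),
       g = c(25 - ((x - 5)^2 + y^2),
             (x - 8)^2 + (y + 3)^2 - 7.7))
}

#' Fonseca and Fleming bi-objective function
#'
#' Three decision variables on \[-4, 4\]^3; objectives
#' `1 - exp(-sum((x_i - 1/sqrt(3))^2))` and
#' `1 - exp(-sum((x_i + 1/sqrt(3))^2))`. The Pareto set is the diagonal
#' segment `x1 = x2 = x3 = t` for `t` in \[-1/sqrt(3), 1/sqrt(3)\].
#'
#' @param x Numeric 3-vector.
#' @return Numeric 2-vector of objective values in \[0, 1).
#' @export
fonseca_fleming <- function(x) {
  n <- length(x)
  c(1 - exp(-sum((x - 1 / sqrt(n))^2)),
    1 - exp(-sum((x + 1 / sqrt(n))^2)))
}

#' Built-in benchmark problems by name
#'
#' Returns a ready-to-run [moo_problem] for one of the three benchmark
#' functions: `"schaffer"` (D = 1, unconstrained), `"binh_korn"` (D = 2,
#' two nonlinear constraints handled by the penalty method) or
#' `"fonseca_fleming"` (D = 3, unconstrained).
#'
#' @param name Problem identifier.
#' @param penalty_lambda Penalty weight for constrained problems,
#'   default 100.
#' @return A [moo_problem].
#' @export
test_problem <- function(name = c("schaffer", "binh_korn",
                                  "fonseca_fleming"),
                         penalty_lambda = 100) {
  name <- match.arg(name)
  switch(name,
    schaffer = moo_problem(schaffer, lower = -10, upper = 10, K = 2L),
    binh_korn = moo_problem(
      function(p) binh_korn(p[1], p[2])$objectives,
      lower = c(0, 0), upper = c(5, 3), K = 2L,
      constraints = list(function(p) binh_korn(p[1], p[2])$g[1],
                         function(p) binh_korn(p[1], p[2])$g[2]),
      penalty_lambda = penalty_lambda),
    fonseca_fleming = moo_problem(fonseca_fleming, lower = rep(-4, 3),
                                  upper = rep(4, 3), K = 2L))
}

# cache for the sampled Binh-Korn front polyline
.front_cache <- new.env(parent = emptyenv())

#' Distance from an objective pair to a benchmark's Pareto front
#'
#' Analytic where available: for Schaffer the front satisfies
#' `O2 = (sqrt(O1) - 2)^2`, and the reported value is
#' `|O2 - (sqrt(O1) - 2)^2|`; for Fonseca-Fleming the front is traced by
#' `x1 = x2 = x3 = t`, `t` in \[-1/sqrt(3), 1/sqrt(3)\], and the value is
#' the Euclidean distance in objective space to a dense parameterization of
#' that curve. For Binh-Korn the front has no convenient closed form, so
#' the value is the distance to a polyline obtained once by non-dominated
#' filtering of a dense feasible grid (cached).
#'
#' @param name One of `"schaffer"`, `"binh_korn"`, `"fonseca_fleming"`.
#' @param point Numeric 2-vector of objective values.
#' @return Non-negative distance to the front.
#' @export
front_distance <- function(name = c("schaffer", "binh_korn",
                                    "fonseca_fleming"), point) {
  name <- match.arg(name)
  stopifnot(length(point) == 2L, all(is.finite(point)))
  switch(name,
    schaffer = abs(point[2] - (sqrt(max(point[1], 0)) - 2)^2),
    fonseca_fleming = {
      tt <- seq(-1 / sqrt(3), 1 / sqrt(3), length.out = 2001L)
      front <- t(vapply(tt, function(t) fonseca_fleming(rep(t, 3)),
                        numeric(2)))
      min(sqrt((front[, 1] - point[1])^2 + (front[, 2] - point[2])^2))
    },
    binh_korn = {
      front <- binh_korn_front()
      min(sqrt((front[, 1] - point[1])^2 + (front[, 2] - point[2])^2))
    })
}

# dense-grid nondominated front of the Binh-Korn problem, computed once
binh_korn_front <- function(n_grid = 400L) {
  key <- paste0("binh_korn_", n_grid)
  if (!is.null(.front_cache[[key]])) return(.front_cache[[key]])
  xs <- seq(0, 5, length.out = n_grid)
  ys <- seq(0, 3, length.out = n_grid)
  grid <- expand.grid(x = xs, y = ys)
  g1 <- 25 - ((grid$x - 5)^2 + grid$y^2)
  g2 <- (grid$x - 8)^2 + (grid$y + 3)^2 - 7.7
  feas <- g1 >= 0 & g2 >= 0
  o1 <- 4 * grid$x[feas]^2 + 4 * grid$y[feas]^2
  o2 <- (grid$x[feas] - 5)^2 + (grid$y[feas] - 5)^2
  ord <- order(o1, o2)
  o1 <- o1[ord]
  o2 <- o2[ord]
  keep <- cummin(o2) == o2  # sorted by o1, a point survives iff o2 is a new low
  front <- cbind(o1[keep], o2[keep])
  .front_cache[[key]] <- front
  front
}

#' Feasibility of a Binh-Korn decision vector
#'
#' @param p Numeric 2-vector `(x, y)`.
#' @param tol Constraint slack tolerance, default 0 (exact feasibility).
#' @return `TRUE` iff both constraints are satisfied to within `tol`.
#' @export
binh_korn_feasible <- function(p, tol = 0) {
  all(binh_korn(p[1], p[2])$g >= -tol)
}
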