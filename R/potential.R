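#' Hamilton-Jacobi potential branches of the mutator model
#'
#' In the large-genome limit the linearised two-chain system admits a
#' Hamilton-Jacobi description whose stationary value at each class
#' coordinate `x` is governed by the 2x2 coefficient matrix
#' \deqn{\begin{pmatrix} f(x) - \mu_1(1-\sqrt{1-x^2}) - \alpha_1 & \alpha_2 \\
#'   \alpha_1 & g(x) - \mu_2(1-\sqrt{1-x^2}) - \alpha_2 \end{pmatrix}}
#' The two eigenvalue branches `V_plus(x) >= V_minus(x)` play the role of
#' potentials: the mean fitness is the maximum of `V_plus` over
#' `x` in `[-1, 1]` (for `alpha2 = 0` the branches are the two diagonals and
#' their pointwise maximum covers both the mixed and the mutator phase).
#'
#' In the fully symmetric case (`mu1 = mu2`, `f = g`, `alpha1 = alpha2`) the
#' top branch is `f(x) - mu1 (1 - sqrt(1 - x^2))`, independent of the switch
#' rate, and `V_plus - V_minus = 2 alpha`.
#'
#' @param params A [mutator_params()] object (only rates are used).
#' @param landscape A [make_landscape()] object.
#' @param x Numeric vector in `[-1, 1]`.
#' @return Object of class `"potential_curve"`: list with `x`, `V_plus`,
#'   `V_minus`, and the maximising abscissas `argmax_plus`, `argmax_minus`.
#' @examples
#' p <- mutator_params(L = 10, mu1 = 1, mu2 = 3.5, alpha1 = 1, alpha2 = 1)
#' ls <- make_landscape("quadratic", c = 3)
#' pc <- potential(p, ls)
#' max(pc$V_plus)  # about 0.1811
#' @export
potential <- function(params, landscape, x = seq(-1, 1, length.out = 2001)) {
  if (any(abs(x) > 1)) stop("'x' must lie in [-1, 1]")
  V <- potential_branches(x, params, landscape)
  structure(list(x = x, V_plus = V$plus, V_minus = V$minus,
                 argmax_plus = x[which.max.last(V$plus)],
                 argmax_minus = x[which.max.last(V$minus)]),
            class = "potential_curve")
}

# eigenvalues of the 2x2 coefficient matrix, vectorised over x
potential_branches <- function(x, params, landscape) {
  c1 <- sqrt(pmax(1 - x^2, 0))
  d1 <- landscape$f(x) - params$mu1 * (1 - c1) - params$alpha1
  d2 <- landscape$g(x) - params$mu2 * (1 - c1) - params$alpha2
  disc <- sqrt(((d1 - d2) / 2)^2 + params$alpha1 * params$alpha2)
  list(plus = (d1 + d2) / 2 + disc, minus = (d1 + d2) / 2 - disc)
}

# last index attaining the maximum (ties broken toward larger x)
which.max.last <- function(v) {
  m <- max(v)
  max(which(v >= m - 1e-15 * (1 + abs(m))))
}

#' Analytic large-genome mean fitness
#'
#' Maximises the top potential branch `V_plus` over `x` in `[-1, 1]` (grid
#' scan of 2001 points plus local refinement; ties broken toward larger
#' `x`).  With `alpha2 = 0` the branches are the two diagonal potentials and
#' the pointwise maximum automatically takes the larger of the mixed-phase
#' and mutator-phase values.  Single-peak landscapes are handled by
#' [single_peak_solution()], not here.
#'
#' @inheritParams potential
#' @return The mean fitness `R` (scalar), with the maximising `x` attached
#'   as attribute `"argmax"`.
#' @examples
#' p <- mutator_params(L = 10, mu1 = 1, mu2 = 3.5, alpha1 = 1, alpha2 = 1)
#' mean_fitness_general(p, make_landscape("quadratic", c = 3))  # 0.1811
#' @export
mean_fitness_general <- function(params, landscape) {
  if (landscape$kind == "single_peak")
    stop("use single_peak_solution() for the single-peak landscape")
  xg <- seq(-1, 1, length.out = 2001)
  Vp <- potential_branches(xg, params, landscape)$plus
  if (any(!is.finite(Vp) & !(Vp == -Inf)))
    stop("non-finite landscape values")
  i <- which.max.last(Vp)
  lo <- xg[max(1, i - 1)]; hi <- xg[min(length(xg), i + 1)]
  opt <- stats::optimize(function(x)
    -potential_branches(x, params, landscape)$plus, c(lo, hi), tol = 1e-12)
  # optimize() never evaluates the bracket endpoints; cover boundary maxima
  cand_x <- c(lo, opt$minimum, hi)
  cand_v <- c(potential_branches(lo, params, landscape)$plus,
              -opt$objective,
              potential_branches(hi, params, landscape)$plus)
  j <- which.max.last(cand_v)
  R <- cand_v[j]
  attr(R, "argmax") <- cand_x[j]
  R
}

#' Mixed-phase and mutator-phase mean fitness (uni-directional model)
#'
#' For `alpha2 = 0` the two potential branches give closed phase-wise
#' expressions: the mixed phase grows with the wild-type machinery,
#' \deqn{R_{mix} = \max_x [f(x) - \mu_1(1-\sqrt{1-x^2})] - \alpha_1,}
#' while in the mutator phase the mutator sub-population evolves as an
#' ordinary Crow-Kimura model with its own rate,
#' \deqn{R_{mu} = \max_x [g(x) - \mu_2(1-\sqrt{1-x^2})].}
#' For linear fitness `k x` the inner maximum is
#' `sqrt(k^2 + mu^2) - mu`.
#'
#' @inheritParams potential
#' @return Scalar mean fitness with attribute `"argmax"`.
#' @examples
#' p <- mutator_params(L = 10, mu1 = 1, mu2 = 10, alpha1 = 0.01, alpha2 = 0)
#' mixed_phase_fitness(p, make_landscape("linear", k = 0.3))  # 0.0340
#' @export
mixed_phase_fitness <- function(params, landscape) {
  fls <- make_landscape_from_fun(landscape$f)
  one <- mutator_params(params$L, params$mu1, params$mu1, 0, 0)
  R0 <- mean_fitness_general(one, fls)
  R <- as.numeric(R0) - params$alpha1
  attr(R, "argmax") <- attr(R0, "argmax")
  R
}

#' @rdname mixed_phase_fitness
#' @export
mutator_phase_fitness <- function(params, landscape) {
  gls <- make_landscape_from_fun(landscape$g)
  one <- mutator_params(params$L, params$mu2, params$mu2, 0, 0)
  mean_fitness_general(one, gls)
}

# wrap a bare x-function as a landscape-like object
make_landscape_from_fun <- function(fn) {
  structure(list(kind = "custom", f = fn, g = fn, params = list()),
            class = "fitness_landscape")
}

#' Surplus and component ratio in the coupled model
#'
#' For `alpha1 * alpha2 != 0` the wild and mutator distributions share a
#' common peak `x = s` (`s1 = s2 = s`).  At the peak the Hamilton-Jacobi
#' momentum vanishes and the mutation losses drop out, so `(R, s)` satisfy
#' the stationary 2x2 system
#' \deqn{(f(s) - \alpha_1 - R)(g(s) - \alpha_2 - R) = \alpha_1 \alpha_2}
#' whose admissible root also fixes the amplitude ratio
#' `v2/v1 = (R - f(s) + alpha1)/alpha2` and hence the infinite-genome mutator
#' fraction `q = v2 / (v1 + v2)`.  For `f = g` this reduces to `f(s) = R`
#' and `q = alpha1 / (alpha1 + alpha2)`.
#'
#' @inheritParams potential
#' @param R Mean fitness; default [mean_fitness_general()].
#' @return List with `s`, `v2_over_v1`, `q`, `R`.
#' @export
surplus_and_ratio <- function(params, landscape,
                              R = mean_fitness_general(params, landscape)) {
  if (params$alpha1 * params$alpha2 == 0)
    stop("surplus_and_ratio() requires alpha1 * alpha2 != 0")
  R <- as.numeric(R)
  h <- function(s)
    (landscape$f(s) - params$alpha1 - R) *
    (landscape$g(s) - params$alpha2 - R) - params$alpha1 * params$alpha2
  xg <- seq(-1 + 1e-9, 1 - 1e-9, length.out = 4001)
  hv <- h(xg)
  sgn <- sign(hv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(h, c(xg[i], xg[i + 1]), tol = 1e-13)$root, numeric(1))
  ratio <- (R - landscape$f(roots) + params$alpha1) / params$alpha2
  ok <- ratio > 0
  if (!any(ok))
    stop("no admissible root in (-1, 1): boundary-dominated regime")
  s <- max(roots[ok])                    # ties toward larger x
  ratio <- (R - landscape$f(s) + params$alpha1) / params$alpha2
  list(s = s, v2_over_v1 = ratio, q = ratio / (1 + ratio), R = R)
}

#' Mean fitness of the d-dimensional mutator model
#'
#' The genome is split into `d` parts of relative lengths `y_i` with
#' per-part fitness contributions `f_i(x_i)` (wild) and `g_i(x_i)` (mutator)
#' and per-part mutation rates `mu_i`, `nu_i`.  The potential is the 2x2
#' eigenvalue construction of [potential()] with additive diagonals
#' `sum_i f_i(x_i) - sum_i mu_i (1 - sqrt(1 - x_i^2)) - alpha1` (and the
#' `g, nu, alpha2` analogue), and the mean fitness is its maximum over the
#' `x` hypercube (coarse grid plus local refinement, `d <= 4`).
#'
#' @param parts List of parts; each part is a list with fields `y` (weight,
#'   positive, summing to 1 across parts), `f`, `g` (functions of one `x`),
#'   `mu`, `nu` (rates).
#' @param alpha1,alpha2 Mutator-gene switch rates.
#' @param n_grid Grid points per dimension for the coarse scan.
#' @return List with `R`, `argmax` (the maximising `x` vector), and
#'   `V_plus`, `V_minus` at the maximiser.
#' @export
multidim_potential <- function(parts, alpha1, alpha2,
                               n_grid = if (length(parts) <= 3) 41L else 15L) {
  d <- length(parts)
  if (d < 1 || d > 4) stop("supported dimensions: 1 <= d <= 4")
  y <- vapply(parts, function(p) p$y, numeric(1))
  if (any(y <= 0) || abs(sum(y) - 1) > 1e-10)
    stop("part weights y_i must be positive and sum to 1")
  branches <- function(xv) {
    c1 <- sqrt(pmax(1 - xv^2, 0))
    d1 <- sum(vapply(seq_len(d), function(i)
      parts[[i]]$f(xv[i]) - parts[[i]]$mu * (1 - c1[i]), numeric(1))) - alpha1
    d2 <- sum(vapply(seq_len(d), function(i)
      parts[[i]]$g(xv[i]) - parts[[i]]$nu * (1 - c1[i]), numeric(1))) - alpha2
    disc <- sqrt(((d1 - d2) / 2)^2 + alpha1 * alpha2)
    c(plus = (d1 + d2) / 2 + disc, minus = (d1 + d2) / 2 - disc)
  }
  g1 <- seq(-1, 1, length.out = n_grid)
  grid <- as.matrix(do.call(expand.grid, rep(list(g1), d)))
  vals <- apply(grid, 1, function(xv) branches(xv)["plus"])
  best <- grid[which.max(vals), , drop = TRUE]
  obj <- function(xv) {
    v <- branches(pmin(pmax(xv, -1), 1))["plus"]
    if (!is.finite(v)) -1e30 else v
  }
  opt <- stats::optim(best, obj, method = "L-BFGS-B",
                      lower = rep(-1, d), upper = rep(1, d),
                      control = list(fnscale = -1, factr = 1e4))
  xstar <- unname(opt$par)
  V <- branches(xstar)
  list(R = unname(V["plus"]), argmax = xstar,
       V_plus = unname(V["plus"]), V_minus = unname(V["minus"]))
}
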