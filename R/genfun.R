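#' Exact generating-function solution for linear fitness
#'
#' For the uni-directional model (`alpha2 = 0`) with linear fitness
#' `f(x) = g(x) = k x`, the steady state of the wild-type chain is exactly
#' solvable through the generating function `P(z) = sum_l P_l z^l`.  The
#' steady-state condition turns into a first-order ODE whose polynomial
#' solutions are `P(z) = (z - z_-)^L` with
#' `z_- = -(k + sqrt(k^2 + mu1^2)) / mu1`, giving the closed-form dominant
#' eigenvalue
#' \deqn{R = \sqrt{k^2 + \mu_1^2} - \mu_1 - \alpha_1}
#' with no finite-`L` correction, and the explicit binomial class
#' distribution `P_l = choose(L, l) (-z_-)^{L - l}`.  The mutator chain is
#' recovered from the slaved linear system driven by `alpha1 * P`.
#'
#' @param params A [mutator_params()] object with `alpha2 = 0`.
#' @param landscape A linear [make_landscape()] with `f = g`.
#' @return List with `R` (exact), `state` (normalised [population_state()]),
#'   and `observables`.
#' @examples
#' p <- mutator_params(L = 200, mu1 = 1, mu2 = 10, alpha1 = 0.01, alpha2 = 0)
#' ls <- make_landscape("linear", k = 0.3)
#' generation_function_solve(p, ls)$R  # sqrt(1.09) - 1 - 0.01
#' @export
generation_function_solve <- function(params, landscape) {
  if (landscape$kind != "linear")
    stop("the generating-function solution requires a linear landscape")
  if (params$alpha2 != 0)
    stop("the generating-function solution requires alpha2 = 0")
  k <- landscape$params$k
  L <- params$L; mu1 <- params$mu1; a <- params$alpha1
  R <- sqrt(k^2 + mu1^2) - mu1 - a
  gamma <- (k + sqrt(k^2 + mu1^2)) / mu1       # -z_-
  lP <- lchoose(L, 0:L) + (L - (0:L)) * log(gamma)
  P <- exp(lP - max(lP))
  x <- 1 - 2 * (0:L) / L
  A2 <- chain_matrix(L, params$mu2, landscape$g(x), 0)
  Rmu <- sqrt(k^2 + params$mu2^2) - params$mu2  # mutator-chain Perron root
  if (R <= Rmu + 1e-12)
    stop("parameters are in the mutator phase; wild chain is not dominant")
  Q <- as.numeric(Matrix::solve(R * Matrix::Diagonal(L + 1L) - A2, a * P))
  st <- population_state(P, Q)
  list(R = R, state = st, observables = observables(st, landscape))
}
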