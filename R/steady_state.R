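#' Linear operator of the two-chain mutator model
#'
#' Builds the `2(L+1)`-dimensional generator of the linearised mutator
#' Crow-Kimura system.  The wild-type block carries diagonal
#' `f(x_l) - mu1 - alpha1` and class transitions `l -> l +/- 1` with the
#' combinatorial coefficients `(L - l + 1)` and `(l + 1)` scaled by the
#' per-site rate `mu1 / L`; the mutator block is analogous with `g`, `mu2`,
#' `alpha2`; the blocks are coupled by the switch rates (`alpha1` maps P into
#' Q, `alpha2` back).  The mean fitness of the model is the dominant
#' (rightmost) eigenvalue of this operator.
#'
#' @param params A [mutator_params()] object.
#' @param landscape A [make_landscape()] object (symmetric families).
#' @return A sparse `Matrix` of class `"mutator_operator"` (rows/columns
#'   ordered wild classes `0..L`, then mutator classes `0..L`) with the
#'   inputs attached as attributes.
#' @seealso [steady_state()], [integrate_nonlinear()]
#' @export
build_operator <- function(params, landscape) {
  stopifnot(inherits(params, "mutator_params"))
  L <- params$L
  x <- 1 - 2 * (0:L) / L
  n <- L + 1L
  A1 <- chain_matrix(L, params$mu1, landscape$f(x), params$alpha1)
  A2 <- chain_matrix(L, params$mu2, landscape$g(x), params$alpha2)
  M <- rbind(cbind(A1, params$alpha2 * Matrix::Diagonal(n)),
             cbind(params$alpha1 * Matrix::Diagonal(n), A2))
  attr(M, "params") <- params
  attr(M, "landscape") <- landscape
  M
}

#' Steady state of the mutator quasispecies model
#'
#' Computes the dominant eigenpair of the linearised system built by
#' [build_operator()]: the dominant eigenvalue is the steady-state mean
#' fitness, and the normalised non-negative eigenvector gives the joint
#' Hamming-class distribution of the wild-type and mutator-type
#' sub-populations.
#'
#' The eigenvalue is located by bisection on the explicitly symmetrised
#' operator (exact for the coupled case `alpha1 * alpha2 > 0`); with
#' `alpha2 = 0` the operator is block-triangular, the dominant eigenvalue is
#' the larger of the two chain Perron roots, and the subdominant chain
#' component of the eigenvector is obtained from the slaved linear solve, so
#' minority masses as small as 1e-7 retain full relative accuracy.  If the
#' two chain roots coincide within `1e-10` the result is flagged
#' `degenerate`.
#'
#' @param params A [mutator_params()] object.
#' @param landscape A [make_landscape()] object.
#' @return Object of class `"steady_state"`: list with
#'   \describe{
#'     \item{`R_numeric`}{dominant eigenvalue (mean fitness),}
#'     \item{`state`}{normalised [population_state()],}
#'     \item{`observables`}{[observables()] of the state,}
#'     \item{`residual`}{max-norm operator residual of the eigenpair,}
#'     \item{`degenerate`}{logical dominance-gap warning flag.}
#'   }
#' @examples
#' p <- mutator_params(L = 50, mu1 = 1, mu2 = 3.5, alpha1 = 1, alpha2 = 1)
#' ls <- make_landscape("quadratic", c = 3)
#' ss <- steady_state(p, ls)
#' ss$R_numeric
#' @export
steady_state <- function(params, landscape) {
  stopifnot(inherits(params, "mutator_params"))
  L <- params$L
  x <- 1 - 2 * (0:L) / L
  fx <- landscape$f(x); gx <- landscape$g(x)
  A1 <- chain_matrix(L, params$mu1, fx, params$alpha1)
  A2 <- chain_matrix(L, params$mu2, gx, params$alpha2)
  s1 <- chain_sym(L, params$mu1, fx, params$alpha1)
  s2 <- chain_sym(L, params$mu2, gx, params$alpha2)
  pr <- perron_two_block(A1, A2, params$alpha1, params$alpha2,
                         sym_tridiag_sparse(s1$d, s1$e),
                         sym_tridiag_sparse(s2$d, s2$e))
  st <- population_state(pr$P, pr$Q, normalize = TRUE)
  obs <- observables(st, landscape)
  structure(
    list(R_numeric = pr$value, state = st, observables = obs,
         residual = pr$residual, degenerate = pr$degenerate,
         params = params, landscape = landscape),
    class = "steady_state"
  )
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("steady state of the mutator model (L = %d)\n", x$params$L))
  cat(sprintf("  R (dominant eigenvalue) = %.8g\n", x$R_numeric))
  cat(sprintf("  mutator fraction q      = %.6g\n", x$observables$q))
  cat(sprintf("  surplus s               = %.6g\n", x$observables$s))
  cat(sprintf("  residual = %.2e%s\n", x$residual,
              if (x$degenerate) "  [degenerate dominance]" else ""))
  invisible(x)
}

#' As a data.frame: the class distribution of a steady state
#'
#' @param x A `"steady_state"` object.
#' @param ... Unused.
#' @return `data.frame` with columns `l`, `x`, `P`, `Q`.
#' @export
as.data.frame.steady_state <- function(x, ...) {
  L <- x$params$L
  data.frame(l = 0:L, x = 1 - 2 * (0:L) / L, P = x$state$P, Q = x$state$Q)
}
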