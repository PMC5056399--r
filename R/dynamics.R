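#' Integrate the nonlinear mutator quasispecies dynamics
#'
#' Integrates the normalised (nonlinear) replicator-mutator system for the
#' class probabilities: `d/dt y = M y - R(t) y` with `M` the linear operator
#' of [build_operator()] and `R(t)` the instantaneous mean fitness
#' `sum(f * P) + sum(g * Q)`, which keeps the total probability at one.
#' This is the dynamical counterpart of the eigenvalue problem solved by
#' [steady_state()]; for long times the mean fitness trajectory converges to
#' the dominant eigenvalue.
#'
#' @param params A [mutator_params()] object.
#' @param landscape A [make_landscape()] object.
#' @param initial A [population_state()] (normalised).  Default: all mass in
#'   the wild-type reference class `l = 0`.
#' @param t_end Final time.
#' @param n_out Number of equally spaced reporting times (including 0).
#' @param rtol,atol Integrator tolerances (stiff-capable `lsoda`).
#' @return Object of class `"mutator_trajectory"`: list with `times`,
#'   `states` (list of [population_state()]), `R` (mean-fitness trajectory),
#'   `drift` (max deviation of total mass from 1 across outputs), and
#'   `clipped` (number of negative entries clipped, all above `-1e-12`).
#' @examples
#' p <- mutator_params(L = 20, mu1 = 1, mu2 = 2, alpha1 = 1, alpha2 = 1)
#' ls <- make_landscape("quadratic", c = 3)
#' tr <- integrate_nonlinear(p, ls, t_end = 50)
#' tail(tr$R, 1)  # close to steady_state(p, ls)$R_numeric
#' @export
integrate_nonlinear <- function(params, landscape, initial = NULL,
                                t_end, n_out = 51L,
                                rtol = 1e-10, atol = 1e-12) {
  L <- params$L
  n <- L + 1L
  if (is.null(initial))
    initial <- population_state(c(1, rep(0, L)), rep(0, n))
  if (!isTRUE(initial$normalized) ||
      abs(sum(initial$P) + sum(initial$Q) - 1) > 1e-9)
    stop("'initial' must be a normalised population_state")
  if (t_end < 0) stop("'t_end' must be non-negative")
  x <- 1 - 2 * (0:L) / L
  fg <- c(landscape$f(x), landscape$g(x))
  M <- build_operator(params, landscape)
  y0 <- c(initial$P, initial$Q)
  times <- seq(0, t_end, length.out = max(2L, n_out))
  if (t_end == 0) {
    return(structure(list(times = 0, states = list(initial),
                          R = sum(fg * y0), drift = 0, clipped = 0L),
                     class = "mutator_trajectory"))
  }
  rhs <- function(t, y, parms) {
    w <- as.numeric(M %*% y)
    list(w - sum(fg * y) * y)
  }
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("integrator failed to meet the requested tolerance")
  Y <- unname(sol[, -1, drop = FALSE])
  neg <- Y < 0
  if (any(Y[neg] < -1e-12))
    stop("negative probabilities beyond -1e-12 in the trajectory")
  clipped <- sum(neg)
  if (clipped > 0) {
    message(sprintf("clipped %d slightly negative entries (all > -1e-12)",
                    clipped))
    Y[neg] <- 0
  }
  mass <- rowSums(Y)
  drift <- max(abs(mass - 1))
  states <- lapply(seq_len(nrow(Y)), function(i)
    structure(list(P = Y[i, 1:n], Q = Y[i, (n + 1):(2 * n)],
                   normalized = TRUE), class = "population_state"))
  R <- as.numeric(Y %*% fg)
  structure(list(times = times, states = states, R = R,
                 drift = drift, clipped = clipped),
            class = "mutator_trajectory")
}

#' @export
print.mutator_trajectory <- function(x, ...) {
  cat(sprintf("mutator-model trajectory: %d outputs on [0, %g]\n",
              length(x$times), max(x$times)))
  cat(sprintf("  final mean fitness R = %.8g\n", x$R[length(x$R)]))
  cat(sprintf("  probability drift    = %.2e\n", x$drift))
  invisible(x)
}
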