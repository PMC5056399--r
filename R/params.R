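#' Model parameters for the mutator quasispecies model
#'
#' Bundles the genome length and the four rates that govern the two-chain
#' Crow-Kimura model with a mutator gene: the per-genome mutation rates of the
#' wild-type and mutator-type sub-populations, and the switch rates of the
#' mutator locus itself.
#'
#' All rates are per genome and per unit time (Malthusian convention).  The
#' regular part of the genome carries `L` two-state sites; the mutator locus
#' is tracked separately through the switch rates `alpha1` (wild -> mutator)
#' and `alpha2` (mutator -> wild).  Class-transition rates of the Hamming
#' chains use the per-site rate `mu/L`.
#'
#' @param L Positive integer genome length (regular part).
#' @param mu1 Per-genome mutation rate of the wild-type, `>= 0`.
#' @param mu2 Per-genome mutation rate of the mutator-type, `>= 0`.
#'   Typically 10--100 times `mu1`.
#' @param alpha1 Forward switch rate wild -> mutator, `>= 0`.
#' @param alpha2 Backward switch rate mutator -> wild, `>= 0`.  The
#'   biologically common case neglects back switching (`alpha2 = 0`).
#'
#' @return An object of class `"mutator_params"`: a list with fields `L`,
#'   `mu1`, `mu2`, `alpha1`, `alpha2`.
#' @seealso [uni_directional()], [build_operator()], [steady_state()]
#' @examples
#' p <- mutator_params(L = 100, mu1 = 1, mu2 = 10, alpha1 = 0.01, alpha2 = 0)
#' uni_directional(p)
#' @export
mutator_params <- function(L, mu1, mu2, alpha1, alpha2) {
  if (length(L) != 1L || !is.finite(L) || L < 1 || L != round(L))
    stop("'L' must be a positive integer")
  rates <- c(mu1 = mu1, mu2 = mu2, alpha1 = alpha1, alpha2 = alpha2)
  if (length(rates) != 4L || any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  structure(
    list(L = as.integer(L), mu1 = mu1, mu2 = mu2,
         alpha1 = alpha1, alpha2 = alpha2),
    class = "mutator_params"
  )
}

#' Is the mutator switching uni-directional?
#'
#' Convenience predicate: `TRUE` iff the backward switch rate `alpha2` is
#' exactly zero, the regime in which the model has the mixed / mutator /
#' non-selective phase structure.
#'
#' @param params A [mutator_params()] object.
#' @return Logical scalar.
#' @export
uni_directional <- function(params) {
  stopifnot(inherits(params, "mutator_params"))
  params$alpha2 == 0
}

#' @export
print.mutator_params <- function(x, ...) {
  cat("Mutator quasispecies parameters\n")
  cat(sprintf("  L = %d sites\n", x$L))
  cat(sprintf("  mutation rates      mu1 = %g, mu2 = %g (per genome)\n",
              x$mu1, x$mu2))
  cat(sprintf("  mutator switching   alpha1 = %g, alpha2 = %g%s\n",
              x$alpha1, x$alpha2,
              if (x$alpha2 == 0) "  [uni-directional]" else ""))
  invisible(x)
}

#' Observables of a population state
#'
#' Computes the steady-state (or instantaneous) observables of a two-chain
#' Hamming-class distribution: mean fitness `R`, total surplus `s` (the
#' population mean of `x = 1 - 2 l / L`), the per-type surpluses `s1`
#' (wild-type) and `s2` (mutator-type), and the mutator fraction `q`.
#'
#' The surplus of a sub-population with zero mass is undefined and reported
#' as `NA`, not as zero.
#'
#' @param state A `"population_state"` object (see [population_state()]) or a
#'   list with numeric vectors `P` and `Q` of equal length `L + 1`.
#' @param landscape A [make_landscape()] object supplying the fitness maps.
#' @return An object of class `"mutator_observables"`: list with fields `R`,
#'   `s`, `s1`, `s2`, `q`.
#' @examples
#' ls <- make_landscape("linear", k = 1)
#' st <- population_state(P = c(1, rep(0, 10)), Q = rep(0, 11))
#' observables(st, ls)  # s = s1 = 1, q = 0
#' @export
observables <- function(state, landscape) {
  P <- state$P; Q <- state$Q
  if (length(P) != length(Q)) stop("'P' and 'Q' must have equal length")
  L <- length(P) - 1L
  x <- 1 - 2 * (0:L) / L
  tot <- sum(P) + sum(Q)
  if (tot <= 0) stop("state has no mass")
  Pn <- P / tot; Qn <- Q / tot
  fx <- landscape$f(x); gx <- landscape$g(x)
  q  <- sum(Qn)
  s1 <- if (sum(Pn) > 0) sum(x * Pn) / sum(Pn) else NA_real_
  s2 <- if (q > 0)       sum(x * Qn) / q       else NA_real_
  structure(
    list(R = sum(fx * Pn) + sum(gx * Qn),
         s = sum(x * (Pn + Qn)),
         s1 = s1, s2 = s2, q = q),
    class = "mutator_observables"
  )
}

#' @export
print.mutator_observables <- function(x, ...) {
  cat(sprintf("mean fitness R = %.8g\n", x$R))
  cat(sprintf("surplus s = %.6g (wild s1 = %s, mutator s2 = %s)\n", x$s,
              format(x$s1, digits = 6), format(x$s2, digits = 6)))
  cat(sprintf("mutator fraction q = %.8g\n", x$q))
  invisible(x)
}

#' Two-chain Hamming-class population state
#'
#' Container for the wild-type (`P`) and mutator-type (`Q`) Hamming-class
#' weights.  With `normalize = TRUE` the state is scaled so that
#' `sum(P) + sum(Q) = 1`.
#'
#' @param P,Q Non-negative numeric vectors of length `L + 1`.
#' @param normalize Scale to total mass one (default `TRUE`).
#' @return Object of class `"population_state"`: list with `P`, `Q`,
#'   `normalized`.
#' @export
population_state <- function(P, Q, normalize = TRUE) {
  if (length(P) != length(Q)) stop("'P' and 'Q' must have equal length")
  if (any(P < 0) || any(Q < 0)) {
    if (min(c(P, Q)) < -1e-12) stop("negative class weights")
    P <- pmax(P, 0); Q <- pmax(Q, 0)
  }
  if (normalize) {
    tot <- sum(P) + sum(Q)
    if (tot <= 0) stop("state has no mass")
    P <- P / tot; Q <- Q / tot
  }
  structure(list(P = P, Q = Q, normalized = normalize),
            class = "population_state")
}
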