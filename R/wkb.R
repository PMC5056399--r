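#' WKB computation of the wild-allele fraction at finite genome length
#'
#' In the mixed phase of the uni-directional model (`alpha2 = 0`, `f = g`
#' smooth) the wild-type chain dominates the eigenvalue but the mutator
#' chain, fed at rate `alpha1` by the wild distribution, accumulates its own
#' exponentially localised packet.  Writing `P_l = exp(L u(x))`, the wild
#' exponent solves the stationary Hamilton-Jacobi equation
#' \deqn{R = f(x) - \mu_1 - \alpha_1 + \mu_1\left[\tfrac{1+x}{2} z +
#'   \tfrac{1-x}{2} z^{-1}\right], \qquad z = e^{2 u'(x)},}
#' peaked at `s1` where `f(s1) = R + alpha1`.  The mutator packet consists
#' of a slaved branch sharing the exponent `u` (valid above the matching
#' point `s3`, where `f(s3) = R + alpha1 mu2/(mu2 - mu1)`) concatenated, with
#' a smooth derivative, onto the homogeneous mutator-chain branch which
#' peaks at `s2` with `f(s2) = R`.  The resulting exponent at the mutator
#' peak,
#' \deqn{\tilde u(s_2) = u(s_3) - \int_{s_2}^{s_3} \tilde u'(x)\,dx,}
#' is exact as `L` grows and controls which allele takes over:
#' the discriminant `K = exp(-L * u_tilde(s2))` is near 1 when the wild type
#' keeps the majority and exponentially small when the mutator allele sweeps.
#'
#' The wild fraction itself additionally needs the Laplace prefactors: the
#' resonance crossing at `s3` injects homogeneous amplitude
#' `a * sqrt(2 pi L / (b g'))` (with `b` twice the local group velocity of
#' the mutator branch and `g' = (mu2 - mu1) f'(s3)` the detuning slope), and
#' the two Gaussian packets contribute their curvature ratio.  The prefactor
#' is accurate to a factor of order one; the exponent is asymptotically
#' exact.
#'
#' @param params A [mutator_params()] with `alpha2 = 0` (mixed-phase regime).
#' @param landscape A smooth [make_landscape()] with `f = g`, increasing
#'   through the relevant root brackets (linear and similar families).
#' @param L Genome length at which to evaluate the exponent (defaults to
#'   `params$L`).
#' @return Object of class `"wkb_result"`: list with `one_minus_q`, `K`,
#'   `s1`, `s2`, `s3`, `exponent` (`L * u_tilde(s2)`), `validity` (`TRUE`
#'   when the exponential regime `exponent >= 1` applies), and `rho`
#'   (the estimated mutator/wild mass ratio).
#' @examples
#' p <- mutator_params(L = 1000, mu1 = 1, mu2 = 10, alpha1 = 0.01, alpha2 = 0)
#' wkb_mutator_fraction(p, make_landscape("linear", k = 0.3))$K  # about 0.93
#' @export
wkb_mutator_fraction <- function(params, landscape, L = params$L) {
  if (params$alpha2 != 0) stop("WKB analysis requires alpha2 = 0")
  if (landscape$kind == "single_peak")
    stop("single-peak landscapes have the closed form single_peak_solution()")
  a <- params$alpha1; mu1 <- params$mu1; mu2 <- params$mu2
  f <- landscape$f
  if (a == 0)
    return(structure(list(one_minus_q = 1, K = 1, s1 = NA_real_,
                          s2 = NA_real_, s3 = NA_real_, exponent = 0,
                          validity = TRUE, rho = 0), class = "wkb_result"))
  if (mu2 <= mu1) stop("WKB mixed-phase analysis requires mu2 > mu1")
  R <- as.numeric(mixed_phase_fitness(params, landscape))
  R_mu <- as.numeric(mutator_phase_fitness(params, landscape))
  if (R <= R_mu) stop("parameters are not in the mixed phase")
  s1 <- surplus_from_R(R + a, f)
  s2 <- surplus_from_R(R, f)
  s3 <- surplus_from_R(R + a * mu2 / (mu2 - mu1), f)
  if (any(is.na(c(s1, s2, s3))) || !(s2 < s3) || !(s1 < s3))
    stop("no smooth matching point s3 in the required ordering; result invalid")
  z_wild <- function(x) {                       # exp(2 u'(x)), wild chain
    W <- (R + mu1 + a - f(x)) / mu1
    (W + sqrt(pmax(W^2 - (1 - x^2), 0))) / (1 + x)
  }
  z_mut <- function(x) {                        # homogeneous mutator branch
    W <- (R + mu2 - f(x)) / mu2
    (W + sqrt(pmax(W^2 - (1 - x^2), 0))) / (1 + x)
  }
  u_s3 <- stats::integrate(function(x) 0.5 * log(z_wild(x)), s1, s3,
                           rel.tol = 1e-10)$value
  int_m <- stats::integrate(function(x) 0.5 * log(z_mut(x)), s2, s3,
                            rel.tol = 1e-10)$value
  u2 <- u_s3 - int_m                            # u_tilde(s2); > 0 in the sweep regime
  E <- L * u2
  K <- exp(-pmin(E, 700))
  # Laplace prefactors for the mass ratio rho = (mutator mass)/(wild mass)
  fp <- function(x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)
  z3 <- z_wild(s3)
  Svel <- function(x, z) mu2 * ((1 + x) / 2 * z - (1 - x) / (2 * z))
  S3 <- Svel(s3, z3); S2 <- mu2 * s2
  g1 <- (mu2 - mu1) * fp(s3)
  A_h <- a * sqrt(2 * pi * L / (2 * S3 * g1))
  upp <- fp(s1) / (2 * mu1 * s1)                # |u''(s1)|
  mpp <- fp(s2) / (2 * mu2 * s2)                # |u_tilde''(s2)|
  rho <- A_h * sqrt(S3 / S2) * sqrt(upp / mpp) * exp(pmin(E, 700))
  structure(list(one_minus_q = 1 / (1 + rho), K = K,
                 s1 = s1, s2 = s2, s3 = s3, exponent = E,
                 validity = E >= 1, rho = rho),
            class = "wkb_result")
}

#' @export
print.wkb_result <- function(x, ...) {
  cat(sprintf("WKB mutator-fraction analysis\n"))
  cat(sprintf("  exponent L*u(s2) = %.6g  (K = %.6g)\n", x$exponent, x$K))
  cat(sprintf("  1 - q = %.6g   [%s regime]\n", x$one_minus_q,
              if (isTRUE(x$validity)) "exponential" else "small-exponent"))
  invisible(x)
}

#' Small-switch-rate asymptotics for linear fitness
#'
#' For linear fitness `f(x) = k x`, small forward switch rate `a` and a
#' strong mutator (`mu2 >> mu1`) the WKB exponent of
#' [wkb_mutator_fraction()] collapses to the closed form
#' \deqn{E = \frac{L a^2}{4 \mu_2 k s_2},}
#' obtained by replacing the matching point `s3` by the wild peak `s1` and
#' expanding the mutator branch quadratically about its peak
#' `s2 = (sqrt(k^2 + mu1^2) - mu1 - a)/k`.  The wild-allele fraction is then
#' `1 - q = 1 / (1 + rho)` with
#' `rho = a sqrt(pi L / ((mu2 - mu1) k s1)) exp(E)`:
#' for small genomes (`E << 1`) the mutator fraction is simply proportional
#' to `a` (linear-response regime), while beyond the crossover length
#' `L* = 4 mu2 k s2 / a^2` the exponential takes over and the mutator allele
#' sweeps.  The exponent is asymptotically exact; the prefactor is an
#' order-one estimate (the three WKB packets merge as `a -> 0`).
#'
#' @param k Linear-fitness slope.
#' @param a Forward switch rate.
#' @param mu Mutator mutation rate `mu2`.
#' @param L Genome length.
#' @param mu1 Wild-type mutation rate (default 1).
#' @return List with `one_minus_q`, `exponent`, `K`, `crossover_L`, `rho`,
#'   `validity` (`FALSE` when `a` is not small or `mu` not large, i.e. the
#'   regime assumptions are violated).
#' @examples
#' small_a_asymptotics(k = 0.3, a = 1e-4, mu = 10, L = 1000)$one_minus_q
#' @export
small_a_asymptotics <- function(k, a, mu, L, mu1 = 1) {
  R0 <- sqrt(k^2 + mu1^2) - mu1
  R <- R0 - a
  s1 <- R0 / k
  s2 <- R / k
  if (s2 <= 0) stop("mixed-phase surplus is non-positive; regime invalid")
  E <- L * a^2 / (4 * mu * k * s2)
  rho <- a * sqrt(pi * L / ((mu - mu1) * k * s1)) * exp(pmin(E, 700))
  list(one_minus_q = 1 / (1 + rho),
       exponent = E, K = exp(-pmin(E, 700)),
       crossover_L = 4 * mu * k * s2 / a^2,
       rho = rho,
       validity = (a <= 0.1 * k * (1 - s1)) && (mu >= 5 * mu1))
}
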