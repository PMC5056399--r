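#' Parameters of the Eigen model with a mutator gene
#'
#' In the Eigen (coupled mutation-selection) setting replication and
#' mutation happen together: a wild-type sequence copies each nucleotide
#' without error with probability `w`, so the whole genome copies cleanly
#' with probability `Q = w^L = exp(-gamma)` where `gamma = -L log(w)` is the
#' genome mutation parameter.  The mutator type has mutation parameter
#' `mu * gamma`.  A replication event switches the offspring to the mutator
#' type with probability `1 - exp(-h)`; back switching is neglected.
#' Fitness values are Wrightian (multiplicative per generation); the
#' single-peak landscape has peak `A` against background 1.
#'
#' @param L Genome length.
#' @param w Errorless-copy probability per nucleotide (wild type); supply
#'   either `w` or `gamma`.
#' @param gamma Genome mutation parameter `-L log(w)`.
#' @param mu Ratio of the mutator to wild mutation parameter (`>= 1`
#'   typically).
#' @param h Per-replication wild -> mutator switch parameter.
#' @param A Peak Wrightian fitness (single-peak landscape), `> 0`.
#' @return Object of class `"eigen_params"`: list with `L`, `w`, `gamma`,
#'   `Q`, `mu`, `h`, `A`.
#' @export
eigen_params <- function(L, w = NULL, gamma = NULL, mu = 1, h = 0, A = NULL) {
  if (is.null(w) && is.null(gamma)) stop("supply 'w' or 'gamma'")
  if (is.null(w)) w <- exp(-gamma / L)
  if (is.null(gamma)) gamma <- -L * log(w)
  if (w <= 0 || w > 1) stop("'w' must lie in (0, 1]")
  if (h < 0) stop("'h' must be non-negative")
  if (!is.null(A) && A <= 0) stop("'A' must be positive")
  structure(list(L = as.integer(L), w = w, gamma = gamma,
                 Q = exp(-gamma), mu = mu, h = h, A = A),
            class = "eigen_params")
}

#' @export
print.eigen_params <- function(x, ...) {
  cat(sprintf("Eigen-model parameters: L = %d, w = %.6g (gamma = %.6g)\n",
              x$L, x$w, x$gamma))
  cat(sprintf("  mutator ratio mu = %g, switch h = %g, peak A = %s\n",
              x$mu, x$h, format(x$A)))
  invisible(x)
}

#' Mean fitness and phase of the continuous-time Eigen mutator model
#'
#' The wild-type chain of the coupled system is the classical Eigen model
#' multiplied by `exp(-h)`, so the mixed-phase mean fitness is the classical
#' expression scaled by `exp(-h)`; the mutator phase is the classical
#' expression at mutation parameter `mu * gamma`; the non-selective value is
#' the background fitness 1.  For the single-peak landscape these are
#' `R_mix = A exp(-(h + gamma))`, `R_mu = A exp(-mu gamma)`, `R_ns = 1`.
#' For a general symmetric Wrightian landscape `f` the classical expression
#' is `max_x f(x) exp(-gamma (1 - sqrt(1 - x^2)))`.
#'
#' @param par An [eigen_params()] object.
#' @param landscape Optional [make_landscape()] with Wrightian values; if
#'   omitted, the single-peak landscape with peak `par$A` is used.
#' @return List with `R`, `phase`, and the three candidate values `R_mix`,
#'   `R_mu`, `R_ns`.
#' @export
eigen_continuous_R <- function(par, landscape = NULL) {
  stopifnot(inherits(par, "eigen_params"))
  if (is.null(landscape)) {
    if (is.null(par$A)) stop("supply a landscape or a peak fitness 'A'")
    R_mix <- par$A * exp(-(par$h + par$gamma))
    R_mu  <- par$A * exp(-par$mu * par$gamma)
  } else {
    cls_max <- function(fn, g) {
      opt <- stats::optimize(function(x)
        -fn(x) * exp(-g * (1 - sqrt(pmax(1 - x^2, 0)))), c(-1, 1),
        tol = 1e-12)
      -opt$objective
    }
    R_mix <- exp(-par$h) * cls_max(landscape$f, par$gamma)
    R_mu  <- cls_max(landscape$g, par$mu * par$gamma)
  }
  R_ns <- 1
  cand <- c(mixed = R_mix, mutator = R_mu, non_selective = R_ns)
  i <- which.max(cand)
  list(R = unname(cand[i]), phase = names(cand)[i],
       R_mix = R_mix, R_mu = R_mu, R_ns = R_ns)
}

#' Phase borders of the single-peak Eigen mutator model
#'
#' The three borders in the `(h, gamma)` plane at fixed `A` and `mu`:
#' non-selective/mutator along `mu * gamma = log A`, non-selective/mixed
#' along `h = log A - gamma`, and mixed/mutator along `h = (mu - 1) gamma`.
#' All three meet at the triple point
#' `(gamma, h) = (log(A)/mu, (mu - 1) log(A)/mu)`.
#'
#' @param A Peak fitness, `> 1`.
#' @param mu Mutator mutation-parameter ratio.
#' @return List with `gamma_mutator_ns` (constant), functions
#'   `h_mixed_ns(gamma)` and `h_mixed_mutator(gamma)`, and `triple_point`.
#' @export
eigen_phase_borders <- function(A, mu) {
  if (A <= 1) stop("'A' must exceed the background fitness 1")
  list(
    gamma_mutator_ns = log(A) / mu,
    h_mixed_ns = function(gamma) log(A) - gamma,
    h_mixed_mutator = function(gamma) (mu - 1) * gamma,
    triple_point = c(gamma = log(A) / mu, h = (mu - 1) * log(A) / mu))
}

#' Mutator fraction of the single-peak Eigen model (mixed phase)
#'
#' In the mixed phase (`R = Q A exp(-h)` with `Q = exp(-gamma)`) the peak
#' occupancies follow from the steady-state balance: the total peak mass is
#' `p0 + q0 = (R - 1)/(A - 1)`, the switching source gives
#' `q0 = (1 - exp(-h)) Q A p0 / (R - A exp(-mu gamma))`, and the wild chain
#' keeps its classical internal structure so that its total mass is
#' `p0 (A - 1)/(Q A - 1)`.  The mutator fraction is one minus that mass.
#' For `h, gamma, A - 1` all small this collapses to
#' \deqn{1 - q = \frac{(S-\gamma-h)((\mu-1)\gamma-h)}{(S-\gamma)(\mu-1)\gamma},
#'   \qquad S = A - 1,}
#' the Eigen-side image of the Crow-Kimura single-peak result.
#'
#' @param par An [eigen_params()] object with `A` set, in the mixed phase.
#' @param small_parameter If `TRUE` return the small-parameter closed form
#'   instead of the full balance expression.
#' @return List with `q`, `one_minus_q`, `p0`, `q0`, `R`.
#' @export
eigen_single_peak_q <- function(par, small_parameter = FALSE) {
  stopifnot(inherits(par, "eigen_params"))
  if (is.null(par$A)) stop("'A' must be set")
  A <- par$A; g <- par$gamma; h <- par$h; mu <- par$mu
  R <- A * exp(-(g + h))
  R_mu <- A * exp(-mu * g)
  if (R <= max(R_mu, 1)) stop("parameters are outside the mixed phase")
  if (small_parameter) {
    S <- A - 1
    omq <- (S - g - h) * ((mu - 1) * g - h) / ((S - g) * (mu - 1) * g)
    return(list(q = 1 - omq, one_minus_q = omq, p0 = NA_real_,
                q0 = NA_real_, R = R))
  }
  QA <- exp(-g) * A
  tot0 <- (R - 1) / (A - 1)                       # p0 + q0
  ratio <- (1 - exp(-h)) * QA / (R - A * exp(-mu * g))  # q0 / p0
  p0 <- tot0 / (1 + ratio)
  q0 <- p0 * ratio
  p_tot <- p0 * (A - 1) / (QA - 1)
  list(q = 1 - p_tot, one_minus_q = p_tot, p0 = p0, q0 = q0, R = R)
}

#' Hamming-class mutation kernel of the Eigen model
#'
#' Exact class-to-class mutation probabilities for a symmetric landscape: a
#' parent in class `l` begets offspring in class `l'` with probability given
#' by the two-index binomial sum over back-flips among the `l` mutated sites
#' and forward flips among the `L - l` reference sites (no Poisson
#' approximation).  Computed by direct convolution for moderate `L` and FFT
#' convolution for large `L`.
#'
#' @param L Genome length.
#' @param w Errorless-copy probability per nucleotide.
#' @return Matrix `K` with `K[i, j] = P(offspring class i - 1 | parent class
#'   j - 1)`; columns sum to one.
#' @export
eigen_class_kernel <- function(L, w) {
  p <- 1 - w
  n <- L + 1L
  K <- matrix(0, n, n)
  use_fft <- L > 256
  for (l in 0:L) {
    back <- stats::dbinom(0:l, l, p)          # flips l -> l - B
    fwd  <- stats::dbinom(0:(L - l), L - l, p)
    if (use_fft) {
      # distribution of (l - B) + F: convolve rev(back) with fwd
      dist <- stats::convolve(rev(back), rev(fwd), type = "open")
      dist[dist < 0] <- 0
    } else {
      dist <- numeric(n)
      for (b in 0:l) dist[(l - b) + seq_len(L - l + 1)] <-
          dist[(l - b) + seq_len(L - l + 1)] + back[b + 1] * fwd
      dist <- dist[1:n]
      K[, l + 1L] <- dist
      next
    }
    K[, l + 1L] <- dist[1:n]
  }
  K
}

#' Discrete-time iteration of the Eigen mutator model
#'
#' Iterates the coupled discrete-time Eigen system: each generation every
#' sequence replicates in proportion to its Wrightian fitness, offspring
#' mutate through the mutation kernel, wild-type offspring switch to the
#' mutator type with probability `1 - exp(-h)`, and the population is
#' renormalised.  The pre-normalisation growth factor converges to the
#' dominant eigenvalue of the transfer matrix, which equals the
#' continuous-time phase value.  Symmetric landscapes use the exact
#' Hamming-class reduction ([eigen_class_kernel()]) at any `L`; the full
#' `2^L` sequence iteration is available for `L <= 10` as an oracle.
#'
#' @param par An [eigen_params()] object.
#' @param landscape A [make_landscape()] with Wrightian values; `NULL` for
#'   the single-peak landscape with peak `par$A` and background 1.
#' @param initial Optional list with components `p`, `q` (class or sequence
#'   space, matching `reduced`).  Default: all wild-type mass in the
#'   reference class/sequence.
#' @param n_steps Number of generations.
#' @param reduced Use the Hamming-class reduction (default `TRUE`).
#' @return List with `p`, `q` (final distributions), `growth` (vector of
#'   per-step growth factors), and `trajectory` (matrix of mutator fractions
#'   and growth per step).
#' @export
eigen_discrete_iterate <- function(par, landscape = NULL, initial = NULL,
                                   n_steps, reduced = TRUE) {
  stopifnot(inherits(par, "eigen_params"))
  L <- par$L
  if (reduced) {
    x <- 1 - 2 * (0:L) / L
    if (is.null(landscape)) {
      if (is.null(par$A)) stop("supply a landscape or 'A'")
      r1 <- c(par$A, rep(1, L)); r2 <- r1
    } else {
      r1 <- landscape$f(x); r2 <- landscape$g(x)
    }
    Kw <- eigen_class_kernel(L, par$w)
    Km <- eigen_class_kernel(L, exp(-par$mu * par$gamma / L))
    p <- if (is.null(initial)) c(1, rep(0, L)) else initial$p
    q <- if (is.null(initial)) rep(0, L + 1) else initial$q
  } else {
    if (L > 10) stop("full sequence iteration limited to L <= 10")
    n <- 2^L
    pc <- integer(n)
    if (n > 1) for (i in 1:(n - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
    xs <- 1 - 2 * pc / L
    if (is.null(landscape)) {
      r1 <- c(par$A, rep(1, n - 1)); r2 <- r1
    } else {
      r1 <- landscape$f(xs); r2 <- landscape$g(xs)
    }
    D <- hamming_matrix(L)
    Kw <- par$w^(L - D) * (1 - par$w)^D
    wm <- exp(-par$mu * par$gamma / L)
    Km <- wm^(L - D) * (1 - wm)^D
    p <- if (is.null(initial)) c(1, rep(0, n - 1)) else initial$p
    q <- if (is.null(initial)) rep(0, n) else initial$q
  }
  if (n_steps == 0)
    return(list(p = p, q = q, growth = numeric(0),
                trajectory = matrix(numeric(0), 0, 2,
                                    dimnames = list(NULL, c("growth", "q")))))
  eh <- exp(-par$h)
  growth <- numeric(n_steps)
  traj <- matrix(0, n_steps, 2, dimnames = list(NULL, c("growth", "q")))
  for (s in seq_len(n_steps)) {
    wp <- as.numeric(Kw %*% (r1 * p))
    p_new <- eh * wp
    q_new <- (1 - eh) * wp + as.numeric(Km %*% (r2 * q))
    tot <- sum(p_new) + sum(q_new)
    growth[s] <- tot
    p <- p_new / tot; q <- q_new / tot
    traj[s, ] <- c(tot, sum(q))
  }
  list(p = p, q = q, growth = growth, trajectory = traj)
}

# pairwise Hamming distances between all 2^L binary sequences
hamming_matrix <- function(L) {
  n <- 2^L
  pc <- integer(n)
  if (n > 1) for (i in 1:(n - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
  idx <- 0:(n - 1)
  X <- outer(idx, idx, bitwXor)
  matrix(pc[X + 1L], n, n)
}

#' Transfer matrix of the class-reduced discrete Eigen model
#'
#' The block lower-triangular one-generation transfer matrix whose dominant
#' eigenvalue is the steady growth factor of [eigen_discrete_iterate()].
#'
#' @inheritParams eigen_discrete_iterate
#' @return Dense matrix of dimension `2(L+1)`.
#' @export
eigen_transfer_matrix <- function(par, landscape = NULL) {
  L <- par$L
  x <- 1 - 2 * (0:L) / L
  if (is.null(landscape)) {
    r1 <- c(par$A, rep(1, L)); r2 <- r1
  } else {
    r1 <- landscape$f(x); r2 <- landscape$g(x)
  }
  Kw <- eigen_class_kernel(L, par$w)
  Km <- eigen_class_kernel(L, exp(-par$mu * par$gamma / L))
  eh <- exp(-par$h)
  n <- L + 1L
  rbind(cbind(eh * Kw %*% diag(r1), matrix(0, n, n)),
        cbind((1 - eh) * Kw %*% diag(r1), Km %*% diag(r2)))
}

#' Effective single peak of a log-normal random fitness landscape
#'
#' For Wrightian fitnesses drawn log-normally (`log r ~ N(0, sdlog^2)`, so
#' the bulk of sequence space has fitness about 1), the largest of the `2^L`
#' draws concentrates at `A_max = exp(sdlog * sqrt(2 L log 2))`.  The random
#' landscape then behaves like a single-peak landscape of height `A_max`,
#' and the mutator fraction follows from [eigen_single_peak_q()].
#'
#' @param par An [eigen_params()] object (its `A` is ignored).
#' @param sdlog Standard deviation of log fitness, `> 0`.
#' @param meanlog Mean of log fitness (default 0).
#' @return List with `A_max`, `q_estimate` (NA outside the mixed phase), and
#'   the [eigen_params()] used.
#' @export
lognormal_effective_peak <- function(par, sdlog, meanlog = 0) {
  if (sdlog <= 0) stop("'sdlog' must be positive")
  A_max <- exp(meanlog + sdlog * sqrt(2 * par$L * log(2)))
  par2 <- eigen_params(L = par$L, w = par$w, mu = par$mu, h = par$h, A = A_max)
  qe <- tryCatch(eigen_single_peak_q(par2)$q, error = function(e) NA_real_)
  list(A_max = A_max, q_estimate = qe, params = par2)
}

#' Map Crow-Kimura parameters to the discrete-time Eigen model
#'
#' Identifies one Crow-Kimura generation of duration `tau` with one
#' discrete Eigen generation: selection coefficient `S = tau * J` (so peak
#' Wrightian fitness `A = 1 + tau * J`), mutation parameter
#' `gamma = tau * mu1`, mutator ratio `mu = mu2 / mu1`, and switch
#' `h = tau * alpha1`.  `eigen_ck_map()` inverts the map; the round trip is
#' the identity.
#'
#' @param ck List with fields `J` (peak Malthusian fitness), `mu1`, `mu2`,
#'   `a` (forward switch rate), and `L`.
#' @param tau Generation time, `> 0`.
#' @return An [eigen_params()] object (for `ck_eigen_map`) or the parameter
#'   list (for `eigen_ck_map`).
#' @export
ck_eigen_map <- function(ck, tau) {
  if (tau <= 0) stop("'tau' must be positive")
  eigen_params(L = ck$L, gamma = tau * ck$mu1, mu = ck$mu2 / ck$mu1,
               h = tau * ck$a, A = 1 + tau * ck$J)
}

#' @rdname ck_eigen_map
#' @param par An [eigen_params()] object produced by `ck_eigen_map()`.
#' @export
eigen_ck_map <- function(par, tau) {
  if (tau <= 0) stop("'tau' must be positive")
  mu1 <- par$gamma / tau
  list(J = (par$A - 1) / tau, mu1 = mu1, mu2 = par$mu * mu1,
       a = par$h / tau, L = par$L)
}
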