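#' Closed-form solution of the single-peak mutator model
#'
#' For the single-peak landscape (`f(1) = g(1) = J`, zero elsewhere) with
#' uni-directional switching (`alpha1 = a`, `alpha2 = 0`) the infinite-genome
#' steady state is fully explicit.  The three candidate mean fitnesses are
#' \deqn{R_{mix} = J - \mu_1 - a, \quad R_{mu} = J - \mu_2, \quad R_{ns} = 0,}
#' and the realised phase is the argmax, with borders `a = J - mu1`
#' (mixed/non-selective), `mu2 = J` (mutator/non-selective) and
#' `mu1 + a = mu2` (mixed/mutator).  In the mixed phase the wild-type class
#' distribution is geometric, `P_l = P_0 (mu1/J)^l`, the peak balance gives
#' `P_0 + Q_0 = (J - mu1 - a)/J` and `Q_0 = a P_0 / (mu2 - mu1 - a)`, so the
#' wild-allele fraction has the closed form
#' \deqn{1 - q = \frac{(J - \mu_1 - a)(\mu_2 - \mu_1 - a)}
#'   {(J - \mu_1)(\mu_2 - \mu_1)}.}
#' Unlike smooth landscapes, this fraction stays finite as `L` grows.
#'
#' Parameters lying exactly on a border (within 1e-12 relative) are reported
#' as the border itself, not as either adjacent phase.
#'
#' @param J Peak fitness, `> 0`.
#' @param a Forward switch rate `alpha1`.
#' @param mu Mutator-type mutation rate `mu2`.
#' @param mu1 Wild-type mutation rate (default 1).
#' @return Object of class `"phase_result"`: list with `phase` (one of
#'   `"mixed"`, `"mutator"`, `"non_selective"`, or `"border"` with the
#'   border named in `border`), `R`, `s`, `q`, `one_minus_q`, `P0`, `Q0`,
#'   and `method`.
#' @examples
#' single_peak_solution(J = 1.05, a = 0.001, mu = 10)
#' @export
single_peak_solution <- function(J, a, mu, mu1 = 1) {
  if (J <= 0) stop("'J' must be positive")
  R_mix <- J - mu1 - a
  R_mu  <- J - mu
  R_ns  <- 0
  eps <- 1e-12 * (1 + abs(J) + mu)
  borders <- c(
    mixed_non_selective   = abs(a - (J - mu1)),
    mutator_non_selective = abs(mu - J),
    mixed_mutator         = abs(mu1 + a - mu))
  # a border is only reported when the two phases it separates are the top two
  cand <- c(mixed = R_mix, mutator = R_mu, non_selective = R_ns)
  ord <- order(cand, decreasing = TRUE)
  top2 <- names(cand)[ord[1:2]]
  on_border <- (all(c("mixed", "non_selective") %in% top2) && borders[1] < eps) ||
               (all(c("mutator", "non_selective") %in% top2) && borders[2] < eps) ||
               (all(c("mixed", "mutator") %in% top2) && borders[3] < eps)
  if (on_border) {
    which_b <- names(borders)[which.min(borders)]
    return(structure(list(phase = "border", border = which_b,
                          R = max(cand), s = NA_real_, q = NA_real_,
                          one_minus_q = NA_real_, P0 = NA_real_, Q0 = NA_real_,
                          method = "single-peak closed form"),
                     class = "phase_result"))
  }
  phase <- names(cand)[ord[1]]
  if (phase == "mixed") {
    P0 <- (J - mu1 - a) * (mu - mu1 - a) / (J * (mu - mu1))
    Q0 <- a * P0 / (mu - mu1 - a)
    one_minus_q <- P0 * J / (J - mu1)
    out <- list(phase = "mixed", border = NA_character_, R = R_mix, s = 1,
                q = 1 - one_minus_q, one_minus_q = one_minus_q,
                P0 = P0, Q0 = Q0, method = "single-peak closed form")
  } else if (phase == "mutator") {
    out <- list(phase = "mutator", border = NA_character_, R = R_mu, s = 1,
                q = 1, one_minus_q = 0, P0 = 0,
                Q0 = (J - mu) / J,  # classic single-peak master fraction
                method = "single-peak closed form")
  } else {
    out <- list(phase = "non_selective", border = NA_character_, R = 0, s = 0,
                q = if (a > 0) 1 else NA_real_,
                one_minus_q = if (a > 0) 0 else NA_real_,
                P0 = NA_real_, Q0 = NA_real_,
                method = "single-peak closed form")
  }
  structure(out, class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  if (identical(x$phase, "border"))
    cat(sprintf("on the %s phase border (R = %.6g)\n", x$border, x$R))
  else
    cat(sprintf("phase: %s  R = %.6g  s = %s  q = %s\n", x$phase, x$R,
                format(x$s, digits = 6), format(x$q, digits = 6)))
  invisible(x)
}

#' Phase classification of a parameter point
#'
#' With uni-directional switching (`alpha2 = 0`) the model has the three-way
#' phase structure: single-peak landscapes delegate to
#' [single_peak_solution()]; smooth landscapes compare
#' [mixed_phase_fitness()] against [mutator_phase_fitness()] (linear
#' landscapes have no non-selective phase).  For `alpha2 > 0` the
#' classification reports the coupled-model mean fitness of
#' [mean_fitness_general()] with surplus and mutator fraction from
#' [surplus_and_ratio()]; `s = 0` marks the non-selective regime.
#'
#' @inheritParams potential
#' @return A `"phase_result"` (see [single_peak_solution()]).
#' @export
classify_phase <- function(params, landscape) {
  if (params$alpha2 > 0) {
    R <- mean_fitness_general(params, landscape)
    sr <- tryCatch(surplus_and_ratio(params, landscape, R),
                   error = function(e) NULL)
    s <- if (is.null(sr)) NA_real_ else sr$s
    q <- if (is.null(sr)) NA_real_ else sr$q
    phase <- if (!is.na(s) && abs(s) < 1e-9) "non_selective" else "mixed"
    return(structure(list(phase = phase, border = NA_character_,
                          R = as.numeric(R), s = s, q = q,
                          one_minus_q = 1 - q, P0 = NA_real_, Q0 = NA_real_,
                          method = "potential maximisation + stationarity"),
                     class = "phase_result"))
  }
  if (landscape$kind == "single_peak")
    return(single_peak_solution(J = landscape$params$J, a = params$alpha1,
                                mu = params$mu2, mu1 = params$mu1))
  R_mix <- as.numeric(mixed_phase_fitness(params, landscape))
  R_mu  <- as.numeric(mutator_phase_fitness(params, landscape))
  eps <- 1e-12 * (1 + abs(R_mix) + abs(R_mu))
  if (abs(R_mix - R_mu) < eps)
    return(structure(list(phase = "border", border = "mixed_mutator",
                          R = R_mix, s = NA_real_, q = NA_real_,
                          one_minus_q = NA_real_, P0 = NA_real_,
                          Q0 = NA_real_, method = "branch comparison"),
                     class = "phase_result"))
  if (R_mix > R_mu) {
    s <- surplus_from_R(R_mix, landscape$f)          # f(s) = R at the peak
    structure(list(phase = "mixed", border = NA_character_, R = R_mix,
                   s = s, q = NA_real_, one_minus_q = NA_real_,
                   P0 = NA_real_, Q0 = NA_real_,
                   method = "branch comparison (q is L-dependent; see wkb_mutator_fraction)"),
              class = "phase_result")
  } else {
    s <- surplus_from_R(R_mu, landscape$g)
    structure(list(phase = "mutator", border = NA_character_, R = R_mu,
                   s = s, q = 1, one_minus_q = 0,
                   P0 = NA_real_, Q0 = NA_real_, method = "branch comparison"),
              class = "phase_result")
  }
}

# surplus of a selective phase: the distribution peaks where its chain's
# momentum vanishes, i.e. fitness(s) = R; ties toward larger x
surplus_from_R <- function(R, fn) {
  h <- function(x) fn(x) - R
  xg <- seq(-1, 1, length.out = 2001)
  hv <- h(xg)
  sgn <- sign(hv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  if (!length(flips)) return(NA_real_)
  max(vapply(flips, function(i)
    stats::uniroot(h, c(xg[i], xg[i + 1]), tol = 1e-13)$root, numeric(1)))
}

#' Critical slope of the linear-fitness phase border
#'
#' For linear fitness `f(x) = g(x) = k x` with `alpha2 = 0` the mixed and
#' mutator phases exchange stability at the slope `k_c` solving
#' \deqn{\sqrt{k^2+\mu_1^2} - \mu_1 - \alpha_1 = \sqrt{k^2+\mu_2^2} - \mu_2,}
#' found here by bracketed bisection to 1e-10.
#'
#' @param mu1,mu2,a Model rates (`a = alpha1`).
#' @param interval Search bracket for `k`.
#' @return The critical slope `k_c`.
#' @examples
#' critical_slope(mu1 = 1, mu2 = 10, a = 0.02)  # about 0.212
#' @export
critical_slope <- function(mu1 = 1, mu2, a, interval = c(1e-8, 100)) {
  h <- function(k) (sqrt(k^2 + mu1^2) - mu1 - a) - (sqrt(k^2 + mu2^2) - mu2)
  stats::uniroot(h, interval, tol = 1e-10)$root
}

#' Phase diagram of the single-peak mutator model
#'
#' Evaluates [single_peak_solution()] on a grid of forward switch rates `a`
#' and mutator mutation rates `mu` at fixed peak height `J`, for plotting or
#' TSV export.  The three regions meet along `a = J - mu1`, `mu = J` and
#' `mu1 + a = mu`.
#'
#' @param J Peak fitness.
#' @param a_grid,mu_grid Numeric grids.
#' @param mu1 Wild-type rate (default 1).
#' @return `data.frame` with columns `a`, `mu`, `phase`, `R`, `s`, `q`.
#' @export
phase_diagram <- function(J, a_grid, mu_grid, mu1 = 1) {
  g <- expand.grid(a = a_grid, mu = mu_grid)
  res <- lapply(seq_len(nrow(g)), function(i)
    single_peak_solution(J, g$a[i], g$mu[i], mu1))
  data.frame(
    a = g$a, mu = g$mu,
    phase = vapply(res, function(r) r$phase, character(1)),
    R = vapply(res, function(r) r$R, numeric(1)),
    s = vapply(res, function(r) r$s, numeric(1)),
    q = vapply(res, function(r) r$q, numeric(1)))
}
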