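test_that("potential branches match a direct 2x2 eigenvalue oracle", {
  draws <- withr::with_seed(42, replicate(25, list(
    x = stats::runif(1, -0.99, 0.99),
    mu1 = stats::runif(1, 0, 2), mu2 = stats::runif(1, 0, 5),
    a1 = stats::runif(1, 0, 2), a2 = stats::runif(1, 0, 2)),
    simplify = FALSE))
  ls <- make_landscape("quadratic", c = 3)
  for (d in draws) {
    p <- mutator_params(10, d$mu1, d$mu2, d$a1, d$a2)
    pc <- potential(p, ls, x = d$x)
    c1 <- sqrt(1 - d$x^2)
    A <- matrix(c(ls$f(d$x) - d$mu1 * (1 - c1) - d$a1, d$a1,
                  d$a2, ls$g(d$x) - d$mu2 * (1 - c1) - d$a2), 2, 2)
    ev <- sort(eigen(A, only.values = TRUE)$values, decreasing = TRUE)
    expect_lt(abs(pc$V_plus - ev[1]), 1e-14 * (1 + abs(ev[1])))
    expect_lt(abs(pc$V_minus - ev[2]), 1e-14 * (1 + abs(ev[2])))
    expect_gte(pc$V_plus, pc$V_minus)
  }
})

test_that("the top branch is switch-rate independent in the fully symmetric case", {
  ls <- make_landscape("quadratic", c = 3)
  x <- seq(-0.99, 0.99, length.out = 51)
  for (alpha in c(0.1, 1, 4)) {
    p <- mutator_params(10, 1.2, 1.2, alpha, alpha)
    pc <- potential(p, ls, x)
    expect_equal(pc$V_plus, ls$f(x) - 1.2 * (1 - sqrt(1 - x^2)),
                 tolerance = 1e-12)
    expect_equal(pc$V_plus - pc$V_minus, rep(2 * alpha, length(x)),
                 tolerance = 1e-12)
  }
})

test_that("analytic mean fitness reproduces closed forms", {
  ls <- make_landscape("quadratic", c = 3)
  # symmetric case: max_x [3x^2/2 - (1 - sqrt(1-x^2))] = 2/3 at x = sqrt(8)/3
  p <- mutator_params(10, 1, 1, 1, 1)
  R <- mean_fitness_general(p, ls)
  expect_equal(as.numeric(R), 2 / 3, tolerance = 1e-10)
  expect_equal(attr(R, "argmax"), sqrt(8) / 3, tolerance = 1e-6)
  # uni-directional linear fitness: sqrt(2) - 1 - a
  pl <- mutator_params(10, 1, 10, 0.3, 0)
  expect_equal(as.numeric(mean_fitness_general(pl, make_landscape("linear", k = 1))),
               sqrt(2) - 1 - 0.3, tolerance = 1e-10)
})

test_that("phase-wise fitness expressions and their small-switch limit agree", {
  ls <- make_landscape("quadratic", c = 3)
  p <- mutator_params(10, 1, 3, 1e-9, 1e-9)
  # with vanishing switching the coupled maximum equals the dominant branch
  pfix <- mutator_params(10, 1, 3, 1e-9, 0)
  expect_equal(as.numeric(mean_fitness_general(p, ls)),
               max(as.numeric(mixed_phase_fitness(pfix, ls)),
                   as.numeric(mutator_phase_fitness(pfix, ls))),
               tolerance = 1e-8)
  # flat landscape: zero
  expect_equal(as.numeric(mixed_phase_fitness(
    mutator_params(10, 0, 1, 0, 0), make_landscape("linear", k = 0))), 0)
  # mutator phase closed form for linear fitness
  pm <- mutator_params(10, 1, 10, 0.1, 0)
  expect_equal(as.numeric(mutator_phase_fitness(pm, make_landscape("linear", k = 1))),
               sqrt(101) - 10, tolerance = 1e-10)
  # mu2 = 0: maximum of g
  expect_equal(as.numeric(mutator_phase_fitness(
    mutator_params(10, 1, 0, 0.1, 0), ls)), 1.5, tolerance = 1e-10)
})

test_that("the mixed/mutator border slope matches its defining equation", {
  kc <- critical_slope(mu1 = 1, mu2 = 10, a = 0.02)
  expect_equal(kc, 0.212, tolerance = 0.001 / 0.212)
  # border consistency: the two phase fitnesses cross at k_c
  lsc <- make_landscape("linear", k = kc)
  p <- mutator_params(10, 1, 10, 0.02, 0)
  expect_lt(abs(as.numeric(mixed_phase_fitness(p, lsc)) -
                as.numeric(mutator_phase_fitness(p, lsc))), 1e-9)
})

test_that("surplus and component ratio solve the stationary system", {
  # f = g: the admissible root gives f(s) = R and q = a1 / (a1 + a2)
  ls <- make_landscape("linear", k = 1)
  p <- mutator_params(800, 1, 1, 1, 1)
  sr <- surplus_and_ratio(p, ls)
  expect_equal(sr$q, 0.5, tolerance = 1e-12)
  expect_equal(ls$f(sr$s), sr$R, tolerance = 1e-9)
  # eigenvector oracle: surplus and mutator fraction at large L
  ss <- steady_state(p, ls)
  expect_equal(sr$s, ss$observables$s, tolerance = 1e-6)
  expect_equal(sr$q, ss$observables$q, tolerance = 1e-6)
  # asymmetric switch rates, unequal mutation rates
  p2 <- mutator_params(400, 1, 3.5, 2, 0.5)
  sr2 <- surplus_and_ratio(p2, make_landscape("quadratic", c = 3))
  expect_equal(sr2$q, 2 / 2.5, tolerance = 1e-12)
  ss2 <- steady_state(p2, make_landscape("quadratic", c = 3))
  expect_equal(sr2$q, ss2$observables$q, tolerance = 2e-3)
  expect_error(surplus_and_ratio(mutator_params(10, 1, 2, 1, 0), ls),
               "alpha1 \\* alpha2")
})

test_that("the single-peak closed forms give phases, borders and q", {
  r <- single_peak_solution(J = 1.05, a = 0.001, mu = 10)
  expect_equal(r$phase, "mixed")
  expect_equal(r$R, 0.049)
  expect_equal(r$one_minus_q, 0.049 * 8.999 / (0.05 * 9), tolerance = 1e-12)
  # non-selective: both selective fitnesses non-positive
  rns <- single_peak_solution(J = 1, a = 0.5, mu = 2)
  expect_equal(rns$phase, "non_selective")
  expect_equal(rns$R, 0); expect_equal(rns$s, 0)
  # mutator phase
  rmu <- single_peak_solution(J = 3, a = 1.5, mu = 1.8)
  expect_equal(rmu$phase, "mutator")
  expect_equal(rmu$R, 3 - 1.8); expect_equal(rmu$q, 1)
  # exact borders are reported as borders, not phases
  rb <- single_peak_solution(J = 3, a = 0.8, mu = 1.8)   # a + mu1 = mu
  expect_equal(rb$phase, "border")
  expect_equal(rb$border, "mixed_mutator")
  rb2 <- single_peak_solution(J = 1.4, a = 0.4, mu = 3)  # a = J - 1, mu > J
  expect_equal(rb2$phase, "border")
  expect_equal(rb2$border, "mixed_non_selective")
})

test_that("the infinite-genome single-peak q matches finite-L numerics", {
  sol <- single_peak_solution(J = 1.05, a = 0.001, mu = 10)
  L <- 3000
  ss <- steady_state(mutator_params(L, 1, 10, 0.001, 0),
                     make_landscape("single_peak", J = 1.05))
  expect_equal(ss$observables$q, sol$q, tolerance = 1e-2)
  # and the deviation shrinks roughly like 1/L
  ss2 <- steady_state(mutator_params(L / 2, 1, 10, 0.001, 0),
                      make_landscape("single_peak", J = 1.05))
  expect_lt(abs(ss$observables$q - sol$q), abs(ss2$observables$q - sol$q))
})

test_that("classify_phase delegates, labels and detects borders", {
  sp <- make_landscape("single_peak", J = 1.05)
  p <- mutator_params(100, 1, 10, 0.001, 0)
  expect_equal(classify_phase(p, sp), single_peak_solution(1.05, 0.001, 10))
  # linear fitness across the critical slope
  kc <- critical_slope(1, 10, 0.02)
  p2 <- mutator_params(100, 1, 10, 0.02, 0)
  expect_equal(classify_phase(p2, make_landscape("linear", k = kc + 0.05))$phase,
               "mixed")
  expect_equal(classify_phase(p2, make_landscape("linear", k = kc - 0.05))$phase,
               "mutator")
  # coupled case: reports the potential maximum and the stationarity q
  p3 <- mutator_params(100, 1, 3.5, 1, 1)
  r3 <- classify_phase(p3, make_landscape("quadratic", c = 3))
  expect_equal(r3$R, 0.1811, tolerance = 1e-3)
  expect_equal(r3$q, 0.5, tolerance = 1e-10)
})

test_that("the single-peak phase diagram has the three-region topology", {
  pd <- phase_diagram(J = 2, a_grid = seq(0.05, 1.9, by = 0.12),
                      mu_grid = seq(1.1, 3.4, by = 0.13))
  expect_setequal(unique(pd$phase), c("mixed", "mutator", "non_selective"))
  # representative points of each region: the mutator allele wins when its
  # rate is below the effective wild rate (mu < mu1 + a), selection is lost
  # when neither selective value is positive (a > J - 1 and mu > J)
  at <- function(a, mu) pd$phase[which.min((pd$a - a)^2 + (pd$mu - mu)^2)]
  expect_equal(at(0.1, 1.5), "mixed")
  expect_equal(at(0.5, 1.2), "mutator")
  expect_equal(at(1.6, 2.9), "non_selective")
  # non-selective region has zero surplus throughout
  expect_true(all(pd$s[pd$phase == "non_selective"] == 0))
  # region adjacency across the analytic borders: crossing mu = 1 + a flips
  # mutator <-> mixed; crossing mu = J at large a flips mutator <-> ns
  expect_equal(at(0.5, 1.8), "mixed")
  expect_equal(at(1.6, 1.9), "mutator")
})

test_that("the d-dimensional potential reduces, separates, and respects lethality", {
  f1 <- function(x) 1.5 * x^2
  one <- multidim_potential(list(list(y = 1, f = f1, g = f1, mu = 1, nu = 3.5)),
                            alpha1 = 1, alpha2 = 1)
  p <- mutator_params(10, 1, 3.5, 1, 1)
  expect_equal(one$R, as.numeric(mean_fitness_general(p, make_landscape("quadratic", c = 3))),
               tolerance = 1e-8)
  # two identical half-genomes with halved rates reproduce the 1-D value
  fh <- function(x) 0.75 * x^2
  two <- multidim_potential(rep(list(list(y = 0.5, f = fh, g = fh,
                                          mu = 0.5, nu = 1.75)), 2),
                            alpha1 = 1, alpha2 = 1)
  expect_equal(two$R, one$R, tolerance = 1e-8)
  # lethal first part confines the maximiser to x_1 = 1
  leth <- function(x) ifelse(x == 1, 0, -Inf)
  k2 <- function(x) 0.5 * (1 - x)
  m <- multidim_potential(list(
    list(y = 0.5, f = leth, g = leth, mu = 0.2, nu = 0.6),
    list(y = 0.5, f = k2, g = k2, mu = 0.5, nu = 1.5)),
    alpha1 = 0.05, alpha2 = 0)
  expect_equal(m$argmax[1], 1, tolerance = 1e-8)
  expect_error(multidim_potential(list(), 1, 1))
})

test_that("the WKB wild-allele fraction matches its oracles", {
  # no forward switching: the wild type keeps everything
  p0 <- mutator_params(1000, 1, 10, 0, 0)
  lsl <- make_landscape("linear", k = 1)
  expect_equal(wkb_mutator_fraction(p0, lsl)$one_minus_q, 1)
  # strong-sweep regime: agreement with the refined eigenvector within
  # half an order of magnitude (the exponent is exact, the prefactor O(1))
  p <- mutator_params(1000, 1, 10, 0.3, 0)
  wk <- wkb_mutator_fraction(p, lsl)
  ss <- steady_state(p, lsl)
  expect_lt(abs(log10(wk$one_minus_q) - log10(1 - ss$observables$q)), 0.5)
  expect_true(wk$validity)
  expect_true(wk$s2 < wk$s3 && wk$s1 < wk$s3)
  # the full exponent collapses onto the small-a closed form
  ps <- mutator_params(1000, 1, 10, 1e-3, 0)
  lk <- make_landscape("linear", k = 0.3)
  wks <- wkb_mutator_fraction(ps, lk)
  sa <- small_a_asymptotics(k = 0.3, a = 1e-3, mu = 10, L = 1000)
  expect_equal(wks$K, sa$K, tolerance = 1e-4)
  expect_error(wkb_mutator_fraction(mutator_params(10, 1, 10, 0.1, 0.1), lsl),
               "alpha2")
})

test_that("small-switch asymptotics track the finite-L mutator fraction", {
  # linear-response regime: q proportional to a, within a factor two
  ss <- steady_state(mutator_params(1000, 1, 10, 1e-4, 0),
                     make_landscape("linear", k = 0.3))
  sa <- small_a_asymptotics(k = 0.3, a = 1e-4, mu = 10, L = 1000)
  expect_true(sa$validity)
  expect_lt(sa$exponent, 1)          # below the crossover length
  expect_gt(sa$crossover_L, 1000)
  q_num <- ss$observables$q
  expect_lt(abs(log(( 1 - sa$one_minus_q) / q_num)), log(2))
  # q grows monotonically with genome length toward the mutator sweep
  lsf <- make_landscape("linear", k = 1)
  qL <- vapply(c(50, 100, 200, 400, 800, 1600), function(L)
    steady_state(mutator_params(L, 1, 10, 0.05, 0), lsf)$observables$q,
    numeric(1))
  expect_true(all(diff(qL) > 0))
})
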