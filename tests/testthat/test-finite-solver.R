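test_that("the operator decouples into identical classical blocks without switching", {
  L <- 12
  ls <- make_landscape("quadratic", c = 3)
  p <- mutator_params(L, mu1 = 1.3, mu2 = 1.3, alpha1 = 0, alpha2 = 0)
  M <- as.matrix(build_operator(p, ls))
  n <- L + 1
  A <- M[1:n, 1:n]; B <- M[(n + 1):(2 * n), (n + 1):(2 * n)]
  expect_equal(A, B)
  expect_true(all(M[1:n, (n + 1):(2 * n)] == 0))
  expect_true(all(M[(n + 1):(2 * n), 1:n] == 0))
  # classical tridiagonal structure with the combinatorial coefficients
  l <- 0:(L - 1)
  expect_equal(A[cbind(l + 2, l + 1)], 1.3 / L * (L - l))    # outflow up
  expect_equal(A[cbind(l + 1, l + 2)], 1.3 / L * (l + 1))    # outflow down
})

test_that("the class operator is the exact projection of the sequence-space generator", {
  p <- mutator_params(4, mu1 = 0.8, mu2 = 2.1, alpha1 = 0.4, alpha2 = 0.15)
  ls <- rand_tabulated(4, seed = 21)
  Mred <- as.matrix(build_operator(p, ls))
  Mproj <- project_sequence_operator(p, ls)
  expect_lt(max(abs(Mred - Mproj)), 1e-12)
})

test_that("a single-peak landscape puts exactly one nonzero fitness entry per block", {
  L <- 400
  p <- mutator_params(L, 1, 10, 0.001, 0)
  ls <- make_landscape("single_peak", J = 1.05)
  g <- landscape_grid(ls, L)
  expect_equal(sum(g$f != 0), 1)
  expect_equal(which(g$f != 0), 1)  # class l = 0
})

test_that("steady_state matches the exact linear-fitness eigenvalue and surplus", {
  # closed forms: R = sqrt(k^2 + mu1^2) - mu1 - alpha1 (no finite-L
  # correction), wild-chain surplus s1 = (R + alpha1) / k exactly
  for (cfg in list(c(L = 200, k = 1, a = 0), c(L = 350, k = 0.3, a = 0.01))) {
    p <- mutator_params(cfg["L"], 1, 10, cfg["a"], 0)
    ls <- make_landscape("linear", k = cfg[["k"]])
    ss <- steady_state(p, ls)
    R_exact <- sqrt(cfg[["k"]]^2 + 1) - 1 - cfg[["a"]]
    expect_equal(ss$R_numeric, R_exact, tolerance = 1e-12)
    expect_lt(ss$residual, 1e-10 * (1 + abs(ss$R_numeric)))
    # Rayleigh consistency of Eq.-(4) observables with the eigenvalue
    expect_equal(ss$observables$R, ss$R_numeric, tolerance = 1e-10)
    expect_equal(ss$observables$s1, (R_exact + cfg[["a"]]) / cfg[["k"]],
                 tolerance = 1e-10)
  }
})

test_that("brute-force sequence space and the Hamming-class reduction agree", {
  cases <- list(
    list(L = 5, seed = 1, uni = FALSE), list(L = 6, seed = 2, uni = TRUE),
    list(L = 7, seed = 3, uni = FALSE), list(L = 8, seed = 4, uni = TRUE),
    list(L = 8, seed = 5, uni = FALSE), list(L = 6, seed = 6, uni = FALSE))
  for (cs in cases) {
    p <- rand_params(cs$L, cs$seed, uni = cs$uni)
    ls <- rand_tabulated(cs$L, cs$seed + 100)
    bf <- brute_force_sequence_model(p, ls)
    ss <- steady_state(p, ls)
    expect_lt(abs(bf$R - ss$R_numeric), 1e-10)
    expect_lt(max(abs(bf$state$P - ss$state$P)), 1e-9)
    expect_lt(max(abs(bf$state$Q - ss$state$Q)), 1e-9)
  }
  # decoupled switching reduces to the classical single-type model
  p0 <- mutator_params(6, 1, 2.5, 0, 0)
  ls0 <- rand_tabulated(6, seed = 9)
  bf0 <- brute_force_sequence_model(p0, ls0)
  one <- steady_state(mutator_params(6, 1, 1, 0, 0), ls0)  # wild chain alone
  expect_equal(bf0$R, max(one$R_numeric,
                          steady_state(mutator_params(6, 2.5, 2.5, 0, 0),
                                       make_landscape("tabulated",
                                                      values = ls0$params$values,
                                                      L = 6))$R_numeric),
               tolerance = 1e-10)
  expect_error(brute_force_sequence_model(mutator_params(14, 1, 2, 0, 0), ls0),
               "L <= 12")
})

test_that("the surplus identity s = (1-q) s1 + q s2 holds at every steady state", {
  for (seed in 1:4) {
    p <- rand_params(30, seed)
    ls <- rand_tabulated(30, seed + 50)
    ob <- steady_state(p, ls)$observables
    expect_equal(ob$s, (1 - ob$q) * ob$s1 + ob$q * ob$s2, tolerance = 1e-10)
  }
})

test_that("mean fitness is non-increasing in the mutator mutation rate", {
  ls <- make_landscape("quadratic", c = 3)
  R <- vapply(c(0.5, 1, 2, 3.5), function(mu)
    steady_state(mutator_params(60, 1, mu, 1, 1), ls)$R_numeric, numeric(1))
  expect_true(all(diff(R) < 0))
})

test_that("with no switching the eigenvalue converges to the classical large-L value", {
  # max_x [3x^2/2 - (1 - sqrt(1-x^2))] = 2/3
  ls <- make_landscape("quadratic", c = 3)
  R <- vapply(c(100, 400, 1600), function(L)
    steady_state(mutator_params(L, 1, 1, 0, 0), ls)$R_numeric, numeric(1))
  err <- abs(R - 2 / 3)
  expect_true(all(diff(err) < 0))   # monotone approach in L
  expect_lt(err[3], 5e-3)
})

test_that("nonlinear integration conserves probability and reaches the eigenpair", {
  p <- mutator_params(30, 1, 2, 1, 1)
  ls <- make_landscape("quadratic", c = 3)
  # t_end = 0 returns the initial state unchanged
  init <- population_state(c(1, rep(0, 30)), rep(0, 31))
  tr0 <- integrate_nonlinear(p, ls, init, t_end = 0)
  expect_identical(tr0$states[[1]]$P, init$P)
  tr <- integrate_nonlinear(p, ls, t_end = 200, n_out = 41)
  expect_lt(tr$drift, 1e-9)
  ss <- steady_state(p, ls)
  expect_equal(tr$R[length(tr$R)], ss$R_numeric, tolerance = 1e-6)
  # the long-time observables match the eigenvector's
  ob <- observables(tr$states[[41]], ls)
  expect_equal(ob$q, ss$observables$q, tolerance = 1e-6)
})

test_that("the generating-function solution is exact and matches the eigenvector", {
  p <- mutator_params(1000, 1, 10, 0.01, 0)
  ls <- make_landscape("linear", k = 0.3)
  gf <- generation_function_solve(p, ls)
  expect_equal(gf$R, sqrt(1.09) - 1 - 0.01, tolerance = 1e-14)
  ss <- steady_state(p, ls)
  keep <- ss$state$P > 1e-12 * max(ss$state$P)
  expect_lt(max(abs(gf$state$P[keep] / ss$state$P[keep] - 1)), 1e-6)
  keepQ <- ss$state$Q > 1e-12 * max(ss$state$Q)
  expect_lt(max(abs(gf$state$Q[keepQ] / ss$state$Q[keepQ] - 1)), 1e-6)
  # no switching: classical single-chain solution, Q stays empty
  gf0 <- generation_function_solve(mutator_params(100, 1, 10, 0, 0), ls)
  expect_equal(gf0$R, sqrt(1.09) - 1, tolerance = 1e-14)
  expect_equal(sum(gf0$state$Q), 0)
  expect_error(generation_function_solve(p, make_landscape("quadratic", c = 1)),
               "linear")
})

test_that("observables handle concentrated, uniform, and empty sub-populations", {
  ls <- make_landscape("linear", k = 1)
  L <- 10
  st <- population_state(c(1, rep(0, L)), rep(0, L + 1))
  ob <- observables(st, ls)
  expect_equal(ob$s, 1); expect_equal(ob$s1, 1); expect_equal(ob$q, 0)
  expect_true(is.na(ob$s2))    # absent, not zero
  st2 <- population_state(rep(0, L + 1), rep(1, L + 1))
  ob2 <- observables(st2, ls)
  expect_equal(ob2$s2, 0)      # uniform over classes
  expect_equal(ob2$q, 1)
  expect_true(is.na(ob2$s1))
})
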