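# Internal numerics: sparse Hamming-chain operators, symmetrisation, and
# dominant-eigenpair extraction.
#
# The two-chain operator is a Metzler matrix (non-negative off-diagonal), so
# after a diagonal shift Perron-Frobenius applies: the rightmost eigenvalue
# is real with a sign-constant eigenvector.  Each birth-death chain is
# similar to a symmetric tridiagonal matrix under the diagonal scaling
# d_l = sqrt(choose(L, l)); the scaling is the same for both chains because
# the hop-rate ratio (L - l)/(l + 1) does not involve mu.  With both switch
# rates positive, additionally scaling the mutator chain by
# sqrt(alpha1/alpha2) renders the full operator symmetric, so the dominant
# eigenvalue can be located exactly by bisection on positive-definiteness of
# (sigma I - S).  The eigenvector is then recovered by inverse iteration on
# the *original* operator: (sigma I - M) is an M-matrix for sigma above the
# Perron root, whose LU solve involves no cancellation, so even components
# ~1e-7 of the norm come out with full relative accuracy.

# single Hamming chain, original (nonsymmetric) coordinates
chain_matrix <- function(L, mu, fx, outflow = 0) {
  l <- 0:L
  Matrix::bandSparse(
    L + 1L, k = c(-1L, 0L, 1L),
    diagonals = list((mu / L) * (L - l[-1] + 1),   # inflow l-1 -> l
                     fx - mu - outflow,
                     (mu / L) * (l[-(L + 1L)] + 1)) # inflow l+1 -> l
  )
}

# symmetrised single chain: diag d, off-diagonal e
chain_sym <- function(L, mu, fx, outflow = 0) {
  l <- 0:(L - 1)
  list(d = fx - mu - outflow,
       e = (mu / L) * sqrt((l + 1) * (L - l)))
}

sym_tridiag_sparse <- function(d, e) {
  Matrix::bandSparse(length(d), k = c(0L, 1L),
                     diagonals = list(d, e), symmetric = TRUE)
}

# largest eigenvalue of a sparse symmetric matrix by bisection on
# positive-definiteness of sigma I - S (sparse Cholesky as the PD test)
sym_maxeig <- function(S, tol = 1e-13, maxit = 200L) {
  n <- nrow(S)
  dS <- Matrix::diag(S)
  lo <- max(dS)                                   # sigma I - S not PD here
  hi <- max(Matrix::rowSums(abs(S)))              # Gershgorin: PD here
  hi <- hi + 1e-8 * (1 + abs(hi))
  I <- Matrix::Diagonal(n)
  is_pd <- function(sigma)
    !inherits(suppressWarnings(tryCatch(
      Matrix::Cholesky(methods::as(sigma * I - S, "symmetricMatrix"),
                       perm = TRUE, LDL = FALSE),
      error = function(e) e)), "error")
  if (is_pd(lo)) return(lo)  # degenerate: diagonal matrix etc.
  for (it in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    if (is_pd(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol * (1 + abs(hi))) break
  }
  (lo + hi) / 2
}

# inverse iteration for the Perron vector of the original operator M at the
# known dominant eigenvalue lam; componentwise positive by the M-matrix
# property of (sigma I - M)
perron_vector <- function(M, lam, iters = 4L) {
  n <- nrow(M)
  delta <- 1e-9 * (1 + abs(lam))
  v <- rep(1 / n, n)
  for (try in 1:4) {
    A <- (lam + delta) * Matrix::Diagonal(n) - M
    ok <- TRUE
    v_new <- v
    for (i in seq_len(iters)) {
      v_new <- tryCatch(as.numeric(Matrix::solve(A, v_new)),
                        error = function(e) { ok <<- FALSE; v_new })
      if (!ok) break
      v_new <- v_new / max(abs(v_new))
    }
    if (ok) { v <- v_new; break }
    delta <- delta * 100    # shift was numerically singular; back off
  }
  v[v < 0] <- 0
  v
}

# dominant eigenpair of the coupled two-block operator
#   M = [A1, a2 I; a1 I, A2]
# given the symmetrised blocks S1, S2 (same symmetriser for both blocks).
# Returns unnormalised positive (P, Q), the eigenvalue, a residual, and a
# flag for near-degenerate dominance.
perron_two_block <- function(A1, A2, a1, a2, S1, S2, gap_tol = 1e-10) {
  n <- nrow(A1)
  if (a1 > 0 && a2 > 0) {
    c12 <- sqrt(a1 * a2)
    S <- rbind(cbind(S1, c12 * Matrix::Diagonal(n)),
               cbind(c12 * Matrix::Diagonal(n), S2))
    S <- methods::as(methods::as(S, "symmetricMatrix"), "CsparseMatrix")
    lam <- sym_maxeig(S)
    M <- rbind(cbind(A1, a2 * Matrix::Diagonal(n)),
               cbind(a1 * Matrix::Diagonal(n), A2))
    v <- perron_vector(M, lam)
    P <- v[1:n]; Q <- v[(n + 1):(2 * n)]
    degenerate <- FALSE
  } else if (a1 == 0 && a2 == 0) {
    l1 <- sym_maxeig(S1); l2 <- sym_maxeig(S2)
    lam <- max(l1, l2)
    degenerate <- abs(l1 - l2) <= gap_tol * (1 + abs(lam))
    if (l1 >= l2) { P <- perron_vector(A1, l1); Q <- numeric(n) }
    else          { P <- numeric(n); Q <- perron_vector(A2, l2) }
  } else if (a2 == 0) {          # block lower-triangular: P feeds Q
    l1 <- sym_maxeig(S1); l2 <- sym_maxeig(S2)
    lam <- max(l1, l2)
    degenerate <- abs(l1 - l2) <= gap_tol * (1 + abs(lam))
    if (l1 >= l2 && !degenerate) {
      P <- perron_vector(A1, l1)
      Q <- as.numeric(Matrix::solve(lam * Matrix::Diagonal(n) - A2, a1 * P))
    } else {
      P <- numeric(n); Q <- perron_vector(A2, l2)
    }
  } else {                       # a1 == 0, a2 > 0: Q feeds P
    l1 <- sym_maxeig(S1); l2 <- sym_maxeig(S2)
    lam <- max(l1, l2)
    degenerate <- abs(l1 - l2) <= gap_tol * (1 + abs(lam))
    if (l2 >= l1 && !degenerate) {
      Q <- perron_vector(A2, l2)
      P <- as.numeric(Matrix::solve(lam * Matrix::Diagonal(n) - A1, a2 * Q))
    } else {
      Q <- numeric(n); P <- perron_vector(A1, l1)
    }
  }
  v <- c(P, Q)
  M <- rbind(cbind(A1, a2 * Matrix::Diagonal(n)),
             cbind(a1 * Matrix::Diagonal(n), A2))
  scale <- max(abs(v))
  res <- max(abs(as.numeric(M %*% v) - lam * v)) / scale
  list(value = lam, P = P, Q = Q, residual = res, degenerate = degenerate)
}
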