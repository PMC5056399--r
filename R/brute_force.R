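#' Brute-force sequence-space model (oracle for the class reduction)
#'
#' Builds the full `2 * 2^L`-dimensional generator over binary sequences
#' times the mutator-gene state, with per-site mutation rate `mu / L` (single
#' site flips) and the switch rates `alpha1`, `alpha2` between the two
#' copies of sequence space, and extracts its dominant eigenpair.  For a
#' symmetric landscape all sequences in a Hamming class are equivalent, so
#' the class-aggregated eigenvector must coincide with the reduced model of
#' [steady_state()]; this function exists as an independent oracle for that
#' reduction and is limited to small `L`.
#'
#' @param params A [mutator_params()] object with `L <= 12`.
#' @param landscape A [make_landscape()] object.
#' @return List with `R` (dominant eigenvalue), `p`, `q` (normalised
#'   sequence-space distributions, length `2^L` each), and `state` (the
#'   class-aggregated [population_state()]).
#' @seealso [sequence_operator()] for the raw generator.
#' @export
brute_force_sequence_model <- function(params, landscape) {
  L <- params$L
  if (L > 12) stop("brute-force enumeration limited to L <= 12")
  n <- 2^L
  bl <- sequence_blocks(params, landscape)
  pr <- perron_two_block(bl$A1, bl$A2, params$alpha1, params$alpha2,
                         bl$A1, bl$A2)  # blocks are already symmetric
  tot <- sum(pr$P) + sum(pr$Q)
  p <- pr$P / tot; q <- pr$Q / tot
  cls <- bl$class
  Pc <- as.numeric(rowsum(p, cls)[, 1])
  Qc <- as.numeric(rowsum(q, cls)[, 1])
  list(R = pr$value, p = p, q = q,
       state = structure(list(P = Pc, Q = Qc, normalized = TRUE),
                         class = "population_state"),
       residual = pr$residual)
}

#' Full sequence-space generator of the mutator model
#'
#' The explicit `2 * 2^L` sparse generator used by
#' [brute_force_sequence_model()]; exposed so that its Hamming-class
#' projection can be compared against [build_operator()].
#'
#' @inheritParams brute_force_sequence_model
#' @return Sparse `Matrix` (wild sequences first, then mutator sequences)
#'   with the popcount class of each sequence attached as attribute
#'   `"class"`.
#' @export
sequence_operator <- function(params, landscape) {
  bl <- sequence_blocks(params, landscape)
  n <- 2^params$L
  M <- rbind(cbind(bl$A1, params$alpha2 * Matrix::Diagonal(n)),
             cbind(params$alpha1 * Matrix::Diagonal(n), bl$A2))
  attr(M, "class_of_seq") <- bl$class
  M
}

# wild and mutator sequence-space blocks plus the popcount of each sequence
sequence_blocks <- function(params, landscape) {
  L <- params$L
  n <- 2^L
  idx <- 0:(n - 1)
  pc <- integer(n)                       # popcount by dynamic programming
  if (n > 1) for (i in 1:(n - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
  x <- 1 - 2 * pc / L
  fx <- landscape$f(x); gx <- landscape$g(x)
  # single-site flips: i <-> xor(i, 2^s), rate mu/L each direction
  from <- rep(idx, L)
  to <- bitwXor(from, rep(2^(0:(L - 1)), each = n))
  block <- function(mu, diagv) {
    Matrix::sparseMatrix(i = c(to, idx) + 1L, j = c(from, idx) + 1L,
                         x = c(rep(mu / L, length(from)), diagv),
                         dims = c(n, n))
  }
  list(A1 = block(params$mu1, fx - params$mu1 - params$alpha1),
       A2 = block(params$mu2, gx - params$mu2 - params$alpha2),
       class = pc)
}

#' Hamming-class projection of the sequence-space generator
#'
#' Aggregates the full generator onto class totals: `B G E` with `E` the
#' embedding of a class distribution spread uniformly within each class and
#' `B` the class-sum map.  Because the generator commutes with sequence
#' permutations fixing the reference, this projection equals the reduced
#' operator of [build_operator()] exactly.
#'
#' @inheritParams brute_force_sequence_model
#' @return Dense matrix of dimension `2(L+1)`.
#' @export
project_sequence_operator <- function(params, landscape) {
  L <- params$L
  G <- sequence_operator(params, landscape)
  cls <- attr(G, "class_of_seq")
  n <- 2^L
  Bh <- Matrix::sparseMatrix(i = cls + 1L, j = seq_len(n), x = 1,
                             dims = c(L + 1L, n))
  Eh <- Matrix::t(Bh) %*% Matrix::Diagonal(L + 1L, 1 / choose(L, 0:L))
  B <- rbind(cbind(Bh, Matrix::Matrix(0, L + 1L, n)),
             cbind(Matrix::Matrix(0, L + 1L, n), Bh))
  E <- rbind(cbind(Eh, Matrix::Matrix(0, n, L + 1L)),
             cbind(Matrix::Matrix(0, n, L + 1L), Eh))
  as.matrix(B %*% G %*% E)
}
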