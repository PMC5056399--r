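# deterministic fixtures used across the suite

# random symmetric tabulated landscape on the class grid of L
rand_tabulated <- function(L, seed, lo = 0, hi = 1.5) {
  vals <- withr::with_seed(seed, stats::runif(L + 1, lo, hi))
  make_landscape("tabulated", values = vals, L = L)
}

# random rate set; uni = TRUE forces alpha2 = 0
rand_params <- function(L, seed, uni = FALSE) {
  r <- withr::with_seed(seed, stats::runif(4, 0, 1))
  mutator_params(L, mu1 = 0.2 + r[1], mu2 = 0.2 + 3 * r[2],
                 alpha1 = 0.05 + r[3], alpha2 = if (uni) 0 else 0.05 + r[4])
}

# class-aggregate a sequence-space vector by popcount
class_totals <- function(v, L) {
  n <- 2^L
  pc <- integer(n)
  if (n > 1) for (i in 1:(n - 1)) pc[i + 1] <- pc[bitwShiftR(i, 1) + 1] + bitwAnd(i, 1L)
  as.numeric(rowsum(v, pc)[, 1])
}
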