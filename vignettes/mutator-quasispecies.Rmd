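---
title: "Quasispecies dynamics with a mutator gene: models, solvers, phase structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasispecies dynamics with a mutator gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutatorQS)
```

## The model

A binary genome of `L` sites evolves in an infinite population under
mutation and selection.  A separate *mutator locus* controls the genomic
mutation rate: in the wild state the regular part of the genome mutates at
per-genome rate $\mu_1$, in the mutator state at $\mu_2$ (typically 10--100
times larger).  The locus itself switches forward (wild $\to$ mutator) at
rate $\alpha_1$ and back at rate $\alpha_2$; because back switching requires
reverting a specific lesion, the biologically common case is
$\alpha_2 = 0$.

For a *symmetric* fitness landscape -- fitness depending only on the Hamming
class $l$, i.e. on the mean spin $x_l = 1 - 2l/L$ -- the state reduces to
two coupled birth--death chains: class probabilities $P_l$ (wild) and $Q_l$
(mutator) with $\sum_l (P_l + Q_l) = 1$.  In the parallel
(Crow--Kimura) formulation, growth and mutation act as independent
processes; the linearised system is

$$
\dot P_l = P_l\,[f(x_l) - \mu_1 - \alpha_1]
 + \frac{\mu_1}{L}\left[(L-l+1)P_{l-1} + (l+1)P_{l+1}\right] + \alpha_2 Q_l,
$$

and the mirror equation for $Q_l$ with $g$, $\mu_2$, $\alpha_2$, source
$\alpha_1 P_l$.  The combinatorial coefficients $(L-l+1)$ and $(l+1)$ count
the sites available for a class transition; the per-site rate is the
per-genome rate divided by $L$.  This convention makes the class operator
the exact permutation-symmetric projection of the $2\cdot 2^L$
sequence-space generator (`project_sequence_operator()` checks this
identity, and `brute_force_sequence_model()` solves the unprojected problem
for $L \le 12$).

The normalised (probability-conserving) dynamics subtracts the
instantaneous mean fitness $R(t) = \sum_l f(x_l)\tilde P_l + g(x_l)\tilde
Q_l$; `integrate_nonlinear()` integrates it with a stiff-capable solver
(relative tolerance $10^{-10}$, absolute $10^{-12}$).  Its long-time limit
and the dominant eigenpair of the linear operator are two routes to the
same steady state; the package provides both and the tests require them to
agree to $10^{-6}$.

Steady-state observables (`observables()`): mean fitness $R$, surplus $s =
\langle x \rangle$ (with per-type surpluses $s_1, s_2$; the surplus of an
empty sub-population is reported as `NA`, not 0), and the mutator fraction
$q = \sum_l \tilde Q_l$.  The identity $s = (1-q)s_1 + q s_2$ holds for
every computed state.

## Steady states as eigenproblems

The mean fitness is the dominant (rightmost) eigenvalue of the
$2(L{+}1)$-dimensional operator, which is Metzler, so Perron--Frobenius
applies after a diagonal shift.  Numerically we exploit two structural
facts:

* each chain is similar to a *symmetric* tridiagonal matrix under the
  scaling $d_l = \sqrt{\binom{L}{l}}$, which is the same for both chains;
  with $\alpha_1\alpha_2 > 0$, scaling the mutator chain by
  $\sqrt{\alpha_1/\alpha_2}$ symmetrises the whole operator.  The dominant
  eigenvalue is then located by bisection on positive-definiteness of
  $\sigma I - S$ (sparse Cholesky as the test), to a relative width of
  $10^{-13}$.  This avoids the accuracy failures of dense nonsymmetric
  `eigen()`, which we measured at $10^{-2}$ absolute on linear-fitness
  chains whose exact eigenvalue is known in closed form.
* the eigenvector is recovered by inverse iteration on the *original*
  operator.  For $\sigma$ above the Perron root, $\sigma I - M$ is an
  M-matrix whose LU solve involves no cancellation, so the iterates stay
  componentwise positive and minority components of relative size
  $10^{-7}$ and below keep full relative accuracy.

With $\alpha_2 = 0$ the operator is block-triangular: the spectrum is the
union of the two chain spectra, the dominant eigenvalue is the larger chain
Perron root, and the slaved component of the eigenvector solves
$(R I - A_2) Q = \alpha_1 P$ -- again an M-matrix system, which is how the
extreme mass ratios of the sweep regime (e.g. $1 - q \sim 10^{-6}$) are
computed reliably.  When the two chain roots coincide within $10^{-10}$
the result carries a `degenerate` flag instead of an arbitrary choice.

For linear fitness $f(x) = kx$ the wild chain is exactly solvable through
generating functions: $P(z) \propto (z - z_-)^L$ with
$z_- = -(k + \sqrt{k^2+\mu_1^2})/\mu_1$, giving
$R = \sqrt{k^2+\mu_1^2} - \mu_1 - \alpha_1$ *with no finite-$L$
correction* and an explicit binomial class distribution
(`generation_function_solve()`).  This closed form doubles as a
machine-precision oracle for the eigensolvers, and it explains why the
numeric and analytic mean-fitness columns of the linear-fitness
reproduction table coincide to all printed digits.

## The large-genome analytic layer

Writing $P_l = v_1(x) e^{L u(x,t)}$, $Q_l = v_2(x) e^{L u(x,t)}$ turns the
linear system into a Hamilton--Jacobi problem.  At each $x$ the stationary
growth is governed by the $2\times 2$ matrix

$$
\begin{pmatrix}
 f(x) - \mu_1(1-\sqrt{1-x^2}) - \alpha_1 & \alpha_2\\
 \alpha_1 & g(x) - \mu_2(1-\sqrt{1-x^2}) - \alpha_2
\end{pmatrix},
$$

whose eigenvalue branches $V_\pm(x)$ are the potentials (`potential()`).
The mean fitness is $R = \max_x V_+(x)$ (`mean_fitness_general()`).  In the
fully symmetric case ($\mu_1=\mu_2$, $f=g$, $\alpha_1=\alpha_2=\alpha$) the
top branch is $f(x) - \mu_1(1-\sqrt{1-x^2})$, independent of $\alpha$, and
$V_+ - V_- = 2\alpha$; random-draw tests pin the branch bookkeeping against
a direct quadratic-formula oracle at $10^{-14}$.

The off-diagonal convention (which entry carries $\alpha_1$ versus
$\alpha_2$) is fixed by requiring that the finite-$L$ eigenvalues converge
to $\max_x V_+$; the quadratic-landscape reproduction table
(`reproduce_table3()`) pins it empirically across seven parameter sets.

Maximisation uses a uniform 2001-point grid on $[-1,1]$, golden-section
refinement inside the bracketing cell to $10^{-12}$ in $x$, explicit
evaluation of the bracket endpoints (so boundary maxima such as a
vanishing mutation rate are exact), and ties broken toward larger $x$.
Near $|x| = 1$ the square root is evaluated through
`sqrt(pmax(1 - x^2, 0))`, and closed forms in the variable
$c=\sqrt{1-x^2}$ are used in the phase-wise expressions, which avoids the
derivative blow-up of $\sqrt{1-x^2}$ at the boundary.

With $\alpha_2 = 0$ the branches are the two diagonals and the model has
phases:

* **mixed** -- $R_{mix} = \max_x[f(x) - \mu_1(1-\sqrt{1-x^2})] - \alpha_1$
  (`mixed_phase_fitness()`); wild machinery drives growth, yet for smooth
  landscapes the mutator *allele* still takes over at large $L$ (below);
* **mutator** -- $R_{mu} = \max_x[g(x) - \mu_2(1-\sqrt{1-x^2})]$, the
  ordinary one-type model at the mutator rate (`mutator_phase_fitness()`);
* **non-selective** -- selection lost, $s = 0$.

For linear fitness the two selective branches cross at the critical slope
$k_c$ solving $\sqrt{k_c^2+\mu_1^2} - \mu_1 - \alpha_1 =
\sqrt{k_c^2+\mu_2^2} - \mu_2$ (`critical_slope()`, bisection to
$10^{-10}$); there is no non-selective phase for linear fitness.

With $\alpha_1\alpha_2 > 0$ both types share one packet position
($s_1 = s_2 = s$): at the peak the Hamilton--Jacobi momentum vanishes and
the mutation terms drop out, so $(f(s)-\alpha_1-R)(g(s)-\alpha_2-R) =
\alpha_1\alpha_2$.  For $f = g$ this reduces to $f(s) = R$ with component
ratio $v_2/v_1 = \alpha_1/\alpha_2$, hence
$q = \alpha_1/(\alpha_1+\alpha_2)$ at infinite $L$
(`surplus_and_ratio()`).  Note that the surplus is *not* the argmax of
$V_+$: for linear fitness the exact binomial eigenvector has mean
$s = R/k$ at every $L$, while the potential peaks at $k/\sqrt{k^2+\mu^2}$;
the package follows the stationarity condition $f(s)=R$, which the
eigenvector oracle confirms to $10^{-10}$.

An even landscape (e.g. quadratic) makes the operator symmetric under
$l \mapsto L-l$, so the exact finite-$L$ eigenvector has $s = 0$ while the
large-$L$ theory spontaneously breaks the symmetry; numerically computed
eigenvectors may localise in either well.  Surplus assertions in the tests
therefore use odd (linear) landscapes.

## The single-peak landscape

With $f(1) = g(1) = J$ and 0 elsewhere (the peak sits exactly at class
$l=0$; we treat the landscape classwise, never as a continuous limit), all
three phases have closed forms: $R_{mix} = J - \mu_1 - \alpha_1$,
$R_{mu} = J - \mu_2$, $R_{ns} = 0$, with borders $\alpha_1 = J - \mu_1$,
$\mu_2 = J$ and $\mu_1 + \alpha_1 = \mu_2$.  The value $R_{ns} = 0$ is the
flat-landscape growth rate of the model's Malthusian convention; it is
implied by the border structure and adopted here explicitly.  Points lying
exactly on a border are reported as the border, not as either phase
(`single_peak_solution()`, `phase_diagram()`).

In the mixed phase the wild distribution is geometric,
$P_l = P_0(\mu_1/J)^l$, the peak balance gives
$P_0 + Q_0 = (J-\mu_1-\alpha_1)/J$ and
$Q_0 = \alpha_1 P_0/(\mu_2-\mu_1-\alpha_1)$, so

$$
1 - q \;=\; \frac{(J-\mu_1-\alpha_1)(\mu_2-\mu_1-\alpha_1)}
                 {(J-\mu_1)(\mu_2-\mu_1)} .
$$

Uniquely among the landscapes considered here, this wild fraction stays
finite as $L \to \infty$.  The finite-$L$ eigenvector approaches the
closed form like $1/L$; at $J=1.05$, $\alpha_1=10^{-3}$, $\mu_2=10$ the
acceptance script measures a relative deviation on $q$ of about $0.4\%$ at
$L=5000$ (and about $0.008\%$ when measured on $1-q$).

## Which allele wins at finite genome length: the WKB computation

For smooth landscapes in the mixed phase the mutator allele's fate depends
on $L$.  The wild packet has exponent $u(x)$ from its stationary
Hamilton--Jacobi equation, peaking at $s_1$ with $f(s_1) = R + \alpha_1$.
The mutator chain carries a *slaved* branch (same exponent, amplitude
$\alpha_1 / [(\mu_2-\mu_1)(f(x) - f(s_3))]$), valid above the resonance
point $s_3$ where $f(s_3) = R + \alpha_1\mu_2/(\mu_2-\mu_1)$, concatenated
with smooth derivative onto the free mutator branch that peaks at $s_2$
with $f(s_2) = R$.  The exponent at the mutator peak,
$\tilde u(s_2) = u(s_3) - \int_{s_2}^{s_3}\tilde u'\,dx$ (adaptive
quadrature, tolerance $10^{-10}$), is asymptotically exact and yields the
discriminant $K = e^{-L\tilde u(s_2)}$: $1 - K \ll 1$ means the wild type
keeps the majority, $K \ll 1$ means the mutator allele sweeps
(`wkb_mutator_fraction()`).

The wild fraction itself needs prefactors: a Landau--Zener-type analysis of
the resonance crossing at $s_3$ gives the injected homogeneous amplitude
$\alpha_1\sqrt{2\pi L/(b\,g')}$ (with $b$ twice the local group velocity
and $g'$ the detuning slope), and the two Gaussian packets contribute
$\sqrt{|u''(s_1)|/|\tilde u''(s_2)|}$.  The prefactor is an order-one
estimate -- the eigenvector oracle shows agreement within half an order of
magnitude in the deep sweep regime ($1-q \sim 10^{-6}$) -- while the
exponent itself is exact; this split is intrinsic to one-term WKB and is
flagged in the returned `validity`/`rho` fields rather than hidden.

For small $\alpha_1$ and $\mu_2 \gg \mu_1$ everything collapses to closed
forms (`small_a_asymptotics()`): exponent $E = L\alpha_1^2/(4\mu_2 k s_2)$
for linear fitness, crossover length $L^* = 4\mu_2 k s_2/\alpha_1^2$,
linear-response regime $q \propto \alpha_1$ below $L^*$ and exponential
sweep above.  As $\alpha_1 \to 0$ the three packets merge and the
asymptotic prefactor is accurate only to a factor of about two, which is
the tolerance the corresponding test asserts.

## The Eigen-model variant

In the coupled (Eigen) formulation mutation accompanies replication:
per-nucleotide errorless-copy probability $w$, genome mutation parameter
$\gamma = -L\log w$, mutator mutation parameter $\mu\gamma$, and a
per-replication switch probability $1-e^{-h}$ applied as the factor
$e^{-h}$ on the wild branch with the complementary source into the mutator
branch; back switching is excluded by default (an optional rate would enter
exactly like $\alpha_2$ above, but the uni-directional setting is the one
analysed).  Fitness is Wrightian.  For the single peak ($A$ against
background 1): $R_{mix} = A e^{-(h+\gamma)}$, $R_{mu} = A e^{-\mu\gamma}$,
$R_{ns} = 1$, with borders $\mu\gamma = \log A$, $h = \log A - \gamma$ and
$h = (\mu-1)\gamma$ meeting at a triple point
(`eigen_continuous_R()`, `eigen_phase_borders()`).

The discrete-time iteration (`eigen_discrete_iterate()`) uses the exact
class-to-class mutation kernel -- a two-index binomial sum, computed by
direct convolution up to $L = 256$ and FFT convolution beyond, never a
Poisson approximation -- so the $L \le 10$ full sequence iteration can
serve as a bitwise oracle for the reduction.  Its growth factor converges
to the dominant eigenvalue of the block-triangular transfer matrix and to
the continuous-time phase value.

Mixed-phase peak occupancies follow from the steady-state balance
($p_0 + q_0 = (R-1)/(A-1)$, switching source, and the classical internal
structure of the wild chain), giving the mutator fraction
`eigen_single_peak_q()`; in the small-parameter regime
($h, \gamma, A-1 \ll 1$) it collapses to the image of the parallel-model
formula under the generation map $S = \tau J$, $\gamma = \tau\mu_1$,
$h = \tau\alpha_1$ (`ck_eigen_map()`, inverse `eigen_ck_map()`).  The
full and mapped expressions converge at first order in $\tau$; tests
assert the convergence rate along $\tau = 10^{-2}, 10^{-3}, 10^{-4}$.
Because the map linearises fitness ($A = 1+\tau J$), large $\tau$ can move
a narrowly selective parameter set out of the mixed phase; the package
rejects such points rather than extrapolating.

A log-normal Wrightian landscape ($\log r \sim N(0, \sigma^2)$, median 1)
behaves like an effective single peak: the largest of the $2^L$ draws
concentrates at $A_{max} = e^{\sigma\sqrt{2L\log 2}}$
(`lognormal_effective_peak()`).  This is the leading-order extreme-value
location; at the enumerable sizes used in tests ($L = 12$) it sits well
inside the resampling band of brute-force maxima but is biased upward
relative to the median maximum, which is the expected size of the
neglected $\log\log$ correction.  Seeded draws
(`lognormal_wrightians()`) are bitwise reproducible.

## What the test fixtures emulate

Randomised tests draw symmetric tabulated landscapes (i.i.d. uniform class
fitnesses) and random rate quadruples under fixed seeds -- enough to
exercise every branch of the solvers and the sequence-space oracle.  They
do not emulate real fitness data: no four-letter alphabet, no asymmetric
(sequence-specific) epistasis, no lethal classes except through the
composite-landscape interface, and no finite-population noise (the model
is deterministic and infinite-population throughout).  Passing tests
therefore certify the mathematics of the model family, not the fit of any
landscape family to data.

## Problem sizes and tolerances

Test and acceptance runs use desk-scale sizes chosen so every quantity is
recomputed from scratch in seconds: coupled-chain eigenproblems at
$L = 400$ (dimension 802), uni-directional chains at $L = 1000$, the
single-peak comparison at $L = 5000$, sequence-space oracles at
$L \le 10$, and 20 randomised oracle parameter sets.  Key tolerances:
eigenvalue bisection $10^{-13}$ relative; eigenpair residual below
$10^{-10}$; probability conservation $10^{-9}$ over $t \in [0, 200]$;
class-projection and oracle identities $10^{-10}$ to $10^{-12}$; WKB
quadrature $10^{-10}$.

## Finite-size effects and known limitations

* The finite-$L$ eigenvalue exceeds the large-$L$ potential maximum and
  the excess decays slowly (roughly a power of $L$): for the quadratic
  landscape at $\mu_2 = 3.5$ the package computes $R = 0.1908$ at
  $L = 100$, $0.1835$ at $L = 400$, against the analytic $0.1811$.
  Comparisons of "numerical" against "analytic" mean fitness are therefore
  meaningful only with the genome length stated; `reproduce_table3()`
  exposes `L` for exactly this reason.
* Near the mutator sweep the wild fraction depends extremely steeply on
  $L$ (orders of magnitude across a factor 2 in $L$), so small
  discrepancies in the stated genome length translate into large ones in
  $1-q$; the package reports the eigenvector value, whose two independent
  computation routes agree to six digits.
* The WKB prefactor (not the exponent) is order-one accurate; use the
  eigensolver when absolute accuracy on $1-q$ matters and the WKB result
  for scaling in $L$ and for $K$.
* Asymmetric per-site mutation, four-letter alphabets, time-dependent
  rates and finite populations are out of scope.
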