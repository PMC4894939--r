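---
title: "Kinetic theory of age-structured birth, death and fission: models, solvers and samplers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic theory of age-structured birth, death and fission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agekin)
```

## The processes

`agekin` works with stochastic populations whose individuals carry an age
$a$ (time since their own birth) and experience events at age-dependent
hazards. Two modes of reproduction are covered:

* **Budding**: an individual of age $a$, in a population of size $n$,
  produces a single age-0 offspring with hazard $\beta_n(a)$ and dies with
  hazard $\mu_n(a)$; the parent survives a birth.
* **Binary fission**: an individual's events arrive with total hazard
  $\gamma(a) = \beta(a) + \mu(a)$; at an event it is replaced by *two*
  age-0 twins (probability $h_2 = \beta/\gamma$) or dies (probability
  $h_0 = \mu/\gamma$). Living twin pairs ("doublets") share one time of
  birth; an individual whose twin has died is a "singlet".

The full state of either process is the *age chart* — the vector of ages of
every living individual. Internally everything is stored in the
time-of-birth (TOB) representation $b = t - a$, because $b$ is constant
along the characteristics of every transport equation in the theory; ages
are derived on demand.

A fission model is conveniently specified by the waiting-time density
$g(\tau)$ between events together with $h_2$, from which
$\beta(a) = h_2\, g(a)/(1 - G(a))$ and $\mu(a) = h_0\, g(a)/(1 - G(a))$
(`hazards_from_waiting_time()`); the no-event probability then reproduces
the waiting-time survival $1 - G$ exactly. Interactions such as a carrying
capacity enter through size-dependent hazards, e.g.
$\beta_n = \beta_0(1 - n/K)$, clamped at zero because a hazard is
nonnegative by definition (`rates_capacity()`).

## Exact simulation

The samplers are event-driven and statistically exact; no time step is ever
discretized away.

* **Inversion** (size-independent hazards, the default): each individual's
  next event age solves $\int_{a_0}^{A}\gamma = E$ with $E \sim$ Exp(1),
  using closed-form inverses where the model provides them (constant,
  linear, waiting-time quantile) and monotone root finding otherwise. At an
  event a competing-risks coin $\beta/\gamma$ picks the kind. A twin pair
  is a single clock with hazard $2\gamma$; after a pair event the surviving
  twin's clock restarts from its current age, which is exact because the
  two members' hazard processes are independent.
* **Thinning** (size-dependent hazards): proposals arrive at rate
  $n\,\bar\gamma(n)$ from a user-supplied bound
  $\bar\gamma(n) \ge \gamma_n(a)$; a uniformly chosen individual is
  accepted with probability $\gamma_n(a)/\bar\gamma(n)$. After every
  accepted event the pending proposal is discarded and the rate recomputed,
  so any $n$-dependence of the bound is honoured. A violated bound is a
  hard error, never silently accepted. When the hazards are
  age-independent the tight bound makes every proposal accept and the
  scheme coincides with the classical exact algorithm for Markov chains.
* **Fixed step** (`method = "fixed-step"`): the historical discretized
  scheme, retained only for fidelity experiments; it carries an $O(\Delta t)$
  bias and is never a default.

Reproducibility: each trajectory draws from a stream seeded by two Lehmer
steps mixing the master seed and the trajectory index (exact in doubles,
below $2^{31}$), and the draw order at each event is fixed and documented
in the source. Identical model, initial state and seed give bitwise
identical event logs. Snapshots record the state *after* any event falling
exactly on the snapshot time.

Spatial budding adds independent Brownian motion with diffusivity $D$;
Gaussian increments are sampled lazily at event and snapshot times (exact
for Brownian motion), and a newborn inherits its parent's position. With
$D = 0$ no Gaussian variates are consumed, so event statistics reduce
exactly to the non-spatial simulator under the same seed.

## Deterministic layer

**Mean field (budding).** The expected age density solves the
McKendrick–von Foerster transport equation with renewal boundary
$\rho(0,t) = B(t) = \int \beta\rho$. `solve_renewal_B()` marches the
Volterra equation for $B$ with the product trapezoidal rule; by default a
single Richardson extrapolation over grids $h$ and $h/2$ removes the
leading $O(h^2)$ term (the plain rule is available for convergence
diagnostics, and its refinement ratio is tested to be $\approx 4$).
`laplace_renewal_B()` evaluates the transform solution
$\hat B = \widehat{gU\beta}/(1 - \widehat{U\beta})$ numerically. Because
the hazards are black-box functions, the transform is only available at
real $s$ by quadrature, so inversion uses Gaver–Stehfest (real nodes only)
rather than a complex contour; a supercritical model is first shifted by
its Malthusian root — the positive solution of
$\widehat{U\beta}(s) = 1$ — so that all nodes lie right of the growth pole.
Accuracy of this route is about four to six significant digits, which is
why it serves as a cross-check of the marching solver rather than the
primary path.

**Master equation.** For age-independent (possibly size-dependent) rates
the population size is a Markov chain; `solve_master_equation()` integrates
the truncated forward equations with `deSolve` and is used as the exact
oracle for the simulator. Mass reaching the truncation boundary above
$10^{-6}$ is an error, not a warning.

**Factorial moments.** For size-independent budding the factorial moments
$X^{(k)}(\mathbf a_k;t) = \sum_n (n)_k\, \rho_n^{(k)}(\mathbf a_k;t)$
satisfy a generalized McKendrick–von Foerster equation whose only hazard is
$\mu$; birth enters through the boundary surface. `solve_Xk()` implements
$k \le 2$ — order 2 is what age-window variances require, and each
additional order would consume the full solution of the previous one along
a moving boundary. The order-2 boundary surface $C(x,\tau) = X^{(2)}(x,0;\tau)$
is *discontinuous* across $x = \tau$ (the older member of the pair switches
between being a founder and being born after the start) and at $\tau = 0$.
The solver therefore carries two smooth sheets and splits every quadrature
at the jump, restoring clean $O(h^2)$ convergence; with Richardson
extrapolation the solution matches the exactly solvable pure-birth
(Yule–Furry) closed forms to better than $10^{-7}$ in max-norm at
$h = 0.015$. Window means and variances follow from
$\mathrm{Var} = \int\!\!\int_{\Omega^2} X^{(2)} + m - m^2$, where the $+m$
is the diagonal atom of the raw second-moment measure
($n^2 = (n)_2 + n$); the window quadrature splits at the age-$t$ kink and
takes one-sided limits there.

On measure-zero branch boundaries of the closed-form Yule–Furry moments
(ages equal to $t$ or to each other) the package evaluates the branch whose
strict inequalities hold on the *later-listed* region — an arbitrary but
fixed convention, applied consistently in the solver and the closed forms.

**Fission mean field.** The expected singlet and doublet TOB densities obey
$X(x,t) = 2B(x)U(1-U)$, $Y(x,t) = BU^2$ for $x > 0$ with
$U = U(x;x,t)$ the no-event propagator, and the pair fecundity $B$ solves
its own Volterra equation. Note the doublet density decays with the
*squared* propagator — both twins must be event-free. The total density
$T = X + 2Y$ satisfies a one-line transport equation whose renewal boundary
is $T(t,t) = 2B(t) = 2\int T\gamma$: the factor 2 is forced by each fission
injecting two newborns, and `mvf_reduction_check()` verifies exactly this
identity on the grid (the same bookkeeping that makes
$Y(t,t) = B(t)$).

**Bellman–Harris equivalence.** Starting from one age-0 individual, the
kinetic route gives $T(t) = (1-G) + 2\int_0^t B(x)(1-G(t-x))dx$ with
$B = h_2 g + 2h_2 B * g$, while the generating-function route gives
$\tilde T(s) = \frac1s \frac{1-\tilde g}{1 - 2h_2\tilde g}$. The package
keeps both (`bellman_harris_mean()`, `bellman_harris_mean_laplace()`) and
their agreement to $10^{-4}$ relative is asserted in the tests — the
computational form of the mean-field equivalence between the two theories.
At $h_2 = \tfrac12$ the process is critical and $T \equiv 1$ for *any*
proper waiting-time density, a sharp internal consistency check.

## The Gamma fission model

With $g \sim$ Gamma($\alpha, \alpha$) (unit mean, variance $1/\alpha$) and
$h_2 = 1$, the transform solutions are explicit:
$\tilde B = \tilde g/(1 - 2\tilde g)$ and
$\tilde T = (1-\tilde g)/\big(s(1 - 2\tilde g)\big)$ with
$\tilde g = (\alpha/(\alpha+s))^\alpha$. Four independent evaluation routes
are retained deliberately — marching Volterra, renewal, numerical
inversion, and the explicit Bromwich solution — and their pairwise
agreement is the package's verification strategy; disagreement beyond
tolerance is a hard test failure.

The Bromwich evaluation deserves three notes:

* For **non-integer** $\alpha$ the inversion is a residue sum over the
  principal-branch poles $s = 2^{1/\alpha}e^{2\pi i n/\alpha}$,
  $|n| \le \lfloor\alpha/2\rfloor$, plus a branch-cut integral damped by
  $e^{-\alpha t(r+1)}$ (adaptive Gauss–Kronrod, truncated where the damping
  falls below $10^{-16}$). Computing the cut discontinuity from first
  principles gives the signs $+\frac{\alpha}{\pi}\int$ for $B$ and
  $-\frac1\pi\int$ for $T$; with these, $T(\alpha, 0) = 1$ exactly and the
  route agrees with Talbot inversion to $10^{-11}$.
* For **integer** $\alpha$ there is no branch cut: the rescaled transform
  is rational and the exact sum over all $\alpha$ roots of $s^\alpha = 2$
  is used, with the exponentials combined as $e^{(s_j-1)\alpha t}$ so that
  nothing overflows even at $\alpha = 100$. This also settles the even-$\alpha$
  case, where the half-open residue listing of the branch-cut form would
  double-count the pole at angle $\pi$.
* **Fixed-Talbot inversion** (32 nodes, optional contour shift past the
  Malthusian pole $\alpha(2^{1/\alpha}-1)$) is excellent for small and
  moderate $\alpha$ but *degrades for large* $\alpha$: the poles crowd the
  imaginary axis and $T(t)$ approaches the Galton–Watson staircase.
  At $\alpha = 100$ it is off by several percent while the residue sum
  matches the exact generation-counting series
  $T(t) = \sum_k 2^k\,[G_k(t) - G_{k+1}(t)]$
  ($G_k$ the Gamma($k\alpha,\alpha$) CDF) to $10^{-14}$; the tests pin the
  implementation to that series.

As $\alpha$ grows, divisions synchronize and the mean population descends
toward discrete doubling: $T$ is nonincreasing in $\alpha$ at fixed $t$,
squeezed between the Markovian envelope $e^t$ and the Galton–Watson step
$2^{\lfloor t\rfloor}$ — where the doubling at integer $t$ has *not yet*
been credited, i.e. the lower envelope at $t$ is the step's left limit.

## Ensemble estimators

`simulate_ensemble()` runs $R$ independent trajectories and stores snapshot
states. Estimators are deliberately simple so their error bars are honest:

* `estimate_number_density()`: the empirical distribution of the total
  count, with binomial standard errors.
* `estimate_marginal_age_density()`: one uniformly chosen individual (or
  one unordered pair, symmetrized) per qualifying trajectory. One draw per
  trajectory keeps trajectories i.i.d., so per-bin standard errors are
  plain binomial; the estimate for fixed $n$ integrates to the empirical
  $P(n)$. A never-realized `n_filter` yields an `empty` flag, not an error.
* `estimate_window_count_moments()`: sample mean and unbiased variance of
  the count with age in a window; the variance's standard error uses the
  empirical fourth moment.

## Reference experiments and what they do (and do not) show

Three built-in configurations (`fixture_config()`) define the package's
reference experiments: a pure-death process with linear hazard
$\mu(a) = a$ started from 10 founders with Gamma(4,4) ages (unit mean,
standard deviation $\tfrac12$); a budding process with $\beta_0 = 1$ and
carrying capacity $K = 5$ from a single founder; and Gamma-fission runs at
$\alpha \in \{1, 10, 100\}$. At full scale they use 400&nbsp;000
trajectories; the desk scale used throughout the tests is 50&nbsp;000
(100&nbsp;000 for the carrying-capacity distribution, whose
total-variation comparison against the master equation is the strictest
statistical gate), sizes at which every 3-standard-error band in the suite
is decisive. The generator simulates exactly the processes the theory
describes — exponential-family hazards, independent individuals up to a
size-dependent rate, perfectly observed states. Passing tests therefore
certify the solvers and samplers against the theory, not the theory
against any organism: real populations have measurement error,
inter-individual heterogeneity and environmental drift that none of these
models emulate.

Known limitations: moment fields stop at order 2; the fission mean field
assumes size-independent hazards (the size-dependent double hierarchy is
not closed); spatial interactions between individuals are out of scope
(only free diffusion is implemented); `laplace_renewal_B()` is restricted
to exponentially bounded hazard kernels, and heavy-tailed initial densities
are truncated (at residual mass $10^{-10}$, recorded in the solution's
metadata).
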