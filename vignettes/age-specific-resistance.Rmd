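---
title: "Modelling the evolution of age-specific resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of age-specific resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageresist)
```

`ageresist` studies a question that arises across plants, invertebrates and
vertebrates: why are juveniles sometimes less resistant to infection than
adults, and sometimes more? The package implements an age-structured
eco-evolutionary model in which innate, infection-preventing resistance can
evolve separately at the juvenile and adult stages, each trait paying a cost
through another life-history trait (maturation, reproduction or mortality).
The system is loosely inspired by sterilising pathogens such as anther smut
in carnations, where infected hosts rarely recover and resistance differs
strongly between seedlings and mature plants.

## The ecological model

Hosts are either susceptible or infected, and either juvenile or adult, with
densities $S_J, S_A, I_J, I_A$ ($N$ is their sum). Juveniles mature at rate
$g$, adults reproduce at rate $a$ subject to density-dependent competition
$q$, natural mortality is $b_J$, $b_A$, and transmission is density
dependent with stage transmission rate $\beta_i = \beta_0 (1 - r_i)$, where
$r_i \in [0, 1]$ is resistance at stage $i$ ($r_i = 0$ fully susceptible,
$r_i = 1$ fully resistant). The force of infection on stage $i$ is
$\lambda_i = \beta_i (I_J + I_A)$. Infection either reduces fecundity to a
fraction $f$ (sterility virulence $1-f$) or adds mortality $\alpha$
(mortality virulence); the headline analyses use one virulence type at a
time, and there is no recovery:

$$
\begin{aligned}
\dot S_J &= a(1-qN)(S_A + f I_A) - (b_J + g + \lambda_J) S_J,\\
\dot S_A &= g S_J - (b_A + \lambda_A) S_A,\\
\dot I_J &= \lambda_J S_J - (b_J + g + \alpha) I_J,\\
\dot I_A &= g I_J + \lambda_A S_A - (b_A + \alpha) I_A.
\end{aligned}
$$

The host is viable when $ag > b_A(b_J + g)$. Solving $g S_J = b_A S_A$
together with the birth balance gives the disease-free equilibrium
$N^* = (ag - b_A(b_J+g))/(agq)$ with $S_A^* = g N^*/(g + b_A)$; note the
$(b_A + g)$ factor in the per-class densities, which matters whenever a
mortality trade-off makes $b_J \neq b_A$ (we verify the closed form against
long-time integration in the test suite). The next-generation method at
that equilibrium yields

$$
R_0 = \frac{\beta_0\,(ag - b_A(b_J+g))\,
  \left[(1-r_J)(b_A+\alpha+g)\,b_A + (1-r_A)\,g\,(b_J+\alpha+g)\right]}
  {a g\,(b_A+\alpha)(b_A+g)(b_J+g+\alpha)\,q},
$$

checked to $10^{-8}$ relative against the spectral radius of a numerically
assembled next-generation matrix. The endemic equilibrium has no closed
form; `endemic_equilibrium()` integrates the stiff system from an interior
initial condition and polishes the state with a damped Newton iteration on
the analytic Jacobian (residuals are driven to machine precision because the
invasion-fitness identities below hold exactly only at the exact
equilibrium). Stability is decided by the Jacobian eigenvalues, and a
`multistart` guard can scan five spread-out initial conditions; in every
region we analyse a single stable endemic equilibrium is found, but the
guard, rather than an assumption, is what establishes that.

Rescaling time by $b_0$ and density by $q$ shows that $q = 1$ and $b_0 = 1$
can be fixed without loss of generality; the test suite verifies the
rescaling map numerically on random parameter draws rather than relying on
the symbolic argument.

## Trade-offs

Resistance at each stage degrades exactly one other life-history trait via
the saturating cost curve

$$c(r) = c_1 \frac{1 - e^{c_2 r}}{1 - e^{c_2}},$$

which rises from 0 to the maximal proportional cost $c_1 \in (0, 1]$ with
curvature $c_2$ ($c_2 > 0$ gives accelerating costs; the removable
singularity at $c_2 = 0$ is implemented as the linear limit $c_1 r$).
Juvenile resistance can be wired to maturation, reproduction or juvenile
mortality; adult resistance to reproduction or adult mortality; when both
traits are wired to reproduction the two cost factors multiply, and
mortality costs enter as $b_0(1 + c)$. Only accelerating costs are analysed
(decelerating costs typically produce evolutionary repellers). Defaults
follow the reference parameterisation: $a_0 = 5$, $g_0 = 1$, $b_0 = 1$,
$q = 1$, $c_{1i} = 0.5$, $c_{2i} = 3$, and cost parameters are kept equal
across stages so that comparisons between wirings are fair.

## Invasion analysis

Evolution is modelled by adaptive dynamics: rare mutants with slightly
different resistance invade (or not) a resident population at its endemic
equilibrium. The invasion fitness of a juvenile-trait mutant $r_J^m$ is

$$
w_J(r_J^m) = \frac{g(r_J^m)\,a(r_J^m, r_A)\,(1-qN^*)\,A_J^m}
 {(b_A+\alpha)(b_J^m+g^m+\alpha)(b_A+\lambda_A^*)(b_J^m+g^m+\lambda_J^*(r_J^m))} - 1,
$$

with
$A_J^m = (b_A+\alpha)(b_J^m+g^m+\alpha) + f(b_J^m+g^m+\alpha)\lambda_A^* +
f \lambda_J^*(r_J^m)(b_A+\lambda_A^*)$, and symmetrically for the adult
trait. Asterisks denote resident endemic-equilibrium quantities, which are
frozen while the mutant trait varies; $\lambda_i^*(r^m) =
\beta_0(1-r^m)(I_J^*+I_A^*)$. Two properties anchor correctness and are
tested over hundreds of random parameter draws: the resident is exactly
neutral in its own environment ($|w| < 10^{-10}$), and the sign of $w$
matches the dominant eigenvalue of the mutant's linearised 4-by-4 invasion
subsystem computed independently.

Selection gradients are central finite differences of $w_i$ in the mutant
trait (step $10^{-5}$, one-sided at the trait boundaries). Co-singular
strategies — points where both gradients vanish — are found by damped Newton
iteration on the gradient field, seeded from every cell of a sign-change
lattice plus user-supplied starts, with duplicates merged within $10^{-5}$.
Evolutionary stability uses the second derivative of $w_i$ in the mutant
trait (step $10^{-4}$; magnitudes below $10^{-6}$ are flagged
indeterminate). Strong convergence stability uses the Jacobian $J$ of the
gradient field with respect to the *resident* traits: we require the
symmetric part $J + J^\top$ to be negative definite, the standard
sufficient condition for convergence under any symmetric mutational
covariance, which implies the negative-real-part eigenvalue condition under
the equal-mutation-rate assumption we make throughout. A point that is both
evolutionarily and strongly convergence stable is a continuously stable
strategy (CSS); convergence-stable but invadable points are flagged
`branching-candidate`; the remainder are repellers or saddle-like.

### Boundary and eradication-frontier attractors

Evolution frequently pins a trait at 0 or 1, so `find_cosingular()` also
scans the edges (a root of the free trait's gradient with the pinned
trait's gradient pushing outward) and the corners. One further attractor
type is needed: because $R_0(1, 1) = 0$, sufficiently high resistance can
eradicate the pathogen, and at high transmissibility selection pushes both
traits up against the $R_0 = 1$ frontier. Where the closed-form $R_0$
crosses 1 along an edge and the endemic-side flow points at the frontier,
the crossing is reported as an `eradication-frontier` attractor; two edge
crossings around the same disease-free pocket (for example at the
full-resistance corner) are merged into one representative point. On the
disease-free side of the frontier the phase-plane flow is defined by mutant
invasion into the *disease-free* resident, where fitness reduces to
$g^m a^m (1-qN^*)/((b_J^m+g^m)\,b_A^m) - 1$: with costs active it points
towards lower resistance, so the frontier is attracting from both sides.
The exported `invasion_fitness()` keeps the stricter contract that the
resident must be endemic.

Phase planes (`phase_plane()`) evaluate the gradients on a lattice
(default 21 per axis), contour the nullclines, and label basins by
integrating the normalised gradient flow through a bilinear interpolation
of the lattice field — a deliberate approximation that keeps a full basin
map to one equilibrium solve per lattice point; its resolution is therefore
that of the lattice, which is ample for counting basins and locating a
monotone separatrix, but not for micrometre-accurate basin boundaries.

## Evolutionary simulations

Adaptive dynamics assumes rare mutations of vanishing effect. To verify
its predictions without those assumptions, `simulate_evolution()` runs a
stochastic trait-substitution process on a discrete trait grid (step 0.02,
51 phenotypes per trait): each event integrates the multi-phenotype
ecological dynamics for a fixed window (100 time units), culls phenotypes
below density $10^{-5}$, and introduces one mutant at density $10^{-4}$ —
the parent is drawn with probability proportional to its birth output
$a(1-qN)(S_A + f I_A)$, one trait moves one grid step in a random
direction, reflecting at the boundaries. All phenotypes share the
density-dependence pool $qN$ and the force of infection sums infecteds over
phenotypes. Runs are deterministic given a seed. The event count is the
run-length knob: roughly 1,200–2,000 events are needed to cross the trait
square at the default grid step, and the package's own acceptance checks
use those sizes with five spread starts and seeds.

Two caveats that the simulations expose deliberately: first, the ecological
window is a fixed horizon rather than an equilibrium solve, which bounds
runtime and mimics overlapping ecological/evolutionary timescales; results
are insensitive to doubling the window. Second, if the trait state enters
the region where $R_0 < 1$, the pathogen goes extinct *in the simulation*
(densities decay below floating-point resolution), after which only the
cost side of selection operates. This is faithful to the model — there is
no external infection reservoir — but it means simulation starts intended
to probe an endemic attractor must themselves lie in the endemic region of
the trait square, and the package chooses its verification starts
accordingly.

What the simulations emulate is the model's own stochastic mutation
process; they do not add demographic noise (densities are continuous), age
within stages, assortative mixing, recovery, pathogen evolution or
stage-specific virulence, so agreement between simulation and invasion
analysis validates the adaptive-dynamics machinery, not those external
features of real systems.

## Sweeps and bistability

`run_sweep()` tracks singular strategies along a parameter grid, either by
continuation (previous attractors seed the next root search; fast, follows
a branch through hysteresis) or by global multistart at every point; the
two modes agree wherever a single attractor exists, and sweeps record the
resident densities at each attractor. `detect_bistability()` uses global
multistart and reports runs of grid points with at least two classified
attractors, plus a stage-divergence check: in every bistable region we
find, the coexisting attractors are high-resistance-at-both-stages versus
low-at-both, never high at one stage and zero at the other.

Headline behaviour reproduced by the test suite at desk scale (21-point
sweeps, 5 simulation seeds):

* sterility-virulence sweeps at $\beta_0 = 8$: no resistance at low
  virulence, a sharp rise then plateau; juvenile resistance exceeds adult
  when juvenile resistance costs juvenile mortality and adult resistance
  costs reproduction; the reverse whenever juvenile resistance costs
  reproduction, which also yields the lowest juvenile resistance of all
  wirings;
* mortality-virulence sweeps at $f = 1$: resistance peaks at intermediate
  $\alpha$ (low $\alpha$: little cost of infection; high $\alpha$: short
  infectious period suppresses prevalence) and vanishes at both ends;
* high transmissibility: bistability between high resistance at both
  stages (an eradication-frontier attractor) and zero resistance at both,
  with basins separated by a monotone boundary.

## Numerical choices

* Equilibria: `lsoda` with analytic Jacobians, integration chunks of 150
  time units, Newton polish to residuals $<10^{-13}$, eigenvalue stability
  check; continuation hints (Newton from a neighbouring solution, verified
  positive and stable before acceptance) accelerate grids and sweeps.
* Epidemic threshold: bisection on $\beta_0$ with continuation seeding, so
  endemic-branch detection stays sharp arbitrarily close to $R_0 = 1$.
* Finite-difference steps: $10^{-5}$ (gradients), $10^{-4}$ (second
  derivatives and gradient Jacobians); classifications are checked to be
  invariant to halving these steps.
* Degenerate inputs: non-viable hosts report `kind = "extinct"`; $R_0 \le
  1$ residents report the disease-free equilibrium; solver failures raise a
  classed error (`ageresist_solver_failure`) rather than returning a wrong
  state; duplicate singular points are resolved by keeping the smaller
  gradient residual.

## A worked example

```{r css, eval = FALSE}
p <- host_params(beta0 = 8, f = 0.1, alpha = 0,
                 juvenile_target = "juvenile_mortality",
                 adult_target = "reproduction")
find_cosingular(p)
pp <- phase_plane(p, grid_n = 21)
autoplot(pp)
sim <- simulate_evolution(p, rJ_init = 0.1, rA_init = 0.8,
                          n_events = 2000, seed = 1)
autoplot(sim)
```

The singular-strategy table reports a single interior CSS near
$(r_J^\*, r_A^\*) \approx (0.60, 0.49)$, the phase plane shows one basin
covering the endemic region, and the simulation's mean traits settle within
one grid step of the CSS.

## Known limitations

* Interior eradication-frontier attractors (frontier arcs not touching an
  edge of the trait square) are not searched for explicitly; none arise in
  the regimes analysed, and basin integration would still reveal them.
* The basin map inherits the lattice resolution of the phase plane.
* Near-threshold residents ($R_0$ within $\sim 10^{-8}$ of 1) sit at the
  edge of the endemic solver's resolution; the threshold itself is located
  by the dedicated continuation bisection, not by equilibrium solves.
* The model excludes recovery, simultaneous sterility and mortality
  virulence, stage-specific virulence, assortative mixing and pathogen
  (co)evolution by design.
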