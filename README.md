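# ageresist

Why are adults more resistant to infection than juveniles in some species,
and less resistant in others? When innate, infection-preventing resistance
can evolve separately at each life stage, the answer depends on which other
life-history trait each resistance trait trades off against. `ageresist`
implements an age-structured susceptible–infected model in which juvenile
and adult resistance coevolve subject to costs paid through maturation,
reproduction or mortality, and provides the full analysis toolchain:
ecological equilibria and $R_0$, evolutionary invasion analysis (selection
gradients, co-singular strategies, evolutionary and strong convergence
stability, phase planes with basins of attraction), stochastic
trait-substitution simulations, and parameter-sweep drivers with
bistability detection.

The package is aimed at evolutionary epidemiologists and ecologists who
want a tested, scriptable implementation of stage-structured
resistance-evolution analyses.

## The model in brief

Susceptible/infected juveniles and adults ($S_J, S_A, I_J, I_A$; total
$N$) mature at rate $g$, reproduce at rate $a(1-qN)$ (infected adults at a
fraction $f$), die at rates $b_J, b_A$ (infected hosts at an extra
$\alpha$), and become infected at force of infection
$\lambda_i = \beta_0(1-r_i)(I_J+I_A)$, where $r_J, r_A \in [0,1]$ are the
evolving resistance traits. Resistance is costly: each trait degrades one
wired life-history trait through the saturating cost
$c_1(1-e^{c_2 r})/(1-e^{c_2})$. The pathogen invades a host population iff

$$R_0 = \frac{\beta_0 (ag-b_A(b_J+g))\left[(1-r_J)(b_A+\alpha+g)b_A +
(1-r_A)g(b_J+\alpha+g)\right]}{ag(b_A+\alpha)(b_A+g)(b_J+g+\alpha)q} > 1 .$$

Mutant invasion fitness against the endemic resident defines selection
gradients on the two traits; their common zeros (co-singular strategies)
are classified as continuously stable strategies, repellers, saddles,
branching candidates, boundary attractors or eradication-frontier
attractors. Trait-substitution simulations verify the predictions without
the rare-/small-mutation assumptions.

## Worked example

```r
library(ageresist)

p <- host_params(beta0 = 8, f = 0.1, alpha = 0,
                 juvenile_target = "juvenile_mortality",
                 adult_target = "reproduction")

r0(p)$R0
#> [1] 4.8

find_cosingular(p)
#> # A tibble: 1 x 12
#>   rJ_star rA_star boundary es_J  es_A  strongly_convergent classification
#>     <dbl>   <dbl> <chr>    <lgl> <lgl> <lgl>               <chr>
#> 1   0.604   0.494 none     TRUE  TRUE  TRUE                CSS
#> # i 5 more variables: attractor <lgl>, grad_resid <dbl>, N_star <dbl>,
#> #   I_star <dbl>, R0 <dbl>
```

With transmissibility $\beta_0 = 8$ and strong sterility virulence
($1-f = 0.9$), a pathogen invading a fully susceptible population causes
4.8 secondary infections, and the two resistance traits evolve to a single
continuously stable strategy at $(r_J^*, r_A^*) \approx (0.60, 0.49)$:
juvenile resistance (costing juvenile mortality) settles *above* adult
resistance (costing reproduction). `phase_plane(p) |> autoplot()` draws the
nullclines and basin; `simulate_evolution(p, n_events = 2000, seed = 1)`
confirms the attractor by stochastic simulation, and
`run_sweep(p, "f", seq(1, 0, length.out = 21))` traces how the strategy
responds to sterility virulence. A command-line wrapper over the same
functions ships at `system.file("scripts", "ageresist", package =
"ageresist")` with subcommands `r0`, `equilibrium`, `singular`,
`phaseplane`, `sweep`, `simulate` and `reproduce-figure`.

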