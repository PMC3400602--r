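# homeostat

Design and analysis of synthetic gene circuits for **artificial tissue
homeostasis**: genetically programmed stem cells that maintain a steady
population of differentiated (e.g. insulin-producing beta) cells despite
continuous cell death. The package implements four circuit designs of
increasing sophistication and the computational framework used to evaluate
and optimise them.

## The models

**Deterministic tier.** Stem cells S divide under growth-arrest feedback and
mature into committed cells; all feedback terms are Hill functions. The
reduced two-population model (system 2) is

    F  = k_c · S · H⁺(S; θ_S) · H⁻(C; θ_C)
    dS/dt = k_div · S · H⁻(S; θ_G) − F
    dC/dt = F − k_kill · C

with `H⁺(x;K) = xⁿ/(Kⁿ+xⁿ)` and `H⁻ = 1 − H⁺`. The four-population model
(system 1) resolves the slow maturation chain S → E → P → B whose feedback
delay can destabilise homeostasis into population oscillations.

**Stochastic spatial tier.** Cells on a 2-D lattice carry per-cell circuits
advanced by the chemical Langevin equation (two-stage stochastic
Runge–Kutta; cell volume Ω sets the noise amplitude) and communicate
through diffusing quorum signals. System 2 gates an irreversible toggle
switch on the product of an uncommitted-density activator and a
committed-density inhibitor; system 3 additionally gates commitment on an
asynchronous per-cell oscillator; system 4 uses a transient
lateral-inhibition "throttle" signal secreted while a neighbour's toggle is
switching. A Gibson next-reaction simulator covers the mechanistically
detailed reaction network.

**Analysis tier.** Homeostasis performance is the S/N of the committed-cell
count (inverse coefficient of variation). RS-HDMR decomposes ensemble
outputs into first/second-order component functions with variance-based
sensitivity indices; a genetic algorithm optimises the density-sensing
(UPC) module against a step-function objective on forward *and* reverse
density sweeps (suppressing hysteresis); local sensitivity signatures are
clustered to map parametric control of hysteresis; module phenotypes
(oscillator period and variability, throttle switching images) are compared
with raw rate constants as predictors of S/N; constrained Bayesian-network
inference integrates rates, phenotypes and performance.

## Worked example

```r
library(homeostat)

# reduced-model equilibrium and the committed-population power law
eq <- find_equilibria("system2", population_params(), n_starts = 50, seed = 1)
scan <- committed_powerlaw_scan(ratio_grid = 10^seq(-2, -0.5, length.out = 8))
powerlaw_exponent(scan)$slope

# spatial stochastic runs: toggle-only design vs oscillator-gated design
b2 <- run_simulation(sim_config(2, T = 600, seed = 1))
b3 <- run_simulation(sim_config(3, T = 600, seed = 1))
signal_to_noise(b2)$snr; en_masse_episodes(b2)$any
signal_to_noise(b3)$snr; en_masse_episodes(b3)$any
```

which prints (up to the equilibrium report formatting):

```
S* = 59.85  C* = 132.20  (stable)      # unique homeostatic equilibrium
power-law exponent: 1.000              # committed pool ~ k_div/k_kill at low ratio
system 2: S/N = 2.49, en-masse episodes: TRUE
system 3: S/N = 5.59, en-masse episodes: FALSE
```

The toggle-only design (system 2) commits *en masse* — population-wide
quorum cues synchronise the cells, the committed count see-saws, and S/N is
low. Gating commitment on each cell's oscillator phase (system 3) lets only
a fraction of cells respond to any one cue, roughly doubling-to-tripling
S/N under identical conditions.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/homeostat.R", package="homeostat"))')" \
    simulate --fixture sys3-default --seed 7 --out run-out
```

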