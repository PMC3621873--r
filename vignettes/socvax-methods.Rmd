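---
title: "Modelling social influence in vaccination decisions: methods and design"
author: "socvax authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social influence in vaccination decisions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Voluntary vaccination programs succeed or fail on individual decisions.
Classic game-theoretic treatments model each person as a cost minimizer:
vaccinate when the perceived risk of infection outweighs the relative cost
of the vaccine. In reality decisions are also social — people are swayed by
what friends, family and colleagues decide. `socvax` implements a hybrid
decision model on a weighted social contact network that combines both
channels, and couples the resulting steady-state vaccination coverage to a
homogeneous-mixing SIR epidemic to quantify the consequences for disease
control.

## The decision model

Each individual $i$ holds a binary decision $d_i \in \{+1, -1\}$
(accept / reject vaccination). One iteration updates every individual as
follows.

**Cost channel.** The perceived infection risk is
$\lambda_i = \beta_{\mathrm{perc}} \cdot n^-_i / (n^+_i + n^-_i)$,
where $n^+_i, n^-_i$ count vaccinated and unvaccinated neighbours and
$\beta_{\mathrm{perc}}$ is the perceived transmission rate. Minimizing the
expected cost (vaccination cost $c_{vac}$ versus risk-weighted infection
cost $\lambda_i c_{inf}$) reduces to a threshold rule on the cost ratio
$r = c_{vac}/c_{inf}$: accept when $\lambda_i > r$, reject when
$\lambda_i < r$, keep the previous decision on an exact tie. The tie rule
matters: a free-rider whose neighbours are all vaccinated perceives zero
risk and stays unvaccinated even at $r = 0$.

**Social channel.** Under social impact theory the influence of an opinion
grows with the closeness of the sources holding it and with their number at
a diminishing rate. For each opinion $o$ we use the multi-source form
$I_o = W_o / \sqrt{n_o}$ with $W_o$ the summed edge weight to neighbours
holding $o$ (equivalently $\sqrt{n_o}$ times their mean closeness). The
normalized discrepancy $\Delta_i = (I_+ - I_-)/(I_+ + I_-) \in [-1, 1]$
feeds a Fermi (logistic) function,
$q_i = 1/(1 + e^{-\Delta_i/\kappa})$, giving the probability that the
socially formed opinion $S_i$ is acceptance. The responsiveness $\kappa$
controls how sharply the dominant camp wins.

**Conformity.** With probability $p$ (the conformity rate) the individual
adopts $S_i$; otherwise the cost-minimized choice stands. $p = 0$ is a pure
cost-based decider, $p = 1$ an absolute social follower.

```{r}
library(socvax)
net <- generate_network(preset = "highschool", seed = 1)
res <- run_decision_dynamics(net, decision_params(r = 0.1, p = 0.8, w0 = 0.5),
                             seed = 1)
res$coverage
```

### Parameters, defaults, and why

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `r` | cost ratio $c_{vac}/c_{inf}$ | swept 0–1 | the decision threshold; dimensionless |
| `p` | conformity rate | swept 0–1 | 0 = cost-only, 1 = social follower |
| `beta_perc` | perceived transmission rate | $R_0\gamma = 1.4 \times 0.312$ | perception assumed accurate, matching the actual epidemic |
| `kappa` | Fermi responsiveness | 0.1 | sharp but non-degenerate opinion dominance; the normalized discrepancy makes this scale-free in the weights |
| `w0` | initial willingness | 0.3 / 0.5 / 0.7 | three levels spanning reluctant to favourable populations |
| `max_iters`, `window` | horizon and averaging window for $p > 0$ | 200, 50 | trajectories stabilize well before 150 iterations on 800-node networks |
| `sit_exponent` | source-count exponent in $I_o$ | 0.5 | the diminishing-returns impact form; 1 gives plain weighted sums as a one-flag alternative reading |

The exact functional form of the impact strength and the value of $\kappa$
are genuinely open modelling choices here; both are exposed as parameters
(`sit_exponent`, `kappa`) rather than hard-coded, and the discrepancy is
normalized so that $\kappa$ is comparable across networks with different
weight magnitudes. Whether perceived risk should weight neighbours by
closeness is equally open; plain counts are the default with
`weighted_risk = TRUE` as the variant.

### Update scheduling and steady states

The default scheme is synchronous: every individual updates from the
previous state simultaneously. At $p = 0$ the dynamics are then fully
deterministic, and iteration stops at a fixed point or a detected 2-cycle
(steady-state coverage is averaged over the cycle). Synchronous best
response in this free-riding game is oscillatory by nature: for
$0 < r < \beta_{\mathrm{perc}}$ essentially the whole population alternates
between accepting and rejecting, so the cycle-averaged coverage sits near
0.5 across that band, dropping to 0 once $r$ exceeds
$\beta_{\mathrm{perc}}$ and pinned at 1 for $r = 0$ from a willing start.
Because cycle membership shifts by a few individuals as $r$ moves, the
coverage-versus-$r$ profile is non-increasing only up to a granularity of
about 1% of the population — the tests assert it at that granularity. An
asynchronous random-order scheme (`update_scheme = "asynchronous"`) is
provided for robustness checks; it damps the oscillation.

For $p > 0$ the chain is stochastic; runs span `max_iters` iterations and
report the mean coverage over the final `window` iterations. All
randomness in a run — initialization, social-opinion draws, conformity
draws — comes from one seeded stream consumed in a fixed order (per step:
opinion uniforms for all nodes, then conformity uniforms), so every run is
exactly replayable; $p = 0$ runs consume no draws beyond initialization.

## The contact network

The study population is a dense, clustered school-type contact network.
Only two summary statistics of such networks are targeted by the
generator's `"highschool"` preset: mean degree 35 and mean edge weight 115
interaction units, on 800 nodes. The generator builds a ring lattice with
$\lfloor \bar d/2 \rfloor$ neighbours per side, tops it up with random
edges so the edge count equals $n\bar d/2$ exactly, and rewires each edge
with probability 0.1, rejecting rewirings that would create loops or
duplicates so the mean degree is preserved exactly (a small-world
construction — school proximity networks are dense and clustered).
Erdős–Rényi and preferential-attachment topologies are available for
sensitivity checks. Weights are i.i.d. log-normal with `sdlog = 1` and
`meanlog` solved so the mean equals the preset target: contact-frequency
counts are positive and right-skewed, and only the published mean is
matched — the degree and weight *dispersions* of the generated networks
are the generator's own, as the real network's dispersions are not
published. Generation retries deterministically until connected, so no
node is isolated.

What passing the calibration tests shows is therefore limited: simulated
coverage levels are faithful to the model on a network with realistic
density and closeness scale, not to the exact empirical topology.

## The epidemic module

Vaccinated individuals are removed from the susceptible pool before
integration (an all-or-nothing, perfectly effective vaccine). The SIR
equations with force of infection $\beta I / N$ are integrated with an
adaptive solver (relative tolerance $10^{-8}$), with the horizon doubled
until the infectious count has peaked and fallen below $10^{-6} N$, and
conservation of $S + I + R$ checked to $10^{-6} N$ along the way. The
recovery rate default is $\gamma = 0.312$ (a 3.2-day infectious period,
calibrated to 2009 H1N1 influenza); the reproduction-number default is
$R_0 = 1.4$, consistent with H1N1 estimates, with $\{1.2, 1.6, 2.0\}$ as
the sensitivity set, and $\beta = R_0\gamma$. The default seeding is
$I_0 = 10^{-4} N$.

Two deliberate numerical choices:

* `final_size_fixed_point()` solves the classic final-size relation
  $z = 1 - e^{-R_0(1-V)z}$ by damped fixed-point iteration to $10^{-10}$.
  It is the zero-seed limit of the ODE and serves as its analytic
  cross-check.
* Near the critical point $R_0(1-V) = 1$ the ODE's final size is dominated
  by the seed itself (of order $\sqrt{2 I_0/N}$, about 1.4% of the
  remaining pool at $I_0/N = 10^{-4}$), while the analytic limit is 0. The
  ODE-versus-analytic agreement tests therefore use $I_0/N = 10^{-7}$,
  where the seed contribution is below the $10^{-3}$ comparison tolerance
  even at criticality; threshold-bracketing behaviour is tested at the
  default $I_0/N = 10^{-4}$.

```{r}
theta <- vaccination_threshold(1.6)
integrate_sir(sir_params(beta = 1.6 * 0.312, V = theta + 0.05))$attack_rate
```

## Monte Carlo sweeps

`run_sweep()` runs a full factorial over $(r, p, w_0, R_0)$ with a shared
network, 50 replicates per cell by default (standard errors of cell means
are then below about 0.02 in coverage), and couples each cell's *mean*
coverage to the SIR attack rate at that $R_0$ — the population-level
convention; per-replicate coupling would propagate replicate noise into
the epidemic stage. Replicate seeds are a documented stable hash of the
master seed and the cell indices (`cell_seed()`), deliberately excluding
the $R_0$ index so sensitivity runs at different $R_0$ share decision
seeds and differ only through the model. `coverage_phase_profile()`
extracts the willingness-to-coverage curve among social followers and
locates the critical willingness as the midpoint of the largest jump
between adjacent levels — a deliberately simple estimator that needs no
parametric form for the transition.

Problem sizes used by the package's own test suite: unit tests run on
60–200-node networks with degree 6–12; the end-to-end checks use the full
800-node preset with 50–100 replicates per condition, which keeps the
whole suite in the low minutes on a single core.

## Known limitations

* Disease transmission is homogeneous-mixing; the network shapes decisions
  only. Network-structured transmission, waning immunity, imperfect
  vaccines and demography are out of scope.
* Influence is local (neighbours only) and individuals are passive
  recipients of it; no public-media "super node", no separate
  decision/transmission layers, no learning across seasons.
* The synchronous cost-only dynamics oscillate rather than settle at the
  mixed free-riding equilibrium; the cycle-average is reported as the
  steady-state coverage, and the asynchronous scheme is the damped
  alternative.
* The generator matches two published means of the study network, nothing
  more; results on it are statements about the model, not about the
  original school population.
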