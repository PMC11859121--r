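---
title: "Modelling the evolution of parochial social learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of parochial social learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parsocial)
```

## The question

Why would a learner ever *discard* information just because it comes from
someone who looks different? `parsocial` simulates a population in which this
similarity bias — parochial social learning — can evolve, and lets you map
the conditions under which it is adaptive: individual learning must be
error-prone, the population must be diverse enough that blindly copying
strangers is risky, and identity markers must be reliable enough cues of who
faces the same adaptive problem as you.

## The model

A population of $N$ agents is divided into two intermixed groups; a
proportion $p$ belongs to group 0. Each agent carries five heritable traits:

* its **group** $T_i \in \{0, 1\}$ — hidden membership that determines which
  behaviour pays;
* a visible binary **marker** $m_i$, matching the group with probability $e$
  (otherwise drawn from the population marker frequencies, so marker
  frequencies are comparable across reliability conditions);
* **parochialism** $\pi_i \in [0,1]$ — the probability of excluding a
  prospective learning target that does not display the agent's own marker;
* **reliance on social learning** $s_i \in [0,1]$ — the weight placed on
  socially acquired information;
* a **social learning strategy** $L_i$: unbiased (UT), conformist (CT), or
  pay-off-biased (PT) transmission.

Behaviour is a point $x_i \in \mathbb{R}^2$. Each group has an optimum
$x^*_g$ on the unit circle; the optima subtend an angle
$\Delta\theta \in [0, \pi]$ (we place them symmetrically at
$\pm\Delta\theta/2$, which makes the groups statistically exchangeable —
several of the package's tests rely on that symmetry). At $\Delta\theta = 0$
the population is effectively homogeneous; at $\Delta\theta = \pi$ what is
optimal for one group is maximally wrong for the other. Two dimensions are
the minimal space in which an agent can be close to one optimum without that
forcing its distance to the other, avoiding the path-dependence a
one-dimensional trait would induce.

Pay-off is Gaussian in the distance to the agent's own optimum,

$$w_i = \exp\!\left(-\frac{\lVert x_i - x^*_{T_i}\rVert^2}{d}\right),$$

with $d > 0$ the selection-intensity denominator (smaller $d$, harsher
selection). Any constant factor conventionally written inside such a
denominator is absorbed into $d$.

Generations are discrete and non-overlapping. Each step has four stages:

1. **Reproduction.** Each group produces offspring equal to its own size, so
   group sizes never change. A parent is drawn by rejection sampling: a
   uniformly chosen group member reproduces with probability $w_i/w_{\max}$,
   which makes the stationary selection probability exactly
   $w_i / \sum_j w_j$. Offspring inherit $s$, $\pi$ and $L$ with mutation:
   with probability `mu_cont` a continuous trait gains a
   $\mathcal N(0, \texttt{delta\_mut}^2)$ perturbation, truncated to
   $[0,1]$; with probability `mu_strat` the strategy is redrawn uniformly
   from the allowed set.
2. **Model choice.** Each offspring observes `n_targets` members of the
   parent generation, sampled uniformly without replacement from the whole
   population, then excludes each unlike-marked target independently with
   probability $\pi_i$. A highly parochial agent can end up with nothing to
   copy.
3. **Learning.** If targets survive, the agent selects a social trait value
   by its strategy (UT: a random target; CT: the marginal, componentwise
   median; PT: the highest-pay-off target, ties uniform) and blends it with
   an individual trial-and-error draw
   $\mathcal N_2(x^*_{T_i}, \sigma^2 I)$:
   $x_i = s_i\,x^{\text{soc}} + (1 - s_i)\,x^{\text{ind}}$. With no
   surviving targets the agent relies exclusively on the individual draw.
4. **Pay-off acquisition**, after which the parent generation is discarded.

Founders are non-parochial pure individual learners ($s = \pi = 0$,
strategy UT).

A useful closed form anchors the whole fitness scale: a pure individual
learner's squared distance to the optimum is $\sigma^2\chi^2_2$, so its
expected pay-off is $d/(d + 2\sigma^2)$ by the $\chi^2$ moment generating
function. At the defaults ($d = 1$, $\sigma = 0.5$) that is $2/3$ — the
floor that social learning has to beat. The acceptance suite verifies the
simulator against this oracle by Monte Carlo at $10^6$ draws.

## Parameters, defaults, and why

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `N` | population size | 500 | large enough that drift does not swamp selection; sweeps and tests use 300 for speed |
| `p` | share in group 0 | 0.5 | equal groups unless majority/minority structure is the question |
| `delta_theta` | optima separation (rad) | 0 | homogeneous baseline |
| `e` | marker reliability | 1 | fully informative markers |
| `sigma` | individual-learning error (unit-circle radii per axis) | 0.5 | mid-range: individual learning is noticeably error-prone (expected pay-off 2/3) without being useless |
| `d` | selection intensity | 1 | at the maximal inter-optimum distance 2, holding the wrong group's optimum pays $e^{-4} \approx 0.018$: strong but not degenerate selection |
| `n_targets` | targets observed | 5 | a small observable sample, as when learners can realistically attend to a handful of models; large enough for CT/PT to act on |
| `mu_cont` | mutation prob., continuous traits | 0.1 | small enough for selection to dominate, large enough to supply variation at desk-scale run lengths |
| `delta_mut` | mutation SD | 0.05 | same reasoning |
| `mu_strat` | strategy mutation prob. | 0.05 | same reasoning |
| `generations` | steps per run | 1000 | past the plateau of the fast regimes (see below) |

`reliance_evolvable = FALSE` clamps $s$ at 0 with mutation disabled — the
individual-learning-only control against which the pay-off benefit of social
learning is measured. `parochialism_evolvable = FALSE` (the default) holds
$\pi \equiv 0$, which is the configuration of the baseline and
diversity-collapse regimes.

## Run lengths and plateaus

Outcome measures are read at the end of a run, so the run must be long
enough for them to stop trending. How long that takes differs sharply by
regime, and the presets and acceptance checks size themselves accordingly
(all at `N = 300`):

* **Fast regimes** — selection for reliance at $\Delta\theta = 0$, and its
  collapse at large $\Delta\theta$ — plateau within a few hundred
  generations; 800 is comfortable.
* **Parochial rescue and strategy competition** involve a stochastic joint
  takeoff: reliance alone is selected against while parochialism alone is
  neutral, so the population must drift into the corner where both pay.
  Takeoff typically happens between generations 400 and 1200; we use 1600.
* **Near-neutral drift** (tiny $\sigma$) has no selection to plateau;
  instead the *across-replicate spread* of mean reliance must stabilize as
  the diffusion from the all-zero founder state fills $[0,1]$. That spread
  stops growing by about generation 1600, which is what runs in that regime
  use.
* **Pay-off-biased competition at intermediate marker reliability** is the
  slowest: the asymmetric one-group-up/one-group-down equilibria accumulate
  over thousands of generations, so those runs use 3200.

## Marker reliability and when parochialism can pay

A point worth making explicit, because it determines where interesting
dynamics live on the $e$ axis. With full parochialism a learner keeps only
same-marker targets, yet some of those are still outgroup: at equal group
sizes, a group-0 learner displaying marker 0 faces
$P(\text{target outgroup} \mid \text{same marker}) = (1 - e)/2$ under marker
re-assignment. The case worth remembering is $e = 0.5$, where a quarter of
same-marker targets are outgroup. Copying an outgroup member at
$\Delta\theta = \pi$ pays
essentially nothing ($e^{-4}$), so the expected pay-off of parochial copying
at $e = 0.5$ is roughly $0.75 \times 0.9 \approx 2/3$ — *exactly* the
individual-learning floor at the default $\sigma = 0.5$. Below that
reliability parochial social learning cannot be favoured at all; the
path-dependent multiple-equilibria dynamics of pay-off-biased transmission
therefore live at intermediate-but-higher reliabilities, and the package
probes them at $e = 0.75$.

## Numerical and design choices

* **Conformist median.** "Median trait value" is ambiguous in two
  dimensions. We use the marginal (componentwise) median — for even counts
  the per-axis mean of the two central values — which is deterministic,
  cheap, and testable against a sort-based oracle. The geometric ($L_1$)
  median would be a defensible alternative; it rarely differs by much for
  the small target counts involved, and we did not implement it.
* **Marker transmission.** Markers are re-assigned at birth by the $e$ rule
  applied to the offspring's (inherited) group. Copying the parent's marker
  verbatim would let the marker–group correlation drift away from $e$,
  breaking comparability across runs at fixed $e$; strict copying remains
  available via `marker_inheritance = "inherit"`.
* **Deterministic group counts.** Groups get exactly `round(N * p)` and the
  remainder at initialization. A Bernoulli assignment would add between-run
  variance in group sizes that the model then freezes forever; fixing the
  counts removes that nuisance without changing anything else.
* **Initial strategy.** Every run starts from pure unbiased transmission,
  so `allowed_strategies` must contain `"UT"`; CT and PT enter only by
  mutation and then compete.
* **Randomness.** All stochastic stages consume R's global RNG; `run()`
  seeds it from `params$seed` and restores the caller's RNG state on exit,
  so a trajectory is a pure function of its parameter object and the
  session stream is never clobbered. Replicate $r$ of a batch derives its
  seed as `base_seed + r - 1` (mod $2^{31}-1$); sweep combination $c$ adds a
  stride of $10007(c-1)$. Replicates therefore reproduce identically alone,
  in batches, reordered, or in parallel.
* **Two engines.** The generation loop exists twice: a compiled core (used
  by default; roughly three orders of magnitude faster) and a pure-R
  reference built directly from the exported primitives
  (`reproduce()`, `choose_and_filter_targets()`, `learn()`, ...). Both
  implement the identical procedure and are cross-checked in the test suite
  on exact fixed points (no mutation, no error: every generation must sit on
  the optima with pay-off 1) and on distributional signatures. They consume
  the RNG stream in different orders, so trait-level results for one seed
  differ between engines by design.
* **Degenerate inputs.** $\sigma = 0$ collapses the individual draw to the
  optimum exactly; `generations = 0` records only the founder generation;
  a single-member group always selects that member as parent; empty
  filtered target sets route to pure individual learning *before* the
  strategy rules, which treat an empty set as a contract violation.

## What the simulator emulates — and what it does not

Runs emulate the study conditions of the underlying model: two fixed
subpopulations with static, group-specific optima, binary one-dimensional
identity, marker reliability held constant, and learning as a single event
per lifetime. Passing tests show that the implementation reproduces the
model's internal logic and its qualitative regime structure. They do not
show anything about real populations: real identities are
multidimensional and context-dependent, environments change within and
between generations, interaction is homophilous rather than
uniformly mixed, and learners revisit their behaviour repeatedly. The
majority/minority results in particular assume minorities cannot
preferentially reach ingroup models; where assortment is strong that
assumption fails, as the model's own authorship tradition is careful to
note.

## A worked run

```{r rescue, fig.width = 6, fig.height = 4}
params <- model_params(N = 300, generations = 1600, sigma = 0.5,
                       delta_theta = pi, e = 1,
                       parochialism_evolvable = TRUE, seed = 5)
res <- run(params)
res$final
```

Both groups end with high reliance on social learning and near-total
parochialism — the rescue in one run. The preset sweeps map the whole
surface:

```{r sweep, eval = FALSE}
spec <- preset("parochial_rescue", n_reps = 20, base_seed = 1)
result <- run_sweep(spec, workers = 1)
plot_sweep(result, x = "delta_theta", y = "mean_reliance", colour = "e")
```

## Known limitations

* Temporally varying environments are out of scope: optima are fixed for
  the lifetime of a run.
* Identity is a single binary marker; no multidimensional or flexible
  identity.
* No spatial structure or homophilous assortment of interaction partners.
* No convergence auto-detection: the run length is configuration, chosen
  per regime as described above.
* The conformist rule is the marginal median only.
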