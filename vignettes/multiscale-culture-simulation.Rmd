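---
title: "Multi-scale stochastic simulation of interferon signaling in a cell culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale stochastic simulation of interferon signaling in a cell culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnabm)
```

## The problem

Dendritic cells in a culture detect viral infection through the cytosolic
sensor Rig-I, transcribe interferon-beta, and secrete it into the medium.
Secreted interferon diffuses, binds surface receptors on other cells, and
up-regulates their Rig-I expression, closing a paracrine positive feedback
loop.  Only a small subpopulation of cells (the *early responders*, on the
order of one percent) carries enough constitutive Rig-I protein to start
transcribing interferon right after infection; everything that follows —
whether and when the rest of the culture wakes up — depends on stochastic,
spatially local interactions between single cells and small numbers of
molecules.

Simulating this coupled system faithfully needs three ingredients, which are
the three computational layers of this package:

1. **Stochastic lattice diffusion** of the extracellular cytokine, exact
   down to single molecules but efficient at the millions-of-molecules
   scale (`diffusion_step()`).
2. **Exact stochastic intracellular kinetics** per cell via the Gillespie
   algorithm, *synchronized* so that the environment may change a cell's
   reaction rates at preset times without breaking the Markov property
   (`run_sync_ssa()`, `step_culture()`).
3. **An agent-based culture** that couples the two through secretion and
   receptor binding, with a multiplicity-of-infection (MOI) sweep harness
   (`run_culture()`, `moi_sweep()`).

The layers have intrinsically different time scales — molecular diffusion
across a cell diameter takes seconds, gene expression minutes to hours —
and the synchronization scheme is what lets each run at its own resolution.

## Stochastic diffusion on a lattice

Space is discretized into squares of side $\delta$ equal to one cell
diameter; each square holds a well-mixed molecule count $n$.  Per time step
$\Delta t$, each molecule leaves its square with probability $p$ and picks
one of the four (2D) or six (3D) neighbors uniformly; boundaries are
periodic.  Rather than deciding per molecule, one step per square draws:

* the emigrant count $n_d \sim \mathrm{Binomial}(n, p)$,
* the north/south vs east/west split $\sim \mathrm{Binomial}(n_d, 1/2)$,
* the north-vs-south and east-vs-west splits, each
  $\sim \mathrm{Binomial}(\cdot, 1/2)$,

so each direction receives a $\mathrm{Binomial}(n, p/4)$ marginal and
exactly four random variates are consumed per occupied square (empty
squares are skipped; skipping draws for $n = 0$ changes no distribution).
Binomial draws are inverse-CDF lookups in a precomputed cumulative table
(`build_cumulative_binomial_table()`), found by binary search in
$O(\log n)$; with $p = 1/2$ a single table serves both the emigration draw
and all direction splits.  Counts above the table capacity `N_max`
(default 1024) switch to a normal approximation
$\mathrm{round}(np + z\sqrt{np(1-p)})$, clamped to $[0, n]$, with $z$
obtained from the same uniform variate — so the variate budget is
unchanged and conservation stays exact.  Updates are synchronous: emigrants
are computed from a frozen copy of the grid and added into a fresh
accumulator, making within-step ordering irrelevant and total count
conservation an exact integer identity.

In 3D the default scheme draws the axis by a $\mathrm{Binomial}(n_d, 1/3)$
split followed by halvings (six variates per voxel, two tables); an
alternative repeat-axis scheme (`diffusion_step_3d_repeat()`) needs only
the $p = 1/2$ table, splitting emigrants into X, Y, Z and a "repeat"
quarter that is re-split until empty.  Both produce the exact
$\mathrm{Binomial}(n, p/6)$ per-direction law; the repeat variant trades a
deterministic variate budget for lower memory.

## Calibration: linking $\delta$, $\Delta t$, $D$ and $p$

The diffusion coefficient $D$ ties the step length to physical time through
$\Delta t = \delta^2 / (c\,D)$ with a dimensionless constant $c$ that
depends on $p$ and the dimensionality.  To measure $c$, the package runs
the *deterministic* (mean-field) variant of the step — each square keeps a
fraction $1-p$ and sends $p/4$ to each neighbor — from a point source on a
201×201 lattice and fits the center concentration to $a/t$ (in 3D,
$a/t^{3/2}$).  Matching the fit to the continuum point-source solution
$u(t) = N/(4\pi D t)^{d/2}\,\delta^d$ gives $c = 4\pi a / N$ in 2D and
$c = 4\pi (a/N)^{2/3}$ in 3D, independent of $\delta$ and $D$.

Numerical choices worth stating:

* The amplitude is estimated in log space with the exponent fixed
  ($\log a = \mathrm{mean}(\log u + m \log t)$).  The two formulations of
  the fit — least squares on $a/t$ and the fixed-slope log-log line — agree
  on clean power-law data, but the log-space form weights every decade
  equally, so the estimate is set by the late-time power law rather than by
  the first tens of steps, which still carry the lattice transient.  With
  the default window (steps 10–1000) this keeps the derived $c$ within
  about 0.5% of the random-walk value $4/p$ across $p \in [0.25, 0.75]$;
  the untransformed estimator is dominated by the earliest window steps and
  can be biased by several percent at small $p$.  $r^2$ is always reported
  on the untransformed values.
* The fit window excludes the first 9 steps by default (configurable); a
  free-exponent diagnostic (`fit_power_law()`) is available but never used
  for calibration.
* 3D calibration runs use an 81³ lattice for 800 steps: large enough that
  no mass wraps around the torus within the run, long enough that the
  transient occupies a small share of the log-spaced window.
* The lazy-random-walk variance oracle predicts $c = 4/p$ (2D) and $6/p$
  (3D); the measured values agree within 2%, which is the package's
  regression bound.

When $\delta$ and $\Delta t$ are both fixed by outside considerations, the
emigration probability follows from a mass balance: integrating the
continuum Gaussian over the central square for one step gives the retained
fraction $\mathrm{erf}(\delta/(2\sqrt{4D\Delta t}))^d$, so
`solve_p_mass_balance()` returns
$p = 1 - \mathrm{erf}(\delta/(2\sqrt{4D\Delta t}))^d$.  Two approximations
separate this from the simulation-calibrated $p$: the analysis assumes all
mass starts at the square center (the simulation assumes well-mixed
squares), and it lets mass travel beyond nearest neighbors in one step.  At
$c = 8$, $d = 2$ the mass balance gives $p \approx 0.534$ against the
simulated $1/2$ — a discrepancy of well under 0.1 that rounds to 0.5.  When
the *exact* $p$ for a target $\Delta t$ is needed, `bisect_p_for_target()`
runs a half-interval search in which every trial $p$ is recalibrated by a
point-source run; $\Delta t(p)$ is monotone in $p$, so bisection converges
to arbitrary tolerance.

## The synchronized Gillespie algorithm

Each cell's six-reaction network runs as a classical Gillespie simulation:
draw the waiting time $\tau \sim \mathrm{Exp}(R)$ from the total propensity
$R$, advance, pick a reaction proportionally to its rate.  The culture,
however, changes a cell's bound-receptor count — hence its Rig-I
transcription rate — every diffusion step, from outside the cell's own
process.  The synchronized variant handles this exactly: if the drawn
$\tau$ would carry the cell past the next synchronization time, the cell
advances *to* the synchronization time, accepts the external update, and
draws a fresh waiting time from the updated rates.  The overshooting draw
is discarded outright — by memorylessness the residual time to the next
event after a rate change is a fresh exponential, so no "remaining
propensity" may be carried over (carrying it over is a different algorithm,
the next-reaction adaptation, out of scope here).  An event landing exactly
on the synchronization time is resolved in favor of the synchronization — a
measure-zero tie given a deterministic break.

The practical consequence, verified in the test suite: inserting *no-op*
synchronizations at any frequency (0.1–10 times the mean waiting time in
the tests) leaves every trajectory statistic unchanged — pooled inter-event
times stay exponential with the correct mean, per-process event shares
follow the rates, and a two-sample Kolmogorov–Smirnov test cannot tell the
synchronized runs from classical ones.

## The cell model

Each cell tracks interferon transcripts $M_I$, Rig-I transcripts $M_R$ and
Rig-I protein $P_R$ through six reactions (two transcriptions, one
translation, three first-order degradations):

| reaction | propensity |
|---|---|
| interferon transcription | $[\mathrm{infected}]\; k_{MI}^{max}\, \mathrm{hill}(P_R; K_P, h_P)$ |
| Rig-I transcription | $k_{MR}^{basal}\,\bigl(1 + (f-1)\,\mathrm{hill}(B; K_B, h_B)\bigr)$ |
| translation | $k_{tl} M_R$ |
| degradations | $d_{MI} M_I$, $d_{MR} M_R$, $d_{PR} P_R$ |

with $\mathrm{hill}(x; K, h) = x^h/(K^h + x^h)$.  Interferon transcription
is gated on infection: the sensing pathway is activated by cytosolic viral
RNA, so uninfected cells induce Rig-I (through bound receptors $B$) but
never interferon.  The basal-plus-induced composition of the Rig-I rate is
chosen so that $B = 0$ gives exactly the constitutive rate and
$B \to \infty$ exactly $f$ times it, matching the definition of the
fold-induction ratio $f$.

Per diffusion step, each cell also:

* **secretes** $\mathrm{Poisson}(M_I\, k_{sec})$ new interferon molecules
  into its own lattice square (transcripts are templates, not consumed;
  secretion is immediate, so the synthesis expectation per step *is* the
  secretion expectation; the Poisson law around it is our choice of
  minimal-assumption counting noise);
* **exchanges receptors** with its square: each free interferon molecule
  binds with probability $1 - e^{-k_{on} F \Delta t}$ (binomial thinning —
  exact for pseudo-first-order kinetics over one step — capped at $F$ so
  receptors never go negative) and each bound receptor unbinds with
  probability $1 - e^{-k_{off}\Delta t}$.  $F + B$ is invariant for the
  whole run, and the global ledger
  $\sum \mathrm{grid} = \mathrm{secreted} - \mathrm{net\ bound}$ holds as
  an exact integer identity after every step.

The within-step order is SSA → secretion → binding → diffusion.  Any fixed
order is defensible; this one lets newly secreted molecules bind locally
before they disperse, which is precisely the locally-high-concentration
mechanism that makes a single secreting cell able to wake its neighbors.

## The culture, its defaults, and what they emulate

`culture_config()` defaults to the headline setting: a 40×40 lattice of
20 µm squares holding 200 randomly placed, immobile cells, one cell per
square at most, simulated for 10 hours.  Infection is Poisson adsorption —
a cell with at least one virion is infected, so the infected fraction is
$1 - e^{-\mathrm{MOI}}$.  Early responders are realized as a two-point
initial-$P_R$ law: each cell independently starts at an elevated Rig-I
protein level (above the interferon half-induction level $K_P$) with
probability 1%, at baseline otherwise; a log-normal alternative with the
same exceedance fraction is available.  Infected early responders differ
from other infected cells in nothing but this initial level.

Every rate in `dc_rate_params()` is *illustrative configuration*, not a
measured constant: the parameter values behind the original experimental
system are not part of this package's inputs.  The bundled set was chosen
once, on biological plausibility and on reproducing the qualitative
phenomenology the model exists to show, and is documented here:

* mRNA half-lives of ~23 min ($d_{MI} = d_{MR} = 5\times10^{-4}\,/s$) and
  a protein half-life of ~1 h ($d_{PR} = 2\times10^{-4}\,/s$) — typical
  scales for cytokine transcripts and signaling proteins;
* constitutive Rig-I at ~10 transcripts and ~1000 proteins per cell
  ($k_{MR}^{basal} = 5\times10^{-3}\,/s$, $k_{tl} = 2\times10^{-2}\,/s$),
  with ten-fold maximal induction ($f = 10$, $K_B = 500$, $h_B = 2$);
* an interferon half-induction level $K_P = 4000$ set four-fold above the
  baseline $P_R$ with a sharp Hill coefficient ($h_P = 4$), so baseline
  infected cells transcribe interferon at ~0.4% of maximum while early
  responders (initial $P_R = 20{,}000 = 5 K_P$) transcribe near maximum
  ($k_{MI}^{max} = 0.1\,/s$) — this separation is what lets a single
  elevated cell dominate a culture's early interferon output;
* receptor kinetics $F_0 = 2000$, $k_{on} = 10^{-5}/(\mathrm{receptor\,s})$,
  $k_{off} = 10^{-4}\,/s$, giving ~2% of local free interferon captured per
  second by a fully unbound cell;
* diffusion at $D = 50\,\mu m^2/s$ (a small secreted protein in medium),
  $\delta = 20\,\mu m$, $p = 1/2$, hence $\Delta t = \delta^2/(8D) = 1$ s —
  3–4 orders of magnitude below the gene-expression time scale, which is
  the separation the synchronization scheme exploits.

What the synthetic cultures do **not** emulate: viral replication and dose
dependence beyond the infected flag, interferon subtypes and the JAK/STAT
cascade, receptor internalization and turnover, cell division, death or
motility, and 3D geometry (3D diffusion is implemented and calibrated but
not wired into the culture).  Passing tests therefore say the *algorithms*
are exact and the *model* behaves as specified — not that the parameter set
quantitatively reproduces any particular wet-lab measurement.

## The MOI sweep and its expected phenomenology

`moi_sweep()` replicates cultures across MOI values, averages the
population curves (interferon transcripts per *infected* cell; Rig-I
transcripts per cell), marks half-maximal induction (first up-crossing of
half the curve maximum, linearly interpolated), and scores pairwise curve
similarity as the root-mean-square distance between peak-normalized mean
curves (averaged over the two curve types).

Under the bundled defaults the sweep exhibits the two qualitative
signatures the model was built to show:

* **Robust timing above a threshold MOI** — for MOI ≥ 0.5 enough infected
  cells seed the interferon field that the paracrine feedback wave
  saturates the culture within the first few hours; over the 10 h window
  the normalized curves for MOI 0.5, 1 and 5 share their plateau and
  cluster tightly.  (At the full 200-cell scale, the ~2 expected early
  responders accelerate the wave further; in the 50-cell regression-scale
  cultures the collective field carries the wave on its own.)
* **A lagging MOI 0.1 response with near-coincident markers** — with only
  ~5 infected cells the field builds several-fold more slowly; cells
  approach self-activation, Rig-I and interferon induction ride the same
  slow clock, and the gap between their half-max times is the smallest of
  the sweep.

Both are *parameter-conditional* statements about the bundled defaults and
scale (the regression tests run a 20×20, 50-cell, 10-hour sweep with five
replicates per MOI); they are ordinal, not quantitative, claims.

## Problem sizes used in the tests

The validation suite scales experiments to run unattended: calibration uses
the full 201×201/1000-step (2D) and 81³/800-step (3D) runs; conservation is
checked over 10⁴ stochastic steps on the 40×40 lattice; sampler
goodness-of-fit uses 10⁵ draws for each $n$ up to 1000; the
synchronized-vs-classical comparison uses 4×10⁵ events per run (the larger
event count keeps the 1% mean tolerance several standard errors wide);
stationary moments integrate a single cell over 6×10⁵ simulated seconds;
and the sweep uses the 50-cell culture above.  Scatter-style per-cell
outputs analogous to flow-cytometry snapshots can be extracted from
`run_culture(..., record_cells = TRUE)` at any record time (e.g. 6 h and
10 h).

## Known limitations

* The lookup table stores $O(N_{max}^2)$ doubles; `N_max = 1024` costs
  ~4 MB, but pushing it much beyond ~10⁴ is impractical — that is what the
  normal-approximation fallback is for.
* The deterministic calibration inherits lattice transients; with windows
  starting below ~10 steps the fitted $c$ drifts by more than the stated
  2% at small $p$.
* `half_max_induction()` reports the first crossing of half the *observed*
  maximum; on a curve still rising at the horizon the marker underestimates
  the asymptotic half-max time.
* Per-cell reproducibility relies on L'Ecuyer-CMRG substreams; runs are
  bit-reproducible for a fixed master seed and cell count, but inserting
  cells renumbers streams for the cells after the insertion point.
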