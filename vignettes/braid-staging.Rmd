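---
title: "Staging patterns of network proteopathy: models, braids, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging patterns of network proteopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braidr)
library(dplyr)
```

## The model

braidr simulates the prion-like spread of a misfolded protein on a weighted
structural brain network and asks in what order anatomical regions become
abnormal. The state at node $i$ is a pair $(p_i, q_i)$: $p_i \in [0, 1]$ is
the normalized concentration of seed-competent (transmissible) protein, and
$q_i \in [0, 1]$ is a monotone marker of accumulated tangle pathology. The
dynamics are a network Fisher–KPP (reaction–diffusion) system coupled to a
saturating damage law:

$$
\frac{dp_i}{dt} = -\beta \sum_j L_{ij}\, p_j + p_i (1 - p_i),
\qquad
\frac{dq_i}{dt} = \delta\, p_i (1 - q_i).
$$

Time is nondimensional: the logistic growth rate is scaled to one, so
$\beta$ is the ratio of transport to local growth ($\beta \ll 1$ growth
dominated, $\beta \gg 1$ diffusion dominated) and $\delta$ is the tangle
accumulation rate per unit of that same time. There is no conversion to
physical time anywhere in the package.

$L$ is a graph Laplacian built from the connectome's weighted adjacency
matrix $W$. Edges carry a fiber count $n_{ij}$ and a fiber length
$\ell_{ij}$ (mm), combined by one of three literature weightings:
length-free $W_{ij} = n_{ij}$ (LW), ballistic $W_{ij} = n_{ij}/\ell_{ij}$
(BW), or diffusive $W_{ij} = n_{ij}/\ell_{ij}^2$ (DW).

## Why the standard Laplacian

Normalized Laplacians are popular in this literature, so the package
implements the whole two-parameter family

$$
L_{a,b} = D^{1-a-b} - D^{-a} W D^{-b},
\qquad a, b \in [0, 1],\; a + b \le 1,
$$

with $D$ the diagonal strength matrix, and audits each member against two
physical requirements on the *transport* term: it must not create or
destroy mass ($\mathbf{1} \cdot L = 0$, zero column sums), and it must
produce no flux between nodes at equal concentration (the Fick condition,
$L \cdot \mathbf{1} = 0$, zero row sums). On a weighted graph the column
sums vanish identically when $a = 0$ and the row sums when $b = 0$, so the
only member satisfying both is the standard Laplacian $L_{0,0} = D - W$ —
unless the graph is strength-regular, in which case every member passes
trivially. `laplacian_scan()` verifies exactly this on any input, and
`simulate_spread()` warns when handed a non-standard member. Condition
checks use a default tolerance of `1e-10` on the row/column sums, relative
to `max(|L|)` (absolute when that scale is below one), so the audit is
meaningful for connectomes whose weights span many orders of magnitude.

## The staging problem, braid diagrams, and braid surfaces

Given disjoint staging regions $\Omega_1, \dots, \Omega_J$ (Roman-numeral
labels, region I seeded by default), the regional signal is the plain
per-region mean $P_j(t) = \frac{1}{N_j}\sum_{i \in \Omega_j} p_i(t)$ (and
$Q_j$ likewise). For a biomarker threshold $T \in (0, 1]$ the crossing time
$t_{j}$ is the first time $P_j \ge T$ (closed threshold: a region already
abnormal at $t = 0$ crosses at zero; a region that never crosses within the
horizon records $\infty$). Sorting regions by crossing time yields the
observed staging pattern, written `I → III → II → IV`.

A *braid diagram* fixes the model parameters and reports the pattern at
every threshold; a *braid surface* additionally sweeps one parameter
(canonically $\ln \beta$, optionally $\delta$ for tangle staging) and maps
every (parameter, threshold) cell to a pattern identity. Patterns are
registered in discovery order under a fixed deterministic sweep (ascending
parameter, then ascending threshold), so pattern ids — and plot colors —
are reproducible across runs, including parallel ones: workers only solve
trajectories, and ids are assigned after collection in canonical order.

The initial condition places a total seed mass of 0.005 (half a percent of
carrying capacity) split equally over the nodes of the seed region, with
$q \equiv 0$; this emulates a focal entorhinal seeding event that is small
enough not to predetermine late-stage orderings.

## Numerical choices

* **Integration.** `deSolve::lsoda` (adaptive, stiff-capable) with
  `rtol = 1e-8`, `atol = 1e-10`. These are tighter than needed for the
  trajectories themselves; the point is that staging is a race between
  regions, and near-ties must be decided by the model rather than by
  integration error.
* **Horizon.** When no horizon is given, integration runs to $t = 10$ and
  doubles until every region's mean exceeds the largest requested
  threshold (plus a small margin), up to a hard cap of $10^6$; thresholds
  still unreached at the cap are reported as $\infty$. When staging the
  tangle marker the settle test watches $Q$ instead of $P$, since $q$ lags
  $p$.
* **Crossing localization.** Crossings are bracketed on the stored grid
  (1500 uniform output points by default) and refined by bisection on the
  cubic Hermite interpolant through the stored states *and their stored
  time derivatives*, to a relative time tolerance of $10^{-8}$. The same
  derivative information drives the corrected-trapezoid quadrature in the
  independent tangle oracle $q_i = 1 - \exp(-\delta \int_0^t p_i\,ds)$.
* **Ties.** Crossing times equal within `tie_tol` (default $10^{-9}$
  absolute, exposed as an argument) are flagged as ties and broken by
  ascending region index. This matters in diffusion-dominated regimes,
  where regional differences can decay below machine precision before any
  threshold is crossed; silent dependence on solver noise there would make
  surfaces irreproducible. The dispersion statistic
  `staging_time_std()` — the population (divisor $J$) standard deviation of
  a threshold's crossing times, undefined whenever a region never
  crosses — quantifies exactly these race-condition cells: low dispersion
  predicts sensitivity of the observed pattern to tiny parameter changes.
* **Clamping.** Solver state is never clamped; reported/averaged outputs
  are clamped to $[0, 1]$. Undershoots beyond $-10^{-6}$ would indicate an
  integration problem and are treated as test failures, not silently fixed.
* **Thresholds.** The default threshold grid is 1% to 99% in 1% steps.
  $T = 100\%$ is deliberately excluded: under Fisher–KPP dynamics
  $p_i < 1$ at every finite time, so a 100% threshold is unreachable by
  construction and would only add a spurious all-unreached pattern to every
  registry.

## Connectome handling

Edge lists are symmetrized on input (directed duplicates averaged, with a
message) and self-loops dropped with a warning, since the model is defined
on undirected networks. Isolated nodes are legal for the standard
Laplacian only; any other family member needs strictly positive strengths.

Two backbone thresholding methods are built in. The naive cutoff removes
edges with $n_{ij}$ below an absolute level. The disparity filter keeps an
edge when its strength-normalized weight is significant at either endpoint
under the closed form $\alpha_{ij} = (1 - w_{ij}/s_i)^{k_i - 1}$, with the
single edge of a degree-1 node always retained; this OR-rule and degree-1
convention are the common ones in the backbone literature, stated here
explicitly because naming the method alone does not pin them down. (The
abbreviation DF is sometimes expanded as "density filter" in figure
captions of the surrounding literature; this package implements the
disparity filter.) Doubly-stochastic, high-salience-skeleton and
noise-corrected backbones are published external algorithms and are out of
scope; `threshold_backbone()` accepts any user function so they can be
plugged in.

The packaged five-region staging map (`braak_region_config()`) assigns
I = entorhinal cortex, II = hippocampus, III = parahippocampal gyrus,
IV = rostral + caudal anterior cingulate, V = cuneus + pericalcarine +
lateral occipital + lingual, matched against node labels by normalized
substring so it works across parcellation naming conventions.

## What the synthetic fixtures do and do not show

`four_node_example()` is the package's deterministic worked example: a
four-node cycle whose DW weight matrix has entries
$3.125 \times 10^{-7}$, $5 \times 10^{-6}$, $10^{-5}$,
$1.5 \times 10^{-4}$ (fiber counts back-computed from those weights and
lengths $\ell_{12} = 40$, others 20, so LW/BW variants of the same network
are also well defined). At $\ln \beta = 3.897$ it stages
`I → III → II → IV` at low thresholds and `I → III → IV → II` at high
ones, and its full braid surface contains exactly those two patterns:

```{r worked-example}
fx <- four_node_example()
bd <- braid_diagram(fx$laplacian, fx$partition,
  ln_beta = fx$params$ln_beta, thresholds = c(0.01, 0.05, 0.40, 0.80)
)
vapply(bd$patterns, as.character, character(1))
```

`random_connectome()` generates connected random-geometric graphs
(heterogeneous degrees, Euclidean lengths, log-uniform fiber counts),
d-regular rings (the degree-homogeneous control for the Laplacian audit),
and stars. These fixtures make every property testable without imaging
data, but they do not emulate real tractography: no log-normal fiber-count
tails, no hemispheric structure, no parcellation-scale effects. Passing
tests therefore demonstrate correctness of the machinery — axiom checks,
integration, crossing localization, pattern bookkeeping — not that any
particular staging pattern will appear on a real connectome, where the
landscape is known to depend strongly on resolution, tractography, and
thresholding.

Problem sizes used in the shipped tests and acceptance script (a 151-point
$\ln \beta$ grid with 99 thresholds for the worked example; ensembles of
100 random 9–12 node fixtures elsewhere) were chosen as the smallest sizes
at which each claim is actually exercised — full grids for the surface
claims, three-region ensembles for the ordering oracle.

## Known limitations

* Single growth law (logistic) and single damage law; no clearance terms,
  no directed or anisotropic transport.
* Crossing accuracy is bounded by solver accuracy; in regimes where
  regional differences sit below `rtol`, orderings are reported via the
  tie rule rather than resolved.
* The disparity filter is the only statistical backbone implemented;
  comparisons across the published backbone family require user-supplied
  implementations through the plug-in hook.
* The region map matches labels by substring; exotic parcellation naming
  schemes may need a custom configuration.
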