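---
title: "Modeling Ft-Ds polarity and growth in the wing disc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Ft-Ds polarity and growth in the wing disc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fatds)
```

## The question the model addresses

Cells throughout the *Drosophila* wing pouch localize the myosin Dachs on
their distal (center-facing) side. Dachs follows the spatial arrangement of
Fat–Dachsous (Ft–Ds) heterodimer bonds around each cell, yet over most of
the pouch the Ds concentration is nearly uniform — the steeply graded
"transition region" of Ds expression is a narrow ring that sweeps outward
during the third instar. `fatds` implements an agent-based model of this
system to ask how a *moving* expression front, a *static* Fj gradient, and
ongoing cell division interact to produce and maintain planar polarity.

## State and per-step procedure

A disc is a set of off-lattice cells (position, radius, integer protein
pools) connected by a pruned Delaunay graph. Each step of `sim_step()`
applies, in a fixed order that is part of the package's contract:

1. field evaluation (morphogen, Fj, Ds expression rate at each cell center);
2. protein expression — Poisson counts, each new molecule phosphorylated
   with probability `fj / (fj + phos_K)`; membrane protein is never
   phosphorylated after the fact;
3. bond dissolution (binomial thinning, released protein keeps its state);
4. degradation of *free* protein only;
5. dephosphorylation of free protein;
6. even partitioning of free pools over interfaces, then bond formation:
   `K = min(Ft, Ds)` pairing attempts per interface and orientation, each
   succeeding with the state-dependent weight;
7. polarity metrics over *mature* neighbors (interfaces older than the
   grace period), computed from 100 min onward;
8. integral-feedback adaptation of the growth signals;
9. the multiplicative growth law; 10. size-triggered division;
11. overdamped mechanics; 12. graph rebuild with establishment stamps and
   bond ledgers carried across.

Binding after supply and decay approximates within-step equilibration, and
polarity precedes growth so that growth uses the current asymmetry.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `C0`, `A`, `t0` | 1, 2.5, 1200 | a.u., –, min | morphogen amplitude, decay-length/disc-size ratio, e-folding time |
| Ds `rate_high`/`rate_low` | 20 / 2 | proteins/min | peripheral vs central plateaus of the Hill rule |
| `hill_n` | 8 | – | makes the transition region a few cell diameters wide |
| Fj `slope`, `fj_min` | 2.5e-2, 0.1 | a.u./µm, a.u. | linear gradient; slope constant in time |
| `w` (uu, up, pu, pp) | .05, .05, .7, .2 | – | phosphorylation raises Ft's and lowers Ds's affinity |
| `k_dissoc`, `k_deg` | 0.08 | /min | bond and free-protein turnover |
| `k_dephos` | 0.02 | /min | slow, so phosphorylation state is a short memory |
| `phos_K` | 0.5 | a.u. | half-saturation of phosphorylation vs Fj |
| `G0` | 6.5e-4 | /min | base radial growth; see calibration below |
| `C_M`, `C_Ft`, `C_Ds` | 0.9 | – | gains; each `C·x < 1` |
| `u_scale` | 5e-4 | /molecule | free-protein growth penalty |
| `tau_adapt` | 300 | min | adaptation fades constant inputs on the hours scale |
| `r_div`, `div_steepness` | 1.9, 0.05 | µm | near-deterministic in size, asynchronous in time |
| grace period | 30 | steps | several bond-replenishment time constants |
| prune `cutoff_factor` | 1.5 | – | drops hull-spanning triangulation edges |

All rates convert to per-step probabilities as `1 − exp(−k·dt)`, so runs
with `dt` of 30 s or 2 min need no re-tuning.

### Calibrations made once

* **Ds threshold.** The Hill threshold is expressed as an absolute
  morphogen concentration `m_star = C0·exp(−A·8/40)`, chosen so the
  transition region of a 40 µm disc sits at radius 8 µm at time zero and
  then moves outward as `r* = (R/A)(t/t0 + ln(C0/m_star))`.
* **Division cycle.** `G0` was set so that the *measured* steady-state
  doubling time of a wild-type disc is ≈ 470 min (≈ 8 h, the observed cell
  cycle); with the gains at 0.9 and typical adapted signals of 0.05–0.1,
  this requires `G0 = 6.5e-4`/min.
* **Initial packing.** 1000 cells with radii drawn U(1.3, 1.8) µm are
  placed by Poisson-disc rejection sampling in a pre-shrunk circle and
  relaxed for 200 mechanics-only steps; the equilibrium disc lands near
  the 40 µm target with a center denser than the periphery (attraction
  compresses the bulk). Cell diameter, cell number, and disc radius
  over-determine each other, so the radii were chosen to keep all three
  approximately right.

## Numerical choices

* **Triangulation.** A Bowyer–Watson incremental Delaunay with a symbolic
  ghost vertex: hull-adjacent conflict tests are pure orientation
  predicates, which avoids both the precision loss and the geometric
  artifacts of a finite super-triangle (near-collinear triples have
  circumcircles large enough to reach any finite enclosure). Inputs are
  jittered deterministically by ~1e-9 µm, indexed per point, so cocircular
  ties resolve reproducibly. A brute-force empty-circumcircle oracle in
  the test suite checks exact agreement on hundreds of random point sets.
* **Mechanics.** Piecewise force law — linear repulsion inside contact,
  exponentially decaying attraction outside — integrated overdamped with a
  displacement cap of 0.25 × mean radius per step.
* **Ties.** The least-bound-Ft neighbor is chosen by a seeded random draw
  among ties; division axes default to a uniform random angle (orientation
  has little effect on outcomes and radial/tangential modes are exposed).
* **Degenerate inputs.** Fewer than three points triangulate to all pairs;
  cells with no mature neighbors are recorded as unpolarized (asymmetry 0)
  rather than maximally asymmetric, which avoids division-burst artifacts;
  cells with mature neighbors but no bonds at all score asymmetry 1 — the
  convention that lets bond-free mutants (ft⁻, ds⁻) overgrow.
* **Edge bookkeeping.** When a graph rebuild drops an edge, its bonds are
  released to the owners' free pools (protein is conserved exactly; the
  test suite audits per-cell mass balance every step of a 500-step run).

## What the simulated conditions do and do not show

Runs at full scale start from 1000 cells (≈ 40 µm) and take 2880 one-minute
steps. The test suite and the reference script use smaller discs — 250–300
starting cells for 600–1200 steps, and 25–60 cells for kinetics audits —
with the same densities and parameters; these sizes keep the full suite in
minutes while preserving per-cell behavior (neighbor statistics, binding
equilibria, and the front's relative dynamics are scale-free by
construction of the morphogen profile).

The generator emulates: scaling and amplification of a single abstract
morphogen, Hill-type Ds expression with a moving or pinned front, linear
Fj, stochastic integer-count binding kinetics, asynchronous ~8 h division,
and the packing geometry of a compressed epithelium. It does **not**
emulate 3-D cell shape or mitotic apical rounding, cell rearrangement or
sorting, mechanotransduction feedback onto the pathway, or explicit
Dpp/Wg/Vg dynamics — so passing tests speak to the pathway logic, not to
tissue mechanics beyond simple packing.

## A known limitation: the length of the polarity memory

In this implementation, dissolved bonds return to the cell-wide free pool
and are re-partitioned *evenly* over interfaces on the next step. An
interface's bond count therefore relaxes toward what the current
neighborhood supplies within ~1/`k_dissoc` ≈ 12 min, and the only durable
memory is the difference in *total* Ds content between neighboring cells,
which decays at `k_deg ×` (free fraction) — a time constant of one to two
hours at the wild-type rates, since the attainable bound fraction is
limited by the per-attempt binding weights. The consequence is a polarized
wake ~10 µm behind the moving front rather than a pouch-wide one: cells
swept long ago lose their inward orientation, while cells near the front
(in both moving and stationary modes) and cells outside it (via the Fj
gradient) stay aligned. The moving-vs-stationary contrast — significantly
positive inward alignment throughout the wake versus none in the
stationary front's center — is robust, but the wake's alignment averages
~0.25 rather than the stronger retention a membrane-local rebinding rule
would give. Making released protein re-bind its own interface
preferentially would lengthen the memory substantially; it is deliberately
out of scope because the present partitioning rule is the model's stated
contract.

## Scenario composition

`scenario_config()` composes genotypes deterministically: `ft_null`/
`ds_null` zero the respective expression and initial pools (no bonds ever
form; asymmetry reads 1); `fj_null` forces all protein unphosphorylated;
`uniform_fj` fixes Fj at 10 a.u. (≈ 10 × the wild-type central level);
`uniform_ds` expresses Ds uniformly at the peripheral rate; `ft_no_icd`
forms bonds that are invisible to the polarity readout and exempts free Ft
from the growth penalty; `ft_no_ecd` makes Ft unbindable (always free);
`uniform_morphogen` fixes the morphogen at `C0·e` — high but constant —
and `no_morphogen` at zero. Clones are circular and concentric
(`clone_spec()`), induced at a configurable step, with labels inherited by
daughters: Ds-overexpressing clones use 200 proteins/min, Fj clones ≈ 10 ×
the central wild-type level, morphogen clones `C0·e`.
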