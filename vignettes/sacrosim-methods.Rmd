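---
title: "Simulating sacrificial-spheroid tissue constructs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sacrificial-spheroid tissue constructs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacrosim)
```

`sacrosim` simulates what happens to a bioprinted multicellular construct
*after* printing: cells rearrange spontaneously, driven by differential
adhesion, and a sacrificial cell population can be eliminated on command to
open perfusable channels. This vignette explains the model, the parameters
that matter, what the synthetic construct generator does and does not
emulate, and the numerical choices behind the implementation.

## The lattice model

A construct is a dense cubic lattice of cell-sized volume elements. Each
site holds a particle-type index $\sigma$: by convention $\sigma = 0$ is
cell culture medium, $\sigma = 1$ is a hydrogel phase where one exists (or
the first cell type otherwise), and higher indices are further cell types.
One site corresponds to one cell diameter, 10 µm by default
(`lattice_unit`); the lattice representation assumes all simulated cell
types have similar diameters, and cells neither divide nor die outside the
scripted elimination.

Every site interacts with its 26 neighbors — 6 nearest (axis), 12
next-nearest (face-diagonal) and 8 second-nearest (cube-diagonal) — and the
interaction energy depends only on the two types involved, not on the
shell. Cohesion is parameterized by *works of adhesion*
$\varepsilon_{\sigma\sigma'} \ge 0$, the energy needed to break one bond
between neighbors of types $\sigma$ and $\sigma'$, expressed in units of
the fluctuation energy scale $E_T$. The configurational energy is the
interfacial sum

$$E \;=\; \sum_{\sigma < \sigma'} \gamma_{\sigma\sigma'}\, N_{\sigma\sigma'},
\qquad
\gamma_{\sigma\sigma'} = \tfrac12\left(\varepsilon_{\sigma\sigma} +
\varepsilon_{\sigma'\sigma'}\right) - \varepsilon_{\sigma\sigma'},$$

where $N_{\sigma\sigma'}$ counts the heterotypic neighbor pairs and
$\gamma$ is the interfacial tension. The difference between this and the
raw works-of-adhesion sum is a configuration-independent constant (the
composition is conserved), so only the interfacial part is tracked.
Positive $\gamma$ drives demixing and compaction of the two phases; zero
$\gamma$ makes an interface energetically invisible; negative $\gamma$
makes one phase wet the other. A phase $b$ spreads as a monolayer between
phases $a$ and $c$ when $\gamma_{ac} > \gamma_{ab} + \gamma_{bc}$ — the
criterion behind the endothelial-lining scenario below.

All medium contacts carry $\varepsilon_{0\sigma} = 0$ in every scenario
table, so $\gamma_{0\sigma} = \varepsilon_{\sigma\sigma}/2 > 0$: condensed
phases round up and minimize their medium-exposed surface, which is what
makes spheroids fuse and lumens shrink.

## Metropolis dynamics

The configuration evolves by swapping the contents of neighboring sites.
One attempt picks a mobile site uniformly at random, then one of its
in-bounds 26-neighbors uniformly; if the two types differ and the pair is
allowed by the mobility policy, the energy change $\Delta E$ is computed
from the two local neighborhoods (it equals the global energy difference
exactly) and the swap is accepted outright when $\Delta E \le 0$, otherwise
with probability $\exp(-\Delta E / E_T)$.

Choices the dynamics makes where the physical prescription is open:

* **One Monte Carlo step (MCS)** is defined as $M$ attempted swaps, with
  $M$ the current number of mobile (cell-type) sites — the standard sweep
  convention that makes an MCS roughly system-size independent. MCS is a
  pseudo-time; no mapping to physical time is claimed or provided.
* **Mobility policy.** Only cells initiate moves. Cells may exchange with
  medium, with cells of another type, and (by default,
  `allow_gel_swap = TRUE`) with hydrogel, modeling a gel that cells invade
  and remodel. Medium and hydrogel never exchange with each other — the
  algorithm cannot describe bulk flow of the medium, and letting gel
  diffuse through medium would be unphysical.
* **Same-type picks** count as attempts and are skipped; this keeps the
  proposal distribution uniform and unbiased.
* **Swap and energy neighborhoods coincide** (all 26 offsets for both).
* **Boundaries are open**: sites outside the finite box contribute no
  bonds. Tube builders pad constructs with at least two (default three)
  medium layers so the box edge is never energetically visible; the
  branched slab intentionally fills its box (see below), which is neutral
  because same-type bonds carry zero tension.
* **$E_T = 1$** by default; all tabulated works of adhesion are of order
  1–4 in these units. As $E_T \to 0^+$ the dynamics becomes greedy and the
  energy trace non-increasing (a property the tests exercise).
* **RNG.** All stochastic choices — builder label permutations, gel
  seeding, site/neighbor picks, Metropolis deviates — are drawn from R's
  global RNG stream in a fixed documented order, so a single `set.seed()`
  (or the seed in an `mmc_schedule`) makes a run bit-reproducible.

`run_schedule()` executes an MCS budget with checkpoints (energy and
snapshot records) and events. The only event type is sacrificial
elimination: every site of a named cell type becomes medium,
instantaneously — the sensitization chemistry that would implement this in
the laboratory is abstracted away. A checkpoint snapshot scheduled at the
same MCS as an event is taken *before* the event fires, so "right before
elimination" states are recoverable; the vacated site indices are kept so
the lumen can be tracked by provenance afterwards.

## The construct generator

The generator is the synthetic-data stage: it emulates the three printed
geometries the study simulates, and its defaults are the study conditions.

**Digital spheroids.** A spheroid of diameter $d$ (in cell diameters) is
digitized as the integer points of the closed Euclidean ball of radius
$d/2$ about a lattice site, excluding surface points lying exactly on the
coordinate axes. This calibration is pinned by the printed cell count: for
$d = 10$ the closed ball holds 515 lattice points and the exclusion removes
the 6 axial ones, giving exactly 509 cells per spheroid. The rule is
isolated in `make_spheroid()` so an alternative digitization can be swapped
in. Its one degenerate corner: at $d = 2$ the exclusion removes everything
but the center, so the smallest practically useful diameter is 4.

**Touching without overlap.** With this rule, two even-diameter spheres
placed exactly $d$ apart do *not* touch (the only candidate contact site is
axial, hence excluded), while at $d-1$ they touch and share no sites.
Rather than hard-coding parities, placement uses a deterministic search for
the smallest integer center offset along the required direction at which
the two digital spheres are disjoint; chains use it along the axis, wall
rings and branch attachments use it radially. Builders additionally refuse
to overwrite non-background sites, so any placement bug surfaces as an
error, and the per-spheroid manifest lets tests verify that the census
equals spheroid count × spheroid size.

**Tubes.** The printed tube is a contiguous axial chain of sacrificial
spheroids wrapped by rings of wall spheroids. The packing of the rendered
construct is not parameterized anywhere, so the generator's choice is: six
wall spheroids per ring at 60° pitch, one ring per chain spheroid,
consecutive rings staggered by half a pitch (a hexagonal-close-packed-style
arrangement), ring radius found by the touching search. Chain length
defaults to five spheroids. The two-type variant keeps the geometry and
makes each wall spheroid an exact-count random 10% endothelial / 90%
smooth-muscle mix; exactness uses largest-remainder apportionment (ties to
the lower index) followed by one `sample()` permutation.

**Branched slab.** The full-scale system is a 210 × 145 × 124 hydrogel
slab — 3,775,800 sites, i.e. 2.1 × 1.45 × 1.24 mm at 10 µm per site — with
a main chain of diameter-30 sacrificial spheroids along the long axis and
side branches of diameter-16 spheroids whose first member touches the
chain. The branch count and angles are not readable from the rendered
construct; the default is two perpendicular branches of three spheroids
attached at interior chain positions, fully configurable through
`branch_layout`. The slab fills its lattice with no medium padding because
the printed census leaves no room for one; hydrogel is immobile, so the
boundary stays inert. Endothelial cells are seeded by independent per-voxel
sampling of hydrogel sites at probability
$p = \text{density} \times (\text{lattice unit in cm})^3$ — $10^{-3}$ at
the study's $10^6$ cells/mL — the simplest model consistent with "randomly
dispersed".

**What the generator does not emulate.** Spheroids are rigid,
non-overlapping digital spheres: no mechanical deformation on printing
contact, no size polydispersity, no pixel-level fidelity to the rendered
figures. Real aggregates flatten against each other at delivery and vary in
cell count; passing the package's tests therefore shows that the *model*
reproduces fusion, sorting and channel formation from idealized printed
states, not that it predicts any particular experimental geometry.

## Scenario parameter tables

The three adhesion tables (`adhesion_preset()`) are the study conditions:

* **Single-type tube**: wall and sacrificial cells share one adhesivity
  ($\varepsilon_{11} = \varepsilon_{12} = \varepsilon_{22} = 1.4$), so
  their mutual tension vanishes and their interface is frozen-in (neutral):
  swaps across it cost exactly zero and the label boundary only diffuses.
  Protocol: 5×10³ MCS of fusion, elimination of the core, 10³ MCS of
  relaxation.
* **Two-type tube**, 5×10⁴ MCS: the *sorting* table
  ($\varepsilon_{11} = 1.6$, $\varepsilon_{12} = 1.4$,
  $\varepsilon_{13} = 1.0$, $\varepsilon_{22} = 2.0$,
  $\varepsilon_{23} = 1.8$, $\varepsilon_{33} = 2.4$; 1 = smooth muscle,
  2 = endothelial, 3 = sacrificial) gives $\gamma_{13} = 1.0 >
  \gamma_{12} + \gamma_{23} = 0.8$, so endothelium wets the
  muscle–sacrificial interface and a lining forms. The *scrambled* table
  differs only in $\varepsilon_{12} = 1.0$, breaking the inequality.
* **Branched slab** (1 = hydrogel, 2 = endothelial, 3 = sacrificial):
  $\varepsilon_{11} = 2.4$, $\varepsilon_{12} = 2.0$,
  $\varepsilon_{13} = 2.0$, $\varepsilon_{22} = 1.6$,
  $\varepsilon_{23} = 2.0$, $\varepsilon_{33} = 4.0$, giving
  $\gamma_{12} = 0$ (endothelium moves freely through gel) and
  $\gamma_{13} = 1.2 > \gamma_{23} = 0.8$: endothelial cells accumulate on
  the gel–sacrificial interface during the 10⁵-MCS fusion window.

## Morphometry

* `phase_components()` labels connected components of a phase; 26-
  connectivity (matching the interaction neighborhood) is the default for
  contiguity claims, with 6-connectivity available as the stricter
  perfusability notion, since flow through a cube-diagonal contact is
  physically dubious.
* `lining_coverage()` is the lining type's share of all non-cavity sites
  among the 26-neighbors of cavity sites; 1 means a complete monolayer.
* `interface_roughness()` is the heterotypic boundary-pair count between
  two phases; at fixed enclosed volume a decreasing count means smoothing.
* `enclosed_medium()` / `lumen_report()` operationalize the *lumen*. Naive
  medium labeling would merge an open-ended channel with the exterior bath,
  so medium sites are first classified by ray casting along the six lattice
  axes (interior = at least four rays blocked by non-medium before the box
  edge; a straight channel keeps two open axial rays), and the lumen is the
  interior component holding the largest share of the sites vacated by the
  elimination event, tracked by provenance. Both thresholds are exposed as
  arguments.

## Problem sizes, budgets, and the reduced scale

Full-scale protocols use the printed conditions above; the branched
full-scale run (≈3.8 M sites for 10⁵ MCS) is a many-CPU-hour computation
kept behind `scale = "full"` (and `--full` in the analysis script). The
package's tests and bundled analyses run the *reduced* protocols: spheroid
diameters halved (5, and 15/8 for the branched scenario), chains of three,
a 70 × 55 × 46 slab, and MCS budgets divided by ten (600 / 5×10³ / 10⁴).
These sizes keep each scenario between seconds and half a minute per seed
while preserving every morphological outcome of interest — fusion,
neutral-interface mixing, hierarchy-controlled lining, lumen opening and
shrinkage, branched-channel contiguity. At the reduced scale the tube wall
is a single spheroid thick and the seeded endothelium in the slab numbers a
few hundred cells, so absolute metric values (e.g. lining coverage of the
reduced slab channel, ≈0.02–0.03) are smaller than their full-scale
counterparts; all claims tested at reduced scale are therefore comparative
or topological, never absolute thresholds taken from the full-scale system.

## Known limitations

* No proliferation, directed migration, chemotaxis, apoptosis beyond the
  scripted elimination, or medium bulk flow; medium trapped between a
  closing wall and the core can therefore prevent complete linings, which
  in experiments would be sealed by proliferation or perfusion seeding.
* MCS is not physical time; only orderings and tendencies are meaningful.
* The reference dynamics is plain Metropolis; no rejection-free or
  parallel-tempering acceleration is included.
* The lumen classifier is geometric (ray casting + provenance); it is
  robust for tubular and branched channels but not a general topological
  cavity detector.
* Elimination is instantaneous and total; no gradual death, debris, or
  spatially graded sensitivity.
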