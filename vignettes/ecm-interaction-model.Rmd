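---
title: "The cell-ECM interaction model: assumptions, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cell-ECM interaction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecmabm)
```

## The model

`ecmabm` couples off-lattice, center-based cell agents to a mesoscale
representation of extracellular matrix (ECM). The ECM is a Cartesian mesh of
elements, each one summarizing the unresolved fiber ensemble in a 20 µm
voxel by three variables:

* **orientation** $\vec f$ — the average local fiber direction, a unit
  3-vector. Fibers have no head or tail, so $\vec f$ and $-\vec f$ are the
  same physical state; every consumer of $\vec f$ in the package is
  sign-invariant, and tests enforce this.
* **anisotropy** $a \in [0,1]$ — the local fiber–fiber alignment
  correlation. It weights how strongly orientation steers migration, and it
  is modeled as stable-or-increasing only: cells can comb fibers into
  alignment but nothing in this model disperses them again.
* **density** $\rho \in [0,1]$ — the fiber volume fraction.

Cells *read* these fields (contact guidance, density-dependent speed,
anisotropy-gated chemotaxis) and *write* them back (reorientation,
anisotropy growth, density remodeling), which closes the stigmergy loop
that the collective-migration experiments probe.

### Reading: the motility update

Each cell performs a biased persistent random walk. With probability
$\Delta t/\tau_P$ per mechanics step the direction is refreshed by the
composition (in this order):

1. base cue $\hat d_{cue} = \widehat{\beta \hat g + (1-\beta)\,\xi}$, with
   $\hat g$ the normalized chemoattractant gradient, $\xi$ a uniformly
   random unit vector (in-plane for single-layer domains), and $\beta$ the
   chemotactic bias;
2. sign matching $\vec f^* = \vec f\,\mathrm{sign}(\vec f \cdot \hat
   d_{cue})$ (with $\mathrm{sign}(0) := +1$);
3. contact guidance $\hat d = \widehat{(1-sa)\,\hat d_{cue} + sa\,\vec
   f^*}$, where $s \in [0,1]$ is the cell's ECM sensitivity;
4. motility vector $\vec v_{mot} = S_{max}\, T(\rho)\, \hat d$.

The order — cue first, guidance second — is a package contract: it
reproduces both limits exactly (pure chemotaxis at $sa = 0$, pure fiber
following at $sa = 1$), which the deterministic proof-of-concept
experiments rely on.

$T(\rho)$ is the piecewise-linear density tent: zero at or below $\rho_l$
(too little matrix to attach to), one at $\rho_{ideal}$ (default 0.5), zero
at or above $\rho_h$ (too dense to pass). Output speed therefore never
exceeds $S_{max}$ and attains it only at ideal density.

Two chemotaxis models are provided. Model I uses a fixed bias $\beta = b$.
Model II sets $\beta = s\,a$: the cell trusts the gradient only where the
matrix is aligned, *and only to the extent that it can sense matrix at
all*. The factor $s$ in Model II is a deliberate design decision: an
ECM-blind cell ($s=0$) must not extract information from anisotropy, or
the writing-only ablation of the leader–follower model would not isolate
what it is meant to isolate.

### Writing: remodeling

Remodeling is local to the single element containing the cell center, uses
the realized velocity of the same mechanics step, and applies in cell-id
order when several cells occupy one element (deterministic per seed;
order-independence holds to $O(\Delta t^2)$):

* orientation: blend toward the sign-matched travel direction with weight
  $k = \min(1, r_{f0}\,|\vec v|\,\Delta t / v_{ref})$, then renormalize.
  The angle to the travel axis decreases monotonically and $k = 1$
  reproduces the instantaneous limit.
* anisotropy: $da/dt = r_{a0}\,(|\vec v|/v_{ref})(1-a)$, integrated
  exactly over the step. Growth is proportional to cell speed; $a$ never
  decreases.
* density: $d\rho/dt = r_\rho(\rho_{target} - \rho)$, integrated exactly;
  one law covers deposition and degradation. Density remodeling is *not*
  speed-gated: a cell stalled in dense matrix still degrades it, which is
  what lets fibroblasts drill through a basement membrane.

$v_{ref} = 1\,$µm/min makes the printed rates (4 min⁻¹ reorientation,
0.004 min⁻¹ realignment) dimensionally usable as stated. The exact
exponential updates remove $\Delta t$ sensitivity and keep $a, \rho \in
[0,1]$ by construction — the acceptance suite checks unit norms to 1e-9 and
the closed forms of both ODEs over randomized updates.

An `instant` flag gives the limit of infinitely fast writing (orientation
snaps to the travel direction, $a \to 1$), used to explore the
leader–follower model before relaxing to finite rates.

### Mechanics and microenvironment

Cells interact through polynomial adhesion/repulsion potentials on center
distance ($(1-d/R)^2$ up to contact $R = R_i + R_j$ for repulsion,
$(1-d/R_A)^2$ up to $R_A = 1.25\,R$ for adhesion, geometric-mean
combination across heterotypic pairs), integrated with explicit Euler at
$\Delta t_{mech} = 0.1$ min in the overdamped regime. Motility and pair
terms add without renormalization, so adhesion pulling against divergent
motility genuinely slows a cluster — the effect that separates the
instant- from the finite-remodeling collective migration outcomes.

Substrates diffuse on the same mesh (shared origin and spacing) by
operator-split implicit tridiagonal sweeps, decay by an exact exponential
factor, with per-face Dirichlet or no-flux conditions. Dirichlet voxels are
held fixed *inside* the line solves; mass is conserved to machine precision
under all-no-flux conditions, and the discrete steady state against
$c_0 e^{-x/L}$ is within 5% at 20 µm resolution for the three length
scales the scenarios use (32, 100, 1000 µm). The builders specify length
scales, not $(D, \lambda)$ pairs: $\lambda = D/L^2$, with
$D_{oxygen} = 10^5$, $D_{inflammatory} = 10^3$,
$D_{debris} = 1$ µm²/min and no debris decay. The "~100 µm in cell-dense
tissue" scale is realized by cellular uptake, not a spatially varying
$\lambda$.

### Rules

Behavioral couplings are declarative: a rule maps one signal (substrate
concentration at the cell's voxel, contact counts by type, or local ECM
density) through a Hill response onto one behavior parameter of one cell
type, overwriting it for that rules step (6 min). At most one rule per
(type, behavior) pair may exist, so evaluation order is irrelevant, and
removing every rule leaves inert types with constant parameters. The Hill
power defaults to 4 — a sharp but smooth switch; only saturation and
half-max are scenario-level parameters.

## Scenario parameterization

Printed quantities are baked into the builders: the invasive front's
600×1000 µm domain, 30 cells per 180 min influx, $C_{cca} = 0.4$,
$C_{ccr} = 25$, $S_{max} = 1.25$ µm/min, static fully anisotropic ECM; the
175 µm discs; the leader-follower 95/5 split, adhesion 10 µm/min and
continuous rates $r_{a0} = 0.004$, $r_{f0} = 4$ min⁻¹; the
basement-membrane density layout (lumen 0, membrane 1, stroma 0.5) with
oxygen entering from the bottom boundary.

Three parameter families deserve explanation because they were genuinely
open:

**Packing and populations.** Discs are hexagonally packed at the pair
mechanical equilibrium spacing computed from $(C_{cca}, C_{ccr})$. With
adhesion 10 and repulsion 25 this spacing is 12.52 µm, and a 175 µm disc
then holds exactly 703 cells — the printed leader-follower population —
while the half-disc holds 365, fixing the basement-membrane fibroblast
count at 152 to meet its printed total of 517. This agreement is why the
package treats $C_{ccr} = 25$ as the default for those two scenarios. The
fibrosis wound uses zero-adhesion dead cells; its disc spacing (18.5 µm)
and recruit counts (40 macrophages, 59 fibroblasts) were chosen so the
initial population equals the printed 412 while leaving enough recruits to
rebuild matrix.

**The fibrosis cascade.** The reference rates were not available, so they
were calibrated once against the reported outcome (most replicates fully
enclose the wound). Two mechanistic constraints fell out of that
calibration and are worth recording. First, a fibroblast depositing at rate
$r_\rho$ while its own speed falls with rising density travels only about
$S_{max}/r_\rho$ before immobilizing itself; fast deposition therefore
produces isolated blocked dots that can never seal a wound, and the default
deposition rate is deliberately slow (0.01 min⁻¹) so each fibroblast
densifies a contiguous patch. Second, the recruitment loop must outlive the
dead cells: inflammatory secretion is driven by the persistent debris field
rather than by transient dead-cell contact, and debris uptake defaults to
zero, because any material uptake lets macrophages extinguish their own
local signal within hours and the cascade fossilizes. The macrophage
hard-stop density is $\rho_h = 0.9$ against a deposition target of 1.0 — an
asymptotic approach to the tent's upper node can never strictly reach it,
so trapping requires the target to exceed $\rho_h$; fibroblasts keep the
full tent ($\rho_h = 1$) and creep. The enclosure classifier keys on the
same $\rho_h = 0.9$. One morphological difference from the reference
figures is documented rather than hidden: the blocked region here grows as
a connected central plug that traps the recruits, not a hollow ring with a
cell-free cyst.

**Chemotactic biases.** Recruitment biases (0.9) and the cancer cells'
oxygen bias (0.9) are unpublished; they were fixed once at "strongly but
not perfectly biased", and the leaders' bias is 1.0, which makes the
leaders' ~16 h transit to the boundary at $S_{max} = 0.5$ µm/min come out
of the geometry.

## What the synthetic experiments do and do not establish

All experiments are generated from configuration — there is no external
data. A green suite establishes that the implemented interaction model
reproduces the qualitative phenomenology it was built to express: fronts
advance fastest across perpendicular fibers, combing aligns a random field
in four passes with the closed-form anisotropy gain, stigmergy requires
both writing and reading, adhesion/speed ratios set three collective
regimes, degradation opens a membrane, deposition can seal a wound. It does
not establish biological calibration: rates whose reference values were
unavailable were chosen to reproduce reported outcomes, and no comparison
against experimental imaging is made anywhere.

Replicate protocols run scaled down in the test suite (5 instead of 21
fibrosis replicates on a 700 µm domain for 5 of 15 days; 3 replicates of
the others; diffusion substep 0.1 min instead of 0.01 — harmless because
the implicit solver's steady states are substep-robust). The full printed
protocols are the builder defaults and run unmodified via
`run_simulation()`, at minutes per replicate.

## Numerical choices and degenerate inputs

* Half-open voxel convention: a point on an interior face belongs to the
  higher-index element, making position-to-element mapping total.
* Exactly anti-aligned guidance vectors (possible only at $\beta sa$
  combinations that cancel) retain the previous direction rather than
  emitting NaN; coincident cell centers are jittered by a seeded random
  1e-6 µm displacement with a warning.
* Boundary influx insets cells by one radius plus a sub-micrometer random
  jitter: an exactly collinear row is mechanically degenerate (pair forces
  never acquire a component away from the edge).
* Dead cells exert mechanics and secrete but have zero motility and do not
  remodel; they shrink exponentially and are removed below 3% of their
  default volume or upon phagocytosis.
* All randomness flows through R's RNG: a run is bit-reproducible from its
  seed, and replicates share a fixed placement seed so only dynamics vary.
* The deterministic proof-of-concept experiments set $\tau_P =
  \Delta t_{mech}$, so the direction refresh happens every step; with
  $\beta = 1$ the composed direction is deterministic and the persistence
  time is immaterial.

## Known limitations

ECM elements are uncoupled (no force transmission between elements, no
remodeling spread to neighbors); anisotropy cannot decrease; contact
guidance is deterministic given the refresh draw (no von Mises sampling);
cells read and write only the element under their center, so fast cells on
tightly curved paths can miss cues — visible as occasional track jumping on
the inner concentric circles, which is why the central 80 µm of that field
is excluded from statistics. The scenarios are single-layer (2-D) although
all state is stored in 3-D; nothing in the engine forbids thicker domains,
but none of the shipped experiments exercise one.
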