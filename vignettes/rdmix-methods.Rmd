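---
title: "Methods: mixed-dimensional reaction-diffusion in rdmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-dimensional reaction-diffusion in rdmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdmix)
```

## The model class

`rdmix` simulates networks of chemical species distributed over a cell-like
geometry in which *volume* species (concentration $u_i^m$, in µM) live in
tagged subdomains $\Omega^m$ of a single simplicial parent mesh, and
*surface* species (density $v_j^q$, in molecules µm⁻²) live on tagged
co-dimension-1 facet sets $\Gamma^q$ (exterior boundaries or interior
interfaces).  The governing equations are mass balances,

$$\partial_t u_i = \nabla\cdot(D_i \nabla u_i) + f_i(u),\qquad
D_i \nabla u_i\cdot n^m = -R_i(u|_\Gamma, v)\ \text{on}\ \Gamma^q,$$
$$\partial_t v_j = \nabla_S\cdot(D_j \nabla_S v_j) + g_j(u|_\Gamma, v),$$

where $f$ collects volume reactions, $g$ surface reactions, and $R$
surface-bound fluxes that may read the *traces* of volume fields on the
membrane — from one side (volume–surface reactions) or both sides of an
interior interface (volume–surface–volume reactions, e.g. a pump).  The
sign convention is fixed and documented next to the assembly code:
$n^m$ is outward from volume $m$ and $R > 0$ is flux *into* the volume.
On interior interfaces the positive direction is outward from the
first-listed bordering volume of the surface compartment — the mesh alone
does not orient an interface, so the declaration order carries that
information.

Units are a fixed base system (µm, s, molecule) with
$1\,\mu M = 602.214076$ molecules µm⁻³.  A surface-bound rate may be
declared either in molecules µm⁻² s⁻¹ or in µM·µm s⁻¹; validation checks
dimensional compatibility of each declared rate unit with the canonical
unit of its reaction type and the assembler applies the conversion on each
side, so a single reaction deposits consistent amounts in a µM volume
equation and a molecules µm⁻² surface equation.  We deliberately check
units only at the granularity of whole rate expressions — inferring units
inside arbitrary nonlinear sub-expressions (e.g. inside a Hill function)
is not well posed without annotating every parameter, and the whole-rate
check already catches the common errors (declaring a µM²/s mass-action
product where µM/s is required).

## Rates, symbols and exact Jacobians

Rate expressions are strings over declared species, parameters, time `t`
and coordinates, in a fixed grammar (`+ - * / ^ pow exp log sqrt tanh
hill softmin`).  They are parsed into R expressions, checked against the
symbol table, and differentiated *exactly* with respect to every species
symbol (`stats::D` after rewriting the smooth macros into primitives), so
the Newton matrix is the true Jacobian of the discrete residual, not an
approximation.  Hard conditionals on species are rejected at parse time:
discontinuous behaviour (a channel that shuts at a threshold) belongs in
the event system, which checks conditions between steps and latches by
default.  This mirrors how threshold-gated conductances are best handled
in implicit schemes — a discontinuity inside the residual destroys
Newton's convergence theory, while a between-step parameter assignment
leaves every solve smooth.

## Discretization

Space is discretized with continuous piecewise-linear (P1) elements on the
parent mesh's simplices.  Constant-coefficient mass and stiffness matrices
are integrated in closed form; surface stiffness uses the per-triangle
tangent-plane (cotangent) form, which is the standard discrete
Laplace–Beltrami operator on a triangulated membrane.  Nonlinear reaction
terms use **vertex (mass-lumped) quadrature**: the load is the lumped mass
weight times the rate evaluated at vertex values.  We chose vertex
quadrature over higher-order rules because it makes every reaction
Jacobian block diagonal per vertex (cheap, sparse, and exactly consistent
with the symbolic derivatives) and it preserves the optimal second-order
L2 accuracy of P1 elements in practice — the convergence study below is
the evidence.  Spatially varying coefficients (diffusivity, the
axisymmetric weight) are integrated exactly for linear variation: closed
moments for mass, centroid values for stiffness (P1 gradients are
element-constant).

Axisymmetric problems are solved on a 2D $(r, z)$ half-section with all
volume and boundary integrals weighted by $r$; because the weight is
linear, this weighting is exact, the $r=0$ axis carries zero measure (and
is thereby a natural no-flux boundary), and reported cylindrical measures
are $2\pi\int r$.

Time is discretized with implicit Euler: each step solves
$M(u^{n+1}-u^n) = \tau(-K u^{n+1} + L(u^{n+1}, t_{n+1}))$ by
Newton–Raphson (absolute residual tolerance $10^{-10}$, relative
$10^{-8}$, at most 25 iterations) with a sparse direct LU solve.  When
every rate derivative involves only constant parameters the Jacobian
depends on $\tau$ alone and its factorization is cached across steps,
which makes long linear runs (and the steady-state drives in the
verification suite) cheap.  A direct solver was chosen over Krylov
iteration for bit-stable determinism at the problem sizes this package
targets (≤ ~10⁵ unknowns); nothing in the block structure precludes an
iterative solver.

Step control: $\tau$ grows by 1.25 when the previous step converged in ≤ 3
Newton iterations, shrinks by 0.7 at ≥ 8, holds otherwise, clamped to
user bounds — a monotone policy (fewer iterations never yields a smaller
step).  The specific factors are declared package defaults satisfying that
contract.  On Newton divergence or concentrations below
$-10^{-8}\times$ the species scale, the step restarts at $\tau/2$, up to
10 times; tiny negative values are clamped to zero *at output only*,
never in the evolving state, so the restart criterion and the dynamics
see the raw solution.

## Scalar coupling and events

A well-mixed pool (e.g. a cytosolic concentration outside the meshed
domain) couples to a PDE field through a membrane-flux integral.  Before
each step the scalar $s$ is advanced by a predictor
$s_{\mathrm{est}} = s + \tau\,p\!\int_\Gamma k\,(F - s)\,d\Gamma$ using the
pre-step field $F$; the PDEs are then solved with $s_{\mathrm{est}}$ bound
to the declared parameter; afterwards a corrector repeats the update with
the post-solve field and $s_{\mathrm{est}}$ in the integrand, once per
accepted step.  For a clamped uniform field this pair contracts the gap
$s-F$ by exactly $1 - \tau a(1-\tau a)$ per step ($a$ = prefactor × rate ×
area); the tests assert that closed form, derived independently, rather
than the plain implicit-Euler factor $1/(1+\tau a)$, which the
predictor–corrector scheme does not produce.

## Model reductions

*Conservation elimination.*  A linear combination of species is a
conservation law when it is annihilated by every reaction's
stoichiometry.  Detection is linear-algebraic — the left null space of the
stoichiometry matrix restricted to eligible species — never name-based.
Eligibility is strict: members must share one compartment and one
diffusion coefficient, must not appear in the stoichiometry of any
surface-bound reaction, and the combination's initial value must be
spatially uniform (a uniform conserved combination stays uniform under
equal-D diffusion; a non-uniform one would have to be evolved, which
defeats the purpose).  One species per independent law is eliminated after
a Gauss–Jordan pass that gives each null vector a unique pivot, so every
reconstruction formula references only kept species.  The membrane
phosphorylation benchmark is deliberately *not* reduced: its conserved
pair is touched by the membrane flux, which fails the eligibility rule
even though the sum is conserved — the rule trades a little generality for
never producing a wrong elimination.

*Well-mixed (0D) reduction.*  Each species collapses to one state; volume
reactions enter directly and surface-bound fluxes are scaled by
(surface measure)/(volume measure) with the same unit conversions as the
PDE assembly.  The reduction refuses space-expression parameters, which
have no well-mixed meaning.  The returned right-hand side works with any
standard initial-value integrator; the diagnostic `ode_limit_check()`
integrates it with `deSolve::lsoda` and compares compartment averages
against the PDE with all volume diffusivities raised.

## Synthetic geometry, and what the tests do and do not show

The generators produce a structured tetrahedral slab (Kuhn subdivision;
membrane on one face), a structured 2D rectangle, and nested
spheres/disks (icosphere- or polygon-based radial meshes with conforming
prism splitting) emulating a cell containing one organelle.  These cover
the topological situations the solver must handle — exterior membranes,
interior interfaces with two-sided traces, curved surfaces — with exactly
known measures, which is what the verification needs.  They do not emulate
the irregular, multi-scale geometry of microscopy-derived meshes: element
quality there is worse and constants in the error bounds larger, so
passing convergence tests here demonstrate the *orders* and the
machinery, not absolute errors on realistic geometries.

## The verification benchmark

The analytic benchmark is a protein phosphorylated at a membrane and
dephosphorylated in the bulk: on a slab of thickness $L$ with equal
diffusivities and uniform initial total $A_{tot}$, the steady
phosphorylated profile is

$$Ap(z) = C\cosh\!\big((L-z)/\lambda\big),\quad \lambda=\sqrt{D/k_p},\quad
C = \frac{k_{kin}A_{tot}}{(D/\lambda)\sinh(L/\lambda) + k_{kin}\cosh(L/\lambda)},$$

derived from $D\,Ap'' = k_p Ap$ with the Robin flux balance
$-D\,Ap'(0) = k_{kin}(A_{tot} - Ap(0))$ and $Ap'(L)=0$.  The tests verify
this closed form against an independent 1D finite-difference
boundary-value solve before using it.  The fixture pins $L = 1$ µm,
$k_{kin} = 1$ µm s⁻¹, $k_p = 1$ s⁻¹, $A_{tot} = 1$ µM — round,
biologically plausible magnitudes chosen once; the verification contract
is convergence *order* and error *ordering* across $D$, both of which are
insensitive to the exact values.

The spatial study solves 4 uniform refinements ($n = 2..16$ boxes per
edge, ~10k unknowns at the finest) to steady state and fits the L2-error
slope (expected 2).  Steady state is declared when the relative change of
the state norm per unit time falls below $10^{-10}$; because the implicit
Euler fixed point *is* the steady state of the spatial discretization for
any $\tau$, the drive uses large cached-factorization steps.  The temporal
study fixes the mesh and halves $\tau$; the order-1 fit uses
self-convergence against the same mesh at $\tau_{\min}/16$, measured at
$t = 2/k_p$ during the active transient (where backward-Euler error
accumulates linearly), while the plateau is measured at $t = 8$ s against
the analytic steady profile: there the continuous transient has decayed
but a coarse $\tau$ still lags it, so the error falls first order in
$\tau$ until it flattens at the spatial floor, and the onset of that
plateau moves to smaller $\tau$ as $D$ grows.  These horizons and the
problem sizes are the package's declared study conditions.

## Numerical choices and degenerate inputs

Simplices with measure below $10^{-12}\times$(bounding-box scale)$^d$ are
rejected as degenerate, naming the entity.  Cells are stored positively
oriented (reordered on load).  Interior facets between like-tagged cells
are rejected unless explicitly declared internal membranes, catching the
most common tagging mistake.  Vertex and cell indices are 1-based
throughout, as is idiomatic in R; the Gmsh reader/writer translates.
Only the MSH 4.1 ASCII dialect is read — one bit-exact dialect beats a
half-supported zoo — and 2.2-format files fail loudly.  Output times are
aligned to accepted steps (the stepper caps $\tau$ to land on them
exactly) rather than interpolated, keeping outputs solver-faithful, and
CSV output uses 17 significant digits so repeated runs can be compared
byte for byte.

## Known limitations

Co-dimension-1 coupling only (no 0D/1D features except through the scalar
coupling); diffusion as the only transport mechanism; P1 elements and
first-order time stepping; serial execution with direct linear solves,
appropriate up to order-10⁵ unknowns; no mesh generation from images and
no mesh-quality conditioning — meshes are taken as given.
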