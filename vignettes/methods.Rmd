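---
title: "Observer-based H-infinity fuzzy tracking control of an activated-sludge process: models, synthesis and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TS modelling, LMI synthesis and closed-loop verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The process model

The plant is the classical four-state activated-sludge loop: an aerated
tank where biomass `X` degrades substrate `S` while consuming dissolved
oxygen `Co`, and a settler that returns thickened biomass `Xr` to the
tank. The mass balances are

    dX/dt   = mu(S,Co) X - D (1+qr) X + qr D Xr
    dXr/dt  = D (1+qr) X - D (beta+qr) Xr
    dS/dt   = -mu(S,Co) X / Y - D (1+qr) S + D (Sin + dSin(t))
    dCo/dt  = -K0 mu(S,Co) X / Y - D (1+qr) Co + D Coin + KLa (Cs - Co)

with the double-Monod growth law `mu = mumax * S/(Ks+S) * Co/(Kc+Co)`.
The manipulated inputs are the dilution rate `D` and the aeration rate
`KLa`; only `Co` is measured. All rates are per hour and all
concentrations in mg/l ("one day" in the disturbance scenario is 24 h);
the default parameters are `asp_parameters()`. The influent-substrate
deviation `dSin(t)` enters as the disturbance `d(t) = D * dSin(t)` on the
substrate balance.

A fact worth stating explicitly, because every numerical choice below
leans on it: at steady state the settler balance pins `Xr/X =
(1+qr)/(beta+qr) = 2` and the substrate balance gives

    X* = Y (Sin - (1+qr) S*) / ((1+qr) beta / (beta+qr)),

about 170--210 mg/l for set-points `S*` between 45 and 60 mg/l, with the
equilibrium dilution `D* = mu(S*, Co*) (beta+qr)/((1+qr) beta)` around
0.05/h (`asp_equilibrium()`). The default operating domain, the default
initial state and the state normalization below are all anchored at these
equilibria.

## Exact Takagi--Sugeno representation

The sector-nonlinearity method rewrites the dynamics as `xdot = A(z) x +
B(z) u + G d` with six scalar premise variables

    z1 = mu - S,  z2 = X,  z3 = Xr,  z4 = Co,
    z5 = mumax S X / ((Ks+S)(Kc+Co))  (= mu X / Co),  z6 = S,

bounds each `zj` over an operating box, and enumerates all `2^6 = 64`
bound combinations as linear vertex models blended by product-form
membership weights. The representation is *exact* inside the box --- the
package treats the identity `sum_i h_i(z(x)) (A_i x + B_i u + G d) ==
plant_rhs(x,u,d)` as the binding contract and tests it to `1e-8` relative
error over random in-domain states.

Two points about the factorization deserve emphasis.

**The factorization is not unique, and the two syntheses want different
ones.** The reaction terms of the oxygen row can be written either as
`-(K0/Y) z5 * Co` alone, or with an added zero-sum pair `-z3 * X + z2 *
Xr = 0`. The pair contributes nothing to the dynamics, but it changes the
vertex matrices:

* With the pair (`factorization = "coupled"`), the biomass states appear
  in the measured dissolved-oxygen row of every vertex model. Without it
  no vertex model is observable from the `Co` measurement at all (each
  vertex's `Co` row would involve only `Co` itself), so the observer
  synthesis *requires* this form.
* Without the pair (`factorization = "tracking"`), the uncontrolled-block
  coupling `A21` of every vertex is zero. With the pair present, `A21`
  carries entries of the size of the biomass concentrations themselves,
  and the tracking LMIs demand that one shared Lyapunov block annihilate
  them at every vertex simultaneously --- which is impossible at finite
  variable scales. Empirically and by a small alignment argument (the
  required `X1` correlation structure violates positive definiteness of
  the first diagonal block), the tracking LMI system with the coupled
  factorization is *weakly infeasible*: its feasibility margin approaches
  zero from below under every domain size and state scaling we tried, but
  never attains it. With the sparse form the same LMIs solve in under a
  second.

Both forms satisfy the exactness contract and both are tested against it;
they differ only in how the zero reaction term is distributed. The
pipeline therefore builds the coupled model for the observer and the
sparse model for the controller. The residual between the two
representations never enters any certified quantity: each energy
inequality is evaluated with the factorization its synthesis used.

**Premise bounds.** Identity premises inherit the state box. `z1` and
`z5` are bounded by dense grid evaluation (200 points per axis over `(S,
Co)`, with `z5 = X * f(S, Co)` factored so the `X` extremes multiply the
grid range of `f > 0`), widened by a 1 percent relative safety margin on
each side. The functions are smooth and monotone in each coordinate on
the box, so grid-plus-margin is a practical enclosure; the enclosure is
property-tested on 10^4 random states. During simulation, premise values
outside their intervals are clipped before membership evaluation, which
keeps the weights on the probability simplex at the price of exactness
outside the box --- that mismatch is charged to the disturbance channels
of the energy inequalities (below), never silently ignored.

**Default operating domain.** `X in [120, 300]`, `Xr in [240, 600]`, `S
in [25, 90]`, `Co in [0.5, 9]` mg/l: a generous band around the
closed-loop equilibria of the benchmark set-point schedule (45 -> 60 ->
50 mg/l substrate, 2 -> 6 -> 4 mg/l oxygen at days 0/20/40). An earlier,
much wider box (biomass up to 1500 mg/l) made the vertex set so extreme
that the tracking synthesis was infeasible at the benchmark relaxation
scalars; shrinking the box to the physically visited region is the
documented fallback, not a silent retuning: no closed-loop trajectory in
the shipped scenarios leaves the default box.

## Reduced-order tracking synthesis

The state is split into `x1 = (X, Xr)` (uncontrolled) and `x2 = (S, Co)`
(controlled). A reference model `x2r' = Ar x2r + r(t)` with `Ar =
diag(-11, -12)` per hour generates the tracked trajectory; the package
drives it with `r = -Ar * setpoint(t)` so each scheduled set-point is an
equilibrium of the reference. `Ar`'s unit is taken as 1/h, making the
reference settle within fractions of an hour --- step-like on plots in
days, consistent with the benchmark figures.

The PDC control law `u = sum_i h_i(zhat) K_i (xhat2 - x2r)` uses the
estimated controlled states and one gain per vertex model. Closing the
loop and collecting the tracking state `xa = (x1, x2 - x2r)` against the
lumped disturbance `xi = (eo2, x2r, r, w1, w2)` (estimation error of the
controlled states, reference state and input, and the residual
disturbance channels) yields the weighted energy inequality

    int xa' Q xa dt  <=  gamma^2 int xi' xi dt,   gamma = sqrt(gamma1+gamma2),

certified by two families of 16x16 LMIs: one per vertex (diagonal terms)
and one per vertex pair (2016 pairs at 64 vertices), in variables `X1,
X2` (Lyapunov blocks), `Y_i` (gain parametrization, `K_i = Y_i X2^-1`)
and the transformed weights `Qtilde`. Two prescribed relaxation scalars
`alpha3, alpha4` replace the nonconvex `-alpha X2^2` term by its affine
tangent bound, and `alpha1, alpha2` bound the disturbance cross terms.
The benchmark scalars are `alpha1 = alpha2 = 0.4`, `alpha3 = 300`,
`alpha4 = 295`, `gamma1 = gamma2 = 0.4`. Equality `alpha = gamma` is
accepted: the corresponding cross term then drops out of the dissipation
inequality, which still certifies the (non-strict) energy bound.

Three numerical choices matter here.

* **State normalization.** The concentrations span two decades; the LMIs
  mix them with fixed identity couplings. All synthesis runs in
  normalized coordinates `x' = T^-1 x` with `T` the geometric means of
  the premise bounds (`default_scaling()`); gains are mapped back to
  physical units (`K = K' T2^-1`). The certified inequality is then the
  energy bound for the *normalized* signals --- each state measured
  relative to its nominal magnitude, which is also the physically
  sensible way to compare a 1 mg/l oxygen error with a 1 mg/l biomass
  error. Certificates and empirical ratios are consistently evaluated in
  these coordinates.
* **Weight normalization.** Pure feasibility is degenerate: the solver
  can grow the Lyapunov blocks until the recovered weight `Q =
  P Qtilde P` (with `P = X^-1`) collapses and the certificate, while
  valid, demands nothing. The pipeline default therefore fixes
  `Qtilde = I` (mirroring the benchmark's reported weights) and minimizes
  `trace(X1) + trace(X2)`, which presses `P` --- and with it the
  effective tracking weight --- as high as the constraints allow. The
  plain feasibility mode remains available.
* **Reduced vertex set.** The controller is synthesized by default on the
  8-vertex set obtained by collapsing the identity premises `z2, z3, z4`
  at their midpoints (`2016 -> 28` pair LMIs). The resulting model error
  off the midpoint slice is part of the certified disturbance channel
  `w1, w2` --- tracking degrades gracefully, and the closed-loop scenario
  confirms sub-mg/l steady errors. The full 64-vertex synthesis is
  exposed (`reduced = FALSE`) but is at the edge of what the built-in
  solver resolves: the pair family couples vertices in which the
  dilution input column changes sign, and we have not obtained a
  certified solution at the benchmark scalars on the default domain.
  The observer, by contrast, always uses the full 64-vertex model: a
  collapsed observer model is exact only on the midpoint slice and its
  off-slice bias (hundreds of mg/l/h in the recycled-biomass balance at
  low oxygen) corrupts the estimates that feed the controller.

## Disturbance-augmented observer

The disturbance `d` is appended as a fifth state with zero nominal
dynamics (`Abar_i = [A_i G; 0 0]`, `Cbar = [0 0 0 1 0]`), and a fuzzy
Luenberger observer with memberships evaluated at the *estimated*
premises reconstructs all five states from the dissolved-oxygen
measurement. Feasibility of the 10x10 LMIs

    [ sym(Po Abar_i - Z_i Cbar) + R,  Po ;  Po,  -eta I ] < 0,  eta < nu^2

yields gains `L_i = Po^-1 Z_i` and certifies `int ebar' R ebar dt <= eta
int wbar' wbar dt` for the estimation error `ebar` against the lumped
disturbance `wbar` (membership mismatch plus the disturbance derivative).
Two modes are provided because the benchmark reports a specific pair
(`nu = 1.0681`, `eta = 1.1408`) without stating which scalar was chosen:
prescribed-`nu` feasibility (the pipeline default, at `nu = 1.0681`), and
minimize-`eta`. The minimization is scale-degenerate --- scaling `(Po,
Z, R, eta)` jointly preserves feasibility, so without a normalization the
infimum of `eta` is an artifact of the positivity floors --- hence
minimize-`eta` floors the error weight at `R >= I`, which makes the
minimized level meaningful. In prescribed mode `R` is only required
positive definite, as the theorem states.

## The LMI solver

No semidefinite-programming backend exists in the R ecosystem this
package targets, so it ships a small dense-block interior-point solver
(RcppArmadillo): affine matrix-inequality blocks are compiled to `(F0,
basis)` form by probing the (literally transcribed) assembly functions at
unit values; feasibility maximizes a common negativity margin `t` with
`F_k(x) <= -t I` by log-barrier path following (damped Newton with a
Jacobi-scaled, adaptively ridged Newton system and a
positive-definiteness-preserving line search); linear objectives run a
second barrier phase from the phase-I point. Box bounds `|x_j| <= 1e9`
give the barrier an analytic center (the bare log-det barrier is
unbounded along directions that inflate every cone), and the slack is
floored at its starting value so early centering steps cannot drag it
orders of magnitude down. Strict inequalities carry an explicit `1e-6`
margin; every solve is re-verified afterwards by direct eigenvalue
computation of all blocks *and* of the pre-relaxation quadratic
conditions (the Lyapunov/Schur chain run backwards), so a solver failure
cannot silently masquerade as a certificate. Declared infeasibility
means the phase-I optimum margin converged to a non-positive value; a
stalled solve reports `"inaccurate"` and the synthesis functions raise an
error rather than returning unverified gains. The solver is
deterministic: identical inputs give identical gains.

## Closed-loop verification

The simulator integrates the coupled 11-state system (plant, 5-state
observer, 2-state reference) with `lsoda` at `rtol 1e-8 / atol 1e-10`,
splitting the time axis at set-point switches and kinetic-event edges so
the integrator never steps across a discontinuity. The scenario is the
benchmark's: a sinusoidal influent-substrate variation (period one day,
amplitude 5 percent of `Sin = 200`) and two temporary +10 percent
kinetic-parameter steps (`mumax` at day 10, `Kc` at day 50, each lasting
two days --- read as a two-day window, reverting afterwards; persistent
changes are a configuration option). Disturbances act on the plant only;
observer and controller keep the nominal model. Inputs are clamped
non-negative (physical dilution/aeration); upper bounds are off by
default. The default initial state is the open-loop equilibrium of the
first set-point, the observer starts at +20 percent of it with zero
disturbance estimate, and the reference at its first set-point. The
set-point schedule itself is visible only in the benchmark's figures, so
the default (45/60/50 and 2/6/4 at days 0/20/40) is a declared artifact
choice, not a printed value.

The empirical energy ratios are computed by trapezoidal quadrature on the
output grid. The residual channels `w1, w2, wbar` are evaluated
*residually*: `w = xdot_true - sum_i h_i(zhat) (A_i x + B_i u)` (rows as
appropriate), with `xdot_true` recomputed from the disturbed plant. This
makes the rewritten closed-loop identities exact along the trajectory and
charges everything the design did not model --- membership mismatch,
kinetic-parameter changes, input clamping (the tracking residual is taken
against the unclamped PDC law, whose gain terms the identity encodes),
and the source formulation's dropped `G2 d` term in the controlled
subsystem --- to the disturbance side, against which the certificates
hold for *arbitrary* signals. Because both inequalities are certified
with zero initial error, the reported `*_certified` flags use the
initial-state-corrected form `num - V(0) + V(tf) <= level * den`; raw
ratios are reported alongside and, in the shipped scenarios, sit orders
of magnitude below their bounds (the `xi` channel contains the reference
signal itself, so its energy is large --- a known weakness of this family
of tracking guarantees, discussed honestly here rather than hidden).
If a disturbance energy integral is below `1e-12` the ratio is reported
as not excited instead of a number.

## Problem sizes and runtimes

The shipped tests and the acceptance script use: the full 64-vertex
observer synthesis (64 LMIs of order 10; about a second), the reduced
8-vertex controller synthesis (8 + 28 LMIs of order 16; a few seconds),
TS exactness on 1000 random states per factorization, membership-simplex
checks on 10^5 random states, and the full 60-day scenario at a 0.25--0.5
h output step (about 20 s). These sizes are the package's default study
conditions; the full 64-vertex controller problem (2080 LMIs, 274 scalar
variables) assembles and runs but, as discussed above, has not produced a
certified solution at the benchmark scalars.

## Known limitations

* The certified tracking inequality weighs states in normalized units
  and includes the reference trajectory in the disturbance channel; it is
  a robustness certificate, not a guarantee of small absolute tracking
  error. The closed-loop simulation is the quantitative check.
* All guarantees are local to the operating box; outside it memberships
  are clipped and only the residual-accounted empirical inequalities
  remain meaningful.
* The printed gain and Lyapunov matrices of the benchmark are not
  reproduced: LMI solutions are non-unique and solver-dependent, so the
  reproducible surface is the certificate properties and attenuation
  levels, not matrix entries.
* No measurement noise, actuator dynamics or sampled-data effects are
  modelled, matching the scope of the source study.
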