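# fuzztrack

Observer-based robust H∞ fuzzy tracking control of an activated-sludge
wastewater-treatment process, in R.

The package is for control engineers and bioprocess modellers who want a
fully scripted, certifiable pipeline for a classic problem: force the
substrate `S` and dissolved-oxygen `Co` concentrations of an activated
sludge plant to follow reference trajectories, manipulating the dilution
rate `D` and the aeration rate `KLa`, when only `Co` is measured and the
influent and kinetics are disturbed.

## What it does

1. **Exact Takagi–Sugeno (TS) modelling.** The four-state mass-balance
   model (biomass `X`, recycled biomass `Xr`, substrate `S`, oxygen `Co`)
   with double-Monod kinetics `μ = μmax·S/(Ks+S)·Co/(Kc+Co)` is rewritten
   *exactly* as a convex blend of 2⁶ = 64 linear vertex models by the
   sector-nonlinearity method, using six premise variables over a
   documented operating box. The identity
   `Σᵢ hᵢ(z(x))(Aᵢx + Bᵢu + Gd) = f(x,u,d)` is property-tested to 1e-8.
2. **LMI controller synthesis.** A reduced-order PDC tracking controller
   `u = Σᵢ hᵢ(ẑ)Kᵢ(x̂₂ − x₂ᵣ)` for the controlled pair `x₂ = (S, Co)`
   against a reference model `ẋ₂ᵣ = Ar x₂ᵣ + r`, with a certified H∞
   bound `∫xₐᵀQxₐ dt ≤ γ²∫ξᵀξ dt`, `γ = √(γ₁+γ₂)`, via two families of
   16×16 linear matrix inequalities (one per vertex, one per vertex
   pair).
3. **LMI observer synthesis.** A disturbance-augmented fuzzy Luenberger
   observer (fifth state = the influent disturbance `d`) with unknown
   premises, certified by `∫ēᵀRē dt ≤ η∫ω̄ᵀω̄ dt`, `η < ν²`, from one
   10×10 LMI per vertex.
4. **Closed-loop verification.** A stiff-capable simulator couples plant,
   observer, PDC law and reference model under the benchmark disturbance
   scenario (5 % sinusoidal influent substrate with a one-day period, and
   temporary +10 % changes of `μmax` at day 10 and `Kc` at day 50), then
   measures the empirical energy ratios against the certified levels.

Because no SDP backend exists in this R stack, the package includes a
small dense-block interior-point LMI solver (RcppArmadillo) with
post-solve certificate re-verification by direct eigenvalue checks —
solved gains are never reported without an independent numerical
certificate. See `vignette source in vignettes/methods.Rmd` for the
science, the numerical choices and their rationale.

## Worked example

```r
library(fuzztrack)
res <- run_pipeline(default_config())
```

This builds the premise bounds over the default operating domain, the two
exact TS factorizations (observer- and controller-oriented), solves both
LMI syntheses (8-vertex reduced controller, full 64-vertex observer at
the prescribed level ν = 1.0681), verifies the certificates, and runs the
60-day disturbance scenario. On this machine it prints, via the summary
lines in the example script:

```
attenuation levels: gamma = 0.8944  nu_effective = 1.0658  (eta = 1.136)
certificates: controller TRUE (worst eig -0.00137) observer TRUE (worst eig -0.0101)
tracking RMSE  S: 2.63 mg/l   Co: 0.168 mg/l
estimation RMSE  X: 7.1  Xr: 16.4 mg/l
energy ratios: tracking 1.44e-06 <= gamma^2 = 0.8 ; observer 0.000178 <= eta = 1.136
```

Reading this: `gamma = √(0.4+0.4) = 0.8944` is the certified tracking
attenuation level and `nu_effective = √η` the achieved observer level
(below the prescribed 1.0681). The certificate lines are the worst
eigenvalues of the independently re-checked Lyapunov conditions — all
strictly negative. The RMSE lines summarize the 60-day simulation:
steady tracking errors are a fraction of a mg/l (the RMSE is dominated by
the set-point transitions), and the unmeasured biomass states are
reconstructed from the oxygen measurement alone to within a few percent.
Both empirical energy ratios sit far below their certified bounds.

The same pipeline is scriptable from a shell via `inst/exec/fuzztrack`
(`build-ts`, `synth-controller`, `synth-observer`, `simulate`,
`reproduce-paper`, `check-certificates`; nonzero exit on any failed
certificate), with every tunable in a YAML config (`default_config()`
documents them all).

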