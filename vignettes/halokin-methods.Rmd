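---
title: "Modelling two-cycle enzymatic halogenation progress curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-cycle enzymatic halogenation progress curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halokin)
```

## The model

halokin analyses the kinetics of enzymes that install up to two halogen
atoms on a phenolic (or aniline) substrate, as the FAD-dependent
halogenase PltM does. The measured quantity is not a concentration but
the HPLC observable: at each quench time, the percent of
substrate-derived material present as unreacted substrate S,
mono-halogenated intermediate P1 and di-halogenated product P2.

The default mechanism is two consecutive catalytic cycles with release
and rebinding of the free intermediate:

$$E + S \underset{k_{d,1}}{\overset{k_{a,1}}{\rightleftharpoons}} ES
  \xrightarrow{k_{cat,1}} E + P_1, \qquad
  E + P_1 \underset{k_{d,2}}{\overset{k_{a,2}}{\rightleftharpoons}} EP_1
  \xrightarrow{k_{cat,2}} E + P_2.$$

Release and rebinding — rather than conversion of an enzyme-bound
intermediate or binding of a second substrate molecule to an
enzyme–product complex — is the only variant consistent with the free
mono-halogenated intermediate that dominates mid-course HPLC traces and
with per-cycle Michaelis constants defined as
$K_m = (k_d + k_{cat})/k_a$. Halide, FAD, NADPH and the coupled
reductase/dehydrogenase cycle are in large excess or continuously
regenerated in the optimized assay and are deliberately not state
variables; the fitted mechanism contains none of them.

For an asymmetric substrate the first cycle yields two distinguishable
mono products (branches *a* and *b*). We model a **single shared ES
complex** that partitions:

$$ES \xrightarrow{k_{cat,1a}} E + P_{1a}, \qquad
  ES \xrightarrow{k_{cat,1b}} E + P_{1b},$$

with each mono product rebound and converted to the common P2. This
choice (over two parallel first-cycle complexes) has three consequences
we consider decisive: the early-time mono ratio is exactly
$k_{cat,1a}:k_{cat,1b}$; setting $k_{cat,1b}=0$ reduces the dynamics
*exactly* to the sequential scheme (a dead-end second complex would
instead sequester enzyme); and the first cycle has a single Michaelis
constant $K_{m,1} = (k_{d,1}+k_{cat,1a}+k_{cat,1b})/k_{a,1}$ shared by
both branches — which is why the branch rows of the published constants
table carry identical $K_m$ values. Because the shared constant is
structural here, no option to release the equal-$K_m$ constraint is
provided.

Units are fixed package-wide: minutes, micromolar, Daltons, percent.

## Parameters and identifiability

Species fractions carry no information about the absolute association
rate: progress curves constrain $k_{cat}$ (through saturated flux) and
$K_m$ (through the sub-saturated tail), not $k_a$ itself. The package
therefore fixes $k_a$ (default 100 µM⁻¹ min⁻¹ — fast but below
diffusion limit; configurable) and parameterizes everything in
macroscopic $(k_{cat}, K_m)$ per step, converting internally via
$k_d = k_a K_m - k_{cat}$. A requested efficiency $k_{cat}/K_m > k_a$
is rejected with an instruction to raise $k_a$.

Two regimes deserve caution:

* **Tight binding** ($K_m \ll E_0$, e.g. the 0.076 µM first-cycle
  constant for resorcinol chlorination against 6 µM enzyme): the curve
  shape is almost independent of $K_m$, so its standard error is orders
  of magnitude larger than that of $k_{cat}$. The fitter reports this
  (huge SEs, or an explicit identifiability warning if the Gauss–Newton
  covariance is singular); it never masks it.
* **Branched second cycles**: with fractions-only data on duplicate
  8-point grids, the four second-cycle constants of a branched scheme
  lie in a nearly flat likelihood valley (saturated versus linear
  regimes with compensating enzyme allocation). First-cycle branch
  turnover numbers are well recovered; second-cycle ones are not a
  recovery target.
* **Allocation ridges**: when the second cycle binds much tighter than
  the first (the 3,5-dihydroxybenzyl-alcohol pattern: $K_{m,1}$ ~ 8 µM,
  $K_{m,2}$ ~ 0.4 µM $\ll E_0$), the substrate-depletion rate is
  $k_{cat,1}$ times the enzyme share sitting in ES, and that share
  depends on $K_{m,2}/K_{m,1}$. A ridge opens along which $k_{cat,1}$
  and $K_{m,1}$ rise together with re-allocated enzyme while the
  fraction curves barely move. At a noise sd of 2 percentage points
  the curve differences sit below the noise floor, so even the
  *global* least-squares optimum can sit tens of percent away from the
  generating $k_{cat,1}$ (noiseless fits recover it exactly). The
  second-cycle turnover, fixed by the saturated late-phase flux, stays
  well determined. This is a property of the design's information
  content, not of the optimizer, and users should read $k_{cat,1}$
  estimates in such regimes together with their (large) standard
  errors.

## Simulation

The mass-action ODE system is assembled symbolically from the reaction
list and integrated with a stiff-capable solver (`deSolve::lsoda`) at
absolute tolerance 1e-9 µM and relative tolerance 1e-8. Tolerances this
tight are needed because Michaelis constants span 0.076–1300 µM, putting
binding relaxation times up to ~10⁵ min⁻¹ against observation windows of
hours. Trajectories are checked against conservation of total enzyme and
of substrate-derived cores, and in the tests against an independent
fixed-step fourth-order integrator (step 10⁻³ min on mildly stiff
schemes, where an explicit method is stable).

Fractions assign enzyme-bound material to its cargo's class (ES counts
as S, EP1 as P1), because quench/extraction releases bound material
before quantification; at the assay's 6:500 enzyme:substrate ratio the
distinction is at most ~1 percentage point.

## The synthetic-data generator

`assay_design()` reproduces the optimized assay: substrate 500 µM for
chlorination/bromination or 250 µM for iodination, enzyme 6 µM,
duplicate reactions, quench grid 0, 5, 15, 30, 60, 120, 240, 360 min
(with an optional 720 min point for slow substrates; iodination uses
0–480 min). `simulate_timecourses()` adds additive Gaussian noise
directly to the percent fractions — the measured quantity — then clips
to [0, 100] and renormalizes each time point to sum 100. The default
noise sd of 2 percentage points was chosen once as a realistic HPLC
peak-area scale that yields Table-style relative standard errors on the
recovered constants (~4–25%); no replicate-level variance was published
to calibrate against. One shared seed drives an independent per-replicate
stream through a counter, so extending the design with more replicates
never perturbs earlier draws.

What the generator does *not* emulate: chromatographic peak shapes,
substrate or intermediate degradation (the natural substrate
phloroglucinol is unstable under the optimized conditions and was not
quantified), iodide-driven enzyme precipitation, or any halide-depletion
effects. Passing recovery tests therefore demonstrate estimator
correctness under the stated error model, not robustness to those
real-data pathologies.

## Global fitting

`fit_kinetics()` minimizes the unweighted sum of squared residuals
between observed and model fractions over every class, time point and
replicate simultaneously (all species share the percent scale, so equal
weights are the natural default; per-class weights are accepted). Free
parameters are $\log_{10} k_{cat}$ and $\log_{10} K_m$ per step, which
enforces positivity and makes the scale-spanning $K_m$ search
well-behaved.

Numerical choices that mattered in practice:

* **Optimizer**: Levenberg–Marquardt (`minpack.lm::nls.lm`) with box
  bounds ($k_{cat} \in [10^{-4}, 10^3]$ min⁻¹,
  $K_m \in [10^{-3}, 10^4]$ µM).
* **Finite-difference step**: the forward-difference Jacobian step is
  forced to ~10⁻³ on the log scale (`epsfcn = 1e-6`). The default
  square-root-machine-epsilon step sits *below* the ODE solver's
  relative tolerance, which turns the numerical gradient into noise and
  stalls the optimizer far from the optimum.
* **Initial guesses**: $k_{cat}$ from the maximal finite-difference
  slope of product-class formation divided by $E_0$; each $K_m$ from a
  1-D log-spaced grid scan (10⁻²–10³ µM) at the $k_{cat}$ guess, ties
  broken toward the smaller value.
* **Multi-start**: 5 seeded starts by default (the heuristic guess plus
  log-scale jitters of half a decade), best objective kept.
* **Failure handling**: parameter sets where the scheme is invalid or
  the integrator fails return a large constant residual, so the
  optimizer retreats instead of crashing; non-convergence is flagged on
  the result, not thrown.

Standard errors come from the Gauss–Newton covariance
$s^2 (J^\top J)^{-1}$ at the optimum (central-difference Jacobian on the
log scale), transformed to the natural scale by the delta method.
Derived efficiencies $k_{cat}/K_m$ carry first-order propagated errors
using the full covariance; the tests check them against Monte-Carlo
propagation and the asymptotic SEs against a parametric bootstrap.

## Product identification

The product module enumerates halogenation states (at most two halogens
— the enzyme's C-terminal helical region sterically excludes a third;
fluoride never yields product), computes monoisotopic masses from a
pinned IUPAC atomic-mass table with [M−H]⁻/[M+H]⁺ adducts, convolves
³⁵Cl/³⁷Cl (75.76/24.24) and ⁷⁹Br/⁸¹Br (50.69/49.31) binomial envelopes
(iodine is monoisotopic; full mode adds ¹³C), and matches observed m/z
lists against candidates inside a closed ±tolerance window restricted to
the 80–600 m/z instrument range. Observed per-substrate restrictions —
bromination of phloroglucinol stopping at the mono stage, the absence of
mixed Br/I products — have no mechanistic model and are supplied as
data (caps and forbidden pairs), not derived.

The regiochemistry engine works on an abstract six-position substituent
map rather than a molecular graph: candidate positions score +1 per
ortho activating group (OH/NH₂); positions flanked by two activating
groups are excluded whenever a non-between candidate exists; a methyl or
styrenyl group meta to two hydroxyls re-includes the between position
with top priority; nitro substrates return nothing. Symmetry-equivalent
selections are collapsed to lowest locants under the ring's automorphism
group. For substrates whose candidates are *all* between (the
phloroglucinol pattern) the exclusion rule is inert by construction, so
dihalogenation is still predicted. Fused or second-ring substrates are
outside the engine's scope, and positions are reported in the input
numbering only.

## Problem sizes in the test-suite and reproduction script

The suites run fits at the full assay design (48–64 observations, 4–7
free parameters), a 30-draw parametric bootstrap for the SE
cross-check, and 20 000-draw Monte-Carlo oracles for the noise model —
sizes chosen so each check exercises the full code path while a complete
run stays comfortably interactive on a single core.

## Known limitations

* Binding steps are pure mass action with a fixed shared $k_a$;
  ordered/ping-pong bisubstrate behaviour, halide dependence, product
  inhibition and FAD-recycling kinetics are out of scope.
* The noise model is additive on fractions; heteroscedastic or
  correlated chromatographic error is not modelled.
* Second-cycle branched constants are structurally weakly identified
  from fractions-only data (see above).
* The regio engine is rule-based; it encodes observed selectivity, not
  electronic-structure reactivity.
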