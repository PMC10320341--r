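---
title: "Energetics of self-positioned Turing patterns: models, methods, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics of self-positioned Turing patterns: models, methods, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's methods document: the models it implements,
the assumptions behind each computation, the tunable parameters and their
defaults, what the stochastic experiments can and cannot establish at desk
scale, and the numerical choices that a maintainer would want spelled out.

## The model

Three conformations $X_1, X_2, X_3$ of one protein complex interconvert
through four reversible reactions on a closed 1-D domain of length $L$
(no-flux walls, total molecule number $N$ conserved):

$$X_1 \underset{k_{21}}{\overset{k_{12}}{\rightleftharpoons}} X_2,\quad
  X_2 \underset{k_{32}}{\overset{k_{23}}{\rightleftharpoons}} X_3,\quad
  X_3 \underset{k_{13}}{\overset{k_{31}}{\rightleftharpoons}} X_1,\quad
  X_1 + 2X_2 \underset{\tilde k_{21}}{\overset{\tilde k_{12}}{\rightleftharpoons}} 3X_2 .$$

Each species diffuses with its own constant; the slow activator $X_2$
(DNA-bound form) against the fast substrate $X_1$ gives the classic Turing
ratio $d = D_1/D_2 > 1$, and $D_3 = D_1$ by default (same protein,
different conformation). Concentrations are 1-D densities $u = n/\Delta x$
in $\mu m^{-1}$, which fixes the units of the cubic rates at
$s^{-1}\mu m^2$.

Two independent reaction cycles exist: the autocatalytic/linear loop
$X_1 \to X_2 \to X_1$ with irreversibility
$\Gamma = \tilde k_{21} k_{12} / (\tilde k_{12} k_{21})$, and the linear
triangle with
$\Gamma' = k_{13} k_{32} k_{21} / (k_{12} k_{23} k_{31})$. Equilibrium is
$\Gamma = \Gamma' = 1$; the chemical driving per cycle is
$W = -\ln\Gamma$ in units of $k_BT$. Throughout the package the driving is
varied through $\tilde k_{21}$ alone, holding every forward rate fixed.

Two bundled presets hold the reference parameter blocks (`presetConfig`):
`"fig3"` (accuracy-energy study; $d = 25$, $N = 7200$, $k_{12}$ swept over
0.1-0.55 $s^{-1}$) and `"fig4"` (robustness study; $d = 150$,
$\Gamma = 0.011$). Two entries are not printed in the source material and
are package choices, made once:

* the fig4 $\tilde k_{12}$ is derived by inverting the cycle formula,
  $\tilde k_{12} = \tilde k_{21} k_{12} / (\Gamma k_{21})$;
* the fig4 default $N = 2800$ sits mid-way inside the three-stripe window
  $[N_{\min} \approx 1955,\ N_{\max} \approx 3765]$ that the package's own
  finite-size onset theory predicts at $\Gamma = 0.011$ ($N$ is the scan
  axis there, so no single value is printed);
* the fig3 preset default $k_{12} = 0.5\,s^{-1}$ (the value the fig4 block
  uses) and default driving $W = 3.21$ (a reference value used for the
  dissipation-fraction scan).

## Exact stochastic simulation

`runSSA` is a statistically exact Gillespie (direct-method) simulator of
the reaction-diffusion master equation on the box lattice: each box holds
integer counts, reactions fire per box with falling-factorial propensities
(`a = k\,\Delta x^{1-m}\, n_1^{\underline{\nu_1}} n_2^{\underline{\nu_2}}`,
exact CME combinatorics -- e.g. the reverse autocatalysis needs three
distinct $X_2$), and molecules hop to nearest neighbours at $D/\Delta x^2$,
end boxes hopping inward only. The weighted total is conserved exactly at
every event; snapshots store counts losslessly and concentrations are
derived on access. Randomness comes from R's RNG, so a seed makes a
trajectory bit-reproducible; ensembles seed replicate $i$ with
`seed_base + i`.

A per-event entropy tally ($\sum \ln a_{\text{fwd}}/a_{\text{bwd}}$,
evaluated at pre-/post-jump states) is available as the exact
trajectory-level dissipation estimator, alongside the cheaper mean-field
plug-in (time-averaged concentrations into the flux formulas). The two are
compared in the tests; the tally carries a one-time relaxation contribution
when started from a fixed state, so equilibrium nulls pre-equilibrate
before tallying.

## Deterministic dynamics and steady patterns

`integratePDE` integrates the mass-action PDEs by method of lines: central
second-order Laplacian with *mirror* ghost cells (the ghost equals the
boundary box, so an end box exchanges through its single interior
interface -- this is the discretisation whose fluxes match the stochastic
hops, and it conserves mass exactly), classical RK4 with a fixed step set
by the diffusion CFL and a reaction-Jacobian bound that uses twice the
largest per-box total as the concentration ceiling (patterns concentrate
mass well above the homogeneous level, so initial maxima are not a safe
stiffness bound).

`patternedSteadyState` seeds the homogeneous fixed point with a 1% cosine
of the target mode ($q_n = 2\pi n/L$; the $-\cos$ phase puts the $n$ peaks
in the interior, matching the tracked central stripe) and alternates PDE
relaxation with a Newton polish until $\max|\partial_t u| \le
10^{-8} c_{\mathrm{tot}}$ per second. The polish solves the full
steady-state system *stacked* with the mass constraint by least squares
(QR, progressively damped, backtracking on the max-residual): the
translational phase mode of a stripe pattern makes the plain Jacobian
near-singular, and replacing one equation by the constraint lets a line
search silently push the dropped component away -- the stacked form avoids
both failure modes. Failures are classified: wrong relaxed mode, vanishing
amplitude (below onset), or residual stall; scans treat all three as "this
(parameter, N) does not sustain the target pattern".

The bifurcation to the striped state is subcritical at the bundled
parameter sets: the amplitude stays finite arbitrarily close to onset and
coexisting homogeneous/pattern states occur. Related to this, at small
$k_{12}$ ($\le 0.3\,s^{-1}$) the well-mixed system is bistable at strong
driving and the equal-partition relaxation branch (the package's
documented fixed-point selection; all roots are available through
`fixedPointRoots`) is the low-activator root, which has no Turing onset.
The error-energy experiments therefore use $k_{12} \in \{0.4, 0.45,
0.5\}$, where the state is unique and the analysis unambiguous.

## Linear stability and onsets

`dispersionRelation` evaluates $\rho(q) = \max \mathrm{Re\,eig}[J - q^2
D]$ at the homogeneous fixed point. $q = 0$ always carries an exact zero
eigenvalue (the conserved total), so the Turing-relevant quantity is the
*interior* band maximum at $q > 0$; onset searches would otherwise latch
onto the zero mode. `onsetKt0` bisects $\tilde k_{21}$ to the value
$\tilde k_0$ where that maximum crosses zero (relative precision
$10^{-6}$).

Finite systems quantise $q$ at $q_n = 2\pi n/L$ (the `"neumann"`
convention $q_n = n\pi/L$ is available as a switch but off by default).
Because $q_n \ne q_0$, phase stability is lost at
$\tilde k_c = \tilde k_0 (1 - 3\xi^2 \Delta q^2) < \tilde k_0$ with
$\Delta q = q_n - q_0$. The growth rate near onset is modelled as
$\rho \approx (\epsilon_0 - \xi^2 \Delta q^2)/\tau$; accordingly $\xi^2 =
-\tfrac{\tau}{2}\, \rho''(q_0)$ with $\tau = 1/(\tilde k_0\,
|\partial\rho_{\max}/\partial \tilde k_{21}|)$ at onset. The printed
definition of $\xi$ omits the timescale ($\rho''$ alone has units
$s^{-1}\mu m^2$); this is the normalisation that makes
$3\xi^2\Delta q^2$ dimensionless and reproduces the finite-size behaviour,
and the package documents rather than asserts that it was the intended
one.

For the molecule-number analysis the dynamics are rewritten in relative
concentrations, giving effective cubic rates $\beta_{12(21)} = \tilde
k_{12(21)} N^2/L^2$. In the large-$d$ limit the critical $\beta_{21}$ has
the closed form
$\beta_0 = -2k_{12}R_1/v_2^{*3} + (2k_{12}R_1R_2 + k_{21})/v_2^{*2}$ with
$R_1 = (k_{31}+k_{32}+k_{13})/(k_{31}+k_{32})$,
$R_2 = (k_{31}+k_{32}+k_{23})/(k_{31}+k_{32})$, and the onset
irreversibility is $\Gamma_0 = \beta_0 k_{12}/(\beta_{12} k_{21})$. The
finite-size factor $\zeta = 1 - 3\xi^2\Delta q^2$ is evaluated once, at
the $N$ maximising $\Gamma_0$, and treated as constant across the scan.
$\Gamma_c(N) = \zeta\,\Gamma_0(N)$ rises sharply to a peak at $N^*$ and
decays as $N^{-2}$; the stable window of a pattern operated at $\Gamma$ is
the pair of roots $\Gamma_c(N) = \Gamma$ (`nRange`), giving
$N_{\max} \propto e^{W/2}$ at strong driving. Fitting $\ln N_{\max}$
against $W$ over the scanned driving range ($W \in [3.5, 6.5]$, the
decade around the operating $\Gamma = 0.011$) yields a slope of about
0.45, slightly below the asymptotic 1/2 because $v_2^*(N)$ has not fully
saturated -- consistent with the published fit.

`findDmin` bisects the smallest $d = D_1/D_2$ (at $\tilde k_{21} = 0$,
i.e. infinite driving) with an unstable band at finite $q$; the result is
invariant under a common rescaling of all rates and diffusivities. The
value depends on the unprinted $k_{12}$ of the $d$-scan figure: 1.72 for
$k_{12} = 0.4$, 1.95 for 0.5, 2.05 for 0.55, no relaxation-branch
instability for $k_{12} \le 0.3$ (bistability, above). The acceptance
script uses $k_{12} = 0.4$ -- the smallest swept value with a monostable
homogeneous state -- which reproduces the published $d_{\min} \approx
1.7$; the choice is a documented resolution of a genuine ambiguity, not a
fit.

## Dissipation accounting

Chemical dissipation density: $\dot w_{\mathrm{chem}} = \sum_i (j_i^+ -
j_i^-)\ln(j_i^+/j_i^-)$ per box, nonnegative term by term. Diffusive
dissipation comes in two modes: the continuum form $\sum_k D_k
(\partial_x u_k)^2/u_k$ (centred differences, mirror ghosts) and the
discrete hop form $(J^+-J^-)\ln(J^+/J^-)$ per interface with $J^\pm =
(D/\Delta x)\,u$; they agree to well under 1% at 4$\times$ grid
refinement, and the discrete form is the one that satisfies the
steady-state identity *exactly* on the lattice.

That identity -- the module's headline check -- states that the spatially
integrated chemical + diffusive dissipation equals a cycle-flux
expression in the species totals alone. One subtlety is worth a
maintainer's attention: the printed two-cycle formula multiplies
$\ln(1/\Gamma)$ by the linear-edge flux $k_{12}N_1 - k_{21}N_2$, which is
*negative* in the driven pattern (the linear edge carries the return flow
of the autocatalytic cycle). The exact identity requires the true cycle
flux $J_{1c} = (k_{21}N_2 - k_{12}N_1) + J_{2c}$ (equivalently, the net
autocatalytic flux), with $J_{2c} = k_{23}N_2 - k_{32}N_3$;
`totalDissipationCycle` implements that orientation and the tests verify
the identity to $\sim 10^{-4}$ relative at the fig4 patterned steady
state. Since $J_{1c} \gg J_{2c}$ in all bundled regimes, the distinction
is numerically a ~4% effect -- but it is what makes the identity exact.

The closed-form estimate of the diffusive/chemical ratio,
$(2\pi^2/W)(\Delta u_2/\langle u_2\rangle)^2$, is implemented as printed
(`diffusiveFractionEstimate`) and its structural properties (zero at zero
amplitude, $1/W$ scaling) are tested. Its absolute normalisation,
however, disagrees with the directly integrated ratio by a roughly
constant factor $\sim$500 for both presets at every distance from onset;
the derivation lives in unavailable supplementary material, and the
implied chemical timescale appears to be a stripe-diffusion time rather
than the measured cycle time. The package reports the direct ratio
(`dissipationBreakdown()$r_diff`) as the quantitative one.

## Pattern metrics and the error-energy relation

`trackPeak` smooths the activator kymograph over a 10-sample moving
window, finds the local maximum nearest $L/2$ (ties between two equal
boxes are admitted -- an exactly symmetric peak sits between boxes), and
refines it by parabolic interpolation (box-resolution quantisation would
floor $\sigma$ at $\Delta x/\sqrt{12} \approx 0.03\,\mu m$). Stripe
classification projects the profile on the Neumann cosine modes and halves
the dominant index, so wall-peaked and interior-peaked variants of the
same wavelength count equally. Samples with the wrong stripe count are
flagged invalid; burn-in discards everything before the count first holds
for 100 consecutive samples and never less than the first 20%; runs with
more than 20% invalid samples are rejected from sweeps with a reason code.
$\sigma$ is the standard deviation of the tracked position over valid
samples. These smoothing/burn-in choices are not printed in the source
material, so absolute $\sigma$ values carry a method dependence; all
package-level conclusions use ratios or trends.

The phase theory treats the pattern phase $\phi$ as a conserved-noise
diffusion field, $\partial_t\phi = D_2\partial_x^2\phi -
D_4\partial_x^4\phi + \partial_x\eta$. With $D_2 = d_2\epsilon$ and
constant $D_4$, the positional variance is $\sigma^2 =
\sigma_0^2/S(\epsilon)$ with $\sigma_0^2 = (\lambda/2\pi)^2\Delta_0 L/D_4$
and $S(\epsilon) = a\sqrt\epsilon/\arctan(a\sqrt\epsilon)$, $a =
(L/\pi)\sqrt{d_2/D_4}$. `sigmaSquaredIntegral` evaluates the underlying
$(q,\omega)$ integral with the frequency integral analytic and the
wavevector integral numeric; the tests verify the closed forms to
$10^{-4}$ and better, and a spectral simulation of the phase equation
itself reproduces the predicted variance within 10%.

Relating $\epsilon = 1 - \Gamma/\Gamma_c$ to the excess driving $\Delta W
= W - W_c$ gives the error-energy relation $\sigma =
\sigma_{\min}/(1 - c_1 e^{-\Delta W})$, truncated at $c_1$ as in the
source fit. `fitErrorEnergy` is a plain `nls` least-squares fit (with
`scaleOffset` so exact data converge); it recovers synthetic parameters to
$10^{-6}$ and is invariant under $\sigma$ rescaling.

**Desk scale.** The published error-energy collapse uses horizons of
$10^4$+ seconds per run and ten $k_{12}$ values. The acceptance-level
experiment here is deliberately reduced: $k_{12} \in \{0.4, 0.45, 0.5\}$,
five $\Delta W$ values, three replicates, horizons of 400 s near onset
and 200 s beyond. At these horizons the slow phase wander near onset is
under-sampled, biasing $\sigma(\Delta W \lesssim 1)$ and hence $c_1$
downward; the reduced sweep lands $c_1 \approx 0.7$-0.8 against the
full-fidelity 0.93. A green desk-scale test therefore establishes the
monotone error-energy trade-off and an order-correct $c_1$, not the
published third digit. The same applies to the $\sigma(N)$ U-shape and the
Muk trends: horizons of 60-150 s resolve the trends far beyond the error
bars quoted, but not absolute long-time $\sigma$ values.

## The five-species Muk model

The MukBEF variant runs on the same engine as a `reactionNetwork` with
species X1 (closed dimer-of-dimers, DNA-free), M1 (post-hydrolysis
intermediate, DNA-bound), X2 (closed DD, DNA-bound), M2 (post-hydrolysis
intermediate, DNA-free), X3 (open dimer); DNA-free species share the fast
diffusion constant, DNA-bound ones the slow one; conservation counts
dimers (weight 2 for DD species, 1 for X3). The DD loop X1→M1→X2→M2→X1
carries one hydrolysis per half-turn; DNA capture is cooperative -- a
basal channel plus a channel enhanced by nearby bound DDs, the same cubic
form as the three-species autocatalysis (a purely cubic capture would
leave the bound pool unable to ignite from the DNA-free state, which is
how cooperativity is normally meant: a basal rate *enhanced* by
neighbours); simultaneous double hydrolysis de-dimerises a bound DD into
two open dimers (X2 → 2X3), which re-dimerise to X1. Counting
species-pair edges the network has exactly two independent cycles,
mirroring the $\Gamma/\Gamma'$ structure; the parallel basal/cooperative
capture channels add a channel-level loop of identically zero affinity.

Thermodynamic consistency is enforced by construction: backward rates are
defined from a reference equilibrium composition through detailed balance
at ATP/ADP = 1, and the ATP/ADP dependence multiplies the
forward/backward *ratio* of each hydrolysis-driven reaction once per
hydrolysis event. The dependence is carried entirely by the backward
rates ($k^+$ fixed, $k^- \propto r^{-h}$): hydrolysis is treated as
ATP-saturated (catalysis-limited) while the reverse, ADP-consuming
direction scales with [ADP]. This mirrors the three-species study, where
only the reverse autocatalytic rate carries the driving; splitting the
dependence symmetrically instead makes the *forward* DD-loop rates grow
with the ratio and marches the stable-$N$ window upward rather than
widening it.

Exact rate values are not printed in the main text; `mukParams()` is the
package's documented default set, chosen once to (a) satisfy cycle
consistency exactly, (b) support a three-stripe pattern at the reference
ratio (ATP/ADP = 100, $N_{\mathrm{ref}} = 26000$ dimer equivalents in $L =
6\,\mu m$), and (c) reproduce the qualitative trends: no pattern at the
equilibrium ratio, lower-ratio patterns forming with a different stripe
number, $\sigma$ non-increasing and $N_{\max}$ non-decreasing in the
ratio. At strong driving the deterministic window saturates (as the
three-species analysis predicts for finite $d$), so the $N_{\max}$ trend
at high ratios is an increase-then-plateau. All defaults are overridable
and validated (violating cycles are named).

## Known limitations

* Subcritical onset: amplitude-based onset detection near $\tilde k_0$ is
  hysteretic; the package's onsets are linear-stability statements.
* $\sigma$ at desk-scale horizons underestimates near-onset error; only
  trends and the collapse are asserted at that scale.
* The Eq-3.2-style closed-form dissipation ratio is structural, not
  quantitative (factor ~500; see above).
* The phase-theory constants $d_2$, $D_4$, $\Delta_0$ are not extracted
  from simulation; the theory is verified against its own quadrature and
  a spectral phase-field simulation, and $\Delta_0 \propto 1/N$ is used
  only qualitatively.
* 1-D only; no spatially varying diffusion; tau-leaping is deliberately
  absent (the simulator's contract is exactness).
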