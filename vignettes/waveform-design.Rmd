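---
title: "Designing energy-efficient desynchronizing stimulation waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing energy-efficient desynchronizing stimulation waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pathologically synchronized firing of thalamic neurons is a target of deep
brain stimulation (DBS). Conventional DBS injects a high-frequency
charge-balanced pulse train whose parameters are tuned by hand and whose
energy cost is large. `desyncdbs` implements an alternative: treat the
population as weakly perturbed limit-cycle oscillators and *design* the
extracellular waveform that maximises the exponential separation rate of
nearby phases — a finite-time Lyapunov exponent — per unit of injected
energy, while limiting Faradaic (electrochemical) charge transfer at the
electrode.

The pipeline has four layers.

### 1. Neuron and phase reduction

The cell model is a reduced conductance-based thalamocortical neuron with
leak, sodium, potassium and low-threshold calcium (T) currents, membrane
state $(V, h, r)$:

$$\dot V = \big(-I_L - I_{Na} - I_K - I_T + I_{SM} + I_{app}\big)/C,\qquad
\dot h = \frac{h_\infty(V)-h}{\tau_h(V)},\qquad
\dot r = \frac{r_\infty(V)-r}{\tau_r(V)}.$$

At the default baseline current $I_{SM}=5\,\mu\mathrm{A/cm^2}$ the cell
fires with period $T = 8.395$ ms; this period is the calibration anchor for
the transcription of the model's functional forms. (The relaxation form of
the $r$ equation is used; the corresponding equation in the source
literature contains an obvious typographical slip, with $h$ in place of
$r$ in the numerator.)

On the stable limit cycle, phase reduction gives
$\dot\theta = \omega + Z(\theta)\,u_e(t)$ with $\omega = 2\pi/T$ and the
phase response curve $Z(\theta)$ computed by the adjoint method:
`compute_prc()` integrates the adjoint equation backwards for 100 periods
(the slow T-current Floquet mode contracts by only ~0.86/period, so a long
horizon is needed), then normalises pointwise so that
$\langle Z, \dot x\rangle = \omega$ on the orbit — the inner product is
conserved analytically, so the pointwise normalisation only removes
integrator drift of the neutral component; the residual after
normalisation is ~1e-16 and retained as a diagnostic. Phase zero is
anchored at the spike (upward crossing of $-20$ mV, located by linear
interpolation). All $\theta$-indexed quantities are tabulated on a
512-point grid and carried as truncated Fourier series (64 harmonics for
the exported $Z$, $f$ and derivatives; a near-Nyquist series internally for
orbit interpolation), so smooth derivatives are cheap at arbitrary phase.
An independent direct-perturbation PRC (`compute_prc_direct()`, small
voltage kicks with a 30-period settle) agrees with the adjoint curve to a
few times $10^{-5}$ of its maximum.

### 2. Electrode interface

The probe couples to the tissue through a double-layer capacitance
$C_{dl}$ in parallel with a Faradaic charge-transfer resistance $R_{ct}$,
in series with the spreading resistance $R_s$:

$$\dot u_e = \dot u_p + \frac{u_p - u_e}{C_{dl}R_{ct}} - \frac{u_e}{C_{dl}R_s}.$$

Here $u_p$ and $u_e$ are the probe drive and the field input in "effective
input units" — fixed positive rescalings of the probe and field voltages by
the activating-function strength $F(d)=a/d^3$ of a spherical probe
(radius $a$, neuron distance $d$) and the intra-axonal resistance. All
control-level computation happens in these units; conversion to volts
(`to_effective_input()` and its inverse) needs an intra-axonal resistance
the user must supply. Defaults: $C_{dl}=5\times10^{-4}$ F, $R_s=29\,\Omega$,
$R_{ct}=2\times10^5\,\Omega$, i.e. time constants of 14.5 ms
($C_{dl}R_s$) and 100 s ($C_{dl}R_{ct}$), converted to ms internally.
`simulate_circuit()` uses the exact exponential update of the continuous
variable $w = u_e - u_p$, which propagates pulse edges without smearing;
the constant-phase-element exponent is fixed at 1 (a true capacitance).

### 3. The design problem and its solvers

The stimulus minimises
$$G[u_p] = \int_0^{t_1}\! \Big[u_e^2 + \alpha\,\dot u_p^2
 - \beta\, Z'(\theta)\,u_e + \gamma\,(u_p-u_e)^2\Big]\,dt ,$$
with $\theta$ driven by the phase equation: energy, probe slew (the
$\alpha$ term regularises an otherwise singular problem), desynchronizing
action (the Lyapunov integrand), and Faradaic current. Defaults
$\alpha=0.2$, $\beta=50$, $\gamma=8$, $t_1 = 8.02$ ms (slightly below $T$,
so the stimulus ends before the next spike). Boundary conditions:
everything starts at zero and $u_p(t_1) = u_e(t_1) = 0$.

The Euler-Lagrange equations form a six-dimensional two-point
boundary-value problem in $(u_p, \dot u_p, \theta, u_e, \lambda_1,
\lambda_2)$, implemented in `el_rhs()` with the constant mass matrix
inverted once symbolically. Shooting on the two initial multipliers is
numerically brutal: the linearised system has an unstable mode of rate
about 2.2/ms, so terminal residuals amplify multiplier errors by roughly
$e^{18}$ over $t_1$, and the bilinear $\lambda_2 u_e$ channel then blows up
super-exponentially. Trial multipliers more than ~1e-5 from a root produce
arithmetic overflow rather than usable residuals, which rules out blind
bracketing over a wide box. The package therefore offers two routes:

* **Transcription (default).** `design_stimulus(method = "transcription")`
  discretises $u_p$ on the output grid, evaluates the cost with the exact
  circuit update and a Heun phase integration, computes the exact discrete
  adjoint gradient in compiled code, and minimises by L-BFGS from a
  canonical start shaped like the pointwise optimum
  $(\beta/2)Z'(\omega t)$. The terminal field condition is enforced by a
  quadratic penalty ($\mu = 10^7$ by default, which leaves
  $|u_e(t_1)| \lesssim 10^{-6}\max|u_p|$). The initial multipliers implied
  by the solution are estimated afterwards by least squares along the
  trajectory (the multiplier subsystem is linear given the path and stable
  backwards in time) and reported as diagnostics.
* **Shooting.** `design_stimulus(method = "shooting")` continues the root
  of the shooting residuals in $\beta$ from the trivial zero-input solution
  (secant predictor, damped Newton corrector), which tracks the solution
  branch connected to $u \equiv 0$. `double_bisection()` implements the
  nested-bisection root search itself, choosing automatically which
  residual pairs with which multiplier axis; it is practical at shorter
  horizons, or in tight boxes around continuation roots.

The two routes converge to *different* local optima. This is a real
feature of the problem, not a solver artifact: both satisfy the
Euler-Lagrange boundary conditions, both are local minima against smooth
perturbation families, and two-neuron simulations of the full conductance
model reproduce each branch's predicted exponent to ~2 % when the stimulus
is applied at its design alignment (onset at the spike). At the default
weights the transcription branch is substantially stronger
(e.g. $\Lambda(T) = 0.109$/ms versus $0.045$/ms at $\gamma = 8$) and has
the lower cost, which is why it is the default.

Two conventions exist for evaluating the exponent
$\Lambda(\tau) = \tau^{-1}\int Z'(\theta(s))u(s)\,ds$ of a designed
waveform: along the *driven* phase (the faithful reading, used by
`exponent_uncoupled()` and confirmed by the variational oracle) or along
the *uniform rotation* $\theta = \omega t$, a shortcut that is accurate
while the input is weak and that the original analysis of this problem
used when quoting its exponents. `design_stimulus()` reports both
(`Lambda_T`, `Lambda_T_uniform`), and the published-table comparisons in
`scripts/acceptance.R` use the uniform-rotation values. The published
gamma-sweep falls between the package's two branches: the strong branch
matches it at low $\gamma$ (within ~3-5 %) and the weak branch at high
$\gamma$ (within ~1-5 %), consistent with the original hand-searched
shooting having landed on different local branches at different weights.
Neither branch reproduces the full published sweep, and the package makes
no attempt to hop branches per weight: the default solver is one
deterministic rule applied everywhere.

### 4. Population simulation and metrics

`simulate_network()` integrates the $3N$ neuron states (all-to-all
electrotonic coupling $\sigma(\bar V - V_i)$, which is the mean-field form
of $(1/N)\sum_j \sigma(V_j - V_i)$ with zero diagonal) plus the circuit
with a fixed-step stochastic Heun scheme (two-stage second-order
Runge-Kutta drift, Euler-Maruyama Gaussian increments
$\sqrt{2D\,dt}\,\mathcal N(0,1)/C$ on the voltage only), default
$dt = 0.01$ ms. The circuit advances by its exact exponential update each
step and persists across stimuli. The two-state event-based controller
triggers stimulus playback when the mean voltage exceeds $-45$ mV with
negative slope (once per upward excursion), drops to an inactive state
when no excursion above $-45$ mV occurs within 1.5 periods after a
stimulus ends, and re-arms when the mean voltage registers above
$-40$ mV. The pulsatile baseline is a charge-balanced biphasic train
(anodic phase first by default — the energy and charge-balance metrics are
order-invariant), each cycle starting from zero so the leading edge falls
inside the simulated window.

Energy is $\int u_e^2\,dt$ and the Faradaic measure
$\int |u_p-u_e|/R_{ct}\,dt$, both by trapezoid in ms-based units. Note a
reproducibility caveat: with the stated circuit constants the
charge-balanced train leaves only a ~0.1-unit double-layer drift between
pulses, so the package's Faradaic total for the standard pulsatile
protocol (~1.8e-4) is an order of magnitude below the value quoted in the
original study (0.00224), while the energy total (~2.9e5) matches it to
5 %. We found no reading of the circuit constants that reproduces both
published numbers at once and implement the equations as printed.

Desynchronization is quantified without noise: each tracked neuron's phase
is inferred ballistically (its frozen state is integrated input-free to
its next spike, $\theta = 2\pi(1 - t_{\text{next}}/T)$, horizon 2.5
periods), and `numerical_exponent()` fits $\log\phi$ of the tracked pair
by least squares from stimulus onset until $\phi$ first exceeds 1 rad
(beyond which the linearisation behind exponential growth fails), flagging
fits with $R^2 < 0.9$ as not exponential.

## Synthetic initial conditions and what the tests do (and do not) show

There is no external data: all inputs are model parameters and seeded
samplers. "Synchronized" runs start all neurons on the orbit at a common
phase plus i.i.d. jitter of 0.1 rad (the original study does not state its
initialisation; 0.1 rad makes the population visibly synchronized — mean
voltage excursions well above the controller threshold — while giving the
tracked pair a measurable separation). Noise follows the stated
$2D = 0.7$ (the running-text value $D = 0.7$ conflicts with the parameter
table; the table is used). Heterogeneous-distance scenarios draw $d_i$
from a user-specified law and scale each neuron's input by $(1/d_i)^3$.

Passing tests show the machinery is internally consistent (adjoint versus
direct PRC, phase-model exponents versus full-model divergence, analytic
circuit responses, boundary conditions, charge balance) and that the
simulated population behaves as the theory predicts under the model's own
assumptions. They do not show that a real thalamic population — with
heterogeneous cells, synaptic rather than electrotonic coupling,
unmodelled electrode chemistry and measurement noise — would desynchronize
at the predicted rate; the model itself is the idealisation.

## Numerical choices

* Deterministic single-cell and adjoint work: adaptive `lsoda` at relative
  tolerance 1e-8 to 1e-10; spike times by linear interpolation.
* Orbit/PRC grids: 512 points, 64 exported harmonics; PRCs computed at 256
  and 512 points agree to <0.5 %.
* Shooting/transcription integration: compiled Cash-Karp RK45, relative
  tolerance 1e-9; transcription grid 0.005 ms.
* Fixed-step network integration: dt = 0.01 ms (halving changes spike
  times by <1e-2 ms over ten periods); states recorded every 0.1 ms.
* Test-suite problem sizes: populations of 2-100 neurons, horizons of
  5-35 periods, ten-seed stochastic medians; the gating-bound property is
  checked over 20 random initial conditions for 5e3 steps.
* Degenerate inputs: $\alpha = 0$ is rejected (singular problem);
  non-oscillating parameter sets raise "not oscillating"; blown-up shots
  return flagged sentinel residuals; inconsistent $u_p/u_e$ pairs are
  rejected by `cost_functional()`.

## Known limitations

* Only the spherical-probe field and the single reduced thalamic model
  ship, and only electrotonic (gap-junction-like) coupling is simulated;
  synaptic coupling, bursting orbits, multi-compartment axons and
  constant-phase-element electrode impedance are out of scope.
* The local optimisation landscape genuinely contains multiple branches;
  the package characterises two and selects by cost, but does not attempt
  global optimisation.
* Event-triggered stimulation engages the waveform at the mean-voltage
  crest ($\theta \approx 0.3$-0.7 by the time the trigger fires), not at
  the spike alignment the waveform was optimised for; closed-loop
  desynchronization rates are therefore protocol-dependent and can sit
  well below the aligned two-neuron prediction.
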