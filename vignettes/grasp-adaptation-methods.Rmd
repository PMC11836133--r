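---
title: "Models and methods behind graspadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind graspadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspadapt)
```

This vignette is the package's own account of the science it implements: the
adaptation model and its sign convention, the simulated experiment and
observer, the motion-capture processing rules, the psychometric and
inferential conventions, and the numerical choices that were genuinely open.

## The state-space adaptation model

Grip apertures scale linearly but imperfectly with object size, so
unperturbed grasping is described by a response function
$MGA_{v} = int + slope \cdot v$ with an intercept in mm and a dimensionless
slope (people open wider than the object; typical margins are ~20 mm). A
visuo-haptic size perturbation dissociates the seen size $v_t$ from the felt
size $h_t$; the motor system's adjustment is modelled as a latent state
$x_t$ added to the seen size before the response function is applied:

$$MGA_{mod_t} = int + slope\,(v_t + x_t), \qquad x_{t+1} = A\,x_t - b\,E_t.$$

$A$ is trial-to-trial retention and $b$ the error-correction rate, both
bounded in $[0,1]$. The error signal is driven purely by haptics: it is the
difference between the grip actually produced and the grip that would have
been comfortable for the object felt in the hand,

$$E_t = MGA_t - (int + slope \cdot h_t).$$

**Sign convention.** Two sign pairings of this model circulate in the
literature and they are not interchangeable: written one way
($E_t = MGA_{h_t} - MGA_t$ with $x_{t+1} = Ax_t - bE_t$) the closed loop has
*positive* feedback — errors grow without bound — which contradicts both the intended behaviour (a grasp that was too large
should push the next prediction down) and the converging behaviour such
models are used to describe. The package
therefore defines $E_t = MGA_t - (int + slope\,h_t)$, which yields a stable
loop and matches the verbal account exactly. The mirrored convention remains
available (`sign_convention = "printed"` in `error_signal()`, `run_forward()`
and `fit_block()`) for auditing; with it, self-driven simulations diverge, as
the tests demonstrate indirectly by asserting convergence under the default.

Two closed-form consequences anchor the tests. Under a constant mismatch
$\Delta$ with slope $s$, the noise-free closed loop converges to
$x^* = b s \Delta / (1 - A + b s)$ (9.6 mm for $A = 0.95$, $b = 0.2$,
$s = 1$, $\Delta = 12$). Under a sinusoidal mismatch the loop is the linear
filter $x_{t+1} = (A - bs)x_t + bs\,\Delta_t$, so the steady-state response
is a sinusoid with gain and phase given by the filter's frequency response
$H(e^{i\omega}) = bs\,e^{-i\omega} / (1 - (A - bs)e^{-i\omega})$ — a lagged,
attenuated copy of the perturbation. Both are verified to $10^{-6}$.

## Fitting

`fit_block()` estimates $(A, b, int)$ per block by minimising the RMSE
between observed and modelled MGAs, the slope held fixed at the
cohort-level mean of per-participant regressions of mean MGA on seen size
(`fit_response_slope()`); fitting a per-block slope would trade off against
$b$, as both express a responsiveness. Numerical choices:

- The optimiser minimises the *mean squared* error — the same argmin as the
  RMSE, but smooth at a perfect fit, where the square root has a kink that
  stalls quasi-Newton steps. The reported `rmse` is the square root at the
  optimum.
- Deterministic multi-start: a coarse grid over $A \in \{0.1,\dots,0.9\}$,
  $b \in \{0.05, 0.15, 0.3, 0.5\}$ with the intercept seeded from the mean
  of baseline (unperturbed) trials, followed by box-constrained L-BFGS-B
  refinement from the three best grid points. The objective is smooth and
  low-dimensional, so this recovers noise-free generating parameters to
  better than $10^{-3}$ and is reproducible run to run.
- The whole block is fitted, baseline and washout included.
- Excluded trials (`NA` observations) still propagate the state — the
  model's own prediction stands in for the missing observation in the error
  term — but contribute no residual. This keeps the state trajectory
  continuous across isolated exclusions. (The alternative, freezing the
  state, would mis-time the washout after runs of exclusions.)
- On unperturbed, constant blocks $b$ is unidentifiable; the fit flags this
  (`flat_ridge`) by probing the objective's sensitivity to $b$ at the
  optimum.

## The synthetic experiment

`simulate_experiment()` reproduces the study design exactly: 12 experimental
blocks per participant — six abrupt (24 trials, 4 unperturbed at each end)
and six sinusoidal (36 trials, 3 cycles, first trial unperturbed) — one per
signed magnitude, $\pm\{3, 6, 12\}$ mm with seen sizes $\{40, 44, 48\}$ mm
randomized per trial in the main experiment, $\pm\{4, 8, 12\}$ mm with seen
sizes $\{40, 45\}$ mm fixed per block (alternating across blocks) in the
pilot; all pilot sinusoids start positive, half of the main-experiment ones
negative. Felt sizes are quantized to 0.5 mm (nearest multiple, ties away
from zero — only the step size is prescribed by the apparatus) and stay
within the manufactured 28–60 mm range for the printed designs. Block order
is as enumerated; the original Latin-square counterbalancing is out of scope
and can be imposed by reordering.

MGAs are simulated in closed loop with the model's *noisy* output: the state
update consumes the noise-corrupted MGA, because that is what the fitted
model sees, and because physiologically the correction acts on the grip that
was actually produced. With the noise at zero, simulation and forward
prediction coincide exactly (a test asserts this), which is what makes exact
recovery oracles possible.

Default generating parameters: $A = 0.95$ and $b = 0.2$ (conventional
reference values for this model class in grasp adaptation), slope 0.93 (a
typical empirical MGA-on-size slope for blocked single-object grasping),
intercept 24 mm — chosen so a 44 mm object is grasped
with a typical ~20 mm margin; the specific value is arbitrary and
documented as such — and 2 mm motor noise, a realistic MGA SD for repeated
grasps of a fixed object.

**The observer model.** The 2AFC response is generated from a decision
variable $d = h - (v + \kappa x) - \mathrm{bias} + \eta$,
$\eta \sim N(0, \sigma_{obs})$, answering "felt larger" iff $d > 0$. The
coupling $\kappa \in [0,1]$ shifts the observer's internal visual reference
by the adaptation state: with $\kappa = 1$ a fully adapted participant
compares the felt size against an expectation that has drifted towards it,
shrinking the effective mismatch. This observer is the package's
operationalisation of the hypothesis that adaptation reduces the error
signal available for detection — a simulation device for generating
plausible data, not an estimated or asserted model of real observers.
$\sigma_{obs}$ defaults to 4 mm, in the range of visuo-haptic size JNDs.
With $\kappa = 0$ the observer is stationary and the empirical psychometric
function equals the generating cumulative normal (tested within binomial
error).

**Trajectories.** Marker trajectories exist so the kinematic pipeline can be
tested end to end against known ground truth; only the extracted MGA feeds
the science. Transport follows a minimum-jerk path (zero velocity at both
ends) from the start position to the object over `movement_time` (default
0.7 s, a brisk natural reach). The aperture profile opens with a trapezoidal
velocity profile, peaks *exactly* at the programmed MGA at `mga_fraction`
(default 0.7) of movement time, and closes at constant velocity onto the
object, stopping abruptly at contact as real closure does. Two deliberate
shape choices matter:

- the peak is an exact parabola over its final/initial 100 ms, so the
  200 ms order-3 Savitzky–Golay filter reproduces it without attenuation
  (polynomial-preservation property), keeping the noise-free pipeline exact
  to well under 0.5 mm;
- opening and closing speeds stay comfortably above the touch-detection
  thresholds except in a brief (~150 ms) zone around the peak, so the
  velocity-based touch criterion can distinguish the momentary zero-crossing
  of aperture velocity at the MGA from the sustained stop at contact.

The generator does not emulate forces, lift, wrist dynamics, movement-time
effects, fatigue, or response biases that drift over a session; passing
tests therefore certify the *pipeline*, not those aspects of real data.

## Motion-capture processing

The per-trial pipeline (`segment_trajectory()`) is: cubic-spline
interpolation of interior gaps per marker coordinate (leading/trailing gaps
are never extrapolated — they stay missing and count towards the
missing-data rule); Savitzky–Golay smoothing with a 200 ms window, forced to
an odd frame count, polynomial order 3 (a standard order for kinematics; the
window is the prescribed value, the order an implementation choice);
movement start at the first frame where *both* thumb and index 3-D speeds
exceed 0.05 m/s; touch at the first frame after start where the aperture
speed falls below 0.075 m/s (main; 0.1 m/s pilot) *and* the thumb–index
midpoint is within 150 mm (main; 300 mm pilot) of the object centre; MGA as
the maximum thumb–index distance before touch, earliest frame on ties.
Velocities are central differences of the smoothed positions.

Threshold crossings must be *sustained* to count: 25 ms for movement start
(suppressing single-frame noise), but 250 ms for touch. The longer touch
window is a deliberate choice: aperture velocity necessarily crosses zero at
the MGA itself, and after 200 ms smoothing it can sit below threshold for
well over 100 ms around the peak while the hand is already inside the
position radius; only the stop at contact is sustained indefinitely, so a
250 ms requirement selects it reliably. With a bare (unsustained) criterion,
touch can fire at the aperture peak — largely harmless for the MGA itself
(the maximum *before* that frame differs from the true peak by a fraction of
a millimetre) but wrong for movement time.

Exclusion rules follow the standard four: (i) MGA on a spline-interpolated
stretch (read as: the MGA frame's thumb *or* index position was filled);
(ii) more than 20% of frames between start and touch missing (counted as
thumb-or-index missing — the rule's per-marker scope was open and this is
the conservative reading); (iii) MGA smaller than the felt (grasped) object
length; (iv) MGA more than 3 interquartile ranges from the participant's
median for the same seen and felt size, skipped with a warning in cells with
fewer than two trials.

## Psychophysics

Correctness of a 2AFC response is the agreement of its direction with the
sign of the mismatch; zero-mismatch trials have no correct answer and are
excluded from all correctness analyses (their correctness is `NA`, and empty
condition cells yield `NA`, never 0). Detection trends are participant-wise
OLS of binary correctness scored 0/100 on trial index, per schedule and peak
magnitude; for balanced designs this equals OLS on per-trial means, and the
binary form was chosen because it is well defined for incomplete cells too.
Half-cycle folding maps sinusoidal trials to position
$((t-1) \bmod P/2) + 1$, where one half-cycle contains each magnitude
exactly once, summarising detection without confounding it with magnitude.

Psychometric functions are cumulative normals in the mismatch,
$P(\text{felt larger}) = \Phi((\text{mismatch} - pse)/\sigma)$, fitted by
maximum likelihood (probit regression, which is exactly the 2-parameter ML
fit). The JND is reported as $\sigma$ — the distance from the PSE to the
84.1% point — by default; the quartile convention ($0.6745\,\sigma$, half
the 25–75% spread) is selectable because published JND magnitudes depend on
it and the convention used for the original numbers is not stated. No
lapse/guess parameters are fitted by default (none are mentioned for the
original analysis); a fixed lapse rate is available for robustness studies.
Perfect separation (a response pattern with no overlap) is flagged rather
than silently returning a collapsed $\sigma$.

## Inference

- Repeated-measures ANOVA uses the classical fully-within decomposition
  (each effect tested against its participant-by-effect interaction),
  and reports the classical uncorrected degrees of freedom (e.g.
  $F(2, 44)$ at $n = 23$ for a three-level factor); sphericity corrections
  are not applied. Cell values are averaged per participant first;
  incomplete designs are refused. Numerically zero effect sums of squares report $F = 0$ rather
  than a 0/0 artefact.
- Paired t-tests report Cohen's $d = t/\sqrt{n}$ for the paired design.
- The JZS t-test Bayes factor integrates the Rouder et al. (2009) marginal
  likelihood over the inverse-gamma mixing density (Cauchy prior scale
  0.707 by default); the test suite cross-checks it against an independent
  derivation through the noncentral-t likelihood.
- The correlation Bayes factor places a stretched-beta prior on $\rho$
  (scale 0.333 by default, i.e. $\rho = 2u - 1$, $u \sim$ Beta(3, 3)) and
  uses the exact sampling density of Pearson's $r$ via the Gauss
  hypergeometric series.
- Deming regression uses the closed-form errors-in-variables solution with
  the variance ratio fixed at 1 (orthogonal regression) — no ratio is
  prescribed, and 1 is the symmetric default.
- Bootstrap CIs are percentile intervals over 10,000 resamples by default,
  deterministic under a seed.

## Problem sizes and runtime

The test suite simulates at sizes chosen to make each property sharply
testable while keeping a full run around half a minute: 200 replicate blocks
per schedule for parameter recovery, a 48-participant main-experiment cohort
(17,280 trials) for the detection asymmetry, 60-cycle noise-free runs for
the frequency-response check, and single trajectories at the full 500 Hz/3 s
(main) and 200 Hz/5 s (pilot) recording formats for the kinematics oracle.
Full-cohort trajectory stores are generated only on request
(`generate_trajectories = TRUE`), since no analysis stage consumes them.

## Limitations

- Single-state model only: fast/slow two-state learners, Kalman-style
  learners and lapse-aware observers are out of scope.
- No Greenhouse-Geisser correction is implemented; with the 2 x 3 designs
  here the two-level factor is sphericity-proof and the three-level factors
  were analysed uncorrected.
- The observer model is an operationalisation for simulation, not a claim
  about mechanism; real detection may involve cues (timing, force, weight)
  the decision variable does not carry.
- The pilot touch threshold (0.1 m/s) is close to plausible aperture
  opening speeds for small grasp amplitudes; simulated pilot fixtures use
  amplitudes with adequate margin, and real low-amplitude data may need the
  thresholds overridden.
- Latin-square block-order counterbalancing is not constructed; block order
  is the caller's responsibility.
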