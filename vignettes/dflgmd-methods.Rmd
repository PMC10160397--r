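---
title: "The DFLGMD network: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DFLGMD network: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dflgmd` implements a five-layer, directionally selective, fractional-order
model of the insect lobula giant movement detector (LGMD): a visual neuron
that fires strongly at objects approaching on a collision course and weakly
at receding or translating ones.  The package takes a grayscale image
sequence and returns per-direction LGMD membrane responses, a per-frame
motion-direction estimate, and a collision-peak summary.  This vignette
records the model, the numerical scheme, and—at some length—the design
decisions that were genuinely open, together with what our implementation
experiments showed about each.

## The model

All dynamic units are conductance membranes of the same affine form

$$D^{\alpha} x \;=\; g_{leak}(V_{rest} - x) \;+\; \textstyle\sum_i u_i\,w_i\,(E_i - x),$$

where $D^{\alpha}$ is a fractional derivative of order
$\alpha \in (0, 1]$, each input $u_i \ge 0$ opens a conductance with weight
$w_i$ towards its battery $E_i$, and the batteries
$E_{in} \le V_{rest} \le 0 \le E_{ex}$ confine the state.  The layers are:

1. **Photoreceptors.** Each pixel is excited by the current luminance
   $L(t)$ (gain $\lambda_{ex}$, battery $E_{ex}$) and inhibited by the
   one-frame-delayed luminance $L(t-1)$ (gain $\lambda_{in}$, battery
   $E_{in}$), so sustained luminance settles near rest while temporal
   change transiently deflects the potential.
2. **ON/OFF split.** Half-wave rectification against small thresholds
   $V_{th1}, V_{th2}$ with gains $\gamma_1, \gamma_2$ separates brightness
   increments (ON) from decrements (OFF).
3. **Excitation / inhibition.** Excitatory neurons copy the channel output;
   inhibitory neurons low-pass it through another membrane (gain
   $\delta_{ex}$), rectify, and spread it laterally: the current field is
   convolved with the nearest-neighbour Gaussian kernel $G_1$ and the
   previous frame's field with the wider kernel $G_2$ (weight
   $\beta_{on/off}$), with replicate padding at the borders.
4. **Summing units.** Each pixel weighs excitation ($\varepsilon_{ex}$,
   battery $E_{ex}$) against the spread lateral signal
   ($\varepsilon_{in}$); the rectified ON and OFF outputs recombine
   superlinearly, $S = \mu_1 \hat S^{ON} + \mu_2 \hat S^{OFF} + \mu_3 \hat
   S^{ON}\hat S^{OFF}$.
5. **Direction layer and LGMD.** For each of the 8 canonical directions
   $\theta$, every pixel is correlated with a partner displaced by $m$
   pixels:
   $$D_{ij}(t,\theta) = S_{ij}(t)\,S_{xy}(t-2) - S_{ij}(t-1)\,S_{xy}(t-1),$$
   the grid sum $R_1(t,\theta)$ drives a direction-selective LGMD membrane
   (gain $\xi_{ex} = 5\cdot128^2/n^2$), and the rectified response
   $\hat L_1(t,\theta)$ is the network output.  The aggregate collision
   trace is $C(t) = \sum_\theta \hat L_1(t,\theta)$; its argmax frame and
   peak-to-median prominence form the collision report, and the per-channel
   time integrals form the direction tuning curve.

### Parameters

`dflgmd_params()` pins every constant; defaults are the model's standard
operating point.  Ranged parameters default to mid-range ($g_{leak} = 30$
of $[25, 50]$, $V_{rest} = 0$ of $[-0.001, 0]$, $E_{in} = -0.5$ of
$[-1, -0.3]$, $\beta = 1.1$ of $[1.0, 1.2]$) and values outside their range
warn rather than error.  Time is measured in frames (the 33 ms sampling
interval is the unit), luminance in $[0, 1]$, potentials in battery units.
The LGMD gain is derived from the grid side, so a 64-pixel run uses
$\xi_{ex} = 20$ and a 128-pixel run uses 5.

## The fractional scheme

The operator $D^{\alpha}$ is discretised with Grünwald–Letnikov binomial
weights $c_k = (-1)^k\binom{\alpha}{k}$, computed by the recurrence
$c_k = c_{k-1}(1 - (\alpha+1)/k)$.  Because every right-hand side is linear
in the state, the implicit solve is an elementwise division (semi-implicit
update), unconditionally stable for non-negative decay fields—which matters
with synaptic weights as large as $\varepsilon_{in} = 100$:

$$x_n\,(1 + h^{\alpha} B) \;=\; h^{\alpha} A \;-\; \sum_{k=1}^{K} c_k\,
x_{n-k} \;+\; S_K\,x_0, \qquad S_K = \sum_{k=0}^{K} c_k .$$

The $S_K x_0$ term applies the operator to the deviation from the initial
state (Caputo-style initialisation).  Without it the scheme discretises the
Riemann–Liouville operator, for which a non-zero constant is not a rest
state: trajectories then fail both the Mittag-Leffler relaxation law and
convergence to the $A/B$ fixed point.  With it, $\alpha = 1$ reduces
exactly to one-step implicit Euler, and the relaxation
$D^{\alpha}x = -x,\ x(0)=1$ tracks $E_\alpha(-t^{\alpha})$ to $10^{-2}$ on
$t \in [1, 10]$ at $h = 0.1$ (the scheme is first-order; at $h = 1$ the
early-time error is a few times larger).  All network state is seeded at
$V_{rest}$; since $V_{rest} = 0$ by default, the correction term vanishes
inside the network and matters only for the oracle tests.

Two practical notes.  First, fractional relaxation approaches its fixed
point as a power law $\sim t^{-\alpha}$, so "converged" statements depend
on the decay rate: at the network's $B \approx 30$ the fixed point is
reached to well under 1% within 200 frames, but a unit-rate system is
still ~15% away at the same horizon.  Second, truncating the memory to a
window $W$ perturbs trajectories by roughly the deviation scale times
$S_W \sim W^{-\alpha}$—a slow decay, so the default keeps the full history
(runs are a few hundred frames at most) and `memory_window` exists for
genuinely long inputs.

The direction-layer sum $R_1$ is signed, so the LGMD input conductance
$\xi_{ex} R_1$ can be negative; a negative total decay would make both the
continuous model and the implicit divide meaningless (the membrane
diverges).  The run loop therefore floors the decay field at zero and
clamps the LGMD state to $[E_{in}, E_{ex}]$—the same battery confinement
the photoreceptor equation states—so strongly negative input silences the
unit (rectified output 0) without destabilising it.

## Design decisions the equations leave open

**ON summing battery.** In the model's reference formulation the ON
summing unit's lateral term carries the excitatory battery $E_{ex}$ while
the OFF unit carries $E_{in}$.  A "symmetric" variant with $E_{in}$ in
both looks more natural—but is numerically dead: with $\varepsilon_{in} = 100$, kernel
mass $\sum G_1 \approx 16.8$, and a leak of 30 per frame (the inhibitory
membrane settles within a single frame), the lateral term exceeds any
attainable excitation roughly fifty-fold, for static and moving input
alike, and every summing unit pins below zero.  We verified this across
translation and looming stimuli, at two grid sizes, and with additionally
delayed inhibition; the network output is identically zero in all cases.
The reference formulation is therefore the default
(`on_lateral_battery = "excitatory"`):
the ON channel passes a saturating copy of its drive, the OFF channel is
suppressed, and the combined $S$ field is a crisp activity map whose
*temporal changes* carry all the signal the correlator needs.  The
symmetric variant remains available behind the flag.

**Correlation orientation.** Writing the partner position as
$(i + m\cos\theta,\ j + m\sin\theta)$ leaves open whether the partner sits
ahead of or behind a $\theta$-ward moving signal.  For the channel labelled
$\theta$ to prefer motion *towards* $\theta$—the convention every readout
of the model uses—the partner must sit where the signal *was* two frames
earlier, i.e. at $-m(\cos\theta, \sin\theta)$.  The default is therefore
`offset_sign = -1`; the opposite orientation measurably prefers the
reversed direction and is kept for sensitivity analysis.

**Velocity tuning.** The correlator compares $S(t)$ with a partner's
$S(t-2)$ at displacement $m = 1$: it is matched to signals that traverse
one partner offset in two frames, i.e. $|{\rm offset}|/2$ px/frame—0.5 for
cardinal, $\sqrt 2/2 \approx 0.71$ for diagonal directions.  At 1 px/frame
and beyond, the preferred-direction coincidence lands outside the
correlation window and the rectified output of *every* channel is zero for
a rigid translate.  All default stimuli and the acceptance suite therefore
move at the matched speed.  This is a genuine property of the model's
$(m, \Delta t) = (1, 2)$ geometry, not of our discretisation.

**Motion-direction estimate.** The direct estimator—per-pixel
$\arctan(D(t,\pi/2), D(t,0))$ followed by a mode—is unusable raw, for two
reasons our experiments isolated.  A negative correlation is ambiguous:
purely temporal change (an edge passing over a pixel) drives
$D = S(t)S(t-2) - S(t-1)^2$ negative regardless of direction, and those
pixels dominate the mode.  And for oblique motion the horizontal and
vertical coincidence evidence peak at *different* pixels, so no single
pixel ever votes diagonal.  The implementation therefore (a) forms
opponent signals $D(\theta) - D(\theta+\pi)$, which cancel the
direction-neutral component exactly, (b) pools them over a Gaussian
neighbourhood (`angle_pool_sigma`, default 3 px) so one pixel carries both
components, and (c) masks pixels below an absolute energy floor
(`energy_floor = 1e-3` in squared-$S$ units) and below a quarter of the
frame's maximum.  The floor sits two orders of magnitude below a moving
edge's pooled energy and well above the power-law settle transient of a
static scene, so a motionless view yields an *undefined* direction rather
than noise.  With these choices the mode recovers the true direction on
every responding frame for all 8 directions in our test conditions.

**Looming signature.** Because the background is tonically active in the
functional configuration, an expanding dark square *shrinks* the active
area: opposite expanding edges cancel within each direction channel and
the net drive during approach is non-positive.  The network's collision
signature is instead a sharp, omnidirectional burst at the frame expansion
stops—the fill (collision) frame—which the peak detector locates to within
a frame or two of the true collision time across fill rates.  A smoothly
rising approach response, as sometimes drawn for such models, is not what
this parameterisation produces; the tests assert the peak-alignment and
prominence-ordering properties the model does have.

**Two delay units.** The lateral pathway is described as having two delay
units while the equations delay only the $G_2$ term.  The default follows
the equations (G1 same-frame, G2 one frame back);
`inhibition_delays = c(1, 2)` provides the fully delayed reading.  Under
the functional configuration the choice is immaterial to every tested
behaviour.

## The stimulus generator

`stim_looming()`, `stim_receding()` and `stim_translating()` emulate the
simulated test videos: a centred dark square whose edge grows linearly
until it fills the field at a controlled `fill_frame` (the ground-truth
collision time), its exact time reverse, and rigid block/bar translation
along the 8 canonical directions, with `add_gaussian_noise()` scaling
zero-mean Gaussian noise to a prescribed SNR (in dB against the temporal
variance of the sequence, the conventional reading of a bare "SNR"
figure).  Objects are rendered with fractional pixel coverage and a
Gaussian optical point-spread (`blur_sigma = 0.8` px).  Integer
rasterisation of sub-pixel motion would make the object jump every other
frame, injecting strong direction-neutral flicker; the anti-aliased,
slightly blurred rendering is both closer to real optics and free of that
artifact.  Default geometry keeps objects well clear of the borders, where
the correlator's zero off-grid contract would otherwise add edge terms.

What the generator does *not* emulate: textured or cluttered backgrounds,
perspective, camera shake, photometric nonlinearities, or multiple
simultaneously moving objects.  Passing tests on these stimuli shows the
network's directional and looming selectivity under clean laboratory-style
conditions; it does not certify performance on natural video.

## Test conditions and problem sizes

Unit tests run on 32–64 pixel grids with 12–40 frames so the whole suite
stays fast; the behavioural acceptance tests use the full 128 × 128 grid
with 60-frame translations (dark 5 px blocks at matched speed, clean and
at SNR 5, 10, 30 and 50 dB) and 134-frame looming/receding sequences
(fill frame 121, i.e. the matched 0.5 px/frame edge speed from an 8 px
start).  The numerical oracles—direct binomial coefficients, an
independent implicit-Euler integrator, and a truncated Mittag-Leffler
series—are implemented in the test helpers, independent of the package's
engine.

## Known limitations

* Directional selectivity is narrow in speed (matched to
  $|{\rm offset}|/2$ px/frame); multi-speed coverage would require a bank
  of $m$ or delay values.
* The ON/OFF division is strongly asymmetric at these parameters
  ($\lambda_{ex}E_{ex} = 1.2$ vs $\lambda_{in}|E_{in}| = 0.6$, and any
  sustained luminance pins the photoreceptor above threshold), so OFF
  responses are transient and much weaker than ON responses; stimulus
  polarity does not simply swap the channels.
* The integer-order ($\alpha = 1$) variant of the same architecture
  produces no rectified looming output at all under these conditions—its
  shorter memory never accumulates positive drive—so the
  fractional-vs-integer comparison is one-sided here.
* Collision *location* and object *speed* are not estimated.
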