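# dflgmd

Directionally selective, fractional-order LGMD collision sensing in R.

The lobula giant movement detector (LGMD) is an insect visual neuron that
fires strongly at objects approaching on a collision course and barely at
receding or translating ones.  `dflgmd` implements a five-layer network
model of the LGMD and its direction-selective companions whose membrane
dynamics follow a *fractional-order* differential operator: every unit
obeys

    D^a x = g_leak (V_rest − x) + Σ_i u_i w_i (E_i − x),    0 < a ≤ 1,

discretised with Grünwald–Letnikov weights c_k = (−1)^k C(a, k) and a
semi-implicit update.  A luminance sequence passes through photoreceptors
(excited by L(t), inhibited by L(t−1)), ON/OFF half-wave rectification,
delayed Gaussian lateral inhibition (3×3 kernel G1, 5×5 kernel G2),
summing units, and a correlation-type direction layer

    D_ij(t, θ) = S_ij(t) · S_xy(t−2) − S_ij(t−1) · S_xy(t−1),

whose grid sums drive eight direction-selective LGMD membranes
(θ = 0, π/4, …, 7π/4).  The package reports the rectified per-direction
responses, a per-frame motion-direction estimate (mode of pooled local
correlation angles), and a collision report (peak frame and prominence of
the aggregate trace C(t) = Σ_θ L̂1(t, θ)).  A synthetic stimulus generator
(looming / receding squares, translating blocks and bars, Gaussian noise
at a prescribed SNR) makes the whole network testable without any data.

The fractional order's power-law memory is what sustains the response:
with the default a = 0.4 the looming burst is strictly larger than with
the integer-order (a = 1) variant of the same architecture.

## Worked example

A dark 5 px block crosses a 128 × 128 field left-to-right at the
correlator's matched speed (0.5 px/frame):

```r
library(dflgmd)

stim <- stim_translating(grid = c(128, 128), n_frames = 60,
                         direction = 0, speed = 0.5, size = 5)
report <- dflgmd_run(stim, dflgmd_params(n = 128))
report
#> <dflgmd_report> 60 frames, alpha=0.4
#>   peak: frame 44, value 0.1985, prominence 1.4
#>   preferred direction: 0 deg
#>   integrated per-direction scores:
#>   theta_0  theta_45  theta_90 theta_135 theta_180 theta_225 theta_270 theta_315
#>    3.1202    2.4826    0.0000    0.0000    0.0000    0.0000    0.0000    2.4826
```

The `theta_0` channel wins (the block moves rightward, θ = 0); the
opposite channel is silent, and the flat prominence (≈1.4) says no
collision is imminent.  A looming stimulus instead produces an
omnidirectional burst whose peak frame falls at the ground-truth collision
(fill) time:

```r
loom <- stim_looming(grid = c(128, 128), n_frames = 134,
                     fill_frame = 121, start_size = 8)
dflgmd_run(loom, dflgmd_params(n = 128))$peak_frame
#> [1] 122
```

A thin CLI wraps the same functions:

```sh
dflgmd synth --kind translate --direction 0 --speed 0.5 --size 5 --out frames/
dflgmd run --input frames/ --out results/
```

`run` writes `timeseries.csv` (frame, C, per-direction L1, MD) and
`summary.json`; `synth` writes PNG frames plus a `stimulus.json` sidecar
with the generator settings and ground truth.

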