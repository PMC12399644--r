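---
title: "Continuous-time video segmentation with echode: models, phantom, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time video segmentation with echode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Echocardiogram analysis needs per-frame segmentation of cardiac structures
that is not only accurate but *temporally consistent*: downstream tasks such
as cardiac-cycle phase detection (finding end-diastole and end-systole) and
ejection-fraction estimation read the evolution of the left-ventricular (LV)
area over time, and frame-to-frame jitter in the masks corrupts them even
when per-frame Dice is high. Clinical video annotations are sparse — often a
single labelled frame per clip — so a per-frame segmenter has no incentive
to be consistent across frames.

`echode` treats the beating heart as a dynamical system. A video clip is a
trajectory of a latent state \(h(t)\) governed by an ordinary differential
equation whose right-hand side is a neural network; segmentation at *any*
time in the clip is the decoding of the state at that time. Because all
frames of a clip decode from one smooth latent trajectory, temporal
consistency is built into the architecture rather than encouraged by a loss.

## Model

**Encoder.** Each frame is embedded by a shared convolutional encoder: four
pairs of 3×3 convolutions with 2×2 max-pooling between pairs, channel pairs
(32,32), (64,64), (128,128), (256,256) at full scale. A `width_scale`
divisor shrinks all widths for CPU-scale runs; the latent grid sits at 1/8
resolution.

**Backward latent ODE (ODE-RNN).** Input times \(\tau = \{t_1 < \dots <
t_n\} \subset [0,1]\). Starting from a zero hidden state placed at
\(t_n + \epsilon\) (\(\epsilon = 0.01\)) and integrated down to \(t_n\), the
encoder alternates: integrate the hidden state backward with a derivative
network \(f_{enc}(h)\), then update it with the encountered frame feature
through a ConvGRU cell,
\[ h^-_{t_{i-1}} = \mathrm{ODESolve}(f_{enc}, h_{t_i}, t_i \to t_{i-1}),
\qquad h_{t_{i-1}} = \mathrm{ConvGRU}(h^-_{t_{i-1}}, E(X_{t_{i-1}})). \]
The state after the earliest-frame update is the per-clip dynamics code
\(D\); one convolution maps \(D\) to the initial decoder state \(h_{s_0}\).
The encoder derivative cannot receive \(D\) (it does not exist yet), so
\(f_{enc}\) sees the state only — the decoder-side derivative is the one
conditioned on the clip.

**Dynamics-conditioned decoder ODE.** For target times \(S\), the state is
\(h_{s_i} = h_{s_0} + \int_0^{s_i} f(h, D)\,ds\), where \(f\) concatenates
\(h\) and \(D\) along channels and applies three convolutions (tanh between,
linear last). Conditioning on \(D\) makes the vector field clip-specific
without per-clip fine-tuning. The solve is a single adaptive Dormand–Prince
4(5) integration; states at all of \(S\) are read out by the solver's
*dense output* interpolant, so 4 input frames yield \(2\cdot4-1 = 7\)
predictions in one pass at negligible extra cost.

**Decoders and skips.** A reconstruction decoder (three upsample+conv
stages back to full resolution, 3-channel output) is trained
self-supervised against the real frames at every dense-output node — frames
exist at every spanned index even where labels do not. Its stage features
feed the target decoder through skip connections at 1/4, 1/2 and full
resolution (direct encoder skips are impossible because target times need
not coincide with input times). The target decoder ends in an
`n_classes`-channel softmax (segmentation) or six sigmoid heatmaps
(begin/end keypoints of IVS, LVID, LVPW) in measurement mode.

**Loss.** \(\ell = \ell_S + \lambda\,\ell_R\) with \(\lambda = 10\):
\(\ell_R\) is mean squared error over all dense-output reconstructions;
\(\ell_S\) is cross-entropy plus soft Dice (smoothing \(\delta = 1\),
macro-averaged over foreground classes), supervised only at the single
annotated node. Optimisation is plain SGD at learning rate 0.05, constant
schedule, no momentum or weight decay. One safeguard is added for
desk-scale stability: global gradient-norm clipping (default 5,
configurable, 0 disables) — early in training the backprop-through-solver
gradients can spike.

## Numerical choices

* **Solver**: adaptive Dopri5, rtol = atol = 1e-4 by default (exposed in
  `ode_solve_config()`), FSAL stepping, standard fourth-order dense-output
  interpolant. Gradients are obtained by direct backpropagation through the
  accepted solver steps (discretise-then-optimise) on a tape-based
  reverse-mode autodiff engine; an adjoint solve is not provided — the
  contract only requires correct gradients, and finite-difference probes
  agree to ~1e-9 at rtol 1e-6.
* **Error control** uses the raw state values (not taped), so step-size
  selection is not differentiated through; this is the standard choice.
* **Nonlinearities** (the sources are silent): ReLU in the encoder and
  reconstruction decoder, leaky ReLU (slope 0.1) in the target decoder —
  under a low-confidence output prior a plain-ReLU target decoder was
  observed to die into a constant-output basin — tanh inside the
  derivative networks (bounded fields keep the ODE well-behaved),
  sigmoid/tanh ConvGRU gating. The final derivative-net convolution is
  initialised at 0.1× He scale so initial dynamics are mild and the first
  solves are cheap.
* **Degenerate inputs**: a single-frame clip (`n_input = 1`) uses
  \(\tau = S = \{0\}\) and passes through the unchanged pipeline; a solver
  step-underflow or step-limit raises an integration-failure error carrying
  the time reached.

## The phantom: what it emulates, and what a green test does not establish

`generate_phantom()` builds a parasternal-long-axis-like scene from
analytic ellipses: LV blood pool, interventricular septum (IVS) and LV
posterior wall (LVPW) as elliptical-annulus bands, right ventricle with its
anterior wall above, left atrium below — seven classes by default,
optionally four (chamber-view-like, walls merged). The LV semiaxes scale as
\(s(t) = 1 + a\,g(\phi)\) with amplitude \(a = 0.2\); walls thicken in
systole, the atrium moves in antiphase. Frames are the intensity map times
multiplicative gamma speckle (mean 1, sd 0.18 by default). Measurement
segments (IVS/LVID/LVPW begin/end points) lie on the vertical line through
the LV centre and are stored with sub-pixel float coordinates for every
frame. Arrhythmia mode draws each cycle's period as
`base_period * (1 + U(-jitter, jitter))`.

The waveform \(g\) is a piecewise raised cosine with one maximum (ED) and
one minimum (ES) per cycle and a systolic fraction of **0.45** — systole
mildly faster than diastole. The fraction was fixed at design time by a
numerical analysis of the downstream phase pipeline: the rigid
Savitzky-Golay(13, 3) filter displaces the peak of a strongly asymmetric
waveform by one frame toward the flatter side, which would contradict the
phantom's own phase ground truth; 0.45 is the mildest physiologically
ordered asymmetry whose smoothed extrema stay on-frame at period 20. The
initial phase is 0.25 so the first ED/ES events sit away from the video
edges.

The phantom's purpose is *capability* testing: the shapes are smooth
analytic ellipses, the speckle is spatially white, there is no probe
geometry, shadowing, dropout, through-plane motion, or observer variability.
A green training-recovery test establishes that the architecture, gradients
and training loop work end-to-end and that the continuous-time model is
more temporally consistent than a per-frame baseline *in this stated
world*; it does not establish clinical-scale accuracy.

## Temporal-consistency metrics

* **TC**: each mask's largest 0.5-level contour (marching squares on a
  zero-padded mask), resampled to 100 points equispaced in arc length;
  shape-context descriptors (5 log-spaced radial × 12 angular bins, radii
  normalised by the mean pairwise distance, out-of-range radii clamped into
  the end bins, rows normalised to 1 — translation- and scale-invariant);
  adjacent frames matched by order-preserving DTW minimised over all cyclic
  start offsets of one sequence under the χ² bin distance. The pair score
  is the mean cost per matched point; TC averages over adjacent pairs, then
  videos. Pairs touching an empty mask are excluded and tallied rather than
  silently dropped. These binning constants are the standard shape-context
  settings; all are exposed as arguments.
* **TCD**: mean absolute adjacent-frame difference of the per-frame Dice
  series (denominator = transitions per video), then the mean over videos.
  Zero for perfectly consistent prediction.

## Downstream tasks

Phase detection extracts the LV area per frame, smooths with
Savitzky-Golay width 13 / order 3 (edge samples refit the polynomial on the
truncated window), and takes local maxima as ED and minima as ES. The
minimum peak separation is `max(4, floor(0.5 * median cycle))`, where the
cycle estimate comes from a first pass with separation 4 — this suppresses
speckle double-peaks; plateau ties resolve to the leftmost index. Detected
and ground-truth events are matched greedily (nearest first, each ground
truth used once) within a 10-frame validity window; MAE is over matched
pairs, with unmatched ground truth and spurious detections reported
separately rather than folded into the MAE (the matching rule and the
treatment of unmatched events are this package's choices; the sources name
only "a peak detection function" and the 10-frame window).

Measurement mode decodes six keypoint heatmaps; a point is the
score-weighted centroid of pixels ≥ 0.3 (no point if nothing reaches the
threshold — structures may be invisible), and a dimension is the Euclidean
distance between its two points times the pixel spacing. Training targets
are Gaussian blobs (σ = 2 px at 64×64, scaled with resolution) under
per-pixel binary cross-entropy with the positive pixels upweighted
(weight `1 + 10·target`), and the head's output bias is initialised at −4
so the sigmoid starts near the background prior — with ~25 positive pixels
in a 64×64 map a zero-bias head spends its early gradient budget
suppressing background. Spatial augmentation is disabled in measurement
mode because the stored keypoint coordinates would desynchronise.

The keypoint head is also the one place the reference optimiser is
overridden. Plain SGD — at every learning rate, positive weight, blob
width and step budget we probed, including a 1000-step single-clip
overfit — converges to diffuse heatmaps whose thresholded centroids
collapse toward the ventricle centre: the loss surface of a heavily
imbalanced sigmoid head conditions very badly for a single global learning
rate. Adam (learning rate 2e-3, gradient-norm clip 5) localises all six
keypoints to sub-pixel accuracy on the same computational graph, so the
measurement-mode experiment trains with `optimizer = "adam"`; every
segmentation experiment keeps the plain-SGD reference setting.

## Scaled experiments and their budgets

The acceptance suite trains a `width_scale = 4` model on 80 phantom clips
at 32×32 for 8 epochs (and a per-frame U-shaped baseline with the same
encoder, identically trained) — deliberately below the 200-clip/64×64/20-
epoch configuration the full experiment would use, to fit a CPU test-run
budget; the pass thresholds (held-out foreground Dice ≥ 0.85, Echo-ODE TC
strictly below the baseline's on 20 held-out videos) are not relaxed. The
single-clip overfit sanity check uses learning rate 0.1 — overfitting one
clip benefits from a step size larger than the full-training default.

## Known limitations

* No adjoint-mode gradients; memory grows with solver steps (irrelevant at
  desk scale, the honest trade-off at clinical scale).
* The tape engine supports single-clip (batch size 1) graphs; batching is
  by gradient accumulation.
* The per-frame baseline exists only as a consistency comparator, not as a
  tuned competitor.
* Decoder channel widths mirror the encoder in reverse; the original
  parameter count is not an acceptance surface and was not matched.
* The phase-detection filter parameters are rigid by design (width 13,
  order 3); on curves much shorter than the filter a reduced width is used
  with a warning.
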