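---
title: "Methods: the NGNDG activation, the multi-branch CNN, and gradient-based saliency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NGNDG activation, the multi-branch CNN, and gradient-based saliency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngndgnet)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which parameters
matter, and what the bundled synthetic data can and cannot demonstrate.

## 1. The activation function

The NGNDG activation is the piecewise algebraic map

$$f(x;\beta)=\begin{cases}\beta x & x\ge 0\\ \dfrac{\beta x}{1+x^2} & x<0,\end{cases}$$

with a single dimensionless slope/polarity parameter $\beta$ (default 1,
fixed rather than trained). Its properties, all enforced by tests:

* **Differentiability at 0.** The analytic derivative is $\beta$ for
  $x\ge 0$ and $\beta(1-x^2)/(1+x^2)^2$ for $x<0$; both one-sided
  derivatives at 0 equal $\beta$, so no subgradient convention is needed
  and `ngndg_grad(0, beta)` returns $\beta$.
* **Bounded negative response.** For $\beta>0$ the minimum is $-\beta/2$
  at $x=-1$, and the negative tail vanishes algebraically as
  $x\to-\infty$. The function is therefore *not* monotonic — its
  derivative is negative for $x<-1$ — although it is often loosely
  described as rectifier-like; the implementation follows the definition
  above and does not enforce monotonicity.
* **Exact homogeneity.** $f(x;\beta)=\beta f(x;1)$, implemented so the
  identity holds bitwise ($\beta$ multiplies last).
* **Sign flip.** For $\beta<0$ both branches flip sign, making the
  negative branch positive.

The second derivative, needed by the Grad-CAM++ pixel weights, is
$-2\beta x(3-x^2)/(1+x^2)^3$ for $x<0$ and 0 for $x>0$ (0 at 0 by the
right-branch convention).

All derivative code is gated by finite-difference oracles. The
environment provides no reverse-mode automatic differentiation for R, so
everywhere a second independent derivative route is wanted the package's
tests use high-order central differences (a 4th-order stencil where
$10^{-6}$ absolute agreement is demanded); these oracles live in the test
helpers and share no code with the analytic paths.

## 2. The multi-branch CNN

`cnn_spec()` describes the classifier: input $28\times 28\times 3$,
four convolutional blocks, then fully connected layers of 256 and 64
units (each NGNDG-activated with dropout) and a 7-class softmax. Block 1
is a single 3×3 convolution; blocks 2–4 each run three parallel branches
— one 1×1 convolution; two stacked 3×3 convolutions; two 3×3 plus one
1×1 — whose outputs are concatenated along channels. Convolutions are
stride-1 with zero "same" padding so branch outputs are spatially
compatible by construction.

**Block closure.** Each block ends with batch normalization, 2×2/stride-2
max pooling, and the NGNDG activation, applied once per block after the
branch concatenation (merge-then-normalize, the usual inception-style
layout). Applying them per branch instead would triple those layers and
is incompatible with the architecture's stated total layer count, which
was the deciding constraint.

**The 34-layer census.** The census convention is: convolution, batch
norm, max pool, flatten, dense, dropout and softmax each count as one
layer; activations are fused into the stage they rectify (the Keras
`activation=` idiom) and are reported in a column of
`layer_census()` rather than as rows. Under this convention the default
network has exactly $19$ convs $+ 4$ batch norms $+ 4$ pools $+ 1$
flatten $+ 3$ dense $+ 2$ dropout $+ 1$ softmax $= 34$ layers. The layer
count is a structural fact — per-conv filter counts cannot change it —
so the filter counts are free design parameters; the defaults
(16 | 8,8,8 | 16,16,16 | 16,16,16) are chosen small enough that the
network trains in minutes on one CPU core while leaving every branch
non-trivial. Swapping NGNDG for ReLU or ELU changes no parameter count
(all three are parameter-free with $\beta$ fixed).

Other unstated details fixed here: max-pool window 2×2 stride 2; branch
merge by channel concatenation; dropout rate 0.3; He-style weight
initialization; batch-norm momentum 0.9 and $\varepsilon=10^{-5}$, with
population variance for batch statistics.

## 3. Training

Sparse categorical cross-entropy
$L=-\tfrac1N\sum_i \log p_{i,y_i}$ (log argument floored at $10^{-12}$)
is minimized with Adam (default) or RMSprop, both implemented from their
standard recurrences:

$$m_t=\beta_1 m_{t-1}+(1-\beta_1)g_t,\quad
  v_t=\beta_2 v_{t-1}+(1-\beta_2)g_t^2,\quad
  \theta_t = \theta_{t-1}-\alpha\,\hat m_t/(\sqrt{\hat v_t}+\varepsilon)$$

with bias corrections $\hat m_t = m_t/(1-\beta_1^t)$,
$\hat v_t=v_t/(1-\beta_2^t)$. The square root on $\hat v_t$ is part of
Adam's definition and is used here; an update without it would not be
dimensionally consistent with the algorithm being invoked.

The backward pass is hand-derived throughout. The reference chain for a
single dense NGNDG-softmax layer is exposed as `manual_gradients()`:
$\partial L/\partial a = (p - y)/N$ (the softmax Jacobian contracted
against the cross-entropy term — the diagonal $p(1-p)$ term alone is not
sufficient, as the off-diagonal softmax couplings contribute),
then multiplication by the analytic activation derivative, then the
input/bias contractions. Tests require agreement with plain central
differences at relative $10^{-5}$ and with the 4th-order stencil at
$10^{-6}$ absolute, across $\beta\in\{0.5,1,2\}$ on instances whose
pre-activations span both branches.

Hyperparameter defaults: batch size 128, learning rate $10^{-3}$,
plateau schedule (decay factor 0.5 after `patience = 2` consecutive
epochs without a new best validation loss, counter reset after each
decay — so after $k$ events the rate is exactly $10^{-3}\cdot 2^{-k}$),
up to 100 epochs. The holdout split is stratified by class; the fraction
is configurable (default 0.2; the bundled end-to-end runs use 1/6,
giving 700/140 on the balanced set). Per-epoch training metrics are
accumulated from the minibatch forward passes (training mode), the usual
framework convention; validation metrics come from a separate
evaluation-mode pass. Optional inverse-frequency class weights
($w_c = N/(Cn_c)$ on the training split) address imbalance; they default
to off.

**Determinism.** One master seed is fanned out to fixed substreams
(split, initialization, training, synthesis, saliency), so two runs with
the same configuration are bitwise identical in single-threaded BLAS
mode, and changing, say, a saliency option cannot perturb training.

## 4. Saliency

Both methods act on the feature maps $A^k_{ij}$ of a chosen stage
(default: the last convolutional block's concatenated output, 3×3 spatial
in the default network; any stage can be named).

**Grad-CAM.** Channel weights are spatially averaged first-order
gradients $\alpha_k=\tfrac1Z\sum_{ij}\partial Y^c/\partial A^k_{ij}$ with
$Z$ the number of positions, and the map is
$f(\sum_k\alpha_k A^k;\beta)$ — NGNDG replaces the classical ReLU
rectification and reduces to it exactly when `activation = "relu"`.
Grad-CAM differentiates the **pre-softmax logit** by default (the
standard convention; saturated softmax probabilities make logit gradients
better conditioned), with `score = "softmax"` available as a flag.

**Grad-CAM++.** Differentiates the **softmax probability**
$Y^c = e^{s_c}/\sum_k e^{s_k}$. Pixel weights are

$$\alpha^c_{ijk}=\frac{\partial^2 Y^c/\partial (A^k_{ij})^2}
 {2f'(d^1_{ijk}) + \sum_{ab}A^k_{ab}\left[f''(d^1_{ijk})\,d^2_{ijk}
  + f'(d^1_{ijk})\,d^3_{ijk}\right]},$$

where $d^n$ is the order-$n$ class-score derivative, with
$\alpha^c_{ijk}=0$ wherever the denominator vanishes (threshold
$10^{-12}$ in absolute value — non-contributing pixels are ignored, and
the threshold avoids catastrophic division near the singular set).
Channel weights are $\omega_k=\sum_{ij}\alpha^c_{ijk}f(d^1_{ijk})$ and
the map is $f(\sum_k\omega_k A^k)$. All-zero gradients (a head detached
from the chosen layer) yield a zero map with a warning, not an error.

**Higher-order derivatives.** With per-class logit Jacobians
$g_k = \partial s_k/\partial A$ (obtained by one backward pass per class)
and $\bar g=\sum_k p_k g_k$, $V=\sum_k p_k(g_k-\bar g)^2$,
$\mu_3=\sum_k p_k(g_k-\bar g)^3$, the closed softmax-chain forms are,
elementwise over positions,

$$d^1 = p_c(g_c-\bar g),\qquad
  d^2 = p_c\!\left[(g_c-\bar g)^2 - V\right],\qquad
  d^3 = p_c\!\left[(g_c-\bar g)^3 - 3V(g_c-\bar g)-\mu_3\right].$$

These are exact whenever the subnetwork from the chosen layer to the
logits is affine — the classical "last convolutional layer" setting, and
the setting of the bundled `toy_conv_net()`, where tests require
agreement with nested central finite differences at
$10^{-4}/10^{-3}/10^{-2}$ for orders 1/2/3. For heads with intermediate
nonlinearities they are the locally-affine approximation that Grad-CAM++
practice has always used (the original formulation likewise treats the
score's dependence beyond the target layer as exponential-of-linear);
the runtime path uses the closed forms because nesting numerical
derivatives through the head would be both slower and less stable.

**Rendering.** `render_overlay()` min-max normalizes the raw map (an
all-constant map normalizes to zeros), upsamples bilinearly with the
`align_corners = FALSE` convention — output pixel centers map to input
coordinates by $(j+\tfrac12)s-\tfrac12$, clamped — applies a fixed
colormap, and alpha-blends with the image. Everything is deterministic,
so overlays are bit-exact across runs.

## 5. The synthetic dermoscopy-like data

`generate_lesions()` draws 28×28 RGB images on a jittered skin-toned
background, one parametric recipe per class: a filled brown disc, a dark
annulus, an elongated blue-grey ellipse, a lesion with a sinusoidally
irregular border, scattered dark speckles, a red diagonal streak, and a
multifocal violet pattern. Geometry and hue differ jointly across
classes, so the classes are linearly separable from raw pixels by
construction (a property test fits a ridge classifier and requires
≥ 0.8 accuracy). Additive Gaussian noise (default $\sigma=0.05$ on the
$[0,1]$ pixel scale, chosen as clearly visible speckle that leaves the
recipes distinguishable) is clipped back to $[0,1]$; with $\sigma=0$
images are recipe-exact.

Presets fix the study conditions: `balanced` has 120 images per class
(840 total; with the 1/6 holdout, 700 train / 140 validation);
`imbalanced` has counts (350, 120, 100, 80, 70, 40, 14) — one dominant
and one rare class, max/min ratio 25 — mirroring the qualitative skew of
public dermoscopy collections without copying any real dataset's counts.

**What passing tests show — and don't.** The generator emulates only the
statistical shape the pipeline needs: seven RGB classes, small images,
controllable imbalance, class-informative pixels. It has none of the
hard properties of real dermoscopy (intra-class heterogeneity, artifacts,
hair, calibration markers, inter-rater ambiguity). Saturating accuracy
here demonstrates that the architecture, gradients, optimizer and metrics
are implemented correctly — not that the model would classify real skin
lesions well.

## 6. Problem sizes and numerical choices

The bundled end-to-end runs train the default network (≈ 66k parameters)
for 20 epochs on 700 images — a deliberate desk-scale choice that keeps
a full train-evaluate-explain cycle in the low minutes on one CPU core
while still exercising every code path at the study's hyperparameters.
Numerical details fixed by the implementation and relied on by tests:

* cross-entropy probability floor $10^{-12}$; probability rows must sum
  to 1 within $10^{-6}$;
* max-pool ties route their gradient to the first maximal candidate in a
  fixed scan order, so backprop is deterministic;
* odd trailing rows/columns are dropped by pooling (28 → 14 → 7 → 3 → 1);
* AUC uses midranks for ties (Mann–Whitney); a class absent from the
  labels yields `NA` AUC and is excluded from the macro average with a
  message;
* micro precision = micro recall = accuracy for single-label multi-class
  data, kept as a conservation test.

## 7. Known limitations

* No reverse-mode autodiff exists in this stack, so "gradient checking"
  always means analytic-vs-finite-difference; the finite-difference side
  limits verifiable precision to roughly $10^{-6}$–$10^{-2}$ depending
  on derivative order.
* Grad-CAM++ higher-order terms are exact only for affine heads
  (Section 4); for the full network they are the standard approximation.
* The trainer targets small images and desk-scale datasets; it is a
  correct, transparent implementation, not a performance-tuned one.
* β is a fixed hyperparameter; learned or per-channel β (PReLU-style) is
  out of scope, as are guided backprop, Score-CAM, occlusion maps, and
  transfer learning from pretrained backbones.
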