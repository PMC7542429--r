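---
title: "Reconstructing compromised surface BOLD signal: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing compromised surface BOLD signal: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state fMRI sampled onto the cortical surface can lose signal in
circumscribed regions — most dramatically around implanted deep-brain
stimulation (DBS) electrodes and their connector wires, whose susceptibility
artifacts attenuate the BOLD signal over centimetres of cortex. `boldpatch`
reconstructs the lost signal frame by frame: a deep convolutional generative
adversarial network (DCGAN) is trained on intact flattened BOLD frames, and a
compromised frame is repaired by searching the generator's latent space for
the point whose generated frame best matches the frame *outside* the
compromised region, then splicing the generated values into the region.
A boundary-diffusion filler provides the natural baseline, and an evaluation
suite quantifies what the reconstructions preserve: per-vertex time courses,
seed-based functional connectivity (FC), and — critically — *whose*
connectivity they resemble.

## The substrate: icosphere, masks, flattening

All signals live on a subdivided icosahedron standing in for one registered
cortical hemisphere; level 4 has 2562 vertices, the resolution the method
operates at after surface downsampling, and level 2 (162 vertices) is the
desk-scale default for experiments. Compromised regions are geodesic masks:
breadth-first rings grown over the mesh adjacency until `round(fraction * V)`
vertices are covered, with the last partial ring admitted in ascending vertex
order so a mask is a pure function of (mesh, center, fraction). Geodesic
masks of a given vertex count replace atlas-derived region labels; the
coverage arithmetic (e.g. 140 of 2562 vertices = 5.5%) is preserved exactly.

The GAN consumes raster images, so each hemisphere is flattened by an
azimuthal-equidistant projection from the pole (polar angle to radius,
azimuth to direction, anisotropically scaled to fill the raster), rounded to
pixel centers; when two vertices round to one pixel the later-indexed vertex
moves to the nearest free pixel by a deterministic spiral search. This is a
deliberate replacement for tool-chain-based cortical flattening: the method
only needs a *fixed bijection* between vertices and pixels, not anatomical
fidelity, and an analytic projection makes the bijection reproducible
everywhere. Both hemispheres are rendered side by side in one image
(left disc | right disc) so the model can exploit contralateral structure;
per-hemisphere rasters remain available by flattening each mesh separately.

## The synthetic cohort

No subject data ships with the package; a generative cohort model emulates
the statistical structure the method depends on:

- each hemisphere is parcellated by seeded k-means on vertex coordinates
  (with a connectivity repair pass), parcels cycle through `N` networks that
  span both hemispheres;
- subject `s` has loading matrix `W_s = W_template + indiv_sd * Z_s` — a
  continuous, per-subject connectivity fingerprint, so "most similar
  individual" has a graded ground truth rather than a categorical one;
- network time courses are AR(1) with coefficient `phi` and unit innovation
  variance — the minimal temporally autocorrelated model consistent with
  band-limited BOLD;
- vertex signal is `W_s %*% eta + noise`, white Gaussian measurement noise.

Defaults (240 frames at TR 3 s; loading 0.9; noise sd 0.8; `phi` 0.4;
`indiv_sd` 0.25; 6 parcels / 3 networks per hemisphere) were chosen once as
a realistic operating point: they give a within-network vertex-pair
correlation near 0.6 and clearly separated within- vs between-subject FC
similarity, both typical of clean resting-state surface data. Subject- and
run-level seeds derive from the master seed through a counter scheme, so
enlarging a cohort never reshuffles existing subjects.

What the generator does *not* emulate: hemodynamic response convolution,
head motion, scanner drift, spatially varying noise, and anatomical
(curvature/sulcal) structure. Tests passing on this cohort therefore
demonstrate the machinery end to end — signal recovery, connectivity
preservation, subject specificity — under a favorable, stationary model of
BOLD statistics, not performance on real scanner data.

The DBS scenario is simulated as a pre/post run pair sharing one subject
fingerprint; inside the affected region the post run carries
`f * structured_signal + sqrt(1 - f^2) * noise`, so at attenuation `f = 0`
the region is pure measurement noise at the model's noise variance, and FC
inside the region degrades smoothly with `f`.

## Preprocessing arithmetic

Four operations mirror the data recipe the method assumes:

- **Session normalization**: divide every value by the single session-wide
  maximum absolute value (one scalar per run). The literal one-scalar
  reading is used — a per-vertex maximum would destroy the spatial amplitude
  patterns the GAN must learn. Output lies in [-1, 1], matching the
  generator's tanh range; idempotent.
- **Global signal regression**: per vertex, project out an intercept and the
  global mean course; a linear projection (twice = once, to 1e-8). A run
  whose global course is already (numerically) zero is returned demeaned
  rather than rejected; a constant *nonzero* course is a degenerate
  regressor and errors.
- **Temporal smoothing**: average non-overlapping blocks of 4 frames
  (window configurable), dropping the trailing partial block; TR scales by
  the window.
- **tSNR**: `1 / sd` per vertex (sample sd, n−1, used everywhere in the
  package), averaged over vertices; zero-variance vertices are excluded and
  counted. tSNR is computed on normalized data by default (the state after
  preprocessing); raw-scale tSNR is a flag away. Smoothing white noise by
  blocks of 4 halves the noise sd, so tSNR roughly doubles on noise-dominated
  data — the directional fact the test suite checks.

## The DCGAN

The generator maps a 100-dimensional latent vector, uniform in [-1, 1], to a
raster through a learned projection to a small spatial representation
followed by four fractionally-strided convolutions (kernel 4, stride 2);
hidden activations are ReLU, the output is tanh, and batch normalization is
applied everywhere except the output layer. The discriminator mirrors it:
four strided convolutions with leaky ReLU (slope 0.2), batch normalization
on all layers except the first, and a single sigmoid unit. Training
alternates one discriminator update (one real and one generated batch) with
two generator updates per iteration — the generator is deliberately favored
to balance learning speeds — using Adam at learning rate 0.0002 for both
players and sigmoid cross-entropy losses from the two-player minimax value
function. The generator loss defaults to the non-saturating form (maximize
`log D(G(z))`), the de-facto DCGAN practice, which trains stably at small
scale; a switch restores the literal minimax gradient.

Conventions the method description leaves open were fixed once and recorded:
Adam betas (0.5, 0.999); weight initialization N(0, 0.02); batch size 64
with batch normalization; uncovered background pixels participate in all
losses at value 0 (the validity raster is constant across frames, so the
generator learns the background exactly). Training length is governed by
early stopping: training ends when the held-out discriminator accuracy has
first clearly exceeded chance and then stays within ±0.05 of 0.5 averaged
over a 200-iteration window — the "optimized discriminator at chance level"
criterion — under a hard epoch cap. The requirement that the discriminator
first leave chance prevents the stop rule from firing at initialization,
when accuracy is trivially near 0.5.

The engine underneath is a purpose-built, fully seeded conv-net core on
dense BLAS matrix operations (im2col + GEMM convolutions, a precomputed
scatter decomposition for the transposed-convolution/col2im pass, batch
normalization with running statistics, Adam). Every gradient path is
verified against central finite differences in the test suite.

## Latent-space inpainting

A compromised frame `x` with compromised-region mask `M` is reconstructed by
minimizing `L(z) = sum_intact (x - G(z))^2`, the masked reconstruction loss
over all pixels *not* in the compromised region (covered intact vertices and
constant background alike — the loss never sees compromised pixels). `z` is
initialized uniformly in [-1, 1] and updated by gradient descent; the
best-observed `z` across all iterations (and optional random restarts) is
kept, so the reported loss can never exceed the initial one, and the output
frame is the input on intact vertices with `G(z)` values spliced into the
mask. `z` is not clipped during optimization (only the initialization range
is constrained); a clip option exists.

The reference iteration count is 500 with plain gradient descent at step
2e-6 — a step size calibrated to the loss scale of a full-size (500×500)
raster. On 32×32 desk-scale rasters that step barely moves `z`, so the
search also offers Adam (default 0.05 in the experiments), which adapts to
the loss scale; this is a package design choice, recorded here, not a claim
about the original recipe. Run-level reconstruction applies the search to
every frame independently — no temporal information crosses frames — and
derives each frame's initialization from the restart seed *and the frame
content*, making reconstruction a pure per-frame function: results are
identical (to BLAS accumulation order) under any frame ordering or batching.

The diffusion baseline layers compromised vertices by graph distance to the
nearest intact vertex and fills layer by layer from the perimeter inwards,
each vertex taking the mean of its already-assigned neighbors, synchronously
within a layer. It is deterministic, relabeling-equivariant, and exact on
constant fields.

Amplitude-contrast mask detection (the DBS use case) averages `|signal|`
per vertex in the pre and post runs, normalizes each map to [0, 1] by its
maximum — divide-by-max rather than min–max, because min–max normalization
explodes ratios when amplitude maps are nearly flat — and flags vertices
whose post/pre ratio falls below a threshold (default 0.5, a package
choice; vertices below a pre-amplitude floor of 0.01 are never flagged).

## Evaluation

- **Time-series recovery**: Pearson r between original and reconstructed
  series per masked vertex; zero-variance vertices yield r = 0 with a flag.
- **FC maps**: seed-vertex correlation against every vertex in both
  hemispheres, clipped to ±(1 − 1e-7) before Fisher z (atanh), so duplicated
  series cannot produce infinities; the self-entry is excluded from all
  similarity computations. Map similarity is the Pearson correlation of two
  z-vectors over all vertices except the seed (compromised-region vertices
  are included by default, with an exclusion option — whether to exclude
  them is genuinely open, and including them is the stricter test).
- **Specificity**: mean over masked seeds of the reconstructed map's
  correlation with (i) the subject's own original map, (ii) the
  training-cohort group-average map (averaged in z-space, the standard
  convention), (iii) the most similar training individual (MSI: arg-max over
  training subjects of mean FC-vector correlation; ties break to the lowest
  index). Subject-specific reconstruction shows own > group.
- **Amplitude recovery**: 100 × mean regional |amplitude| relative to a
  reference run.
- **Mask-size sweep**: FC accuracy as geodesic masks grow from 10% to 60%
  in 10% steps.

Inferential machinery (multilevel models, repeated-measures ANOVA,
Bonferroni) is out of scope; summaries are descriptive means, sds, and
seeded percentile-bootstrap 95% CIs (2000 resamples).

## The desk-scale reference experiment

`recovery_experiment()` runs the whole loop at sizes one CPU handles in
minutes; these sizes are the package's reference conditions and are stated
here as its own choices: level-2 mesh (162 vertices per hemisphere, 324 per
frame), 32×32 rasters, 20 training and 5 test subjects, 240 frames smoothed
by 4 to 60, a 10% geodesic mask on the left hemisphere, generator channels
(128, 64, 32, 16), discriminator channels (16, 32, 64, 128), a 56-epoch cap
(~950 iterations at batch 64), and a 100-iteration Adam latent search per
frame. The mask-size sweep reconstructs 40-frame segments at 2 mask centers
× 6 fractions. `tsnr_smoothing_experiment()` draws 100 seeded single-subject
runs and compares mean tSNR before and after smoothing.

The discriminator is deliberately wider than the generator. With a narrow
discriminator (8, 16, 32, 64) the adversarial game settles into a state
where generated frames match the data's marginal statistics but not its
low-dimensional manifold: the latent search then cannot fit even the intact
region better than an all-zero prediction. Widening the discriminator
restores a useful gradient signal, the masked-frame fit drops well below
the zero baseline, and within-mask recovery roughly doubles. This is the
classic weak-discriminator failure mode, and the diagnostic — comparing the
converged masked-reconstruction loss against the intact-region power — is
a useful health check on any retraining.

## Known limitations

- DCGAN training at this scale remains noisy: reconstruction quality
  oscillates between epochs, and the latent search recovers strong but not
  ceiling-level structure (within-mask time-series r ≈ 0.5–0.7 at the
  reference conditions, against ≈ 0.8 for a linear subspace oracle fit to
  the same frames — so a modest gap to the information-theoretic best
  remains one of training, not information).
- For *small* compromised regions on a coarse mesh, boundary diffusion is an
  extremely strong baseline: nearly every masked vertex is adjacent to
  intact cortex. At the reference conditions diffusion stays ahead on FC
  similarity (the size of the gap oscillates with training state), and the
  GAN's advantage grows with region size. On fine meshes, where a region of equal
  cortical extent is many adjacency rings deep, the balance shifts toward
  the GAN much earlier.
- Frame-wise independence is faithful to the method but leaves temporal
  roughness in reconstructed series; joint multi-frame optimization is
  explicitly out of scope.
- The cohort model is stationary and Gaussian; none of the tests speak to
  motion, drift, or non-stationary artifacts.
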