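---
title: "Methods: unsupervised morphological states from brightfield movies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised morphological states from brightfield movies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, the synthetic data
the tests rest on, and the places where the design was genuinely open and
a choice had to be made. It states no empirical claims beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The problem

Brightfield time-lapse imaging can watch unlabeled, light-sensitive cells
(primary leukemic cells are a motivating case) for days at intervals of a
few minutes. The cost of being label-free is that nothing in the data says
where the cells are, which of them are alive, or which phenotypic state
each one is in. The pipeline answers those questions in sequence, and each
stage is testable against a synthetic generator whose ground truth is
known exactly.

## Label-free segmentation

A regression model learns the mapping brightfield → cytoplasm
fluorescence from a handful of paired frames, after which the predicted
fluorescence channel — clean, high-contrast blobs on a dark background —
is easy to segment by a global Otsu threshold followed by a
distance-transform watershed to split touching cells.

The predictor here is a *patch-based dense encoder–decoder*: a flattened
`patch × patch` brightfield tile is mapped through leaky-ReLU hidden
layers to the corresponding fluorescence tile (sigmoid output, MSE loss,
Adam), and whole frames are assembled by tiling with 50 % overlap and
averaging. For the contrast-transfer task on blob-like cells this
architecture reaches holdout Pearson correlations above 0.8 within a few
hundred steps (the test suite measures this); it has no claim to the
receptive-field economy of a convolutional U-Net, which is what one would
reach for at production scale on real movies.

Parameters that matter: `patch` (default 16 px; smaller patches localize
better but see less context), `minArea`/`maxArea` (px², the size window
that discards debris and merged clumps), and the crop window `cropSize`
(odd, px; must comfortably contain the largest cell).

## Viability filtering

A small dense classifier over the downsampled brightfield crop is trained
with the standard binary cross-entropy
`−[y log p + (1 − y) log(1 − p)]` on `Live`/`Dead` annotations and scores
every crop; `Live` means the score clears the decision threshold
(default 0.5, configurable — the choice trades false rejections of live
cells against contamination of the morphology space by debris). The loss
anchors are exact: 0 at a perfect confident prediction and ln 2 per sample
at an uninformative 0.5.

## Pose normalization

The representation should spend no capacity on position, orientation, or
mirror parity. Each crop is therefore:

1. re-centered on its mask centroid;
2. rotated so the mask's second-moment major axis is vertical. Masks whose
   moment-eigenvalue ratio is below 1.05 skip rotation: a near-circular
   cell has no meaningful orientation, and estimating one would inject
   noise (the tie rule);
3. rescaled isotropically **only as much as needed** so the rotated
   content fits the canonical frame with a 10 % margin. Relative cell size
   is deliberately preserved — size is one of the most informative
   morphological features, and the downstream checks (decoded mask area
   matching the class mean) depend on it. Rescaling everything to fill the
   frame would erase it;
4. reflected so the pixel-count majority lies in the top and right halves.
   A centroid-based rule would be vacuous here — after re-centering the
   centroid *is* the frame center — so the count majority is the stable
   reading of "density skew";
5. split into the binary mask image and the texture image: interior
   intensities standardized per crop (the per-crop choice makes each cell's
   texture contrast self-normalized, at the price of losing absolute
   brightness differences between cells), mapped linearly to [0, 1], with
   every exterior pixel set to 0.5.

Interpolation is bilinear for intensities and nearest-neighbour for masks.
The invariance this buys is tested directly: a crop and its rotated or
mirrored copy canonicalize to images agreeing within a mean absolute pixel
difference of 0.05.

One consequence worth knowing: the texture image necessarily shows the
cell silhouette (interior values against the 0.5 exterior), so texture
latents are never fully independent of shape. The weight-sweep controls
below are designed with that in mind.

## Twin variational autoencoders

Mask and texture images train two independent VAEs. The encoder trunk
(dense, leaky-ReLU) feeds two linear heads for the posterior mean and
log-variance; training samples `z = μ + σ·ε` (reparameterization) and the
decoder reconstructs through a sigmoid. The loss is

\[ L = A\,[\, \gamma \cdot \mathrm{MSE} + (1-\gamma)\cdot \mathrm{KLD} \,],
\qquad \mathrm{KLD} = -\tfrac12 \sum_{i=1}^{J}
  (1 + \log\sigma_i^2 - \mu_i^2 - \sigma_i^2) \]

with per-sample MSE summed over pixels. Defaults: `A = 1`, `γ = 0.9`
(reconstruction-dominant; the KL term regularizes without washing out
class structure), `J = 100` at production scale. Inference uses the
posterior mean μ as the deterministic encoding — standard practice, and it
makes duplicated crops encode identically.

Per-cell representations are fused by weighted concatenation
`z = (w·z_shape, (1−w)·z_texture)`. The weight is selected by sweeping a
grid on [0, 1] and maximizing the mean neighbour-similarity score across
types (below). `w = 1` silences texture exactly; `w = 0` silences shape.

Baselines sharing the interface: a plain autoencoder (MSE only), two
adversarial autoencoders whose discriminator
(`−(1/N) Σ [log D(z_real) + log(1 − D(z_enc))]`, non-saturating generator
update) pulls the latents toward a unit Gaussian or toward a 4-component
Gaussian mixture with means (−1, −0.5, 0.5, 1) and unit sds, and PCA on
flattened images. A caveat learned from the tests: the adversarial
moment-matching succeeds only when the data carry at least J genuine
factors of variation — on degenerate toy data the reconstruction objective
deflates surplus latent dimensions faster than the adversary can inflate
them.

All networks are dense (fully connected) and trained in-package with a
hand-written Adam; layer widths are configuration, not architecture
commitments. A compiled elementwise Adam kernel was benchmarked and
rejected: R's vectorized arithmetic was faster in this setting.

## Scoring, clustering, interpretation

**Neighbour-similarity (homogeneity) score.** For cells of type C,
H_C is the mean over those cells of the fraction of their N nearest
Euclidean neighbours (self excluded, ties broken by index) sharing C.
Under random labels it equals the type frequency; at perfect separation
it is 1. Default `N = 20`; the score is insensitive to N over a broad
range. It is invariant under isometries of latent space, which the suite
asserts on random rotations.

**Louvain clustering.** Communities of the unweighted k-NN graph
(`knn_k = 15`, Euclidean). The resolution default is **0.1, deliberately
far below 1**: VAE latent manifolds are continuous, and plain modularity
near resolution 1 fragments one dense connected cluster of cells into
several communities (in the two-class studies, intermediate resolutions
still split one class in two at moderate training lengths, while 0.1 and
0.05 behave identically). Lowering the resolution can only merge
communities that are actually connected in the graph — merging two
components with no connecting edges always decreases modularity, whatever
the resolution — so genuinely separated classes can never be fused by
this choice. Raw
communities may still be merged explicitly through a configured merge
map (never heuristically), mirroring how raw communities are combined
into named states in practice.

**Interpretation.** Per-cluster z-scores
`Z_{f,C} = (μ_{f,C} − μ_f)/σ_f` (cluster mean minus dataset mean, in
dataset standard deviations) are displayed as hierarchically ordered
clustergrams. Individual texture dimensions are rarely readable, but they
correlate in groups; groups are cut from the correlation dendrogram and
decoded together. Feature exaggeration decodes the population-mean latent
with selected dimensions amplified and subtracts the mean decoding; the
signed difference image shows what those dimensions encode. Morphometrics:
area = mask pixel count (× μm²/px²), eccentricity from second central
moments, edge strength = maximum Sobel gradient magnitude within the mask
dilated by 2 px (so the rim is included). Marker intensities are
mask means minus the frame background, estimated as the median over
non-cell pixels; values near background may legitimately be negative.

## Transition dynamics without tracking

Full trajectory assembly is error-prone for fast-moving cells; the
pipeline instead accepts only unambiguous one-step links. A cell at frame
t qualifies as a source only if every other same-frame cell is farther
than D0; it links to its nearest frame-(t+1) cell if that distance is
below D1. Where two sources contest one target the closer pair wins — the
rule set is silent on collisions, and keeping the closer pair preserves
both the minimum-distance spirit and injectivity. D0 should exceed the
typical same-frame neighbour distance; D1 comes from inspecting
displacement histograms. Border-touching detections are best excluded
upstream via the segmentation area window.

Transition probabilities are row-normalized link counts; rows with no
observed transitions are reported as `NA` rather than imputed. Link
displacements divided by the frame interval give instantaneous speeds,
grouped by the source cell's cluster (this is what exposes the
velocity–eccentricity relationship across states: elongated states move
faster in the synthetic studies by construction). Gridding UMAP-space
displacements yields a coarse vector field of state flow. Condition
comparisons use the chi-square test of independence without continuity
correction over an endpoint window (default: final 5 % of frames), with
a flag when expected counts fall below 5.

## The synthetic generator, and what passing tests do not show

Cells are rendered as randomly oriented ellipses with low-order Fourier
boundary perturbation; the brightfield patch shows an interior intensity
offset, a dark rim just inside the boundary with a lighter outside halo
(amplitude = `edge_contrast`), and Poisson-placed Gaussian granules;
fluorescence is a smoothed mask plus noise. Background sits at 0.5 of the
dynamic range, dark features below, bright rim above. Movies place cells
with an exclusion radius, move them by an isotropic Gaussian random walk
whose step scale is a property of the current state, and switch states by
a known Markov chain; no division or death is modeled, because births
would confound the pairwise linking that the dynamics tests validate.

Study conditions used by the test suite and the acceptance script, chosen
once as representative of well-powered desk-scale experiments:

* *Two-class state discovery*: small round cells (area 180 ± 25 px²,
  eccentricity 0.1 ± 0.05, granule-free, strong rim) versus large
  elongated granulated cells (420 ± 50 px², 0.7 ± 0.05, granule density
  0.08 px⁻², weaker rim); 100 crops per class at 64 × 64; twin VAEs with
  J = 16, hidden widths (128, 32), 800 Adam steps, batch 32, γ = 0.9,
  w = 0.5; Louvain at defaults; three independent seeds.
* *Weight-sweep controls*: class pairs that **overlap** in feature space
  — the homogeneity score saturates (flat at 1 across the grid) for
  perfectly separated classes and the argmax becomes a tie-break
  artifact. In the shape-only control both classes share one granule
  process whose density varies cell-to-cell (0.06 ± 0.05 px⁻²), making
  texture variation genuinely class-independent; in the texture-only
  control the two classes share one shape distribution and differ only in
  granule density (0.01 vs 0.12 px⁻²).
* *Markov recovery*: 3 states, 60 cells, 120 frames, step scale 1.5
  px/frame on a 900² px frame — about 7,000 validated links.
* *Velocity recovery*: two states with planted step scales 1 : 3.

What these tests demonstrate: the estimators are correct (they match
brute-force oracles), the pipeline is internally consistent, and the
learned representations recover planted structure. What they do not
demonstrate: performance on real microscopy. The generator has no optics
(no PSF, no shot-noise calibration), no cell–cell contact, no focus
drift, no imaging artifacts, and its classes are cleaner than any real
cell population; real data will need larger models (J = 100, conv
architectures, 10⁵-step training), careful D0/D1 selection, and manual
review of cluster merges.

## Numerical choices and degenerate inputs

* Texture with a constant interior: the whole image becomes 0.5 and is
  flagged `degenerate` rather than dividing by a zero standard deviation.
* Zero-variance features in z-score and correlation computations: scored
  0 / excluded, with warnings.
* Log-variance clamped to [−8, 8] during VAE training; a non-finite loss
  aborts with diagnostics rather than training through NaNs.
* Empty detection lists, single-frame linking inputs and empty clusters
  return empty-but-valid objects (with warnings where information is
  lost), not errors.
* Louvain and UMAP run under fixed seeds; all generator randomness
  derives from one seed through independent child streams, so identical
  seeds give bit-identical pixels.

## Known limitations

Dense encoders cap the usable image size (64 × 64 here); the patch-based
label-free predictor ignores context beyond its tile; Louvain cluster
counts depend on `knn_k` and `resolution` (cluster number is therefore
never treated as a target quantity); the manual merge map is a modeling
input, not an inference; and the linking scheme deliberately discards
cells in crowded neighbourhoods, which biases sampling toward sparse
regions — acceptable for rate estimation when occupancy is roughly
uniform, but worth remembering when it is not.
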