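---
title: "Voxelwise encoding models of natural language: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelwise encoding models of natural language: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxenc)
```

# The model

A voxelwise encoding model is a regularized linear regression from
time-resolved stimulus features onto a single voxel's BOLD time course. The
stimulus of interest here is natural narrated speech, represented in five
feature spaces that span the processing hierarchy:

* **spectral** — a 256-band mel spectrogram of the audio (0–8 kHz),
* **articulatory** — 22 binary articulation features per phoneme,
* **part of speech** — a 17-category one-hot code per word,
* **word-level semantic** — a 985-dimensional co-occurrence embedding per
  word (out-of-vocabulary words map to the zero vector),
* **context-level semantic** — a 768-dimensional contextual embedding per
  word, consumed as a precomputed table.

Each event-rate stream is resampled to the TR grid (TR = 2 s) with a 3-lobe
Lanczos (windowed sinc) filter, z-scored per column on the concatenated
training stories, and expanded with finite-impulse-response delays of 1–4
TRs so the regression can absorb the hemodynamic response shape without
assuming it. Weights are fit by ridge regression,
$(X^\top X + \lambda I)\,W = X^\top Y$, with a *single* $\lambda$ shared by
all voxels and models so weight scales stay comparable; $\lambda$ is chosen
by bootstrapping held-out contiguous chunks of training data. Performance is
the Pearson correlation $r$ between prediction and held-out data per voxel,
summarized as the signed square $r\cdot|r|$, and averaged (never summed)
within regions so cerebellum and cortex are comparable despite different
voxel counts.

Three analyses sit on top of the fits:

1. **Noise-ceiling correction.** Split-half reliability $CC_{half}$ of the
   repeated test story bounds any model's attainable correlation. We use
   $CC_{max} = \sqrt{2 / (1 + 1/CC_{half}^2)}$, floored at 0.3, and report
   $CC_{norm} = CC_{abs} / CC_{max}$. The printed form of the ceiling
   formula is typographically ambiguous in its source material, so the
   package isolates the chosen algebraic reading in `ccMaxFromHalf()` —
   changing the reading is a one-line edit — and the chosen form satisfies
   the anchor $CC_{half}=1 \Rightarrow CC_{max}=1$. Non-positive $CC_{half}$
   gives an undefined raw ceiling; we set it to 0, so the 0.3 floor applies,
   which is exactly the floor's purpose (preventing corrected correlations
   from exceeding 1).

2. **Variance partitioning.** For the *unique* scheme, a five-way union
   model and five leave-one-out unions are fit; each space's unique
   contribution is the relative complement
   $r^2(\text{union}) - r^2(\text{union without it})$, and the nonunique
   partition is the remainder. For the *pairwise* scheme, each space is
   paired with the context-level space: the intersection is
   $r^2(A) + r^2(X) - r^2(A \cup X)$. Sampling noise penalizes larger joint
   models, so raw partitions can be negative; a per-voxel **bias
   correction** finds the minimum-norm additive adjustment $b$ of the model
   $r^2$ values subject to all derived partitions being non-negative,
   $\min \|b\|^2$ s.t. $h_j(b) \ge 0$. This is a tiny quadratic program (3
   bias terms pairwise, 6 unique); it is solved exactly by a dual active-set
   iteration with an enumeration fallback (`minNormProject()`), since the
   optimum is the projection of the origin onto a polyhedron with at most
   six faces.

3. **Semantic clustering.** Word-level model weights of the best-predicted
   voxels (default top 25%; 20% is equally defensible and is a parameter)
   are unit-normalized per voxel, reduced by PCA to the smallest number of
   components explaining ≥ 80% variance, and clustered with spherical
   k-means (cosine similarity, unit-norm centroids, best of 10 restarts).
   The number of clusters is the elbow of the inertia curve: the k farthest
   from the chord joining the curve's endpoints. Region composition per
   cluster is compared with a label-shuffle permutation test.

Inference throughout is permutation-based: data (or predictions, for the
partition tests) are shuffled in contiguous blocks of 10 TRs, which
preserves local autocorrelation and so yields calibrated nulls for time
series; p values use the add-one convention $(1 + \#\{null \ge obs\}) /
(n_{perm} + 1)$ so they are never zero; multiple comparisons are controlled
with Benjamini–Hochberg FDR (the standard choice in this literature when
only "FDR" is specified).

# The synthetic-data generator

Real BOLD data cannot validate partition estimates because their true
decomposition is unknown. The generator therefore builds scenarios with a
*known* decomposition:

* Event onsets are a homogeneous Poisson process at the configured word
  rate — the simplest stream with irregular spacing, which is exactly the
  resampling problem the Lanczos stage must handle. Embedding tables are
  isotropic Gaussian.
* Ground-truth weights are drawn per space and scaled per voxel so each
  space's noiseless contribution realizes its requested share of signal
  variance **on the realized design** (empirical calibration, so shares are
  exact by construction rather than asymptotically).
* Shared (intersection) variance is carried by a latent TR time course
  planted as a dedicated feature of every designated space. Because the
  latent column is then *exactly* in each designated space's span, the
  intersection partition is controlled directly. The latent's response
  weights are stored on the first designated space's columns.
* Noise is white Gaussian per voxel (optionally AR(1) for permutation
  calibration work). Its standard deviation is solved analytically from the
  test-story signal variance $s$ and the target split-half reliability $c$
  of $n$ repeats: halves of $n/2$ averaged repeats correlate as
  $s / (s + 2\sigma^2/n)$, so $\sigma^2 = n\,s\,(1-c)/(2c)$. No iterative
  tuning is involved.

What the generator does **not** emulate: realistic hemodynamic response
shapes beyond the FIR mixing the analysis itself assumes, scanner artifacts,
motion, physiological noise structure, or the heavy-tailed and highly
correlated nature of real linguistic feature streams (amplitudes are
Gaussian by modeling convenience). Passing tests on synthetic data therefore
demonstrate the *estimators* are correct and calibrated, not that real
cerebellar BOLD has any particular structure.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `trS` | 2.0 | s | sampling interval of the scenario's scanner |
| `delaysTr` | 1–4 | TR | FIR span covering the hemodynamic peak (2–8 s) |
| Lanczos lobes / cutoff | 3 / 0.25 Hz | — | anti-aliasing at the TR Nyquist; kernel evaluated at (event time − TR time); weights not renormalized, keeping the operator linear |
| `lambdaGrid` | $10^0..10^7$, 15 points | — | standard range for z-scored designs |
| `nBoot`, `chunkLenTr`, `holdoutFrac` | 50, 20, 0.2 | — | contiguous-chunk bootstrap respecting autocorrelation; chunk size and fraction are package choices where the method family leaves them open |
| `blockLen` | 10 | TR | permutation block preserving local autocorrelation |
| ceiling floor | 0.3 | — | keeps corrected correlations bounded for unreliable voxels |
| `varianceTarget` | 0.80 | — | PCA retention for weight clustering |
| `kMax` | 20 | — | inertia curve range for the elbow rule |

# Numerical choices

* Ridge is solved through an eigendecomposition of $X^\top X$, reused
  across the whole $\lambda$ grid; at $\lambda = 0$ with rank-deficient
  designs the minimum-norm least-squares solution is returned (zero
  eigenvalues dropped). This matters because planting shared variance makes
  the latent column exactly collinear across spaces.
* z-scoring uses population statistics; zero-variance columns map to zero
  and are flagged rather than raising, since synthetic masks may contain
  empty voxels. Held-out designs always reuse training means/scales — the
  test set never contributes statistics to training-side computation (a
  poisoning test asserts this).
* Savitzky–Golay detrending uses the standard central coefficients in the
  window interior and truncated-window least-squares fits at scan edges;
  edges are discarded by the subsequent trimming anyway.
* Delayed design copies zero-pad story starts; no wrap-around across
  stories, because stories are independent scans.
* The elbow rule's candidates are the interior k (2..kMax−1); an exactly
  linear inertia curve degenerates to k = 2 under the smallest-k tie rule.
* Permutation engines all take a seed and are bit-reproducible; the final
  partial block of a series not divisible by the block length is kept as a
  shorter block.
* In the partition permutation test the same block order is applied to all
  model predictions within one draw, and the bias correction is re-applied
  inside every draw before averaging over voxels (correct-then-average, the
  same ordering as the observed statistic).

# Design decisions that were genuinely open

* **Split-half assignment** of repeats is even/odd by session order
  (balanced across the session axis).
* **"Fisher-corrected" per-voxel partition inference** is not a uniquely
  defined procedure; this package implements per-voxel block-permutation p
  values combined across response sets by Fisher's method where multiple
  sets are supplied, and documents that reading rather than asserting it.
* **z-scoring before delaying** (rather than after) was chosen so delayed
  copies of a feature share one scale; the alternative ordering differs
  only at story boundaries.
* **Whether the 0.3 floor applies to the ceiling or the reliability**: it
  is applied to the ceiling ($CC_{max}$), which is what makes the corrected
  scores bounded.
* The **articulatory table** (39 ARPABET phonemes × 22 features) and the
  **17-tag POS inventory** shipped with the package are synthetic
  stand-ins with the standard phonetic/grammatical structure and the right
  cardinalities; any fixed binary table of the same width preserves the
  method, and both are inputs rather than outputs of the analyses.
* The **top-voxel fraction** for clustering defaults to 0.25 with 0.20
  available as a parameter; both appear in the method family's practice.

# Problem sizes used by the test-suite and acceptance script

The validation scenarios are scaled-down but structurally complete: the
parameter-recovery scenario uses 10 stories × 600 s (3000 training TRs), a
300-TR test story repeated 10 times at target reliability 0.6, five feature
spaces of 6–8 dimensions and 60 voxels; the calibration study uses 500
AR(1) voxels of 300 TRs; clustering recovery uses 5 planted direction
bundles × 40 voxels in 20 dimensions. The demo pipeline
(`pipelineConfig()`) uses 6 stories × 300 s and 40 voxels so a complete
end-to-end run takes seconds. These sizes are the package's own validation
choices; the estimators themselves have no scale assumptions.

```{r demo, eval = FALSE}
res <- runPipeline(pipelineConfig(seed = 1L))
res$regionPerformance            # mean signed r2 per region and model
colMeans(partitionValues(res$uniquePartitions))
res$cluster                      # chosen k, PCA dimensionality
```

# Known limitations

* The generator's feature streams are independent across spaces except for
  the planted latent; real feature spaces are broadly correlated (silence
  vs. speech alone correlates everything), so real nonunique partitions are
  much larger than synthetic ones at the same unique shares.
* The spherical k-means objective is nonconvex; restarts make recovery
  reliable on separated data but label stability on unstructured data is
  not guaranteed (and is not a property the analyses rely on).
* `ccNorm` can exceed 1 when the raw correlation happens to beat the
  estimated ceiling; the floor bounds, but does not eliminate, this.
* The pipeline's trimming stage drops the same TR rows from design and
  responses; it does not re-standardize the design afterwards, a deliberate
  simplification documented here.
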