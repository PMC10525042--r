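---
title: "The cluster structure function: model, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cluster structure function: model, estimators, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfclust)
```

## The model

csfclust treats clustering as model selection in the sense of algorithmic
statistics. A part `A` of a partition is a model of a member `x`; its
quality is the optimality deficiency `delta(A, x) = K(A) + log2|A| - K(x)`,
the overhead of describing `x` as "the set `A` plus an index into it"
relative to the shortest description of `x` alone. A part that is an
algorithmic sufficient statistic for every member would have all
deficiencies zero; for parts with more than two members that is
impossible, so partitions are ranked by a criterion function of the
deficiencies. The default criterion is the bandwidth sum: for each part,
the spread `max(delta) - min(delta)`, summed over parts. It satisfies the
two axioms a criterion needs — zeroing deficiencies never increases it,
and it vanishes when all deficiencies vanish.

The cluster structure function `H_S(k)` is the minimum criterion value
over all partitions of `S` into exactly `k` non-empty parts. Its exact
form (`csf_exact()`) enumerates set partitions — feasible to `n = 12`,
enforced by a guard — and is the reference implementation against which
everything else is validated. Two structural laws pin it down: the curve
is monotone non-increasing in `k`, and it is exactly zero at `k = n`,
where every part is a singleton with deficiency zero by the
small-cardinality branch of the estimator. The test suite checks both on
idealized oracles and on real compressed sizes.

Two readings of the printed definitions required a decision:

* The standard deviation `sigma_S` used for trimming is defined against a
  mean `mu_S`; the surrounding text defines `mu_S` once as a mean of
  *elements* and once as a mean of *deficiencies*. Only the latter
  type-checks inside `sigma_S`, so `sigma_trim()` uses the mean of
  deficiencies (population standard deviation, divide by `n`).
* The trimmed structure function is printed with an inner maximum over a
  part index the criterion does not depend on; `csf_sigma()` implements
  the only evaluable reading, the minimum over partitions of the
  criterion on the sigma-trimmed set.

## Approximating complexity with compressors

`K` is uncomputable; the package substitutes the length in bytes `Z(x)`
of a compressor's output (`compressor_spec()`: gzip, bzip2, xz via
`memCompress`, or PNG for grayscale matrices). The practical deficiency
is `Z(A) - Z(x) + log2|A|`, with `A` compressed as the concatenation of
its members and parts of fewer than two members assigned deficiency 0.
Two unit notes are deliberate: `Z` is measured in bytes while the
`log2|A|` term is in bits, exactly as the practical estimator is written —
the log term is small against byte sizes and no conversion is applied;
and deficiencies are not clamped at zero, since both the theory and real
compressors allow negative values. The self-delimiting multiset encoding
(`serialize_multiset()`, `1^|x| 0 x` per element) is provided for
bit-exact tests of the encoding identity; all compressor calls use plain
concatenation, which is also what the joint-compression term wants.

Pairwise similarity is the normalized compression distance,
`(Z(xy) - min(Z(x), Z(y))) / max(Z(x), Z(y))`, symmetrized as the mean of
both concatenation orders because real compressors are order-sensitive
and the downstream spectral step assumes a symmetric matrix. On
mid-entropy kilobyte corpora the gzip diagonal stays below 0.15;
highly repetitive short strings compress to so few bytes that the
per-stream header overhead dominates and the diagonal rises — a known
artifact of deflate at small sizes, worth remembering when objects are
tiny.

## The empirical pipeline

For sets too large to enumerate, `csf_empirical()` follows the practical
recipe: cluster the full set once per `K` by classic spectral clustering
on the NCD matrix (Gaussian affinity with the median off-diagonal
distance as bandwidth, symmetric normalized Laplacian, unit-normalized
rows of the bottom-`K` eigenvectors, seeded k-means with ten restarts),
then draw `5 K` objects per subsample without replacement, compute
deficiencies per cluster restricted to the subsample, and score the
subsample as `sum(log2(bandwidth + 1)) / k_max` over occupied clusters.
The sum runs over occupied clusters only — clusters beyond `K` do not
exist — while the denominator stays `k_max` so curves across `K` share a
scale. Curves are not forced monotone: the clustering heuristic, the
compressor, and the subsampling all perturb the ideal shape, and the drop
structure is precisely the signal the selection rules read.

Two selection rules are provided because the theory and the practice
emphasize different ones. The one-SD rule takes the first `K` whose mean
drops below the previous mean by more than the previous spread, with
`K = 1` ("no meaningful clusters") as the fallback. The log-ratio rule
compares against a uniform reference placement over the range spanned by
the data and takes the argmax of `log2 H_N(k) - log2 H_S(k)`, excluding
`k` where either curve is zero and breaking ties toward the smallest `k`.
For byte strings the reference placement has no interval construction, so
the reference is seeded uniform random strings of the median length; for
numeric matrices it is a per-dimension midpoint grid (smallest grid with
at least `n` cells, truncated to `n` in row-major order). The
`csf_feature_vector()` export (means then spreads over `K = 1..10`,
twenty numbers) is the input a supervised predictor of `K` would train
on; the predictor itself is out of scope and any classifier can sit
behind it.

An `exhaustive` clustering mode replaces the spectral step by direct
minimization over all partitions and the subsample by the full set; the
acceptance suite uses it to confirm that the pipeline plumbing reproduces
`csf_exact()` to machine precision on small sets.

## Point clouds and the recovery benchmark

For numeric points the complexity difference is approximated by the
Euclidean distance to the cluster centroid (`csf_points()`), clusters
come from seeded k-means, and each cluster contributes its trimmed mean
distance: only points within one standard deviation of the centroid
count, read radially — distance at most the standard deviation of all
member distances — with the nearest point retained as a floor when the
trim would empty a cluster. The radial reading is one of two defensible
ones (the other is a band around the mean distance); it is exposed as the
`trim` knob.

`benchmark_k_recovery()` runs the recovery experiment: three
unit-variance components at `0, r, 2r` on the x axis, 500 points per
component at desk scale (the full-scale layout uses 10,000), scored
against AIC/BIC on a hard-assignment spherical k-means likelihood
(`p = K d + (K - 1) + 1` parameters) and the Gap statistic. A limitation
found while validating, and worth stating plainly: at spacing `r = 1.5`
the three components form a unimodal cloud, and the
dispersion-versus-uniform log ratio peaks at `k = 2` as a population
property — more data does not fix it, and the hard-assignment AIC
prefers `k = 1` there for its own reason (the entropy cost of assigning
overlapping points). Reliable recovery by the log-ratio rule begins
around spacing 3–4; the suite asserts recovery in that regime and records
the overlapping regime as an open failure rather than tuning around it.

## Ensemble segmentation

Candidate nuclear segmentations produced at several expected-radius
settings are combined by scoring each candidate region with
`e_convex + e_boundary + e_background`:

* `e_convex` — region area over convex-hull area, hull taken over the
  corners of the region's pixels so a filled rectangle scores exactly 1.
  2-D only: no computational-geometry backend for 3-D hulls is available
  to the package, and all bundled scenes are 2-D.
* `e_boundary` — `1 - mean(R - T)` over boundary pixels (8-connectivity,
  neighbors beyond the image border ignored), where `R` is the 3×3
  neighborhood intensity maximum and `T` an adaptive threshold (local
  mean over a 31-pixel window minus an offset, default 0.4 — chosen for
  the high-contrast fluorescence regime of the bundled scenes, where it
  keeps the background term's denominator well away from zero).
* `e_background` — mean `I - T` over the region divided by mean `I - T`
  over the background (complement of all candidate supports), capped when
  the denominator degenerates; unclamped above by design.

Overlapping candidates (any shared pixel; a minimum-overlap fraction is
available for noisy stacks) form buckets as connected components of the
overlap graph, and within each bucket a greedy pass repeatedly keeps the
highest-scoring candidate and discards everything overlapping it (ties:
larger region, then smaller id — fully deterministic).

One genuine divergence deserves a note. Reading the selection objective
literally as "maximize the sum of scores over non-overlapping candidates"
is not what the greedy pass optimizes, and on fragment-rich buckets the
two disagree systematically: the efficiency score is scale-free (a half
nucleus scores close to a whole one), so the sum objective always prefers
many small fragments. The greedy rule — one best representative per
overlapping region — is what makes the ensemble work, and it coincides
with the exhaustive optimum exactly in the regime where buckets are
stacks of alternatives for the same object; the acceptance suite checks
that coincidence on stack-structured instances and checks `greedy ≤
optimum` always.

## Synthetic data: what it emulates, what it does not

`template_class_strings()` stands in for class-structured image sets: a
seeded random template per class, each object a copy with bytes resampled
at rate 0.02 (1 kB, 50 per class by default). Templates are drawn over
class-specific alphabet sizes (4 up to 256 symbols), so classes differ in
intrinsic compressed size the way real image classes do. That choice is
load-bearing: the subsampled bandwidth depends only on the spread of
per-object compressed sizes within a cluster, so classes of identical
entropy would be invisible to the curve no matter how distinct their
content. Real data earns its complexity differences; the generator has to
plant them.

`cell_image()` renders elliptical nuclei (semi-axes 7–10 px by default,
contrast 0.6 over a 0.15 background, Gaussian noise 0.05) with a bright
plateau to half the semi-axes and a linear intensity falloff to the full
ellipse — the soft edge a point-spread function produces, and the
gradient without which the boundary efficiency cannot tell a true rim
from a cut through bright interior. The truth mask is the half-maximum
footprint. Candidate masks per radius emulate a single-parameter
segmenter: denoise, threshold at 30 % of contrast, split each foreground
component into `round(area / (pi r^2))` pieces by seeded k-means on pixel
coordinates — small radii over-segment, large radii merge close nuclei.
What the scenes do not emulate: texture inside nuclei, intensity
variation across cells, anisotropic point-spread functions, dense
colonies with many-way contacts, and 3-D stacks. Passing the bundled
comparisons therefore shows the selection machinery works when the score
terms carry signal; it does not certify performance on real microscopy.

`gaussian_mixture()` and `bitflip_string_set()` are exact seeded
constructions; every generator is a pure function of its parameters and
seed.

## Numerical choices and problem sizes

Logarithms are base 2 throughout. Witness partitions break ties to the
first minimizer in canonical enumeration order. Spectral clustering falls
back to a deterministic ordered split when the embedded rows collapse to
fewer distinct points than clusters, and warns on fully degenerate
affinities. The k-means steps use ten restarts and a 200-iteration cap
under the caller's seed. Compressed sizes are cached by content hash.

The suite and the acceptance script run at desk scale by the package's
own choice: exact/pipeline equivalence at `n = 7`, two-class string runs
at 100 objects × 1 kB with 200 subsamples over 10 seeds, the recovery
benchmark at 100 trials × 1,500 points, and twelve seeded scenes for the
ensemble comparison. The full-scale layouts (10,000 points per component;
thousands of subsamples) are reachable through the same arguments.
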