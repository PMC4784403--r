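---
title: "PCA scoring and simplex geometry for continental ancestry inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA scoring and simplex geometry for continental ancestry inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsimplex)
```

## The model

`popsimplex` estimates, for each genotyped individual, the proportion
of their ancestry attributable to each of three or four continental
source populations. It is a distance-based method: individuals are
placed in a low-dimensional principal-component space and their
admixture is read off from their position relative to the reference
populations' centroids. Nothing is iterated and no likelihood is
maximized, which is what makes the method fast and exactly
reproducible.

### Step 1 — portable PC scores

Genotypes are additive counts $x_{ij} \in \{0,1,2\}$ of a fixed,
panel-defined reference allele at SNP $j$ for individual $i$. Given a
training matrix $X_{N \times P}$ with no missing entries, we compute
per-SNP means $\bar{x}_{.j}$, the centered matrix $Y$, and the
covariance $C = Y^\top Y/(N-1)$. The top-$k$ eigenvectors of $C$
(columns of $P_{P\times k}$, eigenvalues $\lambda_1 \ge \dots \ge
\lambda_k$) define the score matrix $Z = Y P$. When $N \le P$ the same
quantities are obtained from the SVD of $Y$ (loadings = right singular
vectors, $\lambda_i = d_i^2/(N-1)$); the `auto` method picks the route
by the $N > P$ test, and the two routes agree to numerical precision —
the test suite asserts $<10^{-8}$ element-wise after sign
canonicalization.

The eigenvectors plus the training means are the **SNP weights**, the
reusable artifact: a new study with genotype matrix $U$ on the same
marker panel is scored as $Z^* = (U - \text{means}) P$ without
refitting. Two centering conventions exist:

* `training_means` (default): subtract the *stored* training means, so
  new scores are directly comparable with the training-derived
  centroids and with scores computed at any other site. This is what
  cross-study ancestry inference requires.
* `own_means`: subtract the new matrix's own column means. This is the
  literal "center the new data" prescription; it shifts every score by
  the constant row vector (own means − training means) × loadings and
  is therefore *not* commensurate with shipped centroids unless the new
  cohort happens to have the training composition. It is provided for
  completeness and for within-study use.

The default follows from the purpose of the weights; both behaviors
are exposed and the analytic offset between them is asserted in the
tests.

Because ancestry-informative panels are chosen to maximize
between-population variance, the leading components capture
continental structure; $k$ = populations − 1 (2 for three populations,
3 for four) is the geometry's intrinsic dimension, and higher
components are ignored by the estimator. SNP weights are best trained
on many more samples than SNPs ($N \gg P$), which stabilizes the
eigenvectors and avoids variance shrinkage when they are reused.

### Step 2 — the ancestry simplex

Each reference population's **centroid** is the coordinate-wise mean
of its labeled samples' first $k$ scores. Three centroids span a
triangle in 2-D, four a tetrahedron in 3-D. A query point $z$ is
classified by the feature of the simplex closest to it, computed
exactly by enumerating every face of the convex hull (vertices, edges,
faces, full simplex), keeping candidates whose affine projection has
nonnegative barycentric coordinates, and taking the minimum distance.
For a triangle this is provably the same partition as the classical
construction that draws the two perpendiculars through each centroid:
the exterior wedge at a centroid is exactly the set of points whose
closest feature is that vertex, and the exterior slab along a side is
the set whose closest feature is that edge.

Proportions then follow inverse-distance rules:

* **Vertex**: 100 % of that population.
* **Edge**: drop the point perpendicularly onto the edge; with $L_1,
  L_2$ the distances from the foot to the two centroids, the first
  population's share is $\frac{1/L_1}{1/L_1 + 1/L_2}$ (equivalently
  $L_2/(L_1+L_2)$), the other populations get 0.
* **Triangle interior**: for each side, the perpendicular distance $H$
  and the foot's two-way split define a side estimate; the three side
  estimates are combined with weights $1/H$ and normalized by
  $\sum 1/H$. Algebraically each side contributes its full $1/H$ to
  the numerator sum, so the three proportions sum to exactly 1 —
  no rescaling is ever applied, and the test suite asserts the sum to
  $10^{-9}$ over tens of thousands of random points.
* **Tetrahedron** (four populations): a vertex or edge feature is
  handled as above; a face feature projects the point orthogonally
  onto the face plane and applies the triangle rule among that face's
  three centroids; an interior point is projected onto *each* of the
  four faces, the triangle rule is applied on each, the population
  absent from a face scores 0 there, and the four estimates are
  averaged.

### Limits and continuity

All inverse distances use a floor of $10^{-12}$: a distance below it
is treated as the exact limit rather than divided through. On a side
($H \to 0$) the interior formula reduces exactly to that side's
two-way split; at a centroid, to the one-hot vector. Consequently the
3-population proportion map is continuous everywhere — across
vertex/edge, edge/interior and all other region boundaries — which the
suite verifies with dense walks (step $10^{-4}$, maximum adjacent
jump below $10^{-3}$).

The 4-population interior rule is *not* continuous at the tetrahedron's
faces: just inside a face the estimate is the average of four per-face
projections, while just outside it is the single nearest-face estimate.
This is a property of the face-averaging convention itself, not of the
implementation; we judged a documented discontinuity preferable to
inventing an interpolation the method does not define. See the design
notes below.

## Open design points and how they were settled

**Four-population interior averaging.** "Average the per-face
estimates" is ambiguous when each population appears on only three of
the four faces: averaging each population's three per-face values over
3 makes the four proportions sum to 4/3. We average over all four
faces with the absent population scored 0 on its opposite face — the
unique simple convention that preserves normalization exactly (each
face's triangle estimate sums to 1, so the average of the four does
too). The regular-tetrahedron barycenter correctly maps to
(¼, ¼, ¼, ¼) under this rule.

**Exterior taxonomy for four populations.** Vertex and face capture
generalize directly from the triangle; points whose nearest feature is
an *edge* of the tetrahedron are completed with the same two-way edge
rule, which is the natural limit of both adjacent face estimates.

**Eigenvector signs.** Signs are mathematically arbitrary and differ
between linear-algebra backends. Every loading column is flipped, if
needed, so its largest-absolute-value entry is positive (ties broken
by lowest SNP index). This makes weights files byte-reproducible and
is idempotent.

**Tie-breaking.** A point equidistant from two simplex features (a
boundary point, within $10^{-12}$) resolves to the lower-dimensional
feature first and then to the lowest population indices — the
proportions agree in the limit from either side, so the choice only
fixes the reported region label deterministically.

**Strand-ambiguous SNPs.** A/T and C/G SNPs cannot be oriented by
base complementation. The default harmonization policy takes their
stated alleles at face value and warns (the expectation being that
genotypes were strand-checked upstream, e.g. with PLINK's flip
machinery); `strict = TRUE` drops them instead. Non-ambiguous SNPs
are matched directly or after complementing both alleles, and counts
are recoded $x \mapsto 2 - x$ when the study coded the panel's
alternate allele.

**QC order.** Samples are filtered before SNPs: a sample with a high
missing rate can masquerade as an artefactual extra "population" in
score space, so per-sample missingness (threshold 0.05) is the primary
filter; the SNP threshold (0.05, recomputed on surviving samples)
mirrors it.

**Imputation.** Missing calls are replaced by the panel's stored
per-SNP training mean when available — so that two sites imputing the
same panel produce identical scores — falling back to the within-study
mean. A panel SNP entirely absent from a study is filled as a whole
column from its training mean during score projection (and logged);
this trades a small loss of resolution for cross-study operability.

**Self-derived centroids.** When no labeled reference samples are
available and the cohort is large enough to contain all source
populations, centroids can be derived from the study itself:
farthest-point initialization followed by k-means refinement, with
clusters named deterministically by their score-space position. This
is a convenience for large cohorts, not a substitute for reference
labels in small ones.

## The synthetic-data generator

Real reference data (HapMap-style continental panels) cannot be
bundled, so the package generates its own study fixtures under the
standard Balding–Nichols model: each SNP has an ancestral frequency
$p \sim \mathrm{Uniform}(0.1, 0.9)$ — bounded away from fixation to
mimic common-variant ancestry-informative panels — and each population
draws its frequency from
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$
with $F$ the target FST. Unadmixed individuals are
$\mathrm{Binomial}(2, f)$ per SNP; an admixed individual draws a true
admixture vector $q \sim \mathrm{Dirichlet}(\alpha)$ and then each of
its two allele copies picks a source population according to $q$
before a Bernoulli draw in that population's frequency. Defaults
(FST 0.15, 200 reference samples per population, 1000 SNPs, uniform
Dirichlet admixture) reflect continental human differentiation and
the panel/cohort scale this estimator targets.

What the generator deliberately does **not** model: linkage
disequilibrium between markers (admixture is drawn per allele copy,
appropriate for genome-spread panels of unlinked AIMs, not for dense
arrays), genotyping error, panel ascertainment bias, and the real
geography of human gene flow (gradients, bottlenecks, more than four
sources). Passing the recovery tests therefore demonstrates that the
estimator correctly inverts its own geometric model under realistic
differentiation and noise — not that real cohort estimates will reach
the same correlations, which depend on panel quality and reference
choice.

## Numerical conventions

* Inverse-distance floor $\varepsilon = 10^{-12}$; boundary snap for
  barycentric feasibility at the same $\varepsilon$.
* Zero-variance (monomorphic) SNP columns are retained with zero
  loadings rather than rejected, so fixed panels still run on small
  or homogeneous cohorts.
* Degenerate geometries (collinear triangle, flat tetrahedron —
  smallest singular value of the edge matrix $\le 10^{-9}$) are
  rejected at construction.
* All writers emit full-precision (`%.17g`) locale-independent text,
  so write→read round trips are bit-exact and identical runs produce
  byte-identical outputs; missing genotypes are read as `NA`, `-9` or
  `.` and always written as `NA`.
* Simulation draws frequencies at `seed` and genotypes at `seed + 1`,
  making each stage independently reproducible.

## Scale of the validation suite

The shipped tests run, among others: 10,000 random query points
against random 3- and 4-population geometries for the normalization,
fixed-point, permutation and rigid-motion invariants; 1,000
interior/edge points against an arbitrary-precision (40-digit)
transcription of the inverse-distance formulas plus an independently
coded double-precision transcription using different geometric
primitives; PCA route agreement on 200×50 and 50×200 matrices; and
full-pipeline admixture recovery at the default study conditions
(three and four populations, 1000 SNPs, 200 reference samples per
population, 200 admixed). These sizes keep the whole suite under a
few minutes on one core while leaving the Monte-Carlo bounds
comfortably powered.

## Known limitations

* At most four source populations; the simplex construction
  generalizes in principle but feature enumeration and the averaging
  convention grow combinatorially.
* No uncertainty quantification on proportions — the method is a
  deterministic geometric map of a point estimate.
* Proportions are only as good as the score space: a marker panel
  that does not separate the source populations, or reference samples
  that do not bracket the cohort, bias the centroids and hence every
  estimate.
* The 4-population estimate is discontinuous at tetrahedron faces
  (see above), with jump size bounded by the spread among the
  per-face estimates.
* Binary PLINK (.bed) and VCF input are out of scope; inputs are the
  text dialects documented in `read_additive_genotypes()`.
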