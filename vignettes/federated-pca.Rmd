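---
title: "Methods: federated PCA, its approximations, and how this package tests them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated PCA, its approximations, and how this package tests them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedpca)
```

## The problem and the model

In a cross-silo federation, a study's samples are held as row blocks
`A_1, …, A_S` of a samples-by-features matrix `A ∈ R^{n×d}` at `S` sites
that may only exchange aggregated parameters with a central aggregator
(star topology). PCA is the eigendecomposition of the feature covariance
`M = (1/n)AᵀA = VΣVᵀ`; the target is the top-k subspace `(V_k, Σ_k)`.
Biomedical matrices are typically `d ≫ n` (hundreds of samples, ~20 000
genes), so at most `n − 1` eigenvalues are nonzero for centered data, and
the per-site sample counts — often extremely skewed, down to single-sample
sites — cap what any local computation can contribute.

All algorithms assume centered (optionally unit-variance) data, which is
itself computed federatedly: each client ships per-column counts, sums and
sums of squares (a `3d + 1`-scalar message), the aggregator returns pooled
means and variances (`2d`). The pooled statistics are exact, independent of
the site layout.

## The five algorithms

**P-COV** uploads exact local Gram matrices `A_sᵀA_s` and eigendecomposes
their sum — exact for any partition, at `O(d²)` upload per client.

**AP-COV / AP-STACK** upload the truncated local SVD `(V_s^{k′}, σ_s^{k′})`.
AP-COV reconstitutes rank-k′ proxy Gram matrices `V_s diag(σ_s²) V_sᵀ` and
sums them; AP-STACK takes the SVD of the vertically stacked
`diag(σ_s) V_sᵀ`. Because the stack's cross-product *is* the summed proxy,
the two are mathematically identical; the pseudocode in the source
literature writes the reconstruction with `Σ` to the first power, which
would break that identity, so this package deliberately uses squared
singular values (the only reading under which the two published claims
"conceptually the same" and "as accurate as" hold). The approximation error
vanishes as `k′` reaches full local rank; `k′` is capped per site at
`min(n_s, d)` with a warning, and the k′ singular values ride along with the
eigenvectors, giving `(d+1)k′` scalars per upload.

**QR-PCA** uploads the triangular factor `R_s` of a local QR factorization
(`min(n_s, d) × d`; short-wide sites produce ragged row counts, which the
vertical stacking handles). The aggregator re-factorizes the stack and takes
the SVD of the merged factor, which shares the right singular vectors of
`A` — exact for any partition. One implementation subtlety matters: R's
`qr()` pivots columns of (near-)rank-deficient input, which would silently
permute features inside a factor; the implementation restores the original
column order, so the uploaded factor always satisfies `FᵀF = A_sᵀA_s`
(triangular up to that rare permutation).

**SUB-IT** is block power iteration federated per round: the aggregator
broadcasts the candidate `V` (`d×k`), each client returns
`A_sᵀ(A_s V)` — computed as two tall-skinny products, never materializing
`d×d` — and the aggregator sums (which equals `AᵀA V` exactly, making the
iteration partition-invariant) and re-orthonormalizes by QR with a
nonnegative-diagonal sign convention, so runs are deterministic per seed.

## Numerical choices

* **Termination of SUB-IT.** Convergence is declared when the *sine* of the
  angle between every candidate column and its predecessor drops below
  `epsilon` (default `1e-9`), computed stably as
  `‖v − (v·v_prev) v_prev‖`. The more common `1 − |v·v_prev| < ε` criterion
  is quadratic in that angle: at `ε = 1e-9` it fires at a successive angle
  of ~`4.5e-5` rad and leaves a residual eigenvector error of order
  `4.5e-5 · ρ/(1−ρ)` rad (ρ the adjacent eigenvalue ratio) — around `1e-2`
  degrees for realistic spectra, which would contradict the exactness this
  package promises (and tests) for the exact methods. The sine-based
  criterion keeps the published threshold value `1e-9`, stays
  sign-insensitive, per-vector and dimensionless, and leaves a residual
  error of order `1e-9 · ρ/(1−ρ)` rad — far below the `1e-4`-degree test
  tolerance for any spectrum with a visible eigengap.
* **Eigenvalues from SUB-IT.** The algorithm iterates on eigenvectors only;
  eigenvalues are Rayleigh quotients read off the diagonal of the final
  merge's triangular factor, divided by `n`. The error is second-order in
  the eigenvector error, comfortably inside the `1e-8` relative tolerance.
* **Eigenvalue normalization.** All aggregation happens on unnormalized Gram
  matrices, as the pseudocode does; reported eigenvalues are divided by `n`
  to match `M = (1/n)AᵀA`. Eigenvectors are unaffected.
* **Sign canonicalization.** Eigenvector sign is arbitrary; every returned
  matrix flips each column so its largest-magnitude entry is positive. Angle
  metrics fold sign anyway (`arccos |x·y|`, clamped into [0, 1]).
* **Degenerate spectra.** Eigenvectors inside a (near-)degenerate eigenvalue
  block are not identifiable; per-vector comparisons in the test-suite skip
  indices whose adjacent relative eigengap is below `1e-6` and rely on
  reconstruction-based checks instead. Ties are otherwise not special-cased.
* **Zero-variance features** cannot be scaled to unit variance; when scaling
  is requested they are dropped from all sites with a warning (scaling a
  constant gene is meaningless and division by zero helps nobody). When only
  centering, a constant column becomes exactly zero and is kept. Variances
  use the `n − 1` sample divisor (configurable), the convention of
  expression analysis.

## Communication accounting

Every exchange is one logged message with a payload shape; `T` is the total
scalar count and `N` the number of rounds (parallel messages share a
round). `predicted_comm_cost()` states the closed forms — `d×d` per client
for P-COV, `min(n_s,d)×d` for QR-PCA, `(d+1)k′_s` for the AP methods,
`2·d·k` per client per iteration for SUB-IT, plus one `d×k` eigenvector
broadcast per client for the single-round methods — and the test-suite
asserts that recorded logs equal these predictions *exactly*, for every
algorithm, over randomized configurations. Two counting decisions are
deliberate: the AP uplink includes the k′ singular values (they are part of
the payload the aggregator needs), while the `k` eigenvalues on the
downlink are not counted, mirroring how the published cost table reports
only the eigenvector matrix. One scalar counts as 1; multiply by 8 for
bytes at double precision.

The centering/scaling statistics protocol is counted separately from the
algorithm costs (`3d + 1` up, `2d` down, per client).

## The synthetic world

`generate_lowrank()` produces `A = Z diag(s) Wᵀ + E` — orthonormal random
feature basis `W`, standard normal scores, i.i.d. Gaussian noise — centered,
with the planted basis attached for recovery checks. It emulates the two
properties that matter for federated PCA accuracy: a controllable
eigen-spectrum (gaps govern both identifiability and SUB-IT's convergence
speed — iteration counts on a (10, 1) spectrum are measurably below those
on (10, 9), and the suite asserts it) and `d ≫ n` shapes. It does **not**
emulate counts: real RNA-seq data are negative-binomial counts with library
sizes; the Gaussian model stands in for already-normalized, scaled
expression values. A green test therefore establishes algorithmic
correctness, not robustness to count noise, outliers or missingness.

`skewed_site_sizes()` draws per-site counts as `min_size` each plus a
multinomial over symmetric Dirichlet(α) weights — the one-knob emulation of
real multi-center skew (α ≈ 0.2–0.3 reproduces cohorts where one site
contributes hundreds of samples and others a handful; the published cohort
shapes ship as presets in `tcga_site_preset()`). This construction, rather
than draw-then-adjust, guarantees the total and the minimum exactly.
Batch effects are per-site constant mean shifts `b_s ~ N(0, shift_scale²)`
— sufficient to reproduce the qualitative phenomenon that exact federated
PCA separates sites in the top-2 projection while locally-centered naive
PCA superimposition cannot (the suite demonstrates this with silhouette
scores); scale or rotation effects are not modeled.

`greedy_meta_sites()` groups small sites into balanced "meta-sites" with the
longest-processing-time heuristic (sort descending, assign to the smallest
group, ties to the lowest index) — the simplest deterministic reading of
"approximately the same size each"; the suite checks the classic LPT
makespan guarantee against brute force for small S.

## Resampled projection views

For visualization without sharing exact projections, each site fits a
Gaussian (sample mean, sample covariance with `1e-9` diagonal jitter) to its
local projections `A_s V_k` and shares `m` draws (default `m = n_s`; the
mean *is* shared implicitly as the Gaussian's center — without it the
surrogate cloud would collapse to the origin and be useless for layout).
`assemble_global_view()` refuses exact foreign clouds outright, which is the
package-level enforcement of the privacy contract; the suite additionally
asserts set-disjointness between resampled and exact foreign points. This
is moment matching, not differential privacy: no formal guarantee is
claimed, and a single-sample site's resampled cloud still reveals that
site's single projection up to jitter.

## Design decisions where the design was open

* The CLI requires an explicit `--k-prime` for the AP methods (fail fast at
  the interface); the programmatic API defaults to `max(2k, k + 5)`, capped
  per site — a sensible oversampling default where no published value
  exists.
* The iteration cap defaults to `max_iter = 1000`, the reported iteration
  count of the reference implementation's federated runs, interpreted as
  its cap; hitting it returns the result with a `converged = FALSE` flag
  and a warning rather than an error.
* Shuffling before site splitting is opt-in, so site files map
  deterministically to row ranges by default; the permutation is stored and
  inverted exactly on reassembly.
* The aggregator is simulated in-process. The access contract — clients
  read only their own block plus broadcasts, the aggregator reads only
  logged payloads — is enforced structurally (client computations live in
  site-indexed `lapply` scopes; aggregator-side merges accept only summary
  objects) and exercised by unit tests that drive the merge functions with
  hand-built summaries alone.
* Epsilon's published value is typeset ambiguously ("10e−9") in one place;
  the prose value `1e-9` is used.

## Known limitations

P-COV and QR-PCA materialize `d×d` (resp. stack `Σ min(n_s,d) × d`)
matrices at the aggregator; for `d` in the tens of thousands this is the
memory bottleneck, and SUB-IT is the exact method that avoids it. Angles
between eigenvectors whose eigenvalues nearly tie are unstable in *any*
implementation — compare subspaces, not vectors, in that regime. The
communication model counts scalars, not wire bytes: serialization overhead,
encryption and relay-server inflation of a real deployment are out of
scope.
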