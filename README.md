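# fedpca — federated PCA for horizontally partitioned biomedical data

`fedpca` simulates **federated principal component analysis** for the
cross-silo setting common in biomedicine: the samples of a study (patients,
cells) are spread over several sites (hospitals, studies), every site
observes the same features (genes), and raw rows may never leave their site.
Only aggregated parameters travel between the clients and a central
aggregator in a star topology. The package is aimed at method developers and
data analysts who want to understand — before running a real federated
study — how accurate each federation strategy is on *their* kind of data
(typically `d ≫ n` expression matrices with strongly skewed site sizes) and
what it costs in network traffic.

## The model

Let `A ∈ R^{n×d}` be the pooled, centered (optionally unit-variance scaled)
samples-by-features matrix, distributed as row blocks `A_1, …, A_S` over `S`
sites. PCA is the eigendecomposition of the feature covariance matrix

```
M = (1/n) AᵀA = V Σ Vᵀ,
```

and the result of interest is the k-subspace `(V_k, Σ_k)` of top
eigenvectors and eigenvalues. Five federation strategies are implemented:

| algorithm | idea | upload per client | exact? |
|-----------|------|-------------------|--------|
| `p_cov`    | sum local Gram matrices `A_sᵀA_s` at the aggregator | `d×d` | yes |
| `ap_cov`   | send truncated local SVD, merge rank-k′ proxy covariances | `(d+1)·k′` | no |
| `ap_stack` | same payload, SVD of the vertically stacked `diag(σ_s)V_sᵀ` | `(d+1)·k′` | no |
| `qr_pca`   | send triangular factors `R_s`, re-factor the stack, SVD | `min(n_s,d)×d` | yes |
| `sub_it`   | block power iteration: clients return `A_sᵀA_s V` per round | `d×k` per round | yes (at convergence) |

`ap_cov` and `ap_stack` are numerically equivalent (the stack's
cross-product *is* the summed proxy covariance); their error is governed by
the intermediate dimensionality `k′`, which is capped per site at
`min(n_s, d)` — a site with 20 samples can contribute at most 20 components,
which is why many-small-site federations hurt the approximate methods.

Accuracy is measured against the centralized SVD as per-eigenvector angles
`θ = arccos |x·y| / (‖x‖‖y‖)` (in degrees; the sign of an eigenvector is
arbitrary) and as the ratio of data-reconstruction errors
`‖A V_k V_kᵀ − A‖_F`. Every message is recorded in a communication log whose
totals match closed-form cost predictions exactly.

## Worked example

```r
library(fedpca)

# simulate a 120 x 200 expression-like matrix, planted rank 5,
# skewed over 6 sites (Dirichlet alpha = 0.3 -> sizes 1 111 1 1 1 5)
sim <- fedpca_simulate("sim", n = 120, d = 200,
                       leading_values = c(12, 9, 7, 5, 4), noise_sd = 0.4,
                       n_sites = 6, alpha = 0.3, seed = 11)

cfg <- run_config(input = sim$matrix, algorithm = "all", k = 4,
                  output = "out", sites = sim$sites, seed = 7)
reports <- fedpca_run(cfg)
```

which prints (per-algorithm report JSONs land in `out/`):

```
p-cov     max angle 0.00e+00 deg  recon ratio 1.000000  T =  244800 scalars  rounds 2
ap-cov    max angle 4.43e-02 deg  recon ratio 1.000000  T =    8418 scalars  rounds 2
ap-stack  max angle 4.43e-02 deg  recon ratio 1.000000  T =    8418 scalars  rounds 2
qr-pca    max angle 8.54e-07 deg  recon ratio 1.000000  T =   28800 scalars  rounds 2
sub-it    max angle 0.00e+00 deg  recon ratio 1.000000  T = 1382400 scalars  rounds 288
```

Reading: the exact methods (`p-cov`, `qr-pca`, `sub-it`) reproduce the
centralized eigenvectors to numerical precision on this very unfavorable
partition (four single-patient sites). The approximate methods deviate by a
small angle — their eigenvector *loadings* are already slightly off even
though the reconstruction ratio is still 1 to six decimals, which is exactly
why angle, not reconstruction error, is the stringent criterion when
loadings feed downstream gene analyses. The traffic column shows the trade:
AP methods ship ~30× fewer scalars than `p-cov` here, while `sub-it` pays
`2·d·k` scalars per client per iteration (288 rounds).

The same pipeline is scriptable from the shell via `inst/cli/fedpca`
(subcommands `simulate`, `run`, `evaluate`, `resample`).

### Privacy-aware visualization

`fedpca_resample()` (or `fedpca resample`) implements the projection
resampling scheme: each site fits a Gaussian to its *local* PC projections
and shares only artificial points drawn from that fit, so every client can
see the global sample layout (e.g. to spot batch effects) without any
foreign exact projection ever being transmitted.

### What is intentionally out of scope

Real network transport and the platform benchmarking that goes with it,
peer-to-peer topologies, vertically partitioned data, homomorphic
encryption / secure aggregation / differential privacy, and sparse
single-cell input formats. A knowledge-disclosure ranking of the algorithms
(who can reconstruct what) exists in the literature; in short, the exact
covariance-based methods disclose the most (the full covariance matrix is
reconstructable at the aggregator), the AP methods disclose rank-k′ local
subspaces, and subspace iteration discloses only the iterates — but
possibly enough of them to reconstruct the covariance over many rounds.
None of this is executable code here.

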