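# embclust

Unsupervised behavioural annotation of animal movement trajectories by
**expectation-maximization binary clustering**: a constrained Gaussian
mixture model whose clusters are forced to correspond to low/high (L/H)
combinations of the input variables, so the output states are readable by
construction. For the canonical velocity/turn pair the four clusters carry
direct behavioural semantics:

| code | velocity | turn | usual reading |
|------|----------|------|----------------|
| LL   | low      | low  | resting        |
| LH   | low      | high | intensive search |
| HL   | high     | low  | travelling / relocation |
| HH   | high     | high | extensive search |

The package is aimed at movement ecologists working with GPS, Argos or
video tracking data who want fast, minimally supervised, reproducible state
annotation across species and tracking technologies.

## The method in brief

Given an `n x m` feature matrix (velocity in m/s and turning angle in rad
by default), the algorithm fits a mixture of `k = 2^m` Gaussians
`(mu_j, Sigma_j, pi_j)` by an EM loop with three modifications:

* **Delimiters** `r_Z` — one splitting value per variable per L/H context of
  the other variables (`m * 2^(m-1)` in all) — are recomputed every
  iteration as the point of minimum pairwise-posterior difference along the
  segment joining adjacent cluster means. They partition variable space
  into binary regions `R_j`.
* The **mean update is bounded** to each cluster's region,
  `mu_j = sum_{i in R_j} u_i w_ij x_i / sum_{i in R_j} u_i w_ij`, while
  covariances stay unbounded over all points. `w_ij` are the usual EM
  posteriors; clusters whose region empties are absorbed, so `2^m` is an
  upper bound on the number of returned states.
* **Reliability weights** `u_i in [0, 1]` (by default
  `min(1, tau_mode / tau_i)`, discounting long sampling gaps) weight each
  point's contribution; pairs of variables combine as
  `sqrt(u_r^2 + u_s^2) / sqrt(2)`.

Initialization is a deterministic maximum-entropy median partition, so the
fit has no random state. A plain (unconstrained) EM clustering baseline, a
posterior-margin label smoother, a synthetic trajectory simulator with
data-loss and jittering degradation protocols, confusion-matrix metrics,
burst segmentation and CSV/KML/GeoJSON export round out the toolkit. See
`vignettes/binary-clustering-methods.Rmd` for the full model account.

## Worked example

```r
library(embclust)

ds  <- simulate_dataset(n = 400, gamma = 0.1, scheme = "markov", seed = 7)
fit <- embc(ds$features)
fit
#> Binary clustering fit (converged) after 16 iterations
#>   active clusters: 4 of 4
#>   mean per-point log-likelihood: 0.114752
#>   label counts:
#>  LL  LH  HL  HH
#> 101 112  98  89

cluster_stats(fit)[, c("code", "pi", "frac", "mean_velocity", "mean_turn")]
#>    code        pi   frac mean_velocity mean_turn
#> LL   LL 0.2495792 0.2525     0.2305384 0.2396458
#> LH   LH 0.2832382 0.2800     0.2298629 0.7491409
#> HL   HL 0.2444202 0.2450     0.7420854 0.2462788
#> HH   HH 0.2227623 0.2225     0.7561500 0.7755559

f_measure(ds$codes[ds$states], fit$labels, levels = ds$codes)
#> [1] 0.9601702
```

The generating modes sit at 0.25/0.75 per axis: the fitted means land on
them, the mixing proportions track the uniform stationary distribution of
the state chain, and 96% of the points are labelled with their generating
state (the Bayes-optimal ceiling at this overlap level is about 96%). The
fitted delimiters (`fit$delimiters`) all land near 0.5, the true boundary.

On a real track the entry point is the same:

```r
tr   <- read_trajectory_csv("track.csv")        # Movebank-style columns
fit  <- embc(compute_velocity_turn(tr))         # reliability-weighted fit
lab  <- smooth_labels(fit$labels, fit$W, delta_w = 0.1)
export_annotation(fit, tr, "track.kml", format = "kml", mode = "burst")
```

A command-line wrapper with `annotate`, `simulate`, `benchmark`,
`robustness`, `smooth` and `fixtures` subcommands is installed at
`system.file("cli", "embclust.R", package = "embclust")`.

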