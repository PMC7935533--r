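---
title: "Hub target diagnosis from paired tumor/control RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub target diagnosis from paired tumor/control RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubdiag)
```

## The model

Signaling networks are scale-free: a few proteins (hubs) concentrate most of
the interactions, and removing a hub disrupts the network far more than
removing a random vertex. `hubdiag` operationalizes a theranostic reading of
that observation. For each patient with a paired tumor and control (stroma)
RNA-seq sample it:

1. normalizes the two count profiles on a common scale;
2. computes the differential profile `d_g = tumor_g − control_g`;
3. models the non-differential bulk of `d` as Gaussian, fits its mean and SD,
   and takes the Gaussian quantile at a one-tail cumulative probability `p`
   (default 0.975) as the *critical value*: genes strictly above it are
   called up-regulated;
4. induces the protein–protein interaction subnetwork of the up-regulated
   proteins from a reference interactome and scores its complexity by the
   Shannon entropy of its degree distribution,
   `H = −Σ_k p(k) log2 p(k)` bits, where `p(k)` is the probability that a
   subnetwork vertex has `k` within-subnetwork neighbours;
5. ranks the up-regulated proteins by their *full-interactome* degree and
   reports the top n (default 20) as candidate therapeutic targets.

Two degree notions coexist deliberately. Entropy uses within-subnetwork
degrees, because it measures the complexity of the malignant subnetwork
itself; target ranking uses full-interactome degrees, because a target's
disruptive potential comes from everything it touches, up-regulated or not.

The cohort-level validation layer compares mean subnetwork entropies between
two cancer types with the Welch unequal-variance statistic

$$u_{obs} = \frac{|\bar x_1-\bar x_2|}{\sqrt{SCE_1/(n_1(n_1-1)) + SCE_2/(n_2(n_2-1))}},$$

with Welch–Satterthwaite degrees of freedom (`welch_statistic()`,
`welch_df()`, `t_quantile()`), and regresses per-cancer-type mean entropy on
5-year overall survival (`entropy_os_regression()`). A negative slope —
higher subnetwork entropy in cancers with worse survival — is the external
criterion for judging normalization choices.

## Normalization chain

Raw counts `RC_g` with coding-sequence lengths `L_g` (bp) can be transformed
by:

| transform | formula | default constants |
|---|---|---|
| `rpkm()` | `RC_g·1e9 / (RC_pc·L_g)` | — |
| `rpkm_upper()` | `RC_g·1e9 / (L_g·(RC_pc − δ·RC_pc))` | `δ = 0.05` |
| `upper_quartile()` | `RC_g·1e9 / (RC_g75·L_g)` | 75th pct of nonzero counts |
| `lognorm()` | `C·x·(log_b(log_b(x+1)) + 1)` | `C = 20`, `b = 1.1` |
| `log2norm()` | `x·log_b(x+1)` | `b = 2` |

`RC_pc` is the sum of counts over the genes present in the sample after
identifier mapping. At `δ = 0`, `rpkm_upper()` reduces exactly to `rpkm()`;
at `δ = 0.25` it rescales by the factor an upper-quartile denominator would.
The two log transforms act on already-normalized values and flatten the
power-law tail of expression magnitudes; `lognorm()` emulates the flattening
that variance-stabilized public expression matrices exhibit. The pipeline
default (`method = "chain"`) is `rpkm_upper(δ = 0.05)` followed by
`log2norm()`, the combination that maximizes the entropy–survival
correlation and keeps subnetwork sizes realistic (a few percent of the
proteome).

Numerical conventions: both log transforms define `f(0) = 0`, since the raw
expression `0·(−∞)` is indeterminate and the `x·log` factors are continuous
from the right. For `0 < x ≲ 0.09` (at `b = 1.1`) `lognorm()` is negative and
is applied as-is, without clamping — thresholding happens downstream on
differential values, so the sign of near-zero normalized values is
immaterial. The 75th percentile uses linear interpolation over *nonzero*
counts, matching the convention of the public repositories that distribute
upper-quartile-normalized data.

## The critical-value fit

`fit_null()` restricts the differential values to a window (default
−20 000…+20 000) and matches moments: the fitted mean and population (1/n)
SD are the Gaussian maximum-likelihood estimates on the in-range values.
Restricting to the window keeps a handful of extreme true signals from
inflating the null SD. `critical_value()` evaluates the Normal quantile at
`p`; if it falls outside the window the function refuses with an explicit
out-of-range error, because heavily flattened normalizations can push the
quantile past any fixed window — the user then widens `fit_range` knowingly
rather than silently thresholding at a meaningless value. `p` is accepted in
`[0.5, 1)`: values at or below the median would make "up-regulated" vacuous.
The selection is strict (`d > cv`), one-sided; down-regulation is never
called.

At least 30 in-range values are required — below that a Gaussian moment fit
is not trustworthy and the function refuses rather than degrade.

## What the synthetic generator emulates

`generate_interactome()` grows a simple connected preferential-attachment
graph: few hubs, many leaves, matching the scale-free premise. Defaults:
2 000 proteins, 2 edges per new vertex (mean degree ≈ 4, comparable to the
sparsity of curated interactomes).

`generate_patient()` draws control expression from a baseline-offset
log-normal law (`10σ + lognormal(log 5σ, 1)` with `σ` the configured noise
SD) — positive, heavy right tail — and sets
`tumor = control + N(0, σ²) + effect·σ·1[injected]`. Subtracting the pair
cancels the control magnitudes exactly, so the differential null is Gaussian
*by construction*: the fixture realizes the model the critical-value fit
assumes, which is what makes threshold calibration testable. The baseline
offset keeps all values positive (the noise would need a 10σ excursion to
cross zero), so written fixtures satisfy the non-negative file contract.
Defaults: `σ = 1000` (so the default ±20 000 window spans ±20σ), 100
injected genes among 2 000, effect 10σ (well-separated recovery), hub bias 1
(injection probability proportional to degree).

`generate_cohort()` builds 6 cancer types whose injected complexity grows
linearly (50→200 injected genes at the defaults) while 5-year overall
survival decreases linearly from 85% to 25% when `os_coupling = 1`; at
`os_coupling = 0` the survival values are shuffled, breaking the link.
More injected hubs produce larger, more degree-diverse subnetworks, hence
higher entropy — so the pipeline should recover a strongly negative
entropy–survival correlation on coupled cohorts, and none on decoupled ones.

What the generator does **not** emulate: read-level sampling noise,
library-size variation, batch effects, GC bias, correlated co-regulation of
neighbouring genes, or the multiplicative (rather than additive) structure
of real RNA-seq noise. Passing the synthetic end-to-end tests therefore
shows that the machinery is self-consistent and correctly calibrated under
its own model, not that the model is an adequate description of any real
cohort.

## Design choices where the design was open

- **Duplicate ids and many-to-one mapping** aggregate by *sum*: transcripts
  of one protein pool their signal. Averaging would understate multi-mapped
  proteins; taking one value would be order-dependent.
- **Self-interactions** are excluded from edges and degrees; hub ranking is
  about connections to other proteins.
- **Isolated up-regulated proteins** (no up-regulated interaction partner)
  are not part of the subnetwork: its vertex counts and entropy describe
  proteins that actually interact within the malignant signature.
- **BLASTx counting** assigns each read to its single best bit-score hit,
  first-seen on ties — deterministic and the simplest defensible rule when
  no counting scheme is prescribed.
- **Ties in hub ranking** break by accession ascending, making reports
  byte-reproducible.
- **Recurrence threshold** is inclusive (≥ 70% of patients by default).
- **Report storage** is a flat JSON document per patient (plus a cohort
  summary TSV) rather than a database, so runs compose inside any workflow
  engine.

## Problem sizes and limitations

The test suite and the acceptance script run on synthetic problems sized for
tight statistical bands at desk scale: 10⁵ null genes for the type-I check,
10⁴ for moment recovery, 2 000-protein interactomes with 8 patients × 6
cancer types for the end-to-end cohort — large enough that the stochastic
checks (selection fraction 2.5% ± 0.5%, SD recovery within 5%, correlation
sign) are stable across seeds, small enough to complete in seconds.

Known limitations: the Gaussian null is a modeling choice, not a theorem —
heavy-tailed differential noise inflates the fitted SD and makes the
threshold conservative; entropy compares cohorts only through a scalar and
ignores which hubs drive it; and the Welch layer treats per-patient
entropies as independent observations, which paired designs with shared
controls may violate.
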