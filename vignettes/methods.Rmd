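---
title: "Directed-information network inference: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed-information network inference: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtinet)
```

This vignette is the package's own account of its science: the quantities
it computes, the assumptions they rest on, the numerical conventions, and
the places where the design was genuinely open and a choice had to be
made. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Directed information on pooled time-course samples

For two processes $X$ and $Y$ observed on a shared equidistant grid of
length $N$, directed information is

$$ I(X^N \to Y^N) \;=\; \sum_{n=2}^{N} I(X^n;\, Y_n \mid Y^{n-1})
   \;=\; \sum_{n=2}^{N}\bigl[\, I(X^n; Y^n) - I(X^n; 0Y^{n-1}) \,\bigr], $$

where $0Y^{n-1}$ is the target series shifted one step into the past.
Conditioning on the target's own history removes the symmetric part of
the dependence; what survives is the flow from the regulator into the
target's future.

**Sample pooling.** Expression grids of length four cannot support
sequence-level density estimation, so every MI term is estimated from
scalar pairs pooled across replicate experiments *and* time:
the simultaneous term at step $n$ pools $(x_{e,t}, y_{e,t})$ and the
lagged term pools $(x_{e,t}, y_{e,t-1})$. This reads the shifted
concatenation literally as the pair sequence
$(X^2,Y^1), (X^3,Y^2), \dots$ — the only reading the sample sizes allow.

**Matched sampling (default `match_samples = TRUE`).** The simultaneous
term is restricted to $t = 2..n$, so both MI terms in each difference see
the same $X$ sample and the same number of pairs. Two reasons, both
verified in the test suite:

* With matched samples the plug-in identity
  $I(\text{now}) - I(\text{lag}) = H(X \mid Y_\text{lag}) - H(X \mid
  Y_\text{now})$ holds *exactly* (to $10^{-12}$) for the histogram
  estimator — the entropy-difference chain that justifies the pairwise
  reformulation in the first place. Unmatched, the $H(X)$ terms refer to
  different samples and the identity only holds asymptotically.
* Plug-in MI has a positive small-sample bias that grows as the sample
  shrinks. Unmatched, the lag term (always one time point short) carries
  more bias than the simultaneous term, shifting every DTI downward by an
  amount unrelated to coupling. On the packaged benchmark this costs more
  than half of the achievable ranking quality (area under the
  precision–recall curve).

The literal variant remains available (`match_samples = FALSE`), as does
the zero-padded lag pair (`include_zero_pad = TRUE`), which completes the
shifted sequence with the formal pair $(x_{e,1}, 0)$; by default only
genuine shifted pairs are used, since the padding symbol is an artifact
of notation, not an observation. DTI values are returned raw — possibly
negative under estimation noise — because the CLR stage centers them
against their empirical background anyway; clamping here would only
distort the nulls.

## 2. Mutual-information estimators

Both continuous estimators return nats.

**B-spline fractional binning** (`mi_bspline`, the default; `bins` M = 10,
`order` k = 3). Each variable is min–max scaled onto the knot domain and
every sample receives fractional weights over the M bins through the
order-k B-spline basis (a partition of unity; the basis weights come from
`splines::splineDesign`). Weighted marginal and joint histograms plug
into $H(X) + H(Y) - H(X,Y)$. Because the joint table has exactly the
weighted marginals as margins, the estimate is a true KL divergence and
therefore nonnegative; it is also invariant under affine transforms of
either variable. A zero-range variable yields MI = 0 by definition —
constant genes occur in real matrices and should carry no information
rather than raise an error.

*Known bias.* Fractional binning smooths: with M = 10 and k = 3 the
effective resolution is $M - k + 1 = 8$ intervals spanning the full
sample range (about $6.6\sigma$ at $n = 2000$ for a Gaussian), and each
basis function spreads a sample over three of them. For strongly
dependent pairs this floor truncates MI: at Gaussian correlation 0.8 the
estimator plateaus near 0.30 nats against a true 0.51, a deficit that
does **not** shrink with sample size (it is resolution, not noise). At
modest dependence ($\rho \le 0.5$) the estimate is within a few
hundredths of the closed form, and near independence the error is pure
estimation noise and decays with $n$. For ranking purposes — the only use
the pipeline makes of MI — the monotone compression is harmless; for
absolute MI at strong dependence, use the kernel estimator.

**Gaussian kernel density** (`mi_kernel`). Product-kernel estimates of
the joint and marginals with per-variable Silverman bandwidths
($1.06\,\hat\sigma n^{-1/5}$, or a user-supplied number), evaluated at
the sample points (leave-self-in), MI as the sample mean of
$\log \hat f(x,y) / (\hat f(x)\hat f(y))$. Slightly positively biased
near independence (~0.03 nats at $n = 2000$) but essentially unbiased at
strong dependence; it is the accuracy reference, the B-spline estimator
the speed default. Values are not clamped and can be mildly negative.

**Histogram plug-in** (`mi_histogram_plugin`). Exact plug-in MI from the
joint frequency table of discrete symbols; used as the brute-force
reference in the directed-information identity tests.

## 3. CLR background correction

The null hypothesis for a pair is "no interaction"; its score
distribution is estimated empirically from the matrix itself, on the
assumption that most pairs do not interact. Each entry is z-scored
against its regulator's row and its target's column — computed **within
the TF × gene matrix only**, not the full gene × gene matrix — with the
sample standard deviation, each component clamped at zero (only positive
deviations from background indicate interaction; a two-sided rule would
reward *unusually low* dependence), and combined as the quadratic mean
$\sqrt{(z_r^2 + z_c^2)/2}$. Taking the mean rather than the sum of
squares differs from the classic CLR statistic by a constant
$\sqrt{2}$, which any precision-calibrated threshold absorbs. Rows or
columns with fewer than two valid entries or zero spread contribute a
component of zero; excluded entries (self-pairs) take no part in any
null. The construction is invariant to location and scale of the score
matrix, so the estimator's units never matter downstream.

## 4. Thresholding and precision

Precision is judged only where the reference network can judge it: the
*reduced graph* keeps edge $(r,t)$ iff $r$ has at least one known target
and $t$ at least one known regulator. `threshold_at_precision` scans the
observed z values (not a continuous grid — between observed values the
edge set does not change) from the top down and returns the **smallest**
threshold whose reduced-graph precision reaches the target, i.e. the
largest network satisfying the constraint; the returned edge set is the
full one at that threshold, known/unknown annotated. Fixed-count
selection breaks boundary ties by (regulator, target) lexicographic
order so results are deterministic. Degenerate cases error loudly:
empty reduced graph (precision undefined) and unreachable targets.

## 5. Sequence-level validation

The validation step asks whether the target's promoter contains a region
resembling the regulator's known binding sites, and whether that region
is phylogenetically conserved. The package implements this as a PWM
log-odds scan seeded from the known sites — a deliberate approximation
of constrained motif discovery: probabilities
$(\text{count} + 0.5) / (n + 2)$ per position, uniform 0.25 background
unless supplied, both strands scored at every offset (the minus strand
scores the reverse complement), coordinates window-local, 0-based,
half-open.

**Acceptance threshold.** The default floor is the *leave-one-out*
minimum of the training sites' own scores: each site is scored under the
PWM rebuilt from the remaining sites. Scoring a site under a model that
contains its own counts inflates the score (each of its bases carries its
own pseudo-evidence), so the resubstitution minimum is systematically
unreachable for an unseen genuine site; the leave-one-out floor is
unbiased for fresh sites while still guaranteeing — provably, from the
count arithmetic — that every known site passes the full PWM.
`pwm_site_threshold(method = "resubstitution")` restores the naive rule.

**Conservation rule.** The best hit is intersected with the union of
conserved intervals on the same window; the edge is accepted iff strictly
more than 50% of the site is covered. Equality rejects — the rule is
"overlaps to more than 50%", and the strictness is pinned by a test.
Splitting a conserved interval into adjacent pieces cannot change the
outcome (union arithmetic, via IRanges).

**Operon expansion.** A site validated in front of an operon's
promoter-proximal gene supports regulation of the whole transcript:
accepted edges whose target *leads* an operon are propagated to the
downstream members, flagged `operon_derived`. Mid-operon targets do not
expand — their promoters were not the validated ones.

## 6. The synthetic benchmark

`simulate_topology` draws TF → gene edges uniformly without replacement
(no self-edges), signed weights uniform in $[0.5, 1.5]$.
`simulate_timecourses` advances each experiment as

$$ x_{t+1,g} = \phi\, x_{t,g} + f\!\Bigl(\sum_r W_{rg}\, x_{t,r}\Bigr)
   + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2), $$

with $f = \tanh$ by default (saturating regulation; a linear mode exists
for analytic sanity checks), $\sigma = 0.3$, 19 experiments × 4 points on
a 30-minute grid, standard-normal initial states. The persistence term
$\phi = 0.8$ is essential, not cosmetic: transcript levels sampled every
30 minutes are strongly serially correlated (decay over hours), and it is
precisely this autocorrelation that lets simultaneous pairs carry
regulatory signal while the lag subtraction sorts out direction. With
$\phi = 0$ the regulator series would be white noise and *no* pairwise
measure — MI or DTI — could recover the network from pooled pairs; the
generator would then contradict the purpose of the module it feeds.

`synthesize_promoters` gives every gene a 400-bp i.i.d. uniform
background window; planted genes receive a consensus copy mutated at 0.1
per base at a random offset, conserved entirely with probability
`conserve_fraction` (otherwise the gene's conserved interval is placed
away from the site); unplanted genes get a random conserved window. Ten
independently mutated copies serve as the known sites. The default
16-bp consensus has maximal per-position information content before
mutation, comparable to strong bacterial repressor sites.

**What the generator does *not* emulate**, and hence what passing tests
do not show about real data: microarray noise is neither Gaussian nor
homoscedastic; real regulation has combinatorial logic, autoregulation
and feedback loops (the topology here is a random bipartite DAG); real
binding sites differ per TF while the benchmark uses one consensus; real
conserved intervals come from cross-species alignments with their own
biases; and real reference databases are biased toward well-studied
regulators, not uniformly incomplete as `make_reference` assumes.
Recovery numbers on the benchmark are an internal consistency check of
the pipeline, not a forecast of performance on a compendium.

## 7. Problem sizes and reproducibility

The shipped tests and the acceptance script use: $n = 2000$ samples × 20
seeds for the Gaussian-MI checks; 8 experiments × 4 points × 50 instances
for the brute-force DTI equivalence; 200 replicates at 19 × 4 for
directionality; 50 × 200 matrices × 10 seeds for CLR null calibration;
100 random 5 × 10 matrices for the threshold sweep; 100 promoters (30
planted) for motif recovery; and 10 seeds of the 20 TF / 200 gene / 150
edge benchmark end to end. These sizes make every property estimate
stable at the tolerance it is tested to while keeping a full run in the
low minutes. All randomness flows from explicit integer seeds; pipeline
reruns under a fixed seed are byte-identical, which the suite asserts
file by file.

## 8. Known limitations

* The B-spline estimator's resolution floor (Section 2) makes its
  absolute MI values untrustworthy above ~0.3 nats at the default
  configuration; rankings are unaffected.
* DTI here is first-order: one-step memory, no conditioning on third
  genes, so indirect chains can still produce edges; the CLR background
  and the sequence filter are the only guards against them.
* The interpolation rescue in `select_equidistant` only handles a
  missing *final* grid point (the case that arises with trailing
  longer-horizon samples); experiments missing interior points are
  dropped.
* Promoter coordinates are window-local; mapping conserved intervals
  from genome coordinates into promoter windows is the caller's job.
* `validate_edges` applies one site set per regulator (or one shared
  set); it does not model TFs with multiple binding modes.
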