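---
title: "Testing neutral community assembly with untbx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing neutral community assembly with untbx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(untbx)
```

## The question

A recurring question in community ecology — and lately in virome and
microbiome studies — is how much of the structure of an OTU table is
explained by *neutral* dynamics: stochastic birth, death, immigration and
speciation acting identically on every taxon, as opposed to deterministic
forces such as selection or competition. untbx implements five complementary
ways of asking this question of a plain OTU count table (taxa in rows,
samples in columns), together with urn-scheme simulators that generate
neutral and non-neutral tables with known ground truth, so every analysis
here can be validated end to end without external data.

The five analyses, and the level each one addresses:

1. **Hubbell standard neutral model (HNM)** — per sample: fit the
   fundamental biodiversity number $\theta$ and migration probability $m$
   by maximum likelihood and test neutrality exactly (`fit_hnm()`,
   `hnm_neutrality_test()`).
2. **Multi-site neutral model (MSN)** — per treatment: all samples share
   one metacommunity but may have different immigration numbers $I_i$;
   fitted as a hierarchical Dirichlet process by Gibbs sampling
   (`fit_msn()`, `msn_neutrality_test()`).
3. **Sloan near-neutral model** — per species: which taxa sit inside the
   95% interval expected under drift plus migration, and which are above
   (positively selected) or below it (`fit_sloan()`, `classify_species()`).
4. **Stochasticity ratio (SR / NSR)** — per treatment: how close observed
   pairwise community similarity is to a null-model expectation (`nsr()`).
5. **Power analysis of the neutrality test (PNT)** — per sample: could the
   test even have detected a non-neutral process of a given kind and
   strength (`run_power_analysis()`, `detect_non_neutral()`)?

`run_pipeline()` chains all five over a multi-treatment collection.

## The sampling-formula likelihood

The core quantity is the probability of an observed species-abundance
configuration $D = (n_1, \dots, n_S)$, $J = \sum n_i$, in a local community
assembled by the neutral urn: individual $n+1$ is an immigrant with
probability $I/(I+n)$, where $I = m(J-1)/(1-m)$ is the immigration number,
and immigrant lineages pick species according to a Chinese restaurant
process at rate $\theta$; otherwise it copies a uniformly chosen prior
individual. Integrating out the latent ancestry gives the Etienne sampling
formula

$$
P(D \mid \theta, I) \;=\; \frac{J!}{\prod_i n_i \prod_j \Phi_j!}\,
\frac{\theta^S}{(I)_J} \sum_{A=S}^{J} K(D, A)\, \frac{I^A}{(\theta)_A},
$$

where $\Phi_j$ counts species of abundance $j$, $(x)_n$ is the rising
factorial, and the coefficients $K(D,A)$ collect, over all ways of
assigning $a_i$ ancestors to species $i$ with $\sum a_i = A$, the products
$\bar s(n_i, a_i)(a_i-1)!/(n_i-1)!$ of unsigned Stirling numbers of the
first kind. `neutral_loglik()` computes this entirely in log space: Stirling
rows by the log-space recurrence, $K(D,\cdot)$ as a log-space convolution of
per-species coefficient vectors, and the final sum by log-sum-exp, so no
linear-space overflow is possible at any $(\theta, I)$. The test suite pins
the implementation against an independent brute-force oracle that
enumerates every ancestry (set partitions of individuals into lineages and
lineages into species) for all configurations with $J \le 8$, and against
the closed-form Ewens sampling formula in the $I \to \infty$ limit.

### Fitting, and the likelihood ridge

`fit_hnm()` maximizes the likelihood over $(\log\theta, \mathrm{logit}\, m)$
with a bounded quasi-Newton optimizer ($\theta \in [10^{-3}, 10^5]$,
$m \in [10^{-6}, 1-10^{-6}]$), started at the Ewens estimate of $\theta$
(the root of $\sum_{i<J} \theta/(\theta+i) = S$) and $m = 0.5$ — the
convention of established neutral-theory fitting software. The start
matters: the sampling-formula surface is ridged in $\theta$ versus $m$ and
usually carries a second local optimum at high $\theta$ and very small $m$
whose likelihood is within about one log-unit of the first. In parameter
recovery experiments at $\theta = 20$, $m = 0.3$, $J = 2000$ an exhaustive
multi-start search picks that alternative mode in roughly half the
replicates; the Ewens-anchored fit recovers $\theta$ reliably (median 19.8
over 20 replicates). A coarse global grid remains available through the
`starts` argument for users who want both optima. Note also that when true
immigration is high the likelihood is nearly flat in $m$ above the true
value — with $I \approx 857$ at $m = 0.3$, $J = 2000$, single-sample
estimates of $m$ spread over $[0.05, 1]$ with several at the upper bound —
so per-sample $\hat m$ should be read as order-of-magnitude only. Degenerate
inputs (one species, or all singletons where $\hat\theta$ diverges) return
boundary fits with a warning, $\theta$ capped at $10^5$.

### The pseudo-P neutrality test

`hnm_neutrality_test()` is a parametric bootstrap: simulate `n_sim` SADs of
the same $J$ from the fitted model using the exact nested urn (no
metacommunity truncation — this is precisely the distribution the
likelihood describes), refit each, and report

$$\text{pseudo-}P = \frac{1 + \#\{\text{simulated} \le \text{observed}\}}{1 + n\_\text{sim}},$$

with ties counted toward the numerator, so $P \in (0, 1]$ and neutrality is
*not* rejected when $P > \alpha$. Refitting each replicate (the default)
makes the statistic a genuine bootstrap of the maximized log-likelihood;
`refit = FALSE` compares at the fixed observed $(\hat\theta, \hat I)$,
which is faster but only approximately calibrated. Under the default, 200
truly neutral communities ($\theta = 20$, $m = 0.3$, $J = 500$) tested with
200 replicates each are rejected at $\alpha = 0.05$ in 3–6% of cases across
seeds — the nominal rate within binomial error (this is the first
acceptance check). Because the neutrality convention puts "passing" at *large* P, FDR
correction would only make passing easier; instead of correcting,
`passing_rate_curve()` sweeps the P-threshold so the reader can see how the
passing rate decays as the bar is raised. Samples beyond 30,000 reads are
subsampled to 30,000 before testing (flagged in the result) to keep the
$O(J^2)$ coefficient recursion affordable; no rarefaction is performed
anywhere else.

## The multi-site model

With several samples per treatment the package fits the hierarchical
Dirichlet process formulation: the metacommunity profile
$\bar\beta \sim \mathrm{Stick}(\theta)$ and each site's composition
$\bar\pi_i \mid I_i, \bar\beta \sim \mathrm{DP}(I_i, \bar\beta)$, with
$I_i = \frac{m_i}{1-m_i}(N_i - 1)$. The Gibbs sampler works in the Chinese
restaurant franchise representation. Conditional on the current
$(\bar\beta, I_i)$, the number of ancestral lineages ("tables") behind
$n$ individuals of species $k$ at site $i$ is a sum of independent
Bernoulli$\big(c/(c+j)\big)$ draws, $j = 0..n-1$, $c = I_i \beta_k$ — the
exact Antoniak conditional without any Stirling-number tables. Given table
counts: $\bar\beta$ is Dirichlet; $\theta$ is updated by the standard
auxiliary-variable (beta–gamma mixture) step under a vague Gamma(1, 0.1)
prior, using the total table count and the observed species count — the
richness conditional here is the Antoniak distribution
$P(S \mid \theta, N) = \bar s(N,S)\,\theta^S \Gamma(\theta)/\Gamma(\theta+N)$
exposed as `antoniak_pmf()`; each $I_i$ is slice-sampled on $\log I$ under
a log-uniform prior on $[10^{-2}, 10^6]$. Defaults are 5000 iterations with
half discarded; a split-chain $\hat R > 1.2$ on $\log\theta$ warns but
never errors.

The neutrality tests simulate whole datasets from the posterior means
(stick-breaking profile truncated at $S_{obs} + 200$ classes, then per-site
Dirichlet-multinomial draws). The joint test statistic is the **sum over
sites of the Etienne log-likelihood at the posterior-mean
$(\hat\theta, \hat I_i)$**. This choice needs a note: a statistic built on
labelled per-species likelihoods against the fitted $\hat\beta$ cannot be
evaluated on simulated datasets (whose species are new labels), and for
exactly-even observed counts it would point the *wrong way* — even counts
maximize a labelled multinomial-type likelihood, so a one-sided test that
rejects low likelihoods would never fire on the most suspicious fixture.
The label-free partition likelihood has the conventional direction: a
perfectly even, perfectly replicated set of sites is strongly rejected
($P_M \le 0.05$), while data simulated from the fitted model pass. $P_M$
compares joint statistics with the same smoothed one-sided convention as
the single-sample test; $P_{L,i}$ does the same per site.

## The Sloan near-neutral model

For large communities the discrete model is replaced by its diffusion
limit. With a source ("mainland") community supplying immigrants at rate
$m$ into a saturated local community of $N_T$ individuals, the per-step
transition probabilities for a focal OTU at abundance $N_i$ with source
frequency $p_i$ are implemented in `sloan_transition_probs()` (they sum to
one identically; the suite checks a dense grid), and the stationary local
frequency is $\mathrm{Beta}\big(N_T m\, p_i,\; N_T m (1 - p_i)\big)$.
`fit_sloan()` estimates the single parameter $m$ by least squares between
observed occurrence frequencies (fraction of destination samples where the
OTU exceeds the detection threshold $d$, default $1/N_T$) and the beta's
upper-tail mass beyond $d$; $N_T$ defaults to the rounded mean destination
sample total, and $R^2$ may legitimately come out negative on poor fits —
it is flagged, never raised. `classify_species()` then labels each OTU by
where its mean local frequency falls relative to the central 95% beta
interval; by construction the neutral fraction under self-generated data is
the interval's coverage, and the suite checks it lands at 95% within
binomial error for 300 species. An occurrence-frequency-interval mode
(`on = "occurrence"`) is also provided. Both pairing schemes are plain
arguments: distinct source/destination matrices, or the same matrix twice
(the "same-set" scheme, which raises the neutral fraction since source and
destination then agree by construction).

## Stochasticity ratio and its normalization

Pairwise community similarity uses the Ružička index
$C_{ij} = \sum_k \min(p_{ki}, p_{kj}) / \sum_k \max(p_{ki}, p_{kj})$ on
relative abundances (the abundance-weighted Jaccard; computed internally
from Manhattan distances since columns sum to one). A null model generates
randomized metacommunities; the default `proportional_frequency` algorithm
preserves each sample's richness, draws that many species with probability
proportional to regional occupancy, and assigns them relative abundances
proportional to the regional means, renormalized. A `richness_uniform`
variant (species drawn uniformly from the pool, observed abundance values
retained) and an `identity` null (for tests) are included; the algorithm id
is recorded in the result. With $\bar E_{ij}$ the mean null similarity over
`n_null` draws (default 1000; tests use 100–500), pairs split into type A
($C > \bar E$: determinism toward similarity, ratio $\bar E_{ij}/C_{ij}$)
and type B ($C < \bar E$, ratio $(1-\bar E_{ij})/(1-C_{ij})$); SR is their
average. Exact ties are excluded from both counts — with continuous
abundances they have measure zero, and if *every* pair ties SR is defined
as 1 with a warning. SR is 100% when observation matches the null and 0%
for fully deterministic assembly; both limits are exercised by the
acceptance checks (mean SR ≈ 97% on self-generated null data; SR ≈ 0.1%
for twenty identical single-species communities against a 1000-species
uniform null).

The normalized ratio rescales SR so those anchors are exact: each type-A
pair's observed similarity is replaced by its extreme attainable value 1
(type-B by 0) to get $SR_{\min}$, the null-coincident extreme gives
$SR_{\max} = 1$, and $NSR = (SR - SR_{\min})/(1 - SR_{\min})$, clipped to
$[0,1]$. This min–max construction realizes the stated 0%/100% anchors but
is the one place this package's numbers may differ from other NSR
implementations, whose exact normalization varies.

## Power analysis and the detection rules

Two non-neutral local generators share the neutral urn's code path so that
a zero effect is *bit-identical* to the neutral model under the same seed:

* **IF (intrinsic fitness):** each species carries a fecundity
  $f_k \sim \mathrm{Gamma}$ with mean 1 and coefficient of variation equal
  to the effect size, drawn once per dataset; immigration weights become
  $\beta_k f_k$ (renormalized) and local reproduction weights $N_k f_k$.
* **PC (density dependence):** local reproduction weights become
  $N_k^{1-\varepsilon}$, a rare-species advantage with effect
  $\varepsilon \in [0,1]$.

These urn formulations are deliberately simple, one-parameter stand-ins for
the non-neutral dynamics families they emulate; time-stepped birth–death
versions are out of scope for speed and exact size conservation.

`run_power_analysis()` matches the generator to a fitted sample (same $J$,
$\hat m$, $\hat\theta$) and reports the fraction of non-neutral datasets
rejected at $\alpha$. By default each dataset gets a **fresh stick-breaking
metacommunity at $\hat\theta$**, so at effect 0 the generator coincides
with the fitted model and measured power equals the type-I error (measured
0.05 over 100 datasets — the calibration anchor). A fixed Fisher log-series
pool (`meta_model = "log_series"`, shape $x = J/(J+\hat\theta)$) is
available, but note that a pool held fixed across datasets is *not* the
model the test integrates over, and its effect-0 pseudo-P values skew high.

The two generators behave very differently under the one-sided likelihood
convention. PC pushes communities toward evenness, which the sampling
formula finds improbable, and power rises steeply (≈0.97 at
$\varepsilon = 0.8$, $J = 1000$). IF dominance, by contrast, is almost
entirely absorbed by refitting $(\theta, m)$, and the residual shape change
*raises* the maximized likelihood — so the one-sided test, which rejects
only unusually low likelihoods, essentially never fires on IF data at
these community sizes: measured power is 0 at cv ∈ {1, 2, 4} while the mean
pseudo-P climbs from 0.44 to 0.91. This is a real property of the test, not
a defect of the generator (both fecundity-weighted and unweighted
immigration variants behave identically), and it is why the complementary
detection rules exist: `detect_non_neutral()` flags a sample when its
observed pseudo-P falls strictly *below* the mean pseudo-P of the matched
non-neutral simulations, and `classify_false_negative()` flags the cases
that additionally still pass the neutrality test
($\alpha < P < \overline{P}$). Ties resolve conservatively toward the
neutral conclusion. `summarize_pnt()` aggregates the flags into the
treatment-level percentages.

## The synthetic-data generator

`simulate_metacommunity()`, the local simulators and
`simulate_treatment()` emulate the study conditions of a multi-treatment
virome survey: per-treatment tables of 5–66 samples, per-sample totals
$10^2$–$10^5$, richness tens to hundreds, assembled neutrally
($\theta \approx 5$–$80$, $m \approx 0.3$–$1$, stick-breaking pools
truncated at `s_max` classes and renormalized — at $\theta = 20$,
$s_\max = 500$ the discarded mass is $\sim 10^{-11}$) or by the IF/PC
dynamics. Deliberately *not* emulated: sequencing noise and uneven library
sizes within a treatment (every site gets exactly $J$ reads), taxonomy,
compositional artifacts, and temporal autocorrelation. Passing tests on
these fixtures therefore demonstrates correctness of the statistical
machinery under the stated models, not robustness to the full messiness of
real virome data. Every generator takes an explicit seed and is
byte-reproducible; multi-site treatments consume one seeded stream
sequentially, and IF fecundities are drawn once per treatment so sites
share the same fitness landscape.

## Numerical choices and problem sizes

* All sampling-formula and Stirling arithmetic is in log space; the
  K-coefficient convolution costs $O(J^2)$ per SAD, and Stirling rows are
  cached up to $n = 4096$ (larger rows are rolled on demand).
* Optimization bounds $\theta \in [10^{-3}, 10^5]$,
  $m \in [10^{-6}, 1-10^{-6}]$; boundary fits flagged. Replicate refits in
  the bootstrap warm-start at the observed optimum.
* The default test sizes used throughout the suite and the acceptance
  script — 200 communities × 200 replicates for calibration, $J$ of
  500–2000, 20-replicate recovery runs, 100–500 null draws — were chosen as
  the smallest sizes at which the binomial/recovery bounds are meaningful;
  production analyses can raise `n_sim`, `n_null` and the Gibbs lengths
  freely.
* `run_pipeline()` derives every stage seed deterministically from one
  master seed and records it in the report, so reruns are byte-identical.

## Known limitations

* Per-sample $\hat m$ is weakly identified when true immigration is high
  (see the ridge discussion above); treat it as qualitative.
* The IF family is effectively undetectable by the one-sided pseudo-P test
  at desk-scale $J$; use the detection-rule comparison, not raw power, to
  reason about intrinsic-fitness alternatives.
* The NSR normalization is one defensible choice among several in use.
* No rarefaction or library-size correction is applied; the read filter
  (`filter_min_reads()`, default 100) is the only sample-level QC, and
  reports say so.
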