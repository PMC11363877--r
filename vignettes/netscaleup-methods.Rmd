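---
title: "Methods: scale-up estimation of hidden population sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scale-up estimation of hidden population sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netscaleup)
```

## The model

The network scale-up method (NSUM) estimates the size of a hidden population
(here: people who inject drugs) from how often its members appear in the
personal social networks of ordinary survey respondents. Two proportionality
relations carry the whole pipeline:

* **Known-population network sizing.** If a respondent's network of size $c$
  is an exchangeable sample of the region (population $t$), the number of
  their alters falling in a collection of subpopulations of known total size
  $e_0$ has mean $c\,e_0/t$. Averaging the reported counts ($m_0$) and
  inverting gives $\hat c = m_0\,t/e_0$. The known subpopulations are name
  groups (people carrying one of 48 last names), each chosen to cover
  0.1–0.2% of the region — small enough to recall accurately, large enough to
  appear in most networks. Sizes outside that band are flagged and warned
  about, not rejected: the band is a recall-bias guideline, not a validity
  condition.

* **Basic scale-up.** The mean number of *hidden-population* alters per
  respondent, $m_1$, satisfies $e_1/t = m_1/c$, so
  $\hat e_1 = (m_1/\hat c)\,t$.

Two mechanisms make $\hat e_1$ an underestimate, both multiplicative at the
tie level:

* **Barrier effect.** Hidden-population members have smaller networks, so
  they are under-represented among alters. Quantified by the *popularity
  ratio* $\delta = c_H/c$, where $c_H$ is the hidden population's mean
  network size.
* **Transmission error.** An alter may not know the person belongs to the
  hidden population. Quantified by the *information transmission rate*
  $\tau$, the fraction of a member's network aware of their membership.

Both are estimated from a respondent-driven sampling (RDS) survey of the
hidden population itself: respondents report name-group alter counts (giving
$\hat c_H$ by the same known-population formula) and how many of those alters
are aware of their membership (giving the aware network size, hence
$\hat\tau$ as the ratio). The adjusted estimate is
$\hat e_1/(\hat\delta\hat\tau)$, and prevalence divides by the 15–64
population.

Because the count of *visible* hidden alters is thinned by $\delta$ and
$\tau$ jointly at the tie level, $E[\hat e_1] \approx N_H\,\delta\tau$ and
the division undoes the bias exactly in expectation. The synthetic generator
(below) implements precisely this thinning, which is what makes end-to-end
parameter recovery a sharp test of the chain rather than a tautology.

## Randomized response unmasking

The hidden-alter question is sensitive, so it is asked through the
two-group unrelated-question randomized response technique (RRT): group $g$
receives the sensitive question with probability $p_g$ (0.8 and 0.2 here)
and an innocuous one (weekly hours online) otherwise; nobody but the
respondent knows which. With group means $\mu_1,\mu_2$,

$$\mu_S = \frac{(1-p_2)\,\mu_1 - (1-p_1)\,\mu_2}{p_1 - p_2},$$

with variance by the delta rule on the independent group means,
$[(1-p_2)^2\mathrm{var}(\hat\mu_1) + (1-p_1)^2\mathrm{var}(\hat\mu_2)]/(p_1-p_2)^2$.
Two design notes:

* The source text's prose defines $p_2$ as the *unrelated*-question share of
  group 2 (0.8), which would zero the denominator. We parameterize both
  $p_1, p_2$ as the sensitive-question probability of their group
  (0.8 / 0.2), the standard convention under which the displayed formula is
  algebraically exact. `unmask_mean()` is exactly linear in the group means
  and invariant to swapping groups together with $(p_1,p_2)$; both
  properties are tested.
* $\hat\mu_S$ can be negative at finite samples. We report the raw value
  with a zero-floored convenience field, never truncating silently — the
  raw value is what the bootstrap must resample to propagate noise honestly.

## Bootstrap uncertainty

All intervals are percentile bootstrap (the simplest defensible default
given that the CI construction in the reference analysis is unstated; BCa is
future work), with `B = 10000` and level 0.95 by default. Three flavors:

* **General survey:** respondents resampled with replacement, or whole
  clusters (department/unit/industry) when requested — the cluster labels
  stand in for the stratified two-stage design the field survey used.
* **RDS survey:** a recruitment-chain bootstrap that regrows the observed
  forest — seed chains drawn with replacement, each node's observed recruits
  resampled with replacement recursively, each chain truncated at the
  observed maximum wave — until the observed sample size is reached, then
  truncated to exactly that size. Drawing chains until the observed size
  (rather than drawing exactly the observed number of seeds) keeps every
  resample at the observed size even when an observed seed recruited nobody;
  with two seeds, one of them dead, a fixed-seed-count resample would be a
  degenerate two-row sample a quarter of the time. Chosen because it
  respects the dependence structure chain referral induces; a plain
  respondent bootstrap is available behind
  `bootstrap_spec(rds_flavor = "respondent")`.
* **Joint:** both surveys resampled independently per replicate and the
  *entire* chain recomputed — including RRT unmasking — so RRT noise and RDS
  dependence propagate into every downstream interval.

One master seed spawns one substream per resample, so results are
reproducible and independent of execution order. Degenerate inputs behave
predictably: a constant dataset yields a zero-width interval; a statistic
failing on more than 1% of resamples aborts with a diagnostic rather than
returning a quietly contaminated interval.

## The synthetic world

`synthetic_truth()` defaults restate the study's published world: the
Taiyuan frame ($t = 4{,}531{,}429$, $e_0 = 302{,}251$ over 48 name groups,
adult population $2{,}820{,}541$), $N_H = 1242$, $c = 123.9$,
$\delta = 0.536$, $\tau = 0.879$, unrelated-answer mean 20, blank-sheet rate
6.3%, and an RDS design of 2 seeds, 3 coupons, 8 waves, $n = 302$. Choices
the source leaves open, fixed once here:

* **Degree dispersion.** Only mean network sizes are published. Real degree
  distributions are overdispersed, so degrees are negative binomial with
  dispersion (size) 2 by default; `Inf` recovers Poisson.
* **Per-name sizes.** The 48 individual name-group sizes were never
  published; the built-in ledger spreads them deterministically across the
  0.1–0.2% band, summing exactly to the published $e_0$. It is labelled
  synthetic in `taiyuan_frame()`'s documentation.
* **Coupon redemption.** Reaching 302 recruits from 2 seeds within 8 waves
  needs effective branching $\approx (302/2)^{1/7} \approx 2.0$; with 3
  coupons this means ~0.7 redemption probability. Default 0.75 (branching
  2.25), which reproduces the published survey shape with margin. If every
  chain goes extinct before the target — probability $\sim 3\times10^{-4}$
  at the defaults — a fresh wave-0 seed is drawn, as a field team would.
* **Cluster structure.** The stratified two-stage design is emulated only as
  exchangeable nested labels (83 departments in 36 units in 20 industries);
  an optional department-level log-normal effect (`cluster_sd`) exists to
  stress the cluster bootstrap. No between-cluster effects by default.
* **No explicit graph.** Counts are drawn from the implied marginal
  binomials: known counts $\mathrm{Bin}(d_i, N_j/t)$, visible hidden ties
  $\mathrm{Bin}(d_i, (N_H/t)\,\delta\tau)$, awareness
  $\mathrm{Bin}(\text{known}, \tau)$. This is sufficient for every
  estimator here, but it means a green recovery test does **not** validate
  robustness to network clustering, homophily between hidden members, or
  recall error — none of which the estimators model either.

## Power analysis for the recovery experiments

The recovery grid ($\delta \in \{0.5, 0.75, 1\} \times \tau \in \{0.6, 0.9,
1\}$, $n_{\mathrm{general}} = 5000$, $n_{\mathrm{RDS}} = 300$, 200 seeds per
cell) asserts that the adjusted estimator's relative bias is below 5%. The
binding noise source is RRT unmasking: with an unrelated answer of mean ~20
against a sensitive mean of order $10^{-2}$–$10^0$, the delta-rule SE of
$\hat m_1$ is $\approx 0.23$ at $n = 5000$ *independently of* $N_H$. The
per-seed SE of the adjusted estimate is therefore
$\approx 0.23\,(t/c)/(\delta\tau)$, about 28,600 persons in the worst cell
($\delta\tau = 0.3$). At the study-sized $N_H = 1242$ the Monte-Carlo SE of
the mean relative bias over 200 seeds would be ~47% — the 5% assertion would
be unmeasurable noise. The recovery and coverage experiments therefore use a
high-signal world with $N_H = 150{,}000$ (~3.3% of $t$), for which that SE
is ~1.4%: large enough to expose a real 5% bias, small enough not to fail by
chance. This was fixed by the delta-method calculation above before the
tests were first run; the default truth keeps the study-sized
$N_H = 1242$. (The flip side, worth stating plainly: with this RRT design
the study's own $n \approx 1600$ could not support a CI as tight as the one
published for $m_1$ unless the unrelated answers were far less variable than
a Poisson(20); the package reports whatever noise the data actually carry.)

## Numerical and replication notes

* $e_0$ and all ledger sizes are exact integers; ratios are computed lazily
  in double precision.
* The estimator is ratio-of-means (one pooled $\hat c$ from the grand mean
  $m_0$), matching the reference analysis; the per-respondent mean-of-ratios
  variant exists for diagnostics only. RDS means are unweighted; an RDS-II
  style inverse-degree weighted variant sits behind `weighted = TRUE`.
* `replicate_paper()` re-derives each published downstream value from the
  published upstream values. Four quantities reproduce exactly at printed
  precision (adjusted size 1241.9, prevalence 0.044%, aware network size
  58.5, basic estimate 585.1 within 0.1%); four do not because the published
  chain mixes rounded and unrounded intermediates ($8.3\,t/e_0 = 124.4$ vs
  printed 123.9; $4.4\,t/e_0 = 66.0$ vs 66.3; $66.3/123.9 = 53.5\%$ vs
  53.6%; $58.5/66.3 = 88.2\%$ vs 87.9%). These four are reported
  side-by-side and are not pass/fail targets. The published composite CIs
  and the field correlation $r = 0.7$ depend on the unavailable raw data and
  are not reproduction targets either.

## Worked example

```{r example, eval = FALSE}
tr <- synthetic_truth()
g <- generate_general_survey(tr, n = 1747, seed = 1)
r <- generate_rds_survey(tr, seed = 2)
report <- run_estimate(g, r, tr$frame,
                       spec = bootstrap_spec(B = 1000, seed = 3))
print(report)
```

## Known limitations

* No MLE or Bayesian NSUM variants; only the estimator chain above.
* Percentile intervals only; no BCa, no analytic delta-method variance for
  the composite estimator.
* The stratified two-stage design is neither weighted for nor simulated
  beyond exchangeable labels.
* The awareness question covers only name-group alters; as in the source
  design, that subnetwork's awareness rate stands in for the whole network.
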