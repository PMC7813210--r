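---
title: "Reading dynamics and lexicon-based opinion scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reading dynamics and lexicon-based opinion scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opiniondyn)
```

This vignette is the package's own account of its methods: the reading-
dynamics model and its estimation, the two lexicon scorers, the rater
adjudication protocol, the synthetic-data generator, and the numerical
choices behind each. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The SRS/I reading-dynamics model

A topic on a microblogging platform recruits readers the way an epidemic
recruits cases. We track three compartments in a fixed population of `N`
users: susceptible `S` (unaware of the topic), reading `R` (actively
reading, and exposing their contacts), immunized `I` (done with the topic).
Three parameters govern the flows:

* `lam` — effective transmission coefficient per (reader × susceptible) per
  day. Structurally `lam = beta * k_avg`, the product of the per-contact
  exposure rate and the mean degree of the dissemination network; only the
  product enters the dynamics, so `lam` is the canonical parameter and
  `(beta, k_avg)` are optional decorations validated for consistency. No
  other network structure is modelled.
* `alpha` — inactivation rate per day; `1/alpha` is the mean time a user
  stays in the reading state.
* `p` — probability that an inactivating reader re-enters the susceptible
  state (and can be recruited again by the same topic) rather than becoming
  immune.

The mean-field system is

$$\frac{dS}{dt} = -\lambda S R + p\alpha R,\qquad
\frac{dR}{dt} = \lambda S R - \alpha R,\qquad
\frac{dI}{dt} = (1-p)\alpha R.$$

States are real-valued (mean-field), not integer counts; time is in days.
Two classical limits serve as oracles in the tests: `p = 1` collapses the
model to a two-compartment SIS system with `I` frozen, and `p = 0` makes
`S` monotone non-increasing (SIR-like).

Linearising at launch gives `R'(0) = (lam * S0 - alpha) * R(0)`, so reading
activity grows iff the **public-opinion reproduction ratio**

$$R_0 = \frac{\lambda S_0}{\alpha}$$

exceeds one. `R0` is the expected number of secondary readers per active
reader while nearly everyone is still susceptible — the natural measure of
a topic's initial propagation potential.

### Integration

`simulate_srsi()` integrates with `deSolve`'s adaptive lsoda at
`rtol = 1e-8`, `atol = 1e-8 * N`. The trajectory is validated rather than
repaired: conservation must hold to `1e-6 * N` at every grid point, and any
compartment more negative than `-1e-9 * N` is an error, never clipped. A
fourth cumulative-flow state `C` (with `dC/dt = lam * S * R`) rides along so
daily incidence is an exact integral, `diff(C)`, not a finite-difference
approximation.

The test suite cross-checks the adaptive solution against an independently
written fixed-step Euler integration. Euler's truncation error is first
order, so the oracle's step must be chosen from the tolerance it is asked to
certify: at step `2e-5` day its own error is comfortably below the
`1e-4 * N` band used in the tests, which a coarser step would not clear for
fast-burning topics.

## Estimating the reproduction ratio from reading counts

The data unit is a `reading_series`: dated daily counts of new reads,
pooled by calendar day (per-topic grouping optional). Platforms publish
cumulative "reading quantity"; `as_reading_series(cumulative = TRUE)` takes
daily differences. `segment_stages()` splits a series into user-supplied,
non-overlapping propagation stages; the packaged defaults are the three
2020 stages (ferment: Jan 25–Jun 30, evolution: July, transmission:
Aug 1–Oct 10), configuration rather than detection — changepoint discovery
is out of scope.

`fit_srsi()` minimises the unweighted sum of squared errors between
observed daily reads and the model's integrated daily new-reader flow. Free
parameters are `(lam, alpha, p, R(0))`; `N` is fixed by configuration with
`S(0) = N - R(0)` and `I(0) = 0`, because `N` is not identifiable from a
single stage. Choices that matter:

* **Search space.** `lam`, `alpha`, `R(0)` are optimised on log scale
  (`p` on its natural [0,1] scale) within box bounds; defaults span
  `lam ∈ [1e-9, 1e-2]`, `alpha ∈ [0.02, 10]` per day, `R(0) ∈ [0.5, 0.1N]`.
* **Multistart.** The objective is multimodal. The optimiser starts from a
  seeded Latin-hypercube design (8 points by default), the caller's guess if
  any, plus data-informed starts: the log-linear slope of the rising limb
  estimates the early growth rate `r = lam*S0 - alpha`, which together with
  an `alpha` grid over plausible reading durations (0.25–2 days) pins
  `(lam, R(0))`.
* **Refinement.** Bounded L-BFGS-B runs from every start; its
  finite-difference gradients stall in the objective's narrow curved
  valleys, so the three best endpoints are refined with Nelder–Mead, and a
  final Nelder–Mead polish (restarted once if the simplex degenerates)
  provides the convergence verdict. The whole procedure is deterministic
  given (data, guess, bounds, seed).
* **Objective integrator.** The fitting loop evaluates the model tens of
  thousands of times, so it uses a compiled fixed-step RK4 kernel (step
  0.02 day) whose discretisation error is orders of magnitude below the
  count noise of any series worth fitting; the simulation-facing API keeps
  the adaptive solver, and the two are cross-checked in the tests.

A population-consistency check accounts for re-entry: cumulative reads may
legitimately exceed `N` when `p > 0` (the same user reads repeatedly), so
the fit requires only that no single day exceeds `N` and that total reads
not exceed `N / (1 - p_max)` under the `p` bounds.

`stage_reproduction_ratios()` applies the fit per stage, isolating
failures: an empty or degenerate stage yields a `converged = FALSE` stub
with an error message instead of aborting its neighbours.

### The recovery study

The published per-stage ratios for the 2020 vaccine discourse
(R₀₁ = 1.1360, R₀₂ = 2.8278, R₀₃ = 3.0729) cannot be reproduced directly —
the underlying message corpus is not deposited — so they serve as reference
magnitudes for a parameter-recovery experiment: `r0_recovery_study()`
simulates 60-day stages at those ratios in a population of `N = 1e5` with
Poisson count noise and refits each replicate. The generating conditions
are fixed once: `alpha = 1`/day (a mean active-reading duration of about
one day, realistic for microblog reading), `p = 0.3`, `R(0) = 10`. The
choice of `alpha = 1` matters for identifiability: it makes all three
ratios produce visibly saturating curves within 60 days, so `alpha` — and
hence `R0 = 1 + r/alpha` — is determined by curve shape. With much slower
inactivation the slowest stage would remain in pure exponential growth,
where only `lam*S0 - alpha` is identified and any `R0` on that ridge fits
equally well. The acceptance checks run 50 replicates per stage (about two
minutes of compute) and require a median relative error under 10% with the
stage ordering recovered in at least 95% of replicates.

## Price-tendency scoring

A `price_lexicon` lists words (or multi-token phrases) with positive
weights on one of two sides, `expensive` or `cheap`; a word may appear on
one side only, enforced at load with line-numbered errors. Scoring choices:

* **Occurrences, not types.** Each matched occurrence contributes its
  weight, so longer, more emphatic messages score higher.
* **Greedy longest-first phrase matching.** A phrase matches a run of
  consecutive tokens whose concatenation equals it and consumes those
  tokens, so the inner words of a matched phrase are not double-counted.
* **Tendency and label.** `s = score_expensive - score_cheap`; `s > 0` is
  labelled `expensive`, `s < 0` `acceptable`, and `s = 0` — which the sign
  rule leaves undefined — `neutral`. The statistic is antisymmetric under
  swapping the sides' word lists and additive over concatenation, both
  asserted as properties in the tests.
* **Tokenization is injected, never embedded.** The scorers consume
  pre-segmented token vectors; `read_messages()` accepts a caller-supplied
  tokenizer for raw text. Scores are therefore exactly reproducible given
  tokens, independent of any segmenter.

`corpus_tendency()` aggregates per calendar day, with unit weights (a
message-count view) or like-count weights (an endorsement view), and
normalizes by the series' maximum absolute daily score, mapping it into
[−1, 1]. Normalization is per series; an all-one-sided corpus is therefore
positive throughout with its peak day at exactly ±1.

## Sentiment polarity and rater adjudication

A `sentiment_lexicon` assigns signed values to words. A sentence's value is
the plain sum over its tokens — the canonical lexicon method — with
out-of-lexicon words contributing zero while still counting toward sequence
length. Polarity is the sign, with a configurable dead-band `epsilon`
(default 0, so the neutral class is exactly `s = 0`).

The three-rater protocol takes A and B's shared label when they agree and
C's label otherwise; with binary labels this equals the 2-of-3 majority,
verified exhaustively in the tests. `sentiment_summary()` reports NP/NN/ZN
counts (conserving `NP + NN + ZN = N`) and percentages rounded to one
decimal, keeping raw fractions alongside. `method_agreement()` builds the
3×3 confusion table over {+1, 0, −1} — manual labels are binary, so the
manual-neutral column is structurally empty — and reports the trace
fraction; no kappa is emitted, since the comparison protocol defines none.

## Vaccine-type attention

Messages are classified by a configurable keyword map over the five Chinese
COVID-19 vaccine development routes (inactivated, adenovirus vector,
attenuated-influenza vector, recombinant protein, nucleic acid); keywords
must be disjoint across types, a unique match classifies, and ambiguous or
keyword-free messages are excluded from all denominators. Per engagement
dimension, `discussions` counts classified messages while forwards,
comments and likes sum message metadata; shares normalize within each
dimension (summing to exactly 1 pre-rounding), are scale-invariant, and are
displayed as integer percentages with raw ratios retained. A zero-total
dimension has undefined shares and is flagged, not fabricated.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
carrying ground truth for every downstream stage:

* **Reading series** come from the SRS/I model itself, deterministic or
  with Poisson noise around the daily incidence.
* **Messages** are token streams, not natural Chinese: planted lexicon
  words realise each message's price label (1–3 words of the labelled side,
  none of the other), sentiment label (1–3 words of the labelled sign) and
  vaccine type (one keyword), shuffled among neutral filler tokens chosen
  not to collide with any lexicon entry. This suffices because every scorer
  is lexicon-driven; with zero noise, planted labels are exactly
  recoverable, which the tests assert.
* **Irony** is modelled purely as label–surface mismatch: with probability
  `irony_rate` a non-neutral message's sentiment words are drawn from the
  opposite sign while its ground-truth label is kept. This captures exactly
  the failure mode that makes lexicon scoring undercount ironic positivity,
  and the tests assert that method agreement against truth degrades
  monotonically as the ironic fraction rises from 0 to 0.5.
* **Engagement** (likes, forwards, comments) is negative-binomial with
  configurable mean and dispersion — heavy-tailed, as platform engagement
  is.
* **Rater panels** flip truth independently per rater with error rates
  bounded below 0.5, so majority adjudication provably improves on any
  single rater (error `3e²(1−e) + e³` at common rate `e`), which the tests
  check by Monte Carlo.

Every generator is a pure function of its spec and a mandatory seed.

What passing these tests does *not* show about real data: natural language
brings segmentation ambiguity, negation and scope, sarcasm beyond simple
sign-flips, topic drift, and engagement dynamics correlated with content —
none of which the generator emulates. Results on synthetic corpora validate
the pipeline's mechanics, not the adequacy of lexicon scoring for any
particular real corpus.

## Default problem sizes

The test suite and acceptance script use 60-day stages, populations of
1e5, corpora of up to 925 messages, 200-sentence oracle comparisons and 50
Monte-Carlo replicates per stage — sizes at which every probabilistic
assertion has comfortable statistical margin while the whole suite runs in
a few minutes on one CPU.

## Known limitations

* Stage boundaries are user configuration; no changepoint detection.
* `N` is fixed, not estimated; reproduction ratios are conditional on it
  (though `R0` itself is robust to moderate misspecification of `N`, since
  `lam*S0` is what the data pin down).
* Uncertainty is quantified only through replicate spread, not analytic
  intervals.
* Multi-topic coupling, degree-distribution-aware dynamics and stochastic
  agent-level simulation are out of scope; the model is mean-field with a
  single effective contact parameter.
* The packaged lexicons are small synthetic stand-ins; real analyses should
  supply full dictionaries.
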