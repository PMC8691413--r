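---
title: "Methods: sentiment profiles and democratic moderation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment profiles and democratic moderation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plebeian)
```

## What this package models

Misinformation on text-based social media correlates with negative
sentiment: a misinformative post is *often* negative, but not certainly
so. That observation suggests a moderation design with two stages — use
cheap sentiment analysis to narrow the candidate set, then a democratic
jury of users to make the actual removal decision. This package
implements that design together with the analytics that motivate it: the
bimodal structure of compound polarity distributions, keyword-taxonomy
contrasts (locational versus biological viral naming), Condorcet
jury-accuracy theory, and a one-byte-per-thread incremental state that
makes interval operation cheap. Because the platform corpora that would
feed it are not redistributable, a seeded synthetic generator provides a
fully specified stand-in world; everything below is careful to say what a
green test on that world does and does not establish.

## Cleaning and scoring

`clean_text()` applies a fixed order: HTML tags, URLs (scheme-prefixed
and bare `www.`), `@handles`, emoji (replaced by lowercase short-name
words, via a compact built-in table), residual non-ASCII symbols,
whitespace collapse. The order is part of the contract (idempotence is
tested; order-independence is not claimed). The English check is a
dictionary-ratio heuristic — at least a fraction `english_threshold`
(default 0.5) of tokens must appear in an English word list — standing in
for a spell-checker backend; the word list is a ~450-word built-in,
overridable per call. Non-English posts are excluded downstream and
counted in the run log, never silently dropped.

`score_text()` scores against any lexicon satisfying the token→valence
contract. The compound is the normalized valence sum `s/√(s²+15)`, the
standard squashing used by social-media valence lexicons, so the built-in
toy lexicon (38 tokens, valences on a 0.25 grid spanning [−3, 3]) and any
production lexicon live on the same scale. *Inconclusive* is defined as
zero lexicon hits — the scorer has no evidence — and such posts are
excluded from distribution summaries along with exact zeros.

## The bimodal summary

`estimate_kde()` evaluates a Gaussian-kernel KDE on a fixed 512-point
grid over [−1, 1], bandwidth by Scott's rule `sd·n^(−1/5)` (overridable;
no bandwidth is prescribed upstream). Mass leaking past ±1 is negligible
at realistic bandwidths, so the trapezoid integral stays within 0.02 of
1 — an invariant the tests check rather than assume. Fewer than 10 scores
or a zero-variance sample is an error, not a degenerate curve.

`find_modes()` takes the density argmax over grid points strictly inside
(−1, 0) and (0, 1); an argmax on the boundary of either half means the
density is monotone there — no peak — and the sample is declared not
bimodal. Peaks are read from the KDE, not the histogram (the histogram,
30 bins by default, is reported alongside for display).

The skewness functional is a genuinely open design point: the upstream
definition survives only as a sign convention (γ in (0, ∞) when the
positive peak is the major mode, (−∞, 0) when it is the minor one, by
implication 0 at equality). The default `γ = ln(f⁺/f⁻)` is the simplest
functional with that sign behaviour, unbounded range, strict
monotonicity in each height, and antisymmetry under swapping the peaks;
it also lands in the magnitude range of typical reported values
(|γ| ≲ 1). Because the reconstruction cannot be confirmed,
`compute_gamma()` takes the functional as an argument and every test
binds only to the sign/monotonicity contract.

## Flag Phase, Jury Phase

`flag_phase()` gates on popularity (`v_act ≥ v_thres`), draws a
without-replacement simple random sample of up to `comment_sample_size`
(default 100) scored comments, and flags when the unweighted mean of root
plus sampled comments falls below `negativity_threshold` (default 0).
The root counts as one item, equal to each comment — no weighting scheme
is prescribed upstream, and equal weighting is the assumption-free
choice. An unscorable root is an error: the flagger cannot reason about a
thread whose anchor it cannot read.

`select_jury()` empanels exactly `⌈0.10 · viewers⌉` users by simple
random sampling without replacement. Whether "viewers" means unique
viewers or view events is left to the caller — the function takes a
count. `run_jury()` counts at quorum or deadline; abstention is always
allowed, removal needs a strict majority of cast votes, and **ties keep
the post**. The tie rule is a design choice: the upstream description
says only that results "will be counted", and keeping is the conservative
reading of its free-expression emphasis. Removal is a feed-state flag,
never deletion.

`condorcet_majority_prob()` is the exact binomial tail for odd panels
(even panels are rejected as tie-ambiguous; the operational tie rule
above covers the even-cast-vote case). `simulate_jury_accuracy()` adds
participation: each juror votes with probability `participation`, and a
deadlocked or empty jury defaults to keep, so with truth = "remove" the
no-participation limit has accuracy 0. Jurors are independent and
identically competent — the classical theorem's assumptions;
heterogeneous competence would be a straightforward extension but is not
required by anything tested here.

## The one-byte thread state

For interval operation each thread stores one byte: the high bit φ_d and
a 7-bit quantized thread sentiment β. The determination value is
`n_d = sgn(v_act − v_thres) · Σ ν(xᵢ)` with ν marking posts new since the
last sweep; φ_d = 1 (skip) iff `n_d ≤ 0`, which captures both stated
behaviours — unpopular threads are skipped, and so are threads with
nothing new. β quantizes the running mean as `round(127·(m̄+1)/2)`
(half-up), so dequantization error is at most 1/127. The recursion
operates on an *exact* shadow mean kept beside the byte (one
multiply-free update per score), quantizing only at write time: recursing
on quantized values would accumulate drift with no offsetting benefit,
since the exact mean costs one double in the sidecar. `write_state()`
persists the literal packed bytes plus a JSON sidecar of ids and shadow
means.

One honesty note on `interval_sweep()`: the only-new-comments economy
applies to the skip decision and the β update. A thread that *is*
selected for analysis has its root and comments scored for the Flag
Phase sample — the savings claimed for the byte are in never touching
skipped threads, which the sweep tests verify (a second sweep with no new
data analyzes nothing).

## The synthetic world

`generate_corpus()` states its world through `synthetic_config()`
defaults, chosen once:

- **Mixture**: root compounds from a two-Gaussian mixture, modes ∓0.5,
  σ = 0.1, truncated to [−1, 1] by resampling (clipping would pile mass
  on the boundary and fake modes). The ∓0.5 centers match where reported
  negative/positive peaks cluster across platforms; equal weights by
  default.
- **Comments**: target `ρ·root + (1−ρ)·fresh + N(0, 0.05)` with
  ρ = 0.9. The convex form shrinks the comment marginal toward the
  centre as ρ falls; 0.9 — comments strongly echoing their root, the
  echo-chamber regime the motivating analyses describe — keeps the
  pooled marginal bimodal with modes near ∓0.46, within the ±0.07
  recovery tolerance. Comment count is Poisson(4): small threads typical
  of mid-popularity posts.
- **Views**: lognormal(5, 1.5), integerized, floored at 1 — heavy-tailed
  with median ≈ 148, so a threshold of 150 splits "popular" roughly in
  half.
- **Misinformation link**: `P(misinfo) = plogis(−2 + 3·(−compound))` —
  ≈ 12% at neutral, ≈ 73% at compound −1. Detectable but imperfect
  coupling: misinformation is *often* negative, not certainly.
- **Taxonomy injection**: 15% of roots carry a phrase from the
  locational or biological list (50/50), with the mode-assignment
  probability tilted by ±0.35 — locational-tagged posts lean negative,
  biological-tagged lean positive, reproducing the direction of the
  violin-plot contrast. The biases are symmetric so the pooled mixture
  weights are undisturbed in expectation.
- **Text**: rendered from the toy lexicon by greedy selection in
  valence-sum space (the target compound inverts to a required sum
  through the squashing), with random tie-breaks and neutral filler
  words; the scored output lands within ±0.1 of the target, in practice
  within ≈ 0.05.

What a green test establishes: the pipeline's *mechanics* — mode
recovery, γ sign behaviour, flag enrichment above base rate, sweep
economics — on a world whose generating process is known. What it does
not establish: anything about real platforms. Real text has negation,
sarcasm, stance (a debunking post and a misinforming one can share
vocabulary), topical drift, and user networks; none are modelled, and
the enrichment result in particular should be read as "the algorithm
exploits a misinfo–negativity coupling when one exists", not as a
measured precision on any real feed.

## Numerical choices and degenerate inputs

- KDE grid 512 points; mode location error is bounded by the ≈ 0.004
  grid step, far below the 0.05 tolerances in use.
- Zero-variance samples, sub-10 samples, one-sided samples: errors with
  named messages, never silent NaNs.
- Quantile reports use the standard linear-interpolation definition
  (type 7).
- Tie-breaks: jury ties keep; `find_modes` ties resolve to the first
  grid argmax (`which.max`), deterministic on a fixed grid.
- All sampling (comment SRS, panels, simulations, generation) flows
  through per-call seeds and restores the caller's RNG state, so library
  use never perturbs a session's stream.

## Known limitations

Text-only; English-only by a deliberately crude heuristic; lexicon
scoring inherits every blind spot of bag-of-valences methods; the γ
functional is a reconstruction (pluggable for that reason); comment trees
are flattened, discarding reply structure; the CLI `jury` command
simulates votes from a flat Bernoulli model because no operational
vote-generating process is specified upstream.
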