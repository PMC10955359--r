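---
title: "Modelling cooperation prediction from first and second impressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperation prediction from first and second impressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopdetect)
```

`coopdetect` is a generative and measurement toolkit for studies in which
online raters predict the choices of players in a repeated "Split or Take
All" Prisoner's Dilemma. This vignette documents the model it simulates,
the parameters that matter and why their defaults are what they are, the
numerical decisions, and what the package's passing tests do and do not
establish about real data.

## The game and the behavioural law

Two matched players repeatedly choose Split or Take All. Mutual Split pays
$5 each; a lone Take All takes the whole $10 stake; mutual Take All pays
nothing. Take All therefore weakly dominates within a round, yet repeated
play sustains cooperation. A random-stopping rule continues the match from
round $n$ with probability $4^{1-n}$: round 2 is always reached, round 3
with probability 1/4, and so on. Match lengths are simulated by literal
sequential continuation draws, truncated at `max_rounds_cap` (default 10;
the probability mass beyond the cap is below $4^{-36}$ and is ignored).

Players come in two types. A *conditional cooperator* intends Split in
round 1 and thereafter mirrors the partner's previous realized choice
(tit-for-tat). A *non-cooperator* always intends Take All. Each round the
realized choice flips the intended one with a symmetric execution-error
probability, the *tremble*. With the tremble at zero the entire match
trajectory is a deterministic function of the two types, which the test
suite checks by enumerating all four type pairs.

### Cohort calibration

The default cohort has 94 players: 44 men with conditional-cooperator
probability 0.614 and 50 women with probability 0.860. This composition is
deliberate: it is the unique split of 94 for which the calibrated rates are
exact count ratios (27/44 = 61.4%, 43/50 = 86.0%) and the overall expected
cooperator share is 70/94 = 74.5%. `expected_round1_split()` returns that
weighted mean. Note the distinction between the *type* share (74.5%
intended round-1 cooperation) and the *realized* round-1 Split share, which
the tremble perturbs to $p + t - 2pt \approx 72\%$ at the default
$t = 0.05$.

The tremble default of 0.05 is the calibration lever for round 2. Under the
pure heuristic with no noise, expected round-2 cooperation is roughly the
squared type share ($\approx$ 55.5%); with the tremble propagating through
both the partner's round-1 realization and the player's own round-2
execution, the simulated round-2 Split share comes out near 53%, the level
the acceptance suite checks to within three percentage points over 200
cohort replications.

Pairing is a uniform random perfect matching, blind to gender — a
maximum-entropy default, since nothing in the design constrains who is
paired with whom. One fixed pairing is used per cohort; there is no
rematching.

## Raters

The rater module is the synthetic-data heart of the package. A recruited
cohort of 445 raters contains the four treatment arms at their
post-exclusion sizes — None 108, Label 101, Photo 108, Video 105 — plus an
exclusion fixture of 11 small-screen and 12 too-fast (< 480 s) recruits
with disjoint flags, so `apply_exclusions()` reproduces the
445 − 11 − 12 = 422 arithmetic exactly and reports a per-rule audit.

Rater genders are drawn at shares 48.53% male / 48.98% female, remainder
neither. Each rater holds a pair of beliefs (percent of male players and of
female players expected to Split in round 1), drawn from a bivariate normal
clipped to [0, 100]. Means depend on the rater's gender — male raters
46.3/61.8, female raters 42.2/66.5, otherwise 44.2/63.9 — with correlation
0.503. The belief standard deviation is a free parameter (default 20
percentage points): the calibration sources pin the means and correlation
but not the spread, so it is exposed in `rater_config()` rather than
hard-coded. Clipping makes realized moments shrink slightly toward the
interior; the tests compare simulated means against a closed-form
clipped-normal oracle rather than the raw means.

### Information sets and guessing strategies

What a rater sees about a player grows across treatments: None shows only
an ID; Label adds gender; Photo and Video add an appearance cue while
keeping gender visible (visual gender identification is treated as
essentially perfect). The cue is modelled as a binary signal that matches
the player's true round-1 choice with a *validity* in [0.5, 1]; validities
below 0.5 (anti-diagnostic cues) are rejected. Both appearance treatments
default to validity 0.55 — weakly informative and deliberately equal, so
that photo-versus-video accuracy contrasts are null by construction unless
the user configures otherwise. In round 2 every treatment additionally
reveals the pair's round-1 history.

A round-1 guess starts from the *effective prior*: the gender-specific
belief when gender is visible, otherwise the average of the two beliefs
(the "belief about players"). A cue, when present, shifts the prior on the
log-odds scale by `cue_weight × log(validity / (1 − validity))`, signed by
the cue. The guess itself mixes two classic strategies: with probability
`lambda_optimize` the rater *optimises* (guesses Split iff the posterior is
at least 50%, ties going to Split, mirroring the ≥ 50% convention of the
sufficiently-correct dummy); otherwise the rater *probability-matches*,
guessing Split with probability equal to the posterior. The default
`lambda_optimize = 0.7` reflects that financially motivated raters mostly
optimise: with belief means near 54 and spread 20 it puts the cohort's mean
round-1 Split-guess share in the high 50s, consistent with the calibration
aggregates.

A round-2 guess applies the conditional-cooperation heuristic with
probability `heuristic_adherence` (default 0.8): predict Take All for a
player who took all in round 1, otherwise predict the partner's round-1
choice. With the complementary probability the rater falls back to the
round-1 rule on the same information set. Appearance cues are sampled once
per rater–player pair and reused in round 2, because the stimulus does not
change between rounds. All round-1 guesses are generated before any
round-2 guesses, matching the phase structure of the task; no within-phase
order effects or learning across the 94 targets are modelled.

## Measurement layer

Per rater and round, over all guesses in the round: the cooperator
detection rate $H$ and cheater detection rate $R$ condition correctness on
the player's true choice; rates of exactly 0 or 1 are clamped to
$10^{-5}$ and $1 - 10^{-5}$; accuracy is $Z(H) - Z(1-R)$ and bias
$-0.5[Z(H) + Z(1-R)]$. Clamping guarantees finiteness and gives degenerate
guessers exact chance-level accuracy: an all-Split rater has $H = 1$,
$R = 0$, and both clamped rates map to the same z-score, so accuracy is
exactly zero. Accuracy and bias are always computed per rater and then
averaged — never from pooled rates, because the z-transform is nonlinear
and pooled-rate summaries are not comparable to means of per-rater values.

A rater-round with an empty truth class would yield an undefined rate; it
propagates as `NA` with a warning and is dropped from conditional
summaries. This cannot occur at the default calibration, where both
choices are present among the 94 players in both rounds. The odds ratio
uses the Haldane–Anscombe +0.5 correction on all cells whenever any cell
is zero — the standard default in the absence of a prescribed alternative.
Correctness is the plain percent of matching guesses.

Belief payments follow a windowed quadratic scoring rule: with error
fraction $d = |belief - actual|/100$, the payment is
$\max(0,\, m\,(1 - (d/w)^2))$ with window $w = 1/6$ — maximal at zero
error, continuous, and zero at and beyond the window. This is one
consistent parameterization of a "quadratic rule within 1/6" incentive;
the constants ($m$ = $0.50 per belief, $0.02 per correct guess) are
configuration, not calibrated facts.

## Inference

The regression machinery such designs usually report is replaced by
permutation analogues, which are exact under their randomization nulls and
free of distributional assumptions:

- `permutation_sign_test()` — is a per-rater quantity (e.g. accuracy)
  centred above zero? Null by independent sign flips.
- `paired_round_test()` — sign test on within-rater round-2 minus round-1
  differences.
- `permutation_group_test()` — size-weighted between-group sum of squares
  under label shuffling, for treatment contrasts.

All use the add-one estimator $(1 + \#\{perm \ge obs\})/(1 + B)$ with
$B = 10{,}000$ by default, so p-values are never zero and are bit-for-bit
reproducible under a fixed seed. Constant-zero input gives $p = 1$ by
construction.

### Parameter recovery

`recover_parameters()` validates the pipeline by re-estimating its own
generating parameters from the emitted tables. Gender type probabilities
come from realized round-1 Split shares inverted through the tremble map
$q = p + t - 2pt$; the tremble comes from the share of realized choices in
rounds ≥ 2 that contradict the behavioural law applied to the known types
and realized histories. The strategy weights are estimated by grid-search
maximum likelihood (grid step 0.01, ties toward the smaller value) on the
guesses of raters in the None and Label arms only — in the Photo and Video
arms the likelihood would require integrating over the latent per-record
cue, and the cue-free arms already identify both parameters. The
heuristic-adherence likelihood plugs in the estimated lambda for its
fallback component.

Interval construction is where the obvious choice fails. A naive
percentile bootstrap undercovers here for two reasons: the cohort
proportions sit on 44–50 observations (binomial discreteness near the
boundary), and the grid MLE is discretised. The package therefore uses
Wilson score intervals on the underlying proportions — mapped through the
de-tremble inversion, taking the least favourable tremble within its own
Wilson interval — for the cohort parameters, and a rater-resampling
percentile bootstrap widened by one grid step for the strategy parameters.
The acceptance suite checks ≥ 90% empirical coverage for the cohort
probabilities, the tremble and the adherence over 100 full-pipeline
replications.

## Reproducibility and problem sizes

A run is driven by one root seed; each stage (players, matches, raters,
guesses, inference, recovery) derives its own child seed deterministically,
so identical configurations give byte-identical CSV artifacts and stagewise
CLI invocations agree with all-at-once runs. `run_study()` writes eleven
artifacts (seven CSV tables, three JSON reports, one manifest echoing the
configuration and seed).

The test suite exercises Monte-Carlo properties at sizes chosen to make
binomial error bars a small fraction of the effects under test: $10^5$
draws for the stopping-rule distribution and belief moments, 200 cohort
replications for the round-comparison and round-2 calibration properties,
1000 null simulations for permutation-test size, and 100 full-pipeline
replications for recovery coverage.

## What the generator does and does not emulate

The simulator reproduces the study's *structure* — cohort sizes, arm
sizes, exclusion arithmetic, belief moments, the guessing-strategy mixture,
and the behavioural law — and its aggregate calibration anchors. It does
not model faces: the appearance cue is a one-parameter abstraction of
whatever photos or videos convey, with no face-space, expressivity or
attention dynamics. It does not model response times, within-phase order
effects, rater learning, or session structure. Passing tests therefore
show that the measurement and inference layers behave correctly on data
generated by this model, and that the headline comparative patterns
(second impressions beating first impressions; correct beliefs going with
correct guesses) follow from the model at its calibration — not that the
model captures every mechanism behind real raters' judgements.

Two further caveats. Per-rater mean accuracy and bias cannot be recovered
from pooled detection rates (nonlinear averaging), so pooled-rate
summaries are comparable only qualitatively. And the cohort composition
(44/50) is a reconstruction that makes the calibrated rates exactly
representable; users wanting a different composition can set `n_male`,
`n_female` and the type probabilities freely in `game_config()`.
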