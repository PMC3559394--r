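---
title: "Post-conflict matched-control methods in pcmckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-conflict matched-control methods in pcmckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pcmckit implements the post-conflict/matched-control (PC/MC) method of
quantitative ethology for the analysis of consolation and reconciliation in
a semi-free bonobo colony, together with an agent-based generator that
emulates the observational data structure the analyses assume. This
vignette is the package's account of the science: the method and its
assumptions, the parameters that matter, what the generator does and does
not emulate, the numerical choices, and the design decisions taken where
the protocol left room.

## The PC/MC method

Every recorded agonistic conflict triggers a 10-minute focal follow of the
victim (the PC). A matched control (MC) is a second 10-minute follow of the
same victim on a conflict-free occasion, one to two days later at the same
time of day, valid only if both former opponents are within 10 m of one
another at its start and the focal has been conflict-free for at least 10
minutes (otherwise the MC is postponed). Conflicts that never obtain a
valid MC are excluded from all analyses.

For a chosen relationship the *first-contact latency* of a follow is the
time of the earliest qualifying affiliative contact, right-censored at the
600-second follow end:

* **consolation** — contacts initiated by an uninvolved bystander toward
  the victim (victim-initiated contacts never qualify, and neither do
  contacts by the aggressor);
* **reconciliation** — contacts between the two former opponents, in
  either direction;
* **specific bystander** — consolation restricted to one bystander,
  evaluated only for bystanders *eligible* for that conflict, i.e. present
  in both the PC and the MC.

A PC/MC pair is labeled **attracted** if the contact came earlier in the
PC than in the MC or only in the PC, **dispersed** symmetrically for the
MC, and **neutral** if the contact fell at the same time in both or in
neither. Event times are recorded at 1-second resolution, so "same time"
means equality at that resolution; no extra tolerance is applied.
Labels are conserved: attracted + dispersed + neutral = retained pairs,
always.

From labels grouped over pairs the package computes the tendency score

$$\mathrm{TCT} = 100\,\frac{A - D}{T}$$

with $A$ attracted, $D$ dispersed and $T$ total pairs in the group:
per-victim over any-bystander labels this is the Triadic Contact Tendency
(TCT); over opponent labels, the Conciliatory Contact Tendency (CCT); per
(victim, bystander) dyad over specific-bystander labels it is the dyadic
TCT consumed by the relationship models. The **consolation index** of a
dyad is the fraction of the bystander's opportunities (retained conflicts
of that victim with the bystander eligible) in which that bystander was the
*globally first* individual to console the victim. Both dyadic measures are
kept because they are complementary: the TCT controls for baseline
affiliation but ignores other bystanders' earlier contacts; the index does
the opposite.

## Occurrence, latency and stress analyses

Occurrence is tested by a Wilcoxon signed-rank comparison of the per-focal
proportions of attracted and dispersed pairs. The implementation reports
the SPSS-style tie-corrected normal deviate $Z = (W^+ - \mu)/\sigma$ and,
for up to `exact_max = 12` informative pairs, an exact two-sided p-value
from the full enumeration of the $2^n$ sign patterns of the observed
(possibly tied) ranks; zero differences are dropped before ranking, the
standard signed-rank convention. `stats::wilcox.test` reports neither the
tie-corrected $Z$ nor an exact distribution under ties, which is why the
statistic is implemented in the package; the base function serves as a
cross-check in the no-ties case in the test suite.

Latency is compared by a Kaplan-Meier/log-rank (Mantel-Cox) test on the
censored first-contact latencies, one observation per follow, censored at
600 s (`survival::survdiff`; the survival curves are returned for plotting
the first-minute peak). The test suite checks the statistic against a
hand-computed hypergeometric-variance implementation.

Stress proxies are self-scratching (bouts/min) and self-grooming (s/min)
per follow. Retained PCs are categorized as consolation-only,
reconciliation-only, both, or no affiliation, where *occurrence* means the
corresponding pair label is attracted; PCs with reconciliation are excluded
from the consolation/no-affiliation contrasts to remove its confound. The
three planned contrasts (MC vs PC-without, MC vs PC-with, PC-without vs
PC-with) use paired Wilcoxon tests at a Bonferroni threshold of
$0.05/3$ truncated to three decimals, i.e. 0.016. A control analysis
compares scratch rates in MCs with vs without received contact.

## Mixed models and AIC selection

The occurrence GLMM is binomial-logit over one row per (retained conflict
x eligible bystander), outcome 1 when that bystander's specific pair label
is attracted. Covariates: proximity band (numeric 0/1/2 for <5 m, 5-10 m,
>10 m), bystander age class, sex and rearing, victim attributes,
mother-offspring kinship flags (the only codable kinship in this colony),
log-transformed dyadic affiliation indices, feeding context, conflict
intensity, reconciliation occurrence and redirection occurrence. Random
intercepts: victim, aggressor and bystander identity, group, and the
post-conflict interaction number (the conflict id), the latter read as a
grouping factor since the protocol lists it among random effects.

Fits are maximum likelihood via lme4's Laplace-type approximation
(`glmer`); during enumeration the faster PIRLS-only `nAGQ = 0`
approximation is used and the winning model is refitted at `nAGQ = 1`.
Gaussian dyadic models use `lmer` with ML (not REML) so AIC is comparable
across fixed-effect sets. Selection enumerates all fixed-effect subsets of
the candidate pool (plus declared two-way interactions whose main effects
are present), ranks converged fits by AIC with ties broken by fewer
parameters, and reports a likelihood-ratio test of the winner against the
null model (random effects only). All-subsets enumeration is exponential,
so pools larger than `cap = 10` predictors fall back to forward-backward
stepwise AIC over the same constrained space; no valid branch-and-bound
lower bound exists for logistic subset selection without extra
assumptions, so an honest stepwise search was preferred to a heuristic
bound. Numeric predictor pairs with $|r| > 0.7$ are blocked from joint
inclusion (the threshold is this package's choice; the protocol only
reports the absence of strong collinearity).

Reduced runs repeat the identical pipeline after dropping a bystander
stratum (mother-reared bystanders, or juveniles for the mature-only
analysis). In the packaged roster all mother-reared study subjects are
juveniles, so the age and rearing effects are structurally confounded
exactly as in the field colony; the reduced runs are how that confound is
probed.

For the dyadic TCT/consolation-index LMMs, per-predictor significance is
computed by simulation: 10,000 seedable draws from the normal
approximation $N(\hat\beta, \widehat{\mathrm{Cov}})$ of the coefficient
sampling distribution, two-sided p as the (count+1)/(draws+1)-corrected
tail fraction. Current lme4 provides no MCMC sampler; this normal
posterior simulation is the package's stand-in and is labeled as such.

## The synthetic colony

No raw observations are deposited for the original field study, so every
stage is verified against an agent-based generator whose defaults are the
study conditions:

* **Roster** — the packaged two-group colony (36 study subjects + 6
  dependent infants; `lola_roster()`), or any cell-count configuration via
  `simulate_roster()`. Infants are loaded but excluded from interactions by
  a single filter, preserving roster fidelity.
* **Conflicts** — Poisson arrivals at 356/453 ≈ 0.786 per observation
  hour over 8-hour days; victim class shares 33.1% adolescent-male and
  32.5% juvenile-female, aggressor shares 51.2% adult-female and 25.4%
  adult-male, remainders uniform over the other demographic cells;
  six-level intensity distribution 14.2/2.5/34/32/12.5/4.1% (normalized:
  the printed values sum to 99.3%). Context and proximity shares are not
  printed anywhere and carry field-plausible defaults (feeding-related
  contexts ~50%; proximity roughly balanced across the three bands).
* **Affinity** — latent symmetric dyadic affinities in (0,1), Beta on a
  logit-shifted mean with a +1.5 logit kinship boost; a dyad's affinity
  *is* its per-scan engagement probability, so scan-based indices are
  consistent estimators of it.
* **PC streams** — per-bystander consolation through a logistic hazard
  over the same covariates the GLMM models, exponential latency (scale
  `tau_pc` = 140 s) censored at 600 s; reconciliation analogous over
  opponent covariates; optional victim-initiated contacts that must never
  count as consolation (they exercise the direction rule); redirection as a
  Bernoulli event with adult-female victims most likely to redirect.
* **MC streams** — scheduled +1/+2 days at the same clock time, aggressor
  forced within 10 m, postponed past any conflict of the focal in the
  preceding 10 minutes; flat per-bystander contact probability `p_mc` with
  exponential latency (`tau_mc` = 300 s); 10/356 ≈ 2.8% of PCs never obtain
  an MC.
* **Self-directed behavior** — scratching is a piecewise-constant Poisson
  process switching from `lambda_pc` = 0.43 to `lambda_pc_consoled` = 0.19
  bouts/min at the first consolatory contact; MCs scratch at `lambda_mc` =
  0.37 (all three are the printed field rates). Grooming totals target the
  printed s/min rates.

Contact probabilities were fixed once from the printed per-focal
attracted/dispersed shares by the closed-form relation
$P(\mathrm{attracted}) \approx p_P(1-p_M) + p_P\,p_M\,P(t_P < t_M)$ (and
symmetrically for dispersed), giving a per-bystander consolation intercept
of −1.2 on the logit scale (≈0.09 at baseline covariates), `p_mc` = 0.045,
and reconciliation intercept −0.3 with opponent contact probability 0.06.
These are calibration targets, not fitted values; simulated campaigns land
near, not on, the field numbers.

`null_response_model()` zeroes every covariate effect and equalizes the PC
and MC contact probabilities, latency scales and scratch rates, making the
two streams of a pair exchangeable by construction — the basis of the
type-I-error and zero-TCT calibration checks.

The exponential latency is a modeling decision, not a field claim: the
field data constrain only a first-minute peak, which any decreasing hazard
reproduces. Things the generator deliberately does not emulate: dominance
hierarchies and rank dynamics, spatial movement and visibility bias,
temporal autocorrelation of conflicts (no aggression clusters beyond the
MC postponement rule), seasonal or demographic change, observer error, and
polyadic conflicts. Passing tests therefore show that the analysis code
recovers structure *of the kind the protocol assumes*; they cannot show
robustness to field complications outside that structure.

## Numerical choices and degenerate inputs

* Ties in latencies resolve at the 1-second recording resolution.
* "Only in the PC" is judged against censoring at follow end; pairs
  without an MC are excluded entirely rather than treated as censored MCs.
* Bystander eligibility reads presence at any point of the follow (the
  protocol does not say whether presence at MC start was required;
  `matching_rules(presence_scope=)` records the alternative).
* The day window "the following day (±2 days)" is read as an offset of
  1-2 days, configurable via `matching_rules(day_window=)`.
* The affiliation index combines the five scan behaviors with a scan-level
  OR (a scan counts once however many behaviors a dyad shows);
  `combine = "sum"` is available. The log transform uses
  $\log(x + \epsilon)$ with $\epsilon$ defaulting to half the smallest
  positive index; dyads lacking scan data get the floor and a flag.
* Redirection during a PC does not truncate the follow; it enters the
  models as a covariate only.
* Wilcoxon: zero differences dropped; exact enumeration up to n = 12,
  tie-corrected normal beyond; no continuity correction (matching the
  field-standard reporting).
* Complete separation (constant binomial outcome) is flagged without
  fitting; rank-deficient design matrices raise an error naming the
  aliased columns; non-converged fits are excluded from selection.
* A zero-variance LMM response returns zero slopes with a note rather
  than an error.

## Problem sizes used by the test suite

Simulation-backed checks run at sizes chosen to keep the suite fast while
preserving the statistical content: null calibration uses 500 replicates of
60+30-hour campaigns (~70 pairs each) plus one 180+90-hour campaign (>200
pairs) for the zero-TCT check; qualitative replication uses 200 replicates
at the full campaign scale (301+152 hours, ~350 conflicts, 30+ focal
victims); GLMM coverage uses 100 replicates of 2000-row opportunity
tables; selection consistency uses 50 stepwise replicates of 3 true + 5
noise predictors, with exhaustive enumeration cross-checked for global AIC
optimality on 3 of them (256 mixed-model fits per exhaustive replicate make
50 exhaustive replicates impractical anywhere).

## Known limitations

The analysis reproduces the *method*, not the field dataset: printed
coefficients of the original occurrence models are not recoverable without
the raw observations, and the package's acceptance checks are accordingly
property-based (oracle equivalence, calibration, parameter recovery,
directional replication) rather than coefficient matching. The
normal-approximation posterior simulation understates tail uncertainty
relative to a true MCMC treatment for small dyad tables. The stepwise
fallback can in principle miss the global AIC optimum for pools beyond the
exhaustive cap, which is why the cap is kept at 10 and the exhaustive route
is the default below it.
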