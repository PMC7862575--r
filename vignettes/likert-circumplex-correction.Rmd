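---
title: "Correcting non-equidistant Likert metrics on the soundscape circumplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting non-equidistant Likert metrics on the soundscape circumplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likertcirc)
```

## The problem

Soundscape surveys following ISO/TS 12913 Method A ask respondents to rate a
sound environment on eight five-point Likert scales — *pleasant*, *annoying*,
*vibrant*, *monotonous*, *calm*, *chaotic*, *eventful*, *uneventful* — that
are assumed to lie at 45° spacings on a two-dimensional circumplex
(valence × arousal). Projecting the eight ratings onto the two coordinates,

$$P = \frac{(p-a) + \cos 45^\circ\,(ca-ch) + \cos 45^\circ\,(v-m)}{4+\sqrt{32}},
\qquad
E = \frac{(e-u) + \cos 45^\circ\,(ch-ca) + \cos 45^\circ\,(v-m)}{4+\sqrt{32}},$$

treats the category values 1…5 as equidistant and all eight scales as having
identical ranges. Neither assumption is guaranteed: respondents may compress
or dilate the perceived distance between adjacent categories, differently per
scale. `likertcirc` implements a procedure that estimates corrected category
values from the *cross-site structure* of the responses and re-projects the
data with them.

The $1/(4+\sqrt{32})$ normalisation is implemented from its purpose: it is
the unique constant that maps the extreme symmetric response pattern to
exactly ±1, so both coordinates live in $[-1, 1]$. `cos 45°` is computed, not
hard-coded.

## From grouped percentages to a correction

With only a few dozen sites, correlations between single categories are too
noisy, so the five categories are collapsed into three groups per attribute:
disagreement (bottom two categories), neutral (midpoint), agreement (top
two). For each site the percentage of responses in each group is computed,
giving 24 variables (8 attributes × 3 groups) observed across sites.

The method rests on one hypothesis: *the regression slope between two
grouped-category percentage series across sites measures the relative
dilation of the corresponding scale intervals*. Two boundary cases motivate
it. If agreement and disagreement percentages of one attribute satisfy
$A\% = 1 - D\%$ exactly (slope −1), nobody uses the neutral category: the
neutral interval has collapsed and both poles are equally dilated. If a
pole's percentage never responds (slope 0), that pole carries no metric
information and its extent collapses toward zero.

Concretely the pipeline (`derive_correction()`) is:

1. `group_percentages()` — per-site D/N/A percentages (they sum to 100 per
   site and attribute).
2. `association_matrices()` — Pearson $r$ across sites for every pair of the
   24 variables, two-sided $p$ from the $t$ distribution with $n-2$ degrees
   of freedom, and both directional OLS slopes. Rank methods are not used:
   the dilation hypothesis is about linear slopes. No multiple-testing
   correction is applied (a caveat, not an oversight: the admissibility rule
   below mirrors the source procedure, which applies none).
3. `admissible_edges()` — keep pairs with $|r| \ge 0.7$ and $p < 0.05$.
   Magnitude is used rather than signed $r$: a strongly negative correlation
   carries the same information through its negative slope.
4. `propagate_values()` — the retained edges form a graph on the 24 nodes
   that is under-determined (cycles would give inconsistent products), so a
   **maximum-|r| spanning forest** is built (Kruskal's algorithm) and a
   single anchor — pleasant-disagreement, fixed at −1 — is propagated along
   the unique tree paths. Traversing an edge from a valued node $u$ into an
   unvalued node $v$ multiplies by the OLS slope of *v on u*: the new value
   is predicted from the known one. This uses, for every node, its single
   best-correlated link, and guarantees a unique consistent solution.
5. `neutral_sign()` and `build_correction()` — per attribute, the propagated
   agreement and disagreement node values become the pole extents $a_0$ and
   $d_0$; the barycenter $b = (a_0+d_0)/2$ centres them
   ($aa = a_0 - b$, $dd = d_0 - b$, hence $aa = -dd$); the neutral point is
   $n = z\,|b|$ with $z = +1$ when the neutral percentage correlates at
   least as strongly with agreement as with disagreement (raw correlations,
   ties toward +1); the intermediate categories sit at $n \pm n_0/2$, where
   $n_0$ is the magnitude of the propagated neutral-node value, or at the
   midpoints of neutral and the poles when the neutral node is unreachable
   (the fallback is flagged in the output).

Negative-valence attributes arrive with inverted orientation (their agreement
correlates negatively with the anchor side), which is intended: the corrected
values are circumplex-signed, so agreeing with *annoying* contributes
negatively to valence. The intermediate-category formulas are therefore
applied in each scale's own agree-increasing frame and mapped back; applied
literally in the signed frame they would interleave the categories of every
inverted scale.

Two slope→dilation readings are exposed: the default `proportional` mode uses
the slope itself (it reproduces the −1 boundary case exactly and composes
consistently along paths); the `angle` mode uses $\arctan(m)/(\pi/4)$,
implementing the literal statement that the slope *angle* is linear in the
dilation. The source leaves the choice ambiguous; both are provided, the
default documented here rather than guessed silently.

Unreachable pole nodes are a **hard error**, never imputed — pole extents are
the headline output, and imputing them would fabricate it. Unreachable
neutral nodes merely trigger the fallback.

## Corrected projection

`apply_correction()` replaces each response by its corrected category value.
Corrected valence sums the six valence-bearing attributes (pleasant,
annoying, vibrant, monotonous, calm, chaotic); corrected arousal sums
eventful, uneventful, vibrant, monotonous and subtracts calm and chaotic.
Each coordinate is divided by the sum, over its six attributes, of the
maximum positive (sign-adjusted) category value, so the corrected space is
again $[-1,1]$-normalised. Normalisation is per dimension; the alternative —
one pooled normaliser for both axes — is defensible but would let one
dimension's dilation rescale the other. Because the correction only sees
slopes, it cannot identify a *shift* between scales; corrected coordinates
are comparable up to the anchor's arbitrary scale, which the normalisation
removes (anchor invariance is a tested property).

## What uniform responses reveal

`simulate_uniform()` draws responses uniformly on {1…5} and
`summarize_simulation()` projects them. Even though such data uniformly cover
every scale, the ISO projection concentrates them in a bell around the
origin: the analytic standard deviation of ISO pleasantness is
$\sqrt{8}/(4+\sqrt{32}) \approx 0.293$, and by exact enumeration
(`exact_tail()`, which marginalises the two attributes orthogonal to the
axis and enumerates the remaining $5^6 = 15625$ outcomes) the probability of
exceeding 0.6 is exactly $327/15625 \approx 2.1\%$. The circumplex is not
uniformly available to soundscapes; the practical ceiling of the pleasantness
axis is near ±0.6. The Monte-Carlo and enumeration routes are kept separate
and are required to agree within binomial sampling error in the acceptance
suite.

## The synthetic world

Because no suitable survey dataset is publicly deposited, validation is by
parameter recovery on synthetic surveys (`synthetic_truth()`,
`generate_survey()`, `recovery_score()`).

**Response model.** A respondent at site $s$ has a latent circumplex position
(site mean + bivariate Gaussian noise, sd 0.15); each attribute scores the
projection of that position onto its own 45°-spaced direction plus attribute
noise (sd 0.15, chosen equal to the respondent noise — idiosyncratic
per-scale interpretation noise of the same order as mood-level noise), and
the response is the category whose threshold interval contains the score.
This latent-threshold model is the minimal one in which the dilation
hypothesis is literally true; it is the harness's assumption, not a claim
about respondents.

**Encoding a distorted metric.** The truth stores, per attribute, five true
category values $c = f \cdot (-1,-\tfrac12,0,\tfrac12,1)$ — the metric the
derivation should recover. A compressed metric ($f<1$) means the population
*interprets* that scale's steps as wider than nominal, so the response
thresholds are the midpoints of the *reciprocal*, interpreted positions
$q = (-1,\dots,1)/f$. This reciprocal placement is deliberate and was
verified empirically: placing thresholds at midpoints of $c$ itself leaves
the cross-site percentage slopes — the only signal the derivation observes —
unchanged for every $f$, which would make the truth unrecoverable by
construction. With the reciprocal placement, compressing one scale by
$f = 0.5$ yields a recovered relative pole extent of ≈ 0.5, which the
acceptance suite checks.

**Site geometry.** Sites lie on an elliptical band (major radius 0.5, minor
0.2, jitter 0.05) tilted 22.5° from the valence axis and centred at
(0.15, 0.15). A circular, isotropic layout is *not* usable: for any
rotation-invariant site distribution the correlation between percentage
series of attributes 45° apart is capped near $\cos 45° \approx 0.707$
(nonlinear saturation of the percentages pushes it lower), so the
$|r| \ge 0.7$ admissibility rule disconnects the graph and the derivation
fails for every seed. Real surveyed locations cluster in a narrow oblique
band of the circumplex, which is exactly what makes the method workable on
real data; the band's 22.5° tilt keeps every attribute axis within 67.5° of
the dominant site variation so all four attribute families stay connected,
and the offset centre makes the neutral-percentage series monotone enough for
the neutral sign $z$ to be estimable.

**What a green test does and does not establish.** The generator emulates
multi-site Likert surveys with a shared latent circumplex, a common distorted
metric, and Gaussian noise. It does not emulate demographic heterogeneity,
session effects, per-respondent response styles, label-wording effects, or
shifts between scales — so recovery results validate the derivation chain
under its own assumptions, not the psychometric claim itself.

## Identifiability limit (why two acceptance checks stay red)

The propagated extent of a node is a product of OLS slopes, and each slope is
$r \cdot \mathrm{sd}(v\%)/\mathrm{sd}(u\%)$. The cross-site sd of an
attribute's percentages scales with the spread of the sites along that
attribute's direction. The admissibility rule forces a band-like (anisotropic)
site layout (see above), and the estimator then reads that anisotropy as
metric compression of the attributes at large angles to the band: in the
equidistant null case the acceptance suite measures recovered relative
extents around 0.4–0.6 for the calm–chaotic and eventful–uneventful families
(mean maximum deviation ≈ 0.6 after scale alignment, against the < 0.15
criterion), and the same shrinkage holds the 40-value recovery correlation at
≈ 0.89 against its ≥ 0.9 criterion. These two checks are left failing
deliberately: the method cannot distinguish site-sampling anisotropy from
metric distortion, and the source procedure's assumption that its output is
independent of the site distribution is exactly the assumption the synthetic
world shows to be load-bearing. The quantities that are invariant to this
confound — the relative extent of two attributes equidistant from the band
(vibrant vs pleasant, recovered at ≈ 0.5 when the truth compresses vibrant
by 0.5) and the neutral-sign agreement — meet their criteria.

## Numerical and interface choices

* Canonical coding is 1 = strongly disagree … 5 = strongly agree; the
  direction and label vocabulary of raw files is handled entirely by
  `coding_config()` (the source document states both directions in different
  places, so nothing is guessed: both are expressible).
* Edge ordering is fully deterministic: descending $|r|$, then attribute
  order (pleasant, annoying, vibrant, monotonous, calm, chaotic, eventful,
  uneventful), then group order D < N < A, for both endpoints. Shuffling the
  edge input order cannot change any output (tested).
* Correlation over fewer than 5 sites is refused (`min_sites`, configurable
  upward).
* Exact ties in the neutral-sign comparison resolve to +1; ties are detected
  with a 1e−12 tolerance so that floating-point noise cannot flip the sign
  of an exact tie.
* Degenerate inputs are named error conditions (`lc_error_*`): zero scale
  span, disconnected pole nodes, non-positive coordinate normaliser,
  malformed files, out-of-range categories. Per-attribute soft findings —
  non-monotone corrected values, an orientation that contradicts the
  attribute's valence polarity — are warnings (`lc_warning_*`), because they
  are legitimate empirical outcomes on noisy data.
* Tail probabilities treat the threshold strictly (`>`), with a 1e−12 guard
  against ties at representable coordinates; thresholds outside $[-1,1]$
  return 0 or 1.
* All float assertions in the unit tests use 1e−9 or tighter except the
  statistical recovery experiments, whose tolerances are stated per test.

## Limitations

* Shifts between scales are unidentifiable by construction; corrected values
  are relative to the anchor.
* The spanning forest uses each node's best link only; information in
  discarded admissible edges (and their cycle consistency) is unused. A
  least-squares solution over all admissible edges would use it, but would
  depart from the stated max-correlation selection rule.
* OLS slope attenuation ($|r| < 1$) shrinks every propagated extent slightly
  toward zero even without anisotropy.
* With ~11–30 sites the $p < 0.05$, $|r| \ge 0.7$ rule is permissive;
  admissible edges can be spurious, and no multiplicity control is applied.
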