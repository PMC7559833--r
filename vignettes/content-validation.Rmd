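---
title: "Content validation of questionnaires with expert panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Content validation of questionnaires with expert panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

## The problem

When a new questionnaire is drafted, its items must be shown to represent
the construct they claim to measure before the instrument is fielded. The
standard design is a small panel of subject-matter experts (often around
10 judges) who rate the relevance of each item on a bounded Likert scale,
here 1–5 with 5 the highest relevance. Two statistical questions follow:

1. **Panel quality** — is any judge systematically discordant with the rest
   of the panel, to the point that their ratings should not enter the
   validity computation?
2. **Item validity** — for each item, do the retained judges agree strongly
   enough that the item can be kept?

`panelval` implements both stages as a deterministic pipeline:
screen → replace → compute per-item validity → summarise. The package ships
the complete rating matrices of a published validation of two 30-item
questionnaires on physical activity on prescription (PAP) in primary
healthcare — one rated by 11 sports medicine physicians, one by 11 nurses —
as embedded fixtures, so the whole pipeline can be exercised and checked
against published results without any external data.

## Aiken's V and its confidence interval

For $n$ judges rating an item on an integer scale from $l$ to $h$ with span
$k = h - l$, Aiken's V rescales the rank sum onto $[0, 1]$:

$$ V = \frac{S}{n\,k}, \qquad S = \sum_{i=1}^{n} (r_i - l), $$

equivalently $V = (\bar r - l)/k$. $V = 0$ means every judge chose the
lowest category, $V = 1$ unanimous top ratings. The package treats $V$ as a
proportion over $n k$ effective trials and inverts the normal score test to
get a Wilson-type confidence interval; both endpoints $p$ solve

$$ (V - p)^2 = z^2\, p\,(1 - p) / (n k), $$

giving the closed form

$$ L, U \;=\; \frac{2 n k V + z^2 \mp z\sqrt{4 n k V (1 - V) + z^2}}{2\,(n k + z^2)}. $$

The score interval is preferred over the Wald interval because panel sizes
are small and $V$ sits near 1 in practice: the score interval stays inside
$[0, 1]$, collapses to exact endpoints at $V \in \{0, 1\}$, and is markedly
asymmetric where it should be. At the default 95% level the package uses
$z = 1.96$ rather than the exact quantile 1.95996…, matching the desktop
tool traditionally used for this computation in validation studies; any
other confidence level uses the exact quantile, and `z` can be overridden.

An item is declared valid when its **unrounded** $V$ reaches the threshold
$V_0 = 0.75$ (inclusive). The comparison is never made on displayed values:
a $V$ of 0.7499 printed as “0.75” must still fail.

## The screening rule

Screening is leave-one-out: for judge $e$ and item $j$ in a screening pool
of $p$ judges, the consensus is the mean rating of the other $p - 1$ judges,
and the cell is flagged when

$$ |r_{ej} - \text{LOO mean}_{ej}| \ge d, $$

with $d = 3$ scale points by default. A judge with $m \ge 2$ flagged items
is excluded. Design choices worth stating explicitly:

* **Points, not SD multiples.** The rule could plausibly read “3 rating
  points” or “3 leave-one-out standard deviations”. The package defaults to
  absolute points: on the embedded panels this flags exactly the cells the
  published study marks as deviant (four items for the physicians'
  discordant judge, two for the nurses'), whereas the SD-multiple reading
  flags additional cells that the study does not mark. The SD-multiple mode
  is retained (`deviance_policy(mode = "sd_multiple")`) but documented as
  not reproducing the published screening.
* **Inclusive boundary.** The threshold is “$\ge$”: a difference of exactly
  3.0 flags. One cell in the nurses' panel sits exactly at 3.0; with a
  single flag that judge is retained either way, so the data cannot
  discriminate, and the inclusive reading matches the stated rule.
* **Screening pool.** By default the ten original judges are screened
  (leave-one-out over "the other nine") and the replacement judge joins only
  at panel assembly. Screening over all eleven raters yields the same
  exclusions on both embedded panels; the package exposes the pool as an
  argument rather than hard-coding either choice.
* **Ties.** Every judge meeting the criterion is excluded — there is no
  "worst offender only" selection. Raising $d$ or $m$ can only shrink the
  excluded set (a property the test suite checks).
* **No iteration.** Screening runs once; the panel is not re-screened after
  exclusion. Replacement judges are supplied data, not recruited logic.

## Rounding: computation vs display

All statistics are computed, stored and compared at full precision;
rounding exists only in the rendering layer. Two conventions coexist
because published validation tables are not internally uniform: V and
confidence-bound columns are conventionally **truncated** at 2 decimals
(0.925 prints as 0.92, 0.709 as 0.70), while descriptive statistics round
**half-up** (11.757 prints as 11.8). `render_report()` defaults to
truncation for the coefficient columns and half-up for means; both, plus
full precision, are selectable. The questionnaire-level summary of the
physicians' panel is a visible consequence: its mean V of 0.8475 prints as
0.84 under truncation but 0.85 under half-up — the embedded study prints
0.84. The truncation helper adds an epsilon of 1e-8 before flooring so that
values like 0.85, not exactly representable in binary, do not truncate to
0.84.

## The two readings of the nurses' panel

Three rows of the published per-item summary are internally inconsistent
with the published raw ratings. For two of them (items 15 and 30 of the
nurses' questionnaire) the summary row is impossible on its face (the
frequencies sum to 9 and 1 rather than 10) and the ratings are consistent
with the printed mean and V, so nothing needs deciding. But for nurses'
items 26 and 27 the raw table and the summary disagree substantively: the
ratings as printed give $V = 0.75$ and $V = 0.725$ (the latter **failing**
the 0.75 threshold), while the summary prints $V = 0.77$ for both,
consistent with two single-cell corrections (expert 3, item 26: 2→3;
expert 8, item 27: 1→3). The package refuses to silently prefer either
reading: `load_fixture("nurses")` returns the table verbatim and
`load_fixture("nurses", variant = "reconciled")` applies the two
corrections. Only the reconciled reading reproduces the published
questionnaire-level range (0.77–1.00) and the claim that all items
validated; both readings give a mean V that prints as 0.89. The physicians'
panel is identical under both variants.

## The synthetic generator

`simulate_panel()` emulates the data-generating situation the pipeline
assumes: high-consensus ordinal ratings with occasional strongly discordant
judges. Each rating is

$$ r_{ij} = \operatorname{clamp}\big(\operatorname{round}(\mu_j + \varepsilon_{ij})\big),
\qquad \varepsilon_{ij} \sim \text{(symmetric, SD } \sigma), $$

with Gaussian noise by default (a uniform alternative with the same SD is
available; the generator's contract is symmetry plus scale, not a specific
family). A deviant judge's answer to an item is, with probability
$p_{\text{dev}}$, replaced by $\operatorname{clamp}(\operatorname{round}(\mu_j - \delta))$
— *low-ball* deviance, because in the embedded panels every flagged cell is
a rating of 1 against a 4–5 consensus. Rounding is R's
round-half-to-even; the oracle computations in the test suite use the same
convention.

Defaults mirror the embedded study's conditions: 10 experts, 30 items, 1–5
scale, item relevances $\mu_j$ drawn uniformly from $[4, 5]$ (the fixtures'
item means lie in 4.1–5.0), $\sigma = 0.5$ (reproducing the observed
concentration of ratings on $\{4, 5\}$ with occasional 3s), one deviant
judge, $\delta = 3$, $p_{\text{dev}} = 0.3$ (the observed discordant judges
deviated on 2–4 of 30 items; 0.3 puts the expected count a little above the
exclusion boundary of 2 so that both outcomes occur). Draws happen in a
fixed order (relevances, noise, deviant selection, deviance coin flips), so
configs that differ only in contamination share the same clean panel at the
same seed — that is how `screening_operating_characteristics()` measures
the V bias screening leaves relative to the uncontaminated panel. Replicate
$r$ of the operating-characteristics harness reseeds at `seed + r - 1`, so
enlarging the replicate count never perturbs earlier replicates.

What the generator does **not** emulate: item-specific rater biases,
correlated errors across items within a judge, mixed scales across items,
strategic or adversarial rating, and missingness (the data model rejects
incomplete panels outright). Passing simulation tests therefore show the
pipeline's behaviour under an idealised high-agreement regime, not its
robustness to such structure in real panels.

A property worth knowing before relying on the screening rule: with a flat
relevance of 4.5 and $\sigma = 0.5$, a deviant at $\delta = 3$ lands about
2.5 points from the leave-one-out consensus — **below** the 3-point
threshold — so the rule's sensitivity in that regime is essentially zero
(the test suite pins it against an independently computed Monte-Carlo
value). The rule detects judges who deviate from a *strong* consensus (the
fixtures' flagged cells all sit 3.1–3.7 points out); it is not a general
outlier detector, and users simulating their own designs should check the
operating characteristics at their expected consensus level. Sensitivity is
monotone in both $\delta$ and $p_{\text{dev}}$, and with no injected
deviants the false-exclusion rate under the default generator is far below
5%.

## Numerical and degenerate-input choices

* Threshold comparisons in screening use an epsilon of 1e-9 so that
  differences that are exactly 3 in rational arithmetic (leave-one-out means
  are multiples of $1/(p-1)$) are not lost to float error; no attainable
  difference lies within 1e-9 of the threshold without being exactly on it.
* `score_ci()` clips endpoints into $[0, 1]$ and orders them around V;
  at $V \in \{0,1\}$ the closed form collapses exactly ($U = 1$ when
  $V = 1$).
* Empty rating vectors are an error for `aiken_v()` (V undefined) but valid
  for `rating_frequencies()` (all-zero counts).
* Panels need at least 2 experts; screening pools at least 2 (at least 3 in
  SD-multiple mode, where a leave-one-out SD needs two residual degrees of
  freedom); descriptives at least 2 profiles.
* Leave-one-out variances are floored at 0 before the square root to guard
  round-off.

## Problem sizes in the test suite

The suite reproduces the embedded study end-to-end (all 60 item rows, both
screenings, all headline summaries), checks the score-interval inversion
identity to 1e-9 on 200 random configurations, V bounds and the
frequency-route equivalence on 1000 random rating vectors, screening against
a plain-loop brute-force oracle on every panel shape up to 5×5 over a
3-category scale, and the operating-characteristics calibration at 500
replicates of the 10×30 generator — sizes chosen to exercise every code
path at desk scale while keeping the default run around half a minute.

## Known limitations

* Single scale per panel: items with heterogeneous category counts are out
  of scope.
* The screening rule is the published one; no robust alternatives
  (median-based consensus, iterated screening) are provided.
* No weighting of judges and no agreement coefficients beyond Aiken's V
  (no kappa, ICC, or CVI variants).
* The score interval treats $nk$ ordinal steps as independent Bernoulli
  trials; that approximation is the method's own, inherited deliberately.
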