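---
title: "Bounding adaptive AI-triaged breast-MRI screening: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding adaptive AI-triaged breast-MRI screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscreen)
```

## The policy and its two metrics

Breast-MRI screening can run an abbreviated protocol (fast, but every
radiologist flag forces a recall visit for the full protocol), a full
protocol (no recalls, but slow for everyone), or an adaptive hybrid: every
exam starts abbreviated, and an AI model decides on the spot whether to
continue with the remaining full-protocol sequences. Two quantities
summarise a policy per screened person:

* **Recall rate (RR)** — the fraction of people the radiologist flags on
  the abbreviated images who were *not* already given the full protocol at
  the first visit, and must therefore return.
* **Expected protocol duration (EPD)** — mean scanner seconds per person,
  counting recall visits.

For the adaptive policy these are not point-identified: the radiologist's
and the AI's marginal operating points (sensitivity, specificity) say
nothing about how often they flag the *same* person. The package therefore
computes sharp lower/upper limits.

## Model

All computation is per person (probabilities, a cohort of size one);
expected counts for a finite cohort are probabilities times the size. This
is a deliberate design choice: the duration formula as usually written
mixes counts with a rate inside one bracket, and the probability form is
the dimensionally consistent reading that reproduces every regime result.
A reader with sensitivity $Se$ and specificity $Sp$ at prevalence $p$ has
cells $tp = p\,Se$, $fn = p(1-Se)$, $tn = (1-p)\,Sp$, $fp = (1-p)(1-Sp)$.

With $\omega$ the probability that both readers flag the same person,

$$\mathrm{RR} = tp_{rad} + fp_{rad} - \omega, \qquad
\mathrm{EPD} = t_{full}\,(tp_{ai} + fp_{ai} + \mathrm{RR}) +
              t_{abbr}\,(tn_{ai} + fn_{ai}).$$

A recalled person is charged $t_{abbr}$ for the first visit and $t_{full}$
for the recall visit. (One could argue the recall visit needs only the
missing sequences; we follow the full-visit accounting, which is the
conservative reading of the duration formula — see *Limitations*.)

Agreement can only happen within a disease stratum — a true positive of
one reader cannot coincide with a false positive of the other — so the
feasible range of $\omega$ is the sum of per-stratum Fréchet–Hoeffding
bounds:

$$\omega_{\max} = \min(tp_{rad}, tp_{ai}) + \min(fp_{rad}, fp_{ai}),\quad
\omega_{\min} = \max(0,\, tp_{rad}+tp_{ai}-p) +
                \max(0,\, fp_{rad}+fp_{ai}-(1-p)).$$

$\omega_{\max}$ gives the best case (lower RR and EPD limits),
$\omega_{\min}$ the worst case. These bounds are *sharp*: the cohort
simulator (below) attains them. The stratified form is the only
construction consistent with all the regime boundaries the model exhibits
(kinks at 90%, 10%, 8%, 92% and 80% under the default parameters).

RR is always enveloped by the baselines ($0 \le \mathrm{RR}_{lower} \le
\mathrm{RR}_{upper} \le tp_{rad}+fp_{rad}$); EPD is *not* — the adaptive
policy can beat the abbreviated-only EPD (people flagged up front skip the
recall) and can exceed the full-only EPD (recalled people are scanned
twice).

## Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `rad_sensitivity_abbr`, `rad_specificity_abbr` | 0.90, 0.92 | fraction | radiologist on abbreviated images |
| `rad_sensitivity_full`, `rad_specificity_full` | 0.92, 0.95 | fraction | radiologist on full protocol; carried for completeness, unused by the limit formulas |
| `t_abbr`, `t_full` | 262, 776 | s | protocol durations |
| `prevalence` | 0.0146 | fraction | malignancy rate in screening |
| `ai_sensitivity`, `ai_specificity` | 0.80 | fraction | AI operating point where not swept |
| `band_interval` | [0.75, 0.91] | fraction | literature agreement-accuracy interval (mean 83.4%, n = 14) |

The 80% convention for the non-swept AI parameter is stated for the
radiologist sweeps only; we adopt it for the AI sweeps as well (it is the
only convention on offer, and it is configurable). Configuration files
accept percentages (92) or fractions (0.92); everything is normalised to
fractions on load to prevent silent 100× errors.

## Sweeps, breakpoints, numerical choices

Every metric is piecewise linear along any single parameter, so sweeps use
1001 uniform grid points (durations: half-to-double the default).
`detect_breakpoints()` flags grid points whose second difference per grid
step exceeds a threshold — $10^{-8}$ for probability curves, $10^{-5}$ for
second-scale curves, separating true kinks from arithmetic noise by many
orders of magnitude — and then refines each bracket on the *analytic*
curve by quarter-point scanning: split the bracket in four, keep the two
segments flanking the largest slope change, repeat until the bracket is
below $10^{-9}$. We chose this over the textbook affine-midpoint bisection
because the latter mis-classifies a kink that lands exactly on a probed
midpoint (which happens systematically here, since kinks sit at round
parameter values that uniform grids hit exactly).

Equality tolerances elsewhere: $10^{-12}$–$10^{-9}$ on probabilities,
$10^{-6}$ s on durations; the arithmetic is closed-form throughout, with no
iterative solvers. Degenerate inputs are kept total: prevalence 0 or 1
zeroes the corresponding stratum's overlap; `t_abbr > t_full` is allowed in
sweeps with a warning.

## The "most likely" band

The theoretical envelope is wide; to indicate where an AI trained to
emulate radiologist decisions would plausibly operate, `likely_band()`
converts an agreement-accuracy interval $[q_{lo}, q_{hi}]$ (default
0.75–0.91) into band curves. The construction behind the published figures
is not defined anywhere we could follow, so the package documents two
interpretations and treats the printed summaries ("between 1% and 2%"
recall, 310–410 s) as vicinity checks only:

* **emulation** (default): the AI reproduces each radiologist decision
  independently with per-person agreement $q$, so
  $\omega = q\,(tp_{rad}+fp_{rad})$ and the AI flag rate is
  $q\,(tp_{rad}+fp_{rad}) + (1-q)(1-tp_{rad}-fp_{rad})$; RR and EPD follow
  the formulas above, and the band is the envelope over $q$ (both metrics
  are linear in $q$, so endpoints suffice). Chosen as default because
  emulating the radiologist's recall decision, not maximising standalone
  accuracy, is what makes the adaptive policy work.
* **restricted-limits**: the envelope of the theoretical limits over AI
  operating points confined to $[q_{lo}, q_{hi}]^2$ (a swept AI parameter
  keeps its grid value), evaluated on a 21-point grid per axis.

Either band is clipped to the theoretical limits at every grid value. A
consequence worth knowing: perfect emulation ($q = 1$) collapses the raw
band to the global best case, and clipping then maps it onto the
theoretical *lower limit* of whatever configuration is on the axis — which
is zero only where the AI sensitivity reaches the radiologist's. With the
defaults the emulation band gives RR 0.83%–2.3% and EPD 370–432 s (the raw
EPD endpoint 353 s is clipped up to the 80%/80% best case), i.e. a 44%–52%
duration reduction against the full protocol.

## The cohort simulator: what it emulates and what it does not

`simulate_cohort()` generates per-person records (disease, radiologist
flag, AI flag). Disease is Bernoulli at the configured prevalence; within
each stratum the 2×2 joint flag table has the marginals implied by the
operating points and a "both flag" cell set by the coupling: a Fréchet
extreme, stratum-independence, or a fixed total overlap realised by linear
interpolation between the extremes (one mixing weight reproduces any
feasible target exactly). Two sampling modes:

* `multinomial` — seeded random draws; marginals converge at $1/\sqrt N$.
* `expected_counts` — deterministic largest-remainder rounding within each
  stratum, the "both flag" cell served first, so totals are exact and
  integer-valued expectations are reproduced exactly. This mode is the
  oracle used to validate the analytic bounds bit-for-bit at $N = 10^6$.

`validate_bounds()` runs the two extremes plus random feasible couplings
and reports containment and attainment; it computes metrics from the cell
counts directly rather than materialising $10^6$-row data frames per
coupling, purely for speed — `empirical_metrics()` on the expanded records
gives identical numbers.

The simulator emulates *none* of the structure of real screening data
beyond these three binary variables: no reader drift or inter-reader
variability, no lesion-size or BI-RADS-category structure, no dependence
of radiologist performance on the AI's decision, no alternative follow-up
pathways (ultrasound, biopsy). A green oracle test therefore establishes
that the analytic algebra and its implementation agree — not that the
model describes any clinic.

## Limitations

* The recall-visit cost charges a full protocol per recall; if recalled
  people instead received only the missing sequences, adaptive EPD upper
  limits would drop. The model keeps the conservative accounting.
* The radiologist's sensitivity is assumed identical on abbreviated and
  full images; the full-protocol operating point (92%/95%) is carried in
  the configuration but plays no role in the limits.
* The agreement interval (75%–91%) summarises heterogeneous literature;
  the band is an indication, not a confidence region, and its published
  construction is ambiguous (two interpretations are shipped).
* All results are per-person expectations of a mathematical model; no
  claim about real-world clinical performance follows from them.
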