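---
title: "Screening rice varieties for potassium efficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening rice varieties for potassium efficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kscreen)
```

## The screening problem

Potassium-deficient paddy soils limit rice yield across much of East Asia,
and breeding K-efficient varieties requires mapping populations built from
parents with large, reproducible differences in low-K tolerance. Candidate
parents are screened in hydroponic culture: seedlings of many varieties are
grown across a ladder of medium K$^+$ concentrations, and three questions
are asked of the data.

1. **At which K concentration do genotypes separate best?** Too little K
   and no genotype can express its advantage; too much and the selection
   pressure disappears. The separating power of a level is measured by the
   coefficient of variation (CV) of each trait across varieties at that
   level, and the screening concentration is chosen where CV peaks.
2. **Which varieties are tolerant, which sensitive?** Because varieties
   differ constitutively in stature, absolute trait values are unfair
   comparators; each trait is first divided by its own value at the
   K-replete reference level (40 mg/L), and varieties are ranked by these
   *relative* values under low K.
3. **Is the difference between the chosen extremes real?** Replicate-level
   paired t tests per trait and level, annotated with the conventional
   `*` / `**` / `***` star levels.

Alongside the growth screen, a panel of potassium-efficiency indices
computed from tissue K concentrations and dry weights characterizes *why*
a tolerant variety tolerates: uptake (absorption efficiency and rate),
long-distance transport (translocation rates between root, sheath and
blade), partitioning (distribution rate), economy (utilization
efficiency), and responsiveness (response index).

## Data model and aggregation

The unit of observation is one plant: height, root length, root number,
fresh and dry weights of root / sheath / blade, and tissue K
concentrations (g K per 100 g dry weight) of the three tissues. The
canonical exchange format is a tidy CSV, one row per plant
(`trial_columns()` gives the schema).

Replication is at the tray level: each (variety, concentration) cell has
three replicate trays of six plants. Aggregation is therefore two-stage —
plants are averaged within a replicate, and treatment statistics (mean,
sample SD, n = 3) are taken across replicate means. The paired t tests pair
the two varieties by replicate index, giving n = 3 and df = 2; this is the
replication structure the trial actually has, and pooling the 18 plants
instead would overstate the degrees of freedom. Whether published treatment
means in this field are replicate-mean averages or pooled-plant averages is
usually not stated; the two-stage choice here is deliberate and affects
only SDs, not means (cells are balanced).

Missing cells are reported by `validate_trial()`, never imputed; the index
report and the significance table refuse to run on incomplete cells they
need.

## The index panel

With $q_t$ the K concentration (g/100 g) and $w_t$ the dry weight (g) of
tissue $t$, per-tissue K mass is $m_t = q_t w_t / 100$; aboveground mass
$m_{ab} = m_{sheath} + m_{blade}$; whole-plant K concentration
$q_{plant} = 100\, m_{tot} / w_{tot}$ (dry-mass-weighted by default;
an arithmetic three-tissue mean is available via `tissue_mean`). The panel:

| Index | Definition | Notes |
|---|---|---|
| KAE | $q_{plant} / c$ | mixed units by convention; undefined at $c = 0$ |
| KA  | $m_{tot}$ | K accumulation (reported relative: RKA) |
| KAR | $(m_{tot}^{40} - m_{tot}^{1}) / [100 \cdot 28 \cdot (w_{root}^{40} + w_{root}^{1})/2]$ | uptake per unit root mass per day; 100 is the g/100 g scale, 28 d the culture duration (both arguments) |
| KT-RTA | $q_{ab} / q_{root}$ | $q_{ab}$ = dry-mass-weighted aboveground concentration |
| KT-RTS | $q_{sheath} / q_{root}$ | root-to-sheath translocation |
| KT-STB | $q_{blade} / q_{sheath}$ | sheath-to-blade translocation |
| KD  | $m_{ab} / m_{tot}$ | in $[0,1]$ |
| KUE / KUEA | $w_{tot} / m_{tot}$, $w_{ab} / m_{tot}$ | g DW per g K; KUEA < KUE |
| KRI | $(w_{tot}^{4} - w_{tot}^{1}) / 3$ | growth response per mg/L between the two low levels |

`index_report()` assembles 24 parameters: the absolute values above at the
very-low (1 mg/L) and low (4 mg/L) levels plus their `R`-prefixed
counterparts, each the level value divided by the 40 mg/L reference value.
Two consequences worth noting: relative values are ratios of treatment
means (a per-replicate mode exists for uncertainty work but is not the
default), and because KAE divides by the *medium* concentration, a variety
with identical tissue data at 1, 4 and 40 mg/L has RKAE-1K = 40 and
RKAE-4K = 10, not 1 — the medium concentrations do not cancel. Useful
exact identities, asserted in the test suite: KT-RTS × KT-STB =
$q_{blade}/q_{root}$; KT-RTA always lies between KT-RTS and
KT-RTS × KT-STB (a mixture bound); KUEA/KUE = $w_{ab}/w_{tot}$.

## CV screening and the optimal concentration

`cv()` is $100 \cdot s / \bar{x}$ with the sample SD — the standard
definition. Method descriptions occasionally print the inverted form
(mean over SD); that statistic would *grow* without bound as genotypes
converge at saturating K, the opposite of the observed collapse of
discriminating power, so the package treats the inversion as typographic
and offers it only as `formula = "printed"` for forensic comparison.

`optimal_concentration()` takes the per-trait argmax of the CV profile and
returns the modal argmax across traits as the consensus, breaking ties
toward the lower concentration (a cheaper and more stringent screening
medium). Levels at or above the reference are excluded from candidacy by
default (`exclude_saturated`): a level that saturates every genotype
exerts no selection pressure, whatever its CV noise happens to be. Cells
whose across-variety mean is zero are flagged undefined and are never
candidates.

## Tolerance ranking and the parent pair

The ranking uses three traits — plant height, fresh sheath weight, fresh
blade weight — relative to the reference, averaged over the low-K subset
of levels. The default subset is the strictly positive levels below half
the reference ({1, 2, 3, 4, 5, 10} mg/L on the default grid): the 0 mg/L
starvation control carries essentially no genotype signal (all varieties
are equally prostrate), and levels near the reference are already
saturating, so both ends would only dilute the contrast with noise.

Varieties are ranked per trait (rank 1 = largest mean relative value);
the overall score is the mean rank, and the *consistency* score is
$1 - \mathrm{range(ranks)}/(n-1)$ — 1 when a variety occupies the same
rank on all three traits, 0 when it swings from first to last. The
tolerant parent is the best overall score among varieties with
consistency $\ge \theta$ (default $\theta = 0.7$, i.e. ranks may spread
over at most ~30% of the field), the sensitive parent the worst such; a
genotype that excels on two traits but collapses on the third is exactly
the kind of unstable phenotype the filter is meant to keep out of a
mapping cross. If nobody reaches $\theta$ the threshold relaxes to the
maximum attained, with a warning. The verbal criterion this formalizes —
"difference and consistency" across traits — has no published numeric
form; $\theta = 0.7$ and the rank-range score are this package's
formalization, and both are arguments.

Significance annotation is per cell with no multiple-testing correction by
default, matching how such star tables are conventionally reported; Holm
correction over the whole table is one flag away.

## The synthetic trial generator

There is no public per-plant dataset for this protocol, so the package
ships a generator whose defaults *are* the study conditions: 12 varieties,
K grid {0, 1, 2, 3, 4, 5, 10, 20, 40, 60} mg/L, 3 × 6 replication, 28 d,
with planted tolerance scores $s_v$ evenly spaced on $[0, 1]$.

Growth traits follow a saturating response
$\mu_v(c) = T_{max}\,[b + (1-b)\,(c+\epsilon)/(c+\epsilon+K_{50}(1-\gamma s_v))]$:
tolerant varieties half-saturate at lower K. Every per-plant value
multiplies an independent lognormal factor with log-sd $\sigma$
(default 0.05, a realistic ~5% relative measurement error for seedling
morphology). $\epsilon = 0.05$ mg/L keeps the starvation level alive but
minimal, as four-week survival at 0 mg/L requires. Root K concentration
saturates separately ($Q_{min} = 0.3$, $Q_{max} = 3.5$ g/100 g,
$K_q = 8$ mg/L); the sheath:root concentration ratio is
$r_0 + \delta s_v K_{50}/(c + K_{50})$ capped at $r_{cap}$, so tolerant
varieties translocate relatively more K to the shoot under low K — the
physiological signature the index panel is supposed to detect; blade K is
a fixed 1.1 × sheath. Dry weights are fresh weights times per-tissue
dry-matter fractions (12–20%), which makes dry ≤ fresh true by
construction.

Default response parameters are $b = 0.10$, $K_{50} = 10$ mg/L (all six
growth traits), $\gamma = 0.70$, chosen once, on three grounds:

* **The reference must saturate.** Relative-value screening assumes every
  genotype is near its plateau at 40 mg/L; with $K_{50} \le 10$ the
  slowest genotype sits at ≥ 80% of its maximum there. (If $K_{50}$
  approached the reference the relative values would invert — sensitive
  genotypes, far from saturation at 40, would show *higher* ratios — and
  the design would be self-defeating.)
* **Near-linear low range.** Below ~10 mg/L the response is visually
  close to linear, matching how relative growth curves in such screens
  look.
* **Recoverable truth.** Under these defaults the noise-free
  between-variety CV peaks at 2 mg/L for every growth trait, and the full
  pipeline recovers that planted optimum and the planted extreme pair in
  well over 90% of seeds at $\sigma = 0.05$ (98% and 94% over seeds 1–50;
  `analysis/04_recovery.R` reproduces this).

The planted optimum falling at 2 mg/L rather than, say, 4 mg/L is a
property of this response family with evenly spaced scores: the CV surface
of a saturating family is quite flat between neighboring grid points
1–5 mg/L (differences of well under one CV point, against ~0.5 CV points
of sampling noise per cell at this replication), so the generator plants
its optimum where the family actually puts it instead of pretending to a
sharper peak than the model can produce. Real screening data can and do
peak elsewhere in the low range; recovering *whatever* `planted_truth()`
declares is the meaningful end-to-end check.

What the generator deliberately does not model: variety-specific stature
($T_{max}$ is common, so CV on absolute and relative traits coincide up to
reference noise), tillering and phenology, tray/position effects,
replicate-level (as opposed to plant-level) noise, mortality, and any
genotype × concentration interaction beyond the single tolerance score.
Passing the recovery tests therefore shows the *statistics* behave —
it does not validate the biology of any particular real trial.

## Numerical choices and degenerate inputs

* Sample (n−1) SD throughout; CSV serialization uses `%.17g`, and parsing
  uses base R's correctly-rounded reader, so tables round-trip bit-exactly.
* CV cells with zero mean are flagged, not dropped; `cv()` needs ≥ 2
  values.
* Argmax/argmin ties break toward the lower concentration.
* Paired t with all-zero differences is flagged degenerate (p = 1, no
  stars); zero-SD nonzero differences give $t = \pm\infty$, p = 0.
* KAE excludes the 0 mg/L level by definition; KAR requires nonzero root
  mass; the index report names any missing treatment cell it needs.
* `generate_trial()` is bitwise deterministic in `(design, params, seed)`.

## Problem sizes

The default trial is 2,160 plants (12 × 10 × 3 × 6); a full pipeline run
(simulate → summarize → CV → ranking → significance → indices) takes
about a second, and the 50-seed recovery experiment under a minute. These
sizes are the study conditions themselves, not downsampled stand-ins.

## Known limitations

* The consistency threshold $\theta = 0.7$ and the low-K subset rule are
  formalizations of a verbal criterion; both are exposed as arguments and
  sensitivity to them should be checked on real data.
* df = 2 paired tests have little power individually; the star table is
  descriptive, and the uncorrected default inflates familywise error
  across its 60 cells (use `correction = "holm"` for confirmatory reads).
* The KAR scale constant (100 × days) follows the conventional printed
  formula; published KAR values are only comparable if they used the same
  convention, which is why both factors are arguments.
* With a single tolerance score driving both growth and translocation,
  the generator cannot produce varieties that grow well but translocate
  poorly; real panels can, and the index report is the tool that would
  reveal them.
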