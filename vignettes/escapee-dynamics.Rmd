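---
title: "Methods: hybrid classification, relative survival, and eco-genetic invasion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid classification, relative survival, and eco-genetic invasion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feralsim)
```

feralsim studies what happens to the offspring of escaped farmed Atlantic
salmon (*Salmo salar*) in the wild. It has three linked parts: a synthetic
survey generator, a genetic-class assignment and relative-survival pipeline,
and an individual-based eco-genetic population model. This vignette explains
the science behind each part, the assumptions made, the tunable parameters,
and where the design was genuinely open.

## 1. The six genetic classes and their genotype distributions

Two or three generations after an escape event, a river holds a mixture of
pure wild fish, pure feral fish (wild-born offspring of two escapees),
first- and second-generation hybrids (F1, F2), and backcrosses to either
side (BCW, BCF). With a biallelic SNP panel and two baseline allele
frequency sets — wild (`p_w`) and farm (`p_f`) per locus — each class
implies, by Mendelian segregation of its defining cross, the expected
proportion of loci at which an individual carries two wild-derived alleles,
one from each baseline, or two farm-derived alleles:

| class | both wild | one each | both farm |
|-------|-----------|----------|-----------|
| WILD  | 1         | 0        | 0         |
| FERAL | 0         | 0        | 1         |
| F1    | 0         | 1        | 0         |
| F2    | 1/4       | 1/2      | 1/4       |
| BCW   | 1/2       | 1/2      | 0         |
| BCF   | 0         | 1/2      | 1/2       |

Mixing the three category-conditional Hardy–Weinberg draws with these
proportions gives a closed-form per-locus genotype distribution per class
(`genotype_class_probability()`). Per-locus independence (unlinked,
selectively neutral markers in linkage equilibrium within baselines) lets
log-likelihoods add over loci.

**Classifier.** `classify()` is a plug-in Bayes classifier: posterior
proportional to prior times likelihood, uniform prior over the six classes,
assignment only when the top posterior reaches a threshold (default 0.8).
This deliberately replaces a Markov-chain mixture sampler that jointly
re-estimates baseline frequencies: with large, centred baselines the
plug-in likelihood is an excellent approximation, and it is deterministic
and unit-testable. Two numerical choices matter:

* a per-locus probability floor of `1e-9`, so that a single genotyping
  error at a diagnostic locus (observed duplicate-discordance rates are in
  the 0.01–0.17% range) cannot veto a class with `-Inf`;
* max-log stabilisation before exponentiating posteriors.

Missing genotypes are skipped as uninformative; individuals missing every
locus are rejected. Posteriors are invariant to locus order and to loci
with `p_w = p_f` (tested properties).

## 2. The synthetic survey generator

The generator emulates a multi-river electrofishing survey of juvenile
salmon (parr) in the years following a large escape:

* **Panel**: 95 biallelic loci whose wild–farm frequency difference is
  drawn uniformly on [0.3, 0.7] — the regime of a panel pre-selected to
  discriminate farm from wild, for which six-class accuracy lands above
  90% at the 0.8 threshold. Frequencies are clipped to [0.02, 0.98] by
  default (no perfectly diagnostic loci, as in real panels).
* **Age structure**: fish are binned by fork length — young-of-year (YoY)
  up to 70 mm, 1+ at 71–110 mm, 2+ above 110 mm — and synthetic lengths
  are drawn uniformly within the bin (only bin edges are identifiable from
  field practice; the analysis never uses within-bin position).
* **Cohort dynamics**: each river starts at a class mixture (default 72%
  wild, 10% feral, 10% F1, 8% later-generation classes — the composition
  regime of an invaded system the year after a large escape) and the
  mixture of a cohort at the next age step is the current mixture times
  per-class survival multipliers `true_w`, renormalised. Generation is
  mixture-level rather than individual-tracking: the downstream estimator
  consumes proportions only, so individual fates add nothing but cost.
  The default multipliers (`default_true_w()`) put feral at 0.15 and F1 at
  0.81 — the field point estimates — and extend the remaining classes on
  an ancestry gradient (F2 0.6, BCW 0.95, BCF 0.3).
* **Noise**: genotyping error is modelled as uniform replacement of the
  call with probability ~0.15% (duplicate-genotyping discordance is the
  only observable, and it identifies a replacement rate, not an error
  mechanism), plus ~0.5% missing calls.

What the generator does **not** emulate: linkage disequilibrium within
baselines, river-specific baseline divergence (all rivers share one pair of
baselines), cohort-strength variation between spawning years, and
within-bin length distributions. Passing tests therefore show the pipeline
is correct under its own assumptions, not that real surveys meet them —
in particular, real inter-river genetic structure is the reason the field
protocol centres baselines per river batch.

Genepop is the interchange format (two-digit alleles, `Pop`-delimited
rivers, `0000` missing; the reader tolerates three-digit codes), with
id/river/year/length metadata as CSV.

## 3. Relative survival from within-cohort composition change

If a cohort is sampled at consecutive ages, a class's proportional change
`P(t+1)/P(t)` confounds overall mortality with class-specific mortality;
dividing by the wild class's change cancels the shared part. Per river and
age step the pipeline computes the per-class ratio, averages the included
rivers, and normalises by the wild average:

\[ w_c = \frac{\overline{R_c}}{\overline{R_{\mathrm{WILD}}}}, \qquad
   R_{c,r} = P_{c,r}(t{+}1)/P_{c,r}(t). \]

Exclusion rules follow field practice: rivers with fewer than 10 retained
individuals in either age class are excluded, as are rivers where the
class's starting proportion is zero (a zero denominator carries no
information about survival). Rivers excluded for one class stay eligible
for the others. Only wild, F1 and feral are estimated by default; the
second-generation classes are too rare for stable ratios and are an
explicit opt-in.

**Standard errors.** The source analysis reports only "standard error of
estimates across rivers". We take the SD over rivers of the
wild-normalised per-river ratios divided by √(rivers used). This gives the
wild class itself a nonzero SE (between-river spread of its own ratios),
matching the reported pattern of a wild SE near 0.1 despite `w = 1` by
construction. A delta-method alternative (`se_method = "delta"`)
propagates the two ratio-of-means uncertainties instead.

Overall (regional) class proportions weight each river by its axial length
— a proxy for habitat size that reduces the bias of equal-weighting small
rivers — and year-over-year change factors are ratios of those weighted
proportions. Composition figures drop groups with fewer than 5 assigned
fish; the survival estimator applies its own 10-fish rule.

## 4. The individual-based eco-genetic model

An annual-step, individual-based model of one river population:
parr0 → parr1 → parr2 → smolt (age 3) → one sea-winter → adult spawner,
with post-spawn (kelt) survival 0.1 allowing repeat spawning. Every fish
carries three independent sets of 21 unlinked diploid loci — one set each
for the embryo, juvenile and adult life stages — with wild/farm alleles.
Within a set, locus effects decline exponentially,
`raw_i = exp(-λ(i-1)) - exp(-20λ)` normalised to sum 1, so the 21st locus
is an exactly neutral marker. The genotypic value
`g = Σ w_i (dose_i/2) ∈ [0, 1]` maps linearly to phenotype: 1 reproduces
wild rates, 0 farm rates.

**Selection.** Stage survival interpolates linearly between farm and wild
endpoints: at parr0/parr1, `p = s · (RS + g_juv (1 - RS))` with the
scenario's relative-survival pair (low 0.075/0.13, calculated 0.15/0.26,
high 0.3/0.52); at sea, the adult gene set is selected with a fixed,
scenario-independent `rs_marine = 0.26` — relative survival differentials
in such systems are understood to be expressed substantially at sea, and a
fully neutral adult set would freeze post-invasion farm alleles in the very
gene set whose recovery the model is supposed to project. Growth is also
genotype-dependent: domestication selects for growth, so adult size scales
by `1 + 0.25 (1 - g_adult)`; larger farm-ancestry spawners deposit more
eggs and win more sirings, letting introgression feed back on reproduction
while survival selects against it.

**Reproduction.** Egg deposition is `1500 eggs/kg × female weight`; sires
are drawn per egg with weight `length^2`, escapee males discounted ×0.05,
escapee females ×0.3, and precocious parr1 males (probability 0.2) enter
the lottery with a further ×0.05 siring discount. Offspring inherit one
allele per parent per locus (free recombination — drift is explicit) and
are wild-born regardless of parentage; escapees themselves enter as
all-farm adults at a rounded 1:1 sex ratio.

**Density dependence** acts twice in fresh water. Egg-to-parr0 recruitment
is Beverton–Holt, `E[recruits] = s_egg E / (1 + E/K)` (Poisson-realised) —
the canonical salmonid stock–recruit form. Parr survival is additionally
adjusted for territorial crowding by `(1+θ)/(1+θ B/B_ref)` with θ = 4,
where `B` is the cohort's expected genotype-survivors and `B_ref` its
calibrated equilibrium value; the factor is exactly 1 at equilibrium (so
calibration is untouched), releases survivors when cohort-mates die young,
and compresses survival in crowded years. Without this second regulation
point, recruitment slots consumed by farm-ancestry fry that die of
selection would be permanently lost to wild production, and — contrary to
the system being modelled — weak-surviving (low-RS) invasions would crash
wild abundance hardest. With it, crash depth increases with the relative
survival of feral parr, and weak-survival invasions leave abundance nearly
untouched.

**Calibration.** `calibrate_stationarity()` adjusts the two overall wild
survival knobs (`s_egg`, then `s_marine` if needed) so mean adult
abundance over the last 50 of 200 zero-invasion years is 475 ± 10% across
5 replicates: a closed-form equilibrium solve gives the starting point and
a short stochastic bisection refines it. The demographic defaults describe
a small, grilse-dominated river (parr survivals 0.55/0.65/0.75, marine
0.2, K = 60,000 eggs, female return weight 2.5 kg), giving an equilibrium
parr0 cohort near 8,000 and about 18,000 fish alive — sizes at which the
full 27-cell scenario grid runs on a laptop in minutes.

**Scenarios and outputs.** The grid crosses invasion duration (10/50/100
years), magnitude (zero/intermediate/high, with annual counts chosen so
total invaders match: 500×10 = 100×50 = 50×100) and the RS pair, after a
100-year burn-in and before a 100-year recovery window. Yearly outputs
record adult abundance (wild-born plus escapees present at spawning), the
unweighted mean wild-allele frequency over the 21 adult-set loci among
adults, and the effect-weighted mean genotypic value of the same set (the
"sum of the genetic effects"). The two genetic series differ by design:
the weighted series recovers when the strongly selected leading loci are
purged; the unweighted series contains the neutral marker and a
near-neutral tail and is expected to plateau below baseline after heavy
introgression.

**Recovery criterion.** A run has recovered when the 10-year trailing mean
of a metric reaches 95% of its seed-paired zero-invasion baseline's
long-run mean and stays there for 10 consecutive years; time is counted
from the last invasion year. Applied to single replicates this criterion
is noise-inflated (a series hovering at the threshold waits long for a
clean decade), so `pool_replicates()` first averages the replicate
trajectories and recovery is read off the mean series — the analogue of
judging recovery from a smoothed trend over runs.

## 5. Design decisions that were genuinely open

* **λ = 1** for the effect decay. Only the shape (exponential, neutral
  last locus) is externally fixed. A near-flat profile (λ ≈ 0.25) makes
  every locus weakly selected, and neither abundance nor genetic effects
  then recover on observed-system timescales after invasion; λ = 1 puts
  ~63% of each set's effect on its leading locus, reproducing the regime
  of fast genetic-effect recovery with a slowly decaying neutral tail.
  Configurable for sensitivity analysis.
* **Per-river assignment batches share global baselines.** Real protocols
  centre baselines per river; the generator has no inter-river structure,
  so batching is preserved at the interface but is computationally
  equivalent to a pooled run.
* **Cohort tracking by length bins** (YoY in year 1, 1+ in year 2, 2+ in
  year 3), not marked individuals — exactly what repeated field sampling
  can do.
* **Which two parameters calibration turns**: egg survival and marine
  survival, the two knobs that scale overall wild productivity without
  touching the selection structure.
* **Escapee fertility** uses the same weight–fecundity curve as wild fish,
  then the 0.3 spawning-success multiplier.
* **Embryo-stage selection** defaults to neutral (`rs_embryo = 1`); no
  field estimate constrains it, and enabling it mostly duplicates parr0
  selection one step earlier.

## 6. Known limitations

* One river, no straying or metapopulation buffering; invasion pressure is
  a fixed annual pulse, not stochastic escape events.
* The annual step compresses within-year processes (temperature-driven
  growth, redd-level spawning) into stage transitions; the ~5-year
  life-cycle pipeline sets a floor on how fast abundance can respond.
* Abundance-recovery times read with the strict trailing-mean criterion
  run somewhat longer than visual loess-curve readings of the same
  trajectories; the package reports the criterion, not the eyeball.
* The classifier assumes known, centred baselines; with small or drifting
  baselines its accuracy overstates what a joint-estimation sampler would
  achieve on real data.
* Relative-survival ratios are slightly biased upward at small per-river
  sample sizes (Jensen's inequality on `1/P_t`); the estimator tests
  quantify this at the survey scales used.
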