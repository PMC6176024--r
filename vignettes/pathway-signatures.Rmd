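---
title: "Deriving stress-response pathway signatures and scoring chemical activation capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving stress-response pathway signatures and scoring chemical activation capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxsig)
```

## The problem

Cellular stress responses to xenobiotics are channelled through a small
number of transcription-factor programmes. `toxsig` works with three of
them: the xenobiotic response driven by the aryl hydrocarbon receptor
(AhR), the oxidative-stress response driven by Nrf2, and the ATF4 branch of
the integrated stress / unfolded-protein response. Given a large table of
condition-level log2 fold changes (log2FC over time-matched controls,
pooled from heterogeneous toxicogenomic studies), the package answers two
questions:

1. **Which genes respond to each pathway?** Derived empirically from the
   data produced by a handful of *pathway-specific activator* chemicals —
   compounds whose mode of action engages one pathway without directly
   engaging the other two (for example tunicamycin, an N-glycosylation
   inhibitor, for ATF4).
2. **Which chemicals activate each pathway, how selectively and how
   strongly?** Answered geometrically, by placing every chemical in a
   3-dimensional space whose axes are the pathways.

## Signature derivation

For a pathway with activators $a_1, \dots, a_m$ the derivation is:

1. Select all retained conditions of each activator (after the exposure
   filter, see below). For every gene $g$ with at least one value under
   activator $a_j$, compute the arithmetic mean $\bar{x}_{j}(g)$ of its
   available log2FC values.
2. Combine across activators by the unweighted *mean of means*
   $v(g) = \frac{1}{|J_g|}\sum_{j \in J_g} \bar{x}_{j}(g)$, where $J_g$ are
   the activators under which $g$ has data. This weights each reference
   chemical equally regardless of how many conditions it was tested in;
   with unequal condition counts it deliberately differs from the pooled
   mean over all conditions (demonstrated in the test suite). Genes with no
   data under any activator are excluded and reported, never imputed:
   a blank cell means "not measured", not zero.
3. Over the $v(g)$ of all genes with data, compute the mean $\mu$ and
   standard deviation $\sigma$, and keep the distribution tails:
   *activated* genes with $v(g) > \mu + k\sigma$ and $v(g) > 0$,
   *inhibited* genes with $v(g) < \mu - k\sigma$ and $v(g) < 0$, with
   $k = 2$ by default.

The candidate pool for every pathway is the full measured gene universe,
not each pathway's a-priori curated list: the curated pathway membership is
carried along as reporting metadata so that derived and curated membership
can be compared, but it plays no role in the computation. Genes appearing
in more than one pathway's signature are set apart into overlapping
signatures, giving the 7-zone Venn partition (three exclusive zones, three
pairwise overlaps, one triple overlap). Zone disjointness and coverage are
asserted on every run.

### Numerical choices

* $\sigma$ is the population standard deviation (divisor $N$); at the
  ~800-gene scale of realistic catalogs the difference from the sample
  estimator is negligible, and the choice is configurable
  (`sd_type = "sample"`).
* The threshold inequalities are strict, and signed: a value above
  $\mu + 2\sigma$ that is still negative (possible when $\mu$ is strongly
  negative) is not called "activated", and symmetrically for inhibited
  genes.
* If $\sigma = 0$ (all average activation values identical) the strict
  inequalities admit nothing; the signature is empty and a warning is
  raised.
* Within each signature section genes are ordered by decreasing $|v(g)|$;
  ties are broken alphabetically so output tables are deterministic.
* Genes covered by only a subset of a pathway's activators are averaged
  over the available activators (configurable to `require_all_activators`);
  only genes with no activator data at all are excluded.
* The multiplier $k$ (`sigma_mult`, default 2) is exposed for sensitivity
  analysis.

### Condition selection

Exposures longer than 24 h tend to produce mixed stress responses that
blur the attribution of transcriptional changes to a single initiating
pathway, so `filter_by_max_time()` drops them by default; the bound is
inclusive (24 h data are retained) and every filter emits a
`selection_report` with condition and value counts before and after,
because silent data drops in a multi-stage pipeline must be auditable.
Signatures can be stratified by experimental category (species, tissue,
in vitro/in vivo, dosing) via `category_key()`; a category in which a
pathway has no activator conditions yields an empty signature flagged
unavailable rather than an error, so sparse strata do not abort a run.

## Chemical activation capacity

Scoring uses only the *exclusive* signature genes of each pathway, so a
shared responder cannot credit several pathways at once. The CAC of
chemical $K$ for pathway $p$ is the pooled mean of all available log2FC
values over the chemical's retained conditions and the pathway's exclusive
genes. The three CACs place $K$ at a point in pathway space, defining the
vector $\vec{OK}$:

* **specificity** for pathway $p$ is $\cos\alpha_p = |v_p| / \lVert v
  \rVert$, the absolute cosine of the angle between $\vec{OK}$ and the
  $p$ axis;
* **potency** is the module $\lVert v \rVert$;
* the per-pathway **score** is their product, which algebraically equals
  $|v_p|$ (asserted to $10^{-12}$ in a property test).

A chemical is classified as a pathway-specific potent activator when
$\cos\alpha_p$ strictly exceeds the specificity cut-off (default
$1/\sqrt{3} = 0.57735$, the cosine of the direction equidistant from all
three axes), the module strictly exceeds the potency cut-off (default
0.5), and $p$ is the chemical's *nearest axis* (strictly largest cosine).
Ranked lists sort by decreasing score, ties alphabetical.

### Why the nearest-axis condition

The intent of the specificity cut-off is that a classified chemical is
closer to its pathway's axis than to the other two. The cut-off alone does
not guarantee that below $1/\sqrt{2}$: a chemical on a two-axis diagonal,
$v \propto (1, 1, 0)$, has cosine $1/\sqrt{2} \approx 0.707$ to *both*
axes, so with the $1/\sqrt{3}$ cut-off it would enter two lists at once.
Requiring the axis to carry the strictly largest cosine restores what
"specific" means geometrically and makes the three lists mutually
exclusive for any cut-off choice (verified over 1,000 random vectors in the
acceptance suite). A chemical whose cosines tie at the maximum is listed
nowhere; with continuous data this is a measure-zero event.

A related fragility is worth knowing about: the default cut-off sits
*exactly at* the equidistant cosine. A chemical whose true activation is
perfectly balanced across the three pathways has all three cosines equal
to $1/\sqrt{3}$ and is rejected by the strict inequality — but only with
exact arithmetic. Under any measurement noise, the largest of three
near-equal positive coordinates always satisfies
$\max_i v_i^2 > \tfrac{1}{3}\sum_i v_i^2$, so the nearest-axis cosine of a
balanced-but-noisy chemical lands strictly (if marginally) above the
cut-off, and a sufficiently potent non-selective chemical will be
classified to whichever axis the noise favours. The synthetic-data
acceptance checks measure this directly: balanced probes planted at
$(0.5, 0.5, 0.5)$ are rejected in the noiseless run and accepted under
noise, seed after seed. Screening applications that must exclude
non-selective actives should therefore raise the specificity cut-off above
the equidistant value (e.g. towards $1/\sqrt{2}$) rather than rely on the
boundary itself; the cut-off is a plain argument everywhere it is used.

### Degenerate inputs

* A zero CAC vector has undefined angles; such chemicals are reported with
  module 0, cosines 0, and can never classify.
* A chemical with no data for some pathway's exclusive genes gets an `NA`
  coordinate and is excluded from classification into a "not scorable"
  list: treating a missing coordinate as 0 would fabricate specificity for
  the remaining axes.
* Because specificity uses $|\cos\alpha|$, strong inhibitors (negative
  CACs) classify as specific; the signed CAC is carried through all
  outputs so activators and inhibitors remain distinguishable.

## The synthetic-data generator

Real multi-study fold-change compendia are not redistributable, so every
pipeline stage is validated against `generate_synthetic()`, an additive
signal-plus-noise simulator:

$$x_{c(k), g} = \sum_p a_p(k)\, e_p(g) + \varepsilon, \qquad
\varepsilon \sim \mathcal{N}(0, \texttt{noise\_sd}^2)$$

where $a(k)$ is chemical $k$'s true activation vector and $e_p(g)$ the
planted effect of pathway $p$ on gene $g$ (zero for background genes;
independent per member pathway for overlap-zone genes, with configurable
signs, since real overlap genes can disagree in sign between pathways).
Missing-cell injection and a heavier-tailed Student-t noise option exist to
stress-test the exclusion logic and the $2\sigma$ rule. All draws come from
one seeded stream in documented order, so datasets are exactly
reproducible.

`study_mimic_config()` fixes the generator at the scale of a realistic
consolidated study and is the configuration used by the acceptance checks:

* 800 background genes; 30 exclusive planted genes per pathway
  (27 activated, 3 inhibited, $|e| = 1$); overlap zones of 5 / 7 / 1 / 1
  genes, with the AhR–ATF4 overlap gene activated for AhR and inhibited
  for ATF4;
* `noise_sd = 0.1` per condition-gene cell;
* 160 chemicals: the five classical reference activators
  (Benzo(a)pyrene and Omeprazole for AhR, Potassium Bromate and Phorone
  for Nrf2, Tunicamycin for ATF4) at unit activation, one 0.8-magnitude
  selective probe per pathway, two balanced $(0.5, 0.5, 0.5)$ probes, and
  150 inert chemicals;
* four time points (2, 8, 24, 72 h), one condition each, all human liver
  in vitro — the 72 h conditions exist to exercise the exposure filter,
  leaving three conditions per chemical.

The activated-dominant planted signatures (27 up / 3 down) are a
deliberate choice: the CAC of a reference activator is the signed mean of
the planted effects over its 30 exclusive genes, $(27 - 3)/30 = 0.8$, so
unit-activation references and 0.8-magnitude selective probes clear the
0.5 potency cut-off with a clean margin. A half-up/half-down design would
drive reference CACs towards zero — an instructive reminder that the CAC,
as a signed mean over a mixed-sign gene set, partially cancels; users
deriving signatures from strongly inhibition-dominated responses
should interpret small modules accordingly.

With these defaults, desk calculation puts the background distribution of
combined activation values at SD $\approx 0.04$ (noise averaged over
3 conditions and up to 2 activators), while $\sigma \approx 0.2$ is
dominated by the planted tails, so the $2\sigma$ threshold
($\approx 0.45$) separates planted ($\pm 1$) from background genes almost
perfectly — the noisy-recovery acceptance check requires at least 90%
sensitivity and at most 2% background admission and observes essentially
100% / 0%.

**What the generator does not emulate:** probe-level microarray artefacts,
normalisation and batch effects, correlated noise across genes or
conditions, dose–response structure (dose labels are pass-through
metadata), or cross-species identifier ambiguity (gene symbols are opaque
harmonised keys). Passing the synthetic checks therefore validates the
*analysis logic* — selection, averaging, thresholding, partitioning,
scoring — not robustness to upstream measurement pathology.

## Problem sizes and runtime

The test and acceptance workloads are sized for quick desk runs: oracle
equivalence uses twenty 50-gene × 30-condition random matrices checked
against independent brute-force loops; recovery uses twenty seeds of the
904-gene × 160-chemical study mimic (a few seconds each); the geometry
property suite uses 1,000 random vectors. The complete suite runs in
about a minute.

## Known limitations

* Signature derivation rests entirely on the chosen activator chemicals
  being truly pathway-specific in the data at hand; the package can only
  report uncovered activators, not detect an ill-chosen one.
* Conditions are pooled without weighting by dose, time point or study of
  origin; a chemical tested mostly at ineffective doses is diluted.
* Removing overlap genes from scoring protects specificity but discards
  signal for pathways whose strongest responders are shared — a genuine
  trade-off, visible in the synthetic overlap zones.
* The $\mu \pm 2\sigma$ rule assumes the bulk of genes are unresponsive;
  on a dataset where most genes respond, $\sigma$ inflates and signatures
  shrink.
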