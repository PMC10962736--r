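---
title: "Methods: dependence analysis of mitochondrial stress signaling and rule-based morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dependence analysis of mitochondrial stress signaling and rule-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtisr)
```

## The problem

When mitochondria are stressed — by protein misfolding in the inner
membrane, by loss of mtDNA maintenance, or physiologically by cold-induced
uncoupled respiration in brown adipose tissue — the OMA1 protease cleaves
DELE1, which relays the signal to the cytosolic integrated stress response
(ISR) and reshapes nuclear gene expression. A central question for such a
relay is *attribution*: which of the many stress-induced expression changes
actually depend on the relay, and by how much?

`mtisr` implements the complete quantitative workflow for that question on
factorial stress-by-genotype designs:

1. **Differential expression** per two-group contrast (pooled-variance t
   tests, Benjamini–Hochberg FDR, fold-change + FDR DEG gates).
2. **Dependence classification**: a stress DEG is *modifier-dependent* when
   the knockout contrast (stress,KO vs stress,WT) passes the same gates with
   a fold change opposite to the stress effect — i.e. knockout reverts the
   response toward control — plus a continuous **percent dependence**.
3. **Signature derivation**: direction-consistent shared DEG sets across
   models, k-of-n dependent-gene intersections, cross-tissue overlap, and a
   cross-species overlap through an ortholog map and per-study fold changes.
4. **Morphometry** of instance-segmentation label masks: equivalent-ellipse
   axes and aspect ratios per mitochondrial profile, a nano-mitochondrion
   rule, and per-myofiber cross-sectional area (CSA) and mean intensity.
5. A **synthetic-data module** that plants all of the above with
   machine-readable truth tables, so every stage is verifiable end to end
   without any external download.

## The statistical model

Expression is analysed on the log2 scale. For a contrast between groups
$a$ and $b$ with $n_a, n_b \ge 2$ samples:

$$ t = \frac{\bar x_a - \bar x_b}{s_p\sqrt{1/n_a + 1/n_b}},\qquad
   s_p^2 = \frac{(n_a-1)s_a^2 + (n_b-1)s_b^2}{n_a+n_b-2}, $$

with a two-tailed p value on $n_a+n_b-2$ degrees of freedom and BH
adjustment across all genes in the matrix. A gene is a DEG when
$|\log_2 \mathrm{FC}| \ge \log_2 2 = 1$ **and** $q \le 0.05$ (both bounds
inclusive by default; a `strict` flag switches to strict inequalities for
workflows that quote the thresholds as `>`/`<`). No moderated-variance or
empirical-Bayes shrinkage is applied: the plain pooled-t model is the
procedure being reimplemented, and the synthetic-data noise model is matched
to it.

Degenerate contrasts are defined, not fatal: zero pooled variance with equal
means gives $t=0, p=1$; zero pooled variance with unequal means gives
$p = 0$ with a warning.

### Percent dependence

Writing $\ell_s$ for the stress log2 fold change (stress,WT vs control) and
$\ell_k$ for the knockout log2 fold change (stress,KO vs stress,WT), the
default definition is the log2-scale reversion ratio

$$ \mathrm{dep}\% = 100\,\frac{-\ell_k}{\ell_s}, $$

which is exactly 100 when knockout returns the gene to its control level,
0 when knockout changes nothing, above 100 for overshoot, and negative when
the knockout change is co-directional with stress. Values are reported
unclamped; dependence is `NaN` when $\ell_s = 0$.

A second, linear-scale definition is selectable
(`definition = "linear"`): the fraction of the linear-scale change from
control that is reverted,

$$ \mathrm{dep}\%_{\mathrm{lin}}
   = 100\,\frac{2^{\ell_s} - 2^{\ell_s+\ell_k}}{2^{\ell_s} - 1}. $$

This form also evaluates to 100 at full reversion for both up- and
down-regulated genes. A naive ratio of "percent change in the KO contrast
over percent change in the stress contrast" does *not* have that property
(the two percentages have different denominators), which is why the
log2-scale ratio is the package default and the rescaled linear form is the
documented alternative. The log2 definition is invariant to the baseline and
to any shift applied to all arms equally.

The dependence machinery is agnostic to what the matrix measures; it applies
unchanged to protein-abundance matrices on the log2 scale.

### Dependence calls

`classify_dependent()` emits one record per stress DEG and calls it
dependent iff (i) the KO contrast passes the same FC/FDR gates and (ii)
$\mathrm{sign}(\ell_k) = -\mathrm{sign}(\ell_s)$. A significant
co-directional KO change (amplification) is never dependent. The alternative
threshold definition, `threshold_dependent_set()`, keeps shared DEGs with
percent dependence $\ge$ 50 (inclusive, "at least 50%") in every model;
because a gene can sit above 50% dependence while its KO fold change is
still under the $|\log_2\mathrm{FC}| \ge 1$ gate, this set is typically a
strict superset of the significance-based core — the shipped three-model
fixture plants exactly that situation.

Heterozygous modifier animals are handled in the sample sheet (pooled with
wildtype into the modifier-intact arm), not in code.

## Signature derivation

`shared_degs()` intersects per-model DEG sets, by default requiring the same
direction in every model (the direction-consistent set is provably a subset
of the unconstrained one; a flag disables the requirement, and the choice is
documented rather than asserted as the original analyses' choice).
`k_of_n_dependent()` returns genes dependent in *exactly* k models, so the
n-of-n core and the "additional k-of-n" sets are disjoint by construction.
`cross_species_overlap()` maps signature genes through a one-to-one ortholog
table and keeps those whose **arithmetic** mean of linear fold changes
across study columns is $\ge$ 2 (inclusive); "averaged" is read as the
arithmetic mean, with a geometric-mean option. Genes missing from some
studies are averaged over the available ones and flagged `partial` rather
than dropped — the cohorts profile different platforms, and the flag keeps
the provenance auditable. Unmapped genes are excluded with a warning and a
count. All gene-set outputs are sorted lexicographically for deterministic
files.

## Morphometry conventions

Per label, the features come from the 2×2 second-central-moment matrix of
member pixel coordinates, with pixel centers at integer coordinates and
area = pixel count × (pixel size)². Axis lengths are $4\sqrt{\lambda}$ for
the two eigenvalues — the full major/minor axes of the equivalent ellipse,
the common region-properties convention — converted to nm; aspect ratio is
major/minor. The planted-truth generators use the same convention, and on
rasterized ellipses with minor semi-axis ≥ 8 px the recovered axes agree
with the planted geometry to about 2% relative error (the worst case sits
near that bound for small, near-circular profiles, where the two moment
eigenvalues are nearly degenerate).

The **nano-mitochondrion rule** is strict on both boundaries: minor axis
< 250 nm *and* aspect ratio < 1.5. Profiles at exactly 250 nm or exactly
1.5 are not nano. Labels under 4 pixels are flagged `degenerate` rather
than dropped; a label whose pixels form more than one 8-connected component
is flagged and warned about, not rejected (touching but distinct labels are
legitimate). Manual ultrastructural classes (cristal inclusions,
electrolucent profiles, OMM rupture, mitophagy, ...) are consumed as
annotation tables and tabulated as population frequencies; no image-based
detection is attempted, and segmentation itself is upstream of this
package.

`fiber_quantify()` applies the same area convention to myofiber masks
(CSA in µm²) and adds the mean intensity over member pixels;
`group_percent_difference()` is
$100\,(\bar m_{\mathrm{pos}} - \bar m_{\mathrm{neg}})/\bar m_{\mathrm{neg}}$
over annotated fibers, `NA` with a warning when a group is empty.

## The synthetic-data module

The generators are first-class, tested code, and their defaults *are* the
study conditions the analyses assume.

**Expression fixtures.** Three arms (control; stress, modifier intact;
stress, modifier KO) per model. Planted means: control $= \mu$, stress
$= \mu + \beta$, KO $= \mu + \beta(1 - d/100)$ for planted dependence
$d$; i.i.d. Gaussian noise on the log2 scale (SD 0.1 by default, matching
the pooled-variance t model; heavier-tailed noise is out of scope). Truth
tables derive the expected DEG/dependence flags from the planted means and
the configured thresholds only — noise never enters the expectations.
Replicate counts: 7 per arm for the brown-adipose preset (the one
comparison whose group size the source analyses state) and 6 per arm for
the heart and muscle presets, a documented package default chosen as a
typical microarray cohort size, not inferred from the original study.

Planted effects keep every decision quantity at least ~3 standard errors of
the estimated log2 fold change from its threshold
($\mathrm{SE} = \sigma\sqrt{2/n} \approx 0.058$ at $\sigma = 0.1$, $n=6$),
so recovery is robust to the seed, and noiseless mode recovers every flag
exactly. The preset structure:

* `preset_heart_threemodel`: 111 shared direction-consistent stress DEGs
  (51 dependent in all three models at 85% dependence; 6 at 68% dependence
  whose KO fold change of ±0.816 fails the gate — above the 50% cutoff but
  below strict significance-plus-reversion; 54 at 20% dependence), 39 genes
  dependent in exactly two models, 123 model-specific non-dependent DEGs
  per model (which puts each model's dependent fraction near 30%), and 500
  nulls.
* `preset_bat_coldstress`: 11 dependent genes spanning 70–97% dependence,
  25 weakly-dependent DEGs, 400 nulls.
* `preset_gastroc_overlay`: replants 32 of the 51 heart-core genes as
  dependent and the remaining 19 as sub-threshold trends (log2 FC 0.5),
  plus muscle-specific dependent genes — the cross-tissue overlap is
  32/51 = 63% by construction.

**Mask fixtures.** Planted ellipses are placed by rejection sampling on
enclosing circles (deterministic order under the seed, bounded retries,
failure is an explicit placement error) and rasterized at integer pixel
centers. The `preset_s59l_population` population (200 shapes, 10 nm/px)
plants exactly 22% nano profiles, with every planted minor axis and aspect
ratio at least 20% clear of the 250 nm / 1.5 boundaries so rasterization
error cannot flip a call.

**Fiber fixtures.** Fibers are a seeded raster-run tessellation: each fiber
occupies a contiguous run of pixels, with integer per-fiber pixel counts
jittered under the seed but constrained so each group's mean CSA equals its
planted value *exactly* (330.0 vs 446.9 µm² over 30 fibers per group at
1 µm² pixels by default). A Voronoi-style tessellation was considered and
rejected: with integer pixel areas it cannot hit planted group means
exactly, and exact planted-truth recovery is the point of the fixture.
Fiber shape plays no role in CSA or mean-intensity quantification. Planted
intensities are uniform per fiber with a group ratio of 2.712, i.e. a
percent difference of 171.2%.

**What the fixtures do not emulate.** No probe-level microarray structure,
array normalization, batch effects, or correlated noise; no image texture,
staining gradients, or segmentation errors; no partial-volume effects at
mask boundaries beyond rasterization itself. Passing tests therefore show
that the pipeline's logic and arithmetic recover planted structure under
its own statistical assumptions — not that those assumptions hold for any
particular real dataset.

## Numerical and design choices

* BH adjustment delegates to `stats::p.adjust(method = "BH")`; tests verify
  it against an explicit step-up oracle, and the q ≤ α set equals the
  classic rejection set on random instances.
* The pooled t statistic is computed vectorised from the closed form (one
  matrix pass per contrast) rather than via `t.test()`, so the
  zero-variance contract above is expressible; `t.test(var.equal = TRUE)`
  serves as the independent oracle in the tests.
* Gene ids are case-preserved strings; duplicate ids are an error (probe
  summarization is upstream).
* All randomness flows through explicit integer seeds; generators save and
  restore the caller's RNG state.
* Pipeline outputs are stamped with an MD5 hash of the analytic
  configuration (thresholds, definitions, seed — output paths excluded), so
  re-running a manifest reproduces files byte for byte.
* Problem sizes in the shipped analyses (a ~1000-gene three-model fixture,
  a 200-shape mask, 60 fibers) were chosen so every planted count is large
  enough to be structurally interesting while each analysis stage completes
  in seconds; they are package defaults, and all generators scale.

## Known limitations

* Percent dependence is a ratio of two estimated fold changes; for weak
  stress effects its sampling noise is large, and the package deliberately
  reports it only for stress DEGs unless asked otherwise.
* The dependence criterion is the two-contrast intersection, not an
  interaction-term linear model or causal mediation analysis; that is the
  procedure being reimplemented, and the non-goal is explicit.
* Axis recovery degrades below ~8 px minor semi-axis; degenerate-label
  flags, not silent drops, mark the unreliable records.
* The cross-species operation assumes a clean one-row-per-gene fold-change
  table and a one-to-one ortholog map on the signature; duplicate-probe
  averaging and ortholog inference are out of scope.
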