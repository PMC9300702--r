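---
title: "Quantitative AP-MS interactome scoring and trafficking-assay estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative AP-MS interactome scoring and trafficking-assay estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baitquant)
```

## The problem

Affinity-purification mass spectrometry (AP-MS) against a membrane bait
captured under two trafficking states — surface-labeled with endocytosis
blocked at 4 °C, and after a brief 37 °C internalization chase so that the
captured pool contains endosomes — yields two candidate interactomes that
must each be scored against an unlabeled control pull-down. The abundance
measure is a label-free quantification (LFQ) intensity per protein per run.
Two statistical features dominate such data: intensities are approximately
log-normal, and missingness is *not at random* — low-abundance proteins drop
below the detection limit, so missing values are left-censored.

`baitquant` implements the canonical Perseus-style workflow for this design,
the downstream annotation analysis of the called interactors, and the
estimators for three functional readouts of receptor trafficking at
endothelial adherens junctions (FRAP turnover, biotinylation-ELISA
internalization, transwell permeability). A synthetic-data module generates
inputs with exactly the statistical structure each stage assumes, so every
claim the package makes is testable without instrument data.

## The interactome model

Let $x_{pgi}$ be the log2 LFQ intensity of protein $p$ in group
$g \in \{\text{surface}, \text{endosomal}, \text{control}\}$, replicate
$i = 1,\dots,4$. The pipeline is:

1. **Validity filter.** Keep proteins quantified in at least `min_valid`
   (default 3) of the 4 replicates of at least one group. Proteins failing
   everywhere carry too little information for a per-group test.
2. **log2 scaling.**
3. **Imputation.** Each missing cell in sample column $s$ is drawn from
   $\mathcal{N}(\mu_s - d\,\sigma_s,\; (w\,\sigma_s)^2)$ with $\mu_s,
   \sigma_s$ the mean and SD of the *observed* values of that column,
   downshift $d = 1.8$ and width $w = 0.3$. This places imputed values in
   the left tail where censored observations live; it is the approximately
   correct model precisely when missingness is intensity-dependent.
   Imputation is per column, not matrix-global, respecting per-run depth
   differences, and is governed by a single recorded seed.
4. **Control ratios.** $r_{pi} = x_{p,\text{comp},i} - x_{p,\text{ctrl},i}$:
   replicate $i$ of the compartment paired with replicate $i$ of the
   control, because the experiments are paired biological replicates. An
   unpaired mode (`paired = FALSE`, compartment replicates versus the
   control mean) is provided.
5. **Test.** One-sample t test of the four ratios against 0:
   $t = \bar r / (s_r/\sqrt n)$, two-sided p from $t_{n-1}$. Rows with
   $s_r = 0$ are flagged degenerate (p forced to 0 or 1 by the sign of the
   mean) rather than dropped.
6. **Multiplicity.** Benjamini–Hochberg q values per compartment, reported
   alongside the raw p.
7. **Calling.** Interactor $\iff$ mean linear fold change $\ge$ 1.5
   (i.e. mean log2 ratio $\ge \log_2 1.5$, *inclusive*) **and** raw
   p $< 0.05$ (*strict*). Calling uses the raw p by default — the volcano
   thresholds are stated on p, with q reported "alongside" — but
   `calling_params(use_q = TRUE)` switches the rule to the q value.
8. **Background flagging.** Proteins found in a contaminant-repository
   (CRAPome-style) background table at frequency $\ge$ 0.5 are *flagged*,
   never removed: recurrent background binders can still be genuine
   interactors, so the flag is an annotation for the reader. The repository
   convention of 0.5 is a stand-in; the threshold is exposed.

`fit_interactome()` runs steps 1–8 and returns a classed object with
`print()`, `summary()` and `plot()` (volcano) methods.

## Annotation analysis

Called interactors are classified by UniProt-style free-text annotation,
with case-insensitive substring matching after trimming (free text varies:
"Multi-pass membrane protein; Signal-anchor" must still match):

* **Transmembrane**: topology contains "Single-pass type I membrane
  protein", "Single-pass type II membrane protein" or "Multi-pass membrane
  protein".
* **Endosome-located**: any subcellular location matches "Early endosome",
  "Late endosome", "Lysosome" or "Cytoplasmic vesicle(s)" — singular and
  plural are both accepted since annotation text uses both forms.
* Transmembrane proteins are grouped (multi-membership) into "Membrane",
  "Focal adhesion", "Cell membrane" and "Cell Junction" for the chord-style
  membership export. Because "cell membrane" contains "membrane" as a
  substring, the bare "Membrane" group requires an exact location match.
  Unmatched proteins go to "Other" with a warning.

Category over-representation is a one-sided hypergeometric test
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, BH-adjusted across
categories, significant at q < 0.05. The default universe is the set of
proteins passing the validity filter — not a genome background, which is
what web enrichment services use; the difference is intentional and
documented, since only filtered proteins had any chance to be called.
Categories with fewer than 2 in-universe members are skipped as degenerate.
For the enrichment of the "remaining" interactors, the universe excludes
nothing but the query is the interactor union minus the transmembrane and
endosome-located branches, mirroring the analysis design that treats those
two branches separately.

## Functional-assay estimators

**FRAP.** A trace has 2 pre-bleach, 2 bleach and 50 post-bleach frames
acquired every 1.4 s (all configurable). Recovery is normalized per cell:
pre-bleach mean to 100%, first post-bleach frame to 0%. The mobile
fraction is
$M_f = (F_\text{rec} - F_0) / (F_\text{pre} - F_0)$ with $F_\text{rec}$ the
plateau estimate. The default plateau estimator is the mean of the last 5
post-bleach frames — simple, unbiased once $t \gg \tau$, and robust to
model misfit; a single-exponential fit
($F(t) = F_0 + A(1 - e^{-t/\tau})$, plateau $F_0 + A$) is provided as
`method = "expfit"` and cross-checked against the plateau estimator in the
tests. $F_0$ is the first post-bleach frame (optionally a 2-frame average),
not the trace minimum, which would bias the bleach depth under noise. No
acquisition-photobleaching reference correction is applied by default
(single-ROI normalization); estimates are clipped to $[0,1]$ with the raw
value retained. With the default design the last 5 frames sit at
$t \ge 64$ s, so for $\tau \le 14$ s the plateau underestimates $M_f$ by
$< 10^{-3}$ relative — and the bias cancels in control-versus-treated
percent changes.

**Internalization ELISA.** Surface proteins are biotinylated in the cold, a
short warm chase internalizes part of the pool, surface biotin is stripped
with MesNa, and captured biotinylated protein is read as OD. The estimator
is the background-corrected ratio
$\% = (\bar{OD}_\text{int} - \bar{OD}_\text{bg}) /
(\bar{OD}_\text{tot} - \bar{OD}_\text{bg}) \times 100$, invariant to OD
units.

**Permeability.** Basal tracer signal divided by apical input per
timepoint, with a summary slope (fraction/h) by least squares through the
origin — flux through an initially tracer-free compartment passes through
zero by construction. When aliquot and basal volumes are supplied, tracer
removed by sequential sampling is added back
($s_k \mathrel{+}= \tfrac{v_\text{aliquot}}{v_\text{basal}}\sum_{j<k}
s_j$); otherwise raw signals are used, matching how such assays are
usually reported.

**Comparisons.** `percent_change(ctrl, treat)` returns the reduction
$100(\text{ctrl}-\text{treat})/\text{ctrl}$ (an increase is negative, sign
convention documented) with a delta-method SE from the per-condition SEMs.
The "±" spread on such percent statistics is treated as the reported spread
of the comparison, not re-derived from first principles, because published
error magnitudes of this form are heterogeneous in unit.

## The synthetic-data generator

`simulate_apms()` draws protein baselines
$\mathcal{N}(\mu_b, \sigma_b^2)$ on the log2 scale (defaults 25 and 2,
typical of LFQ intensities), adds the planted log2 fold change in the
planted compartment(s), adds replicate noise (default SD 0.3), and censors
each cell independently with detection probability
$\operatorname{logit}^{-1}(\text{slope}\,(x - \text{midpoint}))$. Control
wells contain background binders at full intensity — beads bind
nonspecifically with or without the ligand — and planted interactors at
their baseline. The dropout defaults (midpoint 22.35, slope 1.1) were
calibrated once so that ~15% of control-channel cells are missing, a
stand-in rate (the observed missingness of real matrices of this design is
not published) exposed through the scenario object. One RNG substream per
protein, derived deterministically from the scenario seed, guarantees that
enlarging a scenario never reshuffles existing proteins.

What the generator does *not* emulate: peptide-level inference, batch
effects, correlated contaminant structure, isotope labeling, or
between-protein intensity correlation. Passing tests therefore demonstrate
the statistical machinery is correct under the stated model, not that the
model captures every pathology of real instrument runs.

Operating characteristics measured by the acceptance tests: under a null
scenario (2000 background proteins, MNAR dropout, 20 seeds) the
per-compartment false-call rate is well below the 0.05 p threshold
(typically 0.3–0.6%, because calling also requires the fold-change
criterion); with planted effects of log2fc ≥ 2 and noise ≤ 0.3 and
detection dropout disabled, ≥ 95% (in practice 100%) of planted proteins
are recovered and the surface/endosomal/shared partition matches the truth
exactly. With the default dropout *on*, recovery at log2fc 2 is ~87%:
low-abundance planted proteins are censored in their own compartment and
imputed into the left tail. That is a genuine property of left-censored
AP-MS, not an implementation artifact, and it is documented rather than
hidden.

## Shipped reference scenarios

`reference_scenario()` provides four named scenarios whose *planted effect
sizes* are the published percent reductions the estimators are designed to
recover; every absolute level the source experiments did not print was
fixed once at a field-plausible value:

| name | planted effect | fixed levels |
|---|---|---|
| `vecad_turnover_frap` | 37% mobile-fraction reduction | control $M_f$ 0.8, $\tau$ 12 s, bleach floor 0.2, noise SD 0.05, 24 cells/condition |
| `vecad_internalization` | 26% internalization reduction | control fraction 0.30, OD scale 1.0, background OD 0.05, CV 5%, 3 replicates |
| `miniwars_nrp1_uptake` | 19% endocytosis reduction | control fraction 0.40, same plate model |
| `miniwars_vecad_uptake` | 18% endocytosis reduction | control fraction 0.30, same plate model |

Control mobile fraction 0.8 and a 12-s recovery constant are typical of
junctional cadherin FRAP at short bleach scales; a 5% OD coefficient of
variation and triplicate wells are routine capture-ELISA practice. The
FRAP cell count (24 per condition) mirrors three independent experiments
of 8 cells each.

## Numerical choices and degenerate inputs

* Fold-change boundary inclusive, p boundary strict ("at least" vs "lower
  than").
* sd = 0 t-test rows flagged, never silently dropped; zero-SD imputation
  columns impute the constant mean with a warning; columns with < 2
  observed values are an error.
* A zero-row matrix is a legal filter result.
* All output tables are written sorted by protein ID so equal seeds give
  byte-identical files; the run seed is echoed into the report JSON.
* FRAP traces with no bleach depth ($F_\text{pre} = F_0$) are rejected, as
  are ELISA plates whose total OD does not exceed background.

## Problem sizes

The test suite simulates matrices of 300–4000 proteins, 20-seed Monte
Carlo batches for the operating characteristics, $10^5$ imputation draws
for the distributional check, and 24-cell FRAP batches; the whole suite
runs in a few seconds. These sizes were chosen because the binomial /
Monte-Carlo standard errors they give are already far below every
tolerance asserted; larger runs sharpen nothing.

## Limitations

* Intensities are taken as given: no protein inference, razor-peptide
  logic, or LFQ algorithm internals.
* Annotation analysis depends on the annotation snapshot supplied by the
  user; term lists are matched as substrings, so exotic annotation dialects
  may need preprocessing.
* Single imputation: the uncertainty added by imputation is not propagated
  into the t statistics (matching the reference workflow, which also
  imputes once).
* FRAP fitting is single-exponential only; no diffusion-model fitting, no
  image processing.
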