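---
title: "Acid-base models and cohort clustering in bovacid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acid-base models and cohort clustering in bovacid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovacid)
```

`bovacid` computes the acid-base status of dairy cattle from venous blood
and urine panels using both the traditional (bicarbonate / base excess /
anion gap) and the strong-ion (physico-chemical) descriptions, derives
reference intervals and qualitative calls, and clusters a cohort into
physiological states. This vignette records the models, the constants and
their provenance class, the design decisions taken where the methodology
was genuinely open, and what the synthetic cohort does and does not
emulate.

## Blood acid-base calculus

All charge-model formulas operate on the pH measured at 37 °C;
temperature-corrected values (`pH_BT`, `pCO2_BT`) are reported alongside
but never fed back into charge formulas, because the dissociation
constants are defined at 37 °C.

**Henderson–Hasselbalch bicarbonate.** cHCO₃⁻ = S·pCO₂·10^(pH−pK₁′) with
CO₂ solubility S = 0.0307 mmol·L⁻¹·mmHg⁻¹ and pK₁′ = 6.12. Strictly
increasing in both arguments; zero at zero pCO₂.

**Van Slyke base excess.** Analyzers compute base excess in firmware
whose exact constants are not published per device; we adopt the standard
Siggaard-Andersen form

BE = (1 − 0.0143·ctHb) · (cHCO₃⁻ − 24.4 + (1.63·ctHb + 9.5)·(pH − 7.40)),

with hemoglobin in g/dL, zero at the reference point (pH 7.40,
cHCO₃⁻ 24.4 mmol/L). The extracellular ("standard") base excess uses
ctHb/3, modelling hemoglobin diluted over the whole extracellular space.
At ctHb = 0 the two coincide.

**Standard bicarbonate.** Defined as the bicarbonate after equilibration
to pCO₂ 40 mmHg. We slide the sample along the non-bicarbonate buffer
line implied by the Van Slyke constants: the pH at 40 mmHg is the root of
BE(pH, cHCO₃⁻(pH, 40), ctHb) = BE(sample), found with `uniroot` on
pH ∈ [6.0, 8.5] at tolerance 1e−10 (BE is strictly increasing in pH, so
the root is unique). A sample already at 40 mmHg is returned unchanged
regardless of its base excess — a stronger fixed-point property than the
definition requires.

**Temperature correction.** The widely published analyzer convention:
ΔpH/ΔT = −0.0147 K⁻¹ and pCO₂ × 10^(0.019·ΔT). Valid for rectal
temperatures in (30, 43) °C; outside that range the input is rejected.

**Charge bookkeeping.** All ion symbols are charge concentrations in
mEq/L. Monovalent ions pass through (mmol/L = mEq/L), ionized calcium is
weighted ×2, and total magnesium ×1.38 — a divalent cation assumed 69 %
dissociated. The anion gap is AG = (Na⁺+K⁺) − (Cl⁻+HCO₃⁻); the measured
strong ion differences are SID_m3 = (Na⁺+K⁺) − Cl⁻, SID_m4 = SID_m3 −
lactate⁻, SID_m5 = SID_m4 + 2·Ca²⁺. The algebraic identity
AG = SID_m3 − cHCO₃⁻ holds to 1e−9 for every panel and is enforced in the
test suite.

**Weak acids.** A_tot(Alb) = 0.76·albumin[g/L], A_tot(Prt) =
0.36·total protein[g/L]; SIG = A_tot/(1 + 10^(pKa−pH)) − AG with
pKa = 7.06, so at pH = pKa exactly half the buffer pool is dissociated.
The individual charges are linear models: albumin
0.141·cAlb·(pH − 5.42), globulin 0.04·(cTP − cAlb)·(pH − 5.58), phosphate
cPi·(0.309·pH − 0.469).

**Unmeasured anions.** XA is the electroneutrality residual

XA = Na⁺ + K⁺ + 2·Ca²⁺ + 1.38·Mg − Cl⁻ − HCO₃⁻ − albumin charge −
globulin charge − phosphate charge.

The formula is implemented literally: it is a cation-minus-anion
residual, so *more* unmeasured anions give a *larger* XA. We do not
negate it; the qualitative classification treats "XA above its interval"
as increased unidentified anions, which is exactly how the residual
behaves (injecting 1 mmol/L of an unmeasured monovalent anion into an
electroneutral panel raises XA by exactly 1, a property the tests verify
to 1e−6).

**Hematocrit** is accepted as an optional input; when absent it is
approximated as ctHb[g/dL]/33 (the MCHC convention), since analyzer
hematocrit is itself firmware-derived.

## Urinary net acid-base excretion

From the standard titration (HCl to pH 4.0 → base excess cBE; NaOH back
to pH 7.0 → acid excess cAE; formaldehyde precipitation → ammonium cAmm),
NABE = cBE − (cAE + cAmm) in mmol/L and BAR = cBE/(cAE + cAmm). NABE > 0
⇔ BAR > 1: net base excretion, the normal state of herbivores. A zero
denominator raises an error rather than returning infinity, because the
titration protocol guarantees a nonzero acid component in practice —
zero indicates corrupt data, not extreme alkalinity. The NABE reference
band (106–210) is interpreted in mmol/L, the unit of the titrimetric
method.

## Reference intervals and qualitative calls

Internal "within-study" intervals are the 25th–75th percentiles of a
designated reference group, computed with the linear-interpolation
quantile convention (R type 7); at least four non-missing values are
required per variable. Literature bounds for variables with published
cattle references ship in `literature_intervals()`; one-sided limits are
stored with an infinite open side and can never produce "marked" calls.

Qualitative calls are ordered:
marked_below < below < within < above < marked_above. Values are
"within" on the closed interval; a call becomes "marked" when the value
lies beyond a bound by more than `marked_margin` × interval width. The
margin defaults to 0.5 — the double-arrow notion of a marked deviation is
nowhere defined numerically, so we pin a configurable default.
Classification is monotone in the value by construction.

The strong-ion interpretation follows the physico-chemical reading: a
decreased SID or an increased A_tot is a metabolic acidosis; an increased
SID or a decreased A_tot is a metabolic alkalosis; elevated XA or a
depressed SIG indicates unidentified anions, and the mirror pattern
unidentified cations. Mixed disorders return multiple labels. The
respiratory component is deliberately out of scope: venous samples do not
support a valid evaluation of pulmonary gas exchange.

## Cohort clustering

The segmentation base starts from eleven candidates in physiological
priority order: pH_BT, A_tot(Alb), SID_m5, the albumin/globulin ratio,
hematocrit, BHB, NEFA, SIG(Prt), urinary Na⁺, urinary Cl⁻, and BAR.
Candidates are admitted in order, dropping any whose absolute Pearson
correlation with an already-retained variable reaches 0.75, and capping
the list at one variable per ten observations. Retained variables are
z-scored (sample sd, n−1 divisor), distances are Euclidean, and the
agglomeration is Ward's minimum variance in the Ward.D2 dialect —
unsquared Euclidean heights, the modern default of the R clustering
stack; the method name alone does not pin the dialect, so we pin it for
reproducibility. The test suite checks the linkage against a brute-force
minimum-variance oracle (exhaustive merge-cost search) for n ≤ 7.

The number of clusters maximizes the mean silhouette width over the
candidate range (default 2..12), ties broken toward fewer clusters. The
complementary criterion used in practice — physiological interpretability
of the clusters — cannot be mechanized and is left to the analyst, who
can inspect the full per-k silhouette table in the fit. Rows with missing
segmentation values are dropped with a message.

Per-cluster profiles report median and quartiles for every numeric
variable; the centered/scaled medians used for tile plots are
(cluster median − overall median)/overall IQR. A variable with zero
overall IQR gets `NA` scaled medians and a warning rather than an error,
since profiling spans all cohort variables, not only the segmentation
base.

## The synthetic cohort

No per-animal data are distributed with the methodology this package
implements, so `simulate_cohort()` generates a stand-in cohort that
emulates the *structure* of a 145-cow post-parturient herd: seven
clusters of sizes 19/37/27/44/5/10/3, a metabolically unremarkable
reference cluster, and cluster-specific deviations (strong-ion acidosis
with or without hypoalbuminemia, ketosis with unmeasured-anion excess,
mineral-loaded high-lactation cows, and a small fat-mobilization outlier
group).

**Prototype construction.** The reference cluster sits at the midpoints
of the reference intervals; other clusters are displaced per variable by
an arrow code: one interval-width beyond the bound for a plain deviation,
two for a marked one, and half a width from the midpoint (inside the
interval) for relative-only deviations. For the one-sided literature
limits (NEFA < 0.62 mmol/L, BHB < 1200 µmol/L, cholesterol > 1.5 mmol/L)
we use bounded working ranges ([0.10, 0.62], [400, 1200], [1.5, 3.5])
chosen from ordinary healthy-cow physiology.

Targets stated on derived quantities are inverted to primitives:

* pCO₂ is solved (by `uniroot`) so the *standard* bicarbonate — the
  quantity the deviation pattern is stated for — hits its target at the
  prototype pH; the extracellular base excess then lands inside its own
  reference band automatically. A consequence of pinning SID and standard
  bicarbonate under one consistent constant set is that the anion gap of
  the reference prototype falls ~2 mEq/L below its printed band: the
  identity AG = SID_m3 − cHCO₃⁻ leaves no freedom, and the printed bands
  originate from real data whose internal relations differ slightly.
* Albumin comes from the A_tot(Alb) target; globulin is the
  γ-globulin target plus a constant 17 g/L α+β pool, letting the two
  protein axes vary independently; total protein and A_tot(Prt) follow.
* Sodium absorbs the SID_m5 target given each cluster's chloride,
  calcium and lactate levels.
* The urine titration components come from the NABE and BAR targets via
  the acid denominator D = cAE + cAmm = NABE/(BAR − 1), with an ammonium
  fraction of 0.25 (0.5 in the ketotic cluster, which excretes ammonium
  heavily). Two target pairs are mutually inconsistent and are resolved
  explicitly: a positive NABE with BAR ≤ 1 is impossible, so that
  cluster's ratio is placed halfway between balance and the lower
  reference bound; a doubly-decreased BAR would be negative and is
  clamped to 0.1. Near-balanced targets use a typical denominator of
  80 mmol/L.

Free centroid choices not pinned by any deviation row (plasma and urinary
chloride and sodium levels, hematocrit shifts, ammonium fractions,
bilirubin/urea/GLDH in the liver-strained outlier group) follow the
per-cluster clinical narrative: high plasma and urinary NaCl in
cluster 1, sodium-bicarbonate feeding with mild anemia of progressive
lactation in cluster 6, hypochloremia with hemoconcentration in the
ketotic cluster 5, hyperchloremia with hypocalcemia in cluster 7. Their
magnitudes were set, within physiologic ranges, so that the generated
cohort realizes the study conditions the clustering stage presumes — all
candidate variables except NEFA pass the |ρ| < 0.75 filter, and the
partition is recoverable at the documented noise level — and then frozen.
NEFA is structurally anticorrelated with SID_m5 under the deviation
pattern (it rises exactly where SID falls), so the filter drops it and
the default pipeline clusters on ten of the eleven candidates.

**Noise model.** Only primitive measured quantities receive Gaussian
noise; every derived variable is recomputed forward, so each record
satisfies all acid-base identities exactly (bicarbonate always matches
its pH/pCO₂, NABE always matches its titration components). The
per-variable noise sd is `noise_sd` × the size-weighted standard
deviation of the prototype targets — the dispersion the prototypes alone
would induce across the cohort — with a documented physiologic fallback
scale for variables whose targets coincide across clusters, and draws are
truncated to physiologic bounds. The default `noise_sd = 0.2` represents
a low-noise herd in which the cluster structure is clearly expressed.

**What passing tests do and do not show.** The generator reproduces the
cluster geometry, not the measurement process: real panels have
assay-specific, often right-skewed error that correlates across derived
variables through shared measurements, real clusters are not Gaussian
blobs, and farm effects are reduced to labels. Recovery of the generating
partition (the suite checks silhouette-selected k, the extreme cluster
sizes, and adjusted Rand index ≥ 0.9 against ground truth at the default
seed) therefore validates the pipeline's correctness, not its power on
real herds.

## Problem sizes and numerical conventions

The identity suites run on 10,000 random valid panels; the Ward oracle
comparison on 200 random matrices with n ≤ 7; clustering checks on the
full 145-animal synthetic cohort — sizes at which the whole suite
completes in seconds while exercising every code path. Quantiles use R's
type-7 convention throughout; standardization uses the sample sd;
silhouette ties break toward smaller k; root-finding tolerances are
1e−9–1e−10, far below any physiologic resolution. CSV output is
lossless for doubles; the pipeline writes derived tables rounded to four
decimals for human consumption while all downstream computation uses
full precision.

## Known limitations

* Base-excess and temperature-correction constants are published
  conventions, not the (unknowable) firmware of any particular analyzer;
  absolute BE values may differ from a given device by fractions of a
  mmol/L.
* Globulin is modelled as a single pool plus a γ target; α/β fractions
  and electrophoretic spectra are not represented.
* The silhouette criterion alone decides k; the interpretability
  criterion applied by clinicians is out of automated scope.
* The printed reference bands are mutually inconsistent at the ~2 mEq/L
  level under a single constant set (see the anion-gap note above); the
  generator favours standard bicarbonate, SID and the protein axes.
* No arterial/venous conversion, no oxygen-status variables, and no
  respiratory-disorder classification are provided.
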