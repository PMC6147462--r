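---
title: "Methods: dual-tracer 13C label propagation and LTP quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tracer 13C label propagation and LTP quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotracer)
```

## The experimental design this package models

Co-infusing [1-13C]glucose and [1,2-13C]acetate probes neuronal and
astrocytic metabolism simultaneously: glucose-derived acetyl-CoA is mostly
produced in neurons, while acetate is taken up and activated almost
exclusively by astrocytes. After a steady-state infusion, the positional
13C isotopomer pattern of glutamate (Glu), glutamine (Gln), GABA and
aspartate (Asp) in brain extract records which compartment, and how many
TCA-cycle turns, each labeled carbon passed through:

* [1-13C]glucose → [3-13C]pyruvate → [2-13C]acetyl-CoA → **[4-13C]Glu**
  on the first turn, and [2-13C]GABA after glutamate decarboxylation;
* [1,2-13C]acetate → [1,2-13C]acetyl-CoA → **[4,5-13C]Glu / [4,5-13C]Gln**
  in astrocytes, returned to neurons through the glutamate–glutamine cycle
  and on to [1,2-13C]GABA;
* second- and third-turn species ([3-13C]Glu, [2-13C]Glu, [2,3-13C]Glu, …)
  appear once label re-enters the cycle through oxaloacetate.

The package implements the full analysis of such data (quantification,
fractional enrichment, metabolic ratios, group comparison), a synthetic-data
generator with exactly this labeling structure, and the accompanying
hippocampal fEPSP/LTP electrophysiology analysis.

## The label-propagation model

### State representation

Each metabolite pool is a probability distribution over binary labeling
vectors (one bit per carbon; ≤ 6 carbons, so ≤ 64 states). All biochemical
steps are exact linear pushforwards of these distributions — there is no
Monte Carlo error anywhere in the expectation layer; randomness enters only
when replicate concentrations are drawn.

### Carbon-fate maps

All maps are standard biochemistry, written as explicit position maps:

| step | fate map |
|---|---|
| glycolysis | glucose C1→pyr C3, C2→C2, C3→C1 and C4→C1, C5→C2, C6→C3; equal mixture of the two triose halves |
| pyruvate dehydrogenase | C1 lost (CO2); C2→acetyl C1, C3→acetyl C2 |
| citrate synthase → isocitrate dehydrogenase | acetyl C1→OG C5, C2→OG C4; OAA C4→OG C1, C3→OG C2, C2→OG C3; OAA C1 lost (IDH CO2) |
| OG dehydrogenase → succinate | OG C1 lost; OG C2..C5 → succinate C1..C4 |
| succinate/fumarate symmetry | each vector and its end-to-end reversal get equal probability |
| glutamate decarboxylase | Glu C1 lost; C5→GABA C1, C4→C2, C3→C3, C2→C4 |
| transaminations (OAA→Asp, pyr→Ala/Lac, Glu↔Gln) | position preserving |

The composite citrate-to-oxoglutarate map deserves a note: aconitase is
stereospecific, so the CO2 released by isocitrate dehydrogenase in a given
turn is the OAA C1 carboxyl, and positional scrambling happens **only** at
the symmetric succinate/fumarate stage. This reproduces the canonical
observations — first-turn [4-13C]Glu from [2-13C]acetyl-CoA, and
second-turn label appearing at Glu C2 or C3 with equal probability.

A molecule-level enumeration oracle (atom-by-atom bookkeeping over every
discrete outcome: triose halves, per-turn acetyl draws, scrambling flips)
is implemented independently in the test helpers; the engine matches it to
total-variation distance < 1e-9 for up to three turns.

### Turns instead of ODEs

No rate constants are available for this system, so the steady state after
a fixed-length infusion is abstracted as a **discrete number of TCA turns**
(default 3). The measured glutamate pool is an equal-weight mixture of the
oxoglutarate distributions of turns 1..T; aspartate derives from the
oxaloacetate entering the final turn (an OAA carbon must complete a full
turn before it can carry label, which makes a one-turn simulation label
Glu/GABA/Ala only — the observed first-turn pattern). Equal weights are the
maximum-entropy choice absent kinetic information; the glucose cycling
ratio computed on simulated output is 0 at one turn and grows monotonically
with T, as it must.

### The two compartments

The neuronal chain is glucose → pyruvate → acetyl-CoA → TCA → Glu → GABA,
with alanine and lactate position-preserving exits from pyruvate. The
astrocytic chain is acetate → acetyl-CoA → TCA → Glu → Gln, and a
configurable fraction of the neuronal transmitter glutamate pool
(`gln_transfer`, default 0.30) is replaced by astrocyte-derived glutamine —
the glutamate–glutamine cycle. The measured whole-tissue Glu and Asp pools
mix the two compartments with a small astrocytic weight
(`astro_fraction`, default 0.10, reflecting the dominant neuronal share of
whole-brain glutamate).

Deliberate simplification: **astrocytic acetyl-CoA derives only from
acetate and neuronal acetyl-CoA only from glucose**. Real astrocytes also
oxidize glucose (the route that labels [2-13C]Gln from [1-13C]glucose);
the generator omits it so that each tracer's signature is attributable to
one compartment, which is what its validation tests assert. Consequently a
simulated data set has structurally zero [4-13C]Gln, and ratio reports
carry NA for ratios whose denominator class cannot arise; this is a known
difference from real brain data. Pyruvate carboxylase anaplerosis is
available behind `pyruvate_carboxylase` but off by default.

### Generator defaults (the stated world)

* `glucose_c1_fraction = 0.30`, `acetate_c12_fraction = 0.25`: chosen once
  so that control-group fractional enrichments land in the observed range
  (Glu C4 about 12% of a 12.2 mM pool); brain glucose is far from the 99%
  enrichment of the infusate because of ongoing unlabeled supply.
* `dilution = 0.15`: exchange with pre-existing unlabeled glutamate.
* knockout scales `glucose_flux_scale = 1.3`, `acetate_flux_scale = 1.15`:
  the hypermetabolic-knockout effect the generator emulates (a ~30%
  first-turn glutamate increase; astrocytic metabolites up by a smaller
  margin). Labeled-substrate delivery scales linearly, so the glycolytic
  index recovers the glucose scale exactly at CV 0.
* `n_replicates = 4`, `cv = 0.10`: the observed group size, and a
  multiplicative log-normal replicate noise whose coefficient of variation
  matches the roughly mean-proportional dispersions of the published
  concentrations. The log-normal is mean-corrected
  (`meanlog = -sdlog^2/2`) so expectations are unbiased; one draw per
  reported concentration — the configured CV *is* the dispersion of the
  concentration.
* Natural-abundance 13C (1.1%) is excluded by default: reported values are
  tracer-attributable. `natural_abundance = TRUE` adds independent
  per-carbon background; `nat_abundance_correct()` performs the matching
  subtraction on the analysis side.

The exact-class percent change of [4-13C]Glu under a 1.3 flux scale is
slightly below 30% (about 24%): raising the labeled-acetyl fraction also
labels oxaloacetate, which moves probability mass from the pure {4} class
into {3,4} and multi-labeled classes. The parameter-recovery criterion
(±10 percentage points around 30) accommodates exactly this nonlinearity;
it is a property of isotopomer classes, not an implementation artifact.

What a green simulator test does **not** establish: agreement with kinetic
(ODE) models, blood–brain transport effects, NAA/myo-inositol labeling (no
pathway is modeled for them; they are fixture-only metabolites), or
realistic inter-animal covariance structure (replicate noise is
independent across patterns).

## Quantification and enrichment

Standard curves are ordinary least squares of peak area against known 13C
concentration per (metabolite, carbon); areas are first rescaled by
(reference internal-standard area / spectrum internal-standard area), the
1,4-dioxane normalization. Inversion floors negative concentrations at 0
and counts them in a `clipped` audit attribute. The synthetic peak
generator is the exact inverse at zero noise (machine precision), which the
tests assert end to end. Doubly labeled adjacent-carbon species are emitted
as doublets — the J-coupling signature by which such isotopomers are
identified — others as singlets.

Fractional enrichment divides each isotopomer concentration by the HPLC
total (12C+13C) pool of its metabolite: at replicate level when replicate
ids align, else by group means with a notice (published tables store only
means, so both modes are needed; which one the original analysis used is
not stated). Values clip to [0, 100] with an audit count.

## Ratios, comparison, statistics

The four ratio families are implemented exactly as printed, including the
quirk that the glucose cycling ratio for glutamine divides by
**glutamate** C4; `matched_denominator = TRUE` exposes the likely intent
([4-13C]Gln). Ratios are computed on group means (the granularity at which
they are reported); all are invariant under uniform rescaling of the
table.

Group comparison uses a two-tailed two-sample t-test, Student
pooled-variance by default with Welch behind a flag, accepting either raw
replicates or (mean, sd, n) summaries since printed tables store only
summaries. No multiple-testing correction is applied by default (none was
applied across the 37 published tests); Benjamini–Hochberg is available
via `bh = TRUE`. The published dispersion is stored as SD (the table
footnote) but flagged in a `dispersion_kind` column because the caption
says SEM; under the SD reading with Welch's test the [4-13C]Glu summary
gives p = 0.0068, which matches the printed 0.007 — a useful consistency
check, though the ambiguity means no printed p value is treated as ground
truth.

## Electrophysiology

fEPSP slope is the voltage difference across two cursors 1 ms apart placed
on the middle of the ascending phase. "Middle portion" is made operational
as: the rise phase between the first crossings of 10% and 90% of the
baseline-to-peak amplitude, required to be strictly monotone, with the
cursor pair centered at its midpoint. (Centering within the longest
strictly-increasing run was tried first and rejected: on a discretized
sigmoid the increasing run extends across the flat top, dragging the
cursors off the rise.) On gentle analytic sigmoids the measured chord
matches the analytic 1 ms chord to < 1%.

I/O curves default to the 100–350 μA grid in 50 μA steps; LTP recordings
use 20 s sweep cadence, a 10 min baseline, ≥ 30 min post-TBS, and the LTP
value is the mean normalized slope of the final 5 min. The TBS protocol
(ten trains of five 100 Hz pulses at 5 Hz) is carried as metadata only —
only its effect (the potentiation factor) matters to the analysis. The
between-group test is the final-window t-test; repeated-measures ANOVA
across time points is out of scope by design.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → (optional peak-synthesis/quantification
round trip) → analyze → report, writing CSV tables and a JSON manifest.
One global seed is expanded into fixed per-stage offsets (+1 simulation,
+2 peak synthesis, +3 electrophysiology), so the same config reproduces
every output byte for byte. Config files are JSON (`jsonlite`), chosen over
YAML to avoid adding a dependency.

```{r}
res <- run_pipeline(pipeline_config(out_dir = tempfile(), seed = 1,
                                    input = "table1", ltp = NULL))
head(res$comparison[, c("pattern", "mean_control", "mean_treated",
                        "pct_change", "p")])
```

## Known limitations

* Discrete turns, not kinetics: absolute fluxes and time courses are out of
  reach; only pattern structure and relative effects are modeled.
* Single-substrate compartments (see above).
* Two published percent-change cells ([2,3-13C]Gln, [2-13C]NAA) are
  internally inconsistent with their own printed means; the package reports
  computed values and its acceptance checks exclude those two cells.
* The published table has 37 isotopomer rows; NAA and myo-inositol rows are
  analyzed (parsed, compared, enriched) but never simulated.
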