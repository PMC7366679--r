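---
title: "Multi-layer differential proteomics of kinase point mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer differential proteomics of kinase point mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mutlayers` implements the statistical core of a multi-layered proteomic
comparison of a panel of kinase point mutants against the wild-type
protein. Three measurement layers are modelled:

1. **Interaction layer** — bait-prey abundances from affinity purification
   (AP-MS) and proximity biotinylation (BioID), scored upstream by SAINT
   and screened against contaminant-control frequencies.
2. **Topology layer** — quantitative cross-linking MS: DSS cross-link
   identifications scored upstream (xQuest ld score), quantified by
   targeted PRM transition traces, and validated as distance restraints
   on a crystal structure.
3. **Cellular layer** — DIA/SWATH phosphoproteome and total proteome,
   scored upstream by m-scores, with decoy-based FDR control.

The package consumes the *outputs* of the upstream identification and
scoring engines as long-format tables; it never re-implements spectral
search, SAINT, xQuest, or localisation scoring. The integration step
combines regulation calls from the layers into a network of cancer-driver
proteins with evidence-filtered reference edges.

```{r, message = FALSE}
library(mutlayers)
```

# The differential model

All three layers share one differential engine. For an analyte $a$ and a
mutant condition $m$ with reference (wild type) $w$:

$$\log_2\mathrm{FC}_{a,m} = \overline{\log_2 x_{a,m,\cdot}} -
\overline{\log_2 x_{a,w,\cdot}},$$

with a two-sided *pooled-variance* (equal-variance) Student's t-test on
the log2 intensities and Benjamini–Hochberg adjustment **within each
mutant-vs-reference contrast**. The per-contrast family was chosen because
regulation counts are reported per mutant; pooling contrasts would couple
the adjustment of unrelated comparisons. An analyte is called regulated
iff $|\log_2\mathrm{FC}| > 1$ (strictly) and the adjusted p-value is at
most 0.05. Both thresholds are slots of the layer threshold classes.

Two degenerate cases are given documented conventions in
`studentTTwoSided()`: when the pooled standard error is numerically zero
(essentially constant groups), equal means give $p = 1$ and unequal means
give $p = 0$. Without this convention, zero-noise data — which arise
legitimately in simulation and in fully imputed blocks — would error out.

The phospho and total-proteome layers use this same engine as a
deliberate, documented surrogate for upstream Bayesian group-comparison
tooling (mapDIA-style): the reported thresholds and call directions are
preserved while the model internals are not reproduced. The surrogate is
recorded in the `method` attribute of the results.

# Interaction layer

**Filtering.** AP-MS preys require SAINT score strictly above 0.95; BioID
preys require a score of 1 (the upstream scorer saturates for
high-confidence proximal interactors, so equality is the meaningful
criterion). Survivors seen in more than 15% of contaminant-control runs,
or in the GFP control pulldowns, are removed. The asymmetry between the
two methods mirrors how the two score distributions behave in practice.

**Bait normalization.** Every intensity is divided by the bait intensity
of the same run, mapping the bait to exactly 1. This cancels per-run
scale factors (injection amount, instrument drift) and converts prey
abundances to stoichiometries relative to the bait — the pipeline is
therefore invariant to multiplying any single run by a constant.

**Imputation.** Intensity-dependent missingness dominates in AP-MS, so
missing values are drawn from a down-shifted Normal on the log2 scale:
centred at the 5th percentile of all observed log2 intensities, with
standard deviation `width_factor` (default 0.3) times the observed sd,
truncated below at the observed minimum minus 3 sd. The phrase "a
distribution based on the lowest quantile" admits several readings; this
one is the standard MNAR down-shift and is the package's choice. Draws
are seeded and reproducible. Only analytes observed in at least half of
the runs of at least one condition are imputed; fully absent analytes are
reported but never tested, because a test on purely imputed values has no
data behind it. Whether imputation pools observations globally or per run
is configurable in principle; the global pool is the default because the
5th percentile of a single run is unstable at typical prey counts.

# Topology layer

**Identifications** are kept iff ld score strictly exceeds 25 and both
linked peptides are at least 5 residues.

**Peak acceptance** (`acceptPeak()`) replaces the manual targeted
chromatogram review with three explicit criteria: apex retention time
within ±2 min of the identification library, light/heavy apex co-elution
within 0.2 min, and Pearson correlation of the six paired light/heavy
transition areas of at least 0.8. The ±2 min tolerance is the documented
review criterion; the co-elution and shape defaults are package choices
tuned to be permissive for genuine isotope pairs (which co-elute by
construction) and rejecting for interference. Fewer than three finite
transition pairs reject the peak outright.

**Quantification** sums the integrated areas of up to twelve transitions
(six per isotope channel) after discarding transitions with
signal-to-noise below 5. If nothing survives, the abundance is missing —
never zero. Summing both channels follows the twelve-transition
definition of the abundance; a single-channel restriction would halve the
signal without changing fold changes.

**Normalization and imputation.** Abundances are divided by the mean of
two non-cross-linked peptides of the same protein acquired in the same
runs (mean rather than sum; the two differ only by a global factor of 2,
which cancels in fold changes). Missing abundances are imputed with the
global observed minimum — the most conservative single-value scheme, and
the one matching the stated analysis. Global (not per-cross-link) is used
because the minimum of a single cross-link with many missing runs is
undefined.

**Distance restraints.** A cross-link maps onto the structure iff both
residues fall inside the covered range and carry a Cα atom; the restraint
is satisfied iff the Euclidean Cα–Cα distance is at most 30 Å
(inclusive; the spacer length of DSS plus side-chain reach is an
approximate bound, so the cutoff is a configurable slot). Links outside
the covered range are *unmappable*, not violated — absence of structure
is not evidence of violation. An integer `offset` aligns construct
numbering with author numbering of the deposited structure; the package
makes no assumption about which numbering the identifications use.

PDB parsing keeps, per residue, the highest-occupancy alternate location
(ties to the first in file order) and uses author residue numbering,
matching how covered ranges are quoted for deposited structures.

# Cellular layer

**Feature filtering.** Phosphopeptide features need best m-score ≤ 0.01
and detection in at least 30% of *all* runs (inclusive, across all
conditions — the denominator follows the wording "of all measurements").
The total-proteome layer uses the global m-score cutoff 3.9811e-5. The
decoy-based FDR is `fft * n_decoy / n_target` with FFT defaulting to
0.46.

**Normalization** equalises run totals to their mean (total ion signal),
conserving the grand total exactly.

**Fragment selection and roll-up.** Per peptide, each fragment's log2
profile is correlated with the peptide's mean fragment profile (the mean
includes the fragment itself — the reference-profile definition is
ambiguous upstream, and the mean-profile reading is the package's
choice); fragments with r < 0.1 are dropped, the top six by total
intensity kept, and peptides need at least three survivors. Peptide
intensity is the per-run sum of kept fragments.

**Motif analysis.** The kinase recognition motif R/K-x-x(-x)-S/T-P is
matched positionally: phosphoacceptor S/T, proline at +1, and R or K at
−3 or −4. Positions beyond a terminus never match. Motif analysis is
restricted to localized phosphopeptides (FLR ≤ 0.01): a motif statement
requires knowing which residue carries the phosphate. Enrichment among
downregulated peptides uses the two-sided Fisher test against all
quantified localized peptides.

**Regulation summaries** report up/down fractions among analytes with
adjusted p ≤ 0.05 in each condition — the significant-only denominator
matches how per-mutant percentages are quoted alongside the significance
threshold; the denominator choice is an argument.

# Integration

A protein enters the driver network iff it is on the user-supplied
cancer-driver list and regulated at the phospho and/or interaction layer
in at least one mutant. The layer criteria default to strict `<` on the
adjusted p (the Methods-style wording) with a switch for inclusive `≤`
(the figure-legend-style wording). Reference edges among selected nodes
are kept only when experimentally validated with at least one PubMed id
(configurable); unconnected nodes remain in the network as isolated —
absence from the reference database is informative. Over-representation
of term sets offers both the two-sided Fisher variant and the
conservative EASE variant (one-sided upper tail with one hit removed from
the overlap, floored at zero), the latter matching common annotation
servers.

# The synthetic-data module

Every pipeline input can be generated with known ground truth:

* `simInteractome()` — prey log2 intensities from a Normal around
  per-prey bases (18–24), planted per-condition log2 fold changes,
  per-run scale factors, a bait present in every run, logistic MNAR
  missingness `P(miss) = plogis(-slope (log2 x - midpoint))`, SAINT
  scores near 1 for true interactors and sub-threshold for contaminants.
* `simStructureCrosslinks()` — a toy all-lysine chain in which each
  cross-linked pair sits on its own coordinate row at a controlled
  distance, declared subsets violating the 30 Å restraint or falling
  outside the covered range; PRM transitions with planted fold changes
  and a declared low signal-to-noise subset; two reference peptides per
  run.
* `simPhospho()` / `simProteome()` — site-centred peptide windows where a
  configurable fraction of planted-down peptides carries the kinase
  motif and all other windows are built motif-free; decoy flags and a
  noisy m-score subset; fragment-level proteome records including planted
  anti-correlated fragments.
* `simAnnotations()` — driver lists at a configured rate, reference
  edges with mixed evidence classes, and term sets.

Defaults mirror the emulated study design: seven mutant conditions plus
wild type, three biological replicates, log2 noise sd 0.3, and planted
effect magnitudes of 2–3 log2 units — the scale of the reported
interaction and cross-link changes. The cross-linking layer defaults to
three conditions, reflecting that only a subset of mutants can be
purified for in-vitro cross-linking. Each generator draws from its own
seeded RNG stream (master seed plus a fixed stage offset) and restores
the caller's RNG state, so layers are independently reproducible and
byte-identical under a fixed configuration.

What the generator does **not** emulate: retention-time drift,
inter-analyte correlation (co-complex preys co-vary in real data),
peptide-level interference, compositional effects of normalization on
strongly regulated proteomes, and sequence realism beyond the motif
window. Passing recovery tests therefore demonstrate correctness of the
statistical machinery under the stated noise model, not robustness to
every artefact of real acquisitions.

# Numerical choices and tie-breaks

* Fisher's two-sided p sums hypergeometric probabilities ≤ the observed
  table's probability with relative tolerance 1e-7 for float ties; any
  zero margin returns p = 1 (degenerate, no evidence either way).
* BH adjustment is the step-up definition with monotonicity enforcement
  and capping at 1, in input order.
* PCA centres features, decomposes the sample covariance by SVD, and
  fixes each component's sign so its largest-magnitude loading is
  positive — scores are then reproducible across sample orderings.
* Replicate CVs use raw (not log) intensities, sd/mean, requiring ≥ 2
  observed replicates.
* Intensities of exactly 0 are invalid on input: missingness must be
  encoded as an empty cell or `NA`, because down-shift imputation has to
  distinguish "absent" from "small".

# Problem sizes

The shipped tests and the acceptance script use compact designs chosen to
exercise every code path at stable statistical resolution: 1,000 planted
nulls for type-I calibration, 200 preys with 40 planted effects for
recovery, 14 cross-links (9 satisfied / 2 violated / 3 unmappable), and
100–400 phosphopeptides for motif recovery. These sizes give binomial
standard errors small enough for 3-SE assertions while keeping a full run
in the order of minutes.

# Known limitations

* The t-test surrogate ignores the intensity-dependent variance structure
  a hierarchical model would capture; at n = 3 replicates its power is
  conservative for low-abundance analytes.
* Imputation-then-test treats imputed values as data; the ≥ 50% support
  rule bounds, but does not eliminate, the resulting anti-conservatism
  for analytes missing in one condition entirely (which is precisely the
  on/off interactor signal the fold-change threshold is meant to catch).
* Distance restraints use Cα–Cα geometry only; side-chain flexibility is
  absorbed into the 30 Å bound rather than modelled.
* The EASE variant reduces the overlap cell while keeping the original
  margins, matching annotation-server semantics; it is intentionally
  conservative and not a calibrated test.
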