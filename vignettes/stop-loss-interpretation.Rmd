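---
title: "Methods: modeling and interpreting stop-loss variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and interpreting stop-loss variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoplossr)
```

# The biological model

A transcript in this package is a coding sequence that ends in one of the
three standard stop codons (TAA, TAG, TGA) plus its 3′ UTR, both in
transcript space on the sense strand. A variant at the stop codon has one
of three consequences:

* **stop-retained** — the mutated codon is still a stop; termination is
  unchanged and the variant is excluded from scoring;
* **stop-loss** — the mutated codon encodes an amino acid; translation
  continues into the 3′ UTR until the nearest downstream in-frame stop,
  yielding a C-terminal extension;
* **stop-loss with NSD** — no in-frame stop exists downstream; the
  ribosome reaches the transcript end and nonstop decay is expected to
  degrade the mRNA. These variants are not scored by the classifier; they
  follow the PVS1 interpretation branch instead.

Only the standard nuclear genetic code is supported; selenocysteine
recoding and programmed read-through are out of scope, as are mRNA
secondary-structure effects on stop selection and non-canonical isoforms
(transcript choice happens upstream of this package). Annotated coding
sequences containing an internal in-frame stop are rejected at validation
rather than silently truncated: for the canonical transcripts this
package models, an internal stop indicates a data error, and guessing the
intended reading frame would corrupt everything downstream.

## Enumeration conventions

Each stop codon admits exactly 9 substitutions (3 positions × 3
alternative bases), 12 single-base insertions and 3 single-base
deletions. The insertion points are the three inter-nucleotide positions
at which the inserted base changes the codon read at the stop position:
before nt1, between nt1–nt2, and between nt2–nt3. Insertion after nt3
lies wholly in the 3′ UTR and never alters the stop codon, so it is
excluded; 4 bases × 3 points gives exactly 12. This convention reproduces
the canonical per-codon counts, though alternative placements of the same
inserted base can receive different HGVS labels in other tools; the
convention is isolated in one function (`mutant_region()`).

Indels are classified by reconstruction: the edited stop-codon bases are
concatenated with the 3′ UTR and the first complete codon of that string
is what the ribosome reads at the original termination position. An indel
can therefore *resurrect* a stop using downstream UTR bases; such alleles
are stop-retained and excluded from scoring, like substitution
stop-retained alleles.

Of the 27 possible substitutions across the three stop codons, 4 are
stop-retained (2 of 9 for TAA; 1 of 9 each for TAG and TGA). Weighting
the per-codon fractions by transcriptome-wide stop-codon usage
(TGA 49.2%, TAA 28.4%, TAG 22.4%) gives a 14.3% stop-retained / 85.7%
stop-loss split; `weighted_stop_retained_fraction()` recomputes this from
the enumeration rather than hard-coding it.

## Extension length convention

`ext_len` counts codons translated from the UTR **strictly before** the
new stop; the residue substituted at the original stop position is
reported separately (`substituted_aa`). HGVS `extTer{M}` is emitted with
`M = ext_len + 1`, since the new Ter occupies position `old + M`. This
matches the arithmetic of published extension names (one substituted
residue paired with a downstream stop M codons away). Whether "extension
length" includes the substituted residue is genuinely ambiguous in the
field; under the alternative convention every length feature shifts by
exactly 1, which a rank-based classifier is insensitive to. A trailing
partial codon (< 3 nt at the UTR end) can never terminate translation and
therefore contributes to the NSD determination.

# The feature vector

The classifier input is a fixed-order 37-entry vector
`X = [V1…V4, T1…T6, P1…P27]`, named in `feature_registry()`:

| Block | Features | Source |
|---|---|---|
| V1–V4 | CADD, GERP, PhyloP100, PhastCons100 | pass-through annotation |
| T1–T6 | 3′ UTR length (nt), 3′ UTR GC (%), mRNA-stability Z, pLI, LOEUF, s_het | computed (T1, T2) / pass-through |
| P1–P2 | original protein length (aa), extension length (codons) | computed |
| P3–P22 | counts of the 20 amino acids in the extension | computed |
| P23–P24 | mean Kyte–Doolittle and Miyazawa–Jernigan hydrophobicity | computed |
| P25–P27 | TANGO maximum, CANYA score, IDP flag | pass-through |

Design notes:

* External scores are never recomputed here — CADD, conservation,
  constraint, TANGO and CANYA are published tools with their own
  pipelines; they enter as annotation columns and missing values are
  median-imputed. For TANGO a per-residue profile hook applies the
  maximum-over-residues reduction.
* The Miyazawa–Jernigan hydrophobicity table has several published
  variants. The values embedded here (`hydrophobicity_scale("MJ")`) are
  the contact-energy-derived "Miyazawa" scale as tabulated by the R
  peptide-analysis ecosystem, recorded with citation in `R/features.R`.
* An empty extension (`ext_len = 0`) has zero composition counts and an
  *undefined* mean hydrophobicity: a mean over zero residues has no
  value. It is stored as missing and median-imputed, not set to 0, which
  would conflate "no residues" with "average hydrophobicity 0".
* 3′ UTR GC and length are computed on the full annotated UTR, not only
  the translated portion, matching the feature definitions.
* Conservation scores, where position-resolved, should be averaged over
  the three reference stop-codon bases before entry; the package treats
  them as one number per variant.

# The classifier

The forest scores a variant as the fraction of trees voting pathogenic —
equivalently the mean of per-tree terminal-node class indicators — so
`f(X) = (1/T) Σ_t h_t(X) ∈ [0, 1]`. `max_node` caps terminal leaves per
tree (the `maxnodes` control of the underlying implementation).
Hyperparameters are selected by grid search over
`mtry ∈ {2, 5, 10, 15, 20}`, `ntree ∈ {20, 50, 100, 200, 300, 400}` and
`max_node ∈ {5, 10, 20, 30}` (120 combinations), maximizing mean
out-of-fold AUROC under 5-fold cross-validation; ties break toward the
smaller `ntree`, then `max_node`, keeping the cheaper model. The shipped
defaults (`mtry = 20`, `ntree = 200`, `max_node = 30`) are the optimum
reported for the original training cohort.

Folds are stratified by class. Plain random folds at cohort sizes around
600 occasionally produce validation folds with very few positives, which
makes fold AUROCs noisy; stratification stabilizes the CV criterion
without changing its expectation. Imputation medians are refitted inside
each training fold and stored with the final model, so prediction-time
data can never leak into the imputation.

AUROC is computed as the tie-averaged rank statistic and AUPRC as the
step-interpolated precision–recall area; both are cross-checked against
independent implementations in the test suite.

# Threshold calibration

A two-component Gaussian mixture is fitted to a score distribution by EM.
Initialization is k-means on the scores with 10 seeded restarts, keeping
the run with the best log-likelihood; variances are floored at 1e-8 to
avoid collapse. Components are labeled by mean order (larger mean =
P/LP). The likelihood ratio uses the **component densities without mixing
weights** — that is the published rule, and it answers "which shape does
this score fit better" independently of cohort composition; a
posterior-odds mode (`weighted = TRUE`) is available behind a flag.

Solving `log LR(x) = ±log(ratio)` is quadratic in `x` for unequal
variances; the root strictly between the component means is selected (if
both quadratic roots fall inside, the one on the matching side of the
midpoint), and a pathological fit with no interior root raises an error
with diagnostics rather than returning an extrapolated value. With equal
variances the closed form
`x = (μ_B + μ_P)/2 + σ² log(ratio)/(μ_P − μ_B)` applies. `ratio = 9`
corresponds to 90% likelihood of the favored class. The published
operating points 0.30/0.70 ship separately as `default_thresholds()`:
reproducing them exactly requires the original genome-wide score
distribution, which is external data, so freshly calibrated thresholds on
other score sets will differ. Classification boundaries are inclusive
toward the decisive bins (`≥ upper`, `≤ lower`).

# Evidence assignment

The flowchart is deterministic: NSD → PVS1 and stop. Otherwise the
extension is matched against a database of classified variants — PS1 for
a byte-identical protein consequence (substituted residue + extension
peptide) carried by a P/LP record, PM5 for a byte-identical extension
peptide with a different substituted residue, PM4 as the fallback — and
PP3 attaches independently when the score is ≥ 0.7. When both PS1-type
and PM5-type records exist, PS1 wins (the stronger, more specific
evidence). Combining codes into a final ACMG classification is
deliberately not performed: the framework proposes evidence, not a
combiner, and PP3 in recessive genes carries a context caution rather
than suppression.

# Cohort statistics

Under iid bases each codon is a stop with probability
`p = P(TAA) + P(TAG) + P(TGA)`, so the scan length until and including
the terminating codon is geometric with mean `1/p` — `64/3 ≈ 21.3` codons
at uniform base frequencies. This distribution is sometimes loosely
called Poisson in the literature; the printed mean 21.3 is the
geometric/iid value, so the geometric model is implemented
(`expected_scan_length()`), cross-checked by Monte-Carlo simulation
(`simulate_scan_lengths()`). Transcriptome-scale observed quantities
(fraction of NSD-susceptible transcripts, observed median extension, the
GC-extension correlation) are supported as computations over
user-supplied transcript sets; they require genome-scale annotation that
is not shipped.

Group comparisons use the Mann–Whitney U test for continuous features and
Fisher's exact test for binary flags, with Benjamini–Hochberg control
across the tested family — standard base-R implementations, verified
against combinatorial oracles in the tests.

# The synthetic-data generator

`gen_labeled_cohort()` exists so that every pipeline stage can be
exercised end-to-end without external databases. Per variant it plants an
extension peptide (residues drawn from label-tilted frequencies),
back-translates it into the 3′ UTR followed by a stop codon and a
GC-quota tail, then runs the *real* pipeline — enumeration, UTR scanning,
feature assembly — so the feature rows are produced by the same code path
as real data. Defaults mirror the published study conditions:

* cohort sizes 310 pathogenic + 310 benign for training (the source
  training set had 619), with an imbalanced 187/371 option matching the
  published test set;
* stop-codon usage TGA/TAA/TAG = 49.2/28.4/22.4%;
* benign extension lengths log-normal with median 15 codons and a ×2
  pathogenic multiplier; log-normal UTR tail lengths (median 250 nt,
  ×1.3 for pathogenic) — values chosen once as realistic for human
  3′ UTRs at package scale;
* a ×2.5 Dirichlet-style tilt of Leu/Pro/Ala/Cys (pathogenic) vs
  Ser/Lys/Glu/Tyr (benign) residue frequencies, matching the reported
  enrichment directions;
* +1.2 SD shifts on the annotation-score proxies, constraint proxies
  shifted in the reported directions (higher pLI and s_het, lower LOEUF
  in pathogenic), IDP rates 10.0% vs 1.3%;
* an allele-frequency proxy drawn rare for pathogenic rows.

`planted_direction()` ships the expected sign of every planted contrast
(for amino-acid features, on composition fractions — enrichment is a
statement about proportions, and raw counts would confound it with the
longer pathogenic extensions). The generator emulates the *statistical
structure* of curated cohorts, not their biology: features are
conditionally independent given the label, annotation scores are Gaussian
proxies rather than real tool outputs, and effect sizes are large by
construction. Passing tests therefore demonstrate that the machinery is
correct and can recover planted signal — the near-perfect synthetic AUROC
asserted in the test suite says nothing about real-data performance,
where the published figures came from curated clinical cohorts.

# Numerical choices and problem sizes

* All randomness (generators, bootstrap, folds, EM restarts) flows from
  explicit integer seeds; identical seeds regenerate identical outputs.
* EM convergence: absolute log-likelihood change < 1e-10, max 500
  iterations; threshold roots are closed-form/quadratic, verified against
  a numeric root-finder at 1e-9 in the tests.
* The test suite uses cohorts of 620 and 558 rows (the published cohort
  scale), 1000-UTR scan-equivalence sweeps, and 50,000-sequence
  Monte-Carlo scans — sizes chosen so the full suite completes in a
  couple of minutes on one CPU while keeping Monte-Carlo error near or
  below the asserted tolerances.
* Degenerate inputs fail loudly: empty sequences, non-ACGT characters,
  all-identical score vectors, single-class labels, all-missing feature
  columns and mismatched feature registries are errors, not warnings.

# Known limitations

* The nearest downstream in-frame stop is assumed to terminate
  translation; read-through and structural effects on stop selection are
  not modeled.
* External annotation scores are pass-through; variants lacking them fall
  back to median imputation, which flattens their contribution.
* The classifier does not separate loss- from gain-of-function
  mechanisms, and scores in recessive genes need zygosity and
  disease-mechanism context (hence the PP3 caution flag).
* Calibrated thresholds depend on the score distribution they are fitted
  to; the shipped 0.30/0.70 operating points are not recoverable from
  synthetic data.
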