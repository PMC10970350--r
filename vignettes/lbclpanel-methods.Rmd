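---
title: "Methods: targeted-panel analysis of large B-cell lymphomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted-panel analysis of large B-cell lymphomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbclpanel)
```

# Scope and model of the data

`lbclpanel` implements the downstream analysis of targeted amplicon-panel
sequencing of large B-cell lymphomas (DLBCL-NOS and HGBCL) from
formalin-fixed, paraffin-embedded (FFPE) tissue. The pipeline starts
*after* alignment and primary variant calling: its inputs are per-sample
variant call tables (TSV or a single-sample VCF dialect), an amplicon
manifest in genomic order, a per-run sample × amplicon matrix of median
base coverage, and a clinical table with immunohistochemistry
percentages, rearrangement status, staging and follow-up. Its stages
are:

1. **Sample QC** — FFPE deamination screening via the
   transition/transversion ratio, plus a mean-read-count floor.
2. **Variant filtering** — depth/VAF thresholds, population-frequency
   and panel-of-normals exclusion, strand-bias and homopolymer-indel
   artifact rules.
3. **Pathogenicity classification** — a deterministic rule cascade over
   curated 5-tier classes, CADD-PHRED, and four prediction tools.
4. **CNV calling** — gene-level gains/losses from normalized amplicon
   coverage via consecutive exceedance of per-amplicon reference
   intervals.
5. **Molecular phenotyping** — Hans cell-of-origin, double-expressor
   status, disease categorization, and post-processing of external
   genetic-subtype (LymphGen-style) probabilities.
6. **Cohort summary** — patient × gene alteration matrix, frequencies,
   burden, oncoprint export.
7. **Survival analysis** — OS/PFS via Kaplan–Meier, log-rank and Cox
   regression; disease-specific mortality as a competing-risks problem
   (Aalen–Johansen incidence, Gray's test, Fine–Gray and cause-specific
   regression side by side).

Because patient-level data of the motivating cohorts are not shareable,
the package carries a first-class synthetic-data generator with known
truth labels; every stage is validated against that truth.

# Thresholds

All tunable thresholds live in one object (`default_thresholds()`),
overridable from a flat YAML file. The defaults are the values used in
diagnostic practice for this assay family:

| parameter | default | meaning |
|---|---|---|
| `min_read_depth` | 100 reads | minimum coverage for a call (inclusive) |
| `min_vaf` | 0.10 | minimum variant allele frequency (inclusive) |
| `max_population_freq` | 0.01 | population-frequency exclusion (strictly above fails) |
| `max_strand_bias` | 0.90 | max fraction of alt reads on one strand (strictly above fails) |
| `titv_exclusion` | 5.0 | Ts/Tv at or above this excludes the sample |
| `min_sample_mean_reads` | 100 reads | sample mean-coverage floor (strictly below excludes) |
| `cadd_high`, `cadd_low` | 25, 10 | CADD-PHRED bands for class-3 upgrade |
| `min_pathogenic_notations` | 2 | predictor votes needed in the mid band |
| `ci_level_default` | 0.99 | CNV reference-interval level |
| `ci_level_overrides` | CDKN2A → 0.95 | per-gene interval override |
| `min_consecutive_amplicons` | 3 | "more than two consecutive amplicons" |
| `homopolymer_min_run` | 5 bp | indels in runs at least this long are artifacts |
| `hans_cutoff` | 0.30 | IHC positivity cutoff (fraction of tumor cells) |
| `myc_expr_cutoff`, `bcl2_expr_cutoff` | 0.40, 0.50 | double-expressor cutoffs |
| `lymphgen_member_prob`, `lymphgen_core_prob` | 0.50, 0.90 | subtype membership bands |
| `admin_censor_months` | 60 | administrative censoring horizon |
| `oncoprint_min_freq` | 0.05 | display threshold (strictly above retained) |

Boundary semantics are deliberate and unit-tested: thresholds phrased
"at least" are inclusive (depth, VAF, IHC cutoffs, Ts/Tv exclusion),
thresholds phrased "more than" are strict (population frequency, strand
bias, oncoprint frequency, subtype membership). The class-3 CADD rules
use a closed band [10, 25] next to a strict "> 25", so the two rules
partition scores of 10 and above without gap or overlap at 25.

The CDKN2A interval override exists because this gene is deleted so
frequently in DLBCL-NOS that its own losses widen a cohort-estimated
reference interval; a narrower 95% interval compensates. The override
map is configurable per gene because the same argument could apply to
other recurrently deleted genes; we did not extend it by default since
CDKN2A is the only gene with firm literature support for the
adjustment.

# Sample QC and variant filtering

The Ts/Tv ratio is computed on **all called SNVs before per-variant
filtering** — sample QC screens the raw caller output, which is where
the deamination signature (C>T/G>A) is visible. Whether to restrict to
exonic SNVs is left open by assay descriptions; we use all SNVs and
document it. A sample with transitions but no transversions gets an
infinite ratio (clearly past any threshold); a sample with no SNVs has
no ratio and is not excluded on this ground. Samples excluded for Ts/Tv
are flagged `repair_candidate`, modeling the
uracil-DNA-glycosylase-repair-and-rerun path used in practice.

The "healthy-donor DNA mixtures" panel of normals is modeled as an
explicit site blacklist (`chrom, pos, ref, alt`), since the underlying
mixtures are not distributable. The homopolymer rule is codified as:
indels whose flanking homopolymer run is at least 5 bp are artifacts
(the run-length is configurable; assay descriptions say only "induced
by homopolymeric regions"). Filter flags are cumulative; a record
passes iff no flag is raised, which makes filtering idempotent and
order-independent (property-tested).

# CNV calling

The coverage model is multiplicative: observed coverage ≈ per-sample
sequencing depth × per-amplicon efficiency × copy-number effect ×
noise. Normalization therefore takes two median steps on the log2
scale: divide each sample by its median across amplicons (removes
depth), then each amplicon by its cross-sample median (removes
efficiency). Medians, not means, so that a handful of true CNV cells do
not shift the baseline. Which scale the original assay used is not
stated; we chose log2 normal-theory and provide a percentile
alternative (`method = "percentile"`) for sensitivity analysis.
Runs are analyzed per sequencing run ("normalized with all samples
included in the run"), not pooled across runs.

Per-amplicon reference intervals are mean ± z(level)·SD of the log2
normalized values across samples (z = 2.576 at 99%, 1.960 at 95%).
Calls are maximal runs of at least `min_consecutive_amplicons = 3`
consecutive amplicons — adjacent in manifest (genomic) order, never
crossing a gene boundary, with masked amplicons breaking runs — all
strictly above the upper bound (gain) or below the lower bound (loss).

**Leave-one-out default.** When `call_cnvs()` is not handed an explicit
interval table, each sample is tested against intervals recomputed from
the *other* samples (closed-form leave-one-out mean/SD updates). The
package initially tested each sample against cohort-wide intervals that
included it; benchmarking showed that a true 1.5× gain inflates its own
column SD enough at run sizes of ~16 samples to mask itself (gain
recall dropped from ~1.0 under leave-one-out to ~0.82 under
self-inclusion, pulling overall recall below 0.9), while the
false-call rate stayed near zero either way. Cohort-wide intervals
remain available — pass the `amplicon_intervals()` table explicitly —
and are what the per-amplicon interval TSV reports.

Coverage sample QC excludes samples whose median raw coverage is below
50 reads or whose dispersion — IQR of log2 sample-median-normalized
coverage across amplicons — exceeds 1.2. The dispersion statistic
includes the panel's amplicon-efficiency spread (≈0.8 under the
generator's defaults), so the ceiling is set above that; a sample with
ten times the typical multiplicative noise lands near 1.6 and is
excluded. Both parameters are logged and configurable.

# Molecular phenotyping

The Hans tree is encoded as ordered rules (CD10+ → GCB; CD10−/BCL6− →
non-GCB; CD10−/BCL6+/MUM1+ → non-GCB; CD10−/BCL6+/MUM1− → GCB) with a
shared, boundary-inclusive 30% positivity cutoff. A missing marker that
the tree actually needs yields "unclassifiable" (`NA`); a marker made
irrelevant by an earlier branch may be missing without harm.

Disease categorization gives each patient exactly one category:
`relapsed` on any prior lymphoma — except a prior diagnosis of
untreated small lymphocytic lymphoma bone-marrow involvement without
transformation, which does not count against a primary categorization —
otherwise `primary` (Ann Arbor IE/IIE), `disseminated` (III/IV), or
`unstaged`.

Genetic-subtype handling consumes externally computed class
probabilities (the classifier itself is a published external algorithm
and is out of scope). Classes strictly above 0.50 are labels; exactly
one label strictly above 0.90 is a core member, at or below 0.90 an
extended member; two or more labels form a genetic composite, rendered
alphabetically as "A/B" (the composite ordering convention is not
specified anywhere authoritative; alphabetical is deterministic). The
classifier input export writes **all retained variants, including
benign and unknown-significance calls** — the external classifier wants
the full mutation list, not the pathogenic subset — plus BCL2/BCL6
rearrangement flags; CNV results are deliberately omitted because a
targeted panel's CNV evidence is too thin for cluster allocation.

# Cohort summary

The alteration matrix unions evidence per (patient, gene):
`pathogenic_variant`, `gain`, `loss` (a gene may hold several).
Patients with no alterations remain as empty columns. A gene counts
once per patient regardless of how many pathogenic variants it carries.
Displayed percentages round half away from zero (so 4/14 prints as
29%); quartiles use linear interpolation between order statistics
(quantile type 7 — this is how fractional quartiles like 8.25 arise).
The oncoprint export retains genes altered in strictly more than 5% of
the cohort, using the full-cohort denominator (per-group denominators
are available through the `group` argument of `gene_frequencies()`).

# Survival analysis

Endpoints: OS is time to death of any cause; PFS time to progression,
relapse, or death; disease-specific mortality treats lymphoma death as
the event of interest with deaths from other *and unknown* causes as
competing events. Relapsed-category patients are excluded from all
survival sets. Administrative censoring at 60 months converts later
events to censorings at 60 — derivation can only remove events, never
create them (tested).

Kaplan–Meier confidence intervals use the log(−log) transform; Cox
models use Efron tie handling (the standard default, stated
explicitly) with Wald intervals and a proportional-hazards check via
the scaled Schoenfeld-residual trend test (flagged at p < 0.05).
Non-convergence and monotone likelihood are raised as errors, never
returned silently. The cumulative-incidence estimator is our own
Aalen–Johansen implementation — the increment of cause *k* at an event
time is the all-cause Kaplan–Meier survival just before it times
d<sub>k</sub>/n — which guarantees the conservation identity (cause
incidences + all-cause survival = 1) to machine precision and is
cross-checked against `cmprsk::cuminc` in the test suite. Gray's test
and Fine–Gray regression are delegated to `cmprsk`; the cause-specific
Cox flavor (competing deaths censored) is reported side by side, and
the two hazard-ratio flavors provably coincide when there are no
competing events (tested).

# The synthetic-data generator

The generator emulates the failure modes this pipeline exists to
handle, with every record carrying exactly one truth label:

- **true_somatic** — clonal variants; VAF ~ Beta around purity/2
  (default purity 0.7), depth negative-binomial (mean 1000, dispersion
  5, matching deep amplicon sequencing where pathogenic variants
  average ~1100 reads), SNV spectrum with transition probability 0.40,
  classes 3–5 with CADD/predictor annotations.
- **germline_common** — population frequency above 1%, or
  low-frequency sites drawn from the generated panel-of-normals
  blacklist; VAF near 0.5/1.
- **deamination_artifact** — exclusively C>T/G>A at low VAF (the FFPE
  signature; loading 50 of these reliably pushes Ts/Tv past 5).
- **strand_bias_artifact** — over 90% of alt reads on one strand by
  construction.
- **homopolymer_artifact** — indels flanked by 5–8 bp runs.

The coverage simulator draws an independent per-sample depth scale
(log-normal, so the sample-median normalization step is doing real
work), a per-amplicon efficiency, injects contiguous fold-change events
inside single genes, and applies log2-normal noise (default SD 0.1).
The cohort simulator draws competing cause-specific exponential event
times (defaults: lymphoma death 0.0075/month, other death 0.0045/month,
progression 0.008/month, random censoring 0.005/month over a 120-month
horizon — chosen once to land near the ~50% 5-year OS regime typical of
elderly extranodal LBCL cohorts), with covariate effects as
cause-specific log hazard ratios (defaults: rituximab −1.5 on lymphoma
death, MYD88 mutation +0.8). All randomness derives from one master
seed via fixed stream offsets, so variants, coverage and cohort can be
regenerated independently and byte-identically.

What the generator does **not** model: read-level data (no FASTQ/BAM),
mutational hotspots and signatures beyond the deamination class,
subclonal structure, purity variation between samples, inter-amplicon
GC effects, correlated multi-gene CNVs, and informative censoring.
Passing tests therefore demonstrate that the *rules and estimators* are
implemented correctly under a faithful noise model — not that the
thresholds themselves are optimal for any particular real cohort.

# Validation scale and numerical choices

The test-suite benchmarks run at sizes chosen to give tight Monte-Carlo
error at interactive runtimes: filter-oracle equivalence on 1000
boundary-spanning records; the exhaustive pathogenicity truth table
(175 cases); Ts/Tv exclusion over 200 single-sample simulations per
condition; CNV recovery over 100 simulated runs of 16 samples on a
20-gene × 8-amplicon panel (300 injected events; observed recall ≈
0.95–0.99, false-call rate ≈ 0); run-detection equivalence with a
brute-force scanner on 200 random matrices; Cox log-HR recovery over
200 cohorts of n = 500 (|bias| ≈ 0.003); and 1000-replicate null
calibration of the log-rank and Gray tests (both ≈ 5%). The end-to-end
smoke test uses the full 128-gene / 3359-amplicon panel with 28
samples.

Known limitations worth stating plainly:

- The inclusive Ts/Tv ≥ 5 rule applied to samples with few called SNVs
  (~10 under generator defaults) excludes roughly 1% of artifact-free
  samples by chance (e.g. 5 transitions against 1 transversion); with
  realistic panel-wide germline call counts this vanishes, but it is an
  intrinsic small-count property of the ratio rule, not a bug.
- Per-amplicon intervals assume approximate log-normality of
  normalized coverage; heavy-tailed amplicons would be better served by
  the percentile method.
- With 16-sample runs, a two-amplicon event adjacent to a noise
  exceedance occasionally yields a three-amplicon call; the
  consecutive-amplicon rule bounds, but cannot eliminate, such
  extensions.
- Gray's test and Fine–Gray regression rely on `cmprsk` asymptotics;
  at very small n (the motivating cohorts have ~22 evaluable patients)
  all the survival machinery is descriptive at best, which is why the
  acceptance checks validate operating characteristics at n = 120–500
  instead.
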