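---
title: "Quantifying spatial and temporal intratumour methylation heterogeneity"
author: "methylhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial and temporal intratumour methylation heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylhet)
```

## The problem

Methylation-based classification of brain tumours assumes that a single
biopsy represents the whole tumour, and that the classification made at
diagnosis still holds at relapse. Testing that assumption requires
quantifying how much the CpG methylation landscape actually differs
between regions of one tumour (spatial heterogeneity, 3–7 biopsies per
surgery) and between a primary tumour and its relapse (temporal
heterogeneity), on Illumina EPIC-style arrays reporting a β-value —
the methylated fraction, in [0, 1] — per CpG probe.

`methylhet` implements that analysis as a reusable pipeline:

1. **DMP calling.** A probe is a differentially methylated position
   (DMP) between two samples of one patient when |Δβ| > 0.3, the
   threshold at which a difference is unambiguous against technical
   variation on these arrays. The inequality is strict: Δβ = 0.30
   exactly is not a DMP.
2. **Copy-number filter.** β-values inside homozygously deleted
   regions are measurement artefacts (there is no DNA to measure), so
   probes falling in any segment with segmented log2 ratio < −0.4 in
   *any* of the patient's samples are removed before calling, together
   with the SNP genotyping probes. The −0.4 cut-off is the standard
   homozygous-deletion threshold for methylation-derived copy-number
   profiles; the inequality is again strict. A deletion in either
   sample of a pair invalidates Δβ, which is why the filter is applied
   patient-wide rather than pairwise.
3. **Aggregation.** A tumour's DMP burden is the size of the *union*
   over all unordered biopsy-pair DMP sets. The union is reported
   alongside per-pair counts and a pair-multiplicity histogram, because
   whether alterations recur across pairs or are private to one pair is
   itself informative. Burdens are also expressed as a percentage of
   the probes retained for that patient (post-filter, non-missing in
   all its samples), printed to one decimal.
4. **Direction.** For ordered primary → relapse pairs, DMPs split into
   hypomethylated (Δβ < −0.3) and hypermethylated (Δβ > +0.3) in the
   relapse, and the majority direction is reported.

## Region enrichment

Each probe carries two annotations: a CpG-island relation (Island,
Shore, Shelf, OpenSea — a partition) and a possibly empty set of
gene-region categories (TSS200, TSS1500, 5'UTR, 1stExon, ExonBnd, Body,
3'UTR); probes with an empty set are reported as IGR (intergenic). On
the gene-region axis a multi-annotated probe counts in every category
it carries, so those proportions may sum above 1.

`enrichment_test()` asks, per category, whether DMPs are over- or
under-represented relative to the array background. The background is
the *retained* probe set (post-CNA-filter, non-SNP), not the full
manifest — the comparison should be against the probes that could have
been called. The test is a two-sided one-sample Wilcoxon signed-rank on
per-patient differences (patient's DMP proportion minus background
proportion): each patient is one observation, matching the one-bar-per-
patient representation of the data. Zero differences are dropped before
ranking, standard signed-rank practice.

For n ≤ 25 non-zero differences the null distribution is computed
*exactly* by convolution over the doubled (mid)ranks, which remains
exact under tied absolute differences — the reason this is implemented
in the package rather than delegated to `stats::wilcox.test`, which
falls back to a normal approximation whenever ties occur. Above n = 25
the normal approximation with continuity correction and tie-corrected
variance is used. Categories are flagged `enriched`/`depleted` at raw
p < 0.01 with the sign of the median difference; no multiple-testing
correction is applied to the flags (Benjamini–Hochberg q-values are
reported alongside for reference). A consequence worth stating plainly:
with 12 categories tested at α = 0.01, the chance of *some* false flag
in a null cohort is roughly 10%, even though each category's error rate
is controlled — judging a single pre-specified category is reliable at
α; scanning all categories is not.

## Phylogenies, clustering, MDS

Per-patient sample relationships use Euclidean distances over the top
5000 most-variable probes (variance with denominator n − 1, ties broken
lexicographically by probe id, so selection is deterministic). The
normal-reference brain sample participates in the distance calculation
but is excluded from the variance ranking — otherwise tumour–normal
differences, not intratumour differences, would dominate the selection.
Only probes non-missing in all participating samples are candidates.

"Minimal evolution" is fixed here as: neighbour-joining starting
topology; ordinary-least-squares branch lengths on the fixed topology
(minimising the squared difference between tree path lengths and
observed distances); then a nearest-neighbour-interchange hill climb
that scans candidate rearrangements in a fixed order and takes the
first move strictly reducing the OLS total tree length, until no move
improves. Negative OLS lengths are clamped to zero only *after* the
search converges, so the criterion is always evaluated on unclamped
fits. For n ≤ 6 leaves the search provably reaches the global optimum
in our tests (exhaustive enumeration of all 105 unrooted topologies for
n = 6); on additive distances it recovers the generating tree exactly.
Trees are serialised to Newick with children ordered by the smallest
leaf label in their subtree, so equal trees always produce identical
text. Balanced (FastME-style) weighting is deliberately out of scope;
the variant is recorded in the tree's metadata as `"OLS+NNI"`.

Cohort-level structure uses complete-linkage hierarchical clustering on
the top 10000 probes (linkage configurable to average; complete is the
default because it is the more conservative choice for compact
same-patient clusters) and classical (Torgerson) MDS on the top 20000:
double-centre −D²/2, take the top eigenpairs, scale eigenvectors by the
square roots of the eigenvalues. Negative eigenvalues — distances that
are not exactly Euclidean — are truncated with a warning; asking for
more dimensions than the centred Gram matrix's rank is an error.

## Sample identity from SNP probes

The EPIC array carries 59 SNP genotyping probes whose β-values are
genotype-determined (tri-modal near 0.05 / 0.5 / 0.95) and identical
across every sample of a patient. `verify_sample_identity()` computes
Euclidean distances over the SNP probes only, and for each sample of a
patient with m ≥ 2 samples takes its m − 1 nearest neighbours and flags
the sample when fewer than half carry its patient label. The majority
vote, rather than the single nearest neighbour, is what makes a single
mislabelled sample flag *itself* and not the correctly labelled
patient-mates sitting next to it in genotype space; for m = 2 it
reduces to the nearest-neighbour rule. Single-sample patients cannot be
checked and are never flagged. The pipeline refuses to continue past
violations unless explicitly told to.

## Association statistics

* **Group comparisons** of DMP burden use Welch's t with Satterthwaite
  degrees of freedom. A group with one observation yields an explicit
  not-computable marker, never a number.
* **Purity association**: tumour cell content dilutes every observed
  Δβ linearly (observed = purity·tumour + (1 − purity)·normal), so a
  spurious association between purity difference and DMP count is the
  main artefact to exclude. The per-patient contrast is max − min
  purity across biopsies (spatial) or |relapse − primary| (temporal),
  correlated with the DMP count via Pearson's r and the t transform on
  n − 2 df.
* **Cox regression**: time to relapse is the outcome and the temporal
  DMP count the covariate, every patient being an event — an unusual
  orientation (the covariate post-dates the outcome) that is reproduced
  deliberately as the established way this association is summarised;
  a censoring vector is accepted for generality. The fit is a
  univariate Newton–Raphson on the Breslow partial likelihood, from 0,
  converging when |score| < 1e−9 (at most 50 iterations). Breslow
  rather than Efron ties because day-resolution intervals rarely tie
  and Breslow admits a simple independent oracle. Two numerical
  choices matter: the covariate is standardised internally (an exact
  reparameterisation — estimate and SE are mapped back), without which
  the score tolerance is unattainable for count-scale covariates; and
  step-halving triggers only on likelihood decreases beyond
  floating-point noise, without which Newton stalls just above the
  tolerance. Counts are used untransformed by default; `log1p_transform
  = TRUE` is available since burden distributions are heavy-tailed.

## The synthetic cohort generator

Real array data for this study design are not publicly deposited, so
validation rests on `simulate_cohort()`, which generates cohorts whose
every answer is known. It encodes exactly the structure the analysis
assumes:

* **Bimodal β**: per-patient baseline profiles from a 45/45/10 mixture
  of Beta(2,18), Beta(18,2), Beta(5,5) — the low/high methylation modes
  near 0.1 and 0.9 with minor intermediate mass.
* **Site-specific alterations**: each spatial biopsy receives 150
  private shifts of magnitude Δ = 0.5 (against noise sd σ = 0.02, so
  Δ > 0.3 + 3σ and injected sites are recoverable), directed toward the
  opposite methylation mode — which keeps shifted values inside [0, 1]
  without truncation (truncation events, if any, are counted and
  logged).
* **Region bias**: injected sites are drawn with 3× weight on OpenSea
  probes and 3× on intergenic probes (multiplicative), the default
  calibrated so enrichment is detectable with 8–10 patients.
* **Relapse accumulation**: the relapse carries Poisson(rate ×
  interval) alterations, hypomethylating with probability 0.6.
  The per-patient rate is 0.2/day scaled by a lognormal factor (mean 1,
  log-sd 0.5, about a 4-fold central 95% range). The heterogeneity is
  essential, not cosmetic: with a single cohort-wide rate the count is
  almost perfectly rank-concordant with the interval and the Cox
  partial likelihood becomes effectively monotone (the fit diverges);
  tumour types genuinely differ in accumulation rate, and the log-sd
  was chosen as the largest value in {0, 0.25, 0.5} at which the
  interval effect remains reliably detectable at the default 33-pair
  cohort.
* **Purity mixing**: each tumour sample is mixed with a shared normal
  profile at purity drawn from [0.7, 1], then perturbed with Gaussian
  noise and re-truncated. When two samples share purity p, the observed
  shift at an injected site is exactly p·Δ — a property the tests
  assert exactly.
* **Homozygous deletions**: one 20-probe deletion per patient
  (seg_mean −1) in one random sample; β over the deleted window is
  replaced by Uniform(0,1) noise, which is what forces the CNA filter
  to matter. Injected alteration sites are disjoint from deletions.
* **SNP probes**: 59 probes with patient-constant tri-modal genotypes
  shared by all of a patient's samples.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: intensity-level (IDAT) artefacts, batch
and fixation (FFPE) effects, probe cross-hybridisation, spatially
correlated alteration blocks (every injected site is independent), a
per-site effect-size distribution (Δ is fixed per design, a documented
simplification), or classifier scores. Results on real cohorts
additionally depend on normalisation upstream of this package.

## Missing data and other conventions

A probe is usable for a pairwise comparison only when non-missing in
both samples, and for variance ranking only when non-missing in all of
the patient's samples; readers reject invalid input (β outside [0, 1],
duplicate ids, overlapping segments) rather than repairing it.
Coordinates are 1-based inclusive throughout, matching array manifests
and SEG practice. Shore/shelf orientation prefixes (`N_`/`S_`) are
folded on read since analyses use four CGI categories. All stochastic
steps flow from a single seed; a pipeline run fans it out to per-stage
child seeds so stages are independently reproducible, and rerunning a
configuration reproduces reports byte-identically.

## Validation problem sizes

The shipped test-suite validates against independent brute-force
implementations (exhaustive DMP scans, full 2^n sign-pattern
enumeration for the signed-rank null, naive agglomeration for
clustering at n = 8, all 105 unrooted topologies at n = 6 for minimal
evolution, dense-grid bracketing and `survival::coxph` cross-checks for
the Cox fit) and on simulated cohorts of 2,000–20,000 probes with
3–11 spatial patients and up to 33 primary/relapse pairs; recovery
checks use noiseless pure cohorts where sensitivity and specificity
are exactly 1. The type-I behaviour of the enrichment *flag set* is
measured over 200 null cohorts; as noted above, the per-category error
rate is controlled while the familywise rate across 12 categories is
approximately 1 − (1 − 0.0098)^12 ≈ 0.11, and the suite documents this
rather than hiding it.

## A minimal session

```{r example, eval = FALSE}
design <- simulation_design(n_probes = 4000, n_spatial_patients = 4,
                            n_temporal_patients = 8, seed = 7)
cohort <- simulate_cohort(design)

idr <- verify_sample_identity(cohort$beta, cohort$sheet, cohort$manifest)
stopifnot(length(idr$violations) == 0)

samples <- cohort$sheet$sample_id[cohort$sheet$patient_id == "SP01"]
retained <- apply_cna_filter(cohort$manifest, cohort$segments, samples)
summary_sp01 <- summarize_patient_spatial(cohort$beta, samples, retained,
                                          patient_id = "SP01")
summary_sp01$union_count
summary_sp01$union_pct_of_retained

probes <- select_top_variable_probes(cohort$beta, c(samples, "NORM1"),
                                     k = 1000,
                                     exclude_from_selection = "NORM1")
D <- euclidean_distances(cohort$beta, c(samples, "NORM1"), probes)
tree <- attach_reference_and_root(build_me_tree(D), "NORM1")
write_newick(tree)
```

Or end-to-end from a YAML configuration with `run_pipeline()`, which
adds enrichment, cohort clustering/MDS and the association statistics,
and writes JSON reports plus Newick trees under the configured output
directory.
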