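---
title: "Methods: somatic interpretation and real-world outcome analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic interpretation and real-world outcome analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncowga)
library(dplyr)
```

oncowga models the post-variant-calling half of a clinical tumor
whole-genome-sequencing service: call sets (somatic small variants, copy
number segments, structural variants, germline calls) come in from upstream
callers, and the package applies the interpretation rules that turn them
into a per-case report, computes pangenomic markers, links cases to
registry and hospital-episode data, and produces cohort-level analytics.
Everything upstream of the call sets — alignment, primary calling,
contamination estimation — is out of scope and consumed as input.

This vignette records the model choices, the tunable parameters, what the
synthetic cohort generator does and does not emulate, and the numerical
decisions a maintainer would want to know about.

## Sequencing quality gate

A tumor–normal pair enters analysis only if the normal sample yields more
than 85 Gb and the tumor more than 210 Gb of high-quality bases (base
quality over 30, duplicates removed), more than 95% of the normal's
autosomal genome is covered at 15×, cross-patient contamination is below 3%
(normal) and 2.5% (tumor), and the pair is concordant. All comparisons are
strict, reading "more than"/"lower than" literally; `qc_gate()` reports
every violated threshold, not just the first. PCA-based monitoring of
sequencing metrics is represented only as a pass-through metrics record: no
published thresholds exist for it, so gating on it would be invented
behavior.

## The five-rule somatic filter cascade

`apply_somatic_filters()` labels each somatic small variant with any of
five flags; flagged variants are *retained and labeled*, never deleted,
because a clinically actionable variant still goes to review even when a
filter fires. The flag-free ("high-confidence") subset is the input to TMB
and mutation catalogs.

| rule | flag | threshold (default) |
|---|---|---|
| population germline allele frequency | `pop_af` | strictly above 1% |
| cohort somatic recurrence | `recurrent` | strictly above 5% |
| simple-repeat overlap | `simple_repeat` | any overlap |
| noisy indel window | `noisy_indel` | at least 10% failed calls in ±50 bp |
| panel-of-normals Fisher test | `pon_artifact` | Phred strictly below 50 |

The rules commute: each consults only the variant and the reference bundle,
so flags are independent of evaluation order.

The noisy-indel window spans 101 positions (the indel position plus 50 on
either side, truncated at the contig start). The caller's read-level
filtering is approximated by a per-position `(fail_frac, depth)` track,
since read-level detail is not reconstructable from call sets; positions
absent from the track are treated as fail-free at a default depth of 30.

### The panel-of-normals test

At each SNV site the tumor's ref/alt allele depths are compared with the
aggregated allele depths of a panel of non-tumor genomes using a two-sided
Fisher's exact test; the p-value is expressed as a Phred score
(−10·log₁₀ p). Artifact sites show low-level alternate reads across many
panel individuals, so the tumor ratio resembles the panel ratio, the
p-value is large, and the Phred score falls below 50. Two-sided is chosen
because "significantly different" carries no direction.

Individuals *carrying the alternate allele as a germline variant* must be
excluded from the aggregation, otherwise common polymorphisms look like
artifacts. We operationalize "carrying" as an alternate allele fraction at
or above `pon_carrier_min_fraction` (default 0.35, i.e. germline-het-like).
Reading "not carrying" as literally "alt depth 0" would zero the panel alt
column identically and make the test blind to the low-level noise it
exists to catch; setting the threshold to 0 recovers that literal reading
if wanted. A site absent from the panel is treated as alt-free at
`pon_default_ref_depth` (30) per individual. Panel depth is not capped.

## Consequence annotation

Annotation is restricted to one canonical transcript per gene (carried in
the gene model; no fallback hierarchy) and one curated consequence set:
stop gained/lost, start lost, frameshift, in-frame insertion/deletion,
missense, splice acceptor/donor, splice region. A variant outside the set —
deep intronic, intergenic, synonymous, UTR — is not reportable. Splice
acceptor/donor sites are the 2 intronic bases flanking an exon
(strand-aware); the splice region is the conventional 3–8 intronic or 1–3
exonic bases from a junction. Coding SNVs are classified by codon
translation; coding indels by length modulo 3. When an exonic variant has
both a coding and a splice-region interpretation the coding one wins
(most-severe-first, as annotators conventionally do).

## Copy-number and fusion rules

Gains in oncogenes are reported when total CN is at least `gain_multiplier`
(default 2) times the case ploidy. "At least twice higher than the overall
ploidy" could be read as 2× or 3×; we use 2×, matching common usage and the
caller-ploidy framing, and expose the multiplier. Losses in tumor
suppressors follow three scenarios with precedence 1 > 2 > 3: (1)
homozygous deletion (CN 0), reported on its own; (2) LOH (CN 1) or
copy-neutral LOH (minor CN 0 with total CN within `cn_neutral_tol` = 0.5 of
ploidy) combined with a nonsynonymous small variant; (3) an SV breakpoint
strictly inside the CDS combined with a nonsynonymous small variant.
Caller CN values are compared unrounded for the 2×-ploidy rule; the
one-copy co-occurrence rule (gain ≥ rounded ploidy + 1, loss ≤ rounded
ploidy − 1) is stated in copies and therefore uses the rounded ploidy.
Cases at or below 30% purity are excluded from all CN actionability.
"Nonsynonymous" means the protein-altering curated set, i.e. everything
except `splice_region_variant`.

Fusion assessment asks whether a breakend junction can produce a 5′→3′
read-through respecting both strands and breakend orientations; if not, the
event is `untranscribed` and discarded. Otherwise the coding phase at each
breakpoint is the cumulative CDS length to the junction modulo 3, walking
exons in transcript order; the fusion is `inframe` when the phases match
and `out_of_frame` (discarded) when both are defined and differ. Two
configurations are deliberately `ambiguous` and reportable: a downstream
breakpoint in the 5′ UTR (whole CDS retained, includes promoter-swap
events) and an exonic breakpoint that splits a codon, where we report
rather than guess the phase. A junction that retains the complete upstream
CDS including its stop codon produces no fusion ORF and is grouped with
`untranscribed`. Reportable = {inframe, ambiguous}, always.

## Germline and pharmacogenomic reporting

For genes in the directory's germline-indicated set (tumor-type-restricted
by default; `germline_tumor_type_restricted = FALSE` widens to the panel),
a variant is reportable either via ClinVar — pathogenic or likely
pathogenic with at least two review stars — or as a predicted
protein-truncating variant (stop gained/lost, start lost, frameshift,
splice acceptor/donor) in a gene whose mechanism of pathogenicity is loss
of function. "Probably pathogenic" maps to the standard "likely
pathogenic" term. PGx flags are exact-match lookups against an allele
table (the packaged table is a documented toy; real DPYD star-alleles drop
in as a TSV) with the recommendation text passed through.

## Pangenomic markers

TMB is the number of nonsynonymous high-confidence somatic small variants
per megabase of coding sequence; the coding footprint is the CDS union of
the gene models (config-overridable). Mutation catalogs use the standard
96 trinucleotide contexts in pyrimidine-strand convention. Signature
refitting is nonnegative least squares against a packaged signature
matrix, with exposures normalized to fractions of assigned mass and the
reconstruction residual reported. NNLS replaces a full de-novo extraction
suite deliberately: it is deterministic, fast, and has the same contract
(catalog in, exposures out).

The packaged matrix is a **synthetic stand-in**: it carries the COSMIC v3
SBS names used by the etiology map (plus decoys) but its profiles are
generated in code (`synthetic_signature_matrix()`), sparse and
well-separated so refits are well-conditioned. Real COSMIC profiles load
via `read_signature_matrix_tsv()`. Conclusions about real tumors require
the real matrix.

Etiology groups are fixed: APOBEC (SBS2/13), aging (SBS1), HRD (SBS3), MMR
deficiency (SBS6/15/20/21/26/44), POLE (SBS10a/10b/14), smoking (SBS4/92),
UV (SBS7a–d). SBS14 sits in the POLE group only, avoiding double counting
between POLE and MMR. A group not above 20% is reassigned to "other", and
a tumor is MMR-deficient when the MMR group exceeds 20%. The 20% rule is
applied per etiology group (not per signature), in the order group →
threshold → MMR call; because both thresholds are 20% the order does not
change the call, but it fixes the reported group table. HRD classifiers
are not re-implemented — scar-based classifier calls are inputs — and only
their concordance is computed.

## Clinical linkage and staging

Tumor-type corroboration is an ordered cascade: registry rows (benign and
in-situ tumors removed) whose ICD-10 site maps to the submitted type;
otherwise the nearest-in-time cancer-primary hospital episode whose ICD-10
matches (ties broken toward the earlier date — the sources are silent, and
determinism matters more than the choice); otherwise a curated operation
code on an episode dated exactly at sampling (primary tumors only);
otherwise, for the configured colorectal-registry/submission pairs, any
episode strictly within 7 days; otherwise the codes submitted at
collection; otherwise unmatched. When the nearest episode is
type-discordant but a farther one matches, we use the nearest
*type-matching* episode — the alternative reading (nearest episode, then
test) is stricter but makes the outcome depend on unrelated admissions.

Stage: metastatic submissions are stage 4 unconditionally. Otherwise FIGO
(ovarian/endometrial; I–IV, sub-letters ignored), Dukes (colon/rectum;
A–D → 1–4) or `stage_best` simplified to its leading digit, taken from the
nearest registry row and only when the diagnosis date is strictly within
365 days of sampling; otherwise unknown. Unparseable codes yield unknown
with a warning.

## Cohort analytics

Actionability prevalence is the per-tumor-type fraction of cases with at
least one finding per gene and variant class, split into
directory-indicated and non-indicated partitions; denominators are the
cases passing the gates relevant to the class (the purity gate for CNA).
Co-occurrence uses a two-sided Fisher's exact test per gene (the source
names no test; Fisher is exact at these counts) with Benjamini–Hochberg
correction across genes (config-exposed Bonferroni); genes with an empty
stratum are reported as undefined rather than dropped silently.

Survival: Kaplan–Meier per group, a stage-stratified log-rank test, and a
Cox model with the group indicator plus categorical stage (1–4) as the
stage correction — unknown-stage cases are excluded rather than imputed,
since no imputation is described for the procedure we model. "Stratified
log-rank" is interpreted as stratification by stage, matching the stage
correction of the Cox model. The survival origin is the registry diagnosis
date, falling back to the sampling date (config-exposed); censoring uses
the last episode or treatment date. TMB stratification contrasts the
lowest against the highest quartile within the analyzed tumor-type subset,
dropping the middle two quartiles.

## The synthetic cohort generator

`simulate_cohort()` generates everything the pipeline reads — reference and
gene models, resource tables, panel of normals, per-case call sets,
clinical tables — with a per-case truth record, so every stage is testable
offline and end-to-end recall of planted events is measurable exactly.

Study conditions baked into the defaults: ten solid-tumor types with
type-specific signature mixtures and MMR/HRD prevalences (e.g. MMR 15–25%
in colorectal/endometrial, HRD 40% in high-grade serous ovarian);
log-normal mutation counts (median 180, higher in melanoma and lung,
5-fold under MMR deficiency); purity Beta-distributed around 0.67 with 10%
of cases below the 30% gate; 10% metastatic submissions; a 60-genome panel
of normals with 40% noise sites at 12% noise VAF; registry mismatch rate
5%; stage availability 85%; exponential survival with a stage-dependent
baseline (stage is also a confounder of marker assignment, so crude
hazard ratios are biased and stage correction is genuinely exercised) and a
protective hazard ratio of 0.5 for HRD-positive cases.

The toy genome is two contigs (~13 kb) carrying 14 three-exon canonical
transcripts with UTRs, clean ORFs and stop-free interior codons, so coding
consequences and fusion frames are exactly computable. What the generator
does *not* emulate: genome-scale mutation density (200 mutations on 13 kb
is dense, so most genes carry background coding hits and prevalence
saturates — planted-event recall, not prevalence realism, is the testable
quantity), subclonal structure, read-level errors, selection, indel/DBS
signatures, and real registry dialects. Passing tests therefore demonstrate
correctness of the rules and recoverability of planted truth, not
performance on real data.

Planted actionable variants get deterministic allele depths (VAF ≈
purity/2, at least 0.30) so that a binomial fluctuation cannot push a
"clean" planted event under the panel-of-normals filter; background
variants keep binomial noise.

## Numerical choices and test scales

Fisher p-values come from `stats::fisher.test` (two-sided); tests compare
them against an independent hypergeometric enumeration to 1e-6 on the
Phred scale. NNLS uses `pracma::lsqnonneg`. Degenerate inputs are defined,
not errors: an all-zero Fisher table has Phred 0; a zero-event group
reports an undefined (NA) hazard ratio; an all-censored cohort is an
error, as is an empty mutation catalog.

Problem sizes used by the test suite and the acceptance script, chosen to
keep the full run at desk scale: 30-case fixture cohorts for unit tests; a
300-case cohort for the end-to-end check; 20 000 mutations × 20 seeds for
signature recovery; 2 000 subjects × 20 seeds per hazard-ratio setting
(about 1 000 per arm under randomized assignment); 200 null cohorts of 200
cases for co-occurrence calibration; exhaustive Fisher tables to total 16
plus 2 000 randomized tables to total 200; and every breakpoint placement
on a 3×3-exon toy transcript pair for the fusion oracle.

## Known limitations

Canonical-transcript annotation ignores multi-transcript effects; the
noisy-indel track is an approximation of read-level counts; CN calls are
taken at face value (no smoothing or re-segmentation); germline CNVs and
ACMG re-classification are out of scope; the co-occurrence test treats
cases as independent; and the packaged signature profiles are synthetic,
as stressed above.
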