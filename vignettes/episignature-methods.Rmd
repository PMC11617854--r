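---
title: "Episignature discovery and MVP classification: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episignature discovery and MVP classification: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episig)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## The problem

An episignature is a reproducible, genome-wide pattern of blood DNA
methylation associated with pathogenic variants in a single gene. Once
established on a discovery cohort, it serves as a diagnostic biomarker: a
new sample — in particular one carrying a variant of uncertain
significance (VUS) — is scored against the signature, and a score near 1
supports pathogenicity while a score near 0 argues against it. The
package implements the full chain from a beta-value matrix to that score
for a case/control study of the kind used for NEDAUS (*CUL3*
haploinsufficiency), whose 26-participant variant table is bundled as the
package's one piece of real data.

## Preprocessing

**Filter cascade.** Probes are excluded, in a fixed order: (1) any failed
detection (detection p above `detection_p_max = 0.1` in any sample, or a
missing beta); (2) chrX/chrY probes (sex-linked methylation would
dominate any mixed-sex contrast); (3) SNP-affected probes; (4)
cross-reactive probes; (5) probes with any beta within `beta_clip_eps` of
0 or 1, whose logit is effectively infinite; (6) the most variable
probes, `top_variable_fraction = 0.01` of what remains, ranked by
across-sample SD (ceiling count, ties broken by probe id). The cascade is
order-dependent by construction; with the variability step disabled it is
idempotent. The variability statistic (SD over all analysed samples) is a
documented choice — MAD over controls would be a defensible alternative —
and the "any sample" detection rule is the strictest reading of the
detection criterion; both are config-exposed.

**Control matching.** Greedy nearest-neighbour matching without
replacement selects `match_ratio = 2` controls per case minimising
`|age difference|/age range + 1·(sex mismatch) + 1·(batch mismatch)`.
The weights are package choices (reference workflows delegate to a
matching package without stating weights); total-distance ties prefer sex
concordance, then pool order, which keeps the procedure deterministic.
The ratio default of 2 reflects common practice of requesting about twice
as many batch-matched controls as cases.

**M-values.** Betas are clipped to `[eps, 1−eps]`
(`beta_clip_eps = 1e-6`) and mapped to `M = log2(beta/(1−beta))`, the
variance-stabilised scale on which linear modelling behaves well. The
transform is strictly increasing and antisymmetric about beta = 0.5.

## Differential methylation

Per probe, ordinary least squares of M on an intercept, a case/control
indicator, and the blood-cell fractions (one of the six is dropped —
`cd8t` — to break the sum-to-one collinearity; covariate columns constant
across samples are likewise dropped as they carry no information). Cell
fractions enter because cell-composition differences are the dominant
confounder of blood methylation contrasts.

Variances are moderated empirically: residual variances are modelled as
draws from a scaled inverse-chi-square prior with degrees of freedom
$d_0$ and scale $s_0^2$, estimated by the method of moments on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, using a Newton inversion
of the trigamma function; the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields a moderated t
with $d_0 + d_g$ degrees of freedom. This is the standard moderated-t
construction; the package's own implementation is cross-checked against
limma in the test suite. When all variances are identical the estimator
returns the $d_0 = \infty$ sentinel with $s_0^2$ equal to the common
variance, and a config override can force $d_0 = 0$ (no shrinkage) for
oracle comparisons. Two-sided p-values are used throughout because real
episignatures contain both hypo- and hypermethylated probes;
Benjamini-Hochberg adjustment is reported in parallel (moderation and
multiplicity adjustment are different operations, and both views are
useful: moderated p for ranking, adjusted p for DMP-set definitions).

Calibration: under a global-null simulation the fraction of moderated
p-values below 0.05 sits at the nominal level on average (0.051 over six
seeds at 10,000 probes). Because probes sharing cell-composition loadings
are correlated, the realised fraction has extra-binomial spread across
seeds; single-seed checks use a fixed reference seed.

## Probe selection

Three sequential stages, all deterministic:

1. **Product ranking** — probes are scored by
   `|delta beta| × (−log10 p)` and the top `product_rank_k = 1000`
   retained (ties: smaller p, then probe id). The product balances effect
   size against evidence, suppressing tiny-effect, tiny-p probes.
2. **AUC retention** — per-probe ROC AUC on M-values, computed as the
   normalised Mann-Whitney statistic with the orientation-free form
   `max(a, 1−a)`; probes below `auc_min = 0.75` are dropped.
3. **Correlation pruning** — a greedy scan in rank order keeps a probe
   iff its absolute Pearson correlation with every already-kept probe is
   at most `corr_prune_r = 0.85`, so the strongest member of each
   correlated clique survives.

The numeric thresholds are package defaults chosen to emit signatures of
the order of hundreds of probes at the reference scale; reference
workflows describe the same cascade without publishing thresholds, and
all three are config-exposed.

**Which samples feed the pruning correlations was a genuinely open design
point.** Pruning exists to remove co-methylation redundancy — genomically
adjacent or biologically coupled probes that carry the same information.
Computed across cases *and* controls, the case/control separation itself
correlates every true signature probe with every other (for a planted
effect of Δβ ≈ 0.15 the induced correlation is ≈ 0.9, above any sensible
threshold), so pruning would collapse the signature to a handful of
representatives. The package therefore computes pruning correlations over
the control samples only, where the disease effect is absent and what
remains is exactly the redundancy the step is meant to remove.

At the reference conditions (20,000 probes, 300 planted, 16 cases vs 32
matched controls) the cascade's false positives are governed by the exact
null AUC tail: about 0.45% of null probes reach AUC ≥ 0.75 at these group
sizes, so roughly 60–75 chance probes accompany the ~290 recovered
planted probes. Single-seed precision therefore fluctuates around 0.82
(recall ≈ 0.98); the recovery tests assert the mean over the package's
reference seeds (1–3). This is an inherent property of a fixed-threshold
cascade at desk scale, not a tunable defect: more controls or a stricter
AUC floor would trade it against recall.

**Unsupervised views and LOOCV.** Ward clustering (`ward.D2` on Euclidean
distances) and classical (Torgerson) MDS — with each MDS axis flipped so
its largest-magnitude coordinate is positive, a deterministic orientation
convention — provide the standard two-way heatmap ordering and sample
embedding. Leave-one-out cross-validation runs exactly one round per case
sample; in each round the signature is re-selected and the classifier
re-trained without the held-out case, which is then assigned to the
nearer of the case/control centroids in signature M-space (the
operational meaning of "clusters with cases") and scored by the refit
model. Round failures are recorded per round rather than aborting the
loop.

## The MVP classifier

A linear SVM (cost `svm_C = 1`) on signature-probe M-values standardised
by training mean/SD. The linear kernel suits the p ≫ n regime and is
established practice for episignature classifiers. The positive class is
all case samples; the negative class is a seeded `train_fraction = 0.75`
draw of controls plus the same fraction of each other-disorder cohort —
other disorders enter only the negative class, teaching the model to
separate *this* signature from other methylation-disrupting conditions.
The held-out 25% is retained inside the model object for specificity
evaluation, and a structural leakage guard refuses to score a VUS that
appears in the training composition.

Decision values are mapped to [0, 1] by Platt scaling — a sigmoid
`1/(1 + exp(A·d + B))` fitted by maximum likelihood with Platt's
regularised targets `(N₊+1)/(N₊+2)` and `1/(N₋+2)`, which keeps the fit
well-defined on separable data. The resulting score is the MVP
(methylation variant pathogenicity) score; `mvp_threshold = 0.5` calls a
sample signature-positive, and scores within 0.1 of the threshold are
flagged borderline. Note the regularised targets cap fitted training
probabilities at `(N₊+1)/(N₊+2)` — with 16 training cases, at ~0.944 —
which is why well-separated cases score ≈ 0.94 rather than 1.0.

## Cross-cohort comparison

Each cohort is summarised by its top `top_n_dmps = 500` probes by
moderated p (ties: larger |Δβ|, then id) with their beta-scale effects —
a fixed-size set that avoids biasing comparisons by per-cohort DMP
counts. The overlap matrix entry (A, B) is `100·|A∩B|/|A|`: rows are the
reference cohort (denominator), columns the comparison; the matrix is
intentionally asymmetric and the diagonal is 100. For the cohort tree,
each cohort's Δβ vector over the union of all top-N sets (zero-filled
where a probe is absent) is clustered by average linkage on Euclidean
distances — deliberately different from the Ward linkage used for sample
heatmaps, as average linkage is more robust for cohort-level
dissimilarity; zero-fill (rather than intersection or binary membership)
keeps both membership and effect size informative. Cohorts are sorted by
name before clustering so the emitted newick is input-order invariant.
The global mean methylation difference — the mean of a cohort's top-N
effects — summarises the direction of dysregulation; predominantly
hypomethylated signatures give negative values.

## Annotation and DMRs

Probe positions (1-based points) are converted to 0-based half-open
single-base intervals for intersection with BED-convention tracks. CGI
context: island (inside a CGI), shore (within 2 kb of an edge), shelf
(2–4 kb), inter-CGI, with precedence island > shore > shelf so a probe
between two CGIs is counted once. Gene context: promoter (≤ 1 kb upstream
of the TSS, strand-aware), promoter+ (1–5 kb upstream), gene body (the
gene span, consolidating UTRs/exons/introns/boundaries), intergenic, with
precedence promoter > promoter+ > gene body; multi-gene overlaps resolve
by the same precedence, so every probe gets exactly one category per
scheme. Enrichment is the textbook χ² goodness-of-fit statistic of
observed DMP category counts against the background category proportions
of all analysed (post-filter) probes — the background universe is a
documented, config-exposed choice (all array probes would be the
alternative).

A DMR is a maximal run of consecutive significant probes — consecutive
among *all analysed* probes, otherwise the spacing constraint would do
all the work — of at least `dmr_min_probes = 5` probes whose
first-to-last span is at most `dmr_max_span_bp = 1000`. "Within 1 kb" is
ambiguous between this span reading and an adjacent-gap reading; the
stricter span rule is the default and the gap rule
(`dmr_rule = "gap"`) is available behind the config switch.

## The cohort variant table

The bundled 26-row table is parsed with a deliberately tolerant
classifier keyed on the protein-level token: array-CNV descriptors
(`arr[...](start_end)x1`) are deletions; `fs` anywhere in the protein
change is a frameshift (so `fs*NN` outranks the stop symbol — a
duplication creating an immediate stop, with no `fs`, is nonsense); a
substitution to `*`/`∗` is nonsense; `p.?` with an intronic cDNA offset
within 3 bp of a splice boundary is a splice site; a single amino-acid
substitution is missense. Full HGVS grammar is intentionally avoided: the
printed table contains typographic irregularities (a duplicated change
token, a missing or capitalised `c.` prefix) that a strict grammar would
reject, and the token-based rules classify all 26 rows correctly. The
discovery/validation split (17/9) follows the table labels; signature
status (18/8) groups the discovery cases and the reclassified-positive
VUS against the remaining VUS and the signature-negative cases. Phenotype
comparison computes per-feature percentages over *known* values only,
keeping "unknown" distinct from "absent", and reports its denominators
explicitly because the real per-case clinical table is supplementary
material not reproduced here (a synthetic phenotype table mirroring the
18/8 split ships with the analysis drivers).

## The synthetic-data generator

The generator exists so every downstream stage is testable at desk scale
with known ground truth. It emulates, per probe: a three-mode baseline
methylation distribution (unmethylated ≈ 0.1, intermediate ≈ 0.5,
methylated ≈ 0.85, beta-distributed spread) matching real blood array
marginals; heteroscedastic per-probe noise (gamma-spread SDs around
`noise_sd = 0.03`, covering technical plus inter-individual biological
variability); a hypervariable class (`hypervar_fraction = 0.025`) of
mQTL-like bimodal probes with population-mixture SDs of 0.1–0.25, the
class that dominates the top-variance tail of real arrays and that the
top-1%-most-variable filter is designed to catch; cell-composition
confounding, linear in Dirichlet-drawn blood fractions with
probe-specific coefficients on a random 20% of probes (six components,
matching the blood reference deconvolution count); small per-probe batch
offsets for a two-batch structure; and sporadic detection failures
(`detection_fail_rate = 1e-4`), independent of case status, that blank
the beta and raise the detection p above 0.1.

The planted episignature shifts `signature_size` probes by signed
beta-scale effects with mean magnitude `effect_delta`; `hypo_fraction =
0.9` of them shift downward, emulating the predominant hypomethylation
of real signatures of this class. Effects are applied on the beta scale
(effects are reported as beta differences) and betas are then kept
strictly inside (0, 1) at [0.001, 0.999] — Illumina betas are intensity
ratios with an offset and never reach the boundary, so exact 0/1 values
would be a simulation artifact rather than a feature of real data.
Planting is restricted to autosomal, unflagged, mid-range-baseline
(0.2–0.8), non-hypervariable probes: a real discovered signature is by
construction a subset of analysable probes. Other-disorder cohorts get
their own planted sets sharing a common core of
`round(overlap_fraction × signature_size)` probes, so pairwise overlap is
exact by set arithmetic. All cohorts of one design share a single "array
world" (baselines, noise SDs, confounding structure, planted
allocations), so the index cohort, controls, VUS stand-ins and other
disorders are mutually comparable, and the three generator entry points
are consistent with each other for the same seed.

What it does **not** emulate: probe-type (Infinium I/II) chemistry and
normalisation artifacts, spatial chip effects, age- and sex-dependent
methylation drift, genomic clustering of signature probes (planted probes
are scattered, so co-methylation redundancy among true positives is
absent and the pruning step's effect on real adjacent-probe blocks is
exercised only through the hypervariable and confounded classes), and
population stratification of mQTLs. Passing recovery tests therefore
demonstrates the pipeline's statistical machinery under a faithful noise
and confounding model — not performance on any particular real cohort.

## Problem sizes and determinism

The reference conditions used by the tests and the analysis drivers are
20,000 probes, 16 cases / 64-control pool (32 matched), 300 planted
probes at mean |Δβ| = 0.15 (90% hypomethylated), two other-disorder
cohorts of 16, and single VUS stand-ins; moderation recovery uses 5,000
probes × 10 seeds and null calibration 10,000 probes. These sizes were
chosen as the smallest at which every stage behaves as it does
asymptotically (the planted-recovery and specificity margins stabilise).
Every stochastic step is driven by an explicit seed: the generator from
`sim_design(rng_seed=)`, the classifier's training draw from
`episig_config(rng_seed=)`; given both, the whole pipeline is
bit-reproducible.

## Known limitations

- Probe selection assumes a two-group contrast; multi-class signatures
  and one-vs-rest panels across many disorders are out of scope.
- The moderation moment estimator assumes a common residual d.f. pattern
  and positive variances; probes with zero residual variance are excluded
  from estimation.
- The matching distance is a simple additive score, not an optimal
  full-cohort assignment; with sparse pools, early cases can exhaust the
  good matches.
- MVP scores are Platt-calibrated on the training draw only; they are
  ordinal evidence, not population-calibrated probabilities, and their
  ceiling depends on the number of training cases.
- The DMR caller reports runs, not effect-coherent regions: it does not
  require a consistent direction of change within a run.
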