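---
title: "Methods: multi-table integration of MRS metabolite profiles and transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-table integration of MRS metabolite profiles and transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsomics)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the assumptions they rest on, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical decisions taken where the design was genuinely open.

## The data and their preparation

Two data types flow through the package. **Metabolite tables** hold one row
per ¹H-MRS measurement — a hemisphere of a mouse at a scan date, or one
voxel of a patient grid — and one column per quantified metabolite, with a
parallel matrix of Cramér–Rao lower bounds (CRLB, in percent) expressing
per-entry quantification uncertainty from spectral fitting. **Count
matrices** hold gene-by-sample raw RNA-seq counts from xenograft tissue in
which every gene carries a species label (`human`, `mouse`, `ambiguous`)
assigned upstream by a read classifier; the package consumes these labels
and never touches reads.

Preparation follows fixed rules, each exposed as its own verb:

- `filter_by_crlb()` excludes entries whose CRLB strictly exceeds a
  threshold — 40% is the usual per-scan rule for high-field mouse spectra,
  50% for patient data. Exclusion means `NA`, never zero: a censored fit
  carries no information about concentration. Retained values are never
  altered.
- `ratio_to_reference()` divides each metabolite by the per-row sum of
  total creatine (Cr + PCr), the internal reference when water scaling is
  unavailable. A `drop_reference` flag controls whether Cr and PCr remain
  in the output (as ratios); the trajectory pipeline keeps them, so the
  loading display carries the full measured panel.
- `tmm_factors()` (via edgeR) and `log_normalize()` implement the TMM /
  log-CPM convention: `log2((count + 0.5) / (lib_size × factor) × 1e6)`.
  The 0.5 pseudocount is the standard guard for zeros; the CPM scale makes
  samples with 20–60 million reads comparable.
- `filter_low_counts()` keeps genes with CPM ≥ 1 in at least 25% of
  samples (defaults; both exposed) and always drops ambiguous genes.
  `partition_species()` and `exclude_low_read_samples()` split the matrix
  by species and drop samples whose (mouse) total falls strictly below one
  million reads — below that, host-response estimates are dominated by
  sampling noise.

Missing metabolite entries are completed by `impute_regularized_pca()`:
iterate column-mean initialization → centering → truncated SVD at `ncomp`
→ reconstruction with singular values shrunken as `d → (d² − σ̂²)/d`, where
σ̂² is the mean of the trailing eigenvalues → restoration of observed
entries, until the imputed cells move less than `tol` (RMS). The shrinkage
is what keeps the algorithm from hallucinating structure into the missing
cells at low signal-to-noise. The default `ncomp = 2` matches the
two-component analyses used throughout the package; the choice is exposed
because nothing in the data dictates it.

## Ordination on statistical triplets

Every ordination operates on a *statistical triplet*: a matrix X with a
diagonal row-weight metric D (weights summing to 1) and a diagonal column
metric. PCA is the generalized SVD of X under those metrics; total inertia
(the weighted sum of squares) always equals the sum of eigenvalues, which
the tests assert to 1e-9. Metabolite tables are unit-variance scaled by
default because metabolites live on heterogeneous concentration scales;
expression tables are not, because log-CPM is already a common scale.

Axis signs are arbitrary in any eigendecomposition. Two conventions are
layered: inside every ordination, each axis is flipped so its
largest-magnitude loading is positive (reproducibility); in the pipelines,
`orient_tumor_axis()` additionally flips STATIS axis 1 so NAA — the
canonical neuronal marker, depleted wherever tumor displaces neurons —
loads negatively, making high scores mean "more tumoral" everywhere.

`within_group_center()` subtracts row-weighted group means; PCA of the
centered triplet is the within-group analysis (WCA) used to remove the
patient-of-origin effect from expression before integration. The
between-group inertia percentage is tested by permutation of group labels
with `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`, which is exchangeable-valid
by construction; its type-I error at α = 0.05 is checked over 500 null
replicates in the acceptance suite.

## STATIS

K tables sharing variables (one per mouse, rows = scans; one per patient,
rows = voxels) are each summarized by their variable-space inertia operator
`C_k = X_k' D_k X_k`, Frobenius-normalized so no table dominates by scale.
The interstructure is the K×K matrix of RV coefficients between operators;
its leading eigenvector — computed by power iteration from the uniform
start, so it is non-negative (Perron–Frobenius) and lands on uniform
weights in the degenerate orthogonal-tables case — gives table weights α
summing to 1. The compromise `C = Σ α_k C_k` is eigendecomposed into
consensus metabolite loadings, and every table's rows are projected onto
those axes (`project_rows()` also scores new tables, with the centering
reference — own means, fitted grand mean, or none — as an explicit
argument). Operators are built in variable space because the tables share
columns, not rows.

## Sparse selection and bootstrap consolidation

`spca()` and `spls()` use the cardinality ("keep-X") form of lasso
regularization: in each alternation step the loading update is
soft-thresholded at the (keep+1)-th largest absolute entry, so exactly
`keep` coordinates survive, with ties broken by variable order. sPLS runs
the same alternation on the cross-covariance `M = X'Y`, thresholding only
the gene-side loading (all metabolites retained), and deflates both blocks
by regression on their own latent scores (canonical mode — the blocks are
co-analyzed, neither predicts the other). With `keep` equal to the number
of variables both reduce to the dense SVD/PLS solutions, which the tests
verify against direct SVD and an independent power-iteration oracle.

Two properties of this scheme are worth stating precisely. First,
soft-thresholding shrinks the surviving entries, so the returned loading is
not the covariance-maximizing unit vector on its support; the meaningful
optimality claim — verified exhaustively over all supports on small planted
instances — is that the *selected support* attains the best achievable
leading singular value. Second, on unstructured noise the alternation is a
heuristic and can settle on a slightly suboptimal support, exactly as the
field's standard implementations do; no test pretends otherwise.

`bootstrap_consolidate()` stabilizes the selection: observations are
resampled with replacement (stratified by subject when labels exist, so no
resample collapses onto a single patient and the paired
injected/contralateral design is respected), the fit is repeated, and a
variable counts as selected in an iteration if it is nonzero in either
component's loading (the per-component denominator is available as an
option). Variables with selection frequency ≥ 0.1 — and > 0, so a cutoff of
0 means "ever selected" — are retained, and the final fit is recomputed on
the full data restricted to the retained set. Defaults are 50 resamples,
2 components, 50 variables per loading, cutoff 0.1.

## Coinertia, RV tests, variation partitioning, clustering

`coinertia_fit()` decomposes the row-weighted cross table `Z = Y'DX` by SVD
under the column metrics into paired co-loadings and row scores; the
squared singular values sum to the total coinertia (asserted to 1e-9). The
global co-structure is the RV coefficient, tested by permuting the rows of
one block (the gene block by default — the choice is statistically
symmetric). `variation_partition()` computes redundancy-analysis R² for
every subset of 2–3 named explanatory sets and derives unique and shared
Venn fractions by inclusion–exclusion; unadjusted fractions sum with the
residual exactly to 1, and an Ezekiel-adjusted variant (fractions may be
slightly negative) matches vegan's convention and is cross-checked against
it. Collinear designs are fit by pseudoinverse with a warning rather than
an error, because indicator sets of related covariates (origin, type,
tumor content) are collinear by nature. `consensus_kmeans()` repeats
k-means from k-means++ initializations (seeds derived from one master
seed), accumulates the co-assignment frequency matrix, and cuts its
average-linkage hierarchy at k; `ward_heatmap_order()` supplies
Euclidean/Ward leaf orders for heatmap display.

## Enrichment

`hypergeom_enrichment()` computes the upper-tail hypergeometric probability
of each overlap, with the universe defined as the genes that actually
survived preprocessing in the analysis at hand — not the genome — because
selection only ever operated on those. Gene sets are intersected with the
universe first; sets with no overlap are not tested, and the Bonferroni
divisor is the number of sets actually tested. Significance is flagged at
adjusted p ≤ 0.1. Mouse symbols are converted through a user-supplied
two-column homolog table (`map_homologs()`; no live database queries), with
provenance kept so each enriched set reports its human read fraction. No
gene-set collection is bundled; the GMT reader accepts any.

## What the generator emulates — and what it does not

The generators produce study-shaped data with planted truth serialized
alongside, so every downstream claim is checkable.

**Longitudinal tables** (`simulate_longitudinal()`): 5 subjects × 3 mice,
injected and contralateral hemispheres scanned every 2 weeks from day 28
to 112. Tumor burden follows `plogis(rate × (t − 70))` per mouse, with
per-mouse rates log-normally spread (CV 0.25) around the subject rate —
mice of one patient engraft at different latencies, and without that
spread the burden would be an exact function of subject × side × time and
covariates like human-read fraction would have no unique variance to
partition. One subject has rate 0 (burden identically zero), mirroring the
non-engrafting IDH-mutant case. The 21-metabolite panel carries a signed
signature — NAA, NAAG, Glu, GABA down; choline compounds, Ins, Gly, Lac,
Gln up — with a relative effect of 0.6 at full burden, and the
contralateral burden lags 21 days at 0.4 attenuation (invasion).
Measurement noise is **additive in concentration units** (sd 0.2 mM-like),
and CRLB values are drawn as the relative uncertainty (noise over value):
this is how spectral-fitting uncertainty actually behaves — low
concentration metabolites quantify worse — and it is what gives the CRLB
filter real work without corrupting the tCr denominator, which is a sum of
two well-quantified metabolites.

**Voxel grids** (`simulate_mvs()`): a 5×5 grid mixes normal and tumor
endmember profiles with a Gaussian weight decaying from the tumor center;
tumor-specific lipids are injected with high missingness so the
"< 50% missing" metabolite-selection rule is exercised. The 16-metabolite
patient panel overlaps the mouse panel in 13 metabolites by construction;
the data-driven exclusion rules can trim a couple more depending on the
draw.

**Coupled counts** (`simulate_coupled_counts()`): negative-binomial counts
(dispersion 0.1) for 300 genes per species plus 20 ambiguous decoys, with
library sizes of 20–60 million reads. Five genes per species track the
standardized latent score with a log2 effect of 1.5; all genes carry
per-subject batch offsets (sd 0.5). The species read balance drifts with
burden — human weight from 0.05 to 1 (roughly half the reads at full
burden, matching a ~50% end-stage tumor/host cell ratio), mouse weight
falling 20% for infiltrative tumors — and designated *compact* subjects
lose ~96% of their mouse reads at full burden, which is what pushes a
sample or two under the million-mouse-read rule downstream. This drift is
a genuine confound, faithfully reproduced: every mouse gene's log-CPM
falls somewhat as tumor content rises, which is precisely why the
planted-gene recovery tests matter.

Not emulated: spectral-domain MRS signals (profiles are generated directly
in concentration space), read-level sequences or classification errors
(species labels are exact), gene–gene correlation beyond the planted
factor and batch structure, and any treatment effect. Passing tests
therefore demonstrate that the machinery recovers truth under this noise
model — not that any particular biological conclusion transfers to real
data.

## Pipelines, determinism, problem sizes

The three drivers (`run_trajectory_analysis()`,
`run_integration_analysis()`, `run_mouse_brain_analysis()`) chain the
stages above with per-stage logging of counts in and out, write every
artifact with a manifest (content hashes and the config hash) when an
output directory is given, and derive every stochastic stage's seed from
one master seed, so a rerun is bit-identical. The integration driver drops
metabolites with ≥ 50% missing entries after CRLB filtering before
imputation: a column that is mostly censored carries no usable signal, and
this mirrors the reduced metabolite panel that enters the coinertia step.

Test and acceptance problem sizes are chosen to exercise every rule at
desk scale: 210 longitudinal observations, 25-voxel grids, 620-gene count
matrices, 50 bootstrap resamples, 999 permutations for reported p-values
and 199 inside the 500-replicate calibration loops. The permutation
minimum attainable p is therefore 0.001 (reported) and the calibration
check asserts the empirical type-I error lies within the binomial 95%
confidence band of α = 0.05.

## Known limitations

- STATIS is implemented in its variable-space form only (tables sharing
  columns); dual STATIS and distance-based variants are out of scope.
- The sparse alternation inherits the local-optimum behavior of all
  soft-thresholding schemes; bootstrap consolidation mitigates, not
  removes, it.
- Imputation assumes a low-rank-plus-noise structure and a fixed `ncomp`;
  cross-validated rank selection is deliberately not included.
- The hypergeometric test treats genes as exchangeable; co-expressed genes
  violate independence, so enrichment p-values on correlated clusters are
  optimistic — the Bonferroni control is partial protection, not a cure.
- Real-data headline values (an RV of 0.73, a cross-species loading
  correlation of 0.68) depend on raw patient/PDOX data that is not
  publicly available; the package's claims are the synthetic-truth
  recovery properties its tests and acceptance script actually compute.
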